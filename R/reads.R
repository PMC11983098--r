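#' @importFrom data.table fread fwrite data.table
NULL

new_read_set <- function(sample_id, target, spikein, dropped = 0L) {
  cols <- c("chrom", "five_prime", "strand")
  stopifnot(all(cols %in% names(target)), all(cols %in% names(spikein)))
  structure(list(sample_id = sample_id,
                 target = target[cols], spikein = spikein[cols],
                 total_target = nrow(target),
                 total_spikein = nrow(spikein),
                 dropped = dropped),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat("ReadSet", x$sample_id, ":", x$total_target, "target reads,",
      x$total_spikein, "spike-in reads",
      if (x$dropped > 0) paste0("(", x$dropped, " dropped)") else "", "\n")
  invisible(x)
}

#' Load stranded single-end reads
#'
#' Reads BED6/tagAlign (plain or gzip) or BAM, reduces each record to its
#' 5' position (`start` on the plus strand, `end - 1` on the minus strand),
#' and partitions reads into target and spike-in species by chromosome-name
#' prefix. Reads on chromosomes absent from the annotation are dropped and
#' counted.
#'
#' @param path BED6/tagAlign file (optionally gzipped) or a BAM file
#'   (requires Rsamtools; only primary, mapped alignments at or above
#'   `min_mapq` are used).
#' @param annotation `GenomeAnnotation` giving known chromosomes.
#' @param sample_id identifier stored in the returned set.
#' @param min_mapq BAM-only MAPQ filter; default 0 (off).
#' @return A `ReadSet` with `target`/`spikein` read tables (`chrom`,
#'   `five_prime`, `strand`), totals and a dropped-read count.
#' @export
load_reads <- function(path, annotation, sample_id = basename(path),
                       min_mapq = 0) {
  if (!file.exists(path)) stop("read file not found: ", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    df <- read_bam_5prime(path, min_mapq)
  } else {
    bed <- tryCatch(
      if (file.size(path) == 0) {
        data.frame()
      } else if (grepl("\\.gz$", path)) {
        utils::read.table(gzfile(path), header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
      } else {
        fread(path, header = FALSE, sep = "\t", data.table = FALSE)
      },
      error = function(e) {
        if (grepl("no lines available", conditionMessage(e)))
          return(data.frame())
        stop("failed to parse ", path, ": ", conditionMessage(e))
      })
    if (nrow(bed) == 0) {
      warning("empty read file: ", path)
      df <- data.frame(chrom = character(), five_prime = numeric(),
                       strand = character())
    } else {
      if (ncol(bed) < 6)
        stop("expected >= 6 BED columns in ", path, ", got ", ncol(bed))
      bad <- which(!bed[[6]] %in% c("+", "-") |
                     is.na(bed[[2]]) | is.na(bed[[3]]) | bed[[3]] <= bed[[2]])
      if (length(bad))
        stop("unparsable BED record(s) at line(s) ",
             paste(head(bad, 10), collapse = ", "), " in ", path)
      df <- data.frame(
        chrom = as.character(bed[[1]]),
        five_prime = ifelse(bed[[6]] == "+", bed[[2]], bed[[3]] - 1),
        strand = bed[[6]], stringsAsFactors = FALSE)
    }
  }
  known <- df$chrom %in% annotation$chroms$name
  dropped <- sum(!known)
  if (dropped > 0)
    warning(dropped, " read(s) on unknown chromosomes dropped")
  df <- df[known, , drop = FALSE]
  sp <- annotation$chroms$species[match(df$chrom, annotation$chroms$name)]
  new_read_set(sample_id,
               df[sp == "target", , drop = FALSE],
               df[sp == "spikein", , drop = FALSE],
               dropped = dropped)
}

read_bam_5prime <- function(path, min_mapq) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM input requires the Rsamtools package")
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flag,
                               what = c("rname", "pos", "strand", "qwidth",
                                        "mapq"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- is.na(b$mapq) | b$mapq >= min_mapq
  # BAM pos is 1-based leftmost; convert to the 0-based 5' end
  start0 <- b$pos[keep] - 1
  end0 <- start0 + b$qwidth[keep]
  strand <- as.character(b$strand[keep])
  data.frame(chrom = as.character(b$rname[keep]),
             five_prime = ifelse(strand == "+", start0, end0 - 1),
             strand = strand, stringsAsFactors = FALSE)
}

#' Write a ReadSet as BED6
#'
#' Records are written with a fixed nominal read length so that the 5' end
#' round-trips exactly through [load_reads].
#'
#' @param reads `ReadSet`.
#' @param path output path (`.gz` for gzip).
#' @param read_length nominal read length in bp.
#' @export
write_reads_bed <- function(reads, path, read_length = 50) {
  df <- rbind(reads$target, reads$spikein)
  start <- ifelse(df$strand == "+", df$five_prime,
                  pmax(df$five_prime - (read_length - 1), 0))
  end <- ifelse(df$strand == "+", df$five_prime + read_length,
                df$five_prime + 1)
  out <- data.table(chrom = df$chrom, start = start, end = end,
                    name = sprintf("r%d", seq_len(nrow(df))),
                    score = 0L, strand = df$strand)
  fwrite(out, path, sep = "\t", col.names = FALSE, compress = "auto")
  invisible(path)
}

read_table_of <- function(reads, use = c("target", "spikein")) {
  use <- match.arg(use)
  reads[[use]]
}

#' Shifted fragment midpoints of a read set
#'
#' The inferred fragment midpoint of a read is its 5' position shifted by
#' `shift` bp in the 3' direction: `five_prime + shift` on the plus strand,
#' `five_prime - shift` on the minus strand. With `shift` set to half the
#' fragment length, plus- and minus-strand reads of one fragment land on
#' (nearly) the same position.
#'
#' @param reads `ReadSet`.
#' @param shift shift in bp (default 150).
#' @param use which species partition to use.
#' @return data.frame `chrom`, `midpoint`.
#' @export
shifted_midpoints <- function(reads, shift = 150,
                              use = c("target", "spikein")) {
  df <- read_table_of(reads, use)
  data.frame(chrom = df$chrom,
             midpoint = ifelse(df$strand == "+",
                               df$five_prime + shift,
                               df$five_prime - shift),
             stringsAsFactors = FALSE)
}

#' Shift-and-extend coverage track
#'
#' Shifts plus- and minus-strand reads towards each other by `shift` bp and
#' extends each read to an `extend`-bp interval, producing per-base coverage.
#' By default the extension is centered on the shifted position
#' (fragment-midpoint smoothing), so the two reads of one ~`2*shift` bp
#' fragment produce identical intervals: a read with shifted midpoint `p`
#' covers `[p - floor(extend/2), p + ceil(extend/2))`. Set
#' `extend_from = "shifted5p"` for the alternative reading (extension
#' downstream of the shifted 5' end).
#'
#' @param reads `ReadSet`.
#' @param shift shift in bp (default 150).
#' @param extend extension in bp (default 40).
#' @param use species partition to cover.
#' @param annotation `GenomeAnnotation` providing chromosome lengths.
#' @param extend_from `"midpoint"` (centered, default) or `"shifted5p"`.
#' @return A `CoverageTrack`: list of per-chromosome numeric vectors plus
#'   bookkeeping (`shift`, `extend`, `n_reads_used`, `n_dropped`,
#'   `clipped_bases`). Total coverage mass equals
#'   `n_reads_used * extend - clipped_bases`.
#' @export
shift_extend_coverage <- function(reads, shift = 150, extend = 40,
                                  use = c("target", "spikein"),
                                  annotation,
                                  extend_from = c("midpoint", "shifted5p")) {
  stopifnot(shift >= 0, extend > 0)
  use <- match.arg(use)
  extend_from <- match.arg(extend_from)
  df <- read_table_of(reads, use)
  p <- ifelse(df$strand == "+", df$five_prime + shift, df$five_prime - shift)
  if (extend_from == "midpoint") {
    s <- p - floor(extend / 2)
  } else {
    s <- ifelse(df$strand == "+", p, p - (extend - 1))
  }
  e <- s + extend

  species <- annotation$chroms$species
  chroms <- annotation$chroms$name[species == ifelse(use == "target",
                                                     "target", "spikein")]
  lens <- annotation$chroms$length[match(chroms, annotation$chroms$name)]
  cov <- setNames(vector("list", length(chroms)), chroms)
  used <- 0L; dropped <- 0L; clipped <- 0
  for (k in seq_along(chroms)) {
    L <- lens[k]
    i <- which(df$chrom == chroms[k])
    si <- pmax(s[i], 0); ei <- pmin(e[i], L)
    on <- ei > si
    dropped <- dropped + sum(!on)
    si <- si[on]; ei <- ei[on]
    used <- used + length(si)
    clipped <- clipped + sum((extend - (ei - si)))
    # difference-array accumulation: +1 at start, -1 at end, then cumsum
    d <- numeric(L + 1)
    if (length(si)) {
      ts <- tabulate(si + 1, nbins = L + 1)
      te <- tabulate(ei + 1, nbins = L + 1)
      d <- ts - te
    }
    cov[[k]] <- cumsum(d)[seq_len(L)]
  }
  structure(list(coverage = cov, shift = shift, extend = extend,
                 n_reads_used = used, n_dropped = dropped,
                 clipped_bases = clipped, extend_from = extend_from),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", length(x$coverage), "chromosome(s), shift =",
      x$shift, "extend =", x$extend, ";", x$n_reads_used, "reads used\n")
  invisible(x)
}

#' Total coverage mass of a track
#' @param track `CoverageTrack`.
#' @return sum of per-base coverage over all chromosomes.
#' @export
coverage_mass <- function(track) sum(vapply(track$coverage, sum, numeric(1)))

#' Count signal in a genomic window
#'
#' Two quantification modes for an interval `[start, end)`:
#' `midpoint_count` (default) counts reads whose shifted fragment midpoint
#' falls in the window — the reading of "total number of reads in a region"
#' used for promoter quantification; `coverage_mass` sums per-base
#' shift-extend coverage — used for profiles and heat maps.
#'
#' @param x a `CoverageTrack` (coverage_mass only) or a `ReadSet`.
#' @param chrom,start,end the window (0-based half-open).
#' @param mode `"midpoint_count"` or `"coverage_mass"`.
#' @param shift shift used to compute midpoints when `x` is a `ReadSet`.
#' @param extend extension used when computing coverage from a `ReadSet`.
#' @param annotation required when computing coverage from a `ReadSet`.
#' @param use species partition when `x` is a `ReadSet`.
#' @return non-negative number (0 for an empty window).
#' @export
window_count <- function(x, chrom, start, end,
                         mode = c("midpoint_count", "coverage_mass"),
                         shift = 150, extend = 40, annotation = NULL,
                         use = "target") {
  mode <- match.arg(mode)
  if (end <= start) return(0)
  if (inherits(x, "CoverageTrack")) {
    if (mode != "coverage_mass")
      stop("midpoint_count requires a ReadSet, not a CoverageTrack")
    v <- x$coverage[[chrom]]
    if (is.null(v)) stop("chromosome not in track: ", chrom)
    s <- max(start, 0); e <- min(end, length(v))
    if (e <= s) return(0)
    return(sum(v[(s + 1):e]))
  }
  stopifnot(inherits(x, "ReadSet"))
  if (mode == "midpoint_count") {
    mp <- shifted_midpoints(x, shift, use)
    return(sum(mp$chrom == chrom & mp$midpoint >= start & mp$midpoint < end))
  }
  track <- shift_extend_coverage(x, shift, extend, use, annotation)
  window_count(track, chrom, start, end, "coverage_mass")
}

# Vectorized per-window midpoint counts for one sample: windows is a
# data.frame(chrom, start, end). Uses per-chromosome sorted midpoints and
# binary search.
count_midpoints_in_windows <- function(reads, windows, shift = 150,
                                       use = "target") {
  mp <- shifted_midpoints(reads, shift, use)
  out <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    m <- sort(mp$midpoint[mp$chrom == ch])
    i <- which(windows$chrom == ch)
    if (!length(m)) { out[i] <- 0; next }
    out[i] <- findInterval(windows$end[i] - 0.5, m) -
      findInterval(windows$start[i] - 0.5, m)
  }
  out
}

# Vectorized per-window coverage mass via per-chromosome cumulative sums.
sum_coverage_in_windows <- function(track, windows) {
  out <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    v <- track$coverage[[ch]]
    if (is.null(v)) stop("chromosome not in track: ", ch)
    cs <- c(0, cumsum(v))
    i <- which(windows$chrom == ch)
    s <- pmax(windows$start[i], 0)
    e <- pmin(windows$end[i], length(v))
    e <- pmax(e, s)
    out[i] <- cs[e + 1] - cs[s + 1]
  }
  out
}

#' Export a coverage track as bedGraph
#'
#' Runs of equal coverage are merged; zero-coverage runs are omitted.
#'
#' @param track `CoverageTrack`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  pieces <- lapply(names(track$coverage), function(ch) {
    v <- track$coverage[[ch]]
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.table(chrom = ch, start = s[keep], end = e[keep],
               value = r$values[keep])
  })
  out <- data.table::rbindlist(pieces)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
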