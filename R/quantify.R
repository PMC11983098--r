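#' Window specification for quantification
#'
#' The four quantification geometries: a fixed-width promoter window
#' upstream of the TSS, a fixed-width window centered on the +1-nucleosome
#' dyad, the full gene body (TSS to TTS), or caller-supplied custom windows.
#'
#' @param kind one of `"promoter_upstream"`, `"plus1_centered"`,
#'   `"gene_body"`, `"custom"`.
#' @param width window width in bp; ignored for `gene_body` and `custom`.
#' @param windows for `kind = "custom"`, a data.frame with `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open).
#' @return A `WindowSpec` object.
#' @export
window_spec <- function(kind = c("promoter_upstream", "plus1_centered",
                                 "gene_body", "custom"),
                        width = NULL, windows = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("promoter_upstream", "plus1_centered")) {
    if (is.null(width))
      width <- if (kind == "promoter_upstream") 400 else 75
    stopifnot(width > 0)
  }
  if (kind == "custom" && is.null(windows))
    stop("custom window spec requires a windows table")
  structure(list(kind = kind, width = width, windows = windows),
            class = "WindowSpec")
}

resolve_windows <- function(spec, annotation) {
  g <- annotation$genes
  switch(spec$kind,
         promoter_upstream = promoter_windows(g, spec$width, annotation),
         plus1_centered = plus1_windows(g, spec$width, annotation),
         gene_body = gene_body_windows(g, annotation),
         custom = {
           w <- spec$windows
           need <- c("gene_id", "chrom", "start", "end")
           stopifnot(all(need %in% names(w)))
           if (is.null(w$clipped)) w$clipped <- FALSE
           w
         })
}

#' Spike-in scaling factor
#'
#' Scaling factor putting `sample` on the spike-in scale of `reference`:
#' because a fixed proportion of foreign chromatin is added to every sample
#' before immunoprecipitation, the spike-in read count tracks technical
#' depth, and dividing by it exposes genuine global shifts in target signal.
#'
#' @param sample,reference `ReadSet`s with spike-in reads.
#' @return `reference$total_spikein / sample$total_spikein`.
#' @export
spikein_factor <- function(sample, reference) {
  if (sample$total_spikein <= 0 || reference$total_spikein <= 0)
    stop("zero spike-in reads in ",
         if (sample$total_spikein <= 0) sample$sample_id
         else reference$sample_id,
         "; fall back to library-size normalization (norm = \"library\")")
  reference$total_spikein / sample$total_spikein
}

#' Library-size scaling factor (per-million target reads)
#'
#' @param sample `ReadSet`.
#' @return `1e6 / total_target`.
#' @export
library_factor <- function(sample) {
  if (sample$total_target <= 0) stop("no target reads in ", sample$sample_id)
  1e6 / sample$total_target
}

#' Quantify normalized per-gene window signals across samples
#'
#' For each gene and sample the raw count is [window_count] over the window
#' defined by `spec` (shifted-midpoint counts by default, coverage mass
#' optionally). Raw counts are scaled by the chosen normalization factor
#' (spike-in relative to the first sample, per-million library size, or
#' none), then optionally divided by a mock-IP sample's scaled counts with a
#' pseudocount: `signal = (scaled + pc) / (mock_scaled + pc)`. The full
#' normalization provenance is stored with the table.
#'
#' @param samples named list of `ReadSet`s (names become column names; if
#'   unnamed, `sample_id`s are used).
#' @param annotation `GenomeAnnotation`.
#' @param spec `WindowSpec`.
#' @param shift,extend shift/extend parameters (defaults 150/40).
#' @param mode `"midpoint_count"` (default) or `"coverage_mass"`.
#' @param norm `"spikein"`, `"library"` or `"none"`.
#' @param mock optional sample id used as mock-IP denominator.
#' @param pseudocount pseudocount added to both numerator and denominator of
#'   the mock ratio (default 1).
#' @return A `SignalTable`: genes x samples matrix with attributes
#'   `window_spec`, `normalization` (factors, mock id, pseudocount, mode)
#'   and `clipped` (per-gene flag).
#' @export
quantify_samples <- function(samples, annotation, spec,
                             shift = 150, extend = 40,
                             mode = c("midpoint_count", "coverage_mass"),
                             norm = c("spikein", "library", "none"),
                             mock = NULL, pseudocount = 1) {
  mode <- match.arg(mode)
  norm <- match.arg(norm)
  stopifnot(inherits(spec, "WindowSpec"))
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- vapply(samples, function(s) s$sample_id, character(1))
  if (!is.null(mock) && !mock %in% names(samples))
    stop("unknown mock sample id: ", mock)

  windows <- resolve_windows(spec, annotation)
  raw <- vapply(samples, function(s) {
    if (mode == "midpoint_count") {
      count_midpoints_in_windows(s, windows, shift)
    } else {
      track <- shift_extend_coverage(s, shift, extend, "target", annotation)
      sum_coverage_in_windows(track, windows)
    }
  }, numeric(nrow(windows)))
  raw <- matrix(raw, nrow = nrow(windows),
                dimnames = list(windows$gene_id, names(samples)))

  factors <- switch(norm,
    spikein = vapply(samples, spikein_factor, numeric(1),
                     reference = samples[[1]]),
    library = vapply(samples, library_factor, numeric(1)),
    none = setNames(rep(1, length(samples)), names(samples)))
  scaled <- sweep(raw, 2, factors, `*`)

  if (!is.null(mock)) {
    if (pseudocount <= 0) stop("pseudocount must be > 0 when using a mock IP")
    signal <- (scaled + pseudocount) / (scaled[, mock] + pseudocount)
  } else {
    signal <- scaled
  }

  structure(signal,
            window_spec = spec,
            normalization = list(norm = norm, factors = factors,
                                 mock_sample_id = mock,
                                 pseudocount = pseudocount,
                                 mode = mode, shift = shift,
                                 extend = extend),
            clipped = setNames(windows$clipped, windows$gene_id),
            class = c("SignalTable", "matrix", "array"))
}

#' @export
print.SignalTable <- function(x, ...) {
  nz <- attr(x, "normalization")
  cat("SignalTable:", nrow(x), "genes x", ncol(x), "samples;",
      attr(x, "window_spec")$kind, "windows;",
      nz$mode, "quantification;", nz$norm, "normalization",
      if (!is.null(nz$mock_sample_id))
        paste0("; mock = ", nz$mock_sample_id) else "", "\n")
  invisible(x)
}

#' Treated/vehicle log2 fold change per gene
#'
#' `log2fc = log2((treated + pc) / (vehicle + pc))` per gene, with a
#' strictly positive pseudocount so no gene ever yields NaN or +/-Inf.
#'
#' @param table `SignalTable`.
#' @param treated,vehicle sample (column) ids.
#' @param pseudocount strictly positive pseudocount (default 1; use a small
#'   value such as 1e-9 when signals are mock ratios near 1).
#' @param contrast_id label for the pair (default "treated/vehicle").
#' @param track which IP the contrast describes
#'   (`"H3K9ac"`, `"Rpb1"`, `"H3"`, `"TF"`, `"other"`).
#' @return A `ContrastResult`: data.frame `gene_id`, `log2fc`,
#'   `treated_signal`, `vehicle_signal` with attributes `contrast_id`,
#'   `track`, `pseudocount`.
#' @export
contrast <- function(table, treated, vehicle, pseudocount = 1,
                     contrast_id = paste0(treated, "/", vehicle),
                     track = c("other", "H3K9ac", "Rpb1", "H3", "TF")) {
  track <- match.arg(track)
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be a positive number")
  for (s in c(treated, vehicle))
    if (!s %in% colnames(table)) stop("sample not in table: ", s)
  t <- table[, treated]
  v <- table[, vehicle]
  res <- data.frame(gene_id = rownames(table),
                    log2fc = log2((t + pseudocount) / (v + pseudocount)),
                    treated_signal = unname(t),
                    vehicle_signal = unname(v),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, contrast_id = contrast_id, track = track,
            pseudocount = pseudocount,
            class = c("ContrastResult", "data.frame"))
}

#' Serialize a SignalTable or ContrastResult to TSV
#'
#' Normalization provenance is written as leading comment lines starting
#' with `#`.
#'
#' @param x `SignalTable` or `ContrastResult`.
#' @param path output path.
#' @export
write_signal_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "SignalTable")) {
    nz <- attr(x, "normalization")
    ws <- attr(x, "window_spec")
    writeLines(c(
      paste0("# window_kind=", ws$kind,
             if (!is.null(ws$width)) paste0(" width=", ws$width) else ""),
      paste0("# mode=", nz$mode, " shift=", nz$shift, " extend=", nz$extend),
      paste0("# norm=", nz$norm,
             " mock=", if (is.null(nz$mock_sample_id)) "none"
                       else nz$mock_sample_id,
             " pseudocount=", nz$pseudocount),
      paste0("# factors=", paste(names(nz$factors),
                                 signif(nz$factors, 10),
                                 sep = ":", collapse = ","))),
      con)
    df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x)),
                     check.names = FALSE)
  } else if (inherits(x, "ContrastResult")) {
    writeLines(c(
      paste0("# contrast=", attr(x, "contrast_id"),
             " track=", attr(x, "track"),
             " pseudocount=", attr(x, "pseudocount"))), con)
    df <- as.data.frame(x)
  } else stop("unsupported object")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
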