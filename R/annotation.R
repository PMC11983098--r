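#' @importFrom utils read.delim write.table head
#' @importFrom stats setNames
NULL

GENE_GROUPS <- c("RP", "RiBi", "GR", "other")

#' Load and validate a genome annotation
#'
#' Reads a gene table and a chromosome table and returns a validated
#' annotation object. All coordinates are 0-based, half-open throughout the
#' package; input files are expected in the same dialect. Chromosomes whose
#' name starts with `spikein_prefix` are classified as spike-in species;
#' genes are only permitted on target chromosomes.
#'
#' @param gene_table_path TSV with header columns `gene_id`, `chrom`,
#'   `strand`, `tss`, `tts`, `plus1_dyad`, `group`. `tss`/`tts` are 0-based
#'   positions of the transcription start/termination sites; for minus-strand
#'   genes `tss > tts`. `plus1_dyad` is the 0-based +1-nucleosome dyad
#'   position. `group` is one of RP, RiBi, GR, other.
#' @param chrom_table_path TSV with header columns `name`, `length`.
#' @param spikein_prefix chromosome-name prefix marking spike-in species.
#' @return A `GenomeAnnotation`: list with `chroms` (data.frame name, length,
#'   species) and `genes` (data.frame of validated gene records).
#' @export
load_annotation <- function(gene_table_path, chrom_table_path,
                            spikein_prefix = "spike_") {
  if (!file.exists(gene_table_path))
    stop("gene table not found: ", gene_table_path)
  if (!file.exists(chrom_table_path))
    stop("chromosome table not found: ", chrom_table_path)
  genes <- read.delim(gene_table_path, stringsAsFactors = FALSE)
  chroms <- read.delim(chrom_table_path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tts", "plus1_dyad", "group")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene table is missing required column(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(c("name", "length"), names(chroms))
  if (length(miss))
    stop("chromosome table is missing required column(s): ",
         paste(miss, collapse = ", "))
  genome_annotation(genes[need], chroms[c("name", "length")], spikein_prefix)
}

#' Construct a validated annotation from in-memory tables
#'
#' @param genes data.frame of gene records (see [load_annotation]).
#' @param chroms data.frame with `name` and `length` columns.
#' @param spikein_prefix chromosome-name prefix marking spike-in species.
#' @return A `GenomeAnnotation` object.
#' @export
genome_annotation <- function(genes, chroms, spikein_prefix = "spike_") {
  chroms$length <- as.numeric(chroms$length)
  if (anyDuplicated(chroms$name))
    stop("duplicated chromosome names: ",
         paste(unique(chroms$name[duplicated(chroms$name)]), collapse = ", "))
  if (any(chroms$length <= 0))
    stop("chromosome lengths must be positive")
  chroms$species <- ifelse(startsWith(chroms$name, spikein_prefix),
                           "spikein", "target")

  genes$tss <- as.numeric(genes$tss)
  genes$tts <- as.numeric(genes$tts)
  genes$plus1_dyad <- as.numeric(genes$plus1_dyad)
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop("gene table validation failed (", what, ") at row(s) ",
           paste(head(idx, 10), collapse = ", "),
           if (length(idx) > 10) " ..." else "",
           "; gene_id(s): ",
           paste(head(genes$gene_id[idx], 10), collapse = ", "))
  }
  bad(duplicated(genes$gene_id), "duplicated gene_id")
  bad(!genes$strand %in% c("+", "-"), "strand must be + or -")
  bad(!genes$group %in% GENE_GROUPS,
      paste0("group must be one of ", paste(GENE_GROUPS, collapse = "/")))
  bad(!genes$chrom %in% chroms$name, "unknown chromosome")
  sp <- chroms$species[match(genes$chrom, chroms$name)]
  bad(sp == "spikein", "gene on spike-in chromosome")
  bad(genes$strand == "+" & genes$tss >= genes$tts, "strand + requires tss < tts")
  bad(genes$strand == "-" & genes$tss <= genes$tts, "strand - requires tss > tts")
  lo <- pmin(genes$tss, genes$tts)
  hi <- pmax(genes$tss, genes$tts)
  len <- chroms$length[match(genes$chrom, chroms$name)]
  bad(lo < 0 | hi >= len, "gene coordinates beyond chromosome bounds")
  bad(genes$plus1_dyad < lo - 500 | genes$plus1_dyad > hi + 500,
      "plus1_dyad further than 500 bp from the transcribed region")

  structure(list(chroms = chroms, genes = genes,
                 spikein_prefix = spikein_prefix),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", nrow(x$genes), "genes on",
      sum(x$chroms$species == "target"), "target chromosome(s);",
      sum(x$chroms$species == "spikein"), "spike-in chromosome(s)\n")
  tab <- table(factor(x$genes$group, levels = GENE_GROUPS))
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

chrom_length <- function(annotation, chrom) {
  i <- match(chrom, annotation$chroms$name)
  if (anyNA(i)) stop("unknown chromosome: ",
                     paste(chrom[is.na(i)], collapse = ", "))
  annotation$chroms$length[i]
}

clip_windows <- function(start, end, len) {
  cs <- pmax(start, 0)
  ce <- pmin(end, len)
  if (any(ce <= cs))
    stop("window entirely off-chromosome for ", sum(ce <= cs), " gene(s)")
  data.frame(start = cs, end = ce, clipped = cs != start | ce != end)
}

#' Promoter windows upstream of the TSS
#'
#' For a plus-strand gene the window is `[tss - width, tss)`; for a
#' minus-strand gene `[tss + 1, tss + 1 + width)` on the reference axis, so
#' the TSS base itself is excluded from "upstream" on both strands. Windows
#' are clipped to chromosome bounds and flagged when clipped.
#'
#' @param genes data.frame with `chrom`, `strand`, `tss` (a `GenomeAnnotation`
#'   gene table or subset of it).
#' @param width window width in bp (default 400, the promoter definition used
#'   for read-count quantification and motif scanning).
#' @param annotation `GenomeAnnotation` providing chromosome bounds.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `clipped`.
#' @export
promoter_windows <- function(genes, width = 400, annotation) {
  stopifnot(width > 0)
  start <- ifelse(genes$strand == "+", genes$tss - width, genes$tss + 1)
  w <- clip_windows(start, start + width, chrom_length(annotation, genes$chrom))
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom, w,
             stringsAsFactors = FALSE)
}

#' Windows centered on the +1-nucleosome dyad
#'
#' The window is `[dyad - floor(width/2), dyad - floor(width/2) + width)`,
#' strand-independent on the reference axis; for even widths the extra base
#' falls 3' of the dyad on the reference axis. Orientation (5'->3' of the
#' gene) is applied only when building metagene profiles, never here.
#'
#' @inheritParams promoter_windows
#' @param width window width in bp (default 75, the +1-nucleosome
#'   quantification window).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `clipped`.
#' @export
plus1_windows <- function(genes, width = 75, annotation) {
  stopifnot(width > 0)
  start <- genes$plus1_dyad - floor(width / 2)
  w <- clip_windows(start, start + width, chrom_length(annotation, genes$chrom))
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom, w,
             stringsAsFactors = FALSE)
}

#' Gene-body windows (TSS to TTS)
#'
#' @inheritParams promoter_windows
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `clipped`.
#' @export
gene_body_windows <- function(genes, annotation) {
  start <- pmin(genes$tss, genes$tts)
  end <- pmax(genes$tss, genes$tts) + 1
  w <- clip_windows(start, end, chrom_length(annotation, genes$chrom))
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom, w,
             stringsAsFactors = FALSE)
}

#' Export windows as BED6
#'
#' @param windows data.frame from [promoter_windows] and friends, plus a
#'   `strand` column if available (taken from `genes` otherwise "."); scores
#'   are written as 0.
#' @param path output file.
#' @param strand optional per-window strand vector.
#' @export
write_windows_bed <- function(windows, path, strand = NULL) {
  if (is.null(strand)) strand <- rep(".", nrow(windows))
  bed <- data.frame(windows$chrom, windows$start, windows$end,
                    windows$gene_id, 0L, strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write annotation tables to disk
#'
#' Inverse of [load_annotation]: writes the gene and chromosome tables in the
#' package's TSV dialect (0-based coordinates).
#'
#' @param annotation `GenomeAnnotation`.
#' @param gene_table_path,chrom_table_path output paths.
#' @export
write_annotation <- function(annotation, gene_table_path, chrom_table_path) {
  g <- annotation$genes
  g$tss <- format(g$tss, scientific = FALSE, trim = TRUE)
  g$tts <- format(g$tts, scientific = FALSE, trim = TRUE)
  g$plus1_dyad <- format(g$plus1_dyad, scientific = FALSE, trim = TRUE)
  write.table(g, gene_table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ch <- annotation$chroms[c("name", "length")]
  ch$length <- format(ch$length, scientific = FALSE, trim = TRUE)
  write.table(ch, chrom_table_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(annotation)
}
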