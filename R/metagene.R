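# Extract per-gene coverage around an anchor, oriented 5'->3' of the gene.
# Returns a genes x (2*flank) matrix plus the excluded (clipped) gene ids.
extract_anchored <- function(track, annotation, anchor, flank) {
  g <- annotation$genes
  pos <- switch(anchor, plus1_dyad = g$plus1_dyad, tss = g$tss,
                stop("anchor must be plus1_dyad or tss"))
  start <- pos - flank
  end <- pos + flank
  len <- chrom_length(annotation, g$chrom)
  ok <- start >= 0 & end <= len
  mat <- matrix(NA_real_, nrow = sum(ok), ncol = 2 * flank,
                dimnames = list(g$gene_id[ok], NULL))
  gi <- which(ok)
  for (k in seq_along(gi)) {
    i <- gi[k]
    v <- track$coverage[[g$chrom[i]]]
    if (is.null(v)) stop("chromosome not in track: ", g$chrom[i])
    w <- v[(start[i] + 1):end[i]]
    if (g$strand[i] == "-") w <- rev(w)
    mat[k, ] <- w
  }
  list(mat = mat, excluded = g$gene_id[!ok])
}

#' Anchor-centered average (metagene) profile per gene group
#'
#' Extracts shift-extend coverage over `[anchor - flank, anchor + flank)`
#' for every gene, reverses minus-strand genes so positions run 5'->3' of
#' the gene, excludes genes whose window leaves the chromosome, and
#' averages per position within each gene group.
#'
#' @param track `CoverageTrack`.
#' @param annotation `GenomeAnnotation`.
#' @param anchor `"plus1_dyad"` (default) or `"tss"`.
#' @param flank half-window in bp (default 800, i.e. the -800..+800 span).
#' @param groups optional named vector gene_id -> group; defaults to the
#'   annotation's group labels. Use a single constant label to average over
#'   all genes.
#' @return A `MetageneProfile`: list with `positions` (-flank..flank-1),
#'   `mean` (positions x groups matrix), `n_genes` per group, `anchor`,
#'   `excluded` gene ids.
#' @export
metagene_profile <- function(track, annotation,
                             anchor = c("plus1_dyad", "tss"),
                             flank = 800, groups = NULL) {
  anchor <- match.arg(anchor)
  stopifnot(flank > 0)
  ex <- extract_anchored(track, annotation, anchor, flank)
  if (is.null(groups))
    groups <- setNames(annotation$genes$group, annotation$genes$gene_id)
  gl <- groups[rownames(ex$mat)]
  lv <- unique(gl[!is.na(gl)])
  means <- sapply(lv, function(g) {
    rows <- which(gl == g)
    colMeans(ex$mat[rows, , drop = FALSE])
  })
  n_genes <- vapply(lv, function(g) sum(gl == g, na.rm = TRUE), integer(1))
  empty <- setdiff(unique(groups), lv)
  if (length(empty))
    warning("group(s) empty after exclusions, omitted: ",
            paste(empty, collapse = ", "))
  structure(list(positions = seq(-flank, flank - 1),
                 mean = matrix(means, ncol = length(lv),
                               dimnames = list(NULL, lv)),
                 n_genes = n_genes, anchor = anchor, flank = flank,
                 excluded = ex$excluded),
            class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat("MetageneProfile anchored on", x$anchor, ": positions",
      min(x$positions), "..", max(x$positions), ";",
      paste(colnames(x$mean), x$n_genes, sep = "=", collapse = " "),
      "genes\n")
  invisible(x)
}

#' Fold-change-sorted heat-map matrix around an anchor
#'
#' Rows are genes sorted by ascending log2 fold change of `sort_by` (ties
#' broken by gene_id, stable); columns are `bin`-averaged coverage over
#' `[anchor - flank, anchor + flank)`, oriented 5'->3' of each gene. Genes
#' absent from `sort_by`, or with clipped windows, are excluded and
#' counted.
#'
#' @inheritParams metagene_profile
#' @param sort_by `ContrastResult` supplying the per-gene sort key.
#' @param bin bin width in bp; must divide `2 * flank` (default 1).
#' @return A `HeatmapMatrix`: list with `matrix` (sorted genes x bins),
#'   `sort_key` (per-row log2fc), `positions` (bin starts relative to
#'   anchor), `n_excluded`.
#' @export
heatmap_matrix <- function(track, annotation,
                           anchor = c("plus1_dyad", "tss"),
                           flank = 800, sort_by, bin = 1) {
  anchor <- match.arg(anchor)
  stopifnot(flank > 0, bin >= 1)
  if ((2 * flank) %% bin != 0)
    stop("bin must divide 2*flank")
  ex <- extract_anchored(track, annotation, anchor, flank)
  keys <- sort_by$log2fc[match(rownames(ex$mat), sort_by$gene_id)]
  keep <- !is.na(keys)
  n_excluded <- length(ex$excluded) + sum(!keep)
  mat <- ex$mat[keep, , drop = FALSE]
  keys <- keys[keep]
  ord <- order(keys, rownames(mat), method = "radix")
  mat <- mat[ord, , drop = FALSE]
  keys <- keys[ord]
  if (bin > 1) {
    nb <- (2 * flank) / bin
    B <- matrix(0, 2 * flank, nb)
    B[cbind(seq_len(2 * flank), rep(seq_len(nb), each = bin))] <- 1 / bin
    rn <- rownames(mat)
    mat <- mat %*% B
    rownames(mat) <- rn
  }
  structure(list(matrix = mat, sort_key = keys,
                 positions = seq(-flank, flank - 1, by = bin),
                 anchor = anchor, flank = flank, bin = bin,
                 n_excluded = n_excluded),
            class = "HeatmapMatrix")
}

#' @export
print.HeatmapMatrix <- function(x, ...) {
  cat("HeatmapMatrix:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "bins (bin =", x$bin, "bp), sorted by ascending log2fc\n")
  invisible(x)
}

#' Serialize a profile or heat-map matrix to TSV
#'
#' @param x `MetageneProfile` or `HeatmapMatrix`.
#' @param path output path.
#' @export
write_metagene_tsv <- function(x, path) {
  if (inherits(x, "MetageneProfile")) {
    df <- data.frame(position = x$positions, x$mean, check.names = FALSE)
  } else if (inherits(x, "HeatmapMatrix")) {
    df <- data.frame(gene_id = rownames(x$matrix), sort_key = x$sort_key,
                     x$matrix, check.names = FALSE)
  } else stop("unsupported object")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
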