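#' @importFrom stats aov cor.test pnorm fisher.test format.pval
#' @importFrom utils combn
NULL

#' Dual-threshold cut-off for stress-repressed promoters
#'
#' A gene is called stress-repressed when its RNA polymerase II (Rpb1)
#' log2 fold change falls below `rpb1_max_log2fc` AND its H3K9ac log2 fold
#' change falls below `h3k9ac_max_log2fc`. Defaults are the stringent
#' cut-off used for the repressed promoter set: Rpb1 < -1 (2-fold
#' transcriptional downregulation) and H3K9ac < -0.41 (~25% deacetylation).
#'
#' @param rpb1_max_log2fc upper bound on Rpb1 log2fc (default -1).
#' @param h3k9ac_max_log2fc upper bound on H3K9ac log2fc (default -0.41).
#' @param strict use strict `<` (default) rather than `<=`.
#' @return A `StringentCutoff` object.
#' @export
stringent_cutoff <- function(rpb1_max_log2fc = -1,
                             h3k9ac_max_log2fc = -0.41,
                             strict = TRUE) {
  stopifnot(is.finite(rpb1_max_log2fc), is.finite(h3k9ac_max_log2fc))
  structure(list(rpb1_max_log2fc = rpb1_max_log2fc,
                 h3k9ac_max_log2fc = h3k9ac_max_log2fc,
                 strict = strict),
            class = "StringentCutoff")
}

#' Classify stress-repressed genes by dual thresholds
#'
#' Intersects the gene universes of the two contrasts (genes missing from
#' either are excluded and counted), applies the cut-off to both log2 fold
#' changes, and annotates members with functional groups when given.
#'
#' @param rpb1 `ContrastResult` for the Rpb1 (transcription) track.
#' @param h3k9ac `ContrastResult` for the H3K9ac (acetylation) track.
#' @param cutoff `StringentCutoff`.
#' @param groups optional named vector gene_id -> group (RP/RiBi/GR/other)
#'   or a `GenomeAnnotation`.
#' @return A `GeneSetResult`: list with `table` (per-gene log2fcs, pass flag
#'   and failure reason), `members`, `cutoff`, `group_sizes`, `n_excluded`.
#' @export
classify_stringent <- function(rpb1, h3k9ac, cutoff = stringent_cutoff(),
                               groups = NULL) {
  shared <- intersect(rpb1$gene_id, h3k9ac$gene_id)
  if (!length(shared))
    stop("contrasts have disjoint gene universes")
  n_excluded <- length(union(rpb1$gene_id, h3k9ac$gene_id)) - length(shared)
  r <- rpb1$log2fc[match(shared, rpb1$gene_id)]
  a <- h3k9ac$log2fc[match(shared, h3k9ac$gene_id)]
  lt <- if (cutoff$strict) `<` else `<=`
  pass_r <- lt(r, cutoff$rpb1_max_log2fc)
  pass_a <- lt(a, cutoff$h3k9ac_max_log2fc)
  pass <- pass_r & pass_a
  reason <- rep("member", length(shared))
  reason[!pass_r & pass_a] <- "rpb1_above_threshold"
  reason[pass_r & !pass_a] <- "h3k9ac_above_threshold"
  reason[!pass_r & !pass_a] <- "both_above_threshold"
  tab <- data.frame(gene_id = shared, rpb1_log2fc = r, h3k9ac_log2fc = a,
                    member = pass, reason = reason,
                    stringsAsFactors = FALSE)
  if (inherits(groups, "GenomeAnnotation"))
    groups <- setNames(groups$genes$group, groups$genes$gene_id)
  group_sizes <- NULL
  if (!is.null(groups)) {
    tab$group <- unname(groups[tab$gene_id])
    mg <- factor(tab$group[tab$member], levels = GENE_GROUPS)
    group_sizes <- table(mg)
  }
  structure(list(table = tab, members = shared[pass], cutoff = cutoff,
                 group_sizes = group_sizes, n_excluded = n_excluded),
            class = "GeneSetResult")
}

#' @export
print.GeneSetResult <- function(x, ...) {
  cat("GeneSetResult:", length(x$members), "of", nrow(x$table),
      "genes pass (Rpb1 <", x$cutoff$rpb1_max_log2fc,
      "and H3K9ac <", x$cutoff$h3k9ac_max_log2fc, ")\n")
  if (!is.null(x$group_sizes))
    cat("  member groups:",
        paste(names(x$group_sizes), x$group_sizes, sep = "=",
              collapse = " "), "\n")
  invisible(x)
}

#' Write a GeneSetResult to TSV (and optionally member promoters to BED)
#'
#' @param x `GeneSetResult`.
#' @param path TSV output path.
#' @param bed_path optional BED6 of member promoter windows.
#' @param annotation required when `bed_path` is given.
#' @param promoter_width promoter width for the BED export.
#' @export
write_gene_set <- function(x, path, bed_path = NULL, annotation = NULL,
                           promoter_width = 400) {
  con <- file(path, "w")
  writeLines(paste0("# cutoff rpb1<", x$cutoff$rpb1_max_log2fc,
                    " h3k9ac<", x$cutoff$h3k9ac_max_log2fc,
                    " strict=", x$cutoff$strict), con)
  write.table(x$table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(bed_path)) {
    stopifnot(!is.null(annotation))
    g <- annotation$genes[annotation$genes$gene_id %in% x$members, ]
    w <- promoter_windows(g, promoter_width, annotation)
    write_windows_bed(w, bed_path, strand = g$strand)
  }
  invisible(path)
}

#' Pearson correlation between two contrasts' fold changes
#'
#' @param contrast_a,contrast_b `ContrastResult`s over a shared gene
#'   universe (intersection used; n >= 3 required).
#' @return A `GroupStats` record: test, statistic (r), p_value, n.
#' @export
pearson_fc <- function(contrast_a, contrast_b) {
  shared <- intersect(contrast_a$gene_id, contrast_b$gene_id)
  if (length(shared) < 3) stop("need >= 3 shared genes")
  a <- contrast_a$log2fc[match(shared, contrast_a$gene_id)]
  b <- contrast_b$log2fc[match(shared, contrast_b$gene_id)]
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(a, b, method = "pearson")
  structure(list(test = "pearson", statistic = unname(ct$estimate),
                 p_value = ct$p.value, n = length(shared)),
            class = "GroupStats")
}

#' @export
print.GroupStats <- function(x, ...) {
  cat("GroupStats [", x$test, "]: statistic =", signif(x$statistic, 4),
      " p =", format.pval(x$p_value, digits = 3), "\n")
  if (!is.null(x$per_group)) print(x$per_group)
  invisible(x)
}

# Mann-Whitney U (rank-sum) test. U is the number of (x, y) pairs with
# x > y plus half the ties. Exact two-sided p by enumeration of all
# choose(n1+n2, n1) group assignments when both groups have <= `exact_max`
# observations (handles ties exactly); otherwise normal approximation with
# tie-corrected variance and 0.5 continuity correction.
mann_whitney <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  u_stat <- function(xi, yi) {
    r <- rank(c(xi, yi))
    sum(r[seq_along(xi)]) - length(xi) * (length(xi) + 1) / 2
  }
  u <- u_stat(x, y)
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    pool <- c(x, y)
    idx <- combn(n1 + n2, n1)
    us <- apply(idx, 2, function(i) u_stat(pool[i], pool[-i]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "exact"
  } else {
    pooled <- c(x, y)
    n <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    method <- "normal_approx"
  }
  list(U = u, p_value = p, method = method)
}

#' Compare a per-gene quantity across gene groups
#'
#' Two designs: `two_group_mw` runs a Mann-Whitney rank-sum test between
#' exactly two groups (exact enumeration when both groups have <= 8
#' observations, tie-corrected normal approximation otherwise);
#' `anova_dunnett_vs_others` fits a one-way ANOVA and tests each group
#' against the `"other"` control group with Dunnett-adjusted p-values.
#'
#' @param values numeric vector of per-gene values (e.g. log2 fold changes).
#' @param groups parallel vector of group labels; for `two_group_mw` exactly
#'   two distinct labels, for the ANOVA design one label must equal
#'   `control`.
#' @param design `"two_group_mw"` or `"anova_dunnett_vs_others"`.
#' @param control control group label for the Dunnett design.
#' @return A `GroupStats` record; for the Dunnett design, `per_group` holds
#'   each group's estimate vs control and adjusted p-value.
#' @export
group_compare <- function(values, groups,
                          design = c("two_group_mw",
                                     "anova_dunnett_vs_others"),
                          control = "other") {
  design <- match.arg(design)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  sizes <- table(groups)
  if (any(sizes == 0) || length(sizes) < 2)
    stop("need >= 2 non-empty groups")
  if (design == "two_group_mw") {
    if (length(sizes) != 2)
      stop("two_group_mw requires exactly 2 groups, got ", length(sizes))
    g <- names(sizes)
    mw <- mann_whitney(values[groups == g[1]], values[groups == g[2]])
    return(structure(list(test = "mann_whitney", statistic = mw$U,
                          p_value = mw$p_value, method = mw$method,
                          group_sizes = sizes),
                     class = "GroupStats"))
  }
  if (!control %in% names(sizes))
    stop("control group '", control, "' absent")
  f <- factor(groups)
  f <- stats::relevel(f, ref = control)
  dat <- data.frame(v = values, g = f)
  fit <- aov(v ~ g, data = dat)
  fstat <- summary(fit)[[1]]$`F value`[1]
  # Dunnett contrasts vs control; mvtnorm's multivariate-t integration is
  # randomized, so pin the RNG locally for reproducible adjusted p-values.
  gl <- withr::with_seed(1, {
    s <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
    data.frame(comparison = names(s$test$coefficients),
               estimate = unname(s$test$coefficients),
               p_adjusted = unname(s$test$pvalues),
               stringsAsFactors = FALSE)
  })
  structure(list(test = "anova_dunnett", statistic = fstat,
                 p_value = summary(fit)[[1]]$`Pr(>F)`[1],
                 per_group = gl, group_sizes = sizes, control = control),
            class = "GroupStats")
}
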