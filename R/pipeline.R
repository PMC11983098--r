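#' Load and validate a declarative run configuration
#'
#' The configuration is a single YAML document (or an equivalent R list)
#' with:
#' \describe{
#'   \item{simulate}{optional `sim_config()` argument list; when present the
#'     pipeline generates its inputs.}
#'   \item{samples}{when not simulating: a list of records with `sample_id`,
#'     `path` (BED6/tagAlign), `track`, `condition`, and optionally `mock`
#'     (the sample_id of its mock IP).}
#'   \item{annotation}{when not simulating: `gene_table`, `chrom_table`,
#'     `spikein_prefix`, and optionally `promoter_fasta`.}
#'   \item{contrasts}{list of records `treated`, `vehicle`, `track`.}
#'   \item{params}{quantification parameters; defaults are the study's
#'     printed values: shift 150, extend 40, promoter width 400, +1 window
#'     75, TF window 500, pseudocount 1, thresholds (-1, -0.41), flank 800.}
#'   \item{seed}{base seed for simulation.}
#' }
#'
#' @param config path to a YAML file or a list.
#' @return validated config list with defaults filled in.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(shift = 150, extend = 40, promoter_width = 400,
                   plus1_width = 75, tf_width = 500, pseudocount = 1,
                   rpb1_max_log2fc = -1, h3k9ac_max_log2fc = -0.41,
                   flank = 800, norm = "spikein", heatmap_bin = 25,
                   mode = "midpoint_count")
  p <- config$params
  for (k in names(defaults)) if (is.null(p[[k]])) p[[k]] <- defaults[[k]]
  config$params <- p
  if (is.null(config$seed)) config$seed <- 1
  if (is.null(config$simulate)) {
    for (k in c("samples", "annotation"))
      if (is.null(config[[k]]))
        stop("config without a simulate block must provide '", k, "'")
    ids <- vapply(config$samples, `[[`, character(1), "sample_id")
    if (anyDuplicated(ids)) stop("duplicate sample_id in manifest")
    for (ct in config$contrasts)
      for (s in c(ct$treated, ct$vehicle))
        if (!s %in% ids)
          stop("contrast references unknown sample: ", s)
    for (s in config$samples)
      if (!is.null(s$mock) && !s$mock %in% ids)
        stop("mock pairing references unknown sample: ", s$mock)
  }
  if (is.null(config$contrasts))
    stop("config must list at least one contrast")
  config
}

log_stage <- function(quiet, ...) if (!quiet) message("[promacet] ", ...)

#' Run the full analysis pipeline
#'
#' Executes (optional) simulation, quantification, contrasts, dual-threshold
#' classification, metagene profiling, group statistics and motif
#' enrichment, writing TSV/BED outputs and a machine-readable JSON summary
#' into `outdir`. Every normalization factor, threshold and count used is
#' recorded in the summary; reruns with the same config and seed are
#' byte-identical.
#'
#' @param config run configuration (path or list; see [load_run_config]).
#' @param outdir output directory (created).
#' @param quiet suppress stage messages.
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  config <- load_run_config(config)
  p <- config$params
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(parameters = p, seed = config$seed)

  # ---- inputs: simulate or load ------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    log_stage(quiet, "simulate: generating genome and reads")
    cfg <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
    sim <- generate_genome(cfg)
    annotation <- sim$annotation
    promoters <- sim$promoters
    truth <- sim$truth
    tracks <- unique(vapply(config$contrasts, `[[`, character(1), "track"))
    samples <- list()
    sample_meta <- list()
    for (tr in tracks) for (co in c("vehicle", "treated")) {
      rs <- generate_reads(annotation, truth, co, tr, cfg)
      samples[[rs$sample_id]] <- rs
      sample_meta[[rs$sample_id]] <- list(track = tr, condition = co)
    }
    summary$simulation <- list(n_genes = cfg$n_genes, rho = cfg$rho,
                               mean_midpoints = cfg$mean_midpoints,
                               spikein_fraction = cfg$spikein_fraction)
  } else {
    log_stage(quiet, "load: annotation and reads")
    a <- config$annotation
    annotation <- load_annotation(a$gene_table, a$chrom_table,
                                  a$spikein_prefix %||% "spike_")
    promoters <- NULL
    if (!is.null(a$promoter_fasta)) {
      dna <- Biostrings::readDNAStringSet(a$promoter_fasta)
      promoters <- setNames(as.character(dna),
                            sub("\\s.*$", "", names(dna)))
    }
    samples <- list()
    sample_meta <- list()
    for (s in config$samples) {
      samples[[s$sample_id]] <- load_reads(s$path, annotation, s$sample_id)
      sample_meta[[s$sample_id]] <- s
    }
  }
  summary$n_reads <- lapply(samples, function(s)
    list(target = s$total_target, spikein = s$total_spikein,
         dropped = s$dropped))

  # ---- quantify + contrast -----------------------------------------------
  log_stage(quiet, "quantify: per-gene window signals")
  spec_for_track <- function(track) {
    switch(track,
           Rpb1 = window_spec("gene_body"),
           TF = window_spec("promoter_upstream", p$tf_width),
           window_spec("plus1_centered", p$plus1_width))
  }
  contrasts <- list()
  summary$normalization <- list()
  for (ct in config$contrasts) {
    ids <- c(ct$treated, ct$vehicle)
    mock_id <- sample_meta[[ct$treated]]$mock
    if (!is.null(mock_id)) ids <- union(ids, mock_id)
    tab <- quantify_samples(samples[ids], annotation,
                            spec_for_track(ct$track),
                            shift = p$shift, extend = p$extend,
                            mode = p$mode, norm = p$norm,
                            mock = mock_id, pseudocount = p$pseudocount)
    res <- contrast(tab, ct$treated, ct$vehicle,
                    pseudocount = p$pseudocount,
                    track = if (ct$track %in% c("H3K9ac", "Rpb1", "H3", "TF"))
                      ct$track else "other")
    key <- paste0(ct$track, ":", ct$treated, "_vs_", ct$vehicle)
    contrasts[[key]] <- res
    summary$normalization[[key]] <-
      as.list(attr(tab, "normalization")$factors)
    write_signal_tsv(tab, file.path(outdir, paste0("signal_", ct$track,
                                                   ".tsv")))
    write_signal_tsv(res, file.path(outdir, paste0("contrast_", ct$track,
                                                   ".tsv")))
    log_stage(quiet, "contrast ", key, ": ", nrow(res), " genes")
  }

  # ---- classify -----------------------------------------------------------
  track_of <- vapply(contrasts, attr, character(1), "track")
  gene_set <- NULL
  if (all(c("Rpb1", "H3K9ac") %in% track_of)) {
    log_stage(quiet, "classify: dual-threshold repressed gene set")
    rpb1 <- contrasts[[which(track_of == "Rpb1")[1]]]
    ac <- contrasts[[which(track_of == "H3K9ac")[1]]]
    cutoff <- stringent_cutoff(p$rpb1_max_log2fc, p$h3k9ac_max_log2fc)
    gene_set <- classify_stringent(rpb1, ac, cutoff, annotation)
    write_gene_set(gene_set, file.path(outdir, "gene_set.tsv"),
                   bed_path = file.path(outdir, "gene_set_promoters.bed"),
                   annotation = annotation,
                   promoter_width = p$promoter_width)
    summary$gene_set <- list(
      size = length(gene_set$members),
      group_sizes = as.list(gene_set$group_sizes),
      thresholds = list(rpb1 = cutoff$rpb1_max_log2fc,
                        h3k9ac = cutoff$h3k9ac_max_log2fc))

    pe <- pearson_fc(ac, rpb1)
    summary$pearson <- list(r = pe$statistic, p = pe$p_value, n = pe$n)
    log_stage(quiet, "pearson r = ", signif(pe$statistic, 3))

    merged <- merge(ac, annotation$genes[c("gene_id", "group")],
                    by = "gene_id")
    gs <- group_compare(merged$log2fc, merged$group,
                        "anova_dunnett_vs_others")
    summary$anova_dunnett <- list(
      F = gs$statistic,
      per_group = setNames(as.list(gs$per_group$p_adjusted),
                           gs$per_group$comparison))
    if (!is.null(truth)) {
      called <- gene_set$members
      planted <- truth$gene_id[truth$repressed]
      tp <- length(intersect(called, planted))
      summary$planted_set <- list(
        n_planted = length(planted), n_called = length(called),
        precision = if (length(called)) tp / length(called) else NA,
        recall = if (length(planted)) tp / length(planted) else NA)
      log_stage(quiet, "planted-set recall = ",
                signif(summary$planted_set$recall, 3))
    }

    if (!is.null(promoters)) {
      log_stage(quiet, "motifs: PAC/RRPE enrichment in the gene set")
      enr <- motif_enrichment(promoters, list(pac_motif(), rrpe_motif()),
                              foreground = gene_set$members,
                              background = gene_set$table$gene_id)
      write.table(enr, file.path(outdir, "motif_enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$motifs <- lapply(seq_len(nrow(enr)), function(i)
        as.list(enr[i, c("motif", "fg_hits", "bg_hits", "odds_ratio",
                         "p_value")]))
    }
  }

  # ---- metagene -----------------------------------------------------------
  ac_keys <- names(contrasts)[track_of == "H3K9ac"]
  if (length(ac_keys)) {
    log_stage(quiet, "metagene: +1-anchored profiles and heat map")
    ct <- config$contrasts[[match(ac_keys[1], names(contrasts))]]
    for (co in c(ct$vehicle, ct$treated)) {
      track <- shift_extend_coverage(samples[[co]], p$shift, p$extend,
                                     "target", annotation)
      prof <- metagene_profile(track, annotation, "plus1_dyad", p$flank)
      write_metagene_tsv(prof, file.path(outdir,
                                         paste0("profile_", co, ".tsv")))
      if (co == ct$treated && "Rpb1" %in% track_of) {
        hm <- heatmap_matrix(track, annotation, "plus1_dyad", p$flank,
                             sort_by = contrasts[[
                               which(track_of == "Rpb1")[1]]],
                             bin = p$heatmap_bin)
        write_metagene_tsv(hm, file.path(outdir, "heatmap_H3K9ac.tsv"))
        summary$heatmap <- list(n_genes = nrow(hm$matrix),
                                n_bins = ncol(hm$matrix),
                                bin = p$heatmap_bin)
      }
    }
  }

  summary_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_stage(quiet, "done: ", summary_path)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
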