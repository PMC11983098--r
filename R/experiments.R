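#' Planted fold-change specification for one gene group
#'
#' Draws are `mean + sd * z` (z standard normal, correlated between tracks
#' via the configuration's `rho`), then clipped to `[floor, cap]`.
#'
#' @param mean,sd location and spread of the planted log2 fold change.
#' @param cap,floor clipping bounds (defaults unbounded).
#' @return list used in `sim_config()`'s `fc_h3k9ac` / `fc_rpb1`.
#' @export
fc_spec <- function(mean, sd, cap = Inf, floor = -Inf)
  group_fc_spec(mean, sd, cap, floor)

#' Fold-change specs planting a repressed set with classification margins
#'
#' Builds per-group planted fold-change specifications in which every
#' repressed-group draw clears both classification thresholds by at least
#' `margin` log2 units (upper caps at threshold - margin) while background
#' genes stay at least `bg_floor` above zero change on the repressed side.
#' Used for classification-recovery experiments where the planted truth
#' must be unambiguous.
#'
#' @param cutoff `StringentCutoff` supplying the two thresholds.
#' @param margin log2 separation of repressed draws beyond each threshold.
#' @param bg_sd spread of background (non-repressed) fold changes.
#' @param bg_floor lower clip for background fold changes.
#' @return list with `fc_h3k9ac` and `fc_rpb1` ready for [sim_config].
#' @export
margin_fc_specs <- function(cutoff = stringent_cutoff(), margin = 0.5,
                            bg_sd = 0.1, bg_floor = -0.2) {
  rep_pol <- fc_spec(cutoff$rpb1_max_log2fc - margin - 0.5, 0.3,
                     cap = cutoff$rpb1_max_log2fc - margin)
  rep_ac <- fc_spec(cutoff$h3k9ac_max_log2fc - margin - 0.3, 0.15,
                    cap = cutoff$h3k9ac_max_log2fc - margin)
  bg <- fc_spec(0, bg_sd, floor = bg_floor)
  list(fc_h3k9ac = list(RP = rep_ac, RiBi = rep_ac, GR = rep_ac,
                        other = bg),
       fc_rpb1 = list(RP = rep_pol, RiBi = rep_pol, GR = rep_pol,
                      other = bg))
}

#' Fold-change specs with one shared bivariate distribution for all groups
#'
#' Every group draws from the same untruncated bivariate normal, so the
#' pooled planted correlation across genes equals the configuration's
#' `rho` exactly. Used for correlation-recovery experiments.
#'
#' @param mean,sd shared location and spread per track (default -0.5, 1).
#' @return list with `fc_h3k9ac`, `fc_rpb1` and `repressed_groups`
#'   (empty, disabling the repressed-side truncation) for [sim_config].
#' @export
homogeneous_fc_specs <- function(mean = -0.5, sd = 1) {
  s <- fc_spec(mean, sd)
  one <- list(RP = s, RiBi = s, GR = s, other = s)
  list(fc_h3k9ac = one, fc_rpb1 = one,
       repressed_groups = character(0))
}

#' Simulate an experiment and estimate its treated/vehicle contrasts
#'
#' Generates the genome and the four read sets (vehicle and treated for
#' each requested track), quantifies each track over its standard geometry
#' (the +1-nucleosome window for H3K9ac/H3, the gene body for Rpb1) and
#' returns per-track contrasts next to the planted truth.
#'
#' @param cfg `SimConfig`.
#' @param tracks tracks to simulate and contrast.
#' @param norm normalization mode passed to [quantify_samples].
#' @param pseudocount pseudocount for quantification and contrast.
#' @return list with `annotation`, `truth`, `promoters`, `samples`
#'   (named `ReadSet` list) and `contrasts` (named by track).
#' @export
simulate_experiment <- function(cfg, tracks = c("H3K9ac", "Rpb1"),
                                norm = "spikein", pseudocount = 1) {
  sim <- generate_genome(cfg)
  samples <- list()
  for (tr in tracks) for (co in c("vehicle", "treated")) {
    rs <- generate_reads(sim$annotation, sim$truth, co, tr, cfg)
    samples[[rs$sample_id]] <- rs
  }
  contrasts <- list()
  for (tr in tracks) {
    spec <- if (tr == "Rpb1") window_spec("gene_body") else
      window_spec("plus1_centered", cfg$plus1_width)
    ids <- paste(tr, c("treated", "vehicle"), sep = "_")
    tab <- quantify_samples(samples[ids], sim$annotation, spec,
                            norm = norm, pseudocount = pseudocount)
    contrasts[[tr]] <- contrast(tab, ids[1], ids[2],
                                pseudocount = pseudocount,
                                track = if (tr %in% c("H3K9ac", "Rpb1",
                                                      "H3")) tr
                                        else "other")
  }
  list(annotation = sim$annotation, truth = sim$truth,
       promoters = sim$promoters, samples = samples,
       contrasts = contrasts)
}

#' Mean absolute error of estimated versus planted fold changes
#'
#' @param contrast_result `ContrastResult`.
#' @param truth `GroundTruth`.
#' @param field `"fc_h3k9ac"` or `"fc_rpb1"`.
#' @return mean over genes of |estimated log2fc - planted log2fc|.
#' @export
contrast_mae <- function(contrast_result, truth,
                         field = c("fc_h3k9ac", "fc_rpb1")) {
  field <- match.arg(field)
  planted <- truth[[field]][match(contrast_result$gene_id, truth$gene_id)]
  mean(abs(contrast_result$log2fc - planted))
}

#' Precision and recall of a called gene set against the planted set
#'
#' @param called character vector of called gene ids.
#' @param planted character vector of planted (true) gene ids.
#' @return list with `precision`, `recall`, `tp`, `n_called`, `n_planted`.
#' @export
set_recovery <- function(called, planted) {
  tp <- length(intersect(called, planted))
  list(precision = if (length(called)) tp / length(called) else NA_real_,
       recall = if (length(planted)) tp / length(planted) else NA_real_,
       tp = tp, n_called = length(called), n_planted = length(planted))
}
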