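#' @importFrom stats rpois rnorm runif rbinom sd relevel
NULL

SIM_TRACKS <- c("H3K9ac", "H3", "Rpb1", "mock")
SIM_CONDITIONS <- c("vehicle", "treated")

group_fc_spec <- function(mean, sd, cap = Inf, floor = -Inf)
  list(mean = mean, sd = sd, cap = cap, floor = floor)

#' Simulation configuration
#'
#' Defines the synthetic experiment: a compact yeast-like genome, gene
#' groups, planted per-gene log2 fold changes for the acetylation (H3K9ac)
#' and transcription (Rpb1) tracks with a tunable between-track correlation,
#' promoter motif planting rates, a fragment model consistent with the
#' 150 bp shift convention, and a fixed-proportion spike-in genome.
#'
#' Defaults emulate the study design: 5673 genes in groups RP/RiBi/GR/other
#' (proportions 0.024/0.035/0.043/0.898), fragment length 300 +/- 30 bp,
#' 200 expected fragment midpoints per promoter per sample, 5% spike-in,
#' stress repression planted in the RP/RiBi/GR groups for both tracks with
#' between-track correlation rho = 0.76, and PAC/RRPE motifs planted
#' preferentially in repressed-group promoters.
#'
#' @param n_genes number of genes.
#' @param group_props named proportions for RP/RiBi/GR/other (sum to 1;
#'   exact counts by largest remainder).
#' @param n_chroms number of target chromosomes.
#' @param gene_spacing per-gene slot width in bp.
#' @param gene_length TSS-to-TTS span in bp.
#' @param promoter_width planted promoter sequence length in bp.
#' @param fragment_mean,fragment_sd fragment length model (bp).
#' @param mean_midpoints expected fragments per gene window per sample.
#' @param background_rate uniform background read rate per bp.
#' @param spikein_fraction expected spike-in fraction of total reads.
#' @param spikein_chrom_length spike-in chromosome length in bp.
#' @param fc_h3k9ac,fc_rpb1 named lists (one entry per group) of planted
#'   log2 fold-change specs `list(mean, sd, cap, floor)`; draws are clipped
#'   to `[floor, cap]`. Groups listed in `repressed_groups` are additionally
#'   capped at 0.
#' @param rho between-track correlation of planted log2 fold changes.
#' @param repressed_groups groups forming the planted repressed set.
#' @param motif_rates named list per motif name (`PAC`, `RRPE`) of named
#'   per-group planting probabilities.
#' @param depth_scale named per-(condition,track) technical depth factors,
#'   e.g. `c(treated_H3K9ac = 1)`; unlisted combinations default to 1.
#' @param midpoint_sd SD of fragment midpoints around the window center.
#' @param plus1_width +1-nucleosome target window width for H3K9ac/H3/mock.
#' @param seed base RNG seed; every generator call derives its stream from
#'   `seed`, the condition and the track.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_genes = 5673,
                       group_props = c(RP = 0.024, RiBi = 0.035,
                                       GR = 0.043, other = 0.898),
                       n_chroms = 16,
                       gene_spacing = 4000,
                       gene_length = 1500,
                       promoter_width = 400,
                       fragment_mean = 300, fragment_sd = 30,
                       mean_midpoints = 200,
                       background_rate = 1e-4,
                       spikein_fraction = 0.05,
                       spikein_chrom_length = 5e5,
                       fc_h3k9ac = list(
                         RP = group_fc_spec(-1.1, 0.25),
                         RiBi = group_fc_spec(-1.0, 0.25),
                         GR = group_fc_spec(-0.9, 0.25),
                         other = group_fc_spec(0, 0.15)),
                       fc_rpb1 = list(
                         RP = group_fc_spec(-2.0, 0.4),
                         RiBi = group_fc_spec(-1.8, 0.4),
                         GR = group_fc_spec(-1.6, 0.4),
                         other = group_fc_spec(0, 0.3)),
                       rho = 0.76,
                       repressed_groups = c("RP", "RiBi", "GR"),
                       motif_rates = list(
                         PAC = c(RP = 0.1, RiBi = 0.9, GR = 0.6,
                                 other = 0.1),
                         RRPE = c(RP = 0.1, RiBi = 0.8, GR = 0.5,
                                  other = 0.1)),
                       depth_scale = NULL,
                       midpoint_sd = 20,
                       plus1_width = 75,
                       seed = 1) {
  stopifnot(n_genes > 0, abs(sum(group_props) - 1) < 1e-8,
            all(group_props >= 0), abs(rho) <= 1,
            background_rate >= 0, mean_midpoints >= 0,
            spikein_fraction > 0, spikein_fraction < 1,
            all(GENE_GROUPS %in% names(group_props)),
            all(repressed_groups %in% GENE_GROUPS))
  genes_per_chrom <- ceiling(n_genes / n_chroms)
  chrom_len <- 2000 + genes_per_chrom * gene_spacing + 2000
  if (gene_spacing < promoter_width + gene_length + 1200)
    stop("gene_spacing too small for promoter + gene body + flanks")
  cfg <- list(n_genes = n_genes, group_props = group_props[GENE_GROUPS],
              n_chroms = n_chroms, gene_spacing = gene_spacing,
              gene_length = gene_length, promoter_width = promoter_width,
              fragment_mean = fragment_mean, fragment_sd = fragment_sd,
              mean_midpoints = mean_midpoints,
              background_rate = background_rate,
              spikein_fraction = spikein_fraction,
              spikein_chrom_length = spikein_chrom_length,
              fc_h3k9ac = fc_h3k9ac, fc_rpb1 = fc_rpb1, rho = rho,
              repressed_groups = repressed_groups,
              motif_rates = motif_rates,
              depth_scale = depth_scale,
              midpoint_sd = midpoint_sd, plus1_width = plus1_width,
              genes_per_chrom = genes_per_chrom, chrom_len = chrom_len,
              seed = seed)
  class(cfg) <- "SimConfig"
  cfg
}

# Largest-remainder allocation of n items to proportions p (sums to n).
largest_remainder <- function(n, p) {
  q <- n * p
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Deterministic RNG substream id for (seed, condition, track); < 2^31.
sim_stream_seed <- function(seed, condition = NULL, track = NULL) {
  off <- 0L
  if (!is.null(condition))
    off <- off + 1000L * match(condition, SIM_CONDITIONS)
  if (!is.null(track))
    off <- off + 100L * match(track, SIM_TRACKS)
  (as.integer(seed) + off) %% .Machine$integer.max
}

depth_of <- function(cfg, condition, track) {
  key <- paste(condition, track, sep = "_")
  d <- cfg$depth_scale[[key]]
  if (is.null(d)) 1 else d
}

#' Generate a synthetic genome with planted ground truth
#'
#' Places non-overlapping genes on `n_chroms` target chromosomes (strand
#' drawn at random, +1-nucleosome dyad 60 bp downstream of the TSS),
#' appends one spike-in chromosome, draws per-gene (H3K9ac, Rpb1) planted
#' log2 fold changes from a per-group bivariate normal with correlation
#' `rho` (clipped at 0 above for repressed groups and to any configured
#' cap/floor), and synthesizes promoter sequences as i.i.d. uniform ACGT
#' with PAC/RRPE motifs planted at per-group rates at random offsets.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg `SimConfig`.
#' @return list with `annotation` (`GenomeAnnotation`), `promoters` (named
#'   character vector of sequences), and `truth` (`GroundTruth`: per-gene
#'   planted log2fcs, repressed flag, motif plants).
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(sim_stream_seed(cfg$seed))

  counts <- largest_remainder(cfg$n_genes, cfg$group_props)
  groups <- sample(rep(GENE_GROUPS, counts))

  i <- seq_len(cfg$n_genes) - 1
  chrom_i <- i %/% cfg$genes_per_chrom + 1
  slot <- i %% cfg$genes_per_chrom
  chrom <- paste0("chr", chrom_i)
  slot_start <- 2000 + slot * cfg$gene_spacing
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  # plus strand: promoter | TSS ... TTS ; minus strand mirrored in the slot
  tss_plus <- slot_start + cfg$promoter_width + 400
  tss <- ifelse(strand == "+", tss_plus, tss_plus + cfg$gene_length - 1)
  tts <- ifelse(strand == "+", tss + cfg$gene_length - 1,
                slot_start + cfg$promoter_width + 400)
  dyad <- ifelse(strand == "+", tss + 60, tss - 60)
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
    chrom = chrom, strand = strand, tss = tss, tts = tts,
    plus1_dyad = dyad, group = groups, stringsAsFactors = FALSE)
  chroms <- data.frame(
    name = c(paste0("chr", seq_len(cfg$n_chroms)), "spike_1"),
    length = c(rep(cfg$chrom_len, cfg$n_chroms), cfg$spikein_chrom_length),
    stringsAsFactors = FALSE)
  annotation <- genome_annotation(genes, chroms, spikein_prefix = "spike_")

  # planted log2 fold changes: per-group bivariate normal, correlation rho
  z1 <- rnorm(cfg$n_genes)
  z2 <- cfg$rho * z1 + sqrt(1 - cfg$rho^2) * rnorm(cfg$n_genes)
  fc_ac <- numeric(cfg$n_genes)
  fc_pol <- numeric(cfg$n_genes)
  for (g in GENE_GROUPS) {
    gi <- which(groups == g)
    sa <- cfg$fc_h3k9ac[[g]]; sp <- cfg$fc_rpb1[[g]]
    a <- sa$mean + sa$sd * z1[gi]
    p <- sp$mean + sp$sd * z2[gi]
    if (g %in% cfg$repressed_groups) { a <- pmin(a, 0); p <- pmin(p, 0) }
    fc_ac[gi] <- pmin(pmax(a, sa$floor), sa$cap)
    fc_pol[gi] <- pmin(pmax(p, sp$floor), sp$cap)
  }

  # promoter sequences with planted motifs
  motif_seqs <- c(PAC = "GATGAG", RRPE = "TGAAAA")
  promoters <- vapply(seq_len(cfg$n_genes), function(j) {
    paste(sample(c("A", "C", "G", "T"), cfg$promoter_width, replace = TRUE),
          collapse = "")
  }, character(1))
  planted <- matrix(FALSE, cfg$n_genes, length(motif_seqs),
                    dimnames = list(NULL, names(motif_seqs)))
  for (m in names(cfg$motif_rates)) {
    rates <- cfg$motif_rates[[m]][groups]
    hit <- runif(cfg$n_genes) < rates
    planted[, m] <- hit
    ms <- motif_seqs[[m]]
    off <- sample.int(cfg$promoter_width - nchar(ms) + 1, cfg$n_genes,
                      replace = TRUE)
    for (j in which(hit)) {
      substr(promoters[j], off[j], off[j] + nchar(ms) - 1) <- ms
    }
  }
  names(promoters) <- genes$gene_id

  truth <- data.frame(
    gene_id = genes$gene_id, group = groups,
    fc_h3k9ac = fc_ac, fc_rpb1 = fc_pol,
    repressed = groups %in% cfg$repressed_groups,
    pac_planted = planted[, "PAC"], rrpe_planted = planted[, "RRPE"],
    stringsAsFactors = FALSE)
  class(truth) <- c("GroundTruth", "data.frame")

  list(annotation = annotation, promoters = promoters, truth = truth)
}

#' Generate a stranded single-end ChIP-seq read set
#'
#' Per gene, the expected fragment count is `mean_midpoints * depth *
#' 2^planted_log2fc` (fold change applied only in the treated condition and
#' only for the H3K9ac and Rpb1 tracks; H3 is flat and the mock IP emits
#' background-only reads at matched library scale). Counts are Poisson;
#' fragment midpoints are normal around the target-window center (the
#' +1-nucleosome window for H3K9ac/H3, the gene body for Rpb1), clipped to
#' the window; fragment lengths are normal, floored at 40 bp; one end of
#' each fragment is sequenced (plus or minus with probability 1/2).
#' Uniform background reads cover the target genome and uniform spike-in
#' reads are emitted at a rate making the expected spike-in fraction equal
#' `spikein_fraction` times the sample's technical depth scale.
#' Deterministic given (`cfg$seed`, condition, track).
#'
#' @param annotation `GenomeAnnotation` from [generate_genome].
#' @param truth `GroundTruth` from [generate_genome].
#' @param condition `"vehicle"` or `"treated"`.
#' @param track `"H3K9ac"`, `"H3"`, `"Rpb1"` or `"mock"`.
#' @param cfg `SimConfig`.
#' @return A `ReadSet` with sample id `<track>_<condition>`.
#' @export
generate_reads <- function(annotation, truth,
                           condition = c("vehicle", "treated"),
                           track = c("H3K9ac", "H3", "Rpb1", "mock"),
                           cfg) {
  condition <- match.arg(condition)
  track <- match.arg(track)
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(sim_stream_seed(cfg$seed, condition, track))
  depth <- depth_of(cfg, condition, track)
  g <- annotation$genes
  n <- nrow(g)

  # per-gene target window and expected fragment counts
  if (track == "Rpb1") {
    w <- gene_body_windows(g, annotation)
  } else {
    w <- plus1_windows(g, cfg$plus1_width, annotation)
  }
  fc <- switch(track, H3K9ac = truth$fc_h3k9ac, Rpb1 = truth$fc_rpb1,
               rep(0, n))
  lambda <- cfg$mean_midpoints * depth *
    if (condition == "treated") 2^fc else rep(1, n)
  if (track == "mock") lambda <- rep(0, n)

  counts <- rpois(n, lambda)
  total <- sum(counts)
  gi <- rep.int(seq_len(n), counts)
  center <- (w$start + w$end) / 2
  mid <- rnorm(total, center[gi], cfg$midpoint_sd)
  mid <- pmin(pmax(mid, w$start[gi]), w$end[gi] - 1)
  frag_chrom <- w$chrom[gi]

  # background over the target genome; the mock IP re-emits the library at
  # background geometry so mock ratios isolate enrichment
  tlen <- annotation$chroms$length[annotation$chroms$species == "target"]
  tnames <- annotation$chroms$name[annotation$chroms$species == "target"]
  baseline <- cfg$mean_midpoints * n + cfg$background_rate * sum(tlen)
  bg_lambda <- cfg$background_rate * sum(tlen) * depth
  if (track == "mock") bg_lambda <- baseline * depth
  n_bg <- rpois(1, bg_lambda)
  bg_pos <- runif(n_bg, 0, sum(tlen))
  cum <- c(0, cumsum(tlen))
  bg_ci <- findInterval(bg_pos, cum, rightmost.closed = TRUE)
  bg_mid <- floor(bg_pos - cum[bg_ci])
  bg_chrom <- tnames[bg_ci]

  mid <- c(mid, bg_mid)
  frag_chrom <- c(frag_chrom, bg_chrom)
  m <- length(mid)
  len <- pmax(round(rnorm(m, cfg$fragment_mean, cfg$fragment_sd)), 40)
  plus <- rbinom(m, 1, 0.5) == 1
  start <- round(mid - len / 2)
  five <- ifelse(plus, start, start + len - 1)
  target <- data.frame(chrom = frag_chrom, five_prime = five,
                       strand = ifelse(plus, "+", "-"),
                       stringsAsFactors = FALSE)
  # keep 5' ends on-chromosome
  clen <- chrom_length(annotation, target$chrom)
  target <- target[target$five_prime >= 0 & target$five_prime < clen, ,
                   drop = FALSE]

  # spike-in: fixed expected fraction of total reads, scaled by depth only
  f <- cfg$spikein_fraction
  sp_name <- annotation$chroms$name[annotation$chroms$species == "spikein"][1]
  sp_len <- chrom_length(annotation, sp_name)
  n_sp <- rpois(1, f / (1 - f) * baseline * depth)
  spikein <- data.frame(
    chrom = rep(sp_name, n_sp),
    five_prime = floor(runif(n_sp, 0, sp_len)),
    strand = sample(c("+", "-"), n_sp, replace = TRUE),
    stringsAsFactors = FALSE)

  new_read_set(paste(track, condition, sep = "_"), target, spikein)
}

#' Write a full simulated experiment to disk
#'
#' Writes the annotation tables, promoter FASTA, ground-truth TSV, the
#' configuration as a reproducibility manifest (YAML), and one gzipped
#' BED6 file per (track, condition) sample.
#'
#' @param cfg `SimConfig`.
#' @param dir output directory (created).
#' @param tracks,conditions which samples to write.
#' @return invisibly, the list from [generate_genome] plus file paths.
#' @export
write_simulation <- function(cfg, dir,
                             tracks = c("H3K9ac", "Rpb1"),
                             conditions = c("vehicle", "treated")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_genome(cfg)
  write_annotation(sim$annotation,
                   file.path(dir, "genes.tsv"),
                   file.path(dir, "chroms.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$promoters),
    file.path(dir, "promoters.fa"))
  write.table(sim$truth, file.path(dir, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, logical(1))],
                   file.path(dir, "sim_config.yaml"))
  paths <- list()
  for (tr in tracks) for (co in conditions) {
    rs <- generate_reads(sim$annotation, sim$truth, co, tr, cfg)
    p <- file.path(dir, paste0(tr, "_", co, ".bed.gz"))
    write_reads_bed(rs, p)
    paths[[rs$sample_id]] <- p
  }
  sim$read_paths <- paths
  invisible(sim)
}
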