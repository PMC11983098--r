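test_that("genome generation is byte-identical for a fixed seed", {
  cfg <- sim_config(n_genes = 10, n_chroms = 2, seed = 7)
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(a$annotation$genes, b$annotation$genes)
  expect_identical(a$promoters, b$promoters)
  expect_identical(a$truth, b$truth)
  r1 <- generate_reads(a$annotation, a$truth, "treated", "H3K9ac", cfg)
  r2 <- generate_reads(b$annotation, b$truth, "treated", "H3K9ac", cfg)
  expect_identical(r1$target, r2$target)
  expect_identical(r1$spikein, r2$spikein)
  # a different seed diverges
  r3 <- generate_reads(a$annotation, a$truth, "treated", "H3K9ac",
                       sim_config(n_genes = 10, n_chroms = 2, seed = 8))
  expect_false(identical(r1$target, r3$target))
})

test_that("group allocation is exact by largest remainder", {
  cfg <- sim_config(n_genes = 1000, n_chroms = 4, seed = 3,
                    group_props = c(RP = 0.1, RiBi = 0.2, GR = 0.1,
                                    other = 0.6))
  sim <- generate_genome(cfg)
  tab <- table(sim$truth$group)
  expect_equal(unname(tab[c("RP", "RiBi", "GR", "other")]),
               as.table(c(100L, 200L, 100L, 600L)),
               ignore_attr = TRUE)
})

test_that("generated annotation satisfies its own validator and geometry", {
  cfg <- sim_config(n_genes = 200, n_chroms = 4, seed = 13)
  sim <- generate_genome(cfg)
  g <- sim$annotation$genes
  # +1 dyad sits 60 bp downstream of the TSS, strand-aware
  expect_true(all(ifelse(g$strand == "+", g$plus1_dyad - g$tss,
                         g$tss - g$plus1_dyad) == 60))
  # promoter sequences have the configured width
  expect_true(all(nchar(sim$promoters) == cfg$promoter_width))
  # no overlapping transcribed regions per chromosome
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, ]
    lo <- pmin(gc$tss, gc$tts); hi <- pmax(gc$tss, gc$tts)
    o <- order(lo)
    expect_true(all(lo[o][-1] > hi[o][-length(o)]))
  }
})

test_that("zero rates produce an empty read set", {
  cfg <- sim_config(n_genes = 10, n_chroms = 2, mean_midpoints = 0,
                    background_rate = 0, seed = 9,
                    spikein_fraction = 0.05)
  sim <- generate_genome(cfg)
  rs <- generate_reads(sim$annotation, sim$truth, "vehicle", "H3K9ac", cfg)
  expect_equal(rs$total_target, 0)
})

test_that("mock IP emits background-only reads at library scale", {
  cfg <- sim_config(n_genes = 100, n_chroms = 2, mean_midpoints = 100,
                    seed = 19)
  sim <- generate_genome(cfg)
  mock <- generate_reads(sim$annotation, sim$truth, "vehicle", "mock", cfg)
  ip <- generate_reads(sim$annotation, sim$truth, "vehicle", "H3K9ac", cfg)
  # comparable library size
  expect_gt(mock$total_target, 0.8 * ip$total_target)
  expect_lt(mock$total_target, 1.2 * ip$total_target)
  # but no promoter concentration: fraction of midpoints in +1 windows is
  # near the windows' share of the genome for the mock, high for the IP
  w <- plus1_windows(sim$annotation$genes, 75, sim$annotation)
  frac <- function(rs)
    sum(promacet:::count_midpoints_in_windows(rs, w)) / rs$total_target
  expect_gt(frac(ip), 0.5)
  expect_lt(frac(mock), 0.05)
})

test_that("spike-in fraction matches the configured value", {
  cfg <- sim_config(n_genes = 300, n_chroms = 2, mean_midpoints = 100,
                    spikein_fraction = 0.05, seed = 29)
  sim <- generate_genome(cfg)
  rs <- generate_reads(sim$annotation, sim$truth, "vehicle", "H3K9ac", cfg)
  frac <- rs$total_spikein / (rs$total_spikein + rs$total_target)
  n <- rs$total_spikein + rs$total_target
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 0.002)
})

test_that("planted fold-change correlation converges to rho", {
  spec <- list(mean = -0.5, sd = 1, cap = Inf, floor = -Inf)
  cfg <- sim_config(n_genes = 5000, n_chroms = 8, seed = 39, rho = 0.76,
                    repressed_groups = character(0),
                    fc_h3k9ac = list(RP = spec, RiBi = spec, GR = spec,
                                     other = spec),
                    fc_rpb1 = list(RP = spec, RiBi = spec, GR = spec,
                                   other = spec))
  sim <- generate_genome(cfg)
  expect_lt(abs(cor(sim$truth$fc_h3k9ac, sim$truth$fc_rpb1) - 0.76), 0.05)
})

test_that("fragment ends 2*shift apart produce matching coverage", {
  ann <- tiny_annotation()
  # a fragment whose two 5' ends are separated by exactly 2*shift
  plus <- make_read_set("chr1", 1000, "+")
  minus <- make_read_set("chr1", 1300, "-")
  t1 <- shift_extend_coverage(plus, 150, 40, annotation = ann)
  t2 <- shift_extend_coverage(minus, 150, 40, annotation = ann)
  expect_equal(t1$coverage$chr1, t2$coverage$chr1)
  # generator fragments with fixed length recover the planted midpoint to
  # within 1 bp from either end
  cfg <- sim_config(n_genes = 50, n_chroms = 2, mean_midpoints = 50,
                    fragment_sd = 0, background_rate = 0, seed = 49)
  sim <- generate_genome(cfg)
  rs <- generate_reads(sim$annotation, sim$truth, "vehicle", "H3K9ac", cfg)
  mp <- shifted_midpoints(rs, 150)
  w <- plus1_windows(sim$annotation$genes, 77, sim$annotation)
  inside <- promacet:::count_midpoints_in_windows(rs, w, 150)
  expect_gte(sum(inside) / rs$total_target, 0.99)
})

test_that("a written simulation reloads into the same experiment", {
  d <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 40, n_chroms = 2, mean_midpoints = 30,
                    seed = 59)
  sim <- write_simulation(cfg, d, tracks = "H3K9ac",
                          conditions = "vehicle")
  ann <- load_annotation(file.path(d, "genes.tsv"),
                         file.path(d, "chroms.tsv"))
  expect_equal(ann$genes, sim$annotation$genes)
  rs <- load_reads(file.path(d, "H3K9ac_vehicle.bed.gz"), ann)
  orig <- generate_reads(sim$annotation, sim$truth, "vehicle", "H3K9ac",
                         cfg)
  expect_equal(rs$total_target, orig$total_target)
  expect_equal(sort(rs$target$five_prime), sort(orig$target$five_prime))
  fa <- Biostrings::readDNAStringSet(file.path(d, "promoters.fa"))
  expect_equal(as.character(fa[["g0001"]]), unname(sim$promoters["g0001"]))
  expect_true(file.exists(file.path(d, "sim_config.yaml")))
})
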