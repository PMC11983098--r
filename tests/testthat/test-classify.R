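test_that("dual-threshold membership follows the printed cut-offs", {
  r <- mk_contrast(c("a", "b", "c", "d"), c(-1.5, -1.0, -2.0, -0.5), "Rpb1")
  a <- mk_contrast(c("a", "b", "c", "d"), c(-0.6, -0.6, -0.3, -0.3), "H3K9ac")
  gs <- classify_stringent(r, a)
  expect_equal(gs$members, "a")                    # (-1.5, -0.6) passes
  tab <- gs$table
  expect_equal(tab$reason[tab$gene_id == "b"], "rpb1_above_threshold")
  expect_equal(tab$reason[tab$gene_id == "c"], "h3k9ac_above_threshold")
  expect_equal(tab$reason[tab$gene_id == "d"], "both_above_threshold")
  # exactly -1.0 fails under strict inequality, passes under <=
  gs2 <- classify_stringent(r, a, stringent_cutoff(strict = FALSE))
  expect_setequal(gs2$members, c("a", "b"))
})

test_that("disjoint universes error; partial overlap is counted", {
  r <- mk_contrast(c("a", "b"), c(-2, -2))
  a <- mk_contrast(c("c", "d"), c(-1, -1))
  expect_error(classify_stringent(r, a), "disjoint")
  a2 <- mk_contrast(c("b", "c"), c(-1, -1))
  gs <- classify_stringent(r, a2)
  expect_equal(gs$n_excluded, 2)
  expect_equal(nrow(gs$table), 1)
})

test_that("tightening either threshold never adds members", {
  set.seed(31)
  ids <- sprintf("g%03d", 1:300)
  r <- mk_contrast(ids, rnorm(300, -0.8, 0.8))
  a <- mk_contrast(ids, rnorm(300, -0.4, 0.4))
  base <- classify_stringent(r, a)$members
  for (dr in c(0.2, 0.5, 1)) {
    tighter <- classify_stringent(
      r, a, stringent_cutoff(-1 - dr, -0.41 - dr / 2))$members
    expect_true(all(tighter %in% base))
    base_dr <- classify_stringent(r, a, stringent_cutoff(-1 - dr, -0.41))
    expect_true(all(base_dr$members %in% base))
  }
})

test_that("group sizes partition the member set", {
  set.seed(32)
  ids <- sprintf("g%03d", 1:200)
  r <- mk_contrast(ids, rnorm(200, -1, 0.6))
  a <- mk_contrast(ids, rnorm(200, -0.5, 0.4))
  groups <- setNames(sample(c("RP", "RiBi", "GR", "other"), 200, TRUE), ids)
  gs <- classify_stringent(r, a, groups = groups)
  expect_equal(sum(gs$group_sizes), length(gs$members))
  expect_equal(unname(gs$group_sizes[["RP"]]),
               sum(groups[gs$members] == "RP"))
})

test_that("fold-change correlation has the self and sign-flip fixed points", {
  set.seed(33)
  ids <- sprintf("g%02d", 1:50)
  x <- rnorm(50)
  a <- mk_contrast(ids, x)
  expect_equal(pearson_fc(a, a)$statistic, 1.0)
  expect_equal(pearson_fc(a, mk_contrast(ids, -x))$statistic, -1.0)
  expect_error(pearson_fc(mk_contrast(ids, rep(1, 50)), a), "variance")
})

test_that("Mann-Whitney matches full-permutation enumeration", {
  # {1,2} vs {3,4}: exact two-sided p = 1/3 over the 6 rank assignments
  gs <- group_compare(c(1, 2, 3, 4), c("x", "x", "y", "y"))
  expect_equal(gs$p_value, 1 / 3)
  expect_equal(gs$statistic, 0)
  # identical groups: U = n1*n2/2, p = 1
  gs2 <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("x", "y"), each = 3))
  expect_equal(gs2$statistic, 4.5)
  expect_gt(gs2$p_value, 0.99)
  set.seed(34)
  for (i in 1:12) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    vals <- sample(1:5, n1 + n2, replace = TRUE)   # ties likely
    g <- rep(c("x", "y"), c(n1, n2))
    got <- group_compare(vals, g)$p_value
    expect_equal(got, bf_mw_exact_p(vals[g == "x"], vals[g == "y"]),
                 tolerance = 1e-12)
  }
})

test_that("Mann-Whitney exact path agrees with wilcox.test without ties", {
  set.seed(35)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    got <- group_compare(c(x, y), rep(c("x", "y"), c(length(x), length(y))))
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact path at n1=n2=8", {
  set.seed(36)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    exact <- group_compare(c(x, y), rep(c("x", "y"), each = 8))$p_value
    approx <- promacet:::mann_whitney(x, y, exact_max = 0)$p_value
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("one-way ANOVA holds its type-I error on null normal groups", {
  set.seed(37)
  n_rep <- 1000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    v <- rnorm(45)
    g <- rep(c("a", "b", "other"), each = 15)
    fit <- summary(stats::aov(v ~ factor(g)))[[1]]
    rej[i] <- fit$`Pr(>F)`[1] < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Dunnett contrasts against the control group are reported", {
  set.seed(38)
  v <- c(rnorm(30, 0), rnorm(25, -1.5), rnorm(20, 0.1), rnorm(40, 0))
  g <- rep(c("RP", "RiBi", "GR", "other"), c(30, 25, 20, 40))
  gs <- group_compare(v, g, "anova_dunnett_vs_others")
  expect_equal(gs$test, "anova_dunnett")
  expect_equal(nrow(gs$per_group), 3)
  pr <- setNames(gs$per_group$p_adjusted, gs$per_group$comparison)
  expect_lt(pr[["RiBi - other"]], 0.001)
  expect_gt(pr[["GR - other"]], 0.05)
  expect_true(all(gs$per_group$p_adjusted >= 0 &
                    gs$per_group$p_adjusted <= 1))
  # deterministic despite the randomized multivariate-t integration
  gs2 <- group_compare(v, g, "anova_dunnett_vs_others")
  expect_identical(gs$per_group, gs2$per_group)
  expect_error(group_compare(v, g, "anova_dunnett_vs_others",
                             control = "none"), "control")
})

test_that("planted repressed genes are recovered from simulated reads", {
  # margins: repressed draws capped 0.5 log2 units beyond both thresholds,
  # background floored well above them
  rep_spec <- function(m, s, cap) list(mean = m, sd = s, cap = cap,
                                       floor = -Inf)
  bg_spec <- list(mean = 0, sd = 0.1, cap = Inf, floor = -0.2)
  cfg <- sim_config(
    n_genes = 600, n_chroms = 4, mean_midpoints = 200, seed = 101,
    group_props = c(RP = 0.05, RiBi = 0.05, GR = 0.1, other = 0.8),
    fc_rpb1 = list(RP = rep_spec(-2, 0.3, -1.5), RiBi = rep_spec(-2, 0.3, -1.5),
                   GR = rep_spec(-1.8, 0.3, -1.5), other = bg_spec),
    fc_h3k9ac = list(RP = rep_spec(-1.2, 0.15, -0.91),
                     RiBi = rep_spec(-1.2, 0.15, -0.91),
                     GR = rep_spec(-1.1, 0.15, -0.91), other = bg_spec))
  sim <- generate_genome(cfg)
  samples <- list()
  for (tr in c("H3K9ac", "Rpb1")) for (co in c("vehicle", "treated"))
    samples[[paste(tr, co, sep = "_")]] <-
      generate_reads(sim$annotation, sim$truth, co, tr, cfg)
  tab_ac <- quantify_samples(samples[c("H3K9ac_treated", "H3K9ac_vehicle")],
                             sim$annotation, window_spec("plus1_centered", 75))
  tab_pol <- quantify_samples(samples[c("Rpb1_treated", "Rpb1_vehicle")],
                              sim$annotation, window_spec("gene_body"))
  gs <- classify_stringent(
    contrast(tab_pol, "Rpb1_treated", "Rpb1_vehicle", track = "Rpb1"),
    contrast(tab_ac, "H3K9ac_treated", "H3K9ac_vehicle", track = "H3K9ac"))
  planted <- sim$truth$gene_id[sim$truth$repressed]
  tp <- length(intersect(gs$members, planted))
  expect_gte(tp / length(gs$members), 0.95)
  expect_gte(tp / length(planted), 0.95)
})
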