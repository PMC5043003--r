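test_that("Lilliefors statistic matches the reference and is calibrated", {
  set.seed(2)
  # statistic agrees with the nortest implementation
  for (i in 1:10) {
    x <- rnorm(sample(10:60, 1))
    ours <- lilliefors_normality(x)
    ref <- nortest::lillie.test(x)
    expect_equal(unname(ours$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
  }
  # studentization invariance
  x <- rnorm(25)
  expect_equal(unname(lilliefors_normality(3 * x + 7)$statistic),
               unname(lilliefors_normality(x)$statistic), tolerance = 1e-12)
  expect_error(lilliefors_normality(rnorm(4)), "at least 5")

  # null calibration at n = 20: Monte-Carlo p-values reject at ~5%
  set.seed(3)
  rej <- mean(replicate(1000, lilliefors_normality(rnorm(20))$p.value) < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)

  # gross non-normality is detected at moderate n
  set.seed(4)
  expect_lt(lilliefors_normality(runif(200))$p.value, 0.01)
})

test_that("Levene's test is an ANOVA on absolute deviations", {
  # identical dispersion pattern in both groups
  same <- levene_test(c(1, 3, 5, 1, 3, 5), rep(1:2, each = 3))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)

  # spreads 1 vs 5 with no within-group deviation variance: capped F
  cap <- levene_test(c(0, 2, -5, 5), c("a", "a", "b", "b"))
  expect_true(is.infinite(cap$statistic))
  expect_equal(cap$p.value, 0)
  expect_true(cap$degenerate)

  # inflating one group's scale increases the statistic
  set.seed(6)
  x <- rnorm(12); y <- rnorm(12)
  g <- rep(1:2, each = 12)
  stats_c <- vapply(c(1, 2, 4, 8), function(c)
    unname(levene_test(c(x, c * y), g)$statistic), numeric(1))
  expect_true(all(diff(stats_c) > 0))

  # median centering is the Brown-Forsythe variant
  bf <- levene_test(c(x, y), g, center = "median")
  expect_match(bf$method, "median")
})

test_that("one-way ANOVA matches the hand decomposition and t^2 identity", {
  a <- one_way_anova(1:6, rep(1:2, each = 3))
  expect_equal(unname(a$statistic), 13.5)
  expect_equal(unname(a$parameter), c(1, 4))
  expect_equal(a$p.value, stats::pf(13.5, 1, 4, lower.tail = FALSE))

  # identical groups: F ~ 0
  expect_equal(unname(one_way_anova(rep(c(1, 2, 3), 3),
                                    rep(1:3, each = 3))$statistic), 0)

  # summary-statistics route reproduces the raw-data route
  set.seed(7)
  x <- rnorm(30); g <- rep(1:3, each = 10)
  raw <- one_way_anova(x, g)
  st <- vapply(split(x, g), function(v) c(mean(v), sd(v)), numeric(2))
  summ <- anova_from_summary(rep(10, 3), st[1, ], st[2, ])
  expect_equal(unname(raw$statistic), unname(summ$statistic),
               tolerance = 1e-12)

  # two groups: F equals the squared pooled t
  for (i in 1:10) {
    x <- rnorm(14); g <- rep(1:2, each = 7)
    f <- unname(one_way_anova(x, g)$statistic)
    t <- stats::t.test(x ~ g, var.equal = TRUE)$statistic
    expect_equal(f, unname(t)^2, tolerance = 1e-10)
  }

  # zero MSW with unequal means follows the capped convention
  cap <- one_way_anova(c(1, 1, 2, 2), rep(1:2, each = 2))
  expect_true(is.infinite(cap$statistic))
  expect_equal(cap$p.value, 0)
})

test_that("Dunnett comparisons reduce, dominate and match mvtnorm", {
  set.seed(8)
  # single treatment: adjusted p equals the pooled two-sample t p
  x <- rnorm(20); g <- rep(c("c", "t"), each = 10)
  dt1 <- dunnett_test(x, g, "c")
  tt <- stats::t.test(x[g == "t"], x[g == "c"], var.equal = TRUE)
  expect_equal(dt1$p_adj, tt$p.value, tolerance = 1e-6)

  # multiplicity dominance and agreement with the multivariate t
  vals <- c(rnorm(10), rnorm(10, 1), rnorm(8, 0.4), rnorm(12, -0.3))
  grp <- rep(c("c", "t1", "t2", "t3"), c(10, 10, 8, 12))
  dt <- dunnett_test(vals, grp, "c")
  expect_true(all(dt$p_adj >= dt$p_unadjusted - 1e-12))

  n0 <- 10; ni <- c(10, 8, 12)
  gam <- sqrt(ni / (ni + n0))
  R <- outer(gam, gam); diag(R) <- 1
  for (i in seq_len(3)) {
    set.seed(123)
    ref <- 1 - mvtnorm::pmvt(lower = rep(-abs(dt$t[i]), 3),
                             upper = rep(abs(dt$t[i]), 3),
                             df = dt$df[i], corr = R,
                             algorithm = mvtnorm::GenzBretz(
                               abseps = 1e-5, maxpts = 100000))[1]
    expect_lt(abs(dt$p_adj[i] - ref), 1e-3)
  }
})

test_that("post hoc t uses the pooled MSE and is anti-conservative", {
  # two groups only: classic pooled two-sample t
  set.seed(9)
  x <- rnorm(16); g <- rep(c("c", "t"), each = 8)
  pt1 <- posthoc_t(x, g, "c")
  tt <- stats::t.test(x[g == "t"], x[g == "c"], var.equal = TRUE)
  expect_equal(pt1$p, tt$p.value, tolerance = 1e-10)

  # |t| = sqrt(F) for the two-group hand example
  pt2 <- posthoc_t(1:6, rep(c("c", "t"), each = 3), "c")
  expect_equal(abs(pt2$t), sqrt(13.5), tolerance = 1e-10)

  # unadjusted p never exceeds the Dunnett-adjusted p
  for (i in 1:10) {
    vals <- rnorm(40); grp <- rep(c("c", "a", "b", "d"), each = 10)
    tp <- posthoc_t(vals, grp, "c")
    dp <- dunnett_test(vals, grp, "c")
    expect_true(all(tp$p <= dp$p_adj[match(tp$group, dp$group)] + 1e-12))
  }
})

test_that("Kruskal-Wallis matches hand ranking and the rank-sum z^2", {
  expect_equal(unname(kruskal_wallis(1:9, rep(1:3, each = 3))$statistic),
               7.2)
  tied <- kruskal_wallis(rep(4, 9), rep(1:3, each = 3))
  expect_equal(unname(tied$statistic), 0)
  expect_equal(tied$p.value, 1)

  # two groups: H equals the squared tie-corrected rank-sum z
  set.seed(10)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(9)
    H <- unname(kruskal_wallis(c(a, b), rep(1:2, c(8, 9)))$statistic)
    r <- rank(c(a, b))
    n <- 17; na <- 8
    W <- sum(r[1:na])
    z <- (W - na * (n + 1) / 2) /
      sqrt(na * (n - na) / (n * (n - 1)) * sum((r - (n + 1) / 2)^2))
    expect_equal(H, z^2, tolerance = 1e-10)
  }
})

test_that("Wilcoxon rank-sum is exact without ties, approximate with", {
  w <- wilcoxon_ranksum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(w$p.value, 0.1)
  expect_equal(wilcoxon_ranksum(c(5, 6, 7), c(5, 6, 7))$p.value, 1)
  ab <- wilcoxon_ranksum(rnorm(6), rnorm(7))
  ba <- wilcoxon_ranksum(rnorm(7), rnorm(6))
  x <- rnorm(6); y <- rnorm(7)
  expect_equal(wilcoxon_ranksum(x, y)$p.value,
               wilcoxon_ranksum(y, x)$p.value)
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "empty")

  # exact path agrees with exhaustive enumeration on a spot check
  set.seed(11)
  a <- rnorm(5); b <- rnorm(6)
  expect_equal(wilcoxon_ranksum(a, b)$p.value, enum_wilcoxon_p(a, b),
               tolerance = 1e-12)
})

test_that("the decision tree routes cells to the appropriate branch", {
  set.seed(12)
  # strong shift in one group: detected through whichever branch is taken
  hits <- 0; parametric <- 0
  n_rep <- 300
  for (i in seq_len(n_rep)) {
    cell <- cell_values(10, c(control = 0, `conventional 2` = 0,
                              `11 % GMO` = 0, `33 % GMO` = 2))
    res <- decision_tree_analyze(cell$values, cell$groups, "control")
    parametric <- parametric + (res$path == "parametric")
    hits <- hits + res$comparisons$significant[
      res$comparisons$group == "33 % GMO"]
  }
  expect_gte(hits / n_rep, 0.95)
  expect_gt(parametric / n_rep, 0.5)

  # heavy-tailed lognormal cells are routed nonparametrically
  set.seed(13)
  nonpar <- mean(replicate(300, {
    cell <- cell_values(10, c(control = 0, `conventional 2` = 0,
                              `11 % GMO` = 0, `33 % GMO` = 0),
                        rfun = function(n) exp(rnorm(n)))
    decision_tree_analyze(cell$values, cell$groups,
                          "control")$path == "nonparametric"
  }))
  expect_gte(nonpar, 0.90)

  # ordinal endpoints skip the gates entirely
  cell <- cell_values(6)
  res <- decision_tree_analyze(round(cell$values), cell$groups, "control",
                               kind = "qualitative-ordinal")
  expect_equal(res$path, "nonparametric")
  expect_null(res$normality)

  # under a fully null normal world the parametric path dominates at the
  # rate implied by the two gates' observed rejection rates
  set.seed(14)
  n_null <- 400
  paths <- replicate(n_null, {
    cell <- cell_values(10)
    res <- decision_tree_analyze(cell$values, cell$groups, "control")
    c(parametric = res$path == "parametric",
      norm_reject = !is.null(res$normality) && res$normality$p.value < 0.05,
      lev_reject = !is.null(res$homogeneity) &&
        res$homogeneity$p.value < 0.05)
  })
  frac <- mean(paths["parametric", ])
  expected <- mean(!paths["norm_reject", ] & !paths["lev_reject", ])
  expect_equal(frac, expected, tolerance = 1e-12) # gates fully explain it
  expect_gte(frac, 0.80) # and both gates hold near their nominal level
  expect_lte(frac, 0.95)
})

test_that("single fixed-method analyses share structure and ordering", {
  design <- small_design(5)
  tab <- simulate_trial(design, dplyr::bind_rows(
    one_endpoint_panel("WBC", mean = 7, sd = 1),
    one_endpoint_panel("RBC", mean = 8, sd = 0.3)
  ), seed = 4)
  cage <- cage_aggregate(tab, design)
  mt <- run_single_method(cage, design, "anova_t")
  md <- run_single_method(cage, design, "anova_dunnett")
  mk <- run_single_method(cage, design, "kw_wilcoxon")

  key <- function(m) paste(m$endpoint, m$gender, m$time, m$comparison)
  expect_identical(key(mt), key(md))
  expect_identical(key(mt), key(mk))
  # p-ordering dominance: every Dunnett flag is also a t flag
  expect_true(all(md$significant <= mt$significant))
})
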