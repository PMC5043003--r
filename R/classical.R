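# internal cache of Monte-Carlo null tables for the Lilliefors statistic;
# the null distribution is distribution-free given n, so one table per
# (n, nsim) serves every call
.lilliefors_cache <- new.env(parent = emptyenv())

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  i <- seq_len(n)
  max(pmax(i / n - p, p - (i - 1) / n))
}

lilliefors_null <- function(n, nsim = 10000L) {
  key <- paste0("n", n, "_s", nsim)
  if (!is.null(.lilliefors_cache[[key]])) return(.lilliefors_cache[[key]])
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(20050131 + n) # fixed internal seed: the table is a constant
  tab <- vapply(seq_len(nsim), function(i) lilliefors_stat(stats::rnorm(n)),
                numeric(1))
  .lilliefors_cache[[key]] <- sort(tab)
  .lilliefors_cache[[key]]
}

#' Kolmogorov-Smirnov normality test with Lilliefors correction
#'
#' KS distance between the empirical distribution and a normal with mean and
#' SD estimated from the sample. Because the parameters are estimated, the
#' classic KS null distribution does not apply (Lilliefors correction); the
#' p-value is taken from a seeded Monte-Carlo null table of the statistic,
#' which is distribution-free given `n` and cached per sample size.
#'
#' @param values Numeric sample, at least 5 finite values.
#' @param alpha Significance level recorded in the result.
#' @param nsim Monte-Carlo draws for the null table.
#' @return An `htest`-like list: `statistic`, `p.value`, `method`, `alpha`.
#' @export
lilliefors_normality <- function(values, alpha = 0.05, nsim = 10000L) {
  x <- values[is.finite(values)]
  if (length(x) < 5) {
    stop("at least 5 finite values are required", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("zero-variance sample: normality test undefined", call. = FALSE)
  }
  D <- lilliefors_stat(x)
  null <- lilliefors_null(length(x), nsim)
  p <- (1 + sum(null >= D)) / (length(null) + 1)
  structure(
    list(statistic = c(D = D), p.value = p, alpha = alpha,
         method = "Lilliefors-corrected Kolmogorov-Smirnov normality test",
         data.name = deparse(substitute(values))),
    class = "htest"
  )
}

#' One-way ANOVA
#'
#' Standard between/within decomposition: `F = MSB / MSW` with
#' `(k - 1, N - k)` df. Zero within-group variance with equal group means
#' returns `F = 0, p = 1`; with unequal means the statistic is reported as
#' `Inf` with `p = 0` and a `degenerate` flag (capped-F convention), so
#' batch analyses never abort.
#'
#' @param values Numeric response.
#' @param groups Grouping vector, same length.
#' @return An `htest`-like list with `statistic`, `parameter` (df),
#'   `p.value`, `degenerate`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  st <- dplyr::tibble(v = values, g = groups) |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$v),
                     sd = stats::sd(.data$v), .groups = "drop")
  anova_from_summary(st$n, st$mean, st$sd)
}

#' One-way ANOVA from group summaries
#'
#' Recomputes the F test from per-group `(n, mean, sd)` alone — the same
#' decomposition as [one_way_anova()], usable directly on printed summary
#' tables.
#'
#' @param n,means,sds Equal-length vectors of group sizes, means, SDs.
#' @return As [one_way_anova()].
#' @export
anova_from_summary <- function(n, means, sds) {
  k <- length(n)
  N <- sum(n)
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((n - 1) * sds^2)
  df1 <- k - 1
  df2 <- N - k
  msb <- ssb / df1
  msw <- ssw / df2
  degenerate <- FALSE
  if (msw == 0) {
    if (msb == 0) {
      f <- 0
      p <- 1
    } else {
      f <- Inf
      p <- 0
      degenerate <- TRUE
    }
  } else {
    f <- msb / msw
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(
    list(statistic = c(F = f), parameter = c(df1 = df1, df2 = df2),
         p.value = p, mse = msw, degenerate = degenerate,
         method = "One-way ANOVA", data.name = "group summaries"),
    class = "htest"
  )
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on absolute deviations from each group's center — the mean
#' for the classic Levene form (default), the median for the
#' Brown-Forsythe variant. Groups whose deviations are all zero contribute
#' zero within-group variance; if all dispersion is identical the statistic
#' is 0 with p = 1, and a zero-MSW/unequal-dispersion configuration follows
#' the capped-F convention of [one_way_anova()].
#'
#' @param values Numeric response.
#' @param groups Grouping vector.
#' @param center `"mean"` or `"median"`.
#' @return As [one_way_anova()].
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- as.factor(groups)
  fun <- if (center == "mean") mean else stats::median
  centers <- tapply(values, groups, fun)
  dev <- abs(values - centers[as.integer(groups)])
  res <- one_way_anova(dev, groups)
  res$method <- paste0("Levene test (center = ", center, ")")
  res
}

#' Pairwise t-tests against control from the pooled ANOVA error
#'
#' For each treatment group, `t = (mean_i - mean_0) / sqrt(MSE (1/n_i +
#' 1/n_0))` with the mean squared error pooled over all groups and
#' `N - k` df; p-values are unadjusted (each comparison at its nominal
#' level). With exactly two groups this is the classic pooled two-sample t.
#'
#' @param values Numeric response.
#' @param groups Grouping vector.
#' @param control Label of the control group.
#' @param two_sided Two-sided p-values (default).
#' @return A tibble: `group`, `estimate`, `t`, `df`, `p`.
#' @export
posthoc_t <- function(values, groups, control, two_sided = TRUE) {
  pre <- dunnett_prep(values, groups, control)
  p <- if (two_sided) {
    2 * stats::pt(abs(pre$t), pre$df, lower.tail = FALSE)
  } else {
    stats::pt(pre$t, pre$df, lower.tail = FALSE)
  }
  tibble::tibble(group = pre$trt, estimate = pre$est, t = pre$t,
                 df = pre$df, p = p)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference (`k - 1` df),
#' computed by [stats::kruskal.test()]. All values tied gives `H = 0`,
#' `p = 1`.
#'
#' @param values Numeric (or ordinal-coded) response.
#' @param groups Grouping vector.
#' @return An `htest` with the usual fields.
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(unique(values)) == 1) {
    return(structure(
      list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
           parameter = c(df = length(unique(groups)) - 1), p.value = 1,
           method = "Kruskal-Wallis rank sum test (all values tied)",
           data.name = "values by groups"),
      class = "htest"
    ))
  }
  stats::kruskal.test(values, as.factor(groups))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact two-sided p by enumeration when the combined sample has at most 20
#' observations and no ties; otherwise the normal approximation with tie and
#' continuity correction ([stats::wilcox.test()] provides both paths).
#'
#' @param a,b Numeric samples (non-empty).
#' @param two_sided Two-sided (default) or greater-than alternative.
#' @return An `htest`.
#' @export
wilcoxon_ranksum <- function(a, b, two_sided = TRUE) {
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  suppressWarnings(stats::wilcox.test(
    a, b, alternative = if (two_sided) "two.sided" else "greater",
    exact = exact, correct = TRUE
  ))
}

#' Decision-tree analysis of one endpoint cell
#'
#' The "classical" testing procedure for one (endpoint, gender, time) cell
#' of cage-level values. Qualitative-ordinal endpoints go straight to the
#' nonparametric branch. Quantitative endpoints are gated: Lilliefors
#' normality on the ANOVA residuals (pooled across groups) and Levene's
#' test at `alpha`; if both pass, the parametric branch runs one-way ANOVA
#' and — when the omnibus test is significant (or `gate = FALSE`) — Dunnett
#' and unadjusted post hoc t comparisons against control. Otherwise the
#' nonparametric branch runs Kruskal-Wallis and pairwise Wilcoxon tests
#' against control under the same gating rule.
#'
#' @param values Cage-level response values for the cell.
#' @param groups Group label per value.
#' @param control Control-group label.
#' @param kind `"quantitative"` or `"qualitative-ordinal"`.
#' @param alpha Significance level for gates, omnibus and comparisons.
#' @param gate Require omnibus significance before per-group comparisons.
#' @param levene_center Passed to [levene_test()].
#' @param all_methods Also fill the flags of the branch not taken (used by
#'   the cross-method comparison).
#' @return A `classical_result` list: `path`, `normality`, `homogeneity`,
#'   `omnibus`, and a `comparisons` tibble with per-group p-values and
#'   significance flags (`dunnett_p`, `t_p`, `wilcoxon_p`, `significant` —
#'   the flag of the test the decision tree prescribes on the taken path:
#'   Dunnett parametrically, Wilcoxon nonparametrically).
#' @export
decision_tree_analyze <- function(values, groups, control,
                                  kind = "quantitative", alpha = 0.05,
                                  gate = TRUE,
                                  levene_center = c("mean", "median"),
                                  all_methods = FALSE) {
  levene_center <- match.arg(levene_center)
  groups <- as.character(groups)
  stopifnot(control %in% groups)
  trt <- setdiff(unique(groups), control)
  degenerate <- stats::sd(values) == 0

  normality <- NULL
  homogeneity <- NULL
  parametric <- FALSE
  if (kind == "quantitative" && !degenerate) {
    centers <- tapply(values, groups, mean)
    resid <- values - centers[groups]
    normality <- tryCatch(lilliefors_normality(resid, alpha),
                          error = function(e) NULL)
    homogeneity <- tryCatch(levene_test(values, groups, levene_center),
                            error = function(e) NULL)
    parametric <- !is.null(normality) && !is.null(homogeneity) &&
      normality$p.value >= alpha && homogeneity$p.value >= alpha
  }
  path <- if (parametric) "parametric" else "nonparametric"

  comp <- tibble::tibble(group = trt, dunnett_p = NA_real_, t_p = NA_real_,
                         wilcoxon_p = NA_real_)
  run_param <- parametric || all_methods
  run_nonpar <- !parametric || all_methods

  omnibus <- NULL
  if (run_param && !degenerate) {
    aov_res <- one_way_anova(values, groups)
    if (parametric) omnibus <- aov_res
    if (!gate || aov_res$p.value < alpha) {
      dt <- dunnett_test(values, groups, control)
      tt <- posthoc_t(values, groups, control)
      comp$dunnett_p <- dt$p_adj[match(comp$group, dt$group)]
      comp$t_p <- tt$p[match(comp$group, tt$group)]
    }
  }
  if (run_nonpar) {
    kw <- kruskal_wallis(values, groups)
    if (!parametric) omnibus <- kw
    if (!gate || kw$p.value < alpha) {
      comp$wilcoxon_p <- vapply(comp$group, function(g) {
        wilcoxon_ranksum(values[groups == g],
                         values[groups == control])$p.value
      }, numeric(1))
    }
  }
  flag_p <- if (parametric) comp$dunnett_p else comp$wilcoxon_p
  comp$significant <- !is.na(flag_p) & flag_p < alpha

  structure(
    list(path = path, degenerate = degenerate, alpha = alpha,
         normality = normality, homogeneity = homogeneity,
         omnibus = omnibus, comparisons = comp),
    class = "classical_result"
  )
}

#' @export
print.classical_result <- function(x, ...) {
  cat("Decision-tree analysis:", x$path, "path\n")
  if (!is.null(x$normality)) {
    cat(sprintf("  normality p = %.4f, homogeneity p = %.4f\n",
                x$normality$p.value, x$homogeneity$p.value))
  }
  if (!is.null(x$omnibus)) {
    cat(sprintf("  omnibus p = %.4f\n", x$omnibus$p.value))
  }
  print(x$comparisons)
  invisible(x)
}

#' Decision-tree analysis of every cell in a cage table
#'
#' Applies [decision_tree_analyze()] to each (endpoint, gender, time) cell.
#'
#' @inheritParams ses_batch
#' @inheritParams decision_tree_analyze
#' @return A tibble with one row per comparison: cell keys, `path`,
#'   assumption p-values, omnibus p, per-test p-values and the decision-tree
#'   significance flag.
#' @export
decision_tree_batch <- function(cage_table, design, alpha = 0.05,
                                gate = TRUE, all_methods = FALSE) {
  cells <- unique(cage_table[, c("gender", "endpoint", "time")])
  cells <- dplyr::arrange(cells, .data$gender, .data$endpoint, .data$time)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- cage_table[cage_table$gender == cells$gender[i] &
                        cage_table$endpoint == cells$endpoint[i] &
                        cage_table$time == cells$time[i], , drop = FALSE]
    if (min(table(sub$group)) < 2 || !design$control %in% sub$group) next
    res <- decision_tree_analyze(
      sub$value, sub$group, design$control,
      kind = sub$kind[1], alpha = alpha, gate = gate,
      all_methods = all_methods
    )
    out[[i]] <- tibble::tibble(
      endpoint = cells$endpoint[i], gender = cells$gender[i],
      time = cells$time[i], comparison = res$comparisons$group,
      path = res$path,
      normality_p = if (is.null(res$normality)) NA_real_ else
        res$normality$p.value,
      homogeneity_p = if (is.null(res$homogeneity)) NA_real_ else
        res$homogeneity$p.value,
      omnibus_p = if (is.null(res$omnibus)) NA_real_ else
        res$omnibus$p.value,
      dunnett_p = res$comparisons$dunnett_p,
      t_p = res$comparisons$t_p,
      wilcoxon_p = res$comparisons$wilcoxon_p,
      significant = res$comparisons$significant
    )
  }
  dplyr::bind_rows(out)
}

#' Single fixed-method analysis of every cell
#'
#' Analyses all cells with one fixed procedure, ignoring the decision tree:
#' `"anova_t"` (ANOVA with unadjusted post hoc t), `"anova_dunnett"` (ANOVA
#' with Dunnett-adjusted comparisons) or `"kw_wilcoxon"` (Kruskal-Wallis
#' with pairwise Wilcoxon). Comparisons are run ungated by default — each
#' cell's per-group tests are evaluated regardless of the omnibus test — so
#' the three methods are compared on identical comparison sets.
#'
#' @inheritParams decision_tree_batch
#' @param method One of `"anova_t"`, `"anova_dunnett"`, `"kw_wilcoxon"`.
#' @return A tibble: cell keys, `comparison`, `p`, `significant`.
#' @export
run_single_method <- function(cage_table, design,
                              method = c("anova_t", "anova_dunnett",
                                         "kw_wilcoxon"),
                              alpha = 0.05, gate = FALSE) {
  method <- match.arg(method)
  cells <- unique(cage_table[, c("gender", "endpoint", "time")])
  cells <- dplyr::arrange(cells, .data$gender, .data$endpoint, .data$time)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- cage_table[cage_table$gender == cells$gender[i] &
                        cage_table$endpoint == cells$endpoint[i] &
                        cage_table$time == cells$time[i], , drop = FALSE]
    if (min(table(sub$group)) < 2 || !design$control %in% sub$group) next
    trt <- setdiff(design$groups, design$control)
    trt <- trt[trt %in% sub$group]
    degenerate <- stats::sd(sub$value) == 0
    p <- rep(NA_real_, length(trt))
    if (!degenerate) {
      gated_off <- FALSE
      if (gate) {
        omni <- if (method == "kw_wilcoxon") {
          kruskal_wallis(sub$value, sub$group)
        } else {
          one_way_anova(sub$value, sub$group)
        }
        gated_off <- omni$p.value >= alpha
      }
      if (!gated_off) {
        p <- switch(
          method,
          anova_t = {
            tt <- posthoc_t(sub$value, sub$group, design$control)
            tt$p[match(trt, tt$group)]
          },
          anova_dunnett = {
            dt <- dunnett_test(sub$value, sub$group, design$control)
            dt$p_adj[match(trt, dt$group)]
          },
          kw_wilcoxon = vapply(trt, function(g) {
            wilcoxon_ranksum(sub$value[sub$group == g],
                             sub$value[sub$group == design$control])$p.value
          }, numeric(1))
        )
      } else {
        p <- rep(1, length(trt))
      }
    }
    out[[i]] <- tibble::tibble(
      endpoint = cells$endpoint[i], gender = cells$gender[i],
      time = cells$time[i], comparison = trt, method = method, p = p,
      significant = !is.na(p) & p < alpha
    )
  }
  dplyr::bind_rows(out)
}
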