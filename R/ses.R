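#' Pooled standard deviation of two groups
#'
#' `sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))` — the denominator
#' of the standardized effect size.
#'
#' @param sd1,sd2 Group standard deviations (non-negative).
#' @param n1,n2 Group sizes (each at least 2).
#' @return The pooled SD.
#' @examples
#' pooled_sd(0.52, 10, 0.96, 10)
#' @export
pooled_sd <- function(sd1, n1, sd2, n2) {
  if (any(n1 < 2) || any(n2 < 2)) {
    stop("each group needs n >= 2 for a pooled SD", call. = FALSE)
  }
  if (any(sd1 < 0) || any(sd2 < 0)) stop("sds must be >= 0", call. = FALSE)
  sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
}

#' Classify a standardized effect against significance and relevance
#'
#' Joint classification of an SES confidence interval against zero
#' (statistical significance) and against the biological relevance limits
#' `(-L, L)`:
#' * case `a`: not significant and CI strictly inside the limits — evidence
#'   for neither a statistical nor a biologically relevant effect;
#' * case `b`: significant but CI not entirely outside the limits —
#'   statistical significance without clear biological relevance;
#' * case `c`: significant and CI entirely outside the limits — potentially
#'   biologically relevant;
#' * case `d`: not significant but CI not contained in the limits —
#'   relevance cannot be clearly negated.
#'
#' Containment uses the open interval and "outside" strict inequalities, so
#' boundary-touching intervals fall into the conservative cases b/d. The
#' four cases are exhaustive and mutually exclusive.
#'
#' @param ci_lo,ci_hi Confidence-interval bounds (vectorized).
#' @param limits Positive relevance limit `L` (the CI is compared with
#'   `c(-L, L)`); default 1 SD.
#' @return A tibble with `case`, `significant`, `relevant`.
#' @examples
#' classify_relevance(-0.3, 0.4) # case a
#' classify_relevance(1.2, 2.4) # case c
#' @export
classify_relevance <- function(ci_lo, ci_hi, limits = 1) {
  stopifnot(limits > 0, all(ci_lo <= ci_hi))
  significant <- ci_lo > 0 | ci_hi < 0
  contained <- ci_lo > -limits & ci_hi < limits
  outside <- ci_lo > limits | ci_hi < -limits
  case <- dplyr::case_when(
    !significant & contained ~ "a",
    significant & !outside ~ "b",
    significant & outside ~ "c",
    TRUE ~ "d"
  )
  tibble::tibble(case = case, significant = significant, relevant = outside)
}

#' Standardized effect size with 95% confidence interval
#'
#' Computes the SES (Cohen's d family: difference of group means divided by
#' the pooled SD) for a treatment-vs-control comparison of experimental
#' units, its large-sample standard error
#' `se_d = sqrt((nC + nT)/(nC nT) + d^2 / (2 (nC + nT - 2)))`,
#' a 95% confidence interval, and the case a--d classification.
#'
#' The default CI multiplier is the standard-normal quantile (1.959964);
#' `ci = "t"` uses the t quantile with `nC + nT - 2` df instead. No
#' small-sample (Hedges) correction is applied unless `hedges = TRUE`: the
#' SES is defined as the plain mean difference over the pooled SD.
#'
#' Zero pooled SD with equal means yields a degenerate result (`d = 0`,
#' undefined CI, flagged); zero pooled SD with unequal means is an error.
#'
#' @param control,treatment Lists or one-row data frames with elements
#'   `mean`, `sd`, `n` summarizing each group's experimental units.
#' @param limits Relevance limit `L` passed to [classify_relevance()].
#' @param ci `"z"` (default) or `"t"` confidence-interval multiplier.
#' @param hedges Apply the Hedges small-sample bias correction to `d`.
#' @return A one-row tibble: `d`, `se_d`, `ci_lo`, `ci_hi`, `n_control`,
#'   `n_treatment`, `case`, `significant`, `relevant`, `degenerate`.
#' @examples
#' ses_estimate(list(mean = 1.85, sd = 0.52, n = 10),
#'              list(mean = 3.65, sd = 0.96, n = 10))
#' @export
ses_estimate <- function(control, treatment, limits = 1,
                         ci = c("z", "t"), hedges = FALSE) {
  ci <- match.arg(ci)
  nc <- control$n
  nt <- treatment$n
  if (nc < 2 || nt < 2) stop("each group needs n >= 2", call. = FALSE)
  sp <- pooled_sd(control$sd, nc, treatment$sd, nt)
  diff <- treatment$mean - control$mean
  if (sp == 0) {
    if (diff != 0) {
      stop("zero pooled SD with unequal means: infinite effect size",
           call. = FALSE)
    }
    return(tibble::tibble(
      d = 0, se_d = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
      n_control = nc, n_treatment = nt, case = NA_character_,
      significant = FALSE, relevant = FALSE, degenerate = TRUE
    ))
  }
  d <- diff / sp
  if (hedges) d <- d * (1 - 3 / (4 * (nc + nt - 2) - 1))
  se_d <- sqrt((nc + nt) / (nc * nt) + d^2 / (2 * (nc + nt - 2)))
  mult <- if (ci == "z") stats::qnorm(0.975) else stats::qt(0.975, nc + nt - 2)
  lo <- d - mult * se_d
  hi <- d + mult * se_d
  cls <- classify_relevance(lo, hi, limits)
  tibble::tibble(
    d = d, se_d = se_d, ci_lo = lo, ci_hi = hi,
    n_control = nc, n_treatment = nt,
    case = cls$case, significant = cls$significant,
    relevant = cls$relevant, degenerate = FALSE
  )
}

#' Power of the two-sample t-test on the SES scale
#'
#' Power of the pooled-variance two-sample t-test for a standardized effect
#' `d` with `n_per_group` experimental units per group, computed from the
#' noncentral t distribution with `2 n - 2` df and noncentrality
#' `d sqrt(n / 2)`.
#'
#' @param d Standardized effect size (difference in means / pooled SD).
#' @param n_per_group Experimental units per group (>= 2).
#' @param alpha Significance level.
#' @param two_sided Two-sided test (default) or one-sided.
#' @return A one-row tibble: `d`, `n_per_group`, `alpha`, `two_sided`,
#'   `power`.
#' @examples
#' ses_power(1.0, 20) # ~0.869
#' @export
ses_power <- function(d, n_per_group, alpha = 0.05, two_sided = TRUE) {
  stopifnot(n_per_group >= 2, alpha > 0, alpha < 1)
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  power <- if (two_sided) {
    crit <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
  } else {
    crit <- stats::qt(1 - alpha, df)
    1 - stats::pt(crit, df, ncp)
  }
  tibble::tibble(d = d, n_per_group = n_per_group, alpha = alpha,
                 two_sided = two_sided, power = power)
}

#' Smallest group size achieving a target power
#'
#' Minimal integer `n` per group with
#' `ses_power(d, n, alpha, two_sided)$power >= target_power`.
#'
#' @inheritParams ses_power
#' @param target_power Target power in (0, 1).
#' @param n_max Search bound.
#' @return The smallest sufficient `n` per group.
#' @examples
#' required_n(1.0, 0.85) # the chronic-design group size is consistent
#' @export
required_n <- function(d, target_power, alpha = 0.05, two_sided = TRUE,
                       n_max = 10000) {
  stopifnot(d != 0, target_power > 0, target_power < 1)
  lo <- 2
  if (ses_power(d, n_max, alpha, two_sided)$power < target_power) {
    stop("target power unreachable within n_max = ", n_max, call. = FALSE)
  }
  hi <- n_max
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (ses_power(d, mid, alpha, two_sided)$power >= target_power) {
      hi <- mid
    } else {
      lo <- mid + 1
    }
  }
  lo
}

#' SES analysis of every endpoint comparison in a trial
#'
#' For each (endpoint, gender, time) cell of an aggregated cage table,
#' compares every non-control group with the control by [ses_estimate()].
#' The number of experimental units is the cage count carrying data in the
#' cell, recorded per comparison. Cells where either group has fewer than 2
#' cages are skipped with a warning; qualitative-ordinal endpoints are
#' excluded (rank-based methods handle them).
#'
#' @param cage_table Output of [cage_aggregate()].
#' @param design A `trial_design` (provides the control label and group
#'   order).
#' @inheritParams ses_estimate
#' @return A tibble of SES results ordered by gender, endpoint, time, group.
#' @export
ses_batch <- function(cage_table, design, limits = 1, ci = c("z", "t"),
                      hedges = FALSE) {
  ci <- match.arg(ci)
  quant <- cage_table[cage_table$kind == "quantitative", , drop = FALSE]
  sums <- group_summary(quant)
  cells <- unique(sums[, c("gender", "endpoint", "time")])
  cells <- dplyr::arrange(cells, .data$gender, .data$endpoint, .data$time)
  out <- vector("list", 0)
  skipped <- 0L
  for (i in seq_len(nrow(cells))) {
    cell <- sums[sums$gender == cells$gender[i] &
                   sums$endpoint == cells$endpoint[i] &
                   sums$time == cells$time[i], , drop = FALSE]
    ctl <- cell[cell$group == design$control, , drop = FALSE]
    if (nrow(ctl) != 1 || ctl$n < 2) {
      skipped <- skipped + 1L
      next
    }
    for (grp in treatment_groups(design)) {
      trt <- cell[cell$group == grp, , drop = FALSE]
      if (nrow(trt) != 1 || trt$n < 2) {
        skipped <- skipped + 1L
        next
      }
      # degenerate zero-variance cells are flagged, never fatal, so a
      # whole-trial batch always completes
      res <- tryCatch(
        ses_estimate(ctl, trt, limits = limits, ci = ci, hedges = hedges),
        error = function(e) tibble::tibble(
          d = NA_real_, se_d = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
          n_control = ctl$n, n_treatment = trt$n, case = NA_character_,
          significant = FALSE, relevant = FALSE, degenerate = TRUE
        )
      )
      out[[length(out) + 1]] <- tibble::tibble(
        endpoint = cells$endpoint[i], gender = cells$gender[i],
        time = cells$time[i], comparison = grp, res
      )
    }
  }
  if (skipped > 0) {
    warning(skipped, " comparison(s) skipped: fewer than 2 cages in a group",
            call. = FALSE)
  }
  dplyr::bind_rows(out)
}
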