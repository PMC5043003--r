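# Whiten a response/design within one cage under continuous-lag AR(1)
# correlation rho^|dt|. The AR(1) process is Markov, so the Cholesky factor
# of the inverse correlation is bidiagonal: w_1 = y_1 and
# w_j = (y_j - r_j y_{j-1}) / sqrt(1 - r_j^2) with r_j = rho^{dt_j}.
# log|R| accumulates as sum log(1 - r_j^2).
ar1_whiten <- function(M, times, rho) {
  M <- as.matrix(M)
  ord <- order(times)
  M <- M[ord, , drop = FALSE]
  t_s <- times[ord]
  n <- length(t_s)
  if (n == 1) return(list(W = M, logdet = 0))
  r <- rho^diff(t_s)
  sc <- sqrt(1 - r^2)
  W <- M
  W[-1, ] <- (M[-1, , drop = FALSE] -
                r * M[-n, , drop = FALSE]) / sc
  list(W = W, logdet = sum(log(1 - r^2)))
}

# REML log-likelihood (up to an additive constant) profiled over beta and
# sigma^2 for a fixed rho, plus the profiled GLS quantities
ar1_reml_eval <- function(y, X, cage, times, rho) {
  Wy <- numeric(0)
  WX <- NULL
  logdet <- 0
  for (cg in unique(cage)) {
    idx <- cage == cg
    wh <- ar1_whiten(cbind(y[idx], X[idx, , drop = FALSE]), times[idx], rho)
    Wy <- c(Wy, wh$W[, 1])
    WX <- rbind(WX, wh$W[, -1, drop = FALSE])
    logdet <- logdet + wh$logdet
  }
  p <- ncol(X)
  n <- length(y)
  XtX <- crossprod(WX)
  qrW <- qr(WX)
  if (qrW$rank < p) {
    aliased <- colnames(X)[qrW$pivot[(qrW$rank + 1):p]]
    stop("singular design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrW, Wy)
  res <- Wy - WX %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  logdet_xtx <- determinant(XtX, logarithm = TRUE)$modulus
  reml <- -0.5 * ((n - p) * log(sigma2) + logdet + as.numeric(logdet_xtx) +
                    (n - p))
  list(reml = reml, beta = beta, sigma2 = sigma2, XtX = XtX)
}

#' Generalized least squares with AR(1) within-cage errors (REML)
#'
#' Fits `value ~ group + time` (optionally `group * time`, optionally plus
#' `gender`) to a longitudinal cage panel, with residuals correlated within
#' cage as continuous-lag AR(1): `cor(e_s, e_t) = rho^|s - t|`, which
#' handles the weekly-then-biweekly recording schedule naturally. `rho` is
#' estimated by maximizing the restricted (REML) likelihood, profiled over
#' the fixed effects and residual variance, with a bounded scalar search on
#' (-0.99, 0.99); the procedure is deterministic.
#'
#' Group offsets are parameterized as treatment-minus-control contrasts
#' (control is the reference level), so each non-control coefficient is
#' directly the contrast of interest; p-values use `n - p` df.
#'
#' @param data Data frame with at least `cage_id`, `group`, a time column
#'   and a response column (e.g. from [simulate_linear_panel()], or a cage
#'   table filtered to one longitudinal endpoint).
#' @param control Control-group label (reference level).
#' @param response,time_col,cage_col Column names.
#' @param gender_col Optional gender column to include as a fixed factor
#'   (pooled-gender analysis); `NULL` to omit.
#' @param interaction Include a group-by-time interaction.
#' @return A `gls_ar1_fit`: `beta`, `vcov`, `rho`, `sigma2`, `logLik_reml`,
#'   `df_resid`, `contrasts` (group offsets vs control with SE, t, p),
#'   `converged`, plus the model frame needed for [lsmeans()] and
#'   [reml_profile()].
#' @export
fit_gls_ar1 <- function(data, control, response = "value",
                        time_col = "week", cage_col = "cage_id",
                        gender_col = NULL, interaction = FALSE) {
  df <- as.data.frame(data)
  for (col in c(response, time_col, cage_col, "group")) {
    if (!col %in% names(df)) stop("missing column: ", col, call. = FALSE)
  }
  if (!control %in% df$group) stop("control group absent", call. = FALSE)
  df$group <- stats::relevel(factor(df$group), ref = control)
  # a single shared time point degenerates to a cross-sectional comparison:
  # drop the (constant) time regressor so the design stays full rank
  single_time <- length(unique(df[[time_col]])) < 2
  form <- if (single_time) {
    "~ group"
  } else {
    paste("~ group", if (interaction) "*" else "+", time_col)
  }
  if (!is.null(gender_col)) form <- paste(form, "+", gender_col)
  X <- stats::model.matrix(stats::as.formula(form), df)
  y <- df[[response]]
  cage <- df[[cage_col]]
  times <- df[[time_col]]

  crit <- function(rho) ar1_reml_eval(y, X, cage, times, rho)$reml
  opt <- stats::optimize(crit, c(-0.99, 0.99), maximum = TRUE,
                         tol = 1e-6)
  fit <- ar1_reml_eval(y, X, cage, times, opt$maximum)
  vcov <- fit$sigma2 * solve(fit$XtX)
  p <- ncol(X)
  n <- length(y)
  grp_terms <- grep("^group", colnames(X), value = TRUE)
  grp_terms <- grp_terms[!grepl(":", grp_terms)]
  est <- fit$beta[grp_terms]
  se <- sqrt(diag(vcov)[grp_terms])
  tv <- est / se
  contrasts <- tibble::tibble(
    group = sub("^group", "", grp_terms), estimate = as.numeric(est),
    se = as.numeric(se), t = as.numeric(tv), df = n - p,
    p = 2 * stats::pt(abs(tv), n - p, lower.tail = FALSE)
  )
  structure(
    list(beta = fit$beta, vcov = vcov, rho = opt$maximum,
         sigma2 = fit$sigma2, logLik_reml = opt$objective,
         df_resid = n - p, contrasts = contrasts,
         converged = TRUE, control = control,
         model = list(y = y, X = X, cage = cage, times = times,
                      formula = form, time_col = time_col,
                      group_levels = levels(df$group))),
    class = "gls_ar1_fit"
  )
}

#' @export
print.gls_ar1_fit <- function(x, ...) {
  cat(sprintf("AR(1) REML GLS fit: rho = %.4f, sigma = %.4f, REML = %.3f\n",
              x$rho, sqrt(x$sigma2), x$logLik_reml))
  cat("Contrasts vs", x$control, ":\n")
  print(x$contrasts)
  invisible(x)
}

#' REML criterion of a fit at given AR parameters
#'
#' Re-evaluates the profiled REML criterion of a [fit_gls_ar1()] model at
#' arbitrary `rho` values (diagnostic for the profile's shape; the fitted
#' `rho` maximizes this curve).
#'
#' @param fit A `gls_ar1_fit`.
#' @param rho Vector of AR(1) parameters in (-1, 1).
#' @return Numeric vector of REML criterion values.
#' @export
reml_profile <- function(fit, rho) {
  m <- fit$model
  vapply(rho, function(r) {
    ar1_reml_eval(m$y, m$X, m$cage, m$times, r)$reml
  }, numeric(1))
}

#' Overall group effect of an AR(1) GLS fit
#'
#' Wald F test that all group terms (offsets and, if present, group-by-time
#' interactions) are zero. With a single time point per cage and no time
#' trend this reduces to the one-way ANOVA F on cage values.
#'
#' @param fit A `gls_ar1_fit`.
#' @return An `htest`-like list with `statistic`, `parameter`, `p.value`.
#' @export
group_wald_f <- function(fit) {
  terms <- grep("^group", colnames(fit$model$X))
  L <- length(terms)
  b <- fit$beta[terms]
  V <- fit$vcov[terms, terms, drop = FALSE]
  f <- as.numeric(t(b) %*% solve(V, b)) / L
  structure(
    list(statistic = c(F = f), parameter = c(df1 = L, df2 = fit$df_resid),
         p.value = stats::pf(f, L, fit$df_resid, lower.tail = FALSE),
         method = "Wald F test for group terms", data.name = "gls_ar1_fit"),
    class = "htest"
  )
}

#' Least-square means and contrasts at a chosen week
#'
#' Model-predicted group means at `at_week` with delta-method standard
#' errors, and their differences from the control group with t-based
#' p-values (`df = n - p`). These adjusted means are the quantities the SES
#' analysis of longitudinal endpoints standardizes. Extrapolation beyond the
#' observed time range warns.
#'
#' @param fit A `gls_ar1_fit`.
#' @param at_week Week at which to evaluate the means.
#' @return A list with `means` (tibble: group, lsmean, se) and `contrasts`
#'   (tibble: group, estimate, se, t, df, p).
#' @export
lsmeans <- function(fit, at_week) {
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  m <- fit$model
  if (at_week < min(m$times) || at_week > max(m$times)) {
    warning("at_week is outside the observed time range (extrapolation)",
            call. = FALSE)
  }
  levels <- m$group_levels
  Xcols <- colnames(m$X)
  rowfor <- function(grp) {
    x <- stats::setNames(numeric(length(Xcols)), Xcols)
    x["(Intercept)"] <- 1
    if (m$time_col %in% Xcols) x[m$time_col] <- at_week
    gterm <- paste0("group", grp)
    if (gterm %in% Xcols) x[gterm] <- 1
    iterm <- paste0(gterm, ":", m$time_col)
    if (iterm %in% Xcols) x[iterm] <- at_week
    # any further fixed factors (e.g. gender) evaluated at reference level
    x
  }
  L <- t(vapply(levels, rowfor, numeric(length(Xcols))))
  mu <- as.numeric(L %*% fit$beta)
  se <- sqrt(rowSums((L %*% fit$vcov) * L))
  means <- tibble::tibble(group = levels, lsmean = mu, se = se)
  ctl <- which(levels == fit$control)
  Ld <- L[-ctl, , drop = FALSE] -
    matrix(L[ctl, ], nrow(L) - 1, ncol(L), byrow = TRUE)
  est <- as.numeric(Ld %*% fit$beta)
  sed <- sqrt(rowSums((Ld %*% fit$vcov) * Ld))
  tv <- est / sed
  contrasts <- tibble::tibble(
    group = levels[-ctl], estimate = est, se = sed, t = tv,
    df = fit$df_resid,
    p = 2 * stats::pt(abs(tv), fit$df_resid, lower.tail = FALSE)
  )
  list(means = means, contrasts = contrasts)
}
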