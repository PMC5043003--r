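#' Default endpoint panel for synthetic trials
#'
#' A panel of quantitative endpoints emulating the scope of a chronic
#' rodent feeding study: haematology and clinical biochemistry measured at
#' every panel month, and relative organ weights at necropsy only. Control
#' means and cage-level SDs are anchored to values typical of year-old
#' Wistar rats (haematology/biochemistry per gender; organ weights as
#' percent of body weight); where no printed anchor exists the values are
#' realistic conventions, chosen once.
#'
#' `w` is the within-cage variance share: the fraction of the cage-mean
#' variance contributed by animal-level residuals (see [simulate_trial()]).
#'
#' @return A tibble with one row per endpoint and gender: `endpoint`,
#'   `class`, `gender`, `mean`, `sd`, `w`, `dist`, `kind`, `terminal_only`.
#' @export
default_endpoint_panel <- function() {
  haem <- tibble::tribble(
    ~endpoint,          ~male_mean, ~male_sd, ~female_mean, ~female_sd,
    "WBC",                    8.0,      1.1,          6.0,       1.4,
    "RBC",                    8.3,      0.25,         7.6,       0.3,
    "HGB",                   16.3,      0.5,         15.5,       0.5,
    "HCT",                   46.0,      1.4,         44.0,       1.6,
    "MCV",                   55.6,      1.2,         57.6,       1.0,
    "MCH",                   19.7,      0.55,        20.5,       0.8,
    "MCHC",                  35.4,      0.5,         35.1,       1.0,
    "PLT",                  715.0,    115.0,        725.0,     125.0,
    "LYM",                    5.8,      1.1,          3.9,       0.9,
    "lymphocytes_pct",       68.0,      4.5,         69.5,       5.0,
    "neutrophils_pct",       27.0,      4.2,         25.5,       5.0,
    "monocytes_pct",          3.0,      0.8,          2.6,       0.8,
    "eosinophils_pct",        2.1,      0.8,          2.4,       1.0
  )
  haem$class <- "haematology"
  biochem <- tibble::tribble(
    ~endpoint, ~male_mean, ~male_sd, ~female_mean, ~female_sd,
    "ALP",          1.3,      0.18,         0.62,      0.15,
    "ALT",          0.41,     0.08,         0.55,      0.25,
    "AST",          2.5,      0.45,         2.3,       0.5,
    "ALB",         40.0,      1.9,         42.8,       2.5,
    "TP",          69.0,      2.1,         71.5,       2.9,
    "GLU",          6.2,      0.9,          5.6,       0.8,
    "K",            4.9,      0.5,          5.0,       0.6,
    "Na",         144.8,      1.7,        142.0,       1.9,
    "P",            2.1,      0.25,         2.0,       0.3,
    "Ca",           2.6,      0.1,          2.6,       0.12,
    "CHOL",         2.2,      0.4,          2.0,       0.4,
    "TG",           1.4,      0.5,          0.9,       0.3,
    "CREA",        38.0,      4.0,         43.0,       5.0,
    "UREA",         6.3,      0.8,          7.1,       1.0,
    "BIL",          2.4,      0.6,          2.7,       0.7,
    "AMYL",        24.0,      3.5,         17.0,       3.0
  )
  biochem$class <- "biochemistry"
  organ <- tibble::tribble(
    ~endpoint,              ~male_mean, ~male_sd, ~female_mean, ~female_sd,
    "kidney_right_relwt",        0.234,    0.018,        0.270,     0.020,
    "kidney_left_relwt",         0.219,    0.015,        0.258,     0.019,
    "spleen_relwt",              0.182,    0.020,        0.200,     0.025,
    "liver_relwt",               2.370,    0.122,        2.600,     0.170,
    "adrenal_right_relwt",       0.004,    0.0006,       0.009,     0.0013,
    "adrenal_left_relwt",        0.004,    0.0006,       0.009,     0.0013,
    "lung_relwt",                0.247,    0.020,        0.340,     0.030,
    "heart_relwt",               0.207,    0.010,        0.270,     0.018,
    "thymus_relwt",              0.095,    0.018,        0.110,     0.022,
    "pancreas_relwt",            0.124,    0.023,        0.160,     0.030,
    "brain_relwt",               0.391,    0.037,        0.560,     0.045,
    "heart_abswt",               2.05,     0.12,         1.60,      0.10
  )
  organ$class <- "organ"
  panel <- dplyr::bind_rows(haem, biochem, organ)
  long <- tidyr::pivot_longer(
    panel,
    cols = c("male_mean", "male_sd", "female_mean", "female_sd"),
    names_to = c("gender", ".value"), names_sep = "_"
  )
  long$w <- 0.5
  long$dist <- "normal"
  long$kind <- "quantitative"
  long$terminal_only <- long$class == "organ"
  long[, c("endpoint", "class", "gender", "mean", "sd", "w", "dist",
           "kind", "terminal_only")]
}

#' Effect specification for synthetic trials
#'
#' Builds the mapping `(group, gender, endpoint, time) -> delta`, where
#' `delta` is the group effect in units of the control cage-mean SD (the
#' scale on which the standardized effect size is defined, and on which the
#' study's power statement is made). The control group always has
#' `delta = 0`.
#'
#' @param group,gender,endpoint,time,delta Equal-length vectors (recycled by
#'   [tibble::tibble()]). Omit all for a null (no-effect) specification.
#' @return A tibble with class `effect_spec` columns.
#' @export
effect_spec <- function(group = character(), gender = character(),
                        endpoint = character(), time = numeric(),
                        delta = numeric()) {
  tibble::tibble(group = group, gender = gender, endpoint = endpoint,
                 time = time, delta = delta)
}

# deterministic 31-adic string hash, kept below 2^31 - 1
endpoint_hash <- function(name) {
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147483647
  h
}

# per-endpoint RNG stream: evaluate expr with a seed derived from the global
# seed and the endpoint name, then restore the caller's RNG state, so adding
# or reordering endpoints never perturbs the draws of existing ones
with_endpoint_seed <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((seed + endpoint_hash(name)) %% 2147483647)
  expr
}

cage_ids <- function(design, gender) {
  g <- substr(gender, 1, 1)
  unlist(lapply(seq_along(design$groups), function(gi) {
    sprintf("%s_g%d_c%02d", g, gi, seq_len(design$cages_per_group_per_gender))
  }))
}

#' Simulate a complete endpoint-panel trial
#'
#' Generates per-animal values with the hierarchical structure the analysis
#' assumes. For a quantitative endpoint with control mean `mu`, cage-mean SD
#' `sigma` and within-cage share `w`, an animal value in a cage of `m`
#' animals is
#' \deqn{y = \mu + \delta\,\sigma + u_{cage} + \varepsilon,\quad
#'   u_{cage} \sim N(0, (1-w)\sigma^2),\
#'   \varepsilon \sim N(0, w\,\sigma^2 m),}
#' so the cage mean has variance exactly `sigma^2` and the group effect
#' `delta` is expressed on the cage-mean SD scale — the directly recoverable
#' quantity of the SES analysis. Lognormal endpoints apply the same
#' construction on the log scale; ordinal endpoints threshold the latent
#' normal into ordered grades.
#'
#' Interim panel months measure the first `subsample_n` animals per group
#' (complete cages); the last month measures all animals. One global seed
#' drives a per-endpoint stream, so the same seed yields byte-identical
#' tables and endpoints can be added without perturbing existing ones.
#'
#' @param design A `trial_design`.
#' @param endpoints Endpoint panel tibble (see [default_endpoint_panel()]);
#'   one row per endpoint and gender.
#' @param effects An [effect_spec()] tibble, or `NULL` for a null trial.
#' @param seed Non-negative integer seed.
#' @param bin_edges Named list of latent-scale cut points for
#'   qualitative-ordinal endpoints.
#' @return A per-animal measurement tibble (see [read_measurements()]).
#' @export
simulate_trial <- function(design, endpoints = default_endpoint_panel(),
                           effects = NULL, seed = 1, bin_edges = list()) {
  stopifnot(inherits(design, "trial_design"), seed >= 0)
  effects <- effects %||% effect_spec()
  if (any(effects$group == design$control & effects$delta != 0)) {
    stop("control-group effects must be zero", call. = FALSE)
  }
  m <- design$animals_per_cage
  n_cage <- design$cages_per_group_per_gender
  months <- design$observation_months
  terminal <- months[length(months)]
  sub_cages <- min(n_cage, ceiling(design$subsample_n / m))

  pieces <- lapply(sort(unique(endpoints$endpoint)), function(ep) {
    spec_ep <- endpoints[endpoints$endpoint == ep, , drop = FALSE]
    with_endpoint_seed(seed, ep, {
      rows <- list()
      for (gender in design$genders) {
        spec <- spec_ep[spec_ep$gender == gender, , drop = FALSE]
        if (nrow(spec) != 1) {
          stop("endpoint spec missing cell: ", ep, " / ", gender,
               call. = FALSE)
        }
        ep_months <- if (isTRUE(spec$terminal_only)) terminal else months
        for (time in ep_months) {
          use_cages <- if (time < terminal) sub_cages else n_cage
          for (gi in seq_along(design$groups)) {
            group <- design$groups[gi]
            delta <- effect_lookup(effects, group, gender, ep, time)
            mu <- spec$mean + delta * spec$sd
            u <- stats::rnorm(use_cages, 0, sqrt((1 - spec$w) * spec$sd^2))
            eps <- stats::rnorm(use_cages * m, 0,
                                sqrt(spec$w * spec$sd^2 * m))
            latent <- rep(mu + u, each = m) + eps
            value <- switch(
              spec$dist,
              normal = latent,
              lognormal = exp(latent),
              stop("unknown distribution: ", spec$dist, call. = FALSE)
            )
            if (spec$kind == "qualitative-ordinal") {
              edges <- bin_edges[[ep]]
              if (is.null(edges)) {
                stop("ordinal endpoint without bin edges: ", ep,
                     call. = FALSE)
              }
              value <- as.numeric(cut(latent, c(-Inf, edges, Inf),
                                      labels = FALSE)) - 1
            }
            cid <- sprintf("%s_g%d_c%02d", substr(gender, 1, 1), gi,
                           seq_len(use_cages))
            rows[[length(rows) + 1]] <- tibble::tibble(
              animal_id = paste0(rep(cid, each = m), "_a", seq_len(m)),
              cage_id = rep(cid, each = m),
              gender = gender, group = group, endpoint = ep,
              time = time, value = value, kind = spec$kind
            )
          }
        }
      }
      dplyr::bind_rows(rows)
    })
  })
  dplyr::bind_rows(pieces)
}

effect_lookup <- function(effects, group, gender, endpoint, time) {
  hit <- effects$group == group & effects$gender == gender &
    effects$endpoint == endpoint & effects$time == time
  if (any(hit)) effects$delta[hit][1] else 0
}

#' Default growth and feed-intake parameters
#'
#' Monomolecular growth `W(t) = A - (A - W0) exp(-k t)` per gender, with
#' asymptotes calibrated so control animals reach ~594 g (males) and ~365 g
#' (females) at week 53; a saturating feed-intake curve per animal-week; a
#' per-animal asymptote CV and a multiplicative measurement CV.
#'
#' @return A tibble with one row per gender.
#' @export
default_growth_spec <- function() {
  tibble::tribble(
    ~gender,   ~W0,  ~A,   ~k,    ~animal_cv, ~cv,   ~feed_baseline,
    ~feed_plateau, ~feed_plateau_scale,
    "male",    150,  600,  0.082, 0.05,       0.01,  130, 180, 6,
    "female",  120,  370,  0.075, 0.05,       0.01,  100, 125, 6
  )
}

#' Simulate longitudinal body weight and feed consumption
#'
#' Body weight per animal: weekly for the first `design$weekly_weeks` weeks,
#' then biweekly to `design$total_weeks`. Each animal gets a lognormal
#' asymptote perturbation (CV `animal_cv`) and multiplicative observation
#' noise (CV `cv`); `cv = 0` and `animal_cv = 0` give the exact deterministic
#' curve. Feed consumption is generated directly at cage level as the total
#' over each recording period (feed is recorded jointly for a cage, so no
#' per-animal values exist), under endpoint name `"feed_consumption"`.
#'
#' Group effects enter as additive offsets on the asymptote `A`, in grams,
#' via `effects_A` (tibble with `group`, `gender`, `dA`).
#'
#' @inheritParams simulate_trial
#' @param growth Growth spec tibble (see [default_growth_spec()]).
#' @param effects_A Optional tibble of asymptote offsets.
#' @return A longitudinal measurement tibble; `time` is the week index.
#' @export
simulate_growth <- function(design, growth = default_growth_spec(),
                            effects_A = NULL, seed = 1) {
  stopifnot(inherits(design, "trial_design"))
  weeks <- c(seq_len(design$weekly_weeks),
             seq(design$weekly_weeks + 2, design$total_weeks, by = 2))
  m <- design$animals_per_cage
  with_endpoint_seed(seed, "body_weight", {
    rows <- list()
    for (gender in design$genders) {
      g <- growth[growth$gender == gender, , drop = FALSE]
      stopifnot(nrow(g) == 1)
      for (gi in seq_along(design$groups)) {
        group <- design$groups[gi]
        dA <- 0
        if (!is.null(effects_A)) {
          hit <- effects_A$group == group & effects_A$gender == gender
          if (any(hit)) dA <- effects_A$dA[hit][1]
        }
        cid <- sprintf("%s_g%d_c%02d", substr(gender, 1, 1), gi,
                       seq_len(design$cages_per_group_per_gender))
        aid <- paste0(rep(cid, each = m), "_a", seq_len(m))
        A_i <- (g$A + dA) * exp(stats::rnorm(length(aid), 0, g$animal_cv))
        for (j in seq_along(aid)) {
          curve <- A_i[j] - (A_i[j] - g$W0) * exp(-g$k * weeks)
          noise <- exp(stats::rnorm(length(weeks), 0, g$cv))
          rows[[length(rows) + 1]] <- tibble::tibble(
            animal_id = aid[j], cage_id = rep(cid, each = m)[j],
            gender = gender, group = group, endpoint = "body_weight",
            time = weeks, value = curve * noise, kind = "quantitative"
          )
        }
      }
    }
    bw <- dplyr::bind_rows(rows)
    feed <- simulate_feed(design, growth, weeks, m)
    dplyr::bind_rows(bw, feed)
  })
}

# cage-level feed totals per recording period; uses the ambient RNG stream
simulate_feed <- function(design, growth, weeks, m) {
  period_len <- ifelse(weeks <= design$weekly_weeks, 1, 2)
  rows <- list()
  for (gender in design$genders) {
    g <- growth[growth$gender == gender, , drop = FALSE]
    intake_per_week <- g$feed_plateau -
      (g$feed_plateau - g$feed_baseline) * exp(-weeks / g$feed_plateau_scale)
    for (gi in seq_along(design$groups)) {
      cid <- sprintf("%s_g%d_c%02d", substr(gender, 1, 1), gi,
                     seq_len(design$cages_per_group_per_gender))
      for (cc in cid) {
        noise <- exp(stats::rnorm(length(weeks), 0, 0.03))
        rows[[length(rows) + 1]] <- tibble::tibble(
          animal_id = cc, cage_id = cc, gender = gender,
          group = design$groups[gi], endpoint = "feed_consumption",
          time = weeks, value = intake_per_week * period_len * m * noise,
          kind = "quantitative"
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a linear AR(1) cage panel
#'
#' A minimal longitudinal data-generating process for exercising the AR(1)
#' REML fit: per cage, `y_t = intercept + offset[group] + slope * t + e_t`
#' with stationary AR(1) errors (`e_t = rho * e_(t-1) + innovation`,
#' marginal SD `sigma`).
#'
#' @param groups Group labels; the first is the control (offset 0 unless
#'   given).
#' @param offsets Named numeric vector of group offsets (units of `y`).
#' @param intercept,slope Fixed-effect parameters.
#' @param rho AR(1) correlation at lag 1 week, in (-1, 1).
#' @param sigma Marginal residual SD.
#' @param n_per_group Cages per group.
#' @param weeks Vector of observation weeks.
#' @param seed Integer seed.
#' @return A tibble with `cage_id`, `group`, `week`, `value`.
#' @export
simulate_linear_panel <- function(groups = c("control", "treated"),
                                  offsets = c(treated = -20),
                                  intercept = 300, slope = 5,
                                  rho = 0.6, sigma = 10,
                                  n_per_group = 10, weeks = 1:20,
                                  seed = 1) {
  stopifnot(abs(rho) < 1, sigma > 0)
  set.seed(seed %% 2147483647)
  rows <- list()
  for (gi in seq_along(groups)) {
    off <- if (groups[gi] %in% names(offsets)) offsets[[groups[gi]]] else 0
    for (cc in seq_len(n_per_group)) {
      e <- numeric(length(weeks))
      e[1] <- stats::rnorm(1, 0, sigma)
      for (t in seq_along(weeks)[-1]) {
        r <- rho^(weeks[t] - weeks[t - 1])
        e[t] <- r * e[t - 1] + stats::rnorm(1, 0, sigma * sqrt(1 - r^2))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        cage_id = sprintf("g%d_c%02d", gi, cc), group = groups[gi],
        week = weeks, value = intercept + off + slope * weeks + e
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Full default synthetic trial fixture
#'
#' One complete panel trial under the default design and endpoint panel with
#' no group effects; its SES analysis yields about 600 endpoint comparisons
#' (3 comparisons x 2 genders x ~100 endpoint-time cells), echoing the scale
#' of a real one-year study.
#'
#' @param seed Integer seed.
#' @return A per-animal measurement tibble.
#' @export
make_panel_fixture <- function(seed = 1) {
  simulate_trial(default_design(), default_endpoint_panel(), NULL, seed)
}
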