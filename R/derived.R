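#' Feed efficiency
#'
#' Weight gain over a recording period divided by feed intake in the same
#' period, expressed as a percentage: `100 * gain / intake`. Negative gains
#' (weight loss) are allowed and propagate their sign.
#'
#' @param weight_gain_g Weight gain in grams (per cage and period).
#' @param feed_intake_g Feed intake in grams over the same period; must be
#'   strictly positive.
#' @return Feed efficiency in percent.
#' @examples
#' feed_efficiency(50, 200) # 25
#' @export
feed_efficiency <- function(weight_gain_g, feed_intake_g) {
  if (any(!is.finite(feed_intake_g)) || any(feed_intake_g <= 0)) {
    stop("feed_intake_g must be finite and > 0", call. = FALSE)
  }
  100 * weight_gain_g / feed_intake_g
}

#' Relative organ weight
#'
#' Organ weight as a percentage of terminal body weight:
#' `100 * organ / body`.
#'
#' @param organ_g Organ weight in grams (non-negative).
#' @param body_g Body weight in grams; must be strictly positive.
#' @return Relative organ weight in percent.
#' @examples
#' relative_organ_weight(14.08, 594) # ~2.37, a typical male rat liver
#' @export
relative_organ_weight <- function(organ_g, body_g) {
  if (any(!is.finite(body_g)) || any(body_g <= 0)) {
    stop("body_g must be finite and > 0", call. = FALSE)
  }
  if (any(organ_g < 0)) stop("organ_g must be >= 0", call. = FALSE)
  100 * organ_g / body_g
}

#' Tukey-fence extreme-value screening
#'
#' Marks values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by
#' linear interpolation of order statistics (type 7). Screening only marks
#' records — it never removes them; downstream inference always sees the
#' full data.
#'
#' @param values Numeric vector; at least 4 finite values are needed for
#'   meaningful fences (fewer returns no flags, with a warning).
#' @return A tibble with `value`, `fence_low`, `fence_high`, `flagged`.
#' @examples
#' flag_extremes(c(1:9, 100))
#' @export
flag_extremes <- function(values) {
  out <- tibble::tibble(value = as.numeric(values),
                        fence_low = NA_real_, fence_high = NA_real_,
                        flagged = FALSE)
  finite <- is.finite(out$value)
  if (sum(finite) < 4) {
    warning("fewer than 4 finite values: no extreme-value flags computed",
            call. = FALSE)
    return(out)
  }
  q <- stats::quantile(out$value[finite], c(0.25, 0.75), type = 7,
                       names = FALSE)
  iqr <- q[2] - q[1]
  out$fence_low <- q[1] - 1.5 * iqr
  out$fence_high <- q[2] + 1.5 * iqr
  out$flagged <- finite &
    (out$value < out$fence_low | out$value > out$fence_high)
  out
}

#' Ingested contaminant dose from feed concentration
#'
#' Converts a contaminant concentration in feed to a body-weight-normalized
#' daily dose: `conc [mg/kg feed] * intake [g/day] / body weight [g]`
#' yields mg per kg body weight per day (the g/kg factors cancel).
#'
#' @param conc_mg_per_kg_feed Contaminant concentration in feed (mg/kg).
#' @param intake_g_per_day Daily feed intake (g/day).
#' @param body_weight_g Body weight (g); must be strictly positive.
#' @return Dose in mg per kg body weight per day.
#' @examples
#' dose_from_feed(5, 20, 500) # 0.2
#' @export
dose_from_feed <- function(conc_mg_per_kg_feed, intake_g_per_day,
                           body_weight_g) {
  if (any(!is.finite(body_weight_g)) || any(body_weight_g <= 0)) {
    stop("body_weight_g must be finite and > 0", call. = FALSE)
  }
  if (any(conc_mg_per_kg_feed < 0) || any(intake_g_per_day < 0)) {
    stop("concentration and intake must be >= 0", call. = FALSE)
  }
  conc_mg_per_kg_feed * intake_g_per_day / body_weight_g
}

#' Diet inclusion-level ratio
#'
#' Ratio of an analyte level between the high- and low-inclusion diets,
#' rounded to a number of significant figures (round-half-even, the R
#' default). Used as a QC check that measured transgene/protein levels scale
#' with the nominal inclusion rates.
#'
#' @param level_high Analyte level in the high-inclusion diet.
#' @param level_low Analyte level in the low-inclusion diet; must be > 0.
#' @param sig_figs Significant figures to round to.
#' @return The rounded ratio.
#' @examples
#' dose_ratio(31.3, 10.4) # 3
#' dose_ratio(1.27, 0.6) # 2.1
#' @export
dose_ratio <- function(level_high, level_low, sig_figs = 2) {
  if (any(!is.finite(level_low)) || any(level_low <= 0)) {
    stop("level_low must be finite and > 0", call. = FALSE)
  }
  signif(level_high / level_low, sig_figs)
}
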