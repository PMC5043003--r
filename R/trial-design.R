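#' Trial design description
#'
#' A `trial_design` captures the layout of a chronic feeding trial in which
#' cages (each housing a fixed number of animals) are the experimental units:
#' the diet groups with one designated control, the genders, cages per
#' group-by-gender cell, animals per cage, the panel sampling months, and the
#' recording schedule for the longitudinal series (weekly for an initial
#' block of weeks, biweekly afterwards).
#'
#' @param groups Character vector of diet group labels (order is kept).
#' @param control Label of the control group; must appear in `groups`.
#' @param genders Character vector of gender labels.
#' @param cages_per_group_per_gender Number of cages per (group, gender) cell
#'   (at least 2, so group dispersion is estimable).
#' @param animals_per_cage Animals housed per cage (at least 1).
#' @param observation_months Strictly increasing vector of panel sampling
#'   times in months.
#' @param weekly_weeks Number of initial weeks with weekly recording before
#'   the schedule switches to biweekly.
#' @param total_weeks Last week of the trial.
#' @param subsample_n Animals per group sampled at interim (non-terminal)
#'   panel months.
#'
#' @return An object of class `trial_design`.
#' @examples
#' d <- default_design()
#' d$groups
#' @export
trial_design <- function(groups,
                         control,
                         genders = c("male", "female"),
                         cages_per_group_per_gender = 10,
                         animals_per_cage = 2,
                         observation_months = c(3, 6, 12),
                         weekly_weeks = 13,
                         total_weeks = 53,
                         subsample_n = 10) {
  stopifnot(is.character(groups), length(groups) >= 2, !anyDuplicated(groups))
  if (!is.character(control) || length(control) != 1L || !control %in% groups) {
    stop("`control` must name exactly one of `groups`", call. = FALSE)
  }
  if (cages_per_group_per_gender < 2) {
    stop("at least 2 cages per group and gender are required", call. = FALSE)
  }
  if (animals_per_cage < 1) stop("animals_per_cage must be >= 1", call. = FALSE)
  if (is.unsorted(observation_months, strictly = TRUE)) {
    stop("observation_months must be strictly increasing", call. = FALSE)
  }
  structure(
    list(
      groups = groups,
      control = control,
      genders = genders,
      cages_per_group_per_gender = as.integer(cages_per_group_per_gender),
      animals_per_cage = as.integer(animals_per_cage),
      observation_months = observation_months,
      weekly_weeks = as.integer(weekly_weeks),
      total_weeks = as.integer(total_weeks),
      subsample_n = as.integer(subsample_n)
    ),
    class = "trial_design"
  )
}

#' Default one-year feeding-trial design
#'
#' Four diet groups (a control fed near-isogenic maize, a second conventional
#' variety, and the test article at two inclusion rates), two genders, ten
#' cages of two animals per group and gender, endpoint panels at months 3, 6
#' and 12 (ten animals per group at the interim months, all at termination),
#' and weekly body-weight/feed recording for 13 weeks followed by biweekly
#' recording to week 53.
#'
#' @return A `trial_design`.
#' @export
default_design <- function() {
  trial_design(
    groups = c("control", "conventional 2", "11 % GMO", "33 % GMO"),
    control = "control"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Trial design:", length(x$groups), "groups x", length(x$genders),
      "genders x", x$cages_per_group_per_gender, "cages x",
      x$animals_per_cage, "animals/cage\n")
  cat("  groups:  ", paste(x$groups, collapse = ", "),
      " (control: ", x$control, ")\n", sep = "")
  cat("  panels at months:", paste(x$observation_months, collapse = ", "), "\n")
  cat("  weekly to week", x$weekly_weeks, "then biweekly to week",
      x$total_weeks, "\n")
  invisible(x)
}

#' Read or write a trial design as YAML/JSON
#'
#' The on-disk document is a flat mapping of the `trial_design` fields; the
#' format is chosen from the file extension (`.yml`/`.yaml` or `.json`).
#'
#' @param path File path.
#' @return `read_design()` returns a `trial_design`; `write_design()` returns
#'   `path` invisibly.
#' @export
read_design <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  needed <- c("groups", "control")
  missing <- setdiff(needed, names(doc))
  if (length(missing)) {
    stop("design document lacks field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  defaults <- formals(trial_design)
  args <- doc[intersect(names(doc), names(defaults))]
  do.call(trial_design, args)
}

#' @rdname read_design
#' @param design A `trial_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "trial_design"))
  doc <- unclass(design)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

# non-control groups in design order
treatment_groups <- function(design) {
  setdiff(design$groups, design$control)
}
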