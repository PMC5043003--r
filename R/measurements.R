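#' Read a per-animal measurement table
#'
#' Reads the tidy observation layer of a trial: one row per animal, endpoint
#' and time, as comma-separated text with a header. Mandatory columns are
#' `animal_id`, `cage_id`, `gender`, `group`, `endpoint`, `time`, `value`;
#' an optional `kind` column marks each endpoint `"quantitative"` (default)
#' or `"qualitative-ordinal"`.
#'
#' Rows with a blank/missing quantitative `value` are dropped with a warning.
#' Duplicate `(animal_id, endpoint, time)` keys and cages that map to more
#' than one `(group, gender)` are rejected: both break the assumption that
#' the cage is a well-defined experimental unit.
#'
#' @param path Path to a CSV file.
#' @param known_endpoints Optional character vector; endpoint names outside
#'   it are kept but reported via a message (screening aid, not a filter).
#' @return A tibble of validated measurement records.
#' @export
read_measurements <- function(path, known_endpoints = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  mandatory <- c("animal_id", "cage_id", "gender", "group",
                 "endpoint", "time", "value")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    stop("measurement file lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"kind" %in% names(raw)) raw$kind <- "quantitative"
  raw$value <- suppressWarnings(as.numeric(raw$value))
  tab <- tibble::as_tibble(raw[mandatory])
  tab$kind <- raw$kind
  validate_measurements(tab, known_endpoints = known_endpoints)
}

#' Validate a measurement table
#'
#' Applies the invariants [read_measurements()] enforces to an in-memory
#' table (useful for simulated data and round-trips).
#'
#' @param measurements A data frame with the measurement-table columns.
#' @inheritParams read_measurements
#' @return The validated tibble.
#' @export
validate_measurements <- function(measurements, known_endpoints = NULL) {
  tab <- tibble::as_tibble(measurements)
  if (!"kind" %in% names(tab)) tab$kind <- "quantitative"

  blank <- !is.finite(tab$value) & tab$kind == "quantitative"
  if (any(blank)) {
    warning(sum(blank), " record(s) with missing quantitative values dropped",
            call. = FALSE)
    tab <- tab[!blank, , drop = FALSE]
  }

  key <- paste(tab$animal_id, tab$endpoint, tab$time, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab[duplicated(key), c("animal_id", "endpoint", "time")]
    stop("duplicate (animal_id, endpoint, time) key(s), e.g. ",
         paste(unlist(dup[1, ]), collapse = " / "), call. = FALSE)
  }

  map <- unique(tab[, c("cage_id", "group", "gender")])
  if (anyDuplicated(map$cage_id)) {
    bad <- map$cage_id[duplicated(map$cage_id)]
    stop("cage(s) mapped to more than one (group, gender): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }

  if (!is.null(known_endpoints)) {
    unknown <- setdiff(unique(tab$endpoint), known_endpoints)
    if (length(unknown)) {
      message("unknown endpoint(s) kept: ", paste(unknown, collapse = ", "))
    }
  }
  tab
}

#' Aggregate animal records to cage level
#'
#' Collapses the per-animal observation layer to one record per
#' `(cage, endpoint, time)` — the experimental unit of all downstream
#' inference. Every endpoint is aggregated as the mean of the cage's animals,
#' except endpoints named in `total_endpoints` (feed consumption), which are
#' recorded jointly for a cage and therefore pass through as the cage total.
#'
#' A cage with no surviving animal for a cell is omitted with a warning
#' (early-sacrifice handling); cages with a single survivor keep the
#' single-animal mean with `n_animals = 1`.
#'
#' @param measurements Measurement tibble (see [read_measurements()]).
#' @param design A `trial_design`; used to bound `n_animals`.
#' @param total_endpoints Endpoints aggregated by sum rather than mean.
#' @return A cage-level tibble: `cage_id`, `gender`, `group`, `endpoint`,
#'   `time`, `kind`, `value`, `n_animals`.
#' @export
cage_aggregate <- function(measurements, design,
                           total_endpoints = "feed_consumption") {
  tab <- validate_measurements(measurements)
  out <- tab |>
    dplyr::group_by(.data$cage_id, .data$gender, .data$group,
                    .data$endpoint, .data$time, .data$kind) |>
    dplyr::summarise(
      n_animals = dplyr::n(),
      value = if (.data$endpoint[1] %in% total_endpoints) {
        sum(.data$value)
      } else {
        mean(.data$value)
      },
      .groups = "drop"
    ) |>
    dplyr::relocate("value", .before = "n_animals")
  if (any(out$n_animals > design$animals_per_cage)) {
    stop("a cage holds more animal records than the design allows",
         call. = FALSE)
  }
  dplyr::arrange(out, .data$gender, .data$endpoint, .data$time,
                 .data$group, .data$cage_id)
}

#' Per-group summary statistics of cage values
#'
#' Computes, for each (group, gender, endpoint, time) cell, the number of
#' experimental units, mean, SD, min, median, max and the t-based 95%
#' confidence interval of the mean.
#'
#' @param cage_table Output of [cage_aggregate()].
#' @return A tibble with one row per summary cell.
#' @export
group_summary <- function(cage_table) {
  cage_table |>
    dplyr::group_by(.data$group, .data$gender, .data$endpoint, .data$time) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      min = min(.data$value),
      median = stats::median(.data$value),
      max = max(.data$value),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      half = ifelse(.data$n > 1,
                    stats::qt(0.975, pmax(.data$n - 1, 1)) * .data$sd /
                      sqrt(.data$n),
                    NA_real_),
      ci95_lo = .data$mean - .data$half,
      ci95_hi = .data$mean + .data$half
    ) |>
    dplyr::select(-"half")
}

#' Write a cage table or group summary as CSV
#'
#' Numeric columns are rounded to 6 significant digits so repeated exports of
#' the same analysis are byte-identical.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], signif, digits = 6)
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
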