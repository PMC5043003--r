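# Shared fixture builders: everything is generated in code at test time.

# minimal two-gender, four-group design with few cages for fast loops
small_design <- function(cages = 4) {
  trial_design(
    groups = c("control", "conventional 2", "11 % GMO", "33 % GMO"),
    control = "control",
    cages_per_group_per_gender = cages,
    observation_months = 12,
    subsample_n = 2 * cages
  )
}

# write a measurement CSV and return its path
write_measurement_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# a well-formed 6-record table: one cage per group/gender is enough here
six_records <- function() {
  data.frame(
    animal_id = paste0("a", 1:6),
    cage_id = rep(c("c1", "c2", "c3"), each = 2),
    gender = rep("male", 6),
    group = rep(c("control", "11 % GMO", "33 % GMO"), each = 2),
    endpoint = "WBC",
    time = 12,
    value = c(7.1, 7.5, 8.2, 8.0, 6.9, 7.3)
  )
}

# cage-level values for one endpoint cell under k groups of n cages
cell_values <- function(n = 10, shifts = c(control = 0, `conventional 2` = 0,
                                           `11 % GMO` = 0, `33 % GMO` = 0),
                        rfun = stats::rnorm) {
  groups <- rep(names(shifts), each = n)
  values <- unlist(lapply(shifts, function(s) rfun(n) + s))
  list(values = as.numeric(values), groups = groups)
}

# one-endpoint panel spec for a given gender set
one_endpoint_panel <- function(name = "WBC", mean = 0, sd = 1, w = 0.5,
                               genders = c("male", "female"),
                               dist = "normal", terminal_only = FALSE) {
  tibble::tibble(
    endpoint = name, class = "haematology", gender = genders,
    mean = mean, sd = sd, w = w, dist = dist, kind = "quantitative",
    terminal_only = terminal_only
  )
}

# panel of many iid replicate endpoints (each endpoint = one replicate cell)
replicate_panel <- function(n_rep, gender = "male", mean = 0, sd = 1,
                            w = 0.5) {
  tibble::tibble(
    endpoint = sprintf("rep%04d", seq_len(n_rep)), class = "sim",
    gender = gender, mean = mean, sd = sd, w = w, dist = "normal",
    kind = "quantitative", terminal_only = FALSE
  )
}

# design used for calibration studies: 2 groups, 1 gender, n cages, 1 month
calib_design <- function(n_cages = 10) {
  trial_design(groups = c("control", "treated"), control = "control",
               genders = "male", cages_per_group_per_gender = n_cages,
               observation_months = 12, subsample_n = 2 * n_cages)
}

# exact two-sided rank-sum p-value by exhaustive enumeration of label
# assignments (no ties assumed); mirrors the two-sided doubling convention
enum_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  all_w <- apply(utils::combn(n, na), 2, function(idx) sum(r[idx]))
  e <- na * (n + 1) / 2
  lo <- mean(all_w <= w_obs)
  hi <- mean(all_w >= w_obs)
  min(1, 2 * min(lo, hi))
}
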