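test_that("measurement files round-trip and invariants are enforced", {
  path <- write_measurement_csv(six_records())
  tab <- read_measurements(path)
  expect_equal(nrow(tab), 6)
  expect_setequal(tab$value, six_records()$value)

  dup <- six_records()
  dup$animal_id[2] <- "a1" # duplicates (animal, endpoint, time)
  expect_error(read_measurements(write_measurement_csv(dup)), "duplicate")

  blank <- six_records()
  blank$value[3] <- NA
  expect_warning(tab5 <- read_measurements(write_measurement_csv(blank)),
                 "dropped")
  expect_equal(nrow(tab5), 5)

  nocol <- six_records()[, -7]
  expect_error(read_measurements(write_measurement_csv(nocol)), "mandatory")

  twogrp <- six_records()
  twogrp$group[2] <- "33 % GMO" # cage c1 now maps to two groups
  expect_error(read_measurements(write_measurement_csv(twogrp)),
               "more than one")
})

test_that("cage aggregation means animals, totals feed, and is idempotent", {
  design <- small_design()
  meas <- tibble::tibble(
    animal_id = c("a1", "a2", "a3", "f1", "f2"),
    cage_id = c("c1", "c1", "c2", "c3", "c3"),
    gender = "male",
    group = c("control", "control", "11 % GMO", "33 % GMO", "33 % GMO"),
    endpoint = c("WBC", "WBC", "WBC", "feed_consumption",
                 "feed_consumption"),
    time = 12,
    value = c(4.0, 6.0, 7.2, 110, 95),
    kind = "quantitative"
  )
  cage <- cage_aggregate(meas, design)
  wbc1 <- cage[cage$cage_id == "c1", ]
  expect_equal(wbc1$value, 5.0)
  expect_equal(wbc1$n_animals, 2L)
  # single survivor keeps its own value
  expect_equal(cage$value[cage$cage_id == "c2"], 7.2)
  expect_equal(cage$n_animals[cage$cage_id == "c2"], 1L)
  # feed consumption is the cage total, never halved
  expect_equal(cage$value[cage$endpoint == "feed_consumption"], 205)

  # idempotence: re-aggregating one-record-per-cage data changes nothing
  again <- cage_aggregate(
    tibble::tibble(animal_id = cage$cage_id, cage_id = cage$cage_id,
                   gender = cage$gender, group = cage$group,
                   endpoint = cage$endpoint, time = cage$time,
                   value = cage$value, kind = cage$kind),
    design
  )
  expect_equal(again$value, cage$value)
})

test_that("cage means stay within the animal range", {
  design <- small_design()
  set.seed(11)
  for (rep in 1:20) {
    vals <- rnorm(design$animals_per_cage, 10, 3)
    meas <- tibble::tibble(
      animal_id = paste0("a", seq_along(vals)), cage_id = "c1",
      gender = "male", group = "control", endpoint = "X", time = 12,
      value = vals, kind = "quantitative"
    )
    cv <- cage_aggregate(meas, design)$value
    expect_gte(cv, min(vals))
    expect_lte(cv, max(vals))
  }
})

test_that("feed efficiency and relative organ weight follow their formulas", {
  expect_equal(feed_efficiency(50, 200), 25.0)
  expect_equal(feed_efficiency(0, 180), 0.0)
  expect_equal(feed_efficiency(-10, 100), -10.0)
  expect_error(feed_efficiency(10, 0), "feed_intake")

  expect_equal(relative_organ_weight(2.0, 400), 0.5)
  expect_equal(relative_organ_weight(0, 400), 0.0)
  # magnitude anchor: a 14.08 g liver in a 594 g male rat
  expect_equal(relative_organ_weight(14.08, 594), 2.370, tolerance = 1e-3)
  expect_error(relative_organ_weight(2, 0), "body_g")
  expect_error(relative_organ_weight(-1, 400), "organ_g")

  # both ratios are homogeneous of degree 0 under joint rescaling
  set.seed(21)
  for (i in 1:25) {
    g <- runif(1, -50, 200); f <- runif(1, 50, 500); c <- runif(1, 0.1, 10)
    expect_equal(feed_efficiency(c * g, c * f), feed_efficiency(g, f))
    o <- runif(1, 0, 20); b <- runif(1, 100, 700)
    expect_equal(relative_organ_weight(c * o, c * b),
                 relative_organ_weight(o, b))
  }
})

test_that("extreme-value screening flags Tukey-fence outliers only", {
  fl <- flag_extremes(c(1:9, 100))
  expect_equal(fl$value[fl$flagged], 100)

  # degenerate distribution: fences collapse, nothing is flagged
  expect_false(any(flag_extremes(rep(3.2, 8))$flagged))

  # 8-point symmetric sample: hand-computed fences contain every point
  x <- c(-4, -3, -2, -1, 1, 2, 3, 4)
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  fl8 <- flag_extremes(x)
  expect_equal(unique(fl8$fence_low), q[1] - 1.5 * diff(q))
  expect_false(any(fl8$flagged))

  expect_warning(fl3 <- flag_extremes(c(1, 2, 3)), "fewer than 4")
  expect_false(any(fl3$flagged))

  # affine invariance with positive scale
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(15); a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_equal(flag_extremes(a * x + b)$flagged, flag_extremes(x)$flagged)
  }
})

test_that("contaminant dose matches stepwise unit analysis", {
  expect_equal(dose_from_feed(5, 20, 500), 0.2)
  expect_equal(dose_from_feed(0, 20, 500), 0)
  expect_equal(dose_from_feed(10, 20, 500), 2 * dose_from_feed(5, 20, 500))
  expect_error(dose_from_feed(5, 20, 0), "body_weight")

  # oracle: convert each unit explicitly, step by step
  set.seed(41)
  for (i in 1:100) {
    conc <- runif(1, 0.01, 50)      # mg per kg feed
    intake <- runif(1, 1, 60)       # g feed per day
    bw <- runif(1, 100, 800)        # g body weight
    mg_per_g_feed <- conc / 1000
    mg_per_day <- mg_per_g_feed * intake
    bw_kg <- bw / 1000
    oracle <- mg_per_day / bw_kg
    expect_equal(dose_from_feed(conc, intake, bw), oracle,
                 tolerance = 1e-12)
  }
})

test_that("diet inclusion ratios reproduce the printed QC values", {
  expect_equal(dose_ratio(31.3, 10.4), 3.0)
  expect_equal(dose_ratio(1.27, 0.6), 2.1)
  expect_equal(dose_ratio(40.2, 12.8), 3.1)
  expect_equal(dose_ratio(1.2, 0.47), 2.6)
  expect_error(dose_ratio(1, 0), "level_low")
})

test_that("trial designs validate and round-trip through YAML and JSON", {
  expect_error(trial_design(c("a", "b"), control = "x"), "control")
  expect_error(trial_design(c("a", "b"), "a", observation_months = c(6, 3)),
               "increasing")
  expect_error(trial_design(c("a", "b"), "a",
                            cages_per_group_per_gender = 1), "2 cages")

  d <- default_design()
  expect_equal(length(d$groups), 4)
  expect_equal(d$control, "control")

  for (ext in c(".yaml", ".json")) {
    p <- tempfile(fileext = ext)
    write_design(d, p)
    d2 <- read_design(p)
    expect_equal(d2$groups, d$groups)
    expect_equal(d2$observation_months, d$observation_months)
    expect_equal(d2$cages_per_group_per_gender, d$cages_per_group_per_gender)
  }
})
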