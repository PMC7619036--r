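test_that("population draws are stratified, seeded, and separable", {
  p <- sample_population_params(10, 0.5, seed = 7)
  expect_equal(sum(p$mi_flag), 5L)
  expect_identical(p, sample_population_params(10, 0.5, seed = 7))
  expect_false(identical(p, sample_population_params(10, 0.5, seed = 8)))
  big <- sample_population_params(2000, 0.5, seed = 1)
  expect_lt(mean(big$ef_target[big$mi_flag]),
            mean(big$ef_target[!big$mi_flag]))
  expect_gt(mean(big$risk_score[big$mi_flag]),
            mean(big$risk_score[!big$mi_flag]))
  expect_error(sample_population_params(0, 0.5, 1), "n_subjects")
  expect_error(sample_population_params(10, 1.5, 1), "mi_fraction")
})

test_that("generated anatomies obey the similarity scaling law", {
  p <- sample_population_params(1, 0, seed = 3)
  p2 <- p
  p2$scale <- 1.1 * p$scale
  s1 <- build_anatomy(p, 512L, seed = 1)
  s2 <- build_anatomy(p2, 512L, seed = 1)
  # analytic cavity volumes scale exactly with scale^3
  expect_equal(s2$truth$lv_edv / s1$truth$lv_edv, 1.1^3, tolerance = 1e-6)
  # and the measured clouds agree
  v1 <- cavity_volume(cloud_class_points(s1$ed, 1L))
  v2 <- cavity_volume(cloud_class_points(s2$ed, 1L))
  expect_equal(v2 / v1, 1.1^3, tolerance = 0.05)
})

test_that("wall separation, volume ordering and EF targets hold", {
  p <- sample_population_params(4, 0.5, seed = 21)
  for (i in seq_len(4)) {
    s <- build_anatomy(p[i, ], 512L, seed = 30 + i)
    w <- p$wall_thickness[i]
    for (phase in list(s$ed, s$es)) {
      nd <- cardiopoint:::cpp_nn_dist(cloud_class_points(phase, 2L),
                                      cloud_class_points(phase, 1L))
      expect_gte(min(nd), 0.8 * w)
    }
    expect_gt(s$truth$lv_edv, s$truth$lv_esv)
    expect_gt(s$truth$rv_edv, s$truth$rv_esv)
    lv_ed <- cavity_volume(cloud_class_points(s$ed, 1L))
    lv_es <- cavity_volume(cloud_class_points(s$es, 1L))
    expect_gt(lv_ed, lv_es)
    ef <- (lv_ed - lv_es) / lv_ed
    expect_lt(abs(ef - p$ef_target[i]), 0.03)
  }
})

test_that("clouds carry all labels at the exact requested counts", {
  s <- build_anatomy(sample_population_params(1, 0, seed = 2), 128L, seed = 9)
  expect_identical(tabulate(s$ed$labels, 3L), rep(128L, 3))
  expect_identical(tabulate(s$es$labels, 3L), rep(128L, 3))
  expect_true(all(is.finite(s$ed$points)))
  # same params + seed reproduce the identical sample
  s2 <- build_anatomy(sample_population_params(1, 0, seed = 2), 128L, seed = 9)
  expect_identical(s$ed$points, s2$ed$points)
  expect_error(build_anatomy(sample_population_params(1, 0, seed = 2), 32L),
               "points_per_class")
})

test_that("impossible shape parameters are rejected with a clear message", {
  p <- as.list(sample_population_params(1, 0, seed = 4))
  p_bad <- p; p_bad$wall_thickness <- -1
  expect_error(build_anatomy(p_bad, 128L), "wall_thickness")
  p_bad <- p; p_bad$ef_target <- 1.2
  expect_error(build_anatomy(p_bad, 128L), "ef_target")
  p_bad <- p; p_bad$basal_tilt <- 40
  expect_error(build_anatomy(p_bad, 128L), "basal")
  p_bad <- p; p_bad$scale <- NaN
  expect_error(build_anatomy(p_bad, 128L), "scale")
})

test_that("survival labels follow the planted hazard model", {
  p <- sample_population_params(400, 0.5, seed = 5)
  # gamma = 0: event occurrence independent of the risk score
  s0 <- make_survival_labels(p, followup_days = 3000, seed = 1, gamma = 0)
  expect_lt(abs(cor(p$risk_score, as.numeric(s0$event_observed))), 0.12)
  # immediate censoring horizon
  s_eps <- make_survival_labels(p, followup_days = 1e-9, seed = 1)
  expect_false(any(s_eps$event_observed))
  expect_true(all(s_eps$event_time_days == 1e-9))
  # positive gamma: higher risk means more events
  s1 <- make_survival_labels(p, followup_days = 3000, seed = 1, gamma = 1)
  expect_gt(mean(s1$event_observed[p$risk_score > 0]),
            mean(s1$event_observed[p$risk_score < 0]))
  expect_identical(s1, make_survival_labels(p, 3000, seed = 1, gamma = 1))
})

test_that("dataset splitting uses largest-remainder sizes and stratifies", {
  cohort <- tiny_cohort()
  # single-group list of 10: 7 / 1 / 2 by largest remainder
  ctl <- Filter(function(s) s$group == "control", cohort)
  ten <- rep(ctl, length.out = 10)
  sp10 <- split_dataset(ten, c(0.70, 0.05, 0.25), seed = 1)
  expect_identical(vapply(sp10, length, integer(1)),
                   c(train = 7L, val = 1L, test = 2L))
  # 100 mixed samples: 70 / 5 / 25 globally even under stratification
  hundred <- rep(cohort, length.out = 100)
  sp <- split_dataset(hundred, c(0.70, 0.05, 0.25), seed = 2)
  expect_identical(vapply(sp, length, integer(1)),
                   c(train = 70L, val = 5L, test = 25L))
  ids <- function(l) sort(vapply(l, function(s) s$subject_id, character(1)))
  # partition: union equals input, intersections empty (by position)
  pos <- lapply(sp, function(l) vapply(l, function(s)
    format(s$event_time_days, digits = 15), character(1)))
  expect_equal(sum(lengths(sp)), 100L)
  expect_identical(split_dataset(hundred, seed = 2)$train, sp$train)
  expect_error(split_dataset(cohort[1:2]), "at least 3")
  expect_error(split_dataset(cohort, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("split partition is disjoint and exhaustive", {
  cohort <- tiny_cohort()
  sp <- split_dataset(cohort, seed = 3)
  tags <- unlist(lapply(cohort, function(s) s$subject_id))
  out <- unlist(lapply(sp, function(l) vapply(l, function(s) s$subject_id,
                                              character(1))))
  expect_setequal(out, tags)
  expect_equal(length(out), length(tags))
})

test_that("labeled point-cloud IO round-trips losslessly", {
  s <- tiny_cohort()[[1]]
  f1 <- tempfile(fileext = ".xyzl")
  write_xyzl(s$ed, f1)
  back <- read_xyzl(f1, phase = "ED")
  expect_lt(max(abs(back$points - s$ed$points)), 1e-6)
  expect_identical(back$labels, s$ed$labels)
  f2 <- tempfile(fileext = ".ply")
  write_ply(s$es, f2)
  back2 <- read_ply(f2, phase = "ES")
  expect_lt(max(abs(back2$points - s$es$points)), 1e-6)
  expect_identical(back2$labels, s$es$labels)
  f3 <- tempfile(fileext = ".csv")
  write_cohort_csv(tiny_cohort(), f3)
  meta <- read_cohort_csv(f3)
  expect_equal(nrow(meta), length(tiny_cohort()))
  expect_true(all(c("subject_id", "group", "event_time_days",
                    "event_observed", "truth_ef_target") %in% names(meta)))
})
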