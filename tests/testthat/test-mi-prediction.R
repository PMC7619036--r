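test_that("latent features are deterministic rows in input order", {
  model <- tiny_trained_model()
  cohort <- tiny_cohort()[1:6]
  ft <- extract_features(model, cohort)
  expect_equal(dim(ft), c(6L, 17L))
  ft2 <- extract_features(model, cohort)
  expect_identical(ft, ft2)
  expect_identical(ft$subject_id,
                   vapply(cohort, function(s) s$subject_id, character(1)))
  untrained <- point_vae(tiny_model_config())
  expect_error(extract_features(untrained, cohort), "trained")
})

test_that("latent features separate MI from control shapes", {
  model <- tiny_trained_model()
  cohort <- cached("tiny_train_cohort", stop("cohort missing"))
  groups <- vapply(cohort, function(s) s$group, character(1))
  keep <- groups %in% c("prevalent_mi", "control")
  ft <- as.matrix(extract_features(model, cohort[keep])[, -1])
  y <- as.integer(groups[keep] == "prevalent_mi")
  aurocs <- apply(ft, 2, function(col) auroc_oracle(col, y))
  expect_gt(max(pmax(aurocs, 1 - aurocs)), 0.55)
})

test_that("balanced subsets are equal-sized, seeded draws from the cohort", {
  cohort <- tiny_cohort()
  groups <- vapply(cohort, function(s) s$group, character(1))
  sub <- balanced_subset(cohort, "prevalent_mi", "control", seed = 4)
  g <- vapply(sub, function(s) s$group, character(1))
  expect_equal(sum(g == "prevalent_mi"), sum(g == "control"))
  expect_equal(length(sub),
               2L * min(sum(groups == "prevalent_mi"),
                        sum(groups == "control")))
  expect_identical(vapply(balanced_subset(cohort, seed = 4), `[[`,
                          character(1), "subject_id"),
                   vapply(sub, `[[`, character(1), "subject_id"))
  expect_true(all(vapply(sub, `[[`, character(1), "subject_id") %in%
                  vapply(cohort, `[[`, character(1), "subject_id")))
  expect_error(balanced_subset(cohort, "prevalent_mi", "no_such_group"),
               "empty group")
})

test_that("cross-validated logistic regression scores known regimes", {
  set.seed(8)
  # perfectly separable single feature
  y <- rep(c(0, 1), each = 50)
  x <- y * 10 + seq(0.001, 0.1, length.out = 100)
  rep1 <- crossval_logistic(matrix(x, ncol = 1), y, k = 10, seed = 1)
  expect_equal(unname(rep1$means["auroc"]), 1)
  expect_equal(unname(rep1$means["accuracy"]), 1)
  # null calibration: labels independent of the feature
  m <- vapply(1:12, function(s) {
    set.seed(100 + s)
    xs <- rnorm(200); ys <- rbinom(200, 1, 0.5)
    unname(crossval_logistic(matrix(xs, ncol = 1), ys, k = 10,
                             seed = s)$means["auroc"])
  }, numeric(1))
  expect_lt(abs(mean(m) - 0.5), 0.1)
  expect_error(crossval_logistic(matrix(rnorm(12), ncol = 1),
                                 rep(c(0, 1), 6), k = 10), "per class")
})

test_that("fold AUROC equals exhaustive concordant-pair enumeration", {
  set.seed(9)
  for (i in 1:5) {
    sc <- round(rnorm(60), 1)  # induce ties
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_true(abs(cardiopoint:::auroc_rank(sc, y) -
                    auroc_oracle(sc, y)) <= 1e-12)
  }
})

test_that("Cox fitting matches brute-force oracles and the score identity", {
  # zero-variance covariate has score identically zero
  fit0 <- fit_cox(matrix(0, 20, 1), times = 1:20,
                  events = rep(TRUE, 20))
  expect_equal(unname(fit0$coefficients), 0)
  # 4-subject case against 1-D grid search of the hand-written likelihood
  # (alternating covariate so the partial likelihood has an interior
  # maximum; a monotone covariate would separate)
  X <- matrix(c(1, 0, 1, 0), ncol = 1)
  tm <- c(1, 2, 3, 4); ev <- rep(TRUE, 4)
  fit <- fit_cox(X, tm, ev)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, function(b) cox_partial_loglik(b, X, tm, ev)$loglik,
               numeric(1))
  expect_lt(abs(unname(fit$coefficients) - grid[which.max(ll)]), 1e-3)
  # score identity at the optimum on a larger random design
  set.seed(12)
  Xr <- matrix(rnorm(300), ncol = 3)
  tr <- rexp(100, exp(Xr %*% c(0.5, -0.3, 0)))
  evr <- runif(100) < 0.8
  fr <- fit_cox(Xr, tr, evr)
  g <- cox_partial_loglik(fr$coefficients, Xr, tr, evr)$gradient
  expect_lt(sqrt(sum(g^2)), 1e-6)
  expect_error(fit_cox(Xr, tr, rep(FALSE, 100)), "events")
})

test_that("Harrell's C follows the usable-pair definition exactly", {
  expect_equal(harrell_c(c(3, 2, 1), c(1, 2, 3), rep(TRUE, 3)), 1)
  expect_equal(harrell_c(c(2, 3, 1), c(1, 2, 3), rep(TRUE, 3)), 2 / 3)
  set.seed(5)
  for (i in 1:4) {
    n <- 120
    risk <- round(rnorm(n), 1)
    time <- rexp(n)
    event <- runif(n) < 0.6
    expect_true(abs(harrell_c(risk, time, event) -
                    harrell_oracle(risk, time, event)) <= 1e-12)
    expect_true(abs(harrell_c(risk, time, event, ties = "half") -
                    harrell_oracle(risk, time, event, half_ties = TRUE)) <=
                1e-12)
  }
  # perfect anti-risk ordering and permutation null
  tm <- sort(rexp(200))
  expect_equal(harrell_c(-tm, tm, rep(TRUE, 200)), 1)
  set.seed(6)
  cs <- vapply(1:50, function(i) harrell_c(sample(-tm), tm, rep(TRUE, 200)),
               numeric(1))
  expect_lt(abs(mean(cs) - 0.5), 0.05)
  expect_error(harrell_c(1, 5, FALSE), "usable")
})

test_that("EF baselines agree with cavity volumes and reject bad input", {
  s <- tiny_cohort()[[1]]
  ef <- ef_baselines(list(s))
  lv_ed <- cavity_volume(cloud_class_points(s$ed, 1L))
  lv_es <- cavity_volume(cloud_class_points(s$es, 1L))
  expect_equal(ef$lv_ef, (lv_ed - lv_es) / lv_ed)
  # ES identical to ED means EF = 0
  s0 <- s
  s0$es <- mc_point_cloud(s$ed$points, s$ed$labels, "ES")
  expect_equal(ef_baselines(list(s0))$lv_ef, 0)
})

test_that("survival records censor at the horizon and drop prevalent MI", {
  cohort <- tiny_cohort()
  horizon <- 1500
  rec <- build_survival_records(cohort, horizon)
  n_prev <- sum(vapply(cohort, function(s) s$group == "prevalent_mi",
                       logical(1)))
  expect_equal(nrow(rec), length(cohort) - n_prev)
  expect_true(all(rec$time_days <= horizon))
  expect_true(all(rec$time_days[!rec$event] == horizon |
                  !rec$event[rec$time_days < horizon] |
                  rec$time_days[!rec$event] <= horizon))
  # events beyond the horizon are censored
  late <- vapply(cohort, function(s) isTRUE(s$event_observed) &&
                   s$event_time_days > horizon, logical(1))
  if (any(late)) {
    ids <- vapply(cohort[late], `[[`, character(1), "subject_id")
    expect_false(any(rec$event[rec$subject_id %in% ids]))
  }
})

test_that("cross-validated Cox recovers strong risk rankings", {
  set.seed(31)
  n <- 300
  x <- rnorm(n)
  tm <- rexp(n, rate = exp(1.5 * x) * 5e-4)
  ev <- tm < 2000
  tm2 <- pmin(tm, 2000)
  cv <- crossval_cox(matrix(x, ncol = 1), tm2, ev, k = 5, seed = 2)
  expect_gt(cv$mean_c, 0.65)
  expect_length(cv$c_index, 5L)
})
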