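test_that("Chamfer distance matches hand cases and is symmetric", {
  p <- matrix(c(0, 0, 0), 1, 3)
  q <- matrix(c(3, 4, 0), 1, 3)
  expect_equal(chamfer_distance(p, q), 5)
  expect_equal(chamfer_distance(p, q, squared = TRUE), 25)
  set.seed(3)
  A <- matrix(rnorm(60), ncol = 3)
  B <- matrix(rnorm(90), ncol = 3)
  expect_identical(chamfer_distance(A, B), chamfer_distance(B, A))
  expect_equal(chamfer_distance(A, A), 0)
  expect_error(chamfer_distance(A[0, , drop = FALSE], B), "non-empty")
})

test_that("Chamfer equals the exhaustive brute-force oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
    A <- matrix(rnorm(3 * n1, sd = 10), ncol = 3)
    B <- matrix(rnorm(3 * n2, sd = 10), ncol = 3)
    expect_true(abs(chamfer_distance(A, B) - chamfer_oracle(A, B)) <= 1e-12)
    expect_true(abs(chamfer_distance(A, B, squared = TRUE) -
                    chamfer_oracle(A, B, squared = TRUE)) <= 1e-10)
  }
})

test_that("Chamfer is invariant to joint rigid motion", {
  set.seed(4)
  A <- matrix(rnorm(90), ncol = 3); B <- matrix(rnorm(120), ncol = 3)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  shift <- c(5, -3, 11)
  A2 <- sweep(A %*% R, 2, shift, "+")
  B2 <- sweep(B %*% R, 2, shift, "+")
  expect_equal(chamfer_distance(A2, B2), chamfer_distance(A, B),
               tolerance = 1e-10)
})

test_that("cavity volume recovers analytic shapes and their invariances", {
  sp <- sphere_points(2000, r = 30)
  v <- cavity_volume(sp)
  expect_lt(abs(v / (4 / 3 * pi * 30^3) - 1), 0.05)
  expect_equal(cavity_volume(1.1 * sp) / v, 1.1^3, tolerance = 1e-3)
  set.seed(9)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  expect_equal(cavity_volume(sp %*% R), v, tolerance = 1e-6)
  expect_equal(cavity_volume(sweep(sp, 2, c(100, -50, 20), "+")), v,
               tolerance = 1e-6)
  flat <- cbind(matrix(rnorm(400), ncol = 2), 0)
  expect_error(cavity_volume(flat), "degenerate")
  expect_error(cavity_volume(sp[1:50, ]), "at least 100")
})

test_that("LV mass matches concentric-sphere analytics and is monotone", {
  endo <- sphere_points(2500, r = 30, seed = 2)
  epi <- sphere_points(2500, r = 40, seed = 3)
  m <- lv_mass(endo, epi)
  truth <- 4 / 3 * pi * (40^3 - 30^3) * 1.05 / 1000
  expect_lt(abs(m / truth - 1), 0.05)
  expect_equal(lv_mass(endo, endo), 0)
  thicker <- sphere_points(2500, r = 45, seed = 4)
  expect_gt(lv_mass(endo, thicker), m)
  expect_error(lv_mass(epi, endo), "enclose")
})

test_that("Gaussian MMD: self-distance, monotone shift, brute-force oracle", {
  set.seed(11)
  X <- matrix(rnorm(90), ncol = 3)
  expect_lt(abs(gaussian_mmd(X, X)), 1e-12)
  h <- 1.5
  scores <- vapply(c(0, 1, 2), function(s) {
    gaussian_mmd(X, sweep(X, 2, c(s * h, 0, 0), "+"), bandwidth = h)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  # direct double-sum oracle
  Y <- matrix(rnorm(30), ncol = 3)
  k <- function(a, b, h) exp(-sum((a - b)^2) / (2 * h^2))
  dsum <- function(A, B, h) {
    s <- 0
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
      s <- s + k(A[i, ], B[j, ], h)
    s / (nrow(A) * nrow(B))
  }
  oracle <- dsum(X, X, h) + dsum(Y, Y, h) - 2 * dsum(X, Y, h)
  expect_true(abs(gaussian_mmd(X, Y, bandwidth = h) - oracle) <= 1e-12)
  expect_gte(gaussian_mmd(X, Y), 0)
  expect_error(gaussian_mmd(X, matrix(rnorm(10), ncol = 2)), "dimension")
})

test_that("population report: degenerate and duplicated populations", {
  tb <- data.frame(metric = rep("lv_volume_ed_ml", 1), value = 120)
  one <- population_report(tb)
  expect_equal(one$sd, 0)
  expect_equal(one$n, 1L)
  cohort <- tiny_cohort()[1:4]
  r1 <- population_report(cohort)
  r2 <- population_report(c(cohort, cohort))
  expect_equal(r1$mean, r2$mean)
  expect_equal(nrow(r1), 3L)
})
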