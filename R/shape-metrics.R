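# Oracle-verified shape metrics: symmetric Chamfer distance, point-cloud
# cavity volumes and LV mass, and Gaussian-kernel maximum mean discrepancy.

#' Symmetric Chamfer distance between two point sets
#'
#' `CD(P1, P2) = 1/2 * (mean over P1 of the nearest-neighbour distance to P2
#' + mean over P2 of the nearest-neighbour distance to P1)`.  With
#' `squared = FALSE` distances are Euclidean (mm); with `squared = TRUE`
#' squared distances are averaged (mm^2), the convention used inside the
#' training loss.  Nearest neighbours are exact (brute force).
#'
#' @param p1,p2 numeric `n x 3` matrices (or [mc_point_cloud()] objects,
#'   which use all points).
#' @param squared average squared distances instead of distances.
#' @return A nonnegative scalar.
#' @export
chamfer_distance <- function(p1, p2, squared = FALSE) {
  p1 <- as_points3(p1); p2 <- as_points3(p2)
  if (nrow(p1) == 0L || nrow(p2) == 0L) {
    stop("Chamfer distance needs non-empty point sets", call. = FALSE)
  }
  cpp_chamfer(p1, p2, isTRUE(squared))
}

as_points3 <- function(x) {
  if (inherits(x, "mc_point_cloud")) x <- x$points
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("points must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  if (nrow(x) && !all(is.finite(x))) stop("points contain non-finite values", call. = FALSE)
  x
}

# Deterministic canonical long axis from PCA (largest-variance direction),
# with signs fixed from third moments so a rigidly moved cloud yields the
# rigidly moved frame.
canonical_frame <- function(X, long_axis = NULL) {
  cen <- colMeans(X)
  Xc <- sweep(X, 2, cen)
  S <- crossprod(Xc) / nrow(Xc)
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[3] < 1e-8 * ev$values[1]) {
    stop("degenerate (near-coplanar) point cloud", call. = FALSE)
  }
  e1 <- if (is.null(long_axis)) ev$vectors[, 1] else long_axis / sqrt(sum(long_axis^2))
  u <- drop(Xc %*% e1)
  if (sum(u^3) > 0) { e1 <- -e1; u <- -u }
  e2 <- ev$vectors[, 2]
  e2 <- e2 - sum(e2 * e1) * e1
  e2 <- e2 / sqrt(sum(e2 * e2))
  if (sum(drop(Xc %*% e2)^3) < 0) e2 <- -e2
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  list(center = cen, e1 = e1, e2 = e2, e3 = e3, u = u,
       v = drop(Xc %*% e2), w = drop(Xc %*% e3))
}

#' Cavity volume enclosed by a ventricular surface point cloud
#'
#' Estimates the volume enclosed by an open-base ventricular surface: the
#' cloud is expressed in cylindrical coordinates about its long axis
#' (supplied or PCA-derived), a radius map over axial bands x azimuthal
#' sectors is fitted, the basal opening is closed along its rim (the
#' best-fit cap of the opening), and the enclosed volume is integrated as
#' `V = 1/2 * sum r^2 dtheta du`.  The estimate is translation and rotation
#' invariant and exact under similarity scaling of the cloud.  This works
#' for any surface that is star-shaped about its long axis, which includes
#' the crescent-shaped RV.
#'
#' @param points `n x 3` matrix (mm) or [mc_point_cloud()]; at least 100
#'   points of one substructure.
#' @param long_axis optional length-3 direction of the long axis; when
#'   omitted the first principal axis is used.
#' @return Volume in mm^3.
#' @export
cavity_volume <- function(points, long_axis = NULL) {
  X <- as_points3(points)
  if (nrow(X) < 100L) stop("need at least 100 points", call. = FALSE)
  fr <- canonical_frame(X, long_axis)
  u <- fr$u
  theta <- atan2(fr$w, fr$v)
  r2 <- fr$v^2 + fr$w^2
  n <- nrow(X)
  n_u <- max(6L, round(sqrt(n / 18)))
  n_th <- 2L * n_u  # even, so a half-turn of the azimuth origin permutes bins
  u_lo <- min(u); u_hi <- max(u)
  du <- (u_hi - u_lo) / n_u
  bi <- pmin(pmax(ceiling((u - u_lo) / du), 1L), n_u)
  ti <- pmin(floor((theta + pi) / (2 * pi) * n_th) + 1L, n_th)
  cell <- (bi - 1L) * n_th + ti
  sums <- rowsum(r2, cell)
  cnts <- rowsum(rep(1, n), cell)
  M <- matrix(NA_real_, n_u, n_th)
  ids <- as.integer(rownames(sums))
  M[ids] <- sums / cnts
  # basal rim: last occupied axial position per azimuth
  u_max_th <- rep(u_lo, n_th)
  agg <- tapply(u, ti, max)
  u_max_th[as.integer(names(agg))] <- agg
  # fill empty interior cells by periodic interpolation over theta
  for (b in seq_len(n_u)) {
    row <- M[b, ]
    if (all(is.na(row))) next
    if (anyNA(row)) {
      idx <- which(!is.na(row))
      ang <- (idx - 0.5) * 2 * pi / n_th
      full <- (seq_len(n_th) - 0.5) * 2 * pi / n_th
      # nearest periodic neighbour fill
      for (j in which(is.na(row))) {
        dd <- pmin(abs(full[j] - ang), 2 * pi - abs(full[j] - ang))
        row[j] <- row[idx[which.min(dd)]]
      }
      M[b, ] <- row
    }
  }
  dtheta <- 2 * pi / n_th
  vol <- 0
  for (b in seq_len(n_u)) {
    lo <- u_lo + (b - 1L) * du
    for (t in seq_len(n_th)) {
      h <- min(u_max_th[t], lo + du) - lo
      if (h <= 0 || is.na(M[b, t])) next
      vol <- vol + 0.5 * M[b, t] * dtheta * h
    }
  }
  vol
}

#' Left-ventricular mass from endo- and epicardial clouds
#'
#' Myocardial shell volume (epicardial minus endocardial cavity volume)
#' converted to grams at the standard myocardial density of 1.05 g/mL.
#'
#' @param endo,epi point clouds (mm) of the LV endo- and epicardium.
#' @param long_axis optional shared long-axis direction.
#' @return Mass in grams.
#' @export
lv_mass <- function(endo, epi, long_axis = NULL) {
  v_epi <- cavity_volume(epi, long_axis)
  v_endo <- cavity_volume(endo, long_axis)
  if (v_epi < v_endo) {
    stop("epicardium must enclose endocardium (negative myocardial volume)",
         call. = FALSE)
  }
  (v_epi - v_endo) * 1.05 / 1000
}

#' Gaussian-kernel maximum mean discrepancy (biased estimator)
#'
#' Biased (V-statistic) squared-MMD between two samples of vectors with the
#' kernel `k(a, b) = exp(-||a - b||^2 / (2 h^2))`.  The bandwidth defaults
#' to the median pairwise distance of the pooled sample (median heuristic).
#' The biased estimator is exactly zero when the two samples coincide.
#'
#' @param X,Y numeric matrices with observations in rows, equal number of
#'   columns.
#' @param bandwidth optional kernel bandwidth `h` (> 0).
#' @return Nonnegative squared-MMD score.
#' @export
gaussian_mmd <- function(X, Y, bandwidth = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0L || nrow(Y) == 0L) stop("empty sample", call. = FALSE)
  if (ncol(X) != ncol(Y)) stop("dimension mismatch between samples", call. = FALSE)
  sq_dists <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
    pmax(d2, 0)
  }
  if (is.null(bandwidth)) {
    P <- rbind(X, Y)
    d2 <- sq_dists(P, P)
    med <- stats::median(sqrt(d2[upper.tri(d2)]))
    bandwidth <- if (is.finite(med) && med > 0) med else 1
  }
  assert_scalar_number(bandwidth, "bandwidth", lower = 1e-300)
  k <- function(D2) exp(-D2 / (2 * bandwidth^2))
  mean(k(sq_dists(X, X))) + mean(k(sq_dists(Y, Y))) - 2 * mean(k(sq_dists(X, Y)))
}

#' Clinical shape metrics of one anatomy sample
#'
#' LV and RV end-diastolic cavity volumes (mL), LV mass (g), and both
#' ejection fractions, all computed from the point clouds via
#' [cavity_volume()].
#'
#' @param sample an [anatomy_sample()].
#' @return A one-row tibble.
#' @export
clinical_metrics <- function(sample) {
  stopifnot(inherits(sample, "anatomy_sample"))
  lv_ed <- cavity_volume(cloud_class_points(sample$ed, 1L))
  lv_es <- cavity_volume(cloud_class_points(sample$es, 1L))
  rv_ed <- cavity_volume(cloud_class_points(sample$ed, 3L))
  rv_es <- cavity_volume(cloud_class_points(sample$es, 3L))
  if (lv_ed <= 0 || rv_ed <= 0) stop("non-positive ED volume", call. = FALSE)
  mass <- lv_mass(cloud_class_points(sample$ed, 1L),
                  cloud_class_points(sample$ed, 2L))
  tibble::tibble(subject_id = sample$subject_id,
                 lv_volume_ed_ml = lv_ed / 1000,
                 rv_volume_ed_ml = rv_ed / 1000,
                 lv_mass_g = mass,
                 lv_ef = (lv_ed - lv_es) / lv_ed,
                 rv_ef = (rv_ed - rv_es) / rv_ed)
}

#' Descriptive statistics of clinical metrics across a population
#'
#' @param x either a list of [anatomy_sample()] objects or a long-format
#'   data frame with columns `metric` and `value`.
#' @return A tibble with `metric`, `mean`, `sd`, `n`.
#' @export
population_report <- function(x) {
  if (is.data.frame(x)) {
    tb <- x
  } else {
    stopifnot(length(x) >= 1L)
    wide <- do.call(rbind, lapply(x, clinical_metrics))
    tb <- do.call(rbind, lapply(
      c("lv_volume_ed_ml", "rv_volume_ed_ml", "lv_mass_g"),
      function(m) data.frame(metric = m, value = wide[[m]])))
  }
  stats_by <- split(tb$value, tb$metric)
  tibble::tibble(
    metric = names(stats_by),
    mean = unname(vapply(stats_by, mean, numeric(1))),
    sd = unname(vapply(stats_by, function(v) if (length(v) > 1) sd(v) else 0,
                       numeric(1))),
    n = unname(vapply(stats_by, length, integer(1))))
}
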