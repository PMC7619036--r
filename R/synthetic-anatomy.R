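# Seeded synthetic biventricular anatomy generator.
#
# Shapes are truncated prolate ellipsoids with an open base: the LV
# endocardium is an ellipsoid about the long (z) axis, the LV epicardium its
# outward normal offset by the wall thickness, and the RV endocardium a
# septally indented ("crescent") ellipsoid placed against the LV free wall.
# All surfaces are cut by a common, possibly tilted, basal plane.  The ES
# anatomy is an apex-anchored radial contraction of the ED anatomy whose
# contraction factor is solved by bisection so the LV cavity hits the target
# ejection fraction, with the ES wall thickness solved to conserve
# myocardial volume (walls thicken in systole).

# ------------------------- triangulated surfaces ---------------------------

# Closed ellipsoid lattice; z is the long axis. `crescent` indents the
# radial coordinate around azimuth pi (the septal side) while keeping the
# surface star-shaped about its center.
ellipsoid_mesh <- function(a, b, center = c(0, 0, 0), n_th = 28L, n_ph = 56L,
                           crescent = NULL) {
  th <- pi * seq_len(n_th) / (n_th + 1)
  ph <- 2 * pi * (seq_len(n_ph) - 1) / n_ph
  s <- rep(1, n_ph)
  if (!is.null(crescent)) {
    dphi <- pmin(abs(ph - pi), 2 * pi - abs(ph - pi))
    s <- 1 - crescent$depth * exp(-0.5 * (dphi / crescent$width)^2)
  }
  sin_th <- sin(th); cos_th <- cos(th)
  X <- b * outer(sin_th, s * cos(ph))
  Y <- b * outer(sin_th, s * sin(ph))
  Z <- matrix(a * cos_th, n_th, n_ph)
  V <- rbind(c(0, 0, a), c(0, 0, -a),
             cbind(as.vector(t(X)), as.vector(t(Y)), as.vector(t(Z))))
  V <- sweep(V, 2, center, "+")
  idx <- function(i, j) 2L + (i - 1L) * n_ph + ((j - 1L) %% n_ph) + 1L
  i_band <- rep(seq_len(n_th - 1L), each = n_ph)
  j_band <- rep(seq_len(n_ph), n_th - 1L)
  f1 <- cbind(idx(i_band, j_band), idx(i_band, j_band + 1L),
              idx(i_band + 1L, j_band + 1L))
  f2 <- cbind(idx(i_band, j_band), idx(i_band + 1L, j_band + 1L),
              idx(i_band + 1L, j_band))
  jj <- seq_len(n_ph)
  top <- cbind(rep(1L, n_ph), idx(1L, jj + 1L), idx(1L, jj))
  bot <- cbind(rep(2L, n_ph), idx(n_th, jj), idx(n_th, jj + 1L))
  mesh <- list(V = V, F = rbind(f1, f2, top, bot))
  if (signed_volume(mesh) < 0) mesh$F <- mesh$F[, c(1L, 3L, 2L)]
  mesh
}

signed_volume <- function(mesh) {
  A <- mesh$V[mesh$F[, 1], , drop = FALSE]
  B <- mesh$V[mesh$F[, 2], , drop = FALSE]
  C <- mesh$V[mesh$F[, 3], , drop = FALSE]
  sum(A[, 1] * (B[, 2] * C[, 3] - B[, 3] * C[, 2]) -
      A[, 2] * (B[, 1] * C[, 3] - B[, 3] * C[, 1]) +
      A[, 3] * (B[, 1] * C[, 2] - B[, 2] * C[, 1])) / 6
}

mesh_volume <- function(mesh) abs(signed_volume(mesh))

triangle_areas <- function(mesh) {
  A <- mesh$V[mesh$F[, 1], , drop = FALSE]
  e1 <- mesh$V[mesh$F[, 2], , drop = FALSE] - A
  e2 <- mesh$V[mesh$F[, 3], , drop = FALSE] - A
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Keep the part of the mesh with nrm . x <= d; triangles crossing the plane
# are clipped exactly against it.
clip_mesh <- function(mesh, nrm, d) {
  s <- drop(mesh$V %*% nrm) - d
  keep_v <- s <= 0
  tri_in <- matrix(keep_v[mesh$F], ncol = 3L)
  n_in <- rowSums(tri_in)
  F_keep <- mesh$F[n_in == 3L, , drop = FALSE]
  cross_id <- which(n_in == 1L | n_in == 2L)
  newV <- list(); newF <- list()
  nv <- nrow(mesh$V)
  for (t in cross_id) {
    tri <- mesh$F[t, ]
    inside <- keep_v[tri]
    # rotate so pattern starts at an inside vertex
    rot <- which(inside)[1] - 1L
    tri <- tri[((0:2 + rot) %% 3L) + 1L]
    inside <- keep_v[tri]
    sv <- s[tri]
    lerp <- function(i, j) {
      w <- sv[i] / (sv[i] - sv[j])
      mesh$V[tri[i], ] + w * (mesh$V[tri[j], ] - mesh$V[tri[i], ])
    }
    if (sum(inside) == 1L) {       # tri[1] inside
      p12 <- lerp(1L, 2L); p13 <- lerp(1L, 3L)
      newV[[length(newV) + 1L]] <- rbind(p12, p13)
      a <- nv + 1L; b <- nv + 2L; nv <- nv + 2L
      newF[[length(newF) + 1L]] <- cbind(tri[1], a, b)
    } else {                       # tri[1], and one of tri[2]/tri[3], inside
      if (inside[2]) {             # tri[3] outside
        p23 <- lerp(2L, 3L); p13 <- lerp(1L, 3L)
        newV[[length(newV) + 1L]] <- rbind(p23, p13)
        a <- nv + 1L; b <- nv + 2L; nv <- nv + 2L
        newF[[length(newF) + 1L]] <- rbind(c(tri[1], tri[2], a),
                                           c(tri[1], a, b))
      } else {                     # tri[2] outside
        p12 <- lerp(1L, 2L); p23 <- lerp(2L, 3L)
        newV[[length(newV) + 1L]] <- rbind(p12, p23)
        a <- nv + 1L; b <- nv + 2L; nv <- nv + 2L
        newF[[length(newF) + 1L]] <- rbind(c(tri[1], a, b),
                                           c(tri[1], b, tri[3]))
      }
    }
  }
  V <- mesh$V
  if (length(newV)) V <- rbind(V, do.call(rbind, newV))
  F2 <- rbind(F_keep, if (length(newF)) do.call(rbind, newF))
  list(V = V, F = F2)
}

boundary_edges <- function(F) {
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (max(e) + 1) + pmax(e[, 1], e[, 2])
  single <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  e[single, , drop = FALSE]
}

# Close all boundary loops by a fan from each loop centroid; orientation of
# the fan follows the (directed) boundary edges so the solid stays
# consistently oriented.
cap_mesh <- function(mesh) {
  be <- boundary_edges(mesh$F)
  if (nrow(be) == 0L) return(mesh)
  verts <- unique(as.vector(be))
  cen <- colMeans(mesh$V[verts, , drop = FALSE])
  ci <- nrow(mesh$V) + 1L
  mesh$V <- rbind(mesh$V, cen)
  mesh$F <- rbind(mesh$F, cbind(be[, 2], be[, 1], ci))
  mesh
}

clipped_volume <- function(mesh, nrm, d) mesh_volume(cap_mesh(clip_mesh(mesh, nrm, d)))

# Outward vertex-normal offset (area-weighted face normals).
offset_mesh <- function(mesh, w) {
  A <- mesh$V[mesh$F[, 1], , drop = FALSE]
  e1 <- mesh$V[mesh$F[, 2], , drop = FALSE] - A
  e2 <- mesh$V[mesh$F[, 3], , drop = FALSE] - A
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  # accumulate face normals onto vertices
  acc <- rowsum(rbind(fn, fn, fn), as.vector(mesh$F))
  N <- matrix(0, nrow(mesh$V), 3)
  N[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  list(V = mesh$V + w * N / len, F = mesh$F)
}

# Area-uniform sampling of a triangulated surface.
sample_mesh <- function(mesh, n) {
  ar <- triangle_areas(mesh)
  ti <- sample.int(nrow(mesh$F), n, replace = TRUE, prob = ar)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  A <- mesh$V[mesh$F[ti, 1], , drop = FALSE]
  B <- mesh$V[mesh$F[ti, 2], , drop = FALSE]
  C <- mesh$V[mesh$F[ti, 3], , drop = FALSE]
  (1 - r1) * A + r1 * (1 - r2) * B + r1 * r2 * C
}

# --------------------------- population model ------------------------------

#' Synthetic population configuration
#'
#' Distribution settings of the generative shape factors.  Values are means
#' and SDs of (truncated) normal draws; the MI group is shifted toward lower
#' ejection fraction, thinner walls and mild dilation so that disease status
#' is recoverable from shape, mirroring post-infarction remodeling.
#' Baseline geometry: LV endocardial semi-axes 45 x 27 mm at scale 1
#' (epicardial apex-base length close to 90 mm), basal plane at 50% of the
#' long semi-axis.
#'
#' @return A list of generator settings.
#' @export
population_config <- function() {
  list(
    control = list(ef = c(0.58, 0.06), wall = c(10, 1.2), scale = c(1.00, 0.07),
                   elongation = c(1.0, 0.08), tilt = c(0, 6),
                   rv_size = c(1.0, 0.08)),
    mi = list(ef = c(0.47, 0.07), wall = c(8.2, 1.2), scale = c(1.06, 0.08),
              elongation = c(1.0, 0.08), tilt = c(0, 6),
              rv_size = c(1.03, 0.09)),
    ef_limits = c(0.2, 0.8), wall_limits = c(5, 16),
    lv_a = 45, lv_b = 27, base_frac = 0.5,
    rv_a_frac = 0.85, rv_b = 30, rv_gap = 2,
    crescent = list(depth = 0.30, width = 0.9),
    es_axial_frac = 0.35,
    risk = c(w_ef = 0.7, w_wall = 0.4, noise = 0.3),
    lattice = c(n_th = 28L, n_ph = 56L)
  )
}

#' Draw generative shape factors for a synthetic cohort
#'
#' Draws `n_subjects` sets of shape factors, of which an exact
#' `round(n_subjects * mi_fraction)` belong to the MI group (stratified
#' draw).  MI subjects come from shifted distributions (lower ejection
#' fraction, thinner walls, mild dilation) and the latent hazard driver
#' `risk_score` is a standardized combination of the shifted factors plus
#' independent noise.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param mi_fraction proportion of MI subjects in `[0, 1]`.
#' @param seed integer seed; the draw is a pure function of the arguments.
#' @param config generator settings, see [population_config()].
#' @return A tibble with one row per subject.
#' @export
sample_population_params <- function(n_subjects, mi_fraction, seed,
                                     config = population_config()) {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  assert_scalar_number(mi_fraction, "mi_fraction", 0, 1)
  n_mi <- as.integer(round(n_subjects * mi_fraction))
  with_seed(seed, {
    mi_flag <- rep(FALSE, n_subjects)
    mi_flag[sample.int(n_subjects, n_mi)] <- TRUE
    draw <- function(spec, n) rnorm(n, spec[1], spec[2])
    take <- function(field) {
      out <- numeric(n_subjects)
      out[!mi_flag] <- draw(config$control[[field]], sum(!mi_flag))
      out[mi_flag] <- draw(config$mi[[field]], sum(mi_flag))
      out
    }
    ef <- pmin(pmax(take("ef"), config$ef_limits[1]), config$ef_limits[2])
    wall <- pmin(pmax(take("wall"), config$wall_limits[1]), config$wall_limits[2])
    sc <- pmax(take("scale"), 0.6)
    el <- pmax(take("elongation"), 0.7)
    tilt <- pmin(pmax(take("tilt"), -18), 18)
    rvs <- pmax(take("rv_size"), 0.6)
    rw <- config$risk
    risk <- rw["w_ef"] * (0.55 - ef) / 0.08 +
      rw["w_wall"] * (9.2 - wall) / 1.4 + rw["noise"] * rnorm(n_subjects)
    rv_ef <- pmin(pmax(0.9 * ef + 0.08 + rnorm(n_subjects, 0, 0.035),
                       config$ef_limits[1]), config$ef_limits[2])
    tibble::tibble(scale = sc, elongation = el, basal_tilt = tilt,
                   wall_thickness = wall, rv_size = rvs, ef_target = ef,
                   rv_ef_target = rv_ef, mi_flag = mi_flag,
                   risk_score = unname(risk))
  })
}

validate_shape_params <- function(p) {
  need <- c("scale", "elongation", "basal_tilt", "wall_thickness", "rv_size",
            "ef_target")
  for (f in need) {
    v <- p[[f]]
    if (is.null(v) || !is.finite(v)) {
      stop(sprintf("shape parameter `%s` missing or non-finite", f), call. = FALSE)
    }
  }
  if (p$wall_thickness <= 0) stop("`wall_thickness` must be positive", call. = FALSE)
  if (p$ef_target <= 0 || p$ef_target >= 1) {
    stop("`ef_target` must be in (0, 1)", call. = FALSE)
  }
  if (p$scale <= 0) stop("`scale` must be positive", call. = FALSE)
  if (abs(p$basal_tilt) >= 25) {
    stop("`basal_tilt` beyond +-25 degrees makes the basal cut degenerate",
         call. = FALSE)
  }
  invisible(p)
}

# Solve f(x) = 0 on [lo, hi] by bisection; f must change sign.
bisect <- function(f, lo, hi, iter = 30L) {
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop("geometrically impossible shape parameters (no bisection bracket)",
         call. = FALSE)
  }
  for (i in seq_len(iter)) {
    mid <- 0.5 * (lo + hi)
    fm <- f(mid)
    if (flo * fm <= 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
  }
  0.5 * (lo + hi)
}

# ---- surfaces of revolution with azimuthal modulation --------------------
#
# Every generator surface is a profile (z, rho) revolved about its own long
# axis, radially modulated by s(phi) (the RV crescent), and truncated by the
# basal plane.  The epicardium's profile is the exact 2-D normal offset of
# the endocardial ellipse, which by symmetry equals the 3-D normal offset
# surface of the prolate spheroid.

ellipse_profile <- function(a, b, n = 169L) {
  th <- seq(0, pi, length.out = n)
  list(z = a * cos(th), rho = b * sin(th))
}

offset_profile <- function(a, b, w, n = 169L) {
  th <- seq(0, pi, length.out = n)
  nr <- sin(th) / b; nz <- cos(th) / a
  nl <- sqrt(nr^2 + nz^2)
  nl[nl == 0] <- 1
  list(z = a * cos(th) + w * nz / nl, rho = b * sin(th) + w * nr / nl)
}

crescent_factor <- function(ph, crescent) {
  if (is.null(crescent)) return(rep(1, length(ph)))
  dphi <- pmin(abs(ph - pi), 2 * pi - abs(ph - pi))
  1 - crescent$depth * exp(-0.5 * (dphi / crescent$width)^2)
}

# Triangulated open surface: profile revolved, modulated, clipped by the
# plane nrm . x <= d.
spec_mesh <- function(prof, center, crescent, nrm, d, n_th = 29L, n_ph = 56L) {
  keep <- unique(round(seq(1, length(prof$z), length.out = n_th)))
  z <- prof$z[keep]; rho <- prof$rho[keep]
  ph <- 2 * pi * (seq_len(n_ph) - 1) / n_ph
  s <- crescent_factor(ph, crescent)
  inner <- 2:(length(z) - 1L)
  X <- outer(rho[inner], s * cos(ph)) + center[1]
  Y <- outer(rho[inner], s * sin(ph)) + center[2]
  Z <- matrix(z[inner], length(inner), n_ph) + center[3]
  n_r <- length(inner)
  V <- rbind(center + c(0, 0, z[1]), center + c(0, 0, z[length(z)]),
             cbind(as.vector(t(X)), as.vector(t(Y)), as.vector(t(Z))))
  idx <- function(i, j) 2L + (i - 1L) * n_ph + ((j - 1L) %% n_ph) + 1L
  i_band <- rep(seq_len(n_r - 1L), each = n_ph)
  j_band <- rep(seq_len(n_ph), n_r - 1L)
  f1 <- cbind(idx(i_band, j_band), idx(i_band, j_band + 1L),
              idx(i_band + 1L, j_band + 1L))
  f2 <- cbind(idx(i_band, j_band), idx(i_band + 1L, j_band + 1L),
              idx(i_band + 1L, j_band))
  jj <- seq_len(n_ph)
  top <- cbind(rep(1L, n_ph), idx(1L, jj + 1L), idx(1L, jj))
  bot <- cbind(rep(2L, n_ph), idx(n_r, jj), idx(n_r, jj + 1L))
  mesh <- list(V = V, F = rbind(f1, f2, top, bot))
  if (signed_volume(mesh) < 0) mesh$F <- mesh$F[, c(1L, 3L, 2L)]
  clip_mesh(mesh, nrm, d)
}

# Volume of the solid of revolution truncated by the plane nrm . x <= d
# (nrm in the x-z plane).  Cylindrical-sector integration over a (z, phi)
# midpoint grid; exact case analysis of the plane cut per sector.
spec_volume <- function(prof, center, crescent, nrm, d, nz = 80L, nph = 72L) {
  ord <- order(prof$z)
  zs <- prof$z[ord]; rs <- prof$rho[ord]
  z_edges <- seq(zs[1], zs[length(zs)], length.out = nz + 1L)
  zm <- 0.5 * (z_edges[-1] + z_edges[-(nz + 1L)])
  dz <- diff(z_edges)[1]
  rho_z <- stats::approx(zs, rs, xout = zm)$y
  ph <- 2 * pi * (seq_len(nph) - 0.5) / nph
  dph <- 2 * pi / nph
  s <- crescent_factor(ph, crescent)
  sin_t <- nrm[1]; cos_t <- nrm[3]
  lim <- d - center[1] * sin_t - (center[3] + zm) * cos_t   # length nz
  c1 <- cos(ph) * sin_t                                     # length nph
  Re <- outer(rho_z, s)                                     # nz x nph
  L <- matrix(lim, nz, nph)
  C1 <- matrix(c1, nz, nph, byrow = TRUE)
  A <- matrix(0, nz, nph)
  pos <- C1 > 1e-12
  if (any(pos)) {
    hi <- pmax(0, pmin(Re[pos], L[pos] / C1[pos]))
    A[pos] <- 0.5 * hi^2
  }
  neg <- C1 < -1e-12
  if (any(neg)) {
    lo <- pmax(0, L[neg] / C1[neg])
    A[neg] <- 0.5 * pmax(0, Re[neg]^2 - lo^2)
  }
  zero <- !pos & !neg
  if (any(zero)) A[zero] <- ifelse(L[zero] >= 0, 0.5 * Re[zero]^2, 0)
  sum(A) * dz * dph
}

# All deterministic geometry of one subject: the six open surface meshes and
# the basal plane. Used by both the point sampler and the tests.
build_anatomy_meshes <- function(params, config = population_config()) {
  p <- as.list(params)
  validate_shape_params(p)
  lat <- config$lattice
  a_en <- config$lv_a * p$elongation * p$scale
  b_en <- config$lv_b * p$scale
  w <- p$wall_thickness
  tilt <- p$basal_tilt * pi / 180
  nrm <- c(sin(tilt), 0, cos(tilt))
  zb <- config$base_frac * a_en
  d <- zb * cos(tilt)
  lv_c <- c(0, 0, 0)
  vol <- function(prof, center, crescent = NULL) {
    spec_volume(prof, center, crescent, nrm, d)
  }
  v_ed <- vol(ellipse_profile(a_en, b_en), lv_c)
  kz_of <- function(k) 1 - config$es_axial_frac * (1 - k)
  es_geom <- function(k) {
    kz <- kz_of(k)
    list(a = kz * a_en, b = k * b_en, c = c(0, 0, -a_en * (1 - kz)))
  }
  k <- bisect(function(k) {
    g <- es_geom(k)
    vol(ellipse_profile(g$a, g$b), g$c) - (1 - p$ef_target) * v_ed
  }, 0.35, 0.999)
  g_es <- es_geom(k)
  v_es <- vol(ellipse_profile(g_es$a, g_es$b), g_es$c)
  myo_ed <- vol(offset_profile(a_en, b_en, w), lv_c) - v_ed
  w_es <- bisect(function(ww) {
    vol(offset_profile(g_es$a, g_es$b, ww), g_es$c) - v_es - myo_ed
  }, w * 0.8, w * 3)
  # RV: indented ("crescent") ellipsoid against the LV free wall; the septal
  # gap is < 3 mm so the offset RV epicardium fuses with the LV wall
  # downstream.
  a_rv <- config$rv_a_frac * a_en * p$rv_size
  b_rv <- config$rv_b * p$scale * p$rv_size
  cres <- config$crescent
  cx <- b_en + w + config$rv_gap + b_rv * (1 - cres$depth)
  rv_c <- c(cx, 0, -0.1 * a_en)
  rv_ef <- p$rv_ef_target %||% p$ef_target
  v_rv_ed <- vol(ellipse_profile(a_rv, b_rv), rv_c, cres)
  rv_es_geom <- function(k) {
    kz <- kz_of(k)
    list(a = kz * a_rv, b = k * b_rv,
         c = rv_c + c(0, 0, -a_rv * (1 - kz)))
  }
  k_rv <- bisect(function(k) {
    g <- rv_es_geom(k)
    vol(ellipse_profile(g$a, g$b), g$c, cres) - (1 - rv_ef) * v_rv_ed
  }, 0.35, 0.999)
  g_rv_es <- rv_es_geom(k_rv)
  mk <- function(prof, center, crescent = NULL) {
    spec_mesh(prof, center, crescent, nrm, d,
              n_th = lat[["n_th"]] + 1L, n_ph = lat[["n_ph"]])
  }
  list(ed = list(lv_endo = mk(ellipse_profile(a_en, b_en), lv_c),
                 lv_epi = mk(offset_profile(a_en, b_en, w), lv_c),
                 rv_endo = mk(ellipse_profile(a_rv, b_rv), rv_c, cres)),
       es = list(lv_endo = mk(ellipse_profile(g_es$a, g_es$b), g_es$c),
                 lv_epi = mk(offset_profile(g_es$a, g_es$b, w_es), g_es$c),
                 rv_endo = mk(ellipse_profile(g_rv_es$a, g_rv_es$b),
                              g_rv_es$c, cres)),
       plane = list(nrm = nrm, d = d),
       volumes = list(lv_ed = v_ed, lv_es = v_es, rv_ed = v_rv_ed,
                      rv_es = vol(ellipse_profile(g_rv_es$a, g_rv_es$b),
                                  g_rv_es$c, cres),
                      myo_ed = myo_ed, wall_es = w_es))
}

#' Build one synthetic anatomy sample
#'
#' Turns one set of shape factors into area-uniform multi-class ED/ES point
#' clouds with exactly `points_per_class` points per substructure and phase.
#'
#' @param params one row of [sample_population_params()] (or a named list).
#' @param points_per_class points per substructure per phase (>= 64).
#' @param seed integer seed for the surface sampling.
#' @param subject_id identifier stored on the sample.
#' @param event_time_days,event_observed optional survival metadata (see
#'   [make_survival_labels()]).
#' @param config generator settings.
#' @return An [anatomy_sample()].
#' @export
build_anatomy <- function(params, points_per_class = 1024L, seed = 1L,
                          subject_id = "S1", event_time_days = NA_real_,
                          event_observed = FALSE,
                          config = population_config()) {
  points_per_class <- assert_count(points_per_class, "points_per_class",
                                   minimum = 64L)
  meshes <- build_anatomy_meshes(params, config)
  p <- as.list(params)
  with_seed(seed, {
    sample_phase <- function(phase_meshes, phase) {
      pts <- lapply(phase_meshes, sample_mesh, n = points_per_class)
      mc_point_cloud(do.call(rbind, pts),
                     rep(1:3, each = points_per_class), phase = phase)
    }
    ed <- sample_phase(meshes$ed, "ED")
    es <- sample_phase(meshes$es, "ES")
    group <- if (isTRUE(p$mi_flag)) {
      "prevalent_mi"
    } else if (isTRUE(event_observed)) {
      "incident_mi"
    } else {
      "control"
    }
    anatomy_sample(subject_id, ed, es, group = group,
                   event_time_days = event_time_days,
                   event_observed = event_observed,
                   truth = c(p, list(lv_edv = meshes$volumes$lv_ed,
                                     lv_esv = meshes$volumes$lv_es,
                                     rv_edv = meshes$volumes$rv_ed,
                                     rv_esv = meshes$volumes$rv_es)))
  })
}

#' Draw survival labels for a synthetic cohort
#'
#' Event times follow an exponential proportional-hazards model,
#' `T ~ Exp(lambda0 * exp(gamma * risk_score))`, administratively censored
#' at `followup_days`.  The generating `gamma` and `lambda0` are recorded as
#' attributes so parameter-recovery tests know the truth.
#'
#' @param params tibble from [sample_population_params()].
#' @param followup_days administrative censoring horizon (> 0), in days.
#' @param seed integer seed.
#' @param gamma log-hazard-ratio per unit of `risk_score`.
#' @param lambda0 baseline hazard per day.
#' @return A tibble with `event_time_days` and `event_observed`.
#' @export
make_survival_labels <- function(params, followup_days = 2555, seed = 1L,
                                 gamma = 1, lambda0 = 1.2e-4) {
  if (followup_days <= 0) stop("`followup_days` must be positive", call. = FALSE)
  assert_scalar_number(gamma, "gamma")
  assert_scalar_number(lambda0, "lambda0", lower = 1e-12)
  with_seed(seed, {
    rate <- lambda0 * exp(gamma * params$risk_score)
    t_event <- rexp(nrow(params), rate)
    observed <- t_event <= followup_days
    out <- tibble::tibble(event_time_days = ifelse(observed, t_event,
                                                   followup_days),
                          event_observed = observed)
    attr(out, "gamma") <- gamma
    attr(out, "lambda0") <- lambda0
    out
  })
}

#' Split a cohort into train / validation / test sets
#'
#' Deterministic seeded partition with largest-remainder rounding of the
#' requested fractions, stratified by group label.  Global split sizes
#' always follow the largest-remainder rule applied to the whole cohort;
#' stratification then distributes each group as evenly as possible under
#' those fixed totals.
#'
#' @param samples list of [anatomy_sample()] objects.
#' @param fractions length-3 positive numeric summing to 1 (train, val, test).
#' @param seed integer seed.
#' @return A named list `train`, `val`, `test` of disjoint sample lists.
#' @export
split_dataset <- function(samples, fractions = c(0.70, 0.05, 0.25), seed = 1L) {
  n <- length(samples)
  if (n < 3L) stop("need at least 3 samples to split", call. = FALSE)
  if (length(fractions) != 3L || any(fractions <= 0)) {
    stop("`fractions` must be 3 positive numbers", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must sum to 1", call. = FALSE)
  }
  largest_remainder <- function(total, frac) {
    ideal <- total * frac
    base <- floor(ideal)
    extra <- total - sum(base)
    if (extra > 0) {
      ord <- order(-(ideal - base), seq_along(frac))
      base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
    }
    as.integer(base)
  }
  sizes <- largest_remainder(n, fractions)
  groups <- vapply(samples, function(s) s$group, character(1))
  with_seed(seed, {
    alloc <- matrix(0L, nrow = 0, ncol = 3)
    g_levels <- unique(groups)
    for (g in g_levels) {
      alloc <- rbind(alloc, largest_remainder(sum(groups == g), fractions))
    }
    # repair per-group allocations so the columns hit the global sizes
    repeat {
      delta <- colSums(alloc) - sizes
      if (all(delta == 0)) break
      s_over <- which.max(delta); s_under <- which.min(delta)
      gi <- which.max(alloc[, s_over])
      alloc[gi, s_over] <- alloc[gi, s_over] - 1L
      alloc[gi, s_under] <- alloc[gi, s_under] + 1L
    }
    assignment <- character(n)
    for (i in seq_along(g_levels)) {
      idx <- which(groups == g_levels[i])
      idx <- idx[sample.int(length(idx))]
      lab <- rep(c("train", "val", "test"), times = alloc[i, ])
      assignment[idx] <- lab
    }
    list(train = samples[assignment == "train"],
         val = samples[assignment == "val"],
         test = samples[assignment == "test"])
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: draws shape factors, survival labels, and builds the
#' anatomy of every subject.
#'
#' @inheritParams sample_population_params
#' @inheritParams build_anatomy
#' @inheritParams make_survival_labels
#' @return A list of [anatomy_sample()] objects.
#' @export
simulate_cohort <- function(n_subjects, mi_fraction = 0.3,
                            points_per_class = 1024L, seed = 1L,
                            followup_days = 2555, gamma = 1,
                            lambda0 = 1.2e-4, config = population_config()) {
  params <- sample_population_params(n_subjects, mi_fraction, seed, config)
  surv <- make_survival_labels(params, followup_days, seed + 1L, gamma, lambda0)
  lapply(seq_len(n_subjects), function(i) {
    build_anatomy(params[i, ], points_per_class, seed = seed + 100L + i,
                  subject_id = sprintf("S%04d", i),
                  event_time_days = surv$event_time_days[i],
                  event_observed = surv$event_observed[i], config = config)
  })
}
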