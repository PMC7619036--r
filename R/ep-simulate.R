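# Electrophysiology simulation: anisotropic eikonal activation, synthetic
# electrode layout, pseudo-ECG synthesis, and population QRS comparison.

#' Eikonal solver configuration
#'
#' Conduction velocities (m/s, equivalently mm/ms) along the fiber, sheet
#' (transmural) and normal directions, the fast endocardial layer speed,
#' and the activation root nodes with their onset times.  Defaults follow
#' reported healthy ventricular myocardium: 0.67, 0.30, 0.17 and 1.20 m/s.
#'
#' @param cv_fiber,cv_sheet,cv_normal,cv_endo conduction velocities in m/s.
#' @param root_nodes integer node indices of the earliest-activation sites
#'   (default: the 7 homologous sites from [default_activation_sites()]).
#' @param onsets onset times (ms) recycled over the roots (default 0).
#' @return An object of class `eikonal_config`.
#' @export
eikonal_config <- function(cv_fiber = 0.67, cv_sheet = 0.30, cv_normal = 0.17,
                           cv_endo = 1.20, root_nodes = NULL, onsets = 0) {
  for (nm in c("cv_fiber", "cv_sheet", "cv_normal", "cv_endo")) {
    assert_scalar_number(get(nm), nm, lower = 1e-9)
  }
  structure(list(cv_fiber = cv_fiber, cv_sheet = cv_sheet,
                 cv_normal = cv_normal, cv_endo = cv_endo,
                 root_nodes = root_nodes, onsets = onsets),
            class = "eikonal_config")
}

#' Solve the anisotropic eikonal activation problem
#'
#' Computes first-arrival activation times (ms) on a tetrahedral mesh by
#' fast-iterative sweeping with exact local solves under the anisotropic
#' metric `M = v_f^2 f f' + v_s^2 s s' + v_n^2 n n'`; endocardial surface
#' edges are additionally traversed at the fast endocardial speed.  The
#' activation time at each root equals its onset, and the solution is the
#' minimal arrival time over all roots.  Nodes unreachable from the roots
#' (disconnected components) keep an infinite time.
#'
#' @param mesh a `tet_mesh` with fibers (see [assign_fibers()]).
#' @param config an [eikonal_config()].
#' @return An object of class `activation_map`: numeric activation times
#'   (ms) per node, with the roots and config attached.
#' @export
solve_eikonal <- function(mesh, config = eikonal_config()) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(config, "eikonal_config"))
  if (is.null(mesh$fibers)) stop("mesh is missing fiber frames", call. = FALSE)
  roots <- config$root_nodes %||% default_activation_sites(mesh)
  roots <- as.integer(roots)
  if (length(roots) < 1L || any(roots < 1L | roots > nrow(mesh$nodes))) {
    stop("invalid root nodes", call. = FALSE)
  }
  onsets <- rep_len(as.numeric(config$onsets), length(roots))
  fb <- mesh$fibers
  sym_outer <- function(a, v) {
    cbind(a[, 1] * a[, 1], a[, 2] * a[, 1], a[, 3] * a[, 1],
          a[, 2] * a[, 2], a[, 3] * a[, 2], a[, 3] * a[, 3]) / v^2
  }
  minv <- sym_outer(fb[, 1:3], config$cv_fiber) +
    sym_outer(fb[, 4:6], config$cv_sheet) +
    sym_outer(fb[, 7:9], config$cv_normal)
  fast <- endocardial_edges(mesh)
  times <- cpp_eikonal(mesh$nodes, mesh$tets, minv, roots, onsets,
                       fast$edges, fast$lengths, config$cv_endo,
                       1e-7, 200L)
  structure(times, class = "activation_map", roots = roots,
            onsets = onsets, config = config)
}

# Boundary-face edges whose endpoints share an endocardial tag: the fast
# endocardial conduction layer.
endocardial_edges <- function(mesh) {
  if (is.null(mesh$tags)) {
    return(list(edges = matrix(integer(0), 0, 2), lengths = numeric(0)))
  }
  bf <- boundary_faces(mesh$tets)
  e <- rbind(bf[, c(1, 2)], bf[, c(2, 3)], bf[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (nrow(mesh$nodes) + 1) + pmax(e[, 1], e[, 2])
  e <- e[!duplicated(key), , drop = FALSE]
  t1 <- mesh$tags[e[, 1]]; t2 <- mesh$tags[e[, 2]]
  keep <- (t1 == "lv_endo" & t2 == "lv_endo") |
    (t1 == "rv_endo" & t2 == "rv_endo")
  e <- e[keep, , drop = FALSE]
  len <- sqrt(rowSums((mesh$nodes[e[, 1], , drop = FALSE] -
                       mesh$nodes[e[, 2], , drop = FALSE])^2))
  list(edges = e, lengths = len)
}

#' @export
print.activation_map <- function(x, ...) {
  fin <- is.finite(x)
  cat(sprintf("<activation_map> %d nodes, range %.1f - %.1f ms%s\n",
              length(x), min(x[fin]), max(x[fin]),
              if (all(fin)) "" else sprintf(" (%d unreachable)", sum(!fin))))
  invisible(x)
}

#' Default synthetic electrode layout
#'
#' Nine electrodes (RA, LA, LL and the precordial V1-V6) placed at fixed
#' offsets on a torso-scale shell around the heart, with V1-V6 ordered
#' along the precordial arc.  The layout is deterministic and translates
#' rigidly with the mesh.
#'
#' @param mesh a `tet_mesh` (only its bounding box is used).
#' @return A `9 x 3` matrix with rownames RA, LA, LL, V1-V6 (mm).
#' @export
default_electrodes <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  lo <- apply(mesh$nodes, 2, min); hi <- apply(mesh$nodes, 2, max)
  cen <- (lo + hi) / 2
  R <- 1.6 * max(hi - lo)
  a <- seq(-0.9, 0.9, length.out = 6)
  prec <- cbind(sin(a), -0.9 * cos(a), -0.2 + 0.1 * a)
  E <- rbind(RA = c(-0.9, 0.4, 0.9), LA = c(0.9, 0.4, 0.9),
             LL = c(0.6, 0.4, -1.2), prec)
  rownames(E) <- c("RA", "LA", "LL", paste0("V", 1:6))
  sweep(E * R, 2, cen, "+")
}

#' Synthesize a pseudo-ECG QRS complex from an activation map
#'
#' Dipole-density integral: every element contributes
#' `w'(t - act) * (-grad act . grad(1/r)) * volume` to the extracellular
#' potential at each electrode, where `w` is a smooth unit depolarization
#' upstroke of the given rise time.  Limb leads are `I = LA - RA`,
#' `II = LL - RA`; the precordial leads are referenced to the Wilson
#' central terminal `(RA + LA + LL)/3`.  Only the 8 independent leads are
#' returned (III and the augmented leads are linear combinations).
#' Amplitudes are in normalized units; the time grid spans
#' `[min activation - 5 ms, max activation + 20 ms]`.
#'
#' @param activation an `activation_map` from [solve_eikonal()].
#' @param mesh the corresponding `tet_mesh`.
#' @param electrodes `9 x 3` electrode matrix (default
#'   [default_electrodes()]).
#' @param dt sampling interval in ms.
#' @param rise_ms upstroke rise time in ms (default 1).
#' @return An object of class `ecg_trace`: `time_ms` and a matrix `leads`
#'   with columns I, II, V1-V6.
#' @export
pseudo_ecg <- function(activation, mesh, electrodes = default_electrodes(mesh),
                       dt = 1, rise_ms = 1) {
  stopifnot(inherits(mesh, "tet_mesh"))
  act <- as.numeric(activation)
  if (!all(is.finite(act))) {
    stop("activation map contains unreachable nodes", call. = FALSE)
  }
  assert_scalar_number(dt, "dt", lower = 1e-6)
  grads <- element_gradients(mesh, act)
  vols <- abs(tet_volumes(mesh$nodes, mesh$tets))
  cen <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
          mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  act_el <- (act[mesh$tets[, 1]] + act[mesh$tets[, 2]] +
             act[mesh$tets[, 3]] + act[mesh$tets[, 4]]) / 4
  tgrid <- seq(min(act) - 5, max(act) + 20, by = dt)
  if (length(tgrid) < 2L) stop("zero-length trace", call. = FALSE)
  E <- as.matrix(electrodes)
  phi <- cpp_pseudo_ecg(cen, grads, act_el, vols, E, tgrid, rise_ms)
  colnames(phi) <- rownames(E)
  wct <- (phi[, "RA"] + phi[, "LA"] + phi[, "LL"]) / 3
  leads <- cbind(I = phi[, "LA"] - phi[, "RA"],
                 II = phi[, "LL"] - phi[, "RA"],
                 phi[, paste0("V", 1:6)] - wct)
  colnames(leads) <- c("I", "II", paste0("V", 1:6))
  structure(list(time_ms = tgrid, leads = leads), class = "ecg_trace")
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat(sprintf("<ecg_trace> 8 leads x %d samples (%.0f - %.0f ms)\n",
              length(x$time_ms), min(x$time_ms), max(x$time_ms)))
  invisible(x)
}

#' QRS duration of a lead
#'
#' Width of the interval where any-lead (or one lead's) absolute amplitude
#' exceeds 5% of its maximum.
#'
#' @param trace an `ecg_trace`.
#' @param lead lead name, or `NULL` to pool all leads.
#' @return Duration in ms.
#' @export
qrs_duration <- function(trace, lead = NULL) {
  stopifnot(inherits(trace, "ecg_trace"))
  a <- if (is.null(lead)) apply(abs(trace$leads), 1, max) else
    abs(trace$leads[, lead])
  on <- which(a > 0.05 * max(a))
  diff(range(trace$time_ms[on]))
}

#' Compare real and virtual ECG populations per lead
#'
#' Resamples every trace to a common length on its own normalized time
#' axis, then reports for each of the 8 leads the Gaussian-kernel MMD
#' between the two populations ("proposed") alongside the MMD between two
#' random halves of the real population ("gold standard", seeded split).
#'
#' @param real,virtual lists of `ecg_trace` objects (>= 10 each).
#' @param seed seed for the gold-standard split.
#' @param n_samples common resampled trace length.
#' @param bandwidth optional shared MMD bandwidth.
#' @return A tibble: `lead`, `mmd_proposed`, `mmd_gold_standard`.
#' @export
qrs_population_compare <- function(real, virtual, seed = 1L,
                                   n_samples = 100L, bandwidth = NULL) {
  if (length(real) < 10L || length(virtual) < 10L) {
    stop("need at least 10 traces per population", call. = FALSE)
  }
  leads <- colnames(real[[1]]$leads)
  resample <- function(traces, lead) {
    t(vapply(traces, function(tr) {
      s <- seq(0, 1, length.out = length(tr$time_ms))
      stats::approx(s, tr$leads[, lead], xout = seq(0, 1,
                    length.out = n_samples))$y
    }, numeric(n_samples)))
  }
  half <- with_seed(seed, sample.int(length(real), floor(length(real) / 2)))
  rows <- lapply(leads, function(ld) {
    Xr <- resample(real, ld)
    Xv <- resample(virtual, ld)
    tibble::tibble(
      lead = ld,
      mmd_proposed = gaussian_mmd(Xr, Xv, bandwidth),
      mmd_gold_standard = gaussian_mmd(Xr[half, , drop = FALSE],
                                       Xr[-half, , drop = FALSE], bandwidth))
  })
  do.call(rbind, rows)
}

#' Run the full electrophysiology pipeline on one anatomy
#'
#' Point cloud to pseudo-ECG: per-substructure surface reconstruction, 3 mm
#' RV epicardial offset, watertight biventricular merge, tetrahedralization,
#' anatomical tagging and rule-based fibers, 7-site anisotropic eikonal
#' activation, and 8-lead QRS synthesis.  Every stage validates its output
#' before the next runs.
#'
#' @param x an [anatomy_sample()] or [mc_point_cloud()].
#' @param phase phase to simulate when `x` is a sample (default ED).
#' @param target_edge tetrahedral lattice spacing (mm).
#' @param grid_res assembly lattice spacing (mm).
#' @param config an [eikonal_config()].
#' @param dt ECG sampling interval (ms).
#' @param rv_offset RV epicardial offset (mm, default 3).
#' @return A list: `mesh`, `activation`, `trace`, `sites`, `surfaces`.
#' @export
simulate_ecg <- function(x, phase = "ED", target_edge = 3.0, grid_res = 1.25,
                         config = eikonal_config(), dt = 1, rv_offset = 3.0) {
  cloud <- if (inherits(x, "anatomy_sample")) {
    if (phase == "ED") x$ed else x$es
  } else {
    x
  }
  stopifnot(inherits(cloud, "mc_point_cloud"))
  lv_endo <- surface_from_cloud(cloud, 1L)
  lv_epi <- surface_from_cloud(cloud, 2L)
  rv_endo <- surface_from_cloud(cloud, 3L)
  rv_epi <- offset_rv_epicardium(rv_endo, rv_offset)
  merged <- assemble_biventricular(lv_endo, lv_epi, rv_endo, rv_epi, grid_res)
  mesh <- tetrahedralize(merged, target_edge)
  mesh <- assign_anatomy(mesh, lv_endo, lv_epi, rv_endo, rv_epi)
  mesh <- assign_fibers(mesh)
  if (is.null(config$root_nodes)) {
    config$root_nodes <- default_activation_sites(mesh)
  }
  act <- solve_eikonal(mesh, config)
  if (!all(is.finite(act))) {
    keep_comp <- is.finite(act)
    stop(sprintf("mesh has %d nodes unreachable from the activation sites",
                 sum(!keep_comp)), call. = FALSE)
  }
  trace <- pseudo_ecg(act, mesh, dt = dt)
  list(mesh = mesh, activation = act, trace = trace,
       sites = config$root_nodes,
       surfaces = list(lv_endo = lv_endo, lv_epi = lv_epi,
                       rv_endo = rv_endo, rv_epi = rv_epi))
}

# ---------------------------------------------------------------------------
# Text outputs

#' Write a tetrahedral mesh as a legacy ASCII VTK unstructured grid
#'
#' Includes per-cell fiber vectors and per-node activation times when
#' available.
#'
#' @param mesh a `tet_mesh`.
#' @param path output file.
#' @param activation optional `activation_map`.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, activation = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  nt <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "cardiopoint tet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$nodes))), con)
  writeLines(sprintf("%.6f %.6f %.6f", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nt, 5 * nt), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("10", nt), con)
  if (!is.null(mesh$fibers)) {
    writeLines(c(sprintf("CELL_DATA %d", nt), "VECTORS fiber double"), con)
    writeLines(sprintf("%.6f %.6f %.6f", mesh$fibers[, 1], mesh$fibers[, 2],
                       mesh$fibers[, 3]), con)
  }
  if (!is.null(activation)) {
    writeLines(c(sprintf("POINT_DATA %d", nrow(mesh$nodes)),
                 "SCALARS activation double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.6f", as.numeric(activation)), con)
  }
  invisible(path)
}

#' Write / read an ECG trace as CSV
#'
#' Columns: `time_ms`, `I`, `II`, `V1` ... `V6`.
#'
#' @param trace an `ecg_trace`.
#' @param path CSV path.
#' @return `write_ecg_csv` returns `path` invisibly; `read_ecg_csv` the
#'   trace.
#' @export
write_ecg_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ecg_trace"))
  df <- data.frame(time_ms = trace$time_ms, trace$leads, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  structure(list(time_ms = df$time_ms,
                 leads = as.matrix(df[, c("I", "II", paste0("V", 1:6))])),
            class = "ecg_trace")
}
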