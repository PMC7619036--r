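# Volumetric stage of the electrophysiology pipeline: tetrahedralization,
# anatomical tags and coordinates, rule-based fibers, activation sites.

#' Tetrahedralize a watertight surface
#'
#' Fills the solid bounded by a watertight triangulated surface with a
#' conforming body-lattice tetrahedral mesh (Kuhn subdivision of lattice
#' cells whose centers lie inside the surface, by exact ray-parity tests).
#' Lattice edges are `target_edge`, `sqrt(2)*target_edge` and
#' `sqrt(3)*target_edge`, so the median edge length sits within the
#' `[0.5, 2] x target_edge` band, all tetrahedra are positively oriented,
#' and the mesh boundary approximates the input surface to within about one
#' lattice spacing.
#'
#' @param surface a watertight [tri_surface()].
#' @param target_edge lattice spacing in mm (default 3; halve for
#'   production-resolution meshes).
#' @return An object of class `tet_mesh` with `nodes`, `tets`, and
#'   per-node `boundary` flags.
#' @export
tetrahedralize <- function(surface, target_edge = 3.0) {
  stopifnot(inherits(surface, "tri_surface"))
  assert_scalar_number(target_edge, "target_edge", lower = 0.1)
  nb <- nrow(boundary_edges(surface$faces))
  if (nb > 0L) {
    stop(sprintf("surface is not watertight (%d boundary edges)", nb),
         call. = FALSE)
  }
  V <- surface$vertices
  lo <- apply(V, 2, min) - 1.5 * target_edge
  hi <- apply(V, 2, max) + 1.5 * target_edge
  n <- ceiling((hi - lo) / target_edge)
  cen <- lapply(1:3, function(d) lo[d] + (seq_len(n[d]) - 0.5) * target_edge)
  inside <- array(cpp_grid_inside(cen[[1]], cen[[2]], cen[[3]], V,
                                  surface$faces), dim = n)
  if (!any(inside)) stop("no lattice cell lies inside the surface", call. = FALSE)
  lt <- lattice_tets(list(origin = lo, h = target_edge, dims = n,
                          keep = inside))
  lt <- largest_component(lt$nodes, lt$tets)
  bf <- boundary_faces(lt$tets)
  boundary <- logical(nrow(lt$nodes))
  boundary[unique(as.vector(bf))] <- TRUE
  structure(list(nodes = lt$nodes, tets = lt$tets, boundary = boundary,
                 h = target_edge), class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tets (h = %g mm)%s%s\n",
              nrow(x$nodes), nrow(x$tets), x$h,
              if (!is.null(x$tags)) ", tagged" else "",
              if (!is.null(x$fibers)) ", fibers" else ""))
  invisible(x)
}

# Per-element linear gradient of a nodal field.
element_gradients <- function(mesh, field) {
  x1 <- mesh$nodes[mesh$tets[, 1], , drop = FALSE]
  e1 <- mesh$nodes[mesh$tets[, 2], , drop = FALSE] - x1
  e2 <- mesh$nodes[mesh$tets[, 3], , drop = FALSE] - x1
  e3 <- mesh$nodes[mesh$tets[, 4], , drop = FALSE] - x1
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c23 <- cr(e2, e3); c31 <- cr(e3, e1); c12 <- cr(e1, e2)
  det <- rowSums(e1 * c23)
  d1 <- field[mesh$tets[, 2]] - field[mesh$tets[, 1]]
  d2 <- field[mesh$tets[, 3]] - field[mesh$tets[, 1]]
  d3 <- field[mesh$tets[, 4]] - field[mesh$tets[, 1]]
  (d1 * c23 + d2 * c31 + d3 * c12) / det
}

#' Tag mesh nodes and compute anatomical coordinates
#'
#' Classifies boundary nodes as LV endocardium, RV endocardium, epicardium
#' or base (by nearest original surface and basal-plane proximity), derives
#' the normalized apex-base coordinate along the long axis, and solves the
#' transmural coordinate as a harmonic (Laplace) interpolation between the
#' endocardial (0) and epicardial (1) boundaries on the tetrahedral graph.
#'
#' @param mesh a `tet_mesh` from [tetrahedralize()].
#' @param lv_endo,lv_epi,rv_endo,rv_epi the [tri_surface()] objects the
#'   mesh was assembled from.
#' @return The mesh with `tags`, `apex_base`, `transmural`, `theta` (global
#'   circumferential angle, 0 toward the RV) and `long_axis` added.
#' @export
assign_anatomy <- function(mesh, lv_endo, lv_epi, rv_endo, rv_epi) {
  stopifnot(inherits(mesh, "tet_mesh"))
  nn <- nrow(mesh$nodes)
  tags <- rep("interior", nn)
  bidx <- which(mesh$boundary)
  bn <- mesh$nodes[bidx, , drop = FALSE]
  thin <- function(V) V[seq(1, nrow(V), by = 2), , drop = FALSE]
  d_lv <- cpp_nn_dist(bn, thin(lv_endo$vertices))
  d_rv <- cpp_nn_dist(bn, thin(rv_endo$vertices))
  d_ep <- cpp_nn_dist(bn, thin(rbind(lv_epi$vertices, rv_epi$vertices)))
  pick <- max.col(-cbind(d_lv, d_rv, d_ep), ties.method = "first")
  tags[bidx] <- c("lv_endo", "rv_endo", "epi")[pick]
  # long axis from the LV epicardium; apex = end with the smaller girth
  fr <- canonical_frame(lv_epi$vertices)
  u_all <- drop(sweep(mesh$nodes, 2, fr$center) %*% fr$e1)
  uv <- drop(sweep(lv_epi$vertices, 2, fr$center) %*% fr$e1)
  rad <- sqrt(rowSums((sweep(lv_epi$vertices, 2, fr$center) -
                       outer(uv, fr$e1))^2))
  qs <- quantile(uv, c(0.15, 0.85))
  axis <- fr$e1
  if (mean(rad[uv <= qs[1]]) > mean(rad[uv >= qs[2]])) {
    axis <- -fr$e1
    u_all <- -u_all
  }
  u01 <- (u_all - min(u_all)) / (max(u_all) - min(u_all))
  base <- mesh$boundary & u01 > 1 - 1.2 * mesh$h / diff(range(u_all))
  tags[base] <- "base"
  # circumferential angle about the long axis, zero toward the RV centroid
  sept <- colMeans(rv_endo$vertices) - colMeans(lv_endo$vertices)
  sept <- sept - sum(sept * axis) * axis
  sept <- sept / sqrt(sum(sept^2))
  e3 <- c(axis[2] * sept[3] - axis[3] * sept[2],
          axis[3] * sept[1] - axis[1] * sept[3],
          axis[1] * sept[2] - axis[2] * sept[1])
  rel <- sweep(mesh$nodes, 2, colMeans(mesh$nodes))
  theta <- atan2(drop(rel %*% e3), drop(rel %*% sept))
  # harmonic transmural coordinate
  dir0 <- tags %in% c("lv_endo", "rv_endo")
  dir1 <- tags == "epi"
  if (!any(dir0) || !any(dir1)) {
    stop("missing endocardial or epicardial tags", call. = FALSE)
  }
  edges <- rbind(mesh$tets[, c(1, 2)], mesh$tets[, c(1, 3)],
                 mesh$tets[, c(1, 4)], mesh$tets[, c(2, 3)],
                 mesh$tets[, c(2, 4)], mesh$tets[, c(3, 4)])
  key <- pmin(edges[, 1], edges[, 2]) * (nn + 1) + pmax(edges[, 1], edges[, 2])
  edges <- edges[!duplicated(key), , drop = FALSE]
  tau <- numeric(nn)
  tau[dir1] <- 1
  free <- !(dir0 | dir1)
  if (any(free)) {
    i <- c(edges[, 1], edges[, 2])
    j <- c(edges[, 2], edges[, 1])
    deg <- tabulate(i, nn)
    L <- Matrix::sparseMatrix(i = c(i, seq_len(nn)), j = c(j, seq_len(nn)),
                              x = c(rep(-1, length(i)), deg),
                              dims = c(nn, nn))
    fi <- which(free)
    rhs <- -L[fi, !free, drop = FALSE] %*% tau[!free]
    # tiny Tikhonov term keeps the system nonsingular when a few nodes are
    # disconnected from every tagged boundary (stair-step islands); such
    # nodes land near 0 and are clamped below
    A <- L[fi, fi] + Matrix::Diagonal(length(fi), 1e-8)
    tau[fi] <- as.numeric(Matrix::solve(A, rhs))
  }
  tau <- pmin(pmax(tau, 0), 1)
  mesh$tags <- tags
  mesh$apex_base <- u01
  mesh$transmural <- tau
  mesh$theta <- theta
  mesh$long_axis <- axis
  mesh
}

#' Assign rule-based myocardial fiber frames
#'
#' Per element: the sheet (transmural) direction is the normalized gradient
#' of the transmural coordinate, the fiber direction lies in the
#' perpendicular plane at a helix angle varying linearly from +60 deg on
#' the endocardium to -60 deg on the epicardium, and the normal completes
#' the right-handed orthonormal frame.
#'
#' @param mesh a tagged `tet_mesh` (see [assign_anatomy()]).
#' @return The mesh with an `fibers` matrix (`n_tets x 9`: f, s, n).
#' @export
assign_fibers <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (is.null(mesh$transmural)) {
    stop("run assign_anatomy() first (transmural coordinate missing)",
         call. = FALSE)
  }
  g <- element_gradients(mesh, mesh$transmural)
  gl <- sqrt(rowSums(g^2))
  cen <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
          mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  rel <- sweep(cen, 2, colMeans(mesh$nodes))
  ax <- mesh$long_axis
  radial <- rel - outer(drop(rel %*% ax), ax)
  rl <- sqrt(rowSums(radial^2)); rl[rl == 0] <- 1
  bad <- gl < 1e-9
  g[bad, ] <- radial[bad, , drop = FALSE] / rl[bad]
  gl[bad] <- 1
  s <- g / gl
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  A <- matrix(ax, nrow(s), 3, byrow = TRUE)
  circ <- cr(A, s)
  cl <- sqrt(rowSums(circ^2))
  deg <- cl < 1e-9
  if (any(deg)) {
    circ[deg, ] <- cr(matrix(c(1, 0, 0), sum(deg), 3, byrow = TRUE),
                      s[deg, , drop = FALSE])
    cl[deg] <- sqrt(rowSums(circ[deg, , drop = FALSE]^2))
  }
  circ <- circ / cl
  tau_el <- (mesh$transmural[mesh$tets[, 1]] + mesh$transmural[mesh$tets[, 2]] +
             mesh$transmural[mesh$tets[, 3]] + mesh$transmural[mesh$tets[, 4]]) / 4
  alpha <- (60 - 120 * tau_el) * pi / 180
  sxc <- cr(s, circ)
  f <- cos(alpha) * circ + sin(alpha) * sxc
  f <- f / sqrt(rowSums(f^2))
  n <- cr(f, s)
  n <- n / sqrt(rowSums(n^2))
  mesh$fibers <- cbind(f, s, n)
  colnames(mesh$fibers) <- c("fx", "fy", "fz", "sx", "sy", "sz",
                             "nx", "ny", "nz")
  mesh$helix_angle <- alpha * 180 / pi
  mesh
}

#' Default earliest-activation sites
#'
#' Selects seven endocardial root nodes at fixed homologous anatomical
#' positions: four on the LV endocardium (mid-septum, basal anterior
#' paraseptal, two mid-posterior) and three on the RV endocardium
#' (mid-septum, two free-wall).  Nodes are chosen deterministically as the
#' nearest tagged node to each rule-based (apex-base, circumferential)
#' coordinate.
#'
#' @param mesh a tagged `tet_mesh`.
#' @return Integer vector of 7 node indices, named by site.
#' @export
default_activation_sites <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (is.null(mesh$tags)) stop("mesh is missing surface tags", call. = FALSE)
  pick <- function(tag, u0, th0) {
    idx <- which(mesh$tags == tag)
    if (length(idx) == 0L) stop("missing tag: ", tag, call. = FALSE)
    dth <- abs(atan2(sin(mesh$theta[idx] - th0), cos(mesh$theta[idx] - th0)))
    score <- ((mesh$apex_base[idx] - u0) / 0.10)^2 + (dth / 0.30)^2
    idx[which.min(score)]
  }
  sites <- c(lv_mid_septum = pick("lv_endo", 0.50, 0),
             lv_basal_ant_paraseptal = pick("lv_endo", 0.75, 0.9),
             lv_mid_posterior_1 = pick("lv_endo", 0.50, -1.9),
             lv_mid_posterior_2 = pick("lv_endo", 0.40, -2.5),
             rv_mid_septum = pick("rv_endo", 0.50, 0.25),
             rv_free_wall_1 = pick("rv_endo", 0.55, 1.1),
             rv_free_wall_2 = pick("rv_endo", 0.40, 0.7))
  sites
}
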