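# Surface stage of the electrophysiology pipeline: triangulated surface
# reconstruction from class point clouds, the 3 mm RV epicardial offset, and
# the watertight biventricular merge.

#' Construct a triangulated surface
#'
#' @param vertices numeric `n x 3` matrix (mm).
#' @param faces integer `m x 3` matrix of 1-based vertex indices.
#' @param class_id optional substructure tag carried per vertex.
#' @return An object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, faces, class_id = NA_integer_) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  stopifnot(ncol(vertices) == 3L)
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  ar <- triangle_areas(list(V = vertices, F = faces))
  if (any(ar <= 0)) stop("degenerate faces in surface", call. = FALSE)
  structure(list(vertices = vertices, faces = faces,
                 class_id = as.integer(class_id)), class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  nb <- nrow(boundary_edges(x$faces))
  cat(sprintf("<tri_surface> %d vertices, %d faces, %d boundary edges%s\n",
              nrow(x$vertices), nrow(x$faces), nb,
              if (is.na(x$class_id)) "" else sprintf(" (class %d)", x$class_id)))
  invisible(x)
}

#' Surface area of a triangulated surface
#'
#' @param surface a [tri_surface()].
#' @return Total area in mm^2.
#' @export
surface_area <- function(surface) {
  stopifnot(inherits(surface, "tri_surface"))
  sum(triangle_areas(list(V = surface$vertices, F = surface$faces)))
}

#' Reconstruct a triangulated surface from a class point cloud
#'
#' Ventricular surfaces (including the crescent RV) are star-shaped about
#' their long axis, so the surface is recovered on a cylindrical lattice: a
#' smoothed radius map over axial bands x azimuthal sectors about the
#' PCA long axis, triangulated as a lattice, with each end closed by an
#' apex fan when the cloud closes there (small end-ring radius) and left
#' open otherwise (the basal opening).  The result is a 2-manifold mesh
#' robust to the sampling noise of decoded clouds.
#'
#' @param cloud an [mc_point_cloud()] or bare point matrix.
#' @param class_id substructure to extract when `cloud` is multi-class.
#' @param n_bands axial resolution; defaults from the point count.
#' @return A [tri_surface()].
#' @export
surface_from_cloud <- function(cloud, class_id = NULL, n_bands = NULL) {
  X <- if (inherits(cloud, "mc_point_cloud")) {
    if (is.null(class_id)) stop("`class_id` required for multi-class clouds",
                                call. = FALSE)
    cloud_class_points(cloud, class_id)
  } else {
    as_points3(cloud)
  }
  if (nrow(X) < 500L) {
    stop(sprintf("need >= 500 points for surface reconstruction, got %d",
                 nrow(X)), call. = FALSE)
  }
  fr <- canonical_frame(X)
  u <- fr$u
  theta <- atan2(fr$w, fr$v)
  r <- sqrt(fr$v^2 + fr$w^2)
  n <- nrow(X)
  n_u <- n_bands %||% max(10L, round(sqrt(n / 6)))
  n_th <- 2L * n_u
  u_lo <- min(u); u_hi <- max(u)
  span <- u_hi - u_lo
  # lattice vertices at band centers; smoothed radius by a separable
  # Gaussian kernel in (axial, azimuthal) distance
  uc <- u_lo + span * (seq_len(n_u) - 0.5) / n_u
  thc <- -pi + 2 * pi * (seq_len(n_th) - 0.5) / n_th
  hu <- 0.7 * span / n_u
  hth <- 0.7 * 2 * pi / n_th
  R <- matrix(0, n_u, n_th)
  for (i in seq_len(n_u)) {
    wu <- exp(-0.5 * ((u - uc[i]) / hu)^2)
    keep <- wu > 0.01
    if (!any(keep)) { R[i, ] <- NA; next }
    tk <- theta[keep]; rk <- r[keep]; wk <- wu[keep]
    for (j in seq_len(n_th)) {
      dth <- pmin(abs(tk - thc[j]), 2 * pi - abs(tk - thc[j]))
      w <- wk * exp(-0.5 * (dth / hth)^2)
      sw <- sum(w)
      R[i, j] <- if (sw > 1e-9) sum(w * rk) / sw else NA_real_
    }
  }
  # fill any empty lattice cells from azimuthal neighbours
  for (i in seq_len(n_u)) {
    row <- R[i, ]
    if (anyNA(row)) {
      ok <- which(!is.na(row))
      if (length(ok) == 0L) {
        R[i, ] <- if (i > 1) R[i - 1, ] else 0
      } else {
        for (j in which(is.na(row))) {
          dd <- pmin(abs(thc[j] - thc[ok]), 2 * pi - abs(thc[j] - thc[ok]))
          row[j] <- row[ok[which.min(dd)]]
        }
        R[i, ] <- row
      }
    }
  }
  E <- cbind(fr$e1, fr$e2, fr$e3)
  ring <- function(i) {
    local <- cbind(rep(uc[i], n_th), R[i, ] * cos(thc), R[i, ] * sin(thc))
    sweep(local %*% t(E), 2, fr$center, "+")
  }
  V <- do.call(rbind, lapply(seq_len(n_u), ring))
  idx <- function(i, j) (i - 1L) * n_th + ((j - 1L) %% n_th) + 1L
  i_band <- rep(seq_len(n_u - 1L), each = n_th)
  j_band <- rep(seq_len(n_th), n_u - 1L)
  Fc <- rbind(cbind(idx(i_band, j_band), idx(i_band, j_band + 1L),
                    idx(i_band + 1L, j_band + 1L)),
              cbind(idx(i_band, j_band), idx(i_band + 1L, j_band + 1L),
                    idx(i_band + 1L, j_band)))
  mean_r <- mean(r)
  # close an end with an apex fan when the cloud closes there; the decision
  # uses the raw radii of the points in the extreme band, not the smoothed
  # lattice, so wide smoothing kernels cannot mask a closed pole
  raw_lo <- mean(r[u <= u_lo + span / n_u])
  raw_hi <- mean(r[u >= u_hi - span / n_u])
  jj <- seq_len(n_th)
  if (raw_lo < 0.45 * mean_r) {
    apex <- fr$center + (u_lo) * fr$e1
    V <- rbind(V, apex)
    Fc <- rbind(Fc, cbind(nrow(V), idx(1L, jj), idx(1L, jj + 1L)))
  }
  if (raw_hi < 0.45 * mean_r) {
    top <- fr$center + (u_hi) * fr$e1
    V <- rbind(V, top)
    Fc <- rbind(Fc, cbind(nrow(V), idx(n_u, jj + 1L), idx(n_u, jj)))
  }
  cid <- if (inherits(cloud, "mc_point_cloud")) class_id else NA_integer_
  tri_surface(V, Fc, cid %||% NA_integer_)
}

vertex_normals <- function(V, F) {
  A <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - A
  e2 <- V[F[, 3], , drop = FALSE] - A
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  acc <- rowsum(rbind(fn, fn, fn), as.vector(F))
  N <- matrix(0, nrow(V), 3)
  N[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(N^2)); len[len == 0] <- 1
  N / len
}

#' Offset the RV endocardium to an approximate RV epicardium
#'
#' Moves every vertex outward along its unit vertex normal by `thickness`
#' (the RV free wall cannot be resolved at cine-MR resolution, so the
#' epicardium is approximated as a fixed 3 mm offset).  Normal orientation
#' is made outward (away from the surface centroid); if the offset flips
#' any triangle, the affected vertices are locally relaxed by neighbourhood
#' averaging.
#'
#' @param rv_endo a [tri_surface()] of the RV endocardium.
#' @param thickness offset in mm (default 3).
#' @return A [tri_surface()] with the same connectivity.
#' @export
offset_rv_epicardium <- function(rv_endo, thickness = 3.0) {
  stopifnot(inherits(rv_endo, "tri_surface"))
  assert_scalar_number(thickness, "thickness", lower = 0)
  V <- rv_endo$vertices; F <- rv_endo$faces
  N <- vertex_normals(V, F)
  cen <- colMeans(V)
  # orient outward: globally, then per vertex (ventricular surfaces are
  # star-shaped about their centroid, so the radial sign is reliable even
  # where sliver triangles corrupt an individual vertex normal)
  radial <- rowSums((V - matrix(cen, nrow(V), 3, byrow = TRUE)) * N)
  if (mean(radial) < 0) {
    N <- -N
    radial <- -radial
  }
  N[radial < 0, ] <- -N[radial < 0, , drop = FALSE]
  V2 <- V + thickness * N
  # detect flipped triangles and relax their vertices toward the local mean
  flipped <- function(Va, Vb) {
    na <- vertex_normals(Va, F); nb <- vertex_normals(Vb, F)
    which(rowSums(na * nb) < 0)
  }
  bad <- flipped(V, V2)
  it <- 0L
  while (length(bad) > 0L && it < 10L) {
    nb_acc <- rowsum(rbind(V2[F[, 2], ] + V2[F[, 3], ],
                           V2[F[, 1], ] + V2[F[, 3], ],
                           V2[F[, 1], ] + V2[F[, 2], ]), as.vector(F))
    cnt <- 2 * tabulate(as.vector(F), nrow(V2))
    lap <- nb_acc[as.character(seq_len(nrow(V2))), ] / cnt
    V2[bad, ] <- 0.5 * V2[bad, , drop = FALSE] + 0.5 * lap[bad, , drop = FALSE]
    bad <- flipped(V, V2)
    it <- it + 1L
  }
  structure(list(vertices = V2, faces = F, class_id = rv_endo$class_id),
            class = "tri_surface")
}

# Close all boundary loops of an open surface with centroid fans.
close_surface <- function(surface) {
  m <- cap_mesh(list(V = surface$vertices, F = surface$faces))
  m
}

#' Assemble the watertight biventricular myocardial surface
#'
#' Builds the myocardial solid as the boolean region
#' `(inside LV epi or inside RV epi) and not inside either endocardial
#' cavity` (each open surface closed across its basal rim), discretizes it
#' on a fine body lattice, and returns the watertight boundary of the
#' lattice solid: a single closed 2-manifold joining the endocardial,
#' epicardial and basal surfaces, with the cavities preserved as basal
#' recesses.
#'
#' @param lv_endo,lv_epi,rv_endo,rv_epi [tri_surface()] objects.
#' @param grid_res lattice spacing in mm (default 1.25).
#' @return A [tri_surface()]; the underlying lattice solid is attached as
#'   attribute `"lattice"` for reuse.
#' @export
assemble_biventricular <- function(lv_endo, lv_epi, rv_endo, rv_epi,
                                   grid_res = 1.25) {
  for (s in list(lv_endo, lv_epi, rv_endo, rv_epi)) {
    stopifnot(inherits(s, "tri_surface"))
  }
  assert_scalar_number(grid_res, "grid_res", lower = 0.1)
  closed <- lapply(list(lv_endo = lv_endo, lv_epi = lv_epi,
                        rv_endo = rv_endo, rv_epi = rv_epi), close_surface)
  allV <- do.call(rbind, lapply(closed, `[[`, "V"))
  lo <- apply(allV, 2, min) - 2 * grid_res
  hi <- apply(allV, 2, max) + 2 * grid_res
  nx <- ceiling((hi[1] - lo[1]) / grid_res)
  ny <- ceiling((hi[2] - lo[2]) / grid_res)
  nz <- ceiling((hi[3] - lo[3]) / grid_res)
  # classify cell centers
  xc <- lo[1] + (seq_len(nx) - 0.5) * grid_res
  yc <- lo[2] + (seq_len(ny) - 0.5) * grid_res
  zc <- lo[3] + (seq_len(nz) - 0.5) * grid_res
  ins <- lapply(closed, function(m) {
    array(cpp_grid_inside(xc, yc, zc, m$V, m$F), dim = c(nx, ny, nz))
  })
  myo <- (ins$lv_epi & !ins$lv_endo) | (ins$rv_epi & !ins$rv_endo)
  if (!any(myo)) stop("empty myocardial region; check surface orientation",
                      call. = FALSE)
  lattice <- list(origin = lo, h = grid_res, dims = c(nx, ny, nz), keep = myo)
  tm <- lattice_tets(lattice)
  bf <- boundary_faces(tm$tets)
  used <- sort(unique(as.vector(bf)))
  remap <- integer(nrow(tm$nodes)); remap[used] <- seq_along(used)
  out <- tri_surface(tm$nodes[used, , drop = FALSE],
                     matrix(remap[bf], ncol = 3L))
  attr(out, "lattice") <- lattice
  out
}

# Kuhn 6-tetrahedra subdivision of the kept lattice cells; the subdivision
# is translation-invariant, so shared faces between neighbouring cells are
# conforming.  Returns positively oriented tets and the node coordinates.
lattice_tets <- function(lattice) {
  dims <- lattice$dims; h <- lattice$h; lo <- lattice$origin
  keep <- which(lattice$keep)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ci <- (keep - 1L) %% nx
  cj <- ((keep - 1L) %/% nx) %% ny
  ck <- (keep - 1L) %/% (nx * ny)
  nxx <- nx + 1L; nyy <- ny + 1L
  vid <- function(i, j, k) 1L + i + nxx * (j + nyy * k)
  corner <- function(di, dj, dk) vid(ci + di, cj + dj, ck + dk)
  c000 <- corner(0L, 0L, 0L); c100 <- corner(1L, 0L, 0L)
  c010 <- corner(0L, 1L, 0L); c110 <- corner(1L, 1L, 0L)
  c001 <- corner(0L, 0L, 1L); c101 <- corner(1L, 0L, 1L)
  c011 <- corner(0L, 1L, 1L); c111 <- corner(1L, 1L, 1L)
  tets <- rbind(cbind(c000, c100, c110, c111),
                cbind(c000, c110, c010, c111),
                cbind(c000, c010, c011, c111),
                cbind(c000, c011, c001, c111),
                cbind(c000, c001, c101, c111),
                cbind(c000, c101, c100, c111))
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nxx * nyy * (nz + 1L)); remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4L)
  gi <- (used - 1L) %% nxx
  gj <- ((used - 1L) %/% nxx) %% nyy
  gk <- (used - 1L) %/% (nxx * nyy)
  nodes <- cbind(lo[1] + gi * h, lo[2] + gj * h, lo[3] + gk * h)
  # enforce positive orientation
  vol <- tet_volumes(nodes, tets)
  if (any(vol < 0)) {
    flip <- vol < 0
    tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  }
  list(nodes = nodes, tets = tets)
}

# Largest connected component of a tet mesh (node-sharing connectivity);
# stair-step discretization can leave a few isolated cell islands.
largest_component <- function(nodes, tets) {
  nn <- nrow(nodes)
  parent <- seq_len(nn)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in 2:4) {
    a <- tets[, 1]; b <- tets[, k]
    for (i in seq_along(a)) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(nn), find, integer(1))
  main <- as.integer(names(which.max(table(roots))))
  keep_node <- roots == main
  keep_tet <- keep_node[tets[, 1]]
  remap <- integer(nn)
  remap[keep_node] <- seq_len(sum(keep_node))
  list(nodes = nodes[keep_node, , drop = FALSE],
       tets = matrix(remap[tets[keep_tet, ]], ncol = 4L))
}

tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  d <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

# Faces (as vertex triples) belonging to exactly one tetrahedron.
boundary_faces <- function(tets) {
  f <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
             tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  N <- max(f) + 1
  a <- pmin(f[, 1], f[, 2], f[, 3])
  cc <- pmax(f[, 1], f[, 2], f[, 3])
  b <- f[, 1] + f[, 2] + f[, 3] - a - cc
  key <- (a * N + b) * N + cc
  single <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  f[single, , drop = FALSE]
}
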