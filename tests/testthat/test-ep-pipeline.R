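test_that("surface reconstruction recovers a sphere", {
  sp <- sphere_points(2500, r = 30, seed = 5)
  surf <- surface_from_cloud(sp)
  # closed genus-0 surface: no boundary edges, Euler characteristic 2
  expect_equal(nrow(cardiopoint:::boundary_edges(surf$faces)), 0L)
  ne <- nrow(unique(t(apply(cbind(rbind(surf$faces[, 1:2], surf$faces[, 2:3],
                                        surf$faces[, c(3, 1)])), 1, sort))))
  chi <- nrow(surf$vertices) - ne + nrow(surf$faces)
  expect_equal(chi, 2L)
  expect_lt(abs(surface_area(surf) / (4 * pi * 30^2) - 1), 0.10)
  # covers >= 95% of the input within twice the mean point spacing
  d <- cardiopoint:::cpp_nn_dist(sp, surf$vertices)
  spacing <- sqrt(4 * pi * 30^2 / nrow(sp))
  expect_gte(mean(d <= 2 * spacing), 0.95)
  # surface vertices stay near the input cloud
  dv <- cardiopoint:::cpp_nn_dist(surf$vertices, sp)
  expect_lt(quantile(dv, 0.99), 3 * spacing)
  expect_error(surface_from_cloud(sp[1:100, ]), "500")
})

test_that("ventricular surfaces stay open at the base and near the cloud", {
  s <- tiny_cohort()[[1]]
  big <- build_anatomy(sample_population_params(1, 0, seed = 13), 1024L,
                       seed = 5)
  for (cl in 1:3) {
    pts <- cloud_class_points(big$ed, cl)
    surf <- surface_from_cloud(big$ed, cl)
    expect_gt(nrow(cardiopoint:::boundary_edges(surf$faces)), 0L)  # open base
    d <- cardiopoint:::cpp_nn_dist(pts, surf$vertices)
    spacing <- sqrt(surface_area(surf) / nrow(pts))
    expect_gte(mean(d <= 2 * spacing), 0.95)
  }
})

test_that("RV epicardial offset displaces along normals by the thickness", {
  # analytic sphere mesh: the offset must give a sphere of radius 33
  sph <- cardiopoint:::ellipsoid_mesh(30, 30, n_th = 40L, n_ph = 80L)
  surf <- tri_surface(sph$V, sph$F)
  off <- offset_rv_epicardium(surf, 3)
  disp <- sqrt(rowSums((off$vertices - surf$vertices)^2))
  expect_lt(max(abs(disp - 3)), 1e-6)
  radii <- sqrt(rowSums(off$vertices^2))
  expect_lt(max(abs(radii - 33)), 0.1)
  ident <- offset_rv_epicardium(surf, 0)
  expect_equal(ident$vertices, surf$vertices)
  # a cloud-reconstructed sphere stays close to the analytic offset
  # (reconstruction noise dominates; a few seam vertices are worst)
  rec <- surface_from_cloud(sphere_points(2500, r = 30, seed = 6))
  off2 <- offset_rv_epicardium(rec, 3)
  err2 <- abs(sqrt(rowSums(off2$vertices^2)) - 33)
  expect_lt(median(err2), 0.5)
  expect_lt(max(err2), 2.5)
})

test_that("the assembled biventricular surface is watertight", {
  big <- cached("ep_anatomy",
                build_anatomy(sample_population_params(1, 0, seed = 13),
                              1024L, seed = 5))
  lv_endo <- surface_from_cloud(big$ed, 1L)
  lv_epi <- surface_from_cloud(big$ed, 2L)
  rv_endo <- surface_from_cloud(big$ed, 3L)
  rv_epi <- offset_rv_epicardium(rv_endo, 3)
  merged <- cached("ep_merged",
                   assemble_biventricular(lv_endo, lv_epi, rv_endo, rv_epi,
                                          grid_res = 1.5))
  expect_equal(nrow(cardiopoint:::boundary_edges(merged$faces)), 0L)
  # closed orientable boundary: even Euler characteristic
  e <- rbind(merged$faces[, 1:2], merged$faces[, 2:3], merged$faces[, c(3, 1)])
  key <- pmin(e[, 1], e[, 2]) * (max(e) + 1) + pmax(e[, 1], e[, 2])
  chi <- nrow(merged$vertices) - length(unique(key)) + nrow(merged$faces)
  expect_equal(chi %% 2, 0)
  # enclosed myocardial volume is positive and plausible
  vol <- abs(cardiopoint:::signed_volume(list(V = merged$vertices,
                                              F = merged$faces)))
  expect_gt(vol, 5e4)
})

test_that("lattice tetrahedralization meets its size and volume contract", {
  box <- box_surface(30, 21, 12)
  mesh <- tetrahedralize(box, target_edge = 1.5)
  vols <- cardiopoint:::tet_volumes(mesh$nodes, mesh$tets)
  expect_true(all(vols > 0))
  expect_lt(abs(sum(vols) / (30 * 21 * 12) - 1), 0.01)
  e <- rbind(mesh$tets[, c(1, 2)], mesh$tets[, c(1, 3)], mesh$tets[, c(1, 4)],
             mesh$tets[, c(2, 3)], mesh$tets[, c(2, 4)], mesh$tets[, c(3, 4)])
  len <- sqrt(rowSums((mesh$nodes[e[, 1], ] - mesh$nodes[e[, 2], ])^2))
  expect_gte(median(len), 0.5 * 1.5)
  expect_lte(median(len), 2 * 1.5)
  # coarser target -> fewer nodes; boundary stays within one spacing
  mesh3 <- tetrahedralize(box, target_edge = 3)
  expect_lt(nrow(mesh3$nodes), nrow(mesh$nodes))
  bn <- mesh$nodes[mesh$boundary, ]
  dist_box <- function(p) {
    dx <- pmax(pmax(0 - p[, 1], p[, 1] - 30), 0)
    inside <- pmin(pmin(p[, 1], 30 - p[, 1]),
                   pmin(p[, 2], 21 - p[, 2]),
                   pmin(p[, 3], 12 - p[, 3]))
    pmax(dx, ifelse(inside > 0, inside, 0)) * 0 + inside
  }
  expect_lt(max(abs(dist_box(bn))), 1.5 + 1e-9)
  # open surfaces are refused
  open_surf <- tri_surface(box$vertices, box$faces[-1, ])
  expect_error(tetrahedralize(open_surf), "watertight")
})

test_that("anatomical tags, coordinates and fibers are consistent", {
  mesh <- cached("ep_mesh", {
    merged <- cached("ep_merged", stop("run assembly test first"))
    big <- cached("ep_anatomy", stop("missing"))
    lv_endo <- surface_from_cloud(big$ed, 1L)
    lv_epi <- surface_from_cloud(big$ed, 2L)
    rv_endo <- surface_from_cloud(big$ed, 3L)
    m <- tetrahedralize(merged, target_edge = 3)
    m <- assign_anatomy(m, lv_endo, lv_epi, rv_endo,
                        offset_rv_epicardium(rv_endo, 3))
    assign_fibers(m)
  })
  expect_setequal(unique(mesh$tags),
                  c("interior", "lv_endo", "rv_endo", "epi", "base"))
  expect_true(all(mesh$transmural >= 0 & mesh$transmural <= 1))
  expect_true(all(mesh$apex_base >= 0 & mesh$apex_base <= 1))
  fb <- mesh$fibers
  f <- fb[, 1:3]; s <- fb[, 4:6]; n <- fb[, 7:9]
  expect_lt(max(abs(rowSums(f * s))), 1e-6)
  expect_lt(max(abs(rowSums(f * n))), 1e-6)
  expect_lt(max(abs(rowSums(s * n))), 1e-6)
  expect_lt(max(abs(rowSums(f^2) - 1)), 1e-6)
  # helix angle: near +60 deg close to the endocardium, near 0 mid-wall
  tau_el <- (mesh$transmural[mesh$tets[, 1]] + mesh$transmural[mesh$tets[, 2]] +
             mesh$transmural[mesh$tets[, 3]] +
             mesh$transmural[mesh$tets[, 4]]) / 4
  expect_true(all(abs(mesh$helix_angle[tau_el < 0.05] - 60) < 7))
  mid <- abs(tau_el - 0.5) < 0.03
  expect_lt(mean(abs(mesh$helix_angle[mid])), 5)
})

test_that("the seven default activation sites sit on the endocardium", {
  mesh <- cached("ep_mesh", stop("missing"))
  sites <- default_activation_sites(mesh)
  expect_length(sites, 7L)
  tags <- mesh$tags[sites]
  expect_equal(sum(tags == "lv_endo"), 4L)
  expect_equal(sum(tags == "rv_endo"), 3L)
  expect_identical(sites, default_activation_sites(mesh))
})

test_that("isotropic eikonal solutions match d/v and a Dijkstra oracle", {
  skip_if_not_installed("igraph")
  mesh <- rod_mesh(45, 12, 9, h = 1.5)
  iso <- eikonal_config(1, 1, 1, 1, root_nodes = nearest_node(mesh, c(0, 0, 0)))
  act <- solve_eikonal(mesh, iso)
  src <- mesh$nodes[attr(act, "roots")[1], ]
  d <- sqrt(rowSums(sweep(mesh$nodes, 2, src)^2))
  far <- d > 7.5  # beyond a few cells of the point source
  expect_lt(max(abs(act[far] - d[far]) / d[far]), 0.05)
  # edge-graph shortest-path oracle
  e <- rbind(mesh$tets[, c(1, 2)], mesh$tets[, c(1, 3)], mesh$tets[, c(1, 4)],
             mesh$tets[, c(2, 3)], mesh$tets[, c(2, 4)], mesh$tets[, c(3, 4)])
  key <- pmin(e[, 1], e[, 2]) * (nrow(mesh$nodes) + 1) + pmax(e[, 1], e[, 2])
  e <- e[!duplicated(key), ]
  w <- sqrt(rowSums((mesh$nodes[e[, 1], ] - mesh$nodes[e[, 2], ])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  dj <- as.numeric(igraph::distances(g, v = attr(act, "roots")[1],
                                     weights = w))
  # the solver must not exceed the graph distance, and along lattice
  # directions (the rod axis) both agree tightly
  expect_true(all(act <= dj + 1e-6))
  axis_nodes <- which(abs(mesh$nodes[, 2] - src[2]) < 1e-9 &
                      abs(mesh$nodes[, 3] - src[3]) < 1e-9 & far)
  expect_lt(max(abs(act[axis_nodes] - dj[axis_nodes]) /
                pmax(dj[axis_nodes], 1e-9)), 0.05)
})

test_that("multi-root solutions equal the pointwise minimum of single roots", {
  mesh <- rod_mesh(30, 9, 9, h = 1.5)
  r1 <- nearest_node(mesh, c(0, 0, 0))
  r2 <- nearest_node(mesh, c(30, 9, 9))
  a1 <- solve_eikonal(mesh, eikonal_config(1, 1, 1, 1, root_nodes = r1))
  a2 <- solve_eikonal(mesh, eikonal_config(1, 1, 1, 1, root_nodes = r2))
  a12 <- solve_eikonal(mesh, eikonal_config(1, 1, 1, 1,
                                            root_nodes = c(r1, r2)))
  dev <- as.numeric(a12) - pmin(as.numeric(a1), as.numeric(a2))
  # the combined solve can only be earlier, and it matches exactly away
  # from the front-collision shock where linear face interpolation across
  # the kink is O(h)
  expect_true(all(dev <= 1e-6))
  away <- abs(as.numeric(a1) - as.numeric(a2)) > 3 * mesh$h
  expect_lt(max(abs(dev[away])), 1e-6)
  expect_lt(max(abs(dev)), 0.2 * mesh$h)
})

test_that("fiber anisotropy reproduces the velocity ratio", {
  # along: fibers down the rod; across: the frame NORMAL points down the
  # rod (fiber transverse, sheet vertical), so propagation runs at cv_normal
  along <- rod_mesh(45, 9, 9, h = 1.5, fiber = c(1, 0, 0), sheet = c(0, 0, 1))
  across <- rod_mesh(45, 9, 9, h = 1.5, fiber = c(0, 1, 0), sheet = c(0, 0, 1))
  cfg <- function(m) eikonal_config(0.67, 0.30, 0.17, 0.17,
                                    root_nodes = nearest_node(m, c(0, 4.5, 4.5)))
  probe <- function(m) {
    act <- solve_eikonal(m, cfg(m))
    act[nearest_node(m, c(45, 4.5, 4.5))]
  }
  t_along <- probe(along)
  t_across <- probe(across)
  expect_lt(abs(t_along / t_across - 0.17 / 0.67), 0.1 * 0.17 / 0.67)
})

test_that("activation times never increase when any velocity increases", {
  mesh <- cached("ep_mesh", stop("missing"))
  sites <- default_activation_sites(mesh)
  base <- eikonal_config(0.5, 0.25, 0.15, 0.8, root_nodes = sites)
  t0 <- as.numeric(solve_eikonal(mesh, base))
  set.seed(33)
  for (i in 1:5) {
    bump <- runif(4, 1.05, 1.6)
    cfg <- eikonal_config(0.5 * bump[1], 0.25 * bump[2], 0.15 * bump[3],
                          0.8 * bump[4], root_nodes = sites)
    t1 <- as.numeric(solve_eikonal(mesh, cfg))
    expect_true(all(t1 <= t0 + 1e-6))
  }
})

test_that("electrode layout is ordered and translation-equivariant", {
  mesh <- rod_mesh(30, 20, 20, h = 2)
  E <- default_electrodes(mesh)
  expect_equal(dim(E), c(9L, 3L))
  expect_identical(rownames(E), c("RA", "LA", "LL", paste0("V", 1:6)))
  vx <- E[paste0("V", 1:6), 1]
  expect_true(all(diff(vx) > 0))
  mesh2 <- mesh
  mesh2$nodes <- sweep(mesh$nodes, 2, c(10, -5, 3), "+")
  E2 <- default_electrodes(mesh2)
  expect_equal(E2, sweep(E, 2, c(10, -5, 3), "+"), tolerance = 1e-12)
})

test_that("pseudo-ECG respects rigid motion and conduction-speed scaling", {
  mesh <- cached("ep_mesh", stop("missing"))
  sites <- default_activation_sites(mesh)
  cfg1 <- eikonal_config(root_nodes = sites)
  act1 <- solve_eikonal(mesh, cfg1)
  E <- default_electrodes(mesh)
  tr1 <- pseudo_ecg(act1, mesh, E, dt = 1)
  expect_equal(ncol(tr1$leads), 8L)
  expect_true(all(is.finite(tr1$leads)))
  # joint translation leaves the trace unchanged
  mesh2 <- mesh
  mesh2$nodes <- sweep(mesh$nodes, 2, c(25, -10, 5), "+")
  tr2 <- pseudo_ecg(act1, mesh2, sweep(E, 2, c(25, -10, 5), "+"), dt = 1)
  expect_equal(tr2$leads, tr1$leads, tolerance = 1e-9)
  # doubling every conduction velocity rescales time by one half: with the
  # upstroke rise time scaled along, the QRS duration halves
  cfg2 <- eikonal_config(2 * 0.67, 2 * 0.30, 2 * 0.17, 2 * 1.20,
                         root_nodes = sites)
  act2 <- solve_eikonal(mesh, cfg2)
  tr_fast <- pseudo_ecg(act2, mesh, E, dt = 0.5, rise_ms = 0.5)
  expect_lt(abs(qrs_duration(tr_fast) / qrs_duration(tr1) - 0.5), 0.1)
})

test_that("the full pipeline is deterministic end-to-end", {
  big <- cached("ep_anatomy", stop("missing"))
  sim1 <- cached("ep_sim", simulate_ecg(big, grid_res = 1.5))
  sim2 <- simulate_ecg(big, grid_res = 1.5)
  expect_identical(as.numeric(sim1$activation), as.numeric(sim2$activation))
  expect_identical(sim1$trace$leads, sim2$trace$leads)
  expect_length(sim1$sites, 7L)
})

test_that("population QRS comparison scores are well-behaved", {
  sim <- cached("ep_sim", stop("missing"))
  base <- sim$trace
  # jittered copies emulate a small population
  jitter_trace <- function(tr, s) {
    set.seed(s)
    tr$leads <- tr$leads * (1 + 0.05 * rnorm(1)) +
      0.02 * sd(tr$leads) * matrix(rnorm(length(tr$leads)), nrow(tr$leads))
    tr
  }
  pop_a <- lapply(1:12, function(i) jitter_trace(base, i))
  pop_b <- lapply(13:24, function(i) jitter_trace(base, i))
  cmp <- qrs_population_compare(pop_a, pop_b, seed = 1)
  expect_equal(nrow(cmp), 8L)
  expect_true(all(is.finite(cmp$mmd_proposed)))
  self <- qrs_population_compare(pop_a, pop_a, seed = 1)
  expect_lt(max(abs(self$mmd_proposed)), 1e-10)
  expect_identical(qrs_population_compare(pop_a, pop_b, seed = 1)$mmd_gold_standard,
                   cmp$mmd_gold_standard)
  expect_error(qrs_population_compare(pop_a[1:3], pop_b), "10")
})

test_that("mesh and ECG text outputs round-trip", {
  sim <- cached("ep_sim", stop("missing"))
  f <- tempfile(fileext = ".vtk")
  write_vtk(sim$mesh, f, sim$activation)
  head <- readLines(f, n = 5)
  expect_match(head[4], "UNSTRUCTURED_GRID")
  f2 <- tempfile(fileext = ".csv")
  write_ecg_csv(sim$trace, f2)
  back <- read_ecg_csv(f2)
  expect_equal(back$leads, sim$trace$leads, tolerance = 1e-6)
})
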