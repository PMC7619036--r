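# Shared fixtures, built once per test run and cached.  Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# Small mixed cohort for module-level tests (256 points/class/phase).
tiny_cohort <- function() {
  cached("tiny_cohort", simulate_cohort(16, 0.5, 256L, seed = 42))
}

# A compact model trained enough for latent structure to emerge; shared by
# the latent-space and prediction tests.
tiny_model_config <- function(total_steps = 1500L, seed = 0L) {
  point_vae_config(n_input_points = 256L, enc_width = 24L, enc_hidden = 48L,
                   m_coarse = 96L, grid_side = 4L, fold_width = 24L,
                   dec_hidden = 48L, train_points = 128L,
                   fold_cells_train = 2L, total_steps = total_steps,
                   val_every = 500L, seed = seed)
}

tiny_trained_model <- function() {
  cached("tiny_trained_model", {
    cohort <- cached("tiny_train_cohort",
                     simulate_cohort(48, 0.5, 256L, seed = 7))
    train_point_vae(point_vae(tiny_model_config()), cohort[1:42],
                    cohort[43:48])
  })
}

tiny_train_cohort <- function() {
  tiny_trained_model()  # ensures the cohort cache is filled
  cached("tiny_train_cohort", stop("unreachable"))
}

# The package's standard experiment: 600-subject cohort, 70/5/25 split,
# desk-scale training.  Built once and shared by the acceptance blocks and
# the latent-space quality tests.
acceptance <- function() {
  cached("acceptance", {
    cohort <- simulate_cohort(600, mi_fraction = 0.3,
                              points_per_class = 1024L, seed = 0)
    split <- split_dataset(cohort, c(0.70, 0.05, 0.25), seed = 1)
    model <- train_point_vae(point_vae(point_vae_config(seed = 0)),
                             split$train, split$val)
    list(cohort = cohort, split = split, model = model)
  })
}

# Cohort in which exactly four generative factors vary (size, elongation,
# wall thickness, ejection fraction); the rest are frozen at their means.
four_factor_cohort <- function(n, seed) {
  params <- sample_population_params(n, 0.5, seed)
  params$basal_tilt <- 0
  params$rv_size <- 1
  params$rv_ef_target <- pmin(pmax(0.9 * params$ef_target + 0.08, 0.2), 0.8)
  lapply(seq_len(n), function(i) {
    build_anatomy(params[i, ], 256L, seed = seed + i,
                  subject_id = sprintf("F%03d", i))
  })
}

# Uniform sphere sample (area-uniform by symmetry).
sphere_points <- function(n, r = 30, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  r * u / sqrt(rowSums(u^2))
}

# Axis-aligned box as a watertight tri_surface.
box_surface <- function(lx, ly, lz, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = c(0, lx), y = c(0, ly), z = c(0, lz)))
  v <- sweep(v, 2, origin, "+")
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  tri_surface(v, f)
}

# A slab/rod mesh with constant fiber frames, for eikonal tests.  `sheet`
# fixes the sheet direction (orthogonalized against the fiber); the normal
# completes the right-handed frame.
rod_mesh <- function(lx = 45, ly = 12, lz = 9, h = 1.5,
                     fiber = c(1, 0, 0), sheet = NULL) {
  mesh <- tetrahedralize(box_surface(lx, ly, lz), target_edge = h)
  f <- fiber / sqrt(sum(fiber^2))
  ref <- if (is.null(sheet)) (if (abs(f[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)) else sheet
  s <- ref - sum(ref * f) * f
  s <- s / sqrt(sum(s^2))
  n <- c(f[2] * s[3] - f[3] * s[2], f[3] * s[1] - f[1] * s[3],
         f[1] * s[2] - f[2] * s[1])
  n <- n / sqrt(sum(n^2))
  nt <- nrow(mesh$tets)
  mesh$fibers <- cbind(matrix(f, nt, 3, byrow = TRUE),
                       matrix(s, nt, 3, byrow = TRUE),
                       matrix(n, nt, 3, byrow = TRUE))
  mesh$tags <- rep("interior", nrow(mesh$nodes))
  mesh
}

# Node index nearest to a point.
nearest_node <- function(mesh, p) {
  which.min(colSums((t(mesh$nodes) - p)^2))
}

# Brute-force O(n^2) Chamfer oracle, independent of the implementation.
chamfer_oracle <- function(P, Q, squared = FALSE) {
  d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
  d2 <- pmax(d2, 0)
  if (squared) {
    0.5 * (mean(apply(d2, 1, min)) + mean(apply(d2, 2, min)))
  } else {
    0.5 * (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min))))
  }
}

# Exhaustive pairwise AUROC oracle (concordant fraction, ties = 1/2).
auroc_oracle <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) {
    tot <- tot + sum(scores[i] > scores[neg]) + 0.5 * sum(scores[i] == scores[neg])
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive Harrell oracle following the usable-pair definition literally.
harrell_oracle <- function(risk, time, event, half_ties = FALSE) {
  n <- length(risk); num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (!event[i]) next
    for (j in seq_len(n)) {
      if (time[i] < time[j]) {
        den <- den + 1
        num <- num + (risk[i] > risk[j]) +
          if (half_ties) 0.5 * (risk[i] == risk[j]) else 0
      }
    }
  }
  num / den
}
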