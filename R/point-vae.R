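# The multi-class variational point-cloud autoencoder: configuration,
# encoding/decoding, losses, training loop, and checkpoint IO.  The network
# kernels live in compiled code; everything here is a thin, validated
# wrapper plus the sample <-> tensor plumbing.

#' Point VAE configuration
#'
#' Collects every architectural and training hyperparameter of the shape
#' model.  Defaults are desk-scale: 16 latent dimensions, beta = 0.2 with
#' the KL summed over latent dimensions, coarse decoder resolution
#' `m_coarse = 384` with 4 x 4 folded patches (dense output 6144 points per
#' substructure/phase channel, folded by a separate head per channel), and
#' 5,000 Adam steps at batch size 4.  The dense-loss weight alpha ramps
#' linearly from `alpha_start` to `alpha_end` over the first
#' `alpha_ramp_frac` of training and is constant afterwards (a monotonic
#' annealing schedule).
#'
#' @param latent_dim latent dimensionality (default 16).
#' @param n_input_points points per substructure per phase expected at
#'   training time.
#' @param phases 1 (ED only) or 2 (ED + ES).
#' @param n_classes anatomical substructures (3).
#' @param enc_width,enc_hidden widths of the per-point encoder blocks and of
#'   the MLP head.
#' @param m_coarse coarse points per channel; `grid_side^2 * m_coarse` dense
#'   points per channel.
#' @param grid_side side of the square folded patch (default 4).
#' @param fold_width,dec_hidden widths of the folding network and of the
#'   coarse decoder MLP.
#' @param coord_scale coordinate normalization (mm) applied before the
#'   encoder; decoder outputs are scaled back by the same factor.
#' @param loss_unit_mm length unit (mm) of the training Chamfer terms.
#'   The default 1 (squared loss in mm^2) makes `beta = 0.2` favour
#'   reconstruction quality; larger units strengthen the relative KL
#'   pressure at fixed beta -- the latent-interpretability configuration
#'   uses 10 (cm^2), under which unused latent dimensions are pruned.
#'   Reported Chamfer values are always mm.
#' @param grid_extent half-extent of the folded patch in normalized units.
#' @param beta KL weight (default 0.2).
#' @param mu_gain optional fixed gain on the posterior-mean head (1 =
#'   neutral).
#' @param beta_warmup_frac fraction of training over which beta ramps
#'   linearly from 0 to its final value (KL warm-up; stabilizes the latent
#'   scale early in training).
#' @param alpha_start,alpha_end,alpha_ramp_frac dense-loss annealing.
#' @param learning_rate Adam learning rate.
#' @param lr_decay fraction of the learning rate linearly decayed away by
#'   the end of training (0 = constant, 0.9 = final rate is 10%).
#' @param total_steps training duration in optimizer steps.
#' @param batch_size minibatch size (default 4).
#' @param train_points random per-channel point subset fed to the encoder
#'   per training step (the permutation-invariant pooling makes a subset an
#'   unbiased summary; inference always uses all points).
#' @param target_points random per-channel subset used as the Chamfer
#'   target per training step (a stochastic estimator of the full loss).
#' @param fold_cells_train number of grid cells folded per training step
#'   (stochastic estimator of the dense loss; inference folds all).
#' @param val_every validation cadence in steps.
#' @param seed integer seed controlling initialization and training.
#' @return An object of class `point_vae_config`.
#' @export
point_vae_config <- function(latent_dim = 16L, n_input_points = 1024L,
                             phases = 2L, n_classes = 3L, enc_width = 48L,
                             enc_hidden = 64L, m_coarse = 384L, grid_side = 4L,
                             fold_width = 48L, dec_hidden = 96L,
                             coord_scale = 60, grid_extent = 0.06,
                             loss_unit_mm = 1, beta = 0.2,
                             mu_gain = 1, beta_warmup_frac = 0.3,
                             alpha_start = 0.1, alpha_end = 2.0,
                             alpha_ramp_frac = 0.5, learning_rate = 1e-3,
                             lr_decay = 0.9, total_steps = 5000L,
                             batch_size = 4L, train_points = 256L,
                             target_points = 768L, fold_cells_train = 3L,
                             val_every = 250L, seed = 0L) {
  cfg <- list(latent_dim = assert_count(latent_dim, "latent_dim"),
              n_input_points = assert_count(n_input_points, "n_input_points"),
              phases = assert_count(phases, "phases"),
              n_classes = assert_count(n_classes, "n_classes"),
              enc_width = assert_count(enc_width, "enc_width"),
              enc_hidden = assert_count(enc_hidden, "enc_hidden"),
              m_coarse = assert_count(m_coarse, "m_coarse"),
              grid_side = assert_count(grid_side, "grid_side", minimum = 2L),
              fold_width = assert_count(fold_width, "fold_width"),
              dec_hidden = assert_count(dec_hidden, "dec_hidden"),
              coord_scale = assert_scalar_number(coord_scale, "coord_scale", 1e-6),
              loss_unit_mm = assert_scalar_number(loss_unit_mm, "loss_unit_mm",
                                                  1e-6),
              grid_extent = assert_scalar_number(grid_extent, "grid_extent", 0),
              beta = assert_scalar_number(beta, "beta", 0),
              mu_gain = assert_scalar_number(mu_gain, "mu_gain", 1e-6),
              beta_warmup_frac = assert_scalar_number(beta_warmup_frac,
                                                      "beta_warmup_frac", 0, 1),
              alpha_start = assert_scalar_number(alpha_start, "alpha_start", 0),
              alpha_end = assert_scalar_number(alpha_end, "alpha_end", 0),
              alpha_ramp_frac = assert_scalar_number(alpha_ramp_frac,
                                                     "alpha_ramp_frac", 0, 1),
              learning_rate = assert_scalar_number(learning_rate,
                                                   "learning_rate", 1e-12),
              lr_decay = assert_scalar_number(lr_decay, "lr_decay", 0, 1),
              total_steps = assert_count(total_steps, "total_steps"),
              batch_size = assert_count(batch_size, "batch_size"),
              train_points = assert_count(train_points, "train_points",
                                          minimum = 8L),
              target_points = assert_count(target_points, "target_points",
                                           minimum = 8L),
              fold_cells_train = assert_count(fold_cells_train,
                                              "fold_cells_train"),
              val_every = assert_count(val_every, "val_every"),
              seed = assert_count(seed, "seed", minimum = 0L))
  if (!cfg$phases %in% 1:2) stop("`phases` must be 1 or 2", call. = FALSE)
  if (cfg$alpha_start > cfg$alpha_end) {
    stop("`alpha_start` must not exceed `alpha_end`", call. = FALSE)
  }
  cfg$fold_cells_train <- min(cfg$fold_cells_train, cfg$grid_side^2)
  structure(cfg, class = "point_vae_config")
}

#' Initialize an untrained Point VAE
#'
#' @param config a [point_vae_config()].
#' @return An object of class `point_vae` holding the configuration, the
#'   (seeded, Xavier-initialized) weights, the optimizer state and the loss
#'   history.
#' @export
point_vae <- function(config = point_vae_config()) {
  stopifnot(inherits(config, "point_vae_config"))
  structure(list(config = config,
                 weights = cpp_vae_init(unclass(config), config$seed),
                 adam = NULL, history = NULL, trained_steps = 0L),
            class = "point_vae")
}

#' @export
print.point_vae <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$weights, length, numeric(1)))
  cat(sprintf(paste0("<point_vae> latent %d, %d phase(s) x %d classes, ",
                     "%d coarse / %d dense points per channel\n",
                     "  %d parameters, trained %d / %d steps\n"),
              cfg$latent_dim, cfg$phases, cfg$n_classes, cfg$m_coarse,
              cfg$grid_side^2 * cfg$m_coarse, np, x$trained_steps,
              cfg$total_steps))
  invisible(x)
}

check_model_input <- function(model, x) {
  cfg <- model$config
  X <- as_vae_input(x)
  cls <- unique(X[, 4])
  if (!setequal(cls, seq_len(cfg$n_classes))) {
    stop(sprintf("input classes {%s} do not match the model's %d classes",
                 paste(sort(cls), collapse = ","), cfg$n_classes), call. = FALSE)
  }
  ph <- unique(X[, 5])
  if (cfg$phases == 2L && !setequal(ph, c(0, 1))) {
    stop("two-phase model needs both ED and ES points", call. = FALSE)
  }
  if (cfg$phases == 1L && !all(ph == 0)) {
    stop("single-phase model accepts ED points only", call. = FALSE)
  }
  X
}

#' Encode an anatomy into the latent posterior
#'
#' Runs the permutation-invariant encoder and returns the mean and SD of
#' the diagonal Gaussian posterior over the latent space.
#'
#' @param model a trained or untrained [point_vae()].
#' @param x an [anatomy_sample()] (two-phase models) or [mc_point_cloud()]
#'   (single-phase models).
#' @return An object of class `latent_code` with fields `mu` and `sigma`.
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "point_vae"))
  X <- check_model_input(model, x)
  out <- cpp_vae_encode(unclass(model$config), model$weights, X)
  structure(list(mu = out$mu, sigma = exp(0.5 * out$logvar),
                 logvar = out$logvar), class = "latent_code")
}

#' Reparameterization trick
#'
#' Draws `z = mu + sigma * eps` with `eps ~ N(0, I)` from the given seed;
#' with `deterministic = TRUE` the noise is suppressed and `z = mu`.
#'
#' @param code a `latent_code` from [encode()].
#' @param seed integer seed for the noise draw.
#' @param deterministic logical; force `eps = 0`.
#' @return Numeric latent vector `z`.
#' @export
reparameterize <- function(code, seed = 1L, deterministic = FALSE) {
  stopifnot(inherits(code, "latent_code"))
  if (any(code$sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  if (deterministic) return(code$mu)
  with_seed(seed, code$mu + code$sigma * rnorm(length(code$mu)))
}

#' Kullback-Leibler divergence of the latent posterior from the prior
#'
#' Closed form for a diagonal Gaussian against the standard normal,
#' summed over latent dimensions:
#' `1/2 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`.
#'
#' @param code a `latent_code`.
#' @return Nonnegative scalar.
#' @export
kl_loss <- function(code) {
  stopifnot(inherits(code, "latent_code"))
  if (any(code$sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  s2 <- code$sigma^2
  0.5 * sum(code$mu^2 + s2 - 1 - log(s2))
}

#' Decode a latent vector
#'
#' @param model a [point_vae()].
#' @param z numeric latent vector of length `latent_dim`.
#' @return An object of class `decoded_anatomy`: arrays `coarse`
#'   (`m_coarse x 3 x channels`) and `dense` (`p x 3 x channels`) in mm,
#'   with channels laid out phase-major, class-minor.
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "point_vae"))
  out <- cpp_vae_decode(unclass(model$config), model$weights, as.numeric(z))
  structure(list(coarse = out$coarse, dense = out$dense,
                 config = model$config), class = "decoded_anatomy")
}

channel_info <- function(cfg) {
  k <- seq_len(cfg$phases * cfg$n_classes)
  tibble::tibble(channel = k,
                 phase = c("ED", "ES")[(k - 1) %/% cfg$n_classes + 1],
                 class = (k - 1) %% cfg$n_classes + 1L)
}

#' Reconstruction loss of a decoded anatomy against a target sample
#'
#' For every (phase, class) channel: squared symmetric Chamfer distance of
#' the coarse channel to the matching target points, plus `alpha` times the
#' squared Chamfer of the dense channel, summed over channels.
#'
#' @param decoded a `decoded_anatomy` from [decode()].
#' @param target the [anatomy_sample()] (or single cloud) to compare with.
#' @param alpha dense-loss weight.
#' @return A list with `total`, per-channel tibble `terms`, and `alpha`.
#' @export
reconstruction_loss <- function(decoded, target, alpha = 1) {
  stopifnot(inherits(decoded, "decoded_anatomy"))
  assert_scalar_number(alpha, "alpha", 0)
  cfg <- decoded$config
  X <- as_vae_input(target)
  info <- channel_info(cfg)
  coarse <- dense <- numeric(nrow(info))
  for (i in seq_len(nrow(info))) {
    ph <- if (info$phase[i] == "ES") 1 else 0
    sel <- X[, 4] == info$class[i] & X[, 5] == ph
    if (!any(sel)) {
      stop(sprintf("target has no points for phase %s class %d",
                   info$phase[i], info$class[i]), call. = FALSE)
    }
    targ <- X[sel, 1:3, drop = FALSE]
    co <- matrix(decoded$coarse[, , i], ncol = 3)
    de <- matrix(decoded$dense[, , i], ncol = 3)
    coarse[i] <- chamfer_distance(co, targ, squared = TRUE)
    dense[i] <- chamfer_distance(de, targ, squared = TRUE)
  }
  terms <- cbind(info, tibble::tibble(coarse = coarse, dense = dense))
  list(total = sum(coarse + alpha * dense), terms = tibble::as_tibble(terms),
       alpha = alpha)
}

#' Dense-loss annealing schedule
#'
#' Linear ramp from `alpha_start` at step 0 to `alpha_end` at
#' `alpha_ramp_frac * total_steps`, constant afterwards; non-decreasing in
#' the step index.
#'
#' @param step step index in `[0, total_steps]`.
#' @param config a [point_vae_config()].
#' @return The dense-loss weight alpha.
#' @export
alpha_schedule <- function(step, config) {
  stopifnot(inherits(config, "point_vae_config"))
  assert_scalar_number(step, "step", 0, config$total_steps)
  cpp_alpha_schedule(unclass(config), step)
}

#' Train the Point VAE
#'
#' Seeded end-to-end minibatch training with Adam on the beta-weighted
#' Chamfer/KL objective.  The per-step loss breakdown (total, KL, coarse and
#' dense Chamfer per channel, alpha, periodic validation loss) is appended
#' to the model's history.  Training aborts with an error naming the step
#' if the loss turns non-finite.
#'
#' @param model a [point_vae()].
#' @param train_samples list of [anatomy_sample()] objects (or clouds for
#'   single-phase models).
#' @param val_samples optional validation list.
#' @param steps number of optimizer steps (default: the remaining steps of
#'   `config$total_steps`).
#' @return The updated model.
#' @export
train_point_vae <- function(model, train_samples, val_samples = list(),
                            steps = NULL) {
  stopifnot(inherits(model, "point_vae"))
  if (length(train_samples) < 1L) stop("empty training set", call. = FALSE)
  cfg <- model$config
  steps <- steps %||% max(0L, cfg$total_steps - model$trained_steps)
  if (steps == 0L) return(model)
  tr <- lapply(train_samples, function(s) check_model_input(model, s))
  va <- lapply(val_samples, function(s) check_model_input(model, s))
  out <- cpp_vae_train(unclass(cfg), model$weights, model$adam, tr, va,
                       as.integer(steps), model$trained_steps,
                       cfg$seed + model$trained_steps)
  model$weights <- out$weights
  model$adam <- out$adam
  hist <- tibble::as_tibble(as.data.frame(out$history))
  model$history <- if (is.null(model$history)) hist else rbind(model$history, hist)
  model$trained_steps <- model$trained_steps + as.integer(steps)
  model
}

#' Noiseless reconstruction of a sample
#'
#' Encodes with `z = mu`, decodes, and reassembles the dense channels into
#' labeled ED/ES point clouds.
#'
#' @param model a trained [point_vae()].
#' @param sample the [anatomy_sample()] to reconstruct.
#' @return An [anatomy_sample()] whose clouds are the dense reconstruction.
#' @export
reconstruct <- function(model, sample) {
  code <- encode(model, sample)
  dec <- decode(model, code$mu)
  decoded_to_sample(dec, subject_id = if (inherits(sample, "anatomy_sample"))
    paste0(sample$subject_id, "_recon") else "recon")
}

# Reassemble decoder channels into labeled clouds.
decoded_to_sample <- function(dec, subject_id = "decoded") {
  cfg <- dec$config
  info <- channel_info(cfg)
  per_phase <- function(phase) {
    sel <- which(info$phase == phase)
    pts <- do.call(rbind, lapply(sel, function(i) dec$dense[, , i]))
    mc_point_cloud(pts, rep(info$class[sel], each = dim(dec$dense)[1]),
                   phase = phase)
  }
  if (cfg$phases == 2L) {
    anatomy_sample(subject_id, per_phase("ED"), per_phase("ES"))
  } else {
    per_phase("ED")
  }
}

#' Save / load a Point VAE checkpoint
#'
#' A checkpoint is a single tar archive holding the configuration as JSON,
#' the weights as a flat IEEE-754 binary blob with a JSON manifest (so
#' reloading is bit-compatible), and the loss history as CSV.
#'
#' @param model a [point_vae()].
#' @param path checkpoint file path.
#' @return `vae_save` returns `path` invisibly; `vae_load` the model.
#' @export
vae_save <- function(model, path) {
  stopifnot(inherits(model, "point_vae"))
  dir <- tempfile("vae_ckpt_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(order = names(model$weights),
                   dims = lapply(model$weights, dim),
                   trained_steps = model$trained_steps)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "weights.bin"), "wb")
  for (w in model$weights) writeBin(as.vector(w), con, size = 8)
  close(con)
  if (!is.null(model$history)) {
    write.csv(as.data.frame(model$history), file.path(dir, "history.csv"),
              row.names = FALSE)
  }
  target <- if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(getwd(), path)
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  utils::tar(target, files = list.files(dir))
  setwd(old)
  invisible(path)
}

#' @rdname vae_save
#' @export
vae_load <- function(path) {
  dir <- tempfile("vae_ckpt_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  utils::untar(path, exdir = dir)
  cfg_l <- jsonlite::read_json(file.path(dir, "config.json"),
                               simplifyVector = TRUE)
  cfg <- do.call(point_vae_config, cfg_l[setdiff(names(cfg_l), character(0))])
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  con <- file(file.path(dir, "weights.bin"), "rb")
  weights <- list()
  for (nm in manifest$order) {
    d <- unlist(manifest$dims[[nm]])
    vals <- readBin(con, "double", n = prod(d), size = 8)
    weights[[nm]] <- matrix(vals, d[1], d[2])
  }
  close(con)
  hist <- NULL
  if (file.exists(file.path(dir, "history.csv"))) {
    hist <- tibble::as_tibble(read.csv(file.path(dir, "history.csv")))
  }
  structure(list(config = cfg, weights = weights, adam = NULL,
                 history = hist,
                 trained_steps = as.integer(manifest$trained_steps)),
            class = "point_vae")
}

#' Reconstruction errors over a dataset
#'
#' Noiselessly reconstructs every sample and reports the mean Euclidean
#' (mm) symmetric Chamfer distance between input and reconstruction for
#' every substructure/phase combination.
#'
#' @param model a trained [point_vae()].
#' @param samples list of [anatomy_sample()] objects.
#' @return A tibble with `phase`, `class`, `mean_chamfer_mm`, `n`.
#' @export
reconstruction_errors <- function(model, samples) {
  stopifnot(inherits(model, "point_vae"), length(samples) >= 1L)
  info <- channel_info(model$config)
  acc <- matrix(0, nrow(info), length(samples))
  for (j in seq_along(samples)) {
    s <- samples[[j]]
    r <- reconstruct(model, s)
    for (i in seq_len(nrow(info))) {
      ph <- if (info$phase[i] == "ES") "es" else "ed"
      acc[i, j] <- chamfer_distance(
        cloud_class_points(if (ph == "ed") r$ed else r$es, info$class[i]),
        cloud_class_points(if (ph == "ed") s$ed else s$es, info$class[i]))
    }
  }
  cbind(info[, c("phase", "class")],
        tibble::tibble(mean_chamfer_mm = rowMeans(acc),
                       n = length(samples)))
}

#' Per-step loss history of a model
#'
#' @param model a [point_vae()].
#' @return A tibble with one row per training step.
#' @export
loss_history <- function(model) {
  stopifnot(inherits(model, "point_vae"))
  model$history %||% tibble::tibble()
}
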