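# Latent-space analysis: component traversal, traversal effect sizes, and
# virtual population generation by sampling the prior and decoding.

# Posterior means of a dataset, one row per sample.
latent_means <- function(model, samples) {
  stopifnot(length(samples) >= 1L)
  t(vapply(samples, function(s) encode(model, s)$mu,
           numeric(model$config$latent_dim)))
}

#' Traverse one latent component
#'
#' Decodes latent vectors equal to the dataset's mean posterior mean in all
#' components except `component`, which is set to its mean plus
#' `values * SD` (SD of the posterior means across the dataset).  This
#' visualizes what aspect of shape the component encodes.
#'
#' @param model a trained [point_vae()].
#' @param dataset list of [anatomy_sample()] objects defining the component
#'   means and SDs.
#' @param component component index (1-based).
#' @param values SD multiples to traverse (default -2, 0, +2).
#' @return A list of `decoded_anatomy` objects, one per value, with the
#'   traversed latent vectors attached as attribute `"z"`.
#' @export
traverse_component <- function(model, dataset, component,
                               values = c(-2, 0, 2)) {
  stopifnot(inherits(model, "point_vae"))
  component <- assert_count(component, "component")
  if (component > model$config$latent_dim) {
    stop(sprintf("`component` must be <= latent_dim (%d)",
                 model$config$latent_dim), call. = FALSE)
  }
  mus <- latent_means(model, dataset)
  base <- colMeans(mus)
  sds <- apply(mus, 2, sd)
  zs <- lapply(values, function(v) {
    z <- base
    z[component] <- base[component] + v * sds[component]
    z
  })
  out <- lapply(zs, function(z) decode(model, z))
  attr(out, "z") <- do.call(rbind, zs)
  attr(out, "values") <- values
  out
}

#' Traversal effect size of one latent component
#'
#' The Euclidean Chamfer distance (mm) between the decoded anatomies at
#' -2 SD and +2 SD of a component, pooling the dense points of all
#' substructure/phase channels.  Components that encode real shape factors
#' score high; collapsed ("dead") components score near zero.
#'
#' @inheritParams traverse_component
#' @return Nonnegative scalar (mm).
#' @export
component_effect_size <- function(model, dataset, component) {
  tr <- traverse_component(model, dataset, component, values = c(-2, 2))
  pool <- function(d) do.call(rbind, lapply(seq_len(dim(d$dense)[3]),
                                            function(k) d$dense[, , k]))
  chamfer_distance(pool(tr[[1]]), pool(tr[[2]]))
}

#' Traversal effect sizes of all latent components
#'
#' @inheritParams traverse_component
#' @return A tibble with `component` and `effect_size_mm`, sorted by
#'   component index.
#' @export
component_effect_sizes <- function(model, dataset) {
  L <- model$config$latent_dim
  mus <- latent_means(model, dataset)
  base <- colMeans(mus)
  sds <- apply(mus, 2, sd)
  pool <- function(d) do.call(rbind, lapply(seq_len(dim(d$dense)[3]),
                                            function(k) d$dense[, , k]))
  es <- vapply(seq_len(L), function(j) {
    zlo <- base; zlo[j] <- base[j] - 2 * sds[j]
    zhi <- base; zhi[j] <- base[j] + 2 * sds[j]
    chamfer_distance(pool(decode(model, zlo)), pool(decode(model, zhi)))
  }, numeric(1))
  tibble::tibble(component = seq_len(L), effect_size_mm = es)
}

#' Generate a virtual heart population
#'
#' Samples latent vectors from the model's latent-space distribution and
#' decodes them into labeled ED/ES anatomies.  The default samples from a
#' Gaussian moment-matched to the aggregate posterior of a reference
#' dataset (the fitted latent distribution); `from = "prior"` samples the
#' `N(0, I)` VAE prior instead, which is only meaningful when the
#' aggregate posterior has converged to the prior.
#'
#' @param model a trained [point_vae()].
#' @param n number of virtual subjects.
#' @param seed integer seed.
#' @param from `"posterior"` (default) or `"prior"`.
#' @param dataset reference dataset, required for `from = "posterior"`.
#' @return A list of [anatomy_sample()] objects with ids `V0001`, ...
#' @export
sample_virtual_population <- function(model, n, seed = 1L,
                                      from = c("posterior", "prior"),
                                      dataset = NULL) {
  stopifnot(inherits(model, "point_vae"))
  n <- assert_count(n, "n")
  from <- match.arg(from)
  L <- model$config$latent_dim
  if (from == "posterior") {
    if (is.null(dataset)) stop("`dataset` required for posterior sampling",
                               call. = FALSE)
    mus <- latent_means(model, dataset)
    mu0 <- colMeans(mus); sd0 <- apply(mus, 2, sd)
  } else {
    mu0 <- rep(0, L); sd0 <- rep(1, L)
  }
  Z <- with_seed(seed, matrix(rnorm(n * L), n, L))
  Z <- sweep(sweep(Z, 2, sd0, "*"), 2, mu0, "+")
  lapply(seq_len(n), function(i) {
    decoded_to_sample(decode(model, Z[i, ]), sprintf("V%04d", i))
  })
}
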