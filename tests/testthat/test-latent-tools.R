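test_that("traversal at value zero is independent of the component", {
  model <- tiny_trained_model()
  ds <- tiny_cohort()[1:8]
  t1 <- traverse_component(model, ds, 1, values = 0)
  t2 <- traverse_component(model, ds, 5, values = 0)
  expect_identical(t1[[1]]$dense, t2[[1]]$dense)
  expect_error(traverse_component(model, ds, 99), "component")
})

test_that("traversal endpoints move both phases, gradually", {
  model <- tiny_trained_model()
  ds <- cached("tiny_train_cohort", stop("missing"))
  es <- component_effect_sizes(model, ds)
  top <- es$component[which.max(es$effect_size_mm)]
  vals <- seq(-2, 2, length.out = 5)
  tr <- traverse_component(model, ds, top, values = vals)
  # both ED and ES channels change between the endpoints
  ed_ch <- chamfer_distance(tr[[1]]$dense[, , 1], tr[[5]]$dense[, , 1])
  es_ch <- chamfer_distance(tr[[1]]$dense[, , 4], tr[[5]]$dense[, , 4])
  expect_gt(ed_ch, 0.05)
  expect_gt(es_ch, 0.05)
  # consecutive steps are much smaller than the endpoint-to-endpoint jump
  pool <- function(d) do.call(rbind, lapply(1:6, function(k) d$dense[, , k]))
  endpoint <- chamfer_distance(pool(tr[[1]]), pool(tr[[5]]))
  steps <- vapply(1:4, function(i) {
    chamfer_distance(pool(tr[[i]]), pool(tr[[i + 1]]))
  }, numeric(1))
  expect_lt(max(steps), endpoint)
})

test_that("component effect sizes are finite and stable under subsampling", {
  model <- tiny_trained_model()
  ds <- cached("tiny_train_cohort", stop("missing"))
  e1 <- component_effect_size(model, ds, 1)
  expect_true(is.finite(e1) && e1 >= 0)
  es_all <- component_effect_sizes(model, ds)$effect_size_mm
  es_sub <- component_effect_sizes(model, ds[seq(1, length(ds), by = 2)])
  expect_gt(cor(es_all, es_sub$effect_size_mm, method = "spearman"), 0.8)
})

test_that("the latent space disentangles a four-factor population", {
  # Train on cohorts in which exactly four generative factors vary, using
  # the interpretability configuration (training loss unit 6 mm, where
  # beta = 0.2 exerts enough KL pressure to prune unused dimensions).  The
  # majority of seeds must show a few dominant components and dead ones.
  verdicts <- vapply(0:2, function(seed) {
    cohort <- cached(paste0("disent_cohort_", seed),
                     four_factor_cohort(40, 60 + seed))
    cfg <- point_vae_config(n_input_points = 256L, enc_width = 24L,
                            enc_hidden = 48L, m_coarse = 96L,
                            fold_width = 24L, dec_hidden = 48L,
                            train_points = 128L, fold_cells_train = 2L,
                            loss_unit_mm = 6, total_steps = 2000L,
                            val_every = 2000L, seed = seed)
    m <- train_point_vae(point_vae(cfg), cohort)
    es <- component_effect_sizes(m, cohort)$effect_size_mm
    med <- median(es)
    sum(es > 5 * med) >= 3 && any(es < med)
  }, logical(1))
  expect_gte(sum(verdicts), 2L)
})

test_that("virtual populations are seeded and schema-valid", {
  acc <- acceptance()
  model <- acc$model
  ds <- acc$split$train
  pop <- sample_virtual_population(model, 5, seed = 11, dataset = ds)
  pop2 <- sample_virtual_population(model, 5, seed = 11, dataset = ds)
  expect_identical(pop[[3]]$ed$points, pop2[[3]]$ed$points)
  pop3 <- sample_virtual_population(model, 5, seed = 12, dataset = ds)
  expect_false(identical(pop[[1]]$ed$points, pop3[[1]]$ed$points))
  for (s in pop) {
    expect_s3_class(s$ed, "mc_point_cloud")
    expect_setequal(unique(s$ed$labels), 1:3)
    expect_true(all(is.finite(s$es$points)))
  }
  # shuffling the population leaves the descriptive statistics unchanged
  r1 <- population_report(pop)
  r2 <- population_report(rev(pop))
  expect_equal(r1$mean, r2$mean)
  expect_equal(r1$sd, r2$sd)
})
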