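# cardiopoint

Population modeling of three-dimensional biventricular anatomy and
function on labeled surface point clouds, with downstream myocardial
infarction (MI) prediction and *in silico* electrophysiology.

Real cardiac cohorts vary widely in heart size, shape and contraction,
and that variability carries diagnostic signal that single clinical
scalars such as the ejection fraction (EF) compress away.  `cardiopoint`
learns this variability with a **multi-class variational point-cloud
autoencoder** (Point VAE): the encoder maps the end-diastolic (ED) and
end-systolic (ES) clouds of three substructures (LV endocardium, LV
epicardium, RV endocardium) through permutation-invariant PointNet-style
blocks to a 16-dimensional Gaussian latent space; the decoder emits a
coarse cloud per substructure/phase channel and folds dense grid patches
around each coarse point.  Training minimizes

    L_total = sum_{phase i, class j} ( L_coarse,ij + alpha * L_dense,ij )
              + beta * KL[ q(z|X) || N(0, I) ],        beta = 0.2

with symmetric Chamfer reconstruction terms and a monotone annealing
schedule on the dense weight `alpha`.  The learned latent space is then
used for prevalent/incident-MI classification (balanced 10-fold logistic
regression against LV/RV-EF baselines), MI survival analysis (Cox
proportional hazards, Harrell's concordance), virtual heart population
synthesis (decode latent-space samples, compare clinical metrics and
Gaussian-kernel MMD), and electrophysiology simulation (watertight
meshing, rule-based fibers, anisotropic eikonal activation from seven
root nodes at 67/30/17/120 cm/s conduction velocities, 8-lead
pseudo-ECG QRS synthesis).

Because imaging data cannot be redistributed, the package ships a seeded
**synthetic anatomy generator** — truncated-ellipsoid biventricular
shapes with controlled population variability (size, elongation, basal
tilt, wall thickness, EF) and a shape-shifted MI subpopulation with
exponential survival times — so every claim is testable end-to-end from
code.

## Worked example

```r
library(cardiopoint)

# a seeded synthetic cohort: 120 subjects, 30% prevalent MI
cohort <- simulate_cohort(120, mi_fraction = 0.3,
                          points_per_class = 512, seed = 1)
split <- split_dataset(cohort, c(0.70, 0.05, 0.25), seed = 2)

# train a compact shape model (a few minutes on one core)
cfg <- point_vae_config(total_steps = 2000L, seed = 0)
model <- train_point_vae(point_vae(cfg), split$train, split$val)

# reconstruction quality on held-out subjects (mm)
reconstruction_errors(model, split$test)
#>   phase class mean_chamfer_mm  n
#> 1    ED     1            1.95 30
#> 2    ED     2            2.36 30
#> 3    ED     3            2.08 30
#> 4    ES     1            1.74 30
#> 5    ES     2            2.17 30
#> 6    ES     3            1.80 30
```

Each row is the mean symmetric Euclidean Chamfer distance between the
input cloud and its noiseless reconstruction for one substructure/phase.
At the package's full desk-scale settings (600 subjects, 1024 points per
class per phase, 5,000 steps -- what `scripts/acceptance.R` runs) these
means drop below the in-plane voxel size of typical cine-MR acquisitions
(1.8 mm), i.e. the 16-D latent space preserves the anatomy at
acquisition resolution; the compact 2,000-step run above lands slightly
above it.

```r
# latent features vs the clinical EF baseline for prevalent-MI detection
mi_classification(model, split$test, task = "prevalent",
                  features = "latent", k = 5, seed = 1)$means
#> accuracy    auroc       f1 precision   recall
#>    0.850    1.000    0.733     0.800    0.700
mi_classification(model, split$test, task = "prevalent",
                  features = "lvef", k = 5, seed = 1)$means
#> accuracy    auroc       f1 precision   recall
#>    0.900    0.950    0.893     0.933    0.900

# survival analysis on the incident cohort (EF covariates at this small n)
rec <- build_survival_records(cohort, horizon = 2555)
keep <- Filter(function(s) s$group != "prevalent_mi", cohort)
X <- as.matrix(ef_baselines(keep)[, c("lv_ef", "rv_ef")])
crossval_cox(X, rec$time_days, rec$event, k = 5, seed = 1)$mean_c
#> [1] 0.603

# a virtual population and its clinical realism
virt <- sample_virtual_population(model, 200, seed = 3,
                                  dataset = split$train)
population_report(virt)

# electrophysiology on one anatomy: mesh, activation map, 8-lead QRS
sim <- simulate_ecg(cohort[[1]], target_edge = 3)
qrs_duration(sim$trace)
#> [1] 86
write_ecg_csv(sim$trace, "subject1_qrs.csv")
```

(Numbers above are the actual output of this script at the seeds given;
stochastic quantities vary a little with the seed, and at this compact
cohort size the latent-versus-EF comparison is noisy -- the full-scale
protocol in the test suite shows the latent features winning
consistently.)

A command-line front-end wrapping these functions (subcommands
`simulate-cohort`, `train`, `reconstruct`, `traverse`,
`generate-population`, `ep-simulate`, `classify`, `survival`, `mmd`)
is installed at `inst/cli/cardiopoint`.

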