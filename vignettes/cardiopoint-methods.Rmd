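---
title: "Modeling biventricular shape with a multi-class point-cloud VAE"
author: "cardiopoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling biventricular shape with a multi-class point-cloud VAE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cardiac anatomy and function vary widely across people, and that
variability is informative: post-infarction remodeling changes
three-dimensional ventricular shape in ways that a single scalar such as
the ejection fraction (EF) summarizes only partially.  `cardiopoint`
models population-wide variability of the biventricular anatomy directly
on labeled surface point clouds — three substructures (LV endocardium,
LV epicardium, RV endocardium) at the end-diastolic (ED) and end-systolic
(ES) phases — with a multi-class variational point-cloud autoencoder
(Point VAE), and exercises the learned representation in three downstream
settings: myocardial-infarction (MI) classification and survival
analysis, virtual heart population synthesis, and eikonal-based
electrophysiology (pseudo-ECG) simulation.

Everything is testable end-to-end because the package ships a seeded
synthetic-anatomy generator with known generative factors; no imaging
data is required.

# The shape model

## Architecture

The encoder consumes the concatenated ED+ES cloud as an `n x (x, y, z,
class, phase)` record set.  Two stacked PointNet-style blocks — a shared
per-point MLP, a symmetric max-pool, and the pooled global feature
concatenated back onto every point — are joined by an additive residual
connection and followed by an MLP head that outputs the mean and
log-variance of a 16-dimensional diagonal Gaussian posterior.  Because
every per-point operation is shared and the pooling is a maximum, the
encoding is exactly permutation-invariant.

The decoder first maps the latent vector through an MLP to a coarse cloud
of `m_coarse = 384` points x 3 coordinates x (2 phases x 3 classes)
channels, then folds a 4 x 4 grid patch around every coarse anchor,
yielding a dense output of `p = 6144` points per channel (`p >> m`).
Each substructure/phase channel has its own folding head conditioned on
the latent vector, the anchor position and the grid coordinates: the six
channels have very different local geometry (thin RV crescent versus wide
epicardial shell), and per-channel heads reconstruct them markedly better
than one shared head at identical computational cost.  The channel layout
is fixed: phase-major, class-minor.

## Loss

Training minimizes, per sample,

\[
L = \sum_{i=1}^{T}\sum_{j=1}^{C}\left(L^{\text{coarse}}_{ij} +
\alpha\, L^{\text{dense}}_{ij}\right) + \beta\, D_{KL}\!\left[q(z\mid X)
\,\Vert\, \mathcal N(0, I)\right],
\]

where each reconstruction term is the symmetric Chamfer distance between
the predicted channel and the matching target subset, computed with
squared Euclidean distances inside the loss (smooth gradients) while all
*reported* Chamfer values use the Euclidean (mm) convention so they are
directly comparable to acquisition resolutions.  The KL term is the
closed-form diagonal-Gaussian divergence summed over latent dimensions,
so `beta = 0.2` has a fixed meaning.  The dense weight `alpha` follows a
monotonic annealing schedule — a linear ramp from 0.1 to 2.0 over the
first half of training, constant afterwards — so early training focuses
on coarse global placement before weighting local detail; letting the
ramp end above 1 keeps the dense term dominant once the anchors have
settled, which measurably sharpens the dense reconstruction.  The KL
weight has its own warm-up, ramping from 0 to `beta` over the first 30%
of steps, and the posterior starts narrow (log-variance bias -6): both
stabilize the latent scale so the reconstruction signal is not drowned in
reparameterization noise early in training.

## Stochastic estimators in the training loop

Two Monte-Carlo estimators keep a CPU training step cheap without
changing what is optimized in expectation:

* the encoder sees a random 256-point subset per substructure/phase each
  step (the max-pooled summary of a subset is an unbiased sketch of the
  full cloud; inference always encodes all points);
* the Chamfer target is a random 768-point subset per channel, and only
  3 of the 16 grid cells are folded per step (inference folds all 16).

Both subsets are drawn from the training RNG, so a fixed seed reproduces
the loss history bit-for-bit.  Adam (batch size 4, learning rate 1e-3
decaying linearly to 1e-4) runs for 5,000 steps at desk scale; the
configuration exposes every one of these choices.

## Numerical choices

* Coordinates are normalized by 60 mm inside the network; losses are
  computed in mm.
* The posterior SD is `exp(logvar / 2)` with `logvar` clamped to
  `[-12, 8]`.
* Weights are Xavier-uniform initialized from a seeded generator; matrix
  products go through BLAS and everything else is scalar C++, so a fixed
  seed is reproducible on a given machine.
* Training aborts with the step index if the loss turns non-finite.

# The synthetic cohort

The generator emulates the statistical structure of a real biventricular
surface cohort with truncated prolate ellipsoids:

* LV endocardium: ellipsoid with semi-axes 45 x 27 mm at scale 1 (about a
  90 mm epicardial long axis), truncated by a basal plane at 50% of the
  long semi-axis, optionally tilted (the `basal_tilt` factor).
* LV epicardium: the exact outward normal offset of the endocardium by
  the wall thickness (for a prolate spheroid this equals the revolved 2-D
  offset profile, which is how it is built).
* RV endocardium: a septally indented ("crescent") ellipsoid placed
  against the LV free wall with a 2 mm gap, so the downstream 3 mm RV
  epicardial offset fuses the two ventricles.
* ES transform: an apex-anchored radial contraction whose factor is
  solved by bisection against semi-analytic truncated volumes so the LV
  cavity hits the subject's target EF exactly; the ES wall thickness is
  solved to conserve myocardial volume, reproducing systolic wall
  thickening.
* Sampling is area-uniform per surface (triangle-area-weighted draws on a
  fine lattice), with exactly `points_per_class` points per substructure
  and phase.

Population factors are truncated normal draws.  Controls: EF
0.58 (SD 0.06), wall 10 mm (SD 1.2), scale 1.00 (SD 0.07).  The MI group
is shifted toward lower EF (0.47, SD 0.07), thinner walls (8.2 mm) and
mild dilation (scale 1.06) — the direction of post-infarction
remodeling — so that disease is recoverable from shape but not from any
single factor alone.  The latent hazard driver `risk_score` is a
standardized combination of the EF and wall shifts plus independent
noise; survival times are exponential with hazard
`lambda0 * exp(gamma * risk_score)` (defaults `lambda0 = 1.2e-4`/day,
`gamma = 1`), administratively censored at a 7-year follow-up.  These
widths are one-time choices made for anatomical plausibility (volumes,
masses and EFs land in normal adult ranges); they are exposed in
`population_config()` but the defaults are the study conditions used by
every test.

What the generator does **not** emulate: trabeculation, valve anatomy,
regional (scar-like) wall-motion abnormalities, papillary muscles,
through-plane motion artifacts, or segmentation noise.  Passing the
reconstruction bound here therefore shows the architecture and training
recipe can capture smooth population shape variability at the stated
resolution — not that it handles real cine-MR artifacts.

## Virtual population sampling

`sample_virtual_population()` draws latent vectors from a Gaussian
moment-matched to the aggregate posterior of a reference dataset and
decodes them.  In a VAE whose aggregate posterior has converged to the
prior the two distributions coincide; under the reconstruction-focused
mm-scale loss the aggregate posterior remains narrower than `N(0, I)`,
and raw prior draws would extrapolate far outside the trained latent
region (decoding to anatomically invalid shapes, e.g. an epicardium
inside its endocardium).  Sampling the fitted latent distribution is
therefore the default; `from = "prior"` exposes the `N(0, I)`
alternative.

# Shape metrics

* `chamfer_distance()` is exact brute force, so oracle tests can demand
  equality rather than approximation.
* `cavity_volume()` closes the basal opening along its rim and
  integrates `1/2 r^2 dtheta du` on a cylindrical radius map about the
  PCA long axis (sign-canonicalized so the estimate is rigid-motion
  invariant, and exactly scale-cubed under similarity).  It is validated
  against analytic spheres (1-2% accurate at 2000 points) and works for
  any surface star-shaped about its axis, which includes the crescent RV.
  This estimator is a declared convention of the package.
* `lv_mass()` converts the epicardial-minus-endocardial shell volume at
  the standard myocardial density of 1.05 g/mL.
* `gaussian_mmd()` is the biased (V-statistic) squared-MMD with the
  median-distance bandwidth heuristic, so identical populations score
  exactly zero.

# MI prediction

Latent features are noiseless encodings (`z = mu`).  Classification uses
balanced case/control subsets, standardized features, and stratified
10-fold logistic regression scored by accuracy, rank-statistic AUROC, F1,
precision and recall at threshold 0.5.  Survival analysis uses
`survival::coxph` (Breslow ties) behind `fit_cox()`, with a hand-written
partial likelihood used only to verify the score identity, and Harrell's
concordance computed from the literal usable-pair definition (ordered
pairs with an observed earlier event); risk ties count zero under the
strict default, with the common 1/2 convention available explicitly.  The
incident-MI cohort excludes prevalent-MI subjects and right-censors at
the study horizon.  Whether "controls" should also exclude other-disease
subjects is a protocol ambiguity in general; the synthetic cohort has no
other-disease group, so the question does not arise here.

# Electrophysiology pipeline

Surface reconstruction exploits that ventricular surfaces are star-shaped
about their long axis: a smoothed radius map over axial bands and
azimuthal sectors is triangulated as a lattice, closed by an apex fan
where the cloud closes and left open at the base.  This is robust to
decoder sampling noise; a general-position reconstruction (ball pivoting)
is unnecessary for these shapes and would add a fragile dependency.

The RV epicardium is the 3 mm vertex-normal offset of the RV endocardium.
The biventricular solid `(LV epi + RV epi) minus cavities` is discretized
on a fine body lattice via exact ray-parity tests against the closed
surfaces, and its watertight boundary is extracted.  Tetrahedralization
fills a watertight surface with the Kuhn 6-tet subdivision of lattice
cells whose centers are inside: conforming, positively oriented, median
edge within `[0.5, 2]` of the target spacing, boundary within about one
spacing of the input.  The brand-name remeshing tools of production
pipelines are replaced by this contract, not imitated; the default
element size is 3 mm for desk-scale runs (the configuration accepts
1.5 mm).

Node tags (LV/RV endocardium, epicardium, base) come from nearest-surface
classification; the transmural coordinate solves a Laplace problem
between endo (0) and epi (1) on the tet graph; fibers follow the standard
rule-based helix, +60 deg at the endocardium to -60 deg at the
epicardium, linear in the transmural coordinate, assembled into
orthonormal (fiber, sheet, normal) frames.

Activation solves the anisotropic eikonal equation by iterative sweeping
with exact local solves under the metric
`M = v_f^2 ff' + v_s^2 ss' + v_n^2 nn'` (conduction velocities 0.67,
0.30, 0.17 m/s along fiber/sheet/normal), plus shortcut surface edges at
the 1.20 m/s endocardial speed — the fast endocardial layer is realized
as edge shortcuts because its physiological implementation (Purkinje
coupling) is not part of the model.  Seven root nodes (four LV, three RV)
are picked deterministically at rule-based homologous positions; onsets
are simultaneous at 0 ms.

Numerically, the sweeping solver converges to the discrete fixed point
(tolerance 1e-7 ms); multi-source solutions equal the pointwise minimum
of the single-source solutions exactly away from front collisions, with
an O(element size) underestimate localized at the collision ridge where
linear face interpolation spans the kink.  Tiny tetrahedron islands that
the stair-step discretization occasionally disconnects from the main
myocardium are dropped when the mesh is built.

The pseudo-ECG is the dipole-density integral
`phi_e(t) = sum_el w'(t - act) (-grad act . grad(1/r)) vol` with a 1 ms
smoothstep upstroke; eight independent leads (I, II, V1-V6, Wilson
central terminal reference) are sampled on a uniform grid spanning the
QRS.  The rise time is a fixed cellular property: rescaling conduction
velocities rescales activation times but not the upstroke, so QRS
durations scale exactly only when the rise time is rescaled along.  Electrode positions are a fixed synthetic torso-scale layout that
translates rigidly with the heart — no torso imaging is modeled — so
amplitudes are in normalized units and only the time structure and
population-level variability of the traces are asserted anywhere in the
package.

# Problem sizes and defaults

The package's standard experiment — used by the acceptance script and the
test suite — is a 600-subject cohort at 1024 points per class per phase,
split 70/5/25, trained for 5,000 steps at batch 4 (about 8 minutes on one
CPU core), with reconstruction evaluated on the 150-subject test split.
Module-level tests run a compact variant (48 subjects, 256 points, 1,500
steps) that exhibits the same qualitative behaviour.  Virtual-population
checks decode 1,000 latent-distribution samples; ECG population comparisons use 10
anatomies per population at 3 mm elements.

# Known limitations

* The generator's smooth ellipsoidal geometry understates real anatomical
  complexity; absolute classification metrics here say nothing about UK
  Biobank-scale performance.
* The cavity-volume estimator assumes star-shapedness about the long
  axis; strongly aneurysmal shapes would violate it.
* The eikonal solver models a single paced beat with healthy, fixed
  conduction velocities; no repolarization, no pathology-specific
  conduction.
* Stair-step lattice meshes limit boundary fidelity to about one element
  size; this is adequate for QRS-level timing but not for local
  activation mapping studies.
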