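---
title: "Quantitative optic-nerve DTI tractometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative optic-nerve DTI tractometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ondti)
```

## The problem

The intraorbital optic nerve is a thin (~4 mm diameter, ~25 mm long) white-matter
bundle running from the back of the globe to the orbital apex.  In unilateral
optic atrophy one nerve degenerates while the fellow nerve and control nerves
stay intact, and the degeneration is visible both in optical coherence
tomography (thinning of the peripapillary retinal nerve fiber layer, RNFL) and
in diffusion MRI (loss of diffusion anisotropy).  `ondti` implements the full
quantitative pipeline for this problem — tensor estimation, nerve tractography,
central-fiber tract profiling and cohort statistics — together with a synthetic
orbital phantom generator so that every stage is testable without patient data.

## Signal model and tensor estimation

Each voxel is modelled by a symmetric positive-definite tensor $D$ with the
monoexponential signal law

$$ S_i = S_0 \exp(-b_i\, g_i^\top D\, g_i), $$

where $b_i$ (s/mm²) and the unit vector $g_i$ describe volume $i$ of the
acquisition.  Diffusivities are stored on the conventional clinical scale
(numerically $10^{-3}$ mm²/s — the scale on which optic-nerve MD is ~0.7);
the factor $10^{-3}$ enters only inside the signal model so that $bD$ is
dimensionless.

`fit_tensor_lls()` solves the log-linearized model
$\ln S_i = \ln S_0 - b_i g_i^\top D g_i$ per voxel by ordinary least squares on
a 7-column design (the six unique tensor components plus $\ln S_0$).
Non-positive measurements are dropped rather than clamped — clamping biases the
log-signal at high SNR — and a voxel is excluded (with a count) when fewer than
7 usable measurements remain.  `bootstrap_tensor()` adds a residual bootstrap
(default 500 replicates): whole-model log-residuals are resampled with
replacement per voxel and the fit repeated, giving per-voxel SDs of the scalar
measures.  A residual (not repetition) bootstrap is the natural choice for a
single-shell acquisition without repeated measurements.  The package reports
the point fit by default and the bootstrap mean alongside.

From the sorted eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$:

* $\mathrm{MD} = (\lambda_1+\lambda_2+\lambda_3)/3$,
  $\mathrm{AD} = \lambda_1$, $\mathrm{RD} = (\lambda_2+\lambda_3)/2$;
* $\mathrm{FA} = \sqrt{3/2}\,\lVert\lambda-\bar\lambda\rVert/\lVert\lambda\rVert$,
  clamped eigenvalues ($\lambda_i \mapsto \max(\lambda_i, 0)$) for FA only.

Clamping only inside FA keeps the identity
$\mathrm{MD} = (\mathrm{AD} + 2\,\mathrm{RD})/3$ *exact* for every voxel and for
any linear average of voxels, nodes or nerves — the package tests this identity
at every aggregation level, and it holds on the published group means too.

## The phantom generator

`phantom_spec()` describes a 2 mm isotropic whole-orbit grid (default
64×64×33) containing a gently S-curved tube of radius 2 mm (4 mm diameter,
~25 mm arc length) built by Catmull–Rom interpolation through control points
and resampled at 0.5 mm arc steps.  In-tube voxels get an axially symmetric
tensor (principal axis = local tangent, eigenvalues
$(\mathrm{AD}, \mathrm{RD}, \mathrm{RD})$); the surround is isotropic with
CSF-like MD 3.0.  The healthy default profile AD/RD = 0.955/0.510 and the
atrophic profile 1.123/0.920 are the published non-affected and atrophic
group means.  The acquisition is two opposed-phase b0 volumes plus 48
directions at $b = 2000$ s/mm² (the shipped direction set was generated by
antipodally symmetric electrostatic repulsion; minimum pairwise axial angle
20.8°).  Rician noise is applied as $|S + \varepsilon_1 + i\varepsilon_2|$
with $\varepsilon \sim N(0, (S_0/\mathrm{snr})^2)$, default SNR 20; a Gaussian
mode exists for analytic tests.

Voxels take the tensor of their centre — no sub-voxel partial-volume mixing.
This is deliberate: the central-fiber design exists to dodge partial-volume
contamination, and a crisp phantom makes recovery errors attributable to noise
and geometry rather than to the generator.

What the phantom does *not* emulate: susceptibility distortion and eddy
currents (the b0-merge stage is therefore a voxel-wise mean of the
opposed-phase pair, preserving only the "49 corrected volumes" contract),
eye motion, fat/CSF multi-compartment signal, and scanner drift.  Passing
tests on phantoms therefore demonstrate correctness of the estimators and the
pipeline plumbing, not robustness to those real-world artifacts.

A known and intended consequence of magnitude-MR noise: at SNR 20 and
$b = 2000$, the in-tube signal of an atrophic-profile nerve is only ~2–3× the
Rician floor, and measured FA of low-anisotropy tissue is biased upward
(about 0.19–0.27 measured against 0.12 truth).  Group *direction* of effects
survives this bias — atrophic FA stays well below the comparators — but
absolute atrophic FA from the imaging route is expected to exceed the truth.

## Tractography

`generate_candidates()` seeds streamlines uniformly in a 3 mm sphere placed at
5% of the centerline arc (just behind the globe; the optic-nerve-head end) and
propagates them in 1 mm steps.  Directions are drawn from a Watson-style axial
distribution $f(d) \propto \exp(\kappa (d^\top e_1)^2)$ centred on the local
principal eigenvector, with concentration $\kappa = \kappa_0\,\mathrm{FA}$
(default $\kappa_0 = 100$).  The linear FA law keeps low-anisotropy atrophic
nerves (fitted FA ≈ 0.17) steerable while background voxels, whose principal
axes are noise-incoherent, still diffuse; a quadratic law was tried and left
atrophic nerves untrackable.  Steps turning more than 45° are redrawn a bounded
number of times, then the candidate fails.  A candidate is accepted when it
enters the apex ROI within twice the straight-line ROI distance; generation
stops at 1000 accepted candidates or a 100×1000 attempt cap.

`score_and_select()` scores each candidate by the length-normalized sum of
$\log f$ under the same angular model — using one model for generation and
scoring keeps the ranking interpretable as a pathway likelihood — and keeps
the top 10%, ties broken by shorter arc, then creation order.
`clean_outliers()` applies the AFQ convention: fibers are resampled to 20
nodes, the bundle core is the node-wise mean with node-wise spatial
covariance, and a fiber is removed when its node-averaged Mahalanobis distance
exceeds 2.6 SD above the bundle mean, or its length exceeds mean + 3 SD;
the two rules iterate to convergence (≤ 5 rounds).  Fiber-averaged (not
per-node) Mahalanobis distance is used; zero-spread bundles remove nothing.
`central_fiber()` then averages the cleaned fibers node-wise, pulls endpoints
radially onto their ROI spheres when needed, and re-resamples to exactly 20
equidistant-arc nodes with node 1 at the optic-nerve-head end.

One property often expected of top-fraction selection does **not** hold here:
shrinking `keep_frac` does not tighten the central fiber around the true
centerline.  Because candidates must reach the target ROI to exist at all,
the candidate bundle is already confined to the nerve; keeping more fibers
mainly averages away sampling noise (measured RMS ≈ 0.19 mm at
`keep_frac = 1` vs ≈ 0.24 mm at 0.1 on straight-tube phantoms without
cleaning).  The 10% selection is retained as the protocol default, and the
package instead guarantees sub-voxel central-fiber accuracy across the whole
`keep_frac` range.  With an unconstrained (ConTrack-style) candidate sampler
the conventional monotone benefit would be expected to reappear.

## Tract profiling

`sample_profile()` interpolates the FA/MD/AD/RD maps trilinearly at the 20
node positions (a nearest-voxel mode mirrors per-voxel sub-sampling
protocols).  `exclude_onh_nodes()` masks the five nodes nearest the
optic-nerve head — the anterior 25%, most affected by eye motion — and
`summarize_profile()` averages the posterior 15 nodes into one value per
measure per nerve.  "Five nodes nearest the ONH" and "posterior 75%" are
treated as the same rule (5/20 = 25%); `k` is configurable.

## Cohort generation and statistics

`cohort_spec()`/`make_cohort()` build the study structure: 6 patients with one
atrophic and one non-affected nerve each, 11 controls with two control nerves
each (34 nerves).  Per-nerve AD/RD are the group profile plus between-subject
Gaussian jitter; a control subject's two eyes share the subject draw, which
reproduces the absence of control inter-eye differences.  The jitter is
bivariate normal with marginal SDs equal to the published per-measure SDs and
correlation chosen (per group, by the delta method at the group profile) so
that the implied FA spread matches the published FA SD — the published
per-measure SDs are marginals of strongly correlated quantities, and
independent AD/RD jitter would inflate the FA spread about four-fold and
destroy the published significance pattern.  The fitted correlations
(≈ 0.94 atrophic, 0.62 non-affected, 0.78 control) also reproduce the
published MD SDs almost exactly, which is a useful internal consistency check.

RNFL (µm) is linear in the nerve's ground-truth FA:
$\mathrm{RNFL} = 22 + 236\,\mathrm{FA} + \varepsilon$,
$\varepsilon \sim N(0, 8^2)$.  Intercept and slope are chosen so the
profile-implied FA values map onto the published group RNFL means
(49.8 atrophic, 109.8 non-affected, 109.6 control); the 8 µm noise SD puts
the analytic $R^2$ of the FA–RNFL association in the mid-0.9s, matching the
published strength of that correlation.  `analytic_rnfl_r2()` exposes the
generator's own variance decomposition so tests compare recovered $R^2$
against the generator rather than against a memorized constant.

The statistical battery mirrors standard clinical practice:

* `average_control_eyes()` replaces each control's two rows by their mean
  (justified by the inter-eye checks).
* `mann_whitney_u()` — exact permutation p when both $n \le 25$ without ties,
  else normal approximation with tie and continuity corrections.
* `chi_square_prop()` — Pearson χ² on 2×2 tables, no continuity correction.
* `fit_lme_rnfl()` / `fit_lme_group()` — REML linear mixed models
  `measure ~ RNFL + (1|subject)` and `measure ~ group + (1|subject)`
  (lme4/lmerTest), p-values from the Satterthwaite ANOVA of the fixed effect.
  REML rather than ML because with 6 patients the ML variance bias is
  material.  $R^2$ for an LME is not uniquely defined; the package uses the
  squared Pearson correlation between fixed-effect fitted values and
  observations (≈ marginal $R^2$) and documents it as such.  With one
  observation per subject the random intercept is unidentifiable; estimates
  then coincide with OLS (tested to 1e-8).  Group contrasts use pairwise
  subsets (atrophic vs eye-averaged controls; atrophic vs non-affected within
  patients).  Tests are two-sided at α = 0.05 with no multiplicity
  correction, mirroring the small-cohort clinical convention.

## Problem sizes and numerical choices

* Unit tests and the cohort pipeline run on a 24×24×16 grid (the nerve
  geometry is identical; only surrounding empty space is trimmed); the
  structural-count check runs once at the full 64×64×33 default.
* The Watson normalization constant is evaluated through a cached spline over
  adaptive-quadrature values (the integrand peaks sharply at $|t|=1$ for
  large κ; naive fixed-grid quadrature loses ~0.2 log units at κ = 80).
* Bootstrap variance accumulators are centred on the point-fit measures;
  the naive sum-of-squares form loses all digits when the spread is ~1e-14
  (noiseless data).
* Eigenvector signs follow the largest-magnitude-component-positive
  convention; degenerate $\lambda_2 = \lambda_3$ planes are compared by
  projectors, never by individual vectors.
* Streamline tie-breaks (equal scores) go to the shorter fiber, then the
  earlier creation index, making selection deterministic under permutation.
* Per-nerve simulation seeds are drawn once from the cohort master seed, so
  any single nerve can be regenerated in isolation.

## Known limitations

* The imaging route inherits Rician bias at low SNR·signal products; absolute
  atrophic diffusivities are recovered with this bias, only the ground-truth
  table route is bias-free.
* The tracker is a local probabilistic walker with ROI termination, not a
  global path sampler; its candidate set is conditioned on success, with the
  keep_frac consequence described above.
* No susceptibility/eddy/motion correction is modelled; the b0-merge stage
  carries the volume-count contract only.
* The generator draws measurement-scale jitter at the subject level; it does
  not decompose within- vs between-subject variance beyond the control
  eye-sharing rule, because no such decomposition is published.
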