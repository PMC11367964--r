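---
title: "Methods: simulating and verifying reprojected planar scintigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and verifying reprojected planar scintigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 5)
set.seed(1)
```

## The question this package answers

In bone-tracer imaging of transthyretin (ATTR) cardiac amyloidosis, the
established quantitative readout is measured on a **conventional anterior
planar** image: the heart-to-contralateral ratio
$$
\mathrm{H/CL} \;=\;
\frac{\text{mean counts/pixel in a 70-mm circular heart ROI}}
     {\text{mean counts/pixel in the mirrored contralateral ROI}},
$$
with $\mathrm{H/CL} \ge 1.5$ supporting ATTR positivity. Ring-geometry
CZT cameras acquire SPECT only and produce no planar image. A
**reprojected planar** image can be synthesized instead: reconstruct the
SPECT volume, then forward-project it toward a virtual anterior detector
with attenuation weighting. The clinical question is whether H/CL ratios
and visual-score classifications measured on reprojected images agree
with those from conventional planar images.

Patient data cannot answer this question reproducibly at desk scale.
`replanar` therefore builds a fully synthetic analogue in which the
ground truth is known by construction: seeded digital phantoms play the
patients, physics simulations play both cameras, and the same agreement
statistics used clinically (percent agreement, Cohen's and Fleiss's
$\kappa$, linear regression, Bland–Altman) quantify the result.

## Pipeline overview

For every subject:

1. **Phantom** (`make_phantom`): analytic thorax with a myocardial shell
   whose activity concentration is `myo_to_rib_ratio` × rib uptake, so
   the subject's visual-score class (0–3) is known exactly.
2. **Conventional pathway** (`simulate_planar`): attenuated anterior
   line-integral projection of the true activity, Poisson noise.
3. **Reprojected pathway**: `simulate_spect` (rotation-based parallel-beam
   projections, Poisson noise) → `bsrem_rdp_reconstruct` (BSREM with the
   relative difference prior, the study's frozen settings
   $\beta = 0.4$, $\gamma = 4$) → `reproject_planar`.
4. **Measurement** (`measure_hcl`): automatic 70-mm heart-ROI placement,
   mirrored contralateral ROI, H/CL with the inclusive $\ge 1.5$ rule.
5. **Agreement** (`run_study` pools everything): regression,
   Bland–Altman, classification concordance at 1.5, and simulated-reader
   $\kappa$ statistics.

## Conventions and the forward model

Volumes are arrays indexed `[z, y, x]`: z caudal→cranial, y
anterior→posterior (index 1 is the anterior face, where the virtual
detector sits), x patient-right→patient-left. Voxels are isotropic,
default 2.46 mm.

The attenuated anterior projection of an activity volume $f$ with
attenuation map $\mu$ (per mm at 140 keV) is
$$
p(z, x) \;=\; s \,\Delta \sum_y f(z, y, x)\,
\exp\!\Big(-\Delta\big(\textstyle\sum_{y' < y}\mu(z, y', x)
  + \tfrac{1}{2}\mu(z, y, x)\big)\Big),
$$
with voxel size $\Delta$ and detector sensitivity $s$. The self-voxel
contributes half a step (midpoint convention, second-order accurate) and
the "edge of the object" is the anterior grid face — air voxels carry
$\mu = 0$, so the two definitions coincide.

SPECT projections reuse the same ray sum after rotating the volume about
the z axis. Rotation is a sparse bilinear-interpolation operator per
angle (cached); its transpose gives the exactly matched adjoint used by
the reconstructions, so $\langle P f, g\rangle = \langle f, P^{\top}
g\rangle$ holds to machine precision — the property EM-type algorithms
assume. An optional depth-dependent Gaussian PSF (FWHM = 4 mm +
0.04·distance, an LEHR-like response) can be enabled in both forward
models and the reconstruction system model; it is off by default and
never applied at reprojection time, where only attenuation integration
belongs.

Noise is Poisson per pixel on the noiseless expectation, seeded. Every
random stage derives its seed deterministically from one master seed
(`cohort_spec(seed = ...)`), so a study is a pure function of its
configuration.

## Phantom and cohort

The thorax is built from analytic primitives on the voxel grid: an
elliptical body cylinder, two lung ellipsoids, spine, sternum, periodic
rib bands, paired kidneys, and a spherical-shell myocardium with
ventricular blood pool, each with an activity concentration and a tissue
$\mu$ (soft 0.0154, lung 0.004, bone 0.025 per mm). Overlaps are
resolved by a fixed later-wins precedence; the returned organ masks
reflect the final labels.

The class mapping is a declared design choice anchored to the visual
score's wording: class 0 ⇔ ratio 0, class 1 ⇔ ratio < 0.8, class 2 ⇔
ratio in [0.8, 1.3], class 3 ⇔ ratio > 1.3 with rib uptake suppressed
(×0.4) to mimic the faint ribs of the top grade. Cohorts sample ratios
uniformly inside class bands kept off the boundaries, apply per-subject
anatomical jitter (±10 mm position, ±10 % size), and calibrate detector
sensitivity per subject so expected planar counts equal the cohort
`count_level` (default 2 × 10⁶; the SPECT pathway distributes the same
total across its angles).

```{r phantom}
library(replanar)
g <- grid_geometry(c(64, 64, 64))
ph <- make_phantom(phantom_spec(g, myo_to_rib_ratio = 1.6), seed = 7)
ph
img <- simulate_planar(ph$activity, ph$mu, g, noiseless = TRUE)
image(t(img$matrix[nrow(img$matrix):1, ]), col = hcl.colors(64, "inferno"),
      axes = FALSE, main = "noiseless anterior planar, class-3 phantom")
```

## Reconstruction

Three members of one EM family share the projector pair:

* **MLEM** — multiplicative update
  $f \leftarrow f \cdot P^{\top}(y / P f) / P^{\top} 1$;
* **OSEM** — the same update over interleaved angle subsets;
* **BSREM-RDP** — relaxed block-sequential update of the penalized
  objective $L(f) - \beta U(f)$ with the relative difference prior
  $$
  U(f) = \sum_{\{j,k\}\ \text{6-neighbours}}
  \frac{(f_j - f_k)^2}{f_j + f_k + \gamma |f_j - f_k| + \varepsilon},
  $$
  summed over unordered neighbour pairs.

Numerical choices worth knowing:

* The relaxation schedule is $\alpha_n = \alpha_0 / (1 + \lambda n)$
  with defaults $\alpha_0 = 1$, $\lambda = 0$, chosen so that
  $\beta = 0$ reduces BSREM to OSEM *iterate for iterate* — a structural
  identity the tests assert exactly.
* Reconstruction is restricted to the field of view actually measured by
  the rotating geometry: the circle inscribed in the (y, x) plane
  intersected with a sensitivity-support mask. The restriction is
  reapplied after the additive update's nonnegativity floor; without it,
  near-zero-sensitivity corner voxels are divided by ~0 and explode.
* The multiplicative (OS)EM branch applies no floor at all, preserving
  exact zeros and EM fixed points to machine precision.

`reconstruct_for_study()` freezes the study configuration: BSREM-RDP,
$\beta = 0.4$, $\gamma = 4$, 20 iterations × 6 subsets. Problem sizes
(64³ voxels, 60 angles) are this package's own desk-scale choices.

## Reprojection and the operator identity

`reproject_planar()` applies the identical attenuated anterior
projection to the reconstructed volume. This gives the pipeline its
central internal oracle: feeding the *true* activity through
reprojection reproduces the noiseless conventional simulation pixel for
pixel, to machine precision. Any disagreement between the two pathways
in a full study therefore comes from counting noise and reconstruction,
never from mismatched projection conventions.

```{r identity}
rp <- reproject_planar(ph$activity, ph$mu, g)
max(abs(rp$matrix - img$matrix))
```

## H/CL measurement

ROI membership is pixel-center-in-circle (no partial areas). The heart
ROI is placed automatically — the feasible center maximizing mean disc
counts in the patient-left half with the lowest 30 % of rows excluded
(keeping kidneys out), ties broken toward smallest z then x — and
mirrored across the mid-sagittal line for the contralateral ROI. A
`center` override mirrors the clinical manual workflow. The boundary is
inclusive: a ratio of exactly 1.5 is positive.

```{r hcl}
measure_hcl(img)
```

## Agreement statistics

All of the battery is implemented natively (and cross-checked in the
test suite against independent oracles): percent agreement with
nearest-integer reporting, Cohen's $\kappa$ with $p_e$ from marginal
products, Fleiss's $\kappa$ from per-subject pairwise agreement, OLS
regression with Pearson $r$, and Bland–Altman with differences taken as
reprojected − conventional and limits $\text{bias} \pm 1.96\,\mathrm{SD}$.
Confidence intervals use a seeded percentile bootstrap over subjects
(2000 replicates) — appropriate at $n = 30$ where large-sample formulas
are shaky. Human visual scoring is out of computational scope; a seeded
reader model (truth ± 1 unit with small probability) stands in so the
$\kappa$ machinery is exercised end to end.

## A small end-to-end study

A reduced study (smaller grid, fewer angles and iterations) runs in
seconds and shows the full report surface; the production-scale
verification (30 subjects, 64³, 60 angles, 20 × 6) is what
`scripts/acceptance.R` runs.

```{r study}
cohort <- cohort_spec(n_subjects = 4L,
                      class_mix = c("0" = 1L, "1" = 1L, "2" = 1L, "3" = 1L),
                      count_level = 5e5, seed = 2L,
                      grid = grid_geometry(c(24, 24, 24)))
cfg <- study_config(cohort = cohort, angles = seq(0, 345, by = 15),
                    n_iterations = 6L, n_subsets = 4L,
                    roi_diameter_mm = 24)
st <- run_study(cfg, progress = FALSE)
summary(st)
plot(st, which = 1)
plot(st, which = 2)
```

## What the generator does and does not emulate

Modelled: attenuated emission projection, Poisson counting statistics,
multi-angle acquisition with matched reconstruction, per-subject anatomy
variation, class-anchored myocardial uptake, the clinical ROI protocol
and statistics.

Deliberately not modelled: realistic (atlas-based) anatomy and motion;
scatter, septal penetration and energy-spectrum effects (the clinical
literature's own caveat about CZT spectral "tailing" is out of scope);
detector sweep kinematics of ring-CZT systems (abstracted to evenly
spaced parallel-beam angles); vendor-adaptive penalty strength (fixed
$\beta$ instead); CT acquisition physics (attenuation maps are generated
directly, with `hu_to_mu()` available for CT-number volumes); and human
perceptual scoring.

These omissions bound the claim: the package verifies that the
*reprojection methodology* preserves H/CL and classification under known
ground truth — it does not predict absolute clinical performance.
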