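---
title: "Depth-stratified quantification of intraretinal hyperreflective foci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-stratified quantification of intraretinal hyperreflective foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihrfslab)
```

## The problem

Intraretinal hyperreflective foci (IHRF) are discrete, well-circumscribed
bright lesions seen on optical coherence tomography (OCT) within the
neurosensory retina of eyes with intermediate age-related macular
degeneration (iAMD). They are defined by two properties: a reflectivity at
least that of the retinal pigment epithelium (RPE) band — the brightest
normal structure in the scan — and a minimum size of 3 pixels. Their number,
and in particular their *depth* within the retina, carries prognostic
information: lesions concentrated in the outer retina, close to the RPE, are
associated with a substantially higher risk of progression to late AMD over
two years than lesions in the inner retina.

`ihrfslab` implements the full quantification protocol as a reproducible
pipeline:

1. partition the retina between the internal limiting membrane (ILM) and the
   inner RPE surface into **five sequential slabs of equal fractional
   thickness** (slab 1 = 80–100% depth, adjacent to the RPE; slab 5 = 0–20%,
   beneath the ILM);
2. project each slab to an **en-face image**;
3. **threshold and binarize** every slab with a single RPE-referenced
   threshold;
4. **mask artifacts** (vessels, drusen-related RPE bleed-through);
5. count lesions per slab by **connected-component particle analysis** with
   a 3-pixel minimum area;
6. relate per-slab counts to progression with **paired count tests and
   logistic regression**, plus Cohen's kappa for grader agreement.

Because clinical OCT volumes cannot be redistributed, the package ships a
synthetic phantom and cohort generator with exact ground truth; every stage
of the pipeline is validated against it.

## Slab geometry

For an A-scan column with ILM depth $z_{ILM}$ and inner-RPE depth $z_{RPE}$
(voxel units, 0-based, increasing posteriorly), slab $k$ with fractional
range $[f_{lo}, f_{hi}]$ is bounded by

$$ z_{lo} = z_{ILM} + f_{lo}\,(z_{RPE} - z_{ILM}), \qquad
   z_{hi} = z_{ILM} + f_{hi}\,(z_{RPE} - z_{ILM}), $$

so both slab surfaces follow the ILM and RPE contours by construction and
the five slabs tile $[z_{ILM}, z_{RPE}]$ exactly. Three numerical choices
matter here:

* **Projection operator.** The device's en-face rendering is not publicly
  specified; we use a maximum-intensity projection by default because the
  pipeline's purpose is to preserve the brightest lesion voxel for
  thresholding. A mean projection is available (`projection = "mean"`) for
  sensitivity analyses.
* **Voxel assignment.** Slab intervals are half-open, $[z_{lo}, z_{hi})$,
  with voxels assigned by their center coordinate, so no interior voxel is
  ever counted in two slabs; slab 1 is closed at the RPE end so the
  outermost voxel is never orphaned. Boundaries are kept continuous — they
  are never rounded to whole voxel rows before the interval test.
* **Boundary straddling.** A 3-D lesion whose ball intersects two slabs
  appears on both en-face images and is counted once in each — the
  double-counting convention for boundary lesions. This is a property of the
  lesion's *extent*, not of the interval bookkeeping above.

If a column's slab interval contains no voxel center (retina thinner than 5
voxels), the pixel falls back to the nearest voxel and a warning is issued.

## Thresholding and detection

IHRF are defined relative to the RPE band, so the default threshold is
*RPE-referenced*: the reflectivity is sampled along the RPE surface in every
column, and the threshold is `threshold_value` × the median sample, applied
identically to all five slabs. The median is robust both to speckle and to
the minority of columns whose RPE is shadowed by an overlying vessel. The
default `threshold_value = 0.9` backs off the nominal "at least RPE-bright"
definition by 10% so that speckle on a true lesion does not drop it below
threshold; absolute and histogram-percentile modes are available. The
published protocol's interactive threshold refinement is modelled as
explicit configuration rather than a manual loop — reproducibility over
fidelity to the manual step.

Binarized slabs are counted by connected-component labeling (two-pass
union-find) under 8-connectivity (the ImageJ particle-analysis default;
4-connectivity available) with components below `min_area_px = 3` discarded.
The 3-pixel minimum is stated for B-scan grading in the source protocol; we
apply it to the en-face component area, since quantification operates on
en-face slabs — this reading is a package decision, noted rather than
asserted as the protocol's intent.

Manual artifact removal is replaced by an automated mask:

* **Vessels** (slabs 4–5 only): pixels suprathreshold in the innermost slab
  whose RPE-band sample is dimmed below 60% of the volume median — the
  vessel-shadow signature — dilated by one pixel.
* **Drusen bleed-through** (slab 1): columns where the RPE is elevated at
  least 4 voxels above a running-median background are treated as a drusen
  apex; there slab 1's boundary runs within a 2-voxel guard band of the
  bright RPE and any suprathreshold signal is masked. A true focus directly
  over a drusen apex would be masked with it — a known limitation of the
  automated surrogate; user-drawn exclusion (or inclusion-sparing) masks can
  be supplied alongside.

An important negative design rule: slab 5's observed emptiness in the
motivating cohort is *data*, not a rule — foci implanted at fractional
depth 0.1 are detected in slab 5 like any other.

## The synthetic phantom

The generator emulates a macular cube at a scaled-down default grid of
128×32×256 voxels (tests use 64×16×160), standing in for a clinical
512×128 cube over 6×6 mm, so that a phantom renders and analyses in a
fraction of a second; full-size grids are a `volume_spec()` call away. The
retina is five reflectivity bands between flat ILM and RPE surfaces
(defaults 0.30/0.14/0.24/0.10/0.28, RPE 0.75, arbitrary units). No published
quantitative band reflectivities exist for this protocol, so the defaults
are conventional: a bright/dark alternation approximating NFL–IPL–INL/ONL
contrast, kept well below the RPE so that the detection margin is realistic
rather than generous. Band realism is cosmetic — the protocol only ever uses
fractional depth, never anatomical layer identity.

Confounders are modelled explicitly: drusen elevate the RPE with cosine
bumps (pointwise-maximum composition) and can deposit an RPE-bright
"segmentation bleed" cap at their apex; vessels are bright inner-band spots
over a dimmed shadow column. Speckle is multiplicative
$\mathrm{Gamma}(\alpha, 1/\alpha)$ noise (mean 1, variance $1/\alpha$), a
standard surrogate for fully developed OCT speckle; $\alpha = 0$ disables
it. What the phantom does **not** model: the A-scan point-spread function,
attenuation and motion artifacts, curved foveal geometry, and real device
file formats. Passing the recovery tests therefore demonstrates the
*bookkeeping* of the protocol (geometry, thresholding, counting, boundary
conventions) — not segmentation robustness on clinical scans, where surface
quality dominates.

Ground truth is computed from the same voxel geometry as the renderer: a
focus' truth entry lists every slab in which its rendered ball has an
en-face footprint, so truth and detection share one definition of "appears
in a slab" and exact-recovery tests are meaningful.

## The cohort simulator

Each simulated eye draws baseline per-slab counts
$c_k \sim \mathrm{Poisson}(\mu_k)$ and follow-up counts
$c_k + \mathrm{Poisson}(\delta_k)$ — follow-up exceeds baseline in
expectation, matching the observed monotone growth in lesion load; a
decrement option was considered and left out. Progression is Bernoulli with

$$ \mathrm{logit}\,P = \mathrm{logit}(p_0) + \textstyle\sum_k \beta_k c_k. $$

Defaults are the motivating study's conditions: 52 eyes, $\mu_k$ and
$\delta_k$ from the published per-slab totals over 52 eyes, slab-5 means
pinned to zero (enforced as an invariant of `cohort_spec()`),
$\beta = \log(2.13, 1.46, 1.11, 1, 1)$ from the published univariate odds
ratios, $p_0 = 0.2$. One master seed drives per-eye substreams derived by
counter, so eyes are independent yet individually reproducible and the
table is invariant to how many eyes are drawn before a given one.

## Statistics

* **Paired count test**: closed-form paired t on follow-up − baseline
  differences (positive t = counts increased), with degenerate inputs
  flagged (`status = "degenerate"`) instead of producing undefined numbers;
  the all-zero-difference case is reported as the exact null (t = 0, p = 1).
* **Logistic regression**: maximum likelihood via `glm`, odds ratio
  $e^\beta$ with Wald intervals and p-values (the convention of the
  mainstream statistical packages this analysis mirrors);
  profile-likelihood intervals behind `ci_method = "profile"`. Predictors
  with no variation, rank-deficient (collinear) terms, and fits with
  complete or quasi-separation (diverging coefficient or exploding standard
  error) are reported as `inestimable` — the analog of the NA entries for
  slabs with too few affected eyes — rather than silently penalized.
  Categorical coding is presence (any lesion) vs absence, absence as
  reference. Two eyes of one patient are treated as independent (eye-level
  models); a one-eye-per-patient sensitivity analysis can be run by
  subsetting the cohort table.
* **Agreement**: unweighted Cohen's kappa with the large-sample
  (Fleiss–Cohen–Everitt) standard error. The source protocol names both ICC
  and an "unweighted k" for the same assessment; the kappa reading is
  implemented.
* **Reporting**: derived means and percentages are rounded half-up to one
  decimal (odds ratios to two), matching printed precision; all raw values
  stay available in the tibbles.

The paired test includes every analysed eye by default, including eyes that
acquired their first lesion after baseline; whether such eyes belong in the
test is not specified by the protocol, so both definitions are supported by
filtering the cohort table before the call.

## Problem sizes used in validation

The package's own validation uses 100 noise-free and 40 speckled
(shape 20) random phantoms on the 64×16×160 grid for detection recovery;
1,000 random 32×32 masks for the particle-analysis oracle; a 5,000-eye
cohort for odds-ratio recovery (recovered univariate OR for
$\beta_1 = \log 2.13$ expected within [1.9, 2.4]); and 500 cohorts of 300
eyes for Wald interval coverage (expected 93–97%). These sizes make the
full suite run in minutes on one CPU while leaving the statistical checks
comfortably powered.

## Worked example

```{r example, eval = FALSE}
# phantom with known truth
spec <- volume_spec(speckle_shape = 20, seed = 7)
surfaces <- generate_surfaces(spec, drusen = list(drusen_spec(90, 20, 9, 10)))
foci <- sample_foci(spec, 5, seed = 7)
vol <- render_volume(spec, surfaces, foci = foci)

q <- quantify_eye(vol, surfaces)
slab_counts(q)          # detected per-slab counts
truth_counts(vol)       # ground truth

# cohort statistics
cohort <- simulate_cohort(cohort_spec(n_eyes = 300, seed = 7))
report <- build_report(cohort, n_eyes_cohort = 600)
report
plot_odds_ratios(report$baseline_or)
```

## Known limitations

* Surfaces are inputs; the package deliberately performs no retinal layer
  segmentation, matching the protocol's reliance on device segmentation
  with manual correction.
* The automated artifact mask trades fidelity to the manual free-hand step
  for reproducibility; over drusen apexes it is intentionally aggressive.
* No 3-D lesion tracking across visits, and no lesion morphometrics beyond
  count — shape and size were out of scope for the protocol.
* No age adjustment, survival modelling or multiple-testing correction, by
  design.
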