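# ihrfslab

Depth-stratified quantification of intraretinal hyperreflective foci (IHRF)
on OCT en-face slabs, with longitudinal progression statistics.

## What problem this solves

IHRF are discrete, well-circumscribed lesions within the neurosensory retina
on optical coherence tomography, defined by a reflectivity at least that of
the retinal pigment epithelium (RPE) band and a minimum size of 3 pixels. In
eyes with intermediate age-related macular degeneration (iAMD), the number
of IHRF — and critically their *depth* within the retina — predicts
progression to late AMD: lesions in the outer retina, adjacent to the RPE,
carry far more risk than lesions near the inner surface.

`ihrfslab` is for image-analysis and reading-center researchers who want
that quantification protocol as tested, scriptable code instead of a manual
ImageJ workflow. It implements:

- **Slab geometry** — the retina between the internal limiting membrane
  (ILM, fractional depth 0) and the inner RPE surface (depth 1) is split
  into five slabs of equal fractional thickness
  (`z_lo = z_ILM + f_lo (z_RPE − z_ILM)`, slab 1 = 80–100% just above the
  RPE, slab 5 = 0–20% under the ILM), each projected to an en-face image by
  maximum-intensity projection.
- **Detection** — one RPE-referenced threshold for all slabs
  (`0.9 × median RPE-band reflectivity` by default), binarization, automated
  vessel/drusen-bleed artifact masks, and particle analysis (connected
  components, 8-connectivity, area ≥ 3 px). A lesion straddling a slab
  boundary appears on both en-face images and is counted once in each slab.
- **Progression statistics** — paired t-tests on per-slab counts between
  visits; univariate and multivariate logistic regression of progression on
  per-slab counts, changes, or presence (odds ratio `exp(β)` with Wald 95%
  CI, inestimable predictors flagged rather than mis-reported); unweighted
  Cohen's kappa with large-sample CI for grader agreement; and a four-table
  report builder.
- **Synthetic ground truth** — an OCT phantom generator (layered retina,
  drusen with RPE bleed-through, vessel shadows, Gamma speckle, implanted
  foci of known fractional depth) and a two-visit cohort simulator with a
  known logistic progression model, so every stage is testable without
  clinical data.

Everything tabular flows as tibbles (`tidy()`, `glance()`, `autoplot()`
methods included), so results pipe straight into dplyr/ggplot2.

## Worked example

```r
library(ihrfslab)

spec     <- volume_spec(speckle_shape = 20, seed = 7)   # 128x32x256 phantom
surfaces <- generate_surfaces(spec, drusen = list(drusen_spec(90, 20, 9, 10)))
foci     <- sample_foci(spec, 5, seed = 7)              # 5 interior foci
vol      <- render_volume(spec, surfaces, foci = foci)

quantify_eye(vol, surfaces)
#> <ihrf_quant> eye1 / baseline: 5 lesion component(s), threshold 0.6603
#> # A tibble: 1 × 5
#>   slab1 slab2 slab3 slab4 slab5
#>   <int> <int> <int> <int> <int>
#> 1     0     2     2     1     0

truth_counts(vol)$n_true
#> [1] 0 2 2 1 0
```

Despite speckle (Gamma shape 20), the detector recovers the implanted
distribution exactly: two lesions in slab 2, two in slab 3, one in slab 4.
The threshold 0.6603 is 0.9 × the median speckled RPE reflectivity (0.75
noise-free).

The reference lesion distribution of the motivating 52-eye cohort ships
with the package; its headline arithmetic:

```r
summarize_counts(ihrf_study_counts())
#> # A tibble: 1 × 6
#>   baseline_total followup_total baseline_mean_per_eye followup_mean_per_eye ...
#> 1            243            604                   4.7                  11.6
```

243 lesions at baseline rising to 604 at two years (11.6 per eye over the
52 analysed eyes, 43.3% of the 120-eye cohort).

For a full simulated study — phantom, slabs, detection, cohort regression
tables, report — run the bundled pipeline:

```r
run_pipeline(pipeline_config("out_dir", seed = 1))
```

or from a shell: `Rscript inst/scripts/ihrf_pipeline.R --out out_dir --seed 1`.

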