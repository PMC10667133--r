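#' Specify a synthetic OCT volume
#'
#' Describes the geometry and reflectivity of a simulated macular OCT cube.
#' The default grid (128 A-scans x 32 B-scans x 256 depth samples) is a
#' scaled-down analog of a clinical 512x128 macular cube over a 6x6 mm field,
#' chosen so that phantoms render and analyse in well under a second.
#'
#' The retina is modelled as five reflectivity bands of equal fractional
#' thickness between the internal limiting membrane (ILM, fractional depth 0)
#' and the inner retinal pigment epithelium surface (RPE, fractional depth 1),
#' with the RPE band rendered below the retina as the brightest structure in
#' the volume. Intraretinal hyperreflective foci (IHRF) are by definition at
#' least as reflective as the RPE band, so `rpe_reflectivity` must strictly
#' exceed every retinal band reflectivity.
#'
#' @param n_ascans_x,n_bscans_y,n_depth_z Grid dimensions (fast lateral axis,
#'   slow lateral axis, depth). All must be at least 8.
#' @param voxel_dz Axial voxel size in micrometers (metadata only; the
#'   analysis operates in voxel units).
#' @param layer_reflectivities Five band intensities in `[0, 1]`, ordered
#'   inner (vitread) to outer (sclerad). Defaults approximate the bright/dark
#'   alternation of NFL, IPL/INL, ONL, EZ-adjacent and outer bands.
#' @param rpe_reflectivity RPE band intensity in `[0, 1]`; must exceed every
#'   entry of `layer_reflectivities`.
#' @param rpe_band_px Rendered RPE band thickness in voxels.
#' @param ilm_depth Depth (voxels, 0-based, increasing posteriorly) of the
#'   flat baseline ILM surface.
#' @param retina_px Baseline retinal thickness in voxels (ILM to inner RPE).
#' @param speckle_shape Shape parameter of the multiplicative Gamma speckle
#'   (mean 1, variance `1/shape`); `0` disables noise entirely.
#' @param seed Integer seed for the speckle field.
#'
#' @return An object of class `volume_spec`.
#' @seealso [generate_surfaces()], [render_volume()]
#' @export
volume_spec <- function(n_ascans_x = 128L, n_bscans_y = 32L, n_depth_z = 256L,
                        voxel_dz = 7.8,
                        layer_reflectivities = c(0.30, 0.14, 0.24, 0.10, 0.28),
                        rpe_reflectivity = 0.75,
                        rpe_band_px = 4L,
                        ilm_depth = 40,
                        retina_px = 100,
                        speckle_shape = 0,
                        seed = 1L) {
  dims <- c(n_ascans_x = n_ascans_x, n_bscans_y = n_bscans_y,
            n_depth_z = n_depth_z)
  if (any(dims < 8)) abort("all volume dimensions must be >= 8")
  if (length(layer_reflectivities) != 5L ||
      any(layer_reflectivities < 0 | layer_reflectivities > 1)) {
    abort("`layer_reflectivities` must be 5 intensities in [0, 1]")
  }
  check_scalar_number(rpe_reflectivity, "rpe_reflectivity", 0, 1)
  if (rpe_reflectivity <= max(layer_reflectivities)) {
    abort(paste0("`rpe_reflectivity` must strictly exceed every retinal band",
                 " reflectivity (the RPE is the brightest band)"))
  }
  check_scalar_number(speckle_shape, "speckle_shape", 0, Inf)
  check_scalar_number(retina_px, "retina_px", 5, n_depth_z)
  if (ilm_depth < 0 || ilm_depth + retina_px + rpe_band_px >= n_depth_z) {
    abort("retina plus RPE band must fit inside the depth range")
  }
  structure(
    list(n_ascans_x = as.integer(n_ascans_x),
         n_bscans_y = as.integer(n_bscans_y),
         n_depth_z = as.integer(n_depth_z),
         voxel_dz = voxel_dz,
         layer_reflectivities = as.numeric(layer_reflectivities),
         rpe_reflectivity = rpe_reflectivity,
         rpe_band_px = as.integer(rpe_band_px),
         ilm_depth = ilm_depth,
         retina_px = retina_px,
         speckle_shape = speckle_shape,
         seed = as.integer(seed)),
    class = "volume_spec")
}

#' Specify a hyperreflective focus to implant in a phantom
#'
#' @param x,y Lateral center indices (1-based A-scan and B-scan index).
#' @param frac_depth Fractional depth of the focus center between the ILM (0)
#'   and the inner RPE surface (1).
#' @param radius_px Ball radius in voxels. The default gives an en-face
#'   footprint comfortably above the 3-pixel minimum lesion size.
#' @param intensity Focus reflectivity in `[0, 1]`. Must be at least the
#'   owning volume's RPE reflectivity (checked at render time), matching the
#'   definition of IHRF as lesions at least as bright as the RPE band.
#' @return An object of class `focus_spec`.
#' @export
focus_spec <- function(x, y, frac_depth, radius_px = 2.5, intensity = 0.95) {
  check_scalar_number(frac_depth, "frac_depth", 0, 1)
  check_scalar_number(radius_px, "radius_px", 1e-6, Inf)
  check_scalar_number(intensity, "intensity", 0, 1)
  structure(list(x = x, y = y, frac_depth = frac_depth,
                 radius_px = radius_px, intensity = intensity),
            class = "focus_spec")
}

#' Specify a druse (focal RPE elevation)
#'
#' Drusen locally elevate the RPE surface towards the ILM with a smooth
#' cosine-bump profile. They are the confounder that lets bright RPE signal
#' bleed into the outermost retinal slab.
#'
#' @param x,y Lateral center indices (1-based).
#' @param radius_px Lateral bump radius in voxels.
#' @param height_px Apex elevation in voxels; must stay below the local
#'   retinal thickness.
#' @param bleed_px Thickness (voxels) of a bright segmentation-artifact cap
#'   rendered just above the elevated RPE at the druse apex. `0` (default)
#'   renders a clean druse; positive values emulate the RPE bleed-through
#'   that the artifact mask is designed to remove.
#' @return An object of class `drusen_spec`.
#' @export
drusen_spec <- function(x, y, radius_px, height_px, bleed_px = 0) {
  check_scalar_number(radius_px, "radius_px", 1e-6, Inf)
  check_scalar_number(height_px, "height_px", 0, Inf)
  check_scalar_number(bleed_px, "bleed_px", 0, Inf)
  structure(list(x = x, y = y, radius_px = radius_px,
                 height_px = height_px, bleed_px = bleed_px),
            class = "drusen_spec")
}

#' Specify a simulated two-visit cohort
#'
#' Defines the generative model for a longitudinal cohort of eyes with
#' per-slab IHRF counts at baseline and a two-year follow-up, and a
#' dichotomous progression outcome driven by a logistic model on the baseline
#' counts:
#' \deqn{\mathrm{logit}\, P(\mathrm{progressed}) =
#'   \mathrm{logit}(\mathrm{base\_rate}) + \sum_k \beta_k \cdot
#'   \mathrm{count}_k.}
#'
#' Defaults reproduce the study conditions of the motivating cohort: 52
#' analysed eyes, baseline per-slab Poisson means equal to per-eye averages of
#' the observed totals (58, 132, 49, 4, 0 lesions), follow-up counts equal to
#' baseline plus a Poisson increment matching the observed growth to
#' (194, 287, 100, 23, 0), log odds-ratios per lesion of
#' `log(c(2.13, 1.46, 1.11, 1, 1))`, and a 20% base progression rate. The
#' innermost slab (slab 5) must have mean count 0 at both visits — no lesion
#' was ever observed there.
#'
#' @param n_eyes Number of eyes.
#' @param base_rate Progression probability at zero lesions, in (0, 1).
#' @param beta_per_slab Five log odds-ratios per baseline lesion (slabs 1-5).
#' @param baseline_mean,followup_mean Five non-negative per-slab mean counts;
#'   `followup_mean` must be elementwise at least `baseline_mean`, and both
#'   must be 0 for slab 5.
#' @param seed Master seed; each eye draws from its own derived substream so
#'   eyes are independent yet individually reproducible.
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_eyes = 52L,
                        base_rate = 0.2,
                        beta_per_slab = log(c(2.13, 1.46, 1.11, 1, 1)),
                        baseline_mean = c(58, 132, 49, 4, 0) / 52,
                        followup_mean = c(194, 287, 100, 23, 0) / 52,
                        seed = 1L) {
  if (n_eyes < 1) abort("`n_eyes` must be positive")
  check_scalar_number(base_rate, "base_rate", 1e-12, 1 - 1e-12)
  if (length(beta_per_slab) != 5L || any(!is.finite(beta_per_slab))) {
    abort("`beta_per_slab` must be 5 finite log odds-ratios")
  }
  for (nm in c("baseline_mean", "followup_mean")) {
    v <- get(nm)
    if (length(v) != 5L || any(v < 0)) {
      abort(sprintf("`%s` must be 5 non-negative mean counts", nm))
    }
  }
  if (baseline_mean[5] != 0 || followup_mean[5] != 0) {
    abort("slab-5 mean counts must be 0 (no lesion is ever observed there)")
  }
  if (any(followup_mean < baseline_mean)) {
    abort("`followup_mean` must be >= `baseline_mean` in every slab")
  }
  structure(list(n_eyes = as.integer(n_eyes), base_rate = base_rate,
                 beta_per_slab = as.numeric(beta_per_slab),
                 baseline_mean = as.numeric(baseline_mean),
                 followup_mean = as.numeric(followup_mean),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Detection parameters for IHRF thresholding and particle counting
#'
#' @param threshold_mode How the binarization threshold is obtained:
#'   * `"rpe_fraction"` (default): `threshold_value` times the median
#'     reflectivity sampled along the RPE band — the reference band IHRF must
#'     match or exceed by definition.
#'   * `"absolute"`: `threshold_value` used directly as an intensity.
#'   * `"percentile"`: the given percentile of the pooled en-face slab
#'     histogram.
#' @param threshold_value In `[0, 1]` for `rpe_fraction`/`absolute`, in
#'   (0, 100) for `percentile`. The default 0.9 tolerates moderate speckle on
#'   lesions that are nominally at least RPE-bright.
#' @param min_area_px Minimum en-face component area in pixels; components
#'   smaller than this are discarded (lesions are at least 3 pixels in size).
#' @param connectivity Pixel connectivity for component labeling, 4 or 8
#'   (8 matches the ImageJ particle-analysis default).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(threshold_mode = c("rpe_fraction", "absolute",
                                                "percentile"),
                             threshold_value = 0.9,
                             min_area_px = 3L,
                             connectivity = 8L) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "percentile") {
    check_scalar_number(threshold_value, "threshold_value", 1e-9, 100 - 1e-9)
  } else {
    check_scalar_number(threshold_value, "threshold_value", 0, 1)
  }
  if (min_area_px < 1) abort("`min_area_px` must be >= 1")
  if (!connectivity %in% c(4L, 8L)) abort("`connectivity` must be 4 or 8")
  structure(list(threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 min_area_px = as.integer(min_area_px),
                 connectivity = as.integer(connectivity)),
            class = "detection_params")
}
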