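#' Generate ILM and RPE segmentation surfaces for a phantom
#'
#' Builds the pair of depth maps bounding the neurosensory retina: a flat ILM
#' at `spec$ilm_depth` and an RPE surface at `ilm + retina_px`, locally
#' elevated (pulled towards the ILM, i.e. to smaller depth) by any drusen.
#' Each druse contributes a smooth cosine bump
#' `h(r) = height_px * (1 + cos(pi * r / radius_px)) / 2` inside its radius;
#' overlapping drusen combine by pointwise maximum elevation.
#'
#' Depth coordinates are 0-based voxel indices increasing posteriorly
#' (vitreous towards RPE), with the voxel center at the integer coordinate.
#'
#' @param spec A [volume_spec()].
#' @param drusen A list of [drusen_spec()] objects (may be empty).
#' @return An object of class `surface_pair`: list with `ilm_z` and `rpe_z`
#'   numeric matrices (`n_ascans_x` x `n_bscans_y`), `rpe_z > ilm_z`
#'   everywhere.
#' @export
generate_surfaces <- function(spec, drusen = list()) {
  stopifnot(inherits(spec, "volume_spec"))
  nx <- spec$n_ascans_x; ny <- spec$n_bscans_y
  ilm <- matrix(spec$ilm_depth, nx, ny)
  rpe_base <- spec$ilm_depth + spec$retina_px
  elev <- matrix(0, nx, ny)
  for (d in drusen) {
    stopifnot(inherits(d, "drusen_spec"))
    if (d$x < 1 || d$x > nx || d$y < 1 || d$y > ny) {
      abort(sprintf("drusen center (%s, %s) lies outside the %dx%d lateral field",
                    format(d$x), format(d$y), nx, ny))
    }
    if (d$height_px >= spec$retina_px) {
      abort("drusen height must be below the local retinal thickness")
    }
    elev <- pmax(elev, drusen_bump(d, nx, ny))
  }
  rpe <- rpe_base - elev
  structure(list(ilm_z = ilm, rpe_z = rpe), class = "surface_pair")
}

# Cosine bump elevation field of one druse on the full lateral grid.
drusen_bump <- function(d, nx, ny) {
  r <- sqrt(outer((seq_len(nx) - d$x)^2, (seq_len(ny) - d$y)^2, `+`))
  b <- matrix(0, nx, ny)
  inside <- r < d$radius_px
  b[inside] <- d$height_px * (1 + cos(pi * r[inside] / d$radius_px)) / 2
  b
}

# Fractional-depth value of every voxel center, as an (nx*ny) x nz matrix:
# row = lateral column (column-major over x, y), column = depth index z
# (0-based). frac = 0 at the ILM, 1 at the inner RPE surface.
frac_depth_matrix <- function(spec, surfaces) {
  nxny <- spec$n_ascans_x * spec$n_bscans_y
  nz <- spec$n_depth_z
  ilm <- as.vector(surfaces$ilm_z)
  thick <- as.vector(surfaces$rpe_z) - ilm
  if (any(thick <= 0)) {
    bad <- which(thick <= 0)
    abort(sprintf("non-positive retinal thickness at %d A-scan column(s), e.g. index %d",
                  length(bad), bad[1]))
  }
  zmat <- matrix(seq(0, nz - 1), nxny, nz, byrow = TRUE)
  (zmat - ilm) / thick
}

# Slab index (1 = outermost, adjacent to the RPE; 5 = innermost, at the ILM)
# of a fractional depth; NA outside [0, 1]. Slab k covers
# [1 - 0.2 k, 1.2 - 0.2 k), except slab 1 which is closed at 1 so the
# outermost voxel is never orphaned.
slab_index_of <- function(frac) {
  k <- 5 - pmin(floor(frac / 0.2), 4)
  k[frac < 0 | frac > 1] <- NA_integer_
  as.integer(k)
}

#' Render a synthetic OCT volume with ground-truth focus locations
#'
#' Voxels between the ILM and the inner RPE surface take the reflectivity of
#' their fractional-depth band (five bands of equal fractional thickness);
#' the RPE band is rendered just below the retina at `rpe_reflectivity`, the
#' brightest structure. Each focus is a ball of its own intensity centered at
#' the depth interpolated from its fractional depth. Vessels are small bright
#' spots in the innermost band whose entire sub-column (outer retina and RPE)
#' is dimmed by `shadow_factor`, reproducing the vessel-shadow confounder.
#' Drusen with `bleed_px > 0` additionally deposit RPE-bright voxels just
#' inside the retina at their apex, emulating segmentation bleed-through.
#' Multiplicative Gamma speckle (mean 1, shape `spec$speckle_shape`) is
#' applied last; shape 0 renders a noise-free volume.
#'
#' @param spec A [volume_spec()].
#' @param surfaces A `surface_pair` from [generate_surfaces()].
#' @param foci List of [focus_spec()] objects.
#' @param vessels List of length-2 vectors `c(x, y)` of vessel positions.
#' @param drusen List of [drusen_spec()]; only needed when a druse should
#'   render its apex bleed artifact (the surfaces already carry the
#'   elevation).
#' @param shadow_factor Multiplier applied beneath vessels, in (0, 1).
#' @param id,visit Identity metadata carried through to detection tables.
#' @return An object of class `oct_volume`: list with `data` (numeric array
#'   `nx x ny x nz`), `spec`, `id`, `visit`, and `truth`, a tibble with one
#'   row per (focus, slab) pair giving the en-face footprint (pixels) that
#'   the focus occupies in that slab. A focus centered exactly on a slab
#'   boundary straddles it and therefore has rows for both adjacent slabs —
#'   the double-counting convention for boundary lesions.
#' @export
render_volume <- function(spec, surfaces, foci = list(), vessels = list(),
                          drusen = list(), shadow_factor = 0.35,
                          id = "eye1", visit = "baseline") {
  stopifnot(inherits(spec, "volume_spec"), inherits(surfaces, "surface_pair"))
  nx <- spec$n_ascans_x; ny <- spec$n_bscans_y; nz <- spec$n_depth_z
  nxny <- nx * ny
  ilm <- as.vector(surfaces$ilm_z)
  rpe <- as.vector(surfaces$rpe_z)
  frac <- frac_depth_matrix(spec, surfaces)
  zmat <- matrix(seq(0, nz - 1), nxny, nz, byrow = TRUE)

  vol <- matrix(0, nxny, nz)
  retina <- frac >= 0 & frac <= 1
  band <- pmin(floor(frac * 5) + 1L, 5L)   # 1 = inner band ... 5 = outer band
  vol[retina] <- spec$layer_reflectivities[band[retina]]
  rpe_band <- zmat > rpe & zmat <= rpe + spec$rpe_band_px
  vol[rpe_band] <- spec$rpe_reflectivity

  # drusen apex bleed: RPE-bright voxels just inside the retina at the apex
  for (d in drusen) {
    if (d$bleed_px <= 0) next
    bump <- drusen_bump(d, nx, ny)
    apex <- which(as.vector(bump) >= 0.8 * d$height_px)
    for (i in apex) {
      zin <- which(zmat[i, ] > rpe[i] - d$bleed_px & zmat[i, ] <= rpe[i])
      vol[i, zin] <- spec$rpe_reflectivity
    }
  }

  for (v in vessels) {
    vx <- v[[1]]; vy <- v[[2]]
    if (vx < 1 || vx > nx || vy < 1 || vy > ny) {
      abort("vessel position lies outside the lateral field")
    }
    cols <- lateral_disk(vx, vy, 1.1, nx, ny)
    for (i in cols) {
      inner <- frac[i, ] >= 0 & frac[i, ] <= 0.1
      vol[i, inner] <- spec$rpe_reflectivity
      below <- frac[i, ] > 0.2 & zmat[i, ] <= rpe[i] + spec$rpe_band_px
      vol[i, below] <- vol[i, below] * shadow_factor
    }
  }

  truth <- list()
  for (fi in seq_along(foci)) {
    f <- foci[[fi]]
    stopifnot(inherits(f, "focus_spec"))
    if (f$x < 1 || f$x > nx || f$y < 1 || f$y > ny) {
      abort("focus center lies outside the lateral field")
    }
    if (f$intensity < spec$rpe_reflectivity) {
      abort("focus intensity must be at least the RPE reflectivity (IHRF definition)")
    }
    col0 <- f$x + (f$y - 1) * nx
    zc <- ilm[col0] + f$frac_depth * (rpe[col0] - ilm[col0])
    if (zc > rpe[col0]) abort("focus lies deeper than the RPE surface")
    r <- f$radius_px
    cols <- lateral_disk(f$x, f$y, r, nx, ny)
    hits <- list()
    for (i in cols) {
      xx <- (i - 1) %% nx + 1
      yy <- (i - 1) %/% nx + 1
      d2 <- (xx - f$x)^2 + (yy - f$y)^2
      if (d2 > r^2) next
      dz <- sqrt(r^2 - d2)
      zin <- which(zmat[i, ] >= zc - dz & zmat[i, ] <= zc + dz)
      if (!length(zin)) next
      vol[i, zin] <- f$intensity
      sl <- slab_index_of(frac[i, zin])
      sl <- unique(sl[!is.na(sl)])
      if (length(sl)) hits[[length(hits) + 1L]] <- tibble(col = i, slab = sl)
    }
    if (length(hits)) {
      h <- dplyr::bind_rows(hits)
      truth[[length(truth) + 1L]] <- h |>
        dplyr::count(.data$slab, name = "footprint_px") |>
        dplyr::mutate(focus = fi, x = f$x, y = f$y,
                      frac_depth = f$frac_depth, .before = 1)
    }
  }
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble(focus = integer(), x = numeric(), y = numeric(),
           frac_depth = numeric(), slab = integer(), footprint_px = integer())

  if (spec$speckle_shape > 0) {
    vol <- with_local_seed(spec$seed, {
      vol * rgamma(length(vol), shape = spec$speckle_shape,
                   rate = spec$speckle_shape)
    })
  }

  structure(list(data = array(vol, dim = c(nx, ny, nz)),
                 spec = spec, id = id, visit = visit, truth = truth),
            class = "oct_volume")
}

# Linear column indices (into the nx*ny lateral grid) within `r` of (cx, cy).
lateral_disk <- function(cx, cy, r, nx, ny) {
  xs <- max(1, floor(cx - r)):min(nx, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(ny, ceiling(cy + r))
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  g$x[keep] + (g$y[keep] - 1) * nx
}

#' Ground-truth per-slab focus counts of a rendered phantom
#'
#' Counts each implanted focus once in every slab where its en-face footprint
#' reaches `min_area_px` pixels — the same minimum-size rule the detector
#' applies, and the convention under which a boundary-straddling lesion is
#' counted once in each adjacent slab.
#'
#' @param volume An `oct_volume` from [render_volume()].
#' @param min_area_px Minimum footprint, defaults to the 3-pixel lesion
#'   minimum.
#' @return A tibble with columns `slab` (1-5) and `n_true`.
#' @export
truth_counts <- function(volume, min_area_px = 3L) {
  stopifnot(inherits(volume, "oct_volume"))
  volume$truth |>
    dplyr::filter(.data$footprint_px >= min_area_px) |>
    dplyr::count(.data$slab, name = "n_true") |>
    tidyr::complete(slab = 1:5, fill = list(n_true = 0L)) |>
    dplyr::arrange(.data$slab)
}

#' Sample random interior foci for a phantom
#'
#' Draws focus positions uniformly over the lateral field (respecting a
#' border margin and a minimum pairwise separation so footprints never merge)
#' and fractional depths that keep each ball strictly inside a single slab,
#' so ground truth is unambiguous.
#'
#' @param spec A [volume_spec()].
#' @param n Number of foci.
#' @param slabs Candidate slabs to place foci in.
#' @param margin Lateral border (pixels) kept clear.
#' @param min_sep Minimum center-to-center lateral separation (pixels).
#' @param radius_px,intensity Passed to [focus_spec()].
#' @param depth_pad_px Extra axial clearance (voxels) between the ball and
#'   the slab boundaries.
#' @param seed Optional seed (local RNG).
#' @return A list of [focus_spec()] objects.
#' @export
sample_foci <- function(spec, n, slabs = 1:4, margin = 6, min_sep = 10,
                        radius_px = 2.5, intensity = 0.95,
                        depth_pad_px = 1.5, seed = NULL) {
  with_local_seed(seed, {
    defs <- slab_definitions()
    pad <- (radius_px + depth_pad_px) / spec$retina_px
    attempt <- function() {
      out <- list(); xs <- numeric(0); ys <- numeric(0)
      tries <- 0L
      while (length(out) < n && tries < 200L * n) {
        tries <- tries + 1L
        x <- round(runif(1, 1 + margin, spec$n_ascans_x - margin))
        y <- round(runif(1, 1 + margin, spec$n_bscans_y - margin))
        if (length(xs) && min((xs - x)^2 + (ys - y)^2) < min_sep^2) next
        k <- sample(slabs, 1)
        lo <- defs$frac_lo[defs$slab == k] + pad
        hi <- defs$frac_hi[defs$slab == k] - pad
        if (hi <= lo) abort("slab too thin for the requested radius and padding")
        out[[length(out) + 1L]] <- focus_spec(x, y,
                                              frac_depth = runif(1, lo, hi),
                                              radius_px = radius_px,
                                              intensity = intensity)
        xs <- c(xs, x); ys <- c(ys, y)
      }
      out
    }
    for (restart in 1:50) {            # rejection sampling, fresh start on jams
      out <- attempt()
      if (length(out) == n) return(out)
    }
    abort("could not place the requested number of foci")
  })
}

#' Simulate a two-visit cohort of eyes with progression labels
#'
#' Baseline per-slab counts are Poisson with the spec's baseline means;
#' follow-up counts are baseline plus an independent Poisson increment (so
#' follow-up stochastically dominates baseline, matching the observed
#' monotone growth in lesion load). The progression label is Bernoulli with
#' `plogis(qlogis(base_rate) + sum(beta_per_slab * baseline))`. Each eye uses
#' a seed substream derived from the master seed by counter, so the table is
#' reproducible and eyes are mutually independent.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per eye: `eye`, `baseline_slab1..5`,
#'   `followup_slab1..5`, `p_progress` (true model probability) and
#'   `progressed` (logical).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  inc_mean <- spec$followup_mean - spec$baseline_mean
  draws <- vapply(seq_len(spec$n_eyes), function(i) {
    with_local_seed(sub_seed(spec$seed, i), {
      base <- rpois(5, spec$baseline_mean)
      fu <- base + rpois(5, inc_mean)
      p <- plogis(qlogis(spec$base_rate) + sum(spec$beta_per_slab * base))
      c(base, fu, p, runif(1) < p)
    })
  }, numeric(12))
  out <- tibble(eye = seq_len(spec$n_eyes))
  for (k in 1:5) out[[paste0("baseline_slab", k)]] <- as.integer(draws[k, ])
  for (k in 1:5) out[[paste0("followup_slab", k)]] <- as.integer(draws[5 + k, ])
  out$p_progress <- draws[11, ]
  out$progressed <- draws[12, ] > 0
  out
}
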