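#' The five fractional-depth slab definitions
#'
#' The neurosensory retina between the ILM (fractional depth 0) and the inner
#' RPE surface (fractional depth 1) is partitioned into five sequential slabs
#' of equal fractional thickness. Slab 1 is the outermost (80-100% depth,
#' just above the RPE), slab 5 the innermost (0-20%, just below the ILM).
#'
#' @return A tibble with columns `slab`, `frac_lo`, `frac_hi`.
#' @export
slab_definitions <- function() {
  tibble(slab = 1:5,
         frac_lo = c(0.8, 0.6, 0.4, 0.2, 0.0),
         frac_hi = c(1.0, 0.8, 0.6, 0.4, 0.2))
}

#' Depth boundaries of one slab under a surface pair
#'
#' For every A-scan column the slab's bounding surfaces are linear
#' interpolations between the ILM and RPE depths:
#' `lo_z = ilm_z + frac_lo * (rpe_z - ilm_z)` and likewise for `hi_z`, so
#' both slab boundaries follow the ILM and RPE contours by construction.
#'
#' @param surfaces A `surface_pair` (matrices `ilm_z`, `rpe_z`; depth must be
#'   strictly positive everywhere).
#' @param slab Slab index 1-5, or a one-row slice of [slab_definitions()].
#' @return A list with matrices `lo_z`, `hi_z` and the slab index `slab`.
#' @export
slab_boundaries <- function(surfaces, slab) {
  stopifnot(inherits(surfaces, "surface_pair"))
  if (is.numeric(slab) && length(slab) == 1L) {
    defs <- slab_definitions()
    slab <- defs[defs$slab == slab, ]
    if (nrow(slab) != 1L) abort("`slab` must be an index in 1..5")
  }
  thick <- surfaces$rpe_z - surfaces$ilm_z
  if (any(thick <= 0)) {
    bad <- which(thick <= 0)
    abort(sprintf("non-positive retinal thickness at %d A-scan column(s), e.g. linear index %d",
                  length(bad), bad[1]))
  }
  list(lo_z = surfaces$ilm_z + slab$frac_lo * thick,
       hi_z = surfaces$ilm_z + slab$frac_hi * thick,
       slab = slab$slab)
}

#' Project one slab of a volume to an en-face image
#'
#' Each en-face pixel summarizes the voxels whose center depth lies in the
#' half-open interval `[lo_z, hi_z)` of its column (closed at the upper end
#' for the outermost slab, so the voxel at the RPE surface is never
#' orphaned). The default summary is the maximum intensity, which preserves
#' the brightest lesion voxel for thresholding; `"mean"` is available for
#' sensitivity analyses. Boundaries are continuous — no rounding to whole
#' voxel rows occurs before the interval test.
#'
#' If a column's interval contains no voxel center (possible when the retina
#' is thinner than 5 voxels), the pixel falls back to the voxel nearest the
#' interval midpoint and a warning is issued.
#'
#' @param volume An `oct_volume`.
#' @param boundaries Output of [slab_boundaries()].
#' @param projection `"max"` (default) or `"mean"`.
#' @param closed_upper Include voxels at exactly `hi_z`? Set automatically
#'   for slab 1 when `boundaries` carries its slab index.
#' @return A numeric `nx x ny` matrix.
#' @export
extract_enface <- function(volume, boundaries,
                           projection = c("max", "mean"),
                           closed_upper = identical(boundaries$slab, 1L)) {
  stopifnot(inherits(volume, "oct_volume"))
  projection <- match.arg(projection)
  spec <- volume$spec
  nx <- spec$n_ascans_x; ny <- spec$n_bscans_y; nz <- spec$n_depth_z
  lo <- as.vector(boundaries$lo_z); hi <- as.vector(boundaries$hi_z)
  if (any(lo < 0) || any(hi > nz - 1 + 1e-9)) {
    abort("slab boundaries fall outside the volume depth range")
  }
  m <- matrix(volume$data, nx * ny, nz)
  zmat <- matrix(seq(0, nz - 1), nx * ny, nz, byrow = TRUE)
  inside <- zmat >= lo & (if (closed_upper) zmat <= hi else zmat < hi)
  nvox <- rowSums(inside)
  if (any(nvox == 0)) {
    warn(sprintf("%d column(s) have no voxel center inside the slab; using the nearest voxel",
                 sum(nvox == 0)))
    mid <- pmin(pmax(round((lo + hi) / 2), 0), nz - 1)
    fix <- which(nvox == 0)
    inside[cbind(fix, mid[fix] + 1L)] <- TRUE
  }
  px <- if (projection == "max") {
    mm <- m
    mm[!inside] <- -Inf
    mm[cbind(seq_len(nrow(mm)), max.col(mm, ties.method = "first"))]
  } else {
    rowSums(m * inside) / rowSums(inside)
  }
  matrix(px, nx, ny)
}

#' Build the full five-slab en-face stack of a volume
#'
#' @param volume An `oct_volume`.
#' @param surfaces A `surface_pair`.
#' @param projection Passed to [extract_enface()].
#' @return An object of class `slab_stack`: list with `images` (list of five
#'   `nx x ny` matrices, outermost slab first), `definitions`, `id`, `visit`.
#' @export
slab_stack <- function(volume, surfaces, projection = "max") {
  defs <- slab_definitions()
  images <- purrr::map(1:5, function(k) {
    extract_enface(volume, slab_boundaries(surfaces, k),
                   projection = projection)
  })
  names(images) <- paste0("slab", 1:5)
  structure(list(images = images, definitions = defs,
                 id = volume$id, visit = volume$visit,
                 projection = projection),
            class = "slab_stack")
}

#' @export
print.slab_stack <- function(x, ...) {
  cat(sprintf("<slab_stack> %s / %s: five %dx%d en-face images (%s projection)\n",
              x$id, x$visit, nrow(x$images[[1]]), ncol(x$images[[1]]),
              x$projection))
  invisible(x)
}
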