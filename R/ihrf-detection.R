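#' Sample reflectivity along the RPE band
#'
#' Returns one intensity per A-scan column, read from the voxel two samples
#' below the inner RPE surface (safely inside the rendered RPE band for any
#' band thickness of at least 2 voxels). The median of this sample is the
#' reference reflectivity that IHRF must match or exceed.
#'
#' @param volume An `oct_volume`.
#' @param surfaces A `surface_pair`.
#' @return A numeric vector of length `nx * ny`.
#' @keywords internal
sample_rpe_band <- function(volume, surfaces) {
  spec <- volume$spec
  nx <- spec$n_ascans_x; ny <- spec$n_bscans_y; nz <- spec$n_depth_z
  z <- pmin(floor(as.vector(surfaces$rpe_z)) + 2L, nz - 1L)
  m <- matrix(volume$data, nx * ny, nz)
  m[cbind(seq_len(nx * ny), z + 1L)]
}

#' Compute the binarization threshold
#'
#' In the default `rpe_fraction` mode the threshold is
#' `threshold_value * median(RPE band sample)`: lesions are defined as at
#' least RPE-bright, and the median over all columns is robust to speckle and
#' to the minority of columns shadowed by vessels. `absolute` passes
#' `threshold_value` through unchanged; `percentile` computes the given
#' percentile of the pooled en-face slab histogram. The same threshold is
#' applied to every slab.
#'
#' @param volume An `oct_volume`.
#' @param surfaces A `surface_pair`.
#' @param params A [detection_params()].
#' @param stack Optional [slab_stack()] (required only for `percentile`
#'   mode; computed on the fly if missing).
#' @return A single intensity threshold.
#' @export
compute_threshold <- function(volume, surfaces, params = detection_params(),
                              stack = NULL) {
  stopifnot(inherits(params, "detection_params"))
  switch(params$threshold_mode,
    rpe_fraction = {
      s <- sample_rpe_band(volume, surfaces)
      med <- median(s)
      if (!is.finite(med) || med <= 0) {
        abort("degenerate RPE sample (median reflectivity is not positive)")
      }
      params$threshold_value * med
    },
    absolute = params$threshold_value,
    percentile = {
      if (is.null(stack)) stack <- slab_stack(volume, surfaces)
      as.numeric(quantile(unlist(stack$images),
                          probs = params$threshold_value / 100))
    })
}

#' Binarize an en-face image
#'
#' A pixel is foreground iff its intensity is at least the threshold and it
#' is not excluded by the mask.
#'
#' @param enface Numeric matrix.
#' @param threshold Finite intensity threshold.
#' @param mask Optional logical matrix of the same size; `TRUE` excludes.
#' @return A logical matrix.
#' @export
binarize <- function(enface, threshold, mask = NULL) {
  if (!is.finite(threshold)) abort("`threshold` must be finite")
  out <- enface >= threshold
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(enface))) {
      abort("`mask` must have the same dimensions as the en-face image")
    }
    out <- out & !mask
  }
  out
}

#' Build per-slab artifact exclusion masks
#'
#' An automated surrogate for manual artifact removal. Two confounders are
#' masked:
#'
#' * **Vessels** (applied to slabs 4-5): pixels that are suprathreshold in
#'   the innermost slab *and* whose RPE-band sample is dimmed below
#'   `shadow_factor` times the volume-wide median — the vessel-shadow
#'   signature. The mask is dilated by one pixel to cover spot edges.
#' * **RPE bleed-through** (applied to slab 1): pixels over a drusen apex,
#'   identified as columns where the RPE surface is elevated at least
#'   `apex_min_elev_px` voxels above a smooth running-median background.
#'   There, slab 1's lower boundary comes within the `guard_px` guard band of
#'   the bright RPE, so any suprathreshold signal is treated as bleed.
#'
#' Any user-supplied mask is unioned into every slab.
#'
#' @param volume An `oct_volume`.
#' @param surfaces A `surface_pair`.
#' @param stack A [slab_stack()].
#' @param threshold Intensity threshold (from [compute_threshold()]).
#' @param shadow_factor Relative RPE dimming that flags a vessel shadow.
#' @param guard_px Guard band (voxels) around the RPE surface.
#' @param apex_min_elev_px Minimum RPE elevation (voxels) flagging a drusen
#'   apex.
#' @param user_mask Optional logical `nx x ny` matrix (or list of five) of
#'   additional exclusions.
#' @return A list of five logical matrices (`TRUE` = excluded), outermost
#'   slab first.
#' @export
build_artifact_mask <- function(volume, surfaces, stack, threshold,
                                shadow_factor = 0.6, guard_px = 2,
                                apex_min_elev_px = 4, user_mask = NULL) {
  spec <- volume$spec
  nx <- spec$n_ascans_x; ny <- spec$n_bscans_y
  empty <- matrix(FALSE, nx, ny)
  masks <- rep(list(empty), 5)

  # vessels: bright inner-band spot above a shadowed sub-column
  rpe_s <- matrix(sample_rpe_band(volume, surfaces), nx, ny)
  shadowed <- rpe_s < shadow_factor * median(rpe_s)
  vessel <- stack$images[["slab5"]] >= threshold & shadowed
  if (any(vessel)) vessel <- dilate3x3(vessel)
  masks[[4]] <- masks[[4]] | vessel
  masks[[5]] <- masks[[5]] | vessel

  # drusen apex bleed into slab 1: RPE locally elevated, slab interval
  # within the guard band of the RPE surface (true at the apex by geometry)
  bg <- smooth_surface(surfaces$rpe_z)
  elev <- bg - surfaces$rpe_z
  b1 <- slab_boundaries(surfaces, 1L)
  near_rpe <- (surfaces$rpe_z - b1$hi_z) <= guard_px   # holds everywhere for slab 1
  masks[[1]] <- masks[[1]] | (elev >= apex_min_elev_px & near_rpe)

  if (!is.null(user_mask)) {
    um <- if (is.list(user_mask)) user_mask else rep(list(user_mask), 5)
    masks <- purrr::map2(masks, um, `|`)
  }
  names(masks) <- paste0("slab", 1:5)
  masks
}

# Smooth a depth map with a separable running median (window wide enough to
# step over drusen-scale bumps), used as the drusen-free RPE background.
smooth_surface <- function(m, kx = 31L, ky = 15L) {
  odd_leq <- function(k, n) max(1L, min(k, if (n %% 2L) n else n - 1L))
  kx <- odd_leq(kx, nrow(m)); ky <- odd_leq(ky, ncol(m))
  out <- apply(m, 2, function(col) runmed(col, kx, endrule = "median"))
  t(apply(out, 1, function(row) runmed(row, ky, endrule = "median")))
}

# 3x3 (8-neighborhood) binary dilation.
dilate3x3 <- function(b) {
  out <- b
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    out <- out | shift_matrix(b, dx, dy, fill = FALSE)
  }
  out
}

# Shift a matrix by (dx, dy), filling exposed cells with `fill`.
shift_matrix <- function(m, dx, dy, fill) {
  n <- matrix(fill, nrow(m), ncol(m))
  xs <- seq_len(nrow(m)); ys <- seq_len(ncol(m))
  xs_to <- xs + dx; ys_to <- ys + dy
  okx <- xs_to >= 1 & xs_to <= nrow(m)
  oky <- ys_to >= 1 & ys_to <= ncol(m)
  n[xs_to[okx], ys_to[oky]] <- m[xs[okx], ys[oky]]
  n
}

#' Label connected components of a binary image
#'
#' Classic two-pass labeling with union-find: a raster scan assigns each
#' foreground pixel the label of an already-visited neighbor (4- or
#' 8-connected) and records label equivalences, which a second pass resolves.
#' Labels are numbered 1..n in first-pixel (column-major) order.
#'
#' @param binary A logical matrix.
#' @param connectivity 4 or 8.
#' @return An integer matrix; 0 = background, k = pixel of component k.
#' @export
label_components <- function(binary, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) abort("`connectivity` must be 4 or 8")
  nr <- nrow(binary); nc <- ncol(binary)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!binary[i, j]) next
    nb <- integer(0)
    if (i > 1L && binary[i - 1L, j]) nb <- c(nb, lab[i - 1L, j])
    if (j > 1L && binary[i, j - 1L]) nb <- c(nb, lab[i, j - 1L])
    if (connectivity == 8L && j > 1L) {
      if (i > 1L && binary[i - 1L, j - 1L]) nb <- c(nb, lab[i - 1L, j - 1L])
      if (i < nr && binary[i + 1L, j - 1L]) nb <- c(nb, lab[i + 1L, j - 1L])
    }
    if (!length(nb)) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i, j] <- nxt
    } else {
      m <- min(nb)
      lab[i, j] <- m
      for (o in nb) if (o != m) union(m, o)
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  fg <- lab > 0L
  lab[fg] <- dense[lab[fg]]
  lab
}

#' Particle analysis: count filtered connected components
#'
#' Labels the binary image, discards components smaller than
#' `params$min_area_px`, and returns one row per surviving component.
#' Clustered but separated foci remain separate components — each lesion is
#' counted separately as long as the foci are clearly separated.
#'
#' @param binary A logical matrix.
#' @param params A [detection_params()].
#' @param slab_index Slab index recorded on each component.
#' @return A tibble with columns `slab`, `component`, `centroid_x`,
#'   `centroid_y`, `area_px`.
#' @export
count_particles <- function(binary, params = detection_params(),
                            slab_index = NA_integer_) {
  lab <- label_components(binary, params$connectivity)
  ids <- lab[lab > 0L]
  if (!length(ids)) {
    return(tibble(slab = integer(), component = integer(),
                  centroid_x = numeric(), centroid_y = numeric(),
                  area_px = integer()))
  }
  idx <- which(lab > 0L, arr.ind = TRUE)
  tibble(id = ids, x = idx[, 1], y = idx[, 2]) |>
    dplyr::summarise(centroid_x = mean(.data$x), centroid_y = mean(.data$y),
                     area_px = dplyr::n(), .by = "id") |>
    dplyr::filter(.data$area_px >= params$min_area_px) |>
    dplyr::arrange(.data$id) |>
    dplyr::mutate(slab = as.integer(slab_index),
                  component = dplyr::row_number(), .before = 1) |>
    dplyr::select(!"id")
}

#' Quantify IHRF for one eye and visit
#'
#' Composes the full per-eye protocol: slab boundary construction, en-face
#' projection of the five slabs, threshold computation, automated artifact
#' masking, binarization and particle counting. The same threshold is applied
#' to every slab. A lesion straddling a slab boundary appears on both
#' adjacent en-face images and therefore contributes one component to each —
#' it is counted twice, once per slab.
#'
#' @param volume An `oct_volume`.
#' @param surfaces A `surface_pair`.
#' @param params A [detection_params()].
#' @param mask_artifacts Apply the automated artifact mask
#'   ([build_artifact_mask()])?
#' @param user_mask Optional extra exclusion mask(s), see
#'   [build_artifact_mask()].
#' @param projection En-face projection operator.
#' @return An object of class `ihrf_quant`: list with `components` (tibble:
#'   `eye`, `visit`, `slab`, `component`, `centroid_x`, `centroid_y`,
#'   `area_px`), `counts` (tibble: `slab`, `n`), the `threshold` used,
#'   `params`, `eye` and `visit`.
#' @export
quantify_eye <- function(volume, surfaces, params = detection_params(),
                         mask_artifacts = TRUE, user_mask = NULL,
                         projection = "max") {
  stack <- slab_stack(volume, surfaces, projection = projection)
  threshold <- compute_threshold(volume, surfaces, params, stack)
  masks <- if (mask_artifacts) {
    build_artifact_mask(volume, surfaces, stack, threshold,
                        user_mask = user_mask)
  } else if (!is.null(user_mask)) {
    um <- if (is.list(user_mask)) user_mask else rep(list(user_mask), 5)
    stats::setNames(um, paste0("slab", 1:5))
  } else {
    stats::setNames(rep(list(NULL), 5), paste0("slab", 1:5))
  }
  comps <- purrr::map(1:5, function(k) {
    bin <- binarize(stack$images[[k]], threshold, masks[[k]])
    count_particles(bin, params, slab_index = k)
  }) |> dplyr::bind_rows()
  comps <- dplyr::mutate(comps, eye = volume$id, visit = volume$visit,
                         .before = 1)
  counts <- comps |>
    dplyr::count(.data$slab) |>
    tidyr::complete(slab = 1:5, fill = list(n = 0L)) |>
    dplyr::arrange(.data$slab)
  structure(list(components = comps, counts = counts, threshold = threshold,
                 params = params, eye = volume$id, visit = volume$visit),
            class = "ihrf_quant")
}

#' Per-slab IHRF counts of a quantification result
#'
#' @param x An `ihrf_quant` object.
#' @return A tibble with columns `slab` (1-5) and `n`.
#' @export
slab_counts <- function(x) {
  stopifnot(inherits(x, "ihrf_quant"))
  x$counts
}

#' @export
print.ihrf_quant <- function(x, ...) {
  cat(sprintf("<ihrf_quant> %s / %s: %d lesion component(s), threshold %.4f\n",
              x$eye, x$visit, nrow(x$components), x$threshold))
  print(tidyr::pivot_wider(x$counts, names_from = "slab", values_from = "n",
                           names_prefix = "slab"))
  invisible(x)
}
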