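#' Write an OCT volume as a multi-page TIFF
#'
#' One page per B-scan, each a `nz x nx` float image (depth down the rows,
#' 0-based depth increasing posteriorly). Intensities are clamped to
#' `[0, 1]` — the storage range of float TIFF pages.
#'
#' @param volume An `oct_volume`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  spec <- volume$spec
  pages <- purrr::map(seq_len(spec$n_bscans_y), function(y) {
    pmin(pmax(t(volume$data[, y, ]), 0), 1)   # nz x nx
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a multi-page TIFF volume written by [write_volume_tiff()]
#'
#' @param path TIFF file, one `nz x nx` page per B-scan.
#' @param spec Optional [volume_spec()] describing the acquisition; if
#'   omitted, a minimal spec is inferred from the image dimensions.
#' @param id,visit Identity metadata.
#' @return An `oct_volume` (with an empty ground-truth table — truth only
#'   exists for rendered phantoms).
#' @export
read_volume_tiff <- function(path, spec = NULL, id = "eye1",
                             visit = "baseline") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- nrow(pages[[1]]); nx <- ncol(pages[[1]]); ny <- length(pages)
  if (is.null(spec)) {
    spec <- volume_spec(n_ascans_x = nx, n_bscans_y = ny, n_depth_z = nz,
                        ilm_depth = 0, retina_px = max(5, nz - 8))
  }
  stopifnot(spec$n_ascans_x == nx, spec$n_bscans_y == ny,
            spec$n_depth_z == nz)
  data <- array(0, dim = c(nx, ny, nz))
  for (y in seq_len(ny)) data[, y, ] <- t(pages[[y]])
  structure(list(data = data, spec = spec, id = id, visit = visit,
                 truth = tibble(focus = integer(), x = numeric(),
                                y = numeric(), frac_depth = numeric(),
                                slab = integer(), footprint_px = integer())),
            class = "oct_volume")
}

#' Write / read segmentation surfaces as CSV
#'
#' Long format with one row per A-scan column: `x`, `y` (1-based lateral
#' indices) and `ilm_z`, `rpe_z` (0-based voxel depth, increasing from the
#' vitreous towards the RPE).
#'
#' @param surfaces A `surface_pair`.
#' @param path CSV file.
#' @return `write_surfaces_csv()` returns `path` invisibly;
#'   `read_surfaces_csv()` returns a `surface_pair`.
#' @export
write_surfaces_csv <- function(surfaces, path) {
  stopifnot(inherits(surfaces, "surface_pair"))
  nx <- nrow(surfaces$ilm_z); ny <- ncol(surfaces$ilm_z)
  df <- tibble(x = rep(seq_len(nx), ny),
               y = rep(seq_len(ny), each = nx),
               ilm_z = as.vector(surfaces$ilm_z),
               rpe_z = as.vector(surfaces$rpe_z))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_surfaces_csv
#' @export
read_surfaces_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  nx <- max(df$x); ny <- max(df$y)
  df <- dplyr::arrange(df, .data$y, .data$x)
  structure(list(ilm_z = matrix(df$ilm_z, nx, ny),
                 rpe_z = matrix(df$rpe_z, nx, ny)),
            class = "surface_pair")
}

#' Write a slab stack as a five-page TIFF
#'
#' Page k holds slab k's en-face image (outermost slab first), intensities
#' clamped to `[0, 1]`.
#'
#' @param stack A [slab_stack()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_slab_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "slab_stack"))
  pages <- purrr::map(stack$images, function(m) pmin(pmax(t(m), 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}
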