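#' Configure an end-to-end pipeline run
#'
#' Bundles the per-stage parameters for [run_pipeline()]. Stages:
#' `"simulate"` (render a phantom and simulate a cohort), `"slabs"` (en-face
#' stack), `"detect"` (per-eye quantification), `"analyze"` + `"report"`
#' (cohort statistics and the four report tables). When `"simulate"` is
#' disabled, downstream stages read their inputs from the paths given in
#' `inputs` — and their existence is validated before any work starts.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it and it is recorded in every output sidecar.
#' @param stages Character vector of stage names, in any order; executed in
#'   pipeline order.
#' @param phantom List of phantom options: `n_foci`, `speckle_shape`,
#'   `vessels` (count), `drusen` (count), `drusen_bleed_px`.
#' @param volume Named list of [volume_spec()] overrides.
#' @param detection A [detection_params()].
#' @param cohort A [cohort_spec()] (its own seed is replaced by one derived
#'   from `seed`).
#' @param inputs Named list of external input paths (`volume_tiff`,
#'   `surfaces_csv`, `cohort_csv`) used by stages whose producing stage is
#'   disabled.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "slabs", "detect",
                                       "analyze", "report"),
                            phantom = list(),
                            volume = list(),
                            detection = detection_params(),
                            cohort = cohort_spec(),
                            inputs = list()) {
  known <- c("simulate", "slabs", "detect", "analyze", "report")
  if (!all(stages %in% known)) {
    abort(sprintf("unknown stage(s): %s",
                  paste(setdiff(stages, known), collapse = ", ")))
  }
  phantom <- utils::modifyList(
    list(n_foci = 6L, speckle_shape = 0, vessels = 1L, drusen = 0L,
         drusen_bleed_px = 0), phantom)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = intersect(known, stages), phantom = phantom,
                 volume = volume, detection = detection, cohort = cohort,
                 inputs = inputs),
            class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  st <- config$stages
  need <- function(what, path_name) {
    p <- config$inputs[[path_name]]
    if (is.null(p) || !file.exists(p)) {
      abort(sprintf("stage '%s' is enabled without the 'simulate' stage, but inputs$%s is missing or does not exist",
                    what, path_name))
    }
  }
  if (!"simulate" %in% st) {
    if (any(c("slabs", "detect") %in% st)) {
      need(intersect(c("slabs", "detect"), st)[1], "volume_tiff")
      need(intersect(c("slabs", "detect"), st)[1], "surfaces_csv")
    }
    if (any(c("analyze", "report") %in% st)) {
      need(intersect(c("analyze", "report"), st)[1], "cohort_csv")
    }
  }
  invisible(config)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

write_sidecar <- function(path, config, extra = list()) {
  side <- c(list(file = basename(path), seed = config$seed,
                 config_md5 = config_hash(config),
                 package = "ihrfslab",
                 version = as.character(utils::packageVersion("ihrfslab"))),
            extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the simulate-slab-detect-analyze-report pipeline
#'
#' Executes the enabled stages in order, writing every artifact under
#' `config$out_dir` together with a JSON provenance sidecar (seed, config
#' hash, package version). Deterministic stages reproduce byte-identical CSV
#' outputs when re-run with the same configuration. Configuration problems
#' (e.g. a missing input file for an enabled stage) fail before any work is
#' done.
#'
#' @param config A [pipeline_config()].
#' @return A list with `status` (0 on success) and `manifest`, a tibble of
#'   every written file with its MD5 checksum (also written to
#'   `manifest.csv`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  written <- character(0)
  emit <- function(path, extra = list()) {
    write_sidecar(path, config, extra)
    written <<- c(written, path, paste0(path, ".json"))
  }
  path <- function(...) file.path(config$out_dir, ...)

  volume <- NULL; surfaces <- NULL; cohort <- NULL

  if ("simulate" %in% st) {
    ph <- config$phantom
    vs <- do.call(volume_spec, utils::modifyList(
      list(seed = sub_seed(config$seed, 1L),
           speckle_shape = ph$speckle_shape), config$volume))
    drusen <- if (ph$drusen > 0) {
      with_local_seed(sub_seed(config$seed, 2L), {
        purrr::map(seq_len(ph$drusen), function(i) {
          drusen_spec(x = runif(1, 15, vs$n_ascans_x - 15),
                      y = runif(1, 8, vs$n_bscans_y - 8),
                      radius_px = 9, height_px = 10,
                      bleed_px = ph$drusen_bleed_px)
        })
      })
    } else list()
    surfaces <- generate_surfaces(vs, drusen)
    foci <- if (ph$n_foci > 0) {
      sample_foci(vs, ph$n_foci, seed = sub_seed(config$seed, 3L))
    } else list()
    vessels <- if (ph$vessels > 0) {
      with_local_seed(sub_seed(config$seed, 4L), {
        purrr::map(seq_len(ph$vessels), function(i) {
          c(round(runif(1, 5, vs$n_ascans_x - 5)),
            round(runif(1, 3, vs$n_bscans_y - 3)))
        })
      })
    } else list()
    volume <- render_volume(vs, surfaces, foci = foci, vessels = vessels,
                            drusen = drusen, id = "sim_eye1")
    emit(write_volume_tiff(volume, path("volume.tif")))
    emit(write_surfaces_csv(surfaces, path("surfaces.csv")))
    readr::write_csv(volume$truth, path("truth.csv"))
    emit(path("truth.csv"))
    cs <- config$cohort
    cs$seed <- sub_seed(config$seed, 5L)
    cohort <- simulate_cohort(cs)
    readr::write_csv(cohort, path("cohort.csv"))
    emit(path("cohort.csv"))
  }

  if (any(c("slabs", "detect") %in% st) && is.null(volume)) {
    volume <- read_volume_tiff(config$inputs$volume_tiff)
    surfaces <- read_surfaces_csv(config$inputs$surfaces_csv)
  }

  if ("slabs" %in% st) {
    stack <- slab_stack(volume, surfaces)
    emit(write_slab_stack_tiff(stack, path("slab_stack.tif")))
  }

  if ("detect" %in% st) {
    q <- quantify_eye(volume, surfaces, config$detection)
    readr::write_csv(q$components, path("ihrf_components.csv"))
    emit(path("ihrf_components.csv"),
         extra = list(threshold = q$threshold,
                      params = unclass(config$detection)))
    readr::write_csv(q$counts, path("ihrf_counts.csv"))
    emit(path("ihrf_counts.csv"))
  }

  if (any(c("analyze", "report") %in% st)) {
    if (is.null(cohort)) {
      cohort <- readr::read_csv(config$inputs$cohort_csv,
                                show_col_types = FALSE)
    }
    report <- build_report(cohort)
    paths <- write_report(report, config$out_dir)
    for (p in paths) emit(p)
  }

  manifest <- tibble(file = basename(written),
                     md5 = unname(tools::md5sum(written)))
  readr::write_csv(manifest, path("manifest.csv"))
  list(status = 0L, manifest = manifest)
}

#' Write the bundled test fixtures
#'
#' Generates the canonical small phantoms used throughout the test suite and
#' documentation:
#' * `fig_style/`: a noise-free phantom with three separated foci, all in
#'   slab 2 (ground-truth counts 0, 3, 0, 0, 0);
#' * `straddle/`: one focus centered exactly on the slab 1/2 boundary
#'   (fractional depth 0.8), counted once in each slab;
#' * `confounder/`: no foci, one vessel and one druse with apex bleed — every
#'   detection after artifact masking is a false positive;
#' * `cohort.csv`: a 200-eye simulated cohort.
#'
#' @param dir Output directory.
#' @param seed Master seed.
#' @return A tibble manifest of the written files with MD5 checksums.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  save_phantom <- function(name, volume, surfaces) {
    d <- file.path(dir, name)
    dir.create(d, showWarnings = FALSE)
    write_volume_tiff(volume, file.path(d, "volume.tif"))
    write_surfaces_csv(surfaces, file.path(d, "surfaces.csv"))
    readr::write_csv(volume$truth, file.path(d, "truth.csv"))
    written <<- c(written, file.path(d, c("volume.tif", "surfaces.csv",
                                          "truth.csv")))
  }
  vs <- volume_spec(n_ascans_x = 64L, n_bscans_y = 16L, n_depth_z = 160L,
                    ilm_depth = 20, retina_px = 100,
                    seed = sub_seed(seed, 1L))

  surf <- generate_surfaces(vs)
  fig <- render_volume(vs, surf, foci = list(
    focus_spec(16, 5, 0.70), focus_spec(32, 8, 0.65),
    focus_spec(48, 12, 0.75)), id = "fig_style")
  save_phantom("fig_style", fig, surf)

  straddle <- render_volume(vs, surf, foci = list(focus_spec(32, 8, 0.8)),
                            id = "straddle")
  save_phantom("straddle", straddle, surf)

  dr <- drusen_spec(44, 8, radius_px = 9, height_px = 12, bleed_px = 1.5)
  surf_c <- generate_surfaces(vs, list(dr))
  conf <- render_volume(vs, surf_c, vessels = list(c(16, 8)),
                        drusen = list(dr), id = "confounder")
  save_phantom("confounder", conf, surf_c)

  cs <- cohort_spec(n_eyes = 200L, seed = sub_seed(seed, 2L))
  readr::write_csv(simulate_cohort(cs), file.path(dir, "cohort.csv"))
  written <- c(written, file.path(dir, "cohort.csv"))

  tibble(file = written, md5 = unname(tools::md5sum(written)))
}
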