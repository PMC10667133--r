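test_that("flat surfaces give constant thickness and drusen thin the retina", {
  spec <- tiny_spec()
  surf <- generate_surfaces(spec)
  thick <- surf$rpe_z - surf$ilm_z
  expect_true(all(thick == spec$retina_px))

  d <- drusen_spec(32, 8, radius_px = 10, height_px = 10)
  surf_d <- generate_surfaces(spec, list(d))
  thick_d <- surf_d$rpe_z - surf_d$ilm_z
  expect_equal(min(thick_d), spec$retina_px - 10)
  expect_equal(which(thick_d == min(thick_d), arr.ind = TRUE)[1, ],
               c(row = 32, col = 8))
  expect_true(all(surf_d$rpe_z > surf_d$ilm_z))
})

test_that("overlapping drusen combine by pointwise maximum elevation", {
  spec <- tiny_spec()
  d1 <- drusen_spec(30, 8, radius_px = 12, height_px = 10)
  d2 <- drusen_spec(38, 8, radius_px = 12, height_px = 6)
  both <- generate_surfaces(spec, list(d1, d2))
  # brute-force pointwise comparison against each single-druse surface
  e1 <- generate_surfaces(spec, list(d1))$rpe_z
  e2 <- generate_surfaces(spec, list(d2))$rpe_z
  expect_equal(both$rpe_z, pmin(e1, e2))
})

test_that("drusen outside the lateral field are rejected with a message", {
  spec <- tiny_spec()
  expect_error(generate_surfaces(spec, list(drusen_spec(999, 8, 5, 5))),
               "outside the.*field")
  expect_error(generate_surfaces(spec, list(drusen_spec(32, 8, 5, 200))),
               "height")
})

test_that("a noise-free focus-free phantom contains only the band intensities", {
  spec <- tiny_spec()
  surf <- generate_surfaces(spec)
  vol <- render_volume(spec, surf)
  vals <- sort(unique(as.vector(vol$data)))
  allowed <- sort(unique(c(0, spec$layer_reflectivities,
                           spec$rpe_reflectivity)))
  expect_true(all(vals %in% allowed))
  expect_true(spec$rpe_reflectivity %in% vals)
})

test_that("truth table assigns slab indices by fractional depth", {
  spec <- tiny_spec()
  surf <- generate_surfaces(spec)
  v <- render_volume(spec, surf, foci = list(focus_spec(32, 8, 0.9)))
  expect_equal(unique(v$truth$slab), 1L)

  # exactly on the slab 1/2 boundary: straddles, one row per adjacent slab
  v2 <- render_volume(spec, surf, foci = list(focus_spec(32, 8, 0.8)))
  expect_setequal(v2$truth$slab, c(1L, 2L))
  expect_equal(nrow(truth_counts(v2) |> dplyr::filter(n_true > 0)), 2)
})

test_that("invalid foci are rejected", {
  spec <- tiny_spec()
  surf <- generate_surfaces(spec)
  expect_error(focus_spec(32, 8, 1.2), "frac_depth")
  expect_error(render_volume(spec, surf,
                             foci = list(focus_spec(32, 8, 0.5,
                                                    intensity = 0.5))),
               "RPE reflectivity")
  expect_error(render_volume(spec, surf, foci = list(focus_spec(999, 8, 0.5))),
               "outside the lateral field")
})

test_that("rendering is deterministic under a fixed seed", {
  spec <- tiny_spec(speckle_shape = 20, seed = 99L)
  surf <- generate_surfaces(spec)
  foci <- list(focus_spec(20, 5, 0.7), focus_spec(45, 11, 0.3))
  v1 <- render_volume(spec, surf, foci = foci)
  v2 <- render_volume(spec, surf, foci = foci)
  expect_identical(v1$data, v2$data)
  expect_identical(v1$truth, v2$truth)
})

test_that("truth slab indices agree with the slab geometry on the volume", {
  # cross-module consistency: a focus' truth slabs are exactly the slabs in
  # whose en-face image its suprathreshold footprint appears
  spec <- tiny_spec()
  surf <- generate_surfaces(spec)
  for (seed in 1:5) {
    ph <- random_phantom(spec, 4, seed = seed)
    q <- quantify_eye(ph$volume, ph$surfaces)
    expect_equal(slab_counts(q)$n, truth_counts(ph$volume)$n_true)
  }
})

test_that("cohort simulator hits the base rate under a null model", {
  spec <- cohort_spec(n_eyes = 2000L, base_rate = 0.3,
                      beta_per_slab = rep(0, 5), seed = 11L)
  co <- simulate_cohort(spec)
  expect_equal(nrow(co), 2000)
  # binomial error at n = 2000: 3 sd ~ 0.031
  expect_lt(abs(mean(co$progressed) - 0.3), 0.035)
  expect_true(all(co$followup_slab1 >= co$baseline_slab1))
  expect_true(all(co$baseline_slab5 == 0L))
})

test_that("cohort simulation is reproducible under a fixed seed", {
  s <- cohort_spec(n_eyes = 150L, seed = 7L)
  expect_identical(simulate_cohort(s), simulate_cohort(s))
})

test_that("a binary predictor's empirical OR converges to exp(beta)", {
  # simulate with a strong slab-1 effect and a 0/1 count distribution,
  # then compare the contingency-table OR with the generative truth
  beta <- log(2.5)
  spec <- cohort_spec(n_eyes = 5000L, base_rate = 0.25,
                      beta_per_slab = c(beta, 0, 0, 0, 0),
                      baseline_mean = c(0.7, 0, 0, 0, 0),
                      followup_mean = c(1.4, 0, 0, 0, 0), seed = 21L)
  co <- simulate_cohort(spec)
  x <- as.integer(co$baseline_slab1 > 0)   # note: 0/1/2... counts; binarize
  co1 <- dplyr::filter(co, .data$baseline_slab1 <= 1)  # keep a 2-level predictor
  tab <- table(co1$baseline_slab1, co1$progressed)
  emp_or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_lt(abs(emp_or - exp(beta)) / exp(beta), 0.15)
})

test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(base_rate = 1.5), "base_rate")
  expect_error(cohort_spec(baseline_mean = c(1, 1, 1, 1, 1)), "slab-5")
  expect_error(cohort_spec(followup_mean = c(0.5, 1, 0.5, 0, 0)), ">=")
})
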