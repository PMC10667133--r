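test_that("rpe_fraction threshold is the scaled median of the RPE sample", {
  spec <- tiny_spec(rpe_reflectivity = 0.8,
                    layer_reflectivities = c(0.3, 0.14, 0.24, 0.1, 0.28))
  surf <- generate_surfaces(spec)
  vol <- render_volume(spec, surf)
  p1 <- detection_params(threshold_value = 1.0)
  expect_equal(compute_threshold(vol, surf, p1), 0.8)
  p2 <- detection_params(threshold_value = 0.9)
  expect_equal(compute_threshold(vol, surf, p2), 0.72)
})

test_that("the median RPE sample is robust to speckle", {
  # Monte-Carlo: at shape >= 20 the threshold stays within 10% of its
  # noise-free value
  surf <- generate_surfaces(tiny_spec())
  clean <- compute_threshold(render_volume(tiny_spec(), surf), surf,
                             detection_params())
  for (seed in 1:5) {
    spec <- tiny_spec(speckle_shape = 20, seed = seed)
    thr <- compute_threshold(render_volume(spec, surf), surf,
                             detection_params())
    expect_lt(abs(thr - clean) / clean, 0.10)
  }
})

test_that("degenerate RPE samples error", {
  spec <- tiny_spec()
  surf <- generate_surfaces(spec)
  vol <- render_volume(spec, surf)
  vol$data[] <- 0
  expect_error(compute_threshold(vol, surf, detection_params()),
               "degenerate RPE sample")
})

test_that("binarize applies threshold and exclusion mask", {
  img <- matrix(c(0.1, 0.8, 0.9, 0.2), 2, 2)  # [[0.1, 0.9], [0.8, 0.2]] row-wise
  expect_equal(binarize(img, 0.75),
               matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  allmask <- matrix(TRUE, 2, 2)
  expect_false(any(binarize(img, 0.75, allmask)))
  somemask <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(binarize(img, 0, somemask), !somemask)
  expect_error(binarize(img, Inf), "finite")
  expect_error(binarize(img, 0.5, matrix(TRUE, 3, 3)), "dimensions")
})

test_that("component labeling matches the flood-fill oracle", {
  set.seed(5)
  for (i in 1:50) {
    b <- matrix(runif(32 * 32) < runif(1, 0.1, 0.6), 32, 32)
    for (conn in c(4L, 8L)) {
      lab <- label_components(b, conn)
      expect_equal(max(lab), flood_fill_count(b, conn)$n)
    }
  }
})

test_that("particle counting filters by area and respects connectivity", {
  # two 8-connected blobs of areas 4 and 2; min area 3 keeps one
  b <- matrix(FALSE, 8, 8)
  b[2:3, 2:3] <- TRUE          # area 4
  b[6, 6:7] <- TRUE            # area 2
  res <- count_particles(b, detection_params(min_area_px = 3))
  expect_equal(nrow(res), 1)
  expect_equal(res$area_px, 4L)

  # diagonal touching: one component under 8-connectivity, two under 4
  d <- matrix(FALSE, 3, 3)
  d[1, 1] <- d[2, 2] <- TRUE
  expect_equal(max(label_components(d, 8L)), 1L)
  expect_equal(max(label_components(d, 4L)), 2L)
})

test_that("three separated mid-retina foci yield counts (0, 3, 0, 0, 0)", {
  spec <- tiny_spec()
  surf <- generate_surfaces(spec)
  vol <- render_volume(spec, surf, foci = list(
    focus_spec(16, 5, 0.70), focus_spec(32, 8, 0.65),
    focus_spec(48, 12, 0.75)))
  counts <- slab_counts(quantify_eye(vol, surf))
  expect_equal(counts$n, c(0L, 3L, 0L, 0L, 0L))
})

test_that("the vessel mask removes shadowed inner-band spots from slabs 4-5", {
  spec <- tiny_spec()
  surf <- generate_surfaces(spec)
  vol <- render_volume(spec, surf, vessels = list(c(32, 8)))
  masked <- slab_counts(quantify_eye(vol, surf, mask_artifacts = TRUE))
  unmasked <- slab_counts(quantify_eye(vol, surf, mask_artifacts = FALSE))
  expect_equal(sum(masked$n), 0L)
  expect_gt(unmasked$n[unmasked$slab == 5], 0L)
})

test_that("the RPE-bleed mask clears drusen bleed-through from slab 1", {
  spec <- tiny_spec()
  d <- drusen_spec(32, 8, radius_px = 9, height_px = 12, bleed_px = 1.5)
  surf <- generate_surfaces(spec, list(d))
  vol <- render_volume(spec, surf, drusen = list(d))
  masked <- slab_counts(quantify_eye(vol, surf, mask_artifacts = TRUE))
  unmasked <- slab_counts(quantify_eye(vol, surf, mask_artifacts = FALSE))
  expect_equal(masked$n[masked$slab == 1], 0L)
  expect_gt(unmasked$n[unmasked$slab == 1], 0L)
})

test_that("with no confounders the artifact mask changes nothing", {
  spec <- tiny_spec()
  ph <- random_phantom(spec, 4, seed = 31)
  on_ <- slab_counts(quantify_eye(ph$volume, ph$surfaces,
                                  mask_artifacts = TRUE))
  off <- slab_counts(quantify_eye(ph$volume, ph$surfaces,
                                  mask_artifacts = FALSE))
  expect_equal(on_, off)
})

test_that("quantify_eye composes the full per-eye protocol", {
  spec <- tiny_spec()
  surf <- generate_surfaces(spec)
  vol <- render_volume(spec, surf, foci = list(
    focus_spec(16, 5, 0.92), focus_spec(48, 12, 0.88),
    focus_spec(32, 8, 0.5)))
  expect_equal(slab_counts(quantify_eye(vol, surf))$n, c(2L, 0L, 1L, 0L, 0L))

  # boundary straddle: one physical lesion, total count 2
  vs <- render_volume(spec, surf, foci = list(focus_spec(32, 8, 0.8)))
  cs <- slab_counts(quantify_eye(vs, surf))
  expect_equal(sum(cs$n), 2L)
  expect_equal(cs$n[cs$slab %in% 1:2], c(1L, 1L))

  # null input
  empty <- render_volume(spec, surf)
  expect_equal(sum(slab_counts(quantify_eye(empty, surf))$n), 0L)
})

test_that("raising the threshold or the area filter is monotone in counts", {
  spec <- tiny_spec()
  ph <- random_phantom(spec, 5, seed = 13)
  thresholds <- seq(0.4, 1.0, by = 0.1)
  counts <- sapply(thresholds, function(tv) {
    p <- detection_params(threshold_mode = "absolute", threshold_value = tv)
    slab_counts(quantify_eye(ph$volume, ph$surfaces, p))$n
  })
  expect_true(all(diff(t(counts)) <= 0))   # never increases with threshold

  areas <- c(1L, 3L, 5L, 9L)
  counts_a <- sapply(areas, function(a) {
    p <- detection_params(min_area_px = a)
    sum(slab_counts(quantify_eye(ph$volume, ph$surfaces, p))$n)
  })
  expect_true(all(diff(counts_a) <= 0))    # never increases with min area
})

test_that("slab-5 emptiness is data, not a rule: shallow foci are detected", {
  spec <- tiny_spec()
  surf <- generate_surfaces(spec)
  vol <- render_volume(spec, surf, foci = list(focus_spec(32, 8, 0.1)))
  counts <- slab_counts(quantify_eye(vol, surf))
  expect_equal(counts$n[counts$slab == 5], 1L)
})

test_that("noise-free random phantoms are recovered exactly", {
  spec <- tiny_spec()
  for (seed in 1:20) {
    ph <- random_phantom(spec, (seed %% 5) + 2, seed = 100 + seed)
    q <- quantify_eye(ph$volume, ph$surfaces)
    expect_equal(slab_counts(q)$n, truth_counts(ph$volume)$n_true)
  }
})
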