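# Brute-force flood-fill component counter: seeds a BFS at every unvisited
# foreground pixel and explores its neighborhood with an explicit stack.
# Deliberately naive and independent of the package's label-propagation
# implementation.
flood_fill_count <- function(binary, connectivity = 8L) {
  nr <- nrow(binary); nc <- ncol(binary)
  seen <- matrix(FALSE, nr, nc)
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L) {
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  n_comp <- 0L
  sizes <- integer(0)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!binary[i, j] || seen[i, j]) next
    n_comp <- n_comp + 1L
    size <- 0L
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (o in offs) {
        q <- p + o
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            binary[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(n = n_comp, sizes = sizes)
}

# Component count after the minimum-area filter, by the brute-force oracle.
flood_fill_filtered <- function(binary, connectivity = 8L, min_area = 1L) {
  sum(flood_fill_count(binary, connectivity)$sizes >= min_area)
}

# Build a cohort table realizing given 2x2 cell counts for slab-1 presence:
# exposed (count 1): a progressed / b not; unexposed (count 0): c / d.
cohort_from_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  tibble::tibble(
    eye = seq_len(n),
    baseline_slab1 = rep(c(1L, 1L, 0L, 0L), c(a, b, c, d)),
    baseline_slab2 = 0L, baseline_slab3 = 0L, baseline_slab4 = 0L,
    baseline_slab5 = 0L,
    followup_slab1 = rep(c(1L, 1L, 0L, 0L), c(a, b, c, d)),
    followup_slab2 = 0L, followup_slab3 = 0L, followup_slab4 = 0L,
    followup_slab5 = 0L,
    progressed = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d)))
}

# Small phantom grid used by most detection tests (renders in ~0.1 s).
tiny_spec <- function(...) {
  volume_spec(n_ascans_x = 64L, n_bscans_y = 16L, n_depth_z = 160L,
              ilm_depth = 20, retina_px = 100, ...)
}

# Render a phantom with n random interior foci and return volume + surfaces.
# Margins/separation sized for the 64x16 tiny grid: footprints (radius 2.5)
# stay >= 3 px apart, so components never merge.
random_phantom <- function(spec, n_foci, seed, slabs = 1:4) {
  surf <- generate_surfaces(spec)
  foci <- sample_foci(spec, n_foci, slabs = slabs, seed = seed,
                      margin = 4, min_sep = 8)
  list(volume = render_volume(spec, surf, foci = foci),
       surfaces = surf, foci = foci)
}
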