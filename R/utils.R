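#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map2 pmap imap list_rbind
#' @importFrom stats median quantile rgamma rpois rbinom runif plogis qlogis
#'   glm binomial coef vcov pnorm pt qnorm sd var glm.control t.test runmed
NULL

# Round half away from zero at `digits` decimals (the convention used for
# printed means and percentages; base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards. `seed = NULL` leaves the RNG alone.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derive a reproducible per-unit sub-seed from a master seed and a counter,
# keeping the result inside the 32-bit integer range.
sub_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 48271 + as.numeric(counter) * 7919) %%
               2147483629)
}

check_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lo), format(hi)))
  }
  invisible(x)
}
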