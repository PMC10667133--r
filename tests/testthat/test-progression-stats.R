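test_that("paired count test matches the closed form and t.test", {
  df <- tibble::tibble(b = c(0, 2, 4), f = c(1, 4, 5))
  res <- paired_count_test(df, b, f)
  # differences (f - b) = (1, 2, 1): mean 4/3, sd 1/sqrt(3), t = 4, df = 2
  expect_equal(res$t, 4.0)
  expect_equal(res$df, 2L)
  ref <- t.test(df$f, df$b, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$baseline_total, 6)
  expect_equal(res$followup_total, 10)
})

test_that("degenerate paired inputs are handled by status, not bogus numbers", {
  same <- tibble::tibble(b = c(1, 3, 5, 2), f = c(1, 3, 5, 2))
  res <- paired_count_test(same, b, f)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  shifted <- tibble::tibble(b = c(1, 3, 5), f = c(3, 5, 7))
  res2 <- paired_count_test(shifted, b, f)
  expect_equal(res2$status, "degenerate")
  expect_true(is.na(res2$p_value))
  expect_error(paired_count_test(tibble::tibble(b = 1:2, f = 2:3), b, f),
               "at least 3")
})

test_that("single-binary-predictor logistic OR equals the cross-product ratio", {
  co <- cohort_from_2x2(6, 4, 2, 8)
  res <- tidy(logistic_univariate(co, 1, coding = "categorical"))
  expect_equal(res$or, (6 * 8) / (4 * 2), tolerance = 1e-6)  # = 6.0
  expect_equal(res$status, "ok")
  expect_true(res$ci_lo < res$or && res$or < res$ci_hi)
})

test_that("predictors without contrast or with separation are inestimable", {
  co <- cohort_from_2x2(6, 4, 2, 8)
  co$baseline_slab1 <- 1L                      # all eyes exposed
  res <- tidy(logistic_univariate(co, 1, coding = "categorical"))
  expect_equal(res$status, "inestimable")
  # complete separation: exposure perfectly predicts progression
  co2 <- cohort_from_2x2(10, 0, 0, 10)
  res2 <- tidy(logistic_univariate(co2, 1, coding = "categorical"))
  expect_equal(res2$status, "inestimable")
})

test_that("a multivariate fit with a single predictor equals the univariate", {
  co <- simulate_cohort(cohort_spec(n_eyes = 400L, seed = 17L))
  uni <- tidy(logistic_univariate(co, 1))
  multi <- tidy(logistic_multivariate(co, slabs = 1))
  expect_equal(multi$or, uni$or, tolerance = 1e-8)
  expect_equal(multi$ci_lo, uni$ci_lo, tolerance = 1e-8)
  expect_equal(multi$p_value, uni$p_value, tolerance = 1e-8)
})

test_that("collinear duplicate predictors are flagged, others reported", {
  co <- simulate_cohort(cohort_spec(n_eyes = 400L, seed = 19L))
  co$baseline_slab3 <- co$baseline_slab1       # exact duplicate
  res <- tidy(logistic_multivariate(co, slabs = c(1, 3)))
  expect_setequal(res$status, c("ok", "inestimable"))
  expect_equal(res$status[res$term == "slab3"], "inestimable")
})

test_that("an orthogonal null predictor has adjusted OR near 1 at large n", {
  spec <- cohort_spec(n_eyes = 5000L,
                      beta_per_slab = c(log(2), 0, 0, 0, 0),
                      baseline_mean = c(1, 1.5, 1, 0.2, 0),
                      followup_mean = c(2, 2, 1.5, 0.4, 0), seed = 23L)
  co <- simulate_cohort(spec)
  res <- tidy(logistic_multivariate(co, slabs = 1:2))
  expect_lt(abs(res$or[res$term == "slab2"] - 1), 0.1)
  expect_lt(abs(res$or[res$term == "slab1"] - 2) / 2, 0.15)
})

test_that("Wald p-values are approximately uniform under the null", {
  spec0 <- cohort_spec(beta_per_slab = rep(0, 5))
  ps <- vapply(1:400, function(i) {
    s <- spec0; s$n_eyes <- 120L; s$seed <- 5000L + i
    co <- simulate_cohort(s)
    tidy(logistic_univariate(co, 2))$p_value
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  # discrete count predictors can tie p-values; the KS exactness warning is
  # immaterial at this alpha
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("kappa reproduces hand-computed and boundary cases", {
  ratings <- tibble::tibble(a = rep(c("p", "a"), c(7, 3)),
                            b = rep(c("p", "a"), c(7, 3)))
  expect_equal(intergrader_agreement(ratings, a, b)$kappa, 1)

  # [[20, 5], [10, 15]]: po = 0.7, pe = 0.5 -> kappa = 0.4
  tab <- matrix(c(20, 10, 5, 15), 2, 2)
  res <- kappa_from_table(tab)
  expect_equal(res$kappa, 0.4)
  expect_true(res$ci_lo < 0.4 && res$ci_hi > 0.4)

  one_cat <- tibble::tibble(a = rep("p", 10), b = rep("p", 10))
  expect_equal(intergrader_agreement(one_cat, a, b)$status, "undefined")
})

test_that("kappa agrees with an independent implementation and nulls out", {
  skip_if_not_installed("e1071")
  set.seed(8)
  a <- sample(c("x", "y", "z"), 500, replace = TRUE)
  b <- sample(c("x", "y", "z"), 500, replace = TRUE)
  res <- intergrader_agreement(tibble::tibble(a, b), a, b)
  expect_lt(abs(res$kappa), 0.1)            # independent raters -> ~0
  ref <- e1071::classAgreement(table(a, b))$kappa
  expect_equal(res$kappa, ref, tolerance = 1e-10)
})

test_that("profile-likelihood intervals are available and sane", {
  co <- simulate_cohort(cohort_spec(n_eyes = 300L, seed = 29L))
  wald <- tidy(logistic_univariate(co, 1))
  prof <- tidy(logistic_univariate(co, 1, ci_method = "profile"))
  expect_equal(prof$or, wald$or)
  expect_true(prof$ci_lo < prof$or && prof$or < prof$ci_hi)
  expect_lt(abs(log(prof$ci_lo) - log(wald$ci_lo)), 0.2)
})
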