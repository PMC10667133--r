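#' Paired comparison of lesion counts between visits
#'
#' Two-sided paired t-test on per-eye counts, with the visit summary
#' (total, mean, SD per visit) alongside. The difference is taken as
#' `follow-up - baseline`, so a positive t statistic means counts increased.
#'
#' Degenerate inputs are flagged rather than mis-reported: if every
#' difference is exactly zero the test is the exact null (`t = 0`, `p = 1`);
#' if the differences are constant but non-zero the t statistic is undefined
#' (zero variance) and `status` is `"degenerate"` with no p-value.
#'
#' @param data A data frame with one row per eye.
#' @param baseline,followup Columns (tidy-select) holding the per-eye counts
#'   at each visit.
#' @return A one-row tibble: `n`, `baseline_total`, `baseline_mean`,
#'   `baseline_sd`, `followup_total`, `followup_mean`, `followup_sd`,
#'   `mean_diff`, `t`, `df`, `p_value`, `status`.
#' @export
paired_count_test <- function(data, baseline, followup) {
  b <- dplyr::pull(data, {{ baseline }})
  f <- dplyr::pull(data, {{ followup }})
  if (length(b) != length(f) || length(b) < 3) {
    abort("`baseline` and `followup` must be equal-length with at least 3 eyes")
  }
  d <- f - b
  n <- length(d)
  sdd <- sd(d)
  out <- tibble(n = n,
                baseline_total = sum(b), baseline_mean = mean(b),
                baseline_sd = sd(b),
                followup_total = sum(f), followup_mean = mean(f),
                followup_sd = sd(f),
                mean_diff = mean(d),
                t = NA_real_, df = n - 1L, p_value = NA_real_,
                status = "ok")
  if (sdd == 0) {
    if (all(d == 0)) {
      out$t <- 0; out$p_value <- 1
    } else {
      out$status <- "degenerate"
    }
    return(out)
  }
  out$t <- mean(d) / (sdd / sqrt(n))
  out$p_value <- 2 * pt(-abs(out$t), df = n - 1)
  out
}

# Maximum-likelihood logistic fit with Wald (default) or profile-likelihood
# intervals, returning one result row per requested term. Terms with no
# variation, and fits showing complete/quasi-separation (diverging
# coefficient or exploding standard error), are reported as inestimable —
# never as a spuriously huge odds ratio.
fit_logistic <- function(df, terms, model, coding, conf_level = 0.95,
                         ci_method = c("wald", "profile")) {
  ci_method <- match.arg(ci_method)
  z <- qnorm(1 - (1 - conf_level) / 2)
  na_row <- function(term, status) {
    tibble(term = term, estimate = NA_real_, std_error = NA_real_,
           or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
           p_value = NA_real_, model = model, coding = coding,
           status = status)
  }
  usable <- terms[vapply(terms, function(t) var(df[[t]]) > 0, logical(1))]
  if (length(unique(df$.outcome)) < 2) {
    return(list(results = dplyr::bind_rows(
      purrr::map(terms, na_row, status = "inestimable")), fit = NULL))
  }
  if (!length(usable)) {
    return(list(results = dplyr::bind_rows(
      purrr::map(terms, na_row, status = "inestimable")), fit = NULL))
  }
  fml <- stats::reformulate(usable, response = ".outcome")
  # glm warns when fitted probabilities reach 0/1; that is exactly the
  # separation condition handled below, so the warning is muffled here
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = df,
        control = glm.control(epsilon = 1e-12, maxit = 200)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  prof <- if (ci_method == "profile") {
    suppressMessages(tryCatch(stats::confint(fit, level = conf_level),
                              error = function(e) NULL))
  }
  rows <- purrr::map(terms, function(t) {
    if (!t %in% usable) return(na_row(t, "inestimable"))
    b <- cf[[t]]
    if (is.na(b)) return(na_row(t, "inestimable"))        # rank deficiency
    s <- se[[t]]
    separated <- !fit$converged || abs(b) > 15 || s > 50
    if (separated) return(na_row(t, "inestimable"))
    ci <- if (!is.null(prof)) {
      pr <- if (length(usable) == 1L && is.null(dim(prof))) prof else prof[t, ]
      exp(pr)
    } else {
      exp(c(b - z * s, b + z * s))
    }
    tibble(term = t, estimate = b, std_error = s, or = exp(b),
           ci_lo = ci[1], ci_hi = ci[2],
           p_value = 2 * pnorm(-abs(b / s)),
           model = model, coding = coding, status = "ok")
  })
  list(results = dplyr::bind_rows(rows), fit = fit)
}

# Assemble the predictor column for one slab under the requested type/coding.
slab_predictor <- function(records, slab, type, coding) {
  x <- switch(type,
    baseline = records[[paste0("baseline_slab", slab)]],
    delta = records[[paste0("followup_slab", slab)]] -
      records[[paste0("baseline_slab", slab)]])
  if (coding == "categorical") as.integer(x > 0) else as.numeric(x)
}

new_ihrf_logit <- function(results, fit, n) {
  structure(list(results = results, fit = fit, n = n), class = "ihrf_logit")
}

#' Univariate logistic regression of progression on one slab's lesion load
#'
#' Fits `progressed ~ predictor` by maximum likelihood, where the predictor
#' is the baseline count (or visit-to-visit change) in one slab, either as a
#' continuous count or as categorical presence (any lesion vs none, absence
#' as reference). The odds ratio is `exp(coefficient)` with a Wald
#' `conf_level` interval and p-value; profile-likelihood intervals are
#' available via `ci_method = "profile"`.
#'
#' Predictors with no variation, and fits exhibiting complete or
#' quasi-separation, are reported with `status = "inestimable"` (the analog
#' of an NA entry for a slab with too few or no affected eyes).
#'
#' @param records A cohort tibble (one row per eye) with columns
#'   `baseline_slab1..5`, `followup_slab1..5` and a logical `progressed`
#'   (see [simulate_cohort()]).
#' @param slab Slab index 1-5.
#' @param type `"baseline"` count or `"delta"` (follow-up minus baseline).
#' @param coding `"continuous"` or `"categorical"` (presence vs absence).
#' @param conf_level Confidence level for the interval.
#' @param ci_method `"wald"` (default) or `"profile"`.
#' @return An object of class `ihrf_logit`; `tidy()` gives the result row
#'   (`term`, `or`, `ci_lo`, `ci_hi`, `p_value`, `model`, `coding`,
#'   `status`), `glance()` the fit summary.
#' @export
logistic_univariate <- function(records, slab,
                                type = c("baseline", "delta"),
                                coding = c("continuous", "categorical"),
                                conf_level = 0.95,
                                ci_method = c("wald", "profile")) {
  type <- match.arg(type); coding <- match.arg(coding)
  term <- paste0(if (type == "delta") "delta_slab" else "slab", slab)
  df <- tibble(.outcome = as.integer(records$progressed))
  df[[term]] <- slab_predictor(records, slab, type, coding)
  res <- fit_logistic(df, term, "univariate", coding, conf_level,
                      match.arg(ci_method))
  new_ihrf_logit(res$results, res$fit, nrow(records))
}

#' Multivariate logistic regression over several slabs
#'
#' Joint maximum-likelihood logistic fit of progression on the listed slab
#' predictors (default slabs 1-3, the slabs with enough affected eyes to be
#' estimable), yielding mutually adjusted odds ratios. Predictors that are
#' constant, collinear (rank-deficient) or separated are flagged
#' `"inestimable"` individually; the remaining terms are still reported.
#'
#' @inheritParams logistic_univariate
#' @param slabs Integer vector of slab indices to adjust jointly.
#' @return An `ihrf_logit` with one result row per slab.
#' @export
logistic_multivariate <- function(records, slabs = 1:3,
                                  type = c("baseline", "delta"),
                                  coding = c("continuous", "categorical"),
                                  conf_level = 0.95,
                                  ci_method = c("wald", "profile")) {
  type <- match.arg(type); coding <- match.arg(coding)
  if (nrow(records) <= length(slabs) + 1) {
    abort("need more eyes than predictors to fit the joint model")
  }
  terms <- paste0(if (type == "delta") "delta_slab" else "slab", slabs)
  df <- tibble(.outcome = as.integer(records$progressed))
  for (i in seq_along(slabs)) {
    df[[terms[i]]] <- slab_predictor(records, slabs[i], type, coding)
  }
  # exact duplicates explicitly flagged (glm would silently alias them)
  res <- fit_logistic(df, terms, "multivariate", coding, conf_level,
                      match.arg(ci_method))
  new_ihrf_logit(res$results, res$fit, nrow(records))
}

#' @export
print.ihrf_logit <- function(x, ...) {
  cat(sprintf("<ihrf_logit> %s logistic model, n = %d eye(s)\n",
              x$results$model[1], x$n))
  print(x$results)
  invisible(x)
}

#' Unweighted Cohen's kappa from an agreement table
#'
#' @param tab A square contingency table (raters in rows/columns).
#' @param conf_level Confidence level of the large-sample interval.
#' @return A one-row tibble: `kappa`, `se`, `ci_lo`, `ci_hi`, `po`, `pe`,
#'   `n`, `status`. `status = "undefined"` when both raters used a single
#'   identical category (chance agreement is 1).
#' @export
kappa_from_table <- function(tab, conf_level = 0.95) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) abort("agreement table must be square")
  n <- sum(tab)
  p <- tab / n
  po <- sum(diag(p))
  rowm <- rowSums(p); colm <- colSums(p)
  pe <- sum(rowm * colm)
  if (1 - pe < 1e-12) {
    return(tibble(kappa = NA_real_, se = NA_real_, ci_lo = NA_real_,
                  ci_hi = NA_real_, po = po, pe = pe, n = n,
                  status = "undefined"))
  }
  k <- (po - pe) / (1 - pe)
  # large-sample variance (Fleiss, Cohen & Everitt)
  a <- sum(diag(p) * (1 - (rowm + colm) * (1 - k))^2)
  bmat <- p * outer(colm, rowm, `+`)^2
  diag(bmat) <- 0
  b <- (1 - k)^2 * sum(bmat)
  cterm <- (k - pe * (1 - k))^2
  se <- sqrt(max(0, a + b - cterm) / (n * (1 - pe)^2))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(kappa = k, se = se,
         ci_lo = max(-1, k - z * se), ci_hi = min(1, k + z * se),
         po = po, pe = pe, n = n, status = "ok")
}

#' Inter-grader agreement (unweighted Cohen's kappa)
#'
#' Cross-tabulates two graders' categorical ratings over the union of
#' observed categories and returns the unweighted kappa with its large-sample
#' confidence interval.
#'
#' @param data A data frame with one row per graded item.
#' @param rater_a,rater_b Columns (tidy-select) holding each grader's rating.
#' @param conf_level Confidence level.
#' @return See [kappa_from_table()].
#' @export
intergrader_agreement <- function(data, rater_a, rater_b, conf_level = 0.95) {
  a <- dplyr::pull(data, {{ rater_a }})
  b <- dplyr::pull(data, {{ rater_b }})
  if (length(a) != length(b)) abort("ratings must have equal length")
  lev <- sort(unique(c(a, b)))
  tab <- table(factor(a, levels = lev), factor(b, levels = lev))
  kappa_from_table(tab, conf_level = conf_level)
}
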