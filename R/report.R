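#' Published per-slab IHRF distribution used in worked examples
#'
#' The per-slab lesion totals reported for the motivating iAMD cohort: 52 of
#' 120 eyes carried lesions at baseline and were analysed at baseline and at
#' the 2-year follow-up. These printed totals serve as the reference input
#' for the worked-example arithmetic (overall totals, per-eye means, subgroup
#' fraction) and for the cohort simulator's default intensity.
#'
#' @return A tibble with columns `slab` (1 = outermost), `baseline`,
#'   `followup` (lesion totals over the 52 analysed eyes), carrying
#'   attributes `n_eyes_analyzed` (52) and `n_eyes_cohort` (120).
#' @export
ihrf_study_counts <- function() {
  out <- tibble(slab = 1:5,
                baseline = c(58L, 132L, 49L, 4L, 0L),
                followup = c(194L, 287L, 100L, 23L, 0L))
  attr(out, "n_eyes_analyzed") <- 52L
  attr(out, "n_eyes_cohort") <- 120L
  out
}

#' Worked-example summary of a per-slab count table
#'
#' Computes the headline arithmetic of a lesion-distribution table: overall
#' totals per visit, per-eye means (rounded half-up to 1 decimal, the printed
#' precision), the fold increase, and the percentage of cohort eyes in the
#' analysed (lesion-bearing) subgroup.
#'
#' @param counts A tibble with columns `slab`, `baseline`, `followup`
#'   (per-slab lesion totals), e.g. [ihrf_study_counts()].
#' @param n_eyes_analyzed Number of analysed (lesion-bearing) eyes.
#' @param n_eyes_cohort Total cohort size (optional; enables the subgroup
#'   percentage).
#' @return A one-row tibble: `baseline_total`, `followup_total`,
#'   `baseline_mean_per_eye`, `followup_mean_per_eye`, `fold_increase`,
#'   `pct_eyes_with_ihrf` (NA if `n_eyes_cohort` missing).
#' @export
summarize_counts <- function(counts,
                             n_eyes_analyzed = attr(counts, "n_eyes_analyzed"),
                             n_eyes_cohort = attr(counts, "n_eyes_cohort")) {
  if (is.null(n_eyes_analyzed)) abort("`n_eyes_analyzed` is required")
  bt <- sum(counts$baseline); ft <- sum(counts$followup)
  tibble(baseline_total = bt,
         followup_total = ft,
         baseline_mean_per_eye = round_half_up(bt / n_eyes_analyzed, 1),
         followup_mean_per_eye = round_half_up(ft / n_eyes_analyzed, 1),
         fold_increase = round_half_up(ft / bt, 2),
         pct_eyes_with_ihrf = if (is.null(n_eyes_cohort)) NA_real_ else
           round_half_up(100 * n_eyes_analyzed / n_eyes_cohort, 1))
}

#' Build the full progression report for a cohort
#'
#' Runs the complete statistical stage on a cohort table and assembles the
#' four standard tables:
#'
#' 1. per-slab lesion totals and per-eye mean (SD) at each visit with the
#'    paired-test p-value;
#' 2. univariate and multivariate odds ratios for the baseline counts
#'    (continuous);
#' 3. the same for the visit-to-visit change;
#' 4. univariate and multivariate odds ratios for baseline lesion presence
#'    (categorical).
#'
#' Slabs whose predictor cannot be estimated (no variation, separation) are
#' retained as NA rows, mirroring the convention for slabs with too few
#' affected eyes. Multivariate models adjust over `multi_slabs` only; slabs
#' outside that set get NA adjusted entries.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()] for the column
#'   contract).
#' @param multi_slabs Slabs entering the joint models.
#' @param n_eyes_cohort Optional total cohort size for the subgroup
#'   percentage in the summary.
#' @param conf_level Confidence level for all intervals.
#' @return An object of class `ihrf_report`: list of tibbles `counts_by_slab`,
#'   `baseline_or`, `delta_or`, `presence_or`, one-row `summary`, and `text`
#'   (a character vector, one line each).
#' @export
build_report <- function(cohort, multi_slabs = 1:3, n_eyes_cohort = NULL,
                         conf_level = 0.95) {
  n <- nrow(cohort)

  t1 <- purrr::map(1:5, function(k) {
    paired_count_test(cohort,
                      baseline = !!rlang::sym(paste0("baseline_slab", k)),
                      followup = !!rlang::sym(paste0("followup_slab", k))) |>
      dplyr::mutate(slab = k, .before = 1)
  }) |> dplyr::bind_rows() |>
    dplyr::select("slab", "baseline_total", "baseline_mean", "baseline_sd",
                  "followup_total", "followup_mean", "followup_sd",
                  "t", "p_value", "status")

  or_table <- function(type, coding) {
    uni <- purrr::map(1:5, function(k) {
      generics::tidy(logistic_univariate(cohort, k, type = type,
                                         coding = coding,
                                         conf_level = conf_level))
    }) |> dplyr::bind_rows()
    multi_fit <- logistic_multivariate(cohort, slabs = multi_slabs,
                                       type = type, coding = coding,
                                       conf_level = conf_level)
    multi <- generics::tidy(multi_fit) |>
      dplyr::mutate(slab = multi_slabs)
    uni |>
      dplyr::mutate(slab = 1:5) |>
      dplyr::select("slab", or_uni = "or", ci_lo_uni = "ci_lo",
                    ci_hi_uni = "ci_hi", p_uni = "p_value",
                    status_uni = "status") |>
      dplyr::left_join(dplyr::select(multi, "slab", or_multi = "or",
                                     ci_lo_multi = "ci_lo",
                                     ci_hi_multi = "ci_hi", p_multi = "p_value",
                                     status_multi = "status"),
                       by = "slab") |>
      dplyr::mutate(status_multi = dplyr::coalesce(.data$status_multi,
                                                   "not_in_model"))
  }

  t2 <- or_table("baseline", "continuous")
  t3 <- or_table("delta", "continuous")
  t4 <- or_table("baseline", "categorical")

  counts_in <- tibble(slab = 1:5,
                      baseline = t1$baseline_total,
                      followup = t1$followup_total)
  summary <- summarize_counts(counts_in, n_eyes_analyzed = n,
                              n_eyes_cohort = n_eyes_cohort)

  fmt_or <- function(or, lo, hi, p, status) {
    ifelse(status == "ok",
           sprintf("%.2f (%.2f-%.2f), p=%.3g", round_half_up(or, 2),
                   round_half_up(lo, 2), round_half_up(hi, 2), p),
           "NA")
  }
  text <- c(
    sprintf("IHRF progression report (%d eyes)", n),
    sprintf("Total lesions: %d at baseline, %d at follow-up (x%.2f); mean %.1f -> %.1f per eye",
            summary$baseline_total, summary$followup_total,
            summary$fold_increase, summary$baseline_mean_per_eye,
            summary$followup_mean_per_eye),
    if (!is.null(n_eyes_cohort))
      sprintf("Analysed subgroup: %d of %d cohort eyes (%.1f%%)",
              n, n_eyes_cohort, summary$pct_eyes_with_ihrf),
    "",
    "Per-slab counts (baseline / follow-up, paired p):",
    sprintf("  slab %d: %d / %d, p=%s", t1$slab, t1$baseline_total,
            t1$followup_total,
            ifelse(is.na(t1$p_value), "NA", sprintf("%.3g", t1$p_value))),
    "",
    "Baseline count odds ratios (univariate; multivariate):",
    sprintf("  slab %d: %s; %s", t2$slab,
            fmt_or(t2$or_uni, t2$ci_lo_uni, t2$ci_hi_uni, t2$p_uni,
                   t2$status_uni),
            fmt_or(t2$or_multi, t2$ci_lo_multi, t2$ci_hi_multi, t2$p_multi,
                   t2$status_multi)),
    "",
    "Change (follow-up - baseline) odds ratios (univariate; multivariate):",
    sprintf("  slab %d: %s; %s", t3$slab,
            fmt_or(t3$or_uni, t3$ci_lo_uni, t3$ci_hi_uni, t3$p_uni,
                   t3$status_uni),
            fmt_or(t3$or_multi, t3$ci_lo_multi, t3$ci_hi_multi, t3$p_multi,
                   t3$status_multi)),
    "",
    "Baseline presence odds ratios (univariate; multivariate):",
    sprintf("  slab %d: %s; %s", t4$slab,
            fmt_or(t4$or_uni, t4$ci_lo_uni, t4$ci_hi_uni, t4$p_uni,
                   t4$status_uni),
            fmt_or(t4$or_multi, t4$ci_lo_multi, t4$ci_hi_multi, t4$p_multi,
                   t4$status_multi)))

  structure(list(counts_by_slab = t1, baseline_or = t2, delta_or = t3,
                 presence_or = t4, summary = summary, text = text),
            class = "ihrf_report")
}

#' @export
print.ihrf_report <- function(x, ...) {
  cat(paste(x$text, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a report to disk as CSV tables plus a text rendering
#'
#' @param report An `ihrf_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ihrf_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts_by_slab = file.path(dir, "counts_by_slab.csv"),
    baseline_or = file.path(dir, "baseline_or.csv"),
    delta_or = file.path(dir, "delta_or.csv"),
    presence_or = file.path(dir, "presence_or.csv"),
    summary = file.path(dir, "summary.csv"),
    text = file.path(dir, "report.txt"))
  for (nm in setdiff(names(paths), "text")) {
    readr::write_csv(report[[nm]], paths[[nm]])
  }
  writeLines(report$text, paths[["text"]])
  invisible(paths)
}
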