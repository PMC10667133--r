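#' Plot the five en-face slab images
#'
#' @param object A [slab_stack()].
#' @param ... Unused.
#' @return A ggplot: one raster panel per slab, outermost slab first.
#' @export
autoplot.slab_stack <- function(object, ...) {
  df <- purrr::imap(object$images, function(m, nm) {
    tibble(slab = nm,
           x = rep(seq_len(nrow(m)), ncol(m)),
           y = rep(seq_len(ncol(m)), each = nrow(m)),
           intensity = as.vector(m))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slab, nrow = 1) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("En-face slabs: %s / %s", object$id,
                                  object$visit),
                  x = "A-scan (x)", y = "B-scan (y)")
}

#' Plot per-slab lesion counts of a quantification result
#'
#' @param object An `ihrf_quant`.
#' @param ... Unused.
#' @return A ggplot bar chart of counts by slab.
#' @export
autoplot.ihrf_quant <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(factor(.data$slab), .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "slab (1 = outermost)", y = "IHRF count",
                  title = sprintf("%s / %s", object$eye, object$visit))
}

#' Forest plot of odds ratios from a report table
#'
#' @param or_table One of the odds-ratio tibbles of an [build_report()]
#'   result (`baseline_or`, `delta_or` or `presence_or`).
#' @param title Plot title.
#' @return A ggplot with univariate and multivariate odds ratios and their
#'   confidence intervals per slab, on a log scale; inestimable slabs are
#'   omitted.
#' @export
plot_odds_ratios <- function(or_table, title = "Progression odds ratios") {
  long <- dplyr::bind_rows(
    or_table |>
      dplyr::filter(.data$status_uni == "ok") |>
      dplyr::transmute(slab = .data$slab, model = "univariate",
                       or = .data$or_uni, lo = .data$ci_lo_uni,
                       hi = .data$ci_hi_uni),
    or_table |>
      dplyr::filter(.data$status_multi == "ok") |>
      dplyr::transmute(slab = .data$slab, model = "multivariate",
                       or = .data$or_multi, lo = .data$ci_lo_multi,
                       hi = .data$ci_hi_multi))
  ggplot2::ggplot(long, ggplot2::aes(.data$or, factor(.data$slab),
                                     color = .data$model)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = "slab (1 = outermost)",
                  title = title)
}
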