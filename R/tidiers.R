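#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a logistic regression result
#'
#' @param x An `ihrf_logit`.
#' @param ... Unused.
#' @return One row per term: `term`, `estimate` (log-OR), `std_error`, `or`,
#'   `ci_lo`, `ci_hi`, `p_value`, `model`, `coding`, `status`.
#' @export
tidy.ihrf_logit <- function(x, ...) x$results

#' Fit-level summary of a logistic regression result
#'
#' @param x An `ihrf_logit`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `model`, `converged`, `deviance`,
#'   `null_deviance`, `aic`, `df_residual`.
#' @export
glance.ihrf_logit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(n = x$n, model = x$results$model[1], converged = NA,
                  deviance = NA_real_, null_deviance = NA_real_,
                  aic = NA_real_, df_residual = NA_integer_))
  }
  tibble(n = x$n, model = x$results$model[1], converged = x$fit$converged,
         deviance = x$fit$deviance, null_deviance = x$fit$null.deviance,
         aic = x$fit$aic, df_residual = x$fit$df.residual)
}

#' Tidy a per-eye quantification result
#'
#' @param x An `ihrf_quant`.
#' @param ... Unused.
#' @return The component tibble (one row per detected lesion component).
#' @export
tidy.ihrf_quant <- function(x, ...) x$components
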