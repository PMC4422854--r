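#' Variance of the field-based mean AGB under simple random sampling
#'
#' `sum((y_i - ybar)^2) / (n (n - 1))`, with no finite-population
#' correction.
#'
#' @param y Per-plot field reference AGB (Mg/ha), length >= 2.
#' @return Variance of the mean, (Mg/ha)^2.
#' @export
variance_field <- function(y) {
  n <- length(y)
  if (n < 2) stop("need at least 2 plots")
  sum((y - mean(y))^2) / (n * (n - 1))
}

#' Variance of the model-assisted (GREG) mean AGB estimate
#'
#' With model residuals `e_i = y_i - yhat_i` and their mean `ebar`, the
#' generalized regression estimator's variance is
#' `sum((e_i - ebar)^2) / (n (n - 1))`: residual scatter replaces raw
#' scatter, so a useful model shrinks the variance below the field-based
#' one.
#'
#' @param y Per-plot field reference AGB (Mg/ha).
#' @param y_hat Per-plot model predictions (Mg/ha), same length.
#' @return Variance of the mean, (Mg/ha)^2.
#' @export
variance_greg <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("`y` and `y_hat` lengths differ")
  n <- length(y)
  if (n < 2) stop("need at least 2 plots")
  e <- y - y_hat
  sum((e - mean(e))^2) / (n * (n - 1))
}

#' Relative efficiency of model-assisted over field-based estimation
#'
#' The ratio of the field-based to the model-assisted variance estimate;
#' values above 1 mean the ALS-assisted estimator is the more precise one.
#'
#' @param v_field Field-based (SRS) variance of the mean.
#' @param v_als Model-assisted (GREG) variance of the mean.
#' @return Unitless ratio `v_field / v_als`; `Inf` with a warning when
#'   `v_als` is zero.
#' @export
relative_efficiency <- function(v_field, v_als) {
  if (v_als < 0 || v_field < 0) stop("variances must be >= 0")
  if (v_als == 0) {
    warning("model-assisted variance is zero; relative efficiency infinite")
    return(Inf)
  }
  v_field / v_als
}

#' Standard error as a percentage of the mean
#'
#' @param v Variance of the mean, >= 0.
#' @param mean Mean AGB (Mg/ha), > 0.
#' @return `sqrt(v) / mean * 100` (percent).
#' @export
se_percent <- function(v, mean) {
  if (!is.finite(mean) || mean <= 0) stop("`mean` must be > 0")
  if (any(v < 0)) stop("`v` must be >= 0")
  sqrt(v) / mean * 100
}
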