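#' Relative model residuals of predicted versus field reference AGB
#'
#' For the boundary-effect analysis the residual is taken as prediction
#' minus reference, scaled by the reference:
#' `rel_resid = (yhat - y) / y`. (The accuracy measures RMSE% and MPE% use
#' the opposite subtraction order, `y - yhat`; both conventions are stated
#' where used.) Records with non-positive reference AGB are dropped with a
#' warning.
#'
#' @param field_agb Field reference AGB per plot (Mg/ha).
#' @param predictions Model-predicted AGB per plot (Mg/ha).
#' @return Data frame with columns `rel_resid` and `abs_rel_resid`; rows
#'   with `field_agb <= 0` removed.
#' @export
relative_residuals <- function(field_agb, predictions) {
  stopifnot(length(field_agb) == length(predictions))
  ok <- is.finite(field_agb) & field_agb > 0
  if (!all(ok)) {
    warning(sum(!ok), " record(s) dropped: non-positive field AGB")
  }
  rel <- (predictions[ok] - field_agb[ok]) / field_agb[ok]
  data.frame(rel_resid = rel, abs_rel_resid = abs(rel))
}

#' Mixed-model regression of relative residuals on buffer biomass
#'
#' Fits a random-intercept linear mixed model of the relative residual on a
#' buffer biomass indicator (`sagb_ratio`: total buffer AGB relative to the
#' plot's field AGB, or `magb_ratio`: largest single buffer tree), with plot
#' identity as the grouping factor. Records are pooled across plot sizes, so
#' each plot contributes repeated measures. Estimation is by maximum
#' likelihood so AIC values are comparable between the two fixed-effect
#' structures.
#'
#' @param records Data frame with columns `rel_resid`, `plot_id` and the
#'   chosen predictor; typically pooled output of the pipeline's boundary
#'   stage.
#' @param predictor `"sagb_ratio"` or `"magb_ratio"`.
#' @return Object of class `lme_result`: `intercept`, `slope`, `slope_se`,
#'   `intercept_p`, `slope_p`, `aic`, `random_intercept_sd`, `n_plots`,
#'   `n_records`.
#' @export
fit_buffer_lme <- function(records, predictor = c("sagb_ratio", "magb_ratio")) {
  predictor <- match.arg(predictor)
  stopifnot(all(c("rel_resid", "plot_id", predictor) %in% names(records)))
  n_plots <- length(unique(records$plot_id))
  if (n_plots < 10) stop("need at least 10 plots, got ", n_plots)
  reps <- table(records$plot_id)
  if (max(reps) < 2) stop("need repeated measures (>= 2 plot sizes per plot)")
  dat <- data.frame(rel_resid = records$rel_resid,
                    x = records[[predictor]],
                    plot_id = factor(records$plot_id))
  fit <- tryCatch(
    nlme::lme(rel_resid ~ x, random = ~ 1 | plot_id, data = dat,
              method = "ML"),
    error = function(e) stop("mixed model failed: ", conditionMessage(e))
  )
  tt <- summary(fit)$tTable
  structure(list(
    predictor = predictor,
    intercept = unname(nlme::fixef(fit)[1]),
    slope = unname(nlme::fixef(fit)[2]),
    slope_se = unname(tt[2, "Std.Error"]),
    intercept_p = unname(tt[1, "p-value"]),
    slope_p = unname(tt[2, "p-value"]),
    aic = stats::AIC(fit),
    random_intercept_sd = as.numeric(nlme::VarCorr(fit)["(Intercept)", "StdDev"]),
    n_plots = n_plots,
    n_records = nrow(dat)
  ), class = "lme_result")
}

#' Linear trend of absolute relative residuals against plot size
#'
#' Simple OLS of `abs_rel_resid` on plot size in m². Under boundary effects
#' the expected slope is negative: small plots carry relatively larger
#' model errors.
#'
#' @param records Data frame with columns `abs_rel_resid` and `plot_size`.
#' @return Object of class `size_trend`: `intercept`, `slope` (per m²),
#'   `slope_p`.
#' @export
fit_absres_vs_size <- function(records) {
  stopifnot(all(c("abs_rel_resid", "plot_size") %in% names(records)))
  if (length(unique(records$plot_size)) < 2) {
    stop("need at least 2 distinct plot sizes")
  }
  fit <- stats::lm(abs_rel_resid ~ plot_size, data = records)
  cf <- summary(fit)$coefficients
  structure(list(
    intercept = unname(cf[1, 1]),
    slope = unname(cf[2, 1]),
    slope_p = unname(cf[2, 4])
  ), class = "size_trend")
}
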