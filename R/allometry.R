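#' Predict total tree height from diameter at breast height
#'
#' Gompertz-type diameter-height curve for tropical rain forest,
#' `h = 1.3 + 45.5103 * exp(-2.7163 * exp(-0.0354 * dbh))`.
#' The curve starts just above breast height (1.3 m) and saturates at
#' 46.8103 m for very large diameters.
#'
#' @param dbh Diameter at breast height in cm. Vectorised; must be >= 0.
#' @return Predicted total height in m, same length as `dbh`.
#' @examples
#' predict_height(c(5, 20, 50))
#' @export
predict_height <- function(dbh) {
  if (!is.numeric(dbh) || any(!is.finite(dbh)) || any(dbh < 0)) {
    stop("`dbh` must be finite and non-negative (cm)")
  }
  1.3 + 45.5103 * exp(-2.7163 * exp(-0.0354 * dbh))
}

#' Aboveground biomass of a single tree
#'
#' Allometric power law `AGB = 0.4020 * dbh^1.4365 * h^0.8613`, with
#' diameter in cm and height in m. The result is taken to be kg of dry
#' aboveground biomass per tree; per-hectare scaling to Mg happens in
#' [field_agb_density()].
#'
#' @param dbh Diameter at breast height in cm, >= 0. Vectorised.
#' @param h Total tree height in m, >= 0. Vectorised.
#' @return Aboveground biomass (kg), same length as the inputs.
#' @examples
#' tree_agb(50, predict_height(50))
#' @export
tree_agb <- function(dbh, h) {
  if (!is.numeric(dbh) || any(!is.finite(dbh)) || any(dbh < 0)) {
    stop("`dbh` must be finite and non-negative (cm)")
  }
  if (!is.numeric(h) || any(!is.finite(h)) || any(h < 0)) {
    stop("`h` must be finite and non-negative (m)")
  }
  0.4020 * dbh^1.4365 * h^0.8613
}
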