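#' Build the candidate predictor set from a metrics table
#'
#' Takes a table of per-plot ALS metrics (one row per plot) and returns the
#' model candidate matrix: every metric as-is plus a log-transformed copy of
#' every strictly positive metric (labelled `log.<name>`). Rows containing a
#' non-finite metric are rejected with a warning (these are plots without
#' canopy echoes); constant columns are dropped since they carry no signal.
#'
#' @param metrics Data frame of numeric metric columns, one row per plot.
#' @return Object of class `candidate_set`: list with `names` (labels),
#'   `values` (numeric matrix, rows = retained plots) and `kept` (logical
#'   vector over the input rows).
#' @export
build_candidates <- function(metrics) {
  m <- as.matrix(metrics)
  storage.mode(m) <- "double"
  kept <- apply(is.finite(m), 1, all)
  if (!all(kept)) {
    warning(sum(!kept), " row(s) rejected: non-finite metrics (rows ",
            paste(which(!kept), collapse = ", "), ")")
  }
  m <- m[kept, , drop = FALSE]
  is_const <- apply(m, 2, function(v) max(v) - min(v) == 0)
  m <- m[, !is_const, drop = FALSE]
  pos <- apply(m, 2, function(v) all(v > 0))
  logm <- log(m[, pos, drop = FALSE])
  colnames(logm) <- paste0("log.", colnames(m)[pos])
  values <- cbind(m, logm)
  structure(list(names = colnames(values), values = values, kept = kept),
            class = "candidate_set")
}

#' Fit a log-scale OLS biomass model on a fixed design
#'
#' Ordinary least squares of log(AGB) on the given predictors, returning the
#' quantities the analysis tracks per plot size: coefficients, mean square
#' error `SSE / (n - p - 1)`, adjusted R-squared, per-slope variance
#' inflation factors, BIC (`n log(SSE/n) + (p + 1) log(n)`) and coefficient
#' p-values.
#'
#' @param log_agb Numeric response, log of field AGB (Mg/ha).
#' @param design Data frame or matrix of predictor columns (1 or more).
#' @return Object of class `agb_fit`.
#' @export
fit_model <- function(log_agb, design) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  n <- length(log_agb)
  p <- ncol(X)
  stopifnot(nrow(X) == n, p >= 1)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), log_agb)
  if (fit$rank < p + 1) stop("rank-deficient design")
  sse <- sum(fit$residuals^2)
  mse <- sse / (n - p - 1)
  sst <- sum((log_agb - mean(log_agb))^2)
  adj_r2 <- 1 - (sse / (n - p - 1)) / (sst / (n - 1))
  vif <- if (p == 1) stats::setNames(1, colnames(X)) else {
    diag(solve(stats::cor(X)))
  }
  d <- diag(chol2inv(qr.R(fit$qr)))
  se <- sqrt(mse * d[order(fit$qr$pivot)])
  names(se) <- names(fit$coefficients)
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(abs(tval), df = n - p - 1, lower.tail = FALSE)
  structure(list(
    selected = colnames(X),
    coefficients = fit$coefficients,
    se = se,
    mse = mse,
    adj_r2 = adj_r2,
    vif = vif,
    bic = n * log(sse / n) + (p + 1) * log(n),
    p_values = pval,
    n = n
  ), class = "agb_fit")
}

#' Select the best biomass model by exhaustive subset search
#'
#' Enumerates every subset of 1 to `max_terms` candidate predictors, fits
#' each by OLS on the log-scale response, discards subsets whose variance
#' inflation factors reach `vif_limit`, and returns the minimum-BIC
#' survivor. Ties resolve to the smaller subset, then to the
#' lexicographically earlier one (candidate order). The search runs in
#' compiled code on centered cross-products; [fit_model()] refits the winner
#' for the full set of reported statistics.
#'
#' @param log_agb Numeric response, log of field AGB.
#' @param candidates A [build_candidates()] result.
#' @param max_terms Largest subset size considered (default 3).
#' @param vif_limit Subsets with any VIF at or above this are discarded
#'   (default 10).
#' @return An `agb_fit` (see [fit_model()]).
#' @export
select_model <- function(log_agb, candidates, max_terms = 3, vif_limit = 10) {
  stopifnot(inherits(candidates, "candidate_set"))
  X <- candidates$values
  n <- length(log_agb)
  if (nrow(X) != n) stop("response and candidate rows differ")
  if (n <= max_terms + 2) stop("too few observations for selection")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- log_agb - mean(log_agb)
  res <- best_subset_cpp(crossprod(Xc), drop(crossprod(Xc, yc)),
                         sum(yc^2), stats::cor(X), n, as.integer(max_terms),
                         vif_limit)
  if (length(res$indices) == 0) {
    stop("no admissible subset: all ", ncol(X), " candidates (max_terms = ",
         max_terms, ") failed the VIF < ", vif_limit, " screen or were singular")
  }
  sel <- res$indices + 1L
  fit_model(log_agb, X[, sel, drop = FALSE])
}

#' Predict AGB from a fitted log-scale model with bias correction
#'
#' Back-transforms the log-scale linear predictor with the standard
#' correction for log-transformation bias: half the model mean square error
#' is added to the intercept before exponentiation,
#' `exp(b0 + mse/2 + sum(b_k x_k))`.
#'
#' @param fit An `agb_fit`.
#' @param newdata Data frame or matrix containing the selected predictor
#'   columns.
#' @return Predicted AGB in Mg/ha.
#' @export
predict_agb <- function(fit, newdata) {
  stopifnot(inherits(fit, "agb_fit"))
  X <- as.matrix(as.data.frame(newdata)[, fit$selected, drop = FALSE])
  eta <- fit$coefficients[1] + drop(X %*% fit$coefficients[-1])
  exp(eta + fit$mse / 2)
}

#' Leave-one-out cross-validation of a selected biomass model
#'
#' Refits the model coefficients on each n-1 subset and predicts the held
#' out plot with bias-corrected back-transformation. By default the
#' predictor labels stay fixed at the full-data selection and only the
#' coefficients are re-estimated per fold; `refit_selection = TRUE` reruns
#' the subset search inside every fold instead. Accuracy is summarized as
#' `RMSE% = sqrt(sum((y - yhat)^2) / n) / mean(y) * 100` and
#' `MPE% = (sum(y - yhat) / n) / mean(y) * 100` (positive MPE% means
#' under-prediction).
#'
#' @param field_agb Per-plot field reference AGB (Mg/ha, > 0).
#' @param candidates A [build_candidates()] result aligned with `field_agb`.
#' @param selected Character vector of predictor labels (from
#'   [select_model()]).
#' @param refit_selection Rerun subset selection within each fold.
#' @param max_terms,vif_limit Passed to the in-fold selection when
#'   `refit_selection = TRUE`.
#' @return Object of class `cv_result`: list with `rmse_pct`, `mpe_pct` and
#'   `predictions` (Mg/ha).
#' @export
loocv <- function(field_agb, candidates, selected, refit_selection = FALSE,
                  max_terms = 3, vif_limit = 10) {
  stopifnot(inherits(candidates, "candidate_set"))
  n <- length(field_agb)
  if (n < 5) stop("LOOCV needs at least 5 plots")
  if (any(field_agb <= 0)) stop("field AGB must be positive")
  X <- candidates$values
  if (nrow(X) != n) stop("response and candidate rows differ")
  y <- log(field_agb)
  yhat <- numeric(n)
  for (i in seq_len(n)) {
    sub <- structure(list(names = candidates$names,
                          values = X[-i, , drop = FALSE]),
                     class = "candidate_set")
    fit_i <- if (refit_selection) {
      select_model(y[-i], sub, max_terms, vif_limit)
    } else {
      tryCatch(fit_model(y[-i], X[-i, selected, drop = FALSE]),
               error = function(e) stop("fold ", i, ": ", conditionMessage(e)))
    }
    yhat[i] <- predict_agb(fit_i, X[i, , drop = FALSE])
  }
  ybar <- mean(field_agb)
  structure(list(
    rmse_pct = sqrt(mean((field_agb - yhat)^2)) / ybar * 100,
    mpe_pct = mean(field_agb - yhat) / ybar * 100,
    predictions = yhat
  ), class = "cv_result")
}
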