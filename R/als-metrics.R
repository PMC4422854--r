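#' Pool echo classes into "first" and "last" height datasets
#'
#' The area-based convention: `single` and `first_of_many` echoes form the
#' "first" dataset (canopy-surface dominated), `single` and `last_of_many`
#' echoes form the "last" dataset (deeper penetration). Counts are recorded
#' before any height threshold.
#'
#' @param cloud An `echo_cloud`.
#' @return List with numeric vectors `first` and `last` (echo heights, m)
#'   and counts `n_first`, `n_last`.
#' @export
pool_echoes <- function(cloud) {
  stopifnot(inherits(cloud, "echo_cloud"))
  e <- cloud$echoes
  bad <- setdiff(unique(e$echo_class),
                 c("single", "first_of_many", "last_of_many"))
  if (length(bad)) stop("unknown echo_class: ", paste(bad, collapse = ", "))
  first <- e$z[e$echo_class %in% c("single", "first_of_many")]
  last <- e$z[e$echo_class %in% c("single", "last_of_many")]
  list(first = first, last = last,
       n_first = length(first), n_last = length(last))
}

# Canopy threshold (m) separating vegetation echoes from ground features.
CANOPY_THRESHOLD <- 2.0

#' Canopy height percentiles of an echo height distribution
#'
#' Computes the 10th..90th percentiles of the echo heights above the 2.0 m
#' canopy threshold, using the linear-interpolation quantile definition
#' (type 7). When no height exceeds the threshold all percentiles are `NA`
#' (the plot is flagged missing and excluded from modelling downstream).
#'
#' @param heights Numeric vector of pooled first or last echo heights (m).
#' @return Named numeric vector `H10`..`H90`.
#' @export
height_percentiles <- function(heights) {
  canopy <- heights[heights > CANOPY_THRESHOLD]
  p <- seq(0.1, 0.9, by = 0.1)
  out <- if (length(canopy) == 0) rep(NA_real_, 9) else
    unname(stats::quantile(canopy, probs = p, type = 7, names = FALSE))
  names(out) <- paste0("H", seq(10, 90, 10))
  out
}

#' Canopy density metrics of an echo height distribution
#'
#' The vertical range between the lowest canopy height (> 2 m) and the 95th
#' percentile of canopy heights is split into 10 equal fractions. Density
#' `D0` is the proportion of echoes above 2.0 m; `Di` (i = 1..9) the
#' proportion strictly above the i-th fraction threshold
#' `L + i * (U - L) / 10`. The denominator is the total echo count of the
#' class, including echoes at or below 2 m, so `D0` reads as canopy cover.
#'
#' @param heights Pooled (unthresholded) first or last echo heights (m).
#' @param denominator `"all"` (default, total echo count) or `"canopy"`
#'   (echoes above 2 m only).
#' @return Named numeric vector `D0`..`D9`, proportions in `[0, 1]`; all
#'   `NA` when no height exceeds 2 m.
#' @export
canopy_densities <- function(heights, denominator = c("all", "canopy")) {
  denominator <- match.arg(denominator)
  canopy <- heights[heights > CANOPY_THRESHOLD]
  out <- rep(NA_real_, 10)
  names(out) <- paste0("D", 0:9)
  if (length(canopy) == 0) return(out)
  lo <- min(canopy)
  up <- unname(stats::quantile(canopy, 0.95, type = 7, names = FALSE))
  thresholds <- c(CANOPY_THRESHOLD, lo + (1:9) * (up - lo) / 10)
  n_tot <- if (denominator == "all") length(heights) else length(canopy)
  out[] <- vapply(thresholds, function(t) sum(heights > t), 0L) / n_tot
  out
}

#' Summary statistics of canopy echo heights
#'
#' Maximum, mean, sample standard deviation (n-1 denominator), coefficient
#' of variation and moment-coefficient skewness `g1 = m3 / m2^(3/2)` of the
#' echo heights above the 2 m canopy threshold.
#'
#' @param heights Pooled first or last echo heights (m).
#' @return Named numeric vector `Hmax`, `Hmean`, `Hsd`, `Hcv`, `Hskewness`;
#'   spread statistics are `NA` for fewer than two canopy echoes, skewness
#'   is `NA` for a constant sample (0/0).
#' @export
summary_stats <- function(heights) {
  canopy <- heights[heights > CANOPY_THRESHOLD]
  out <- c(Hmax = NA_real_, Hmean = NA_real_, Hsd = NA_real_,
           Hcv = NA_real_, Hskewness = NA_real_)
  n <- length(canopy)
  if (n == 0) return(out)
  out["Hmax"] <- max(canopy)
  out["Hmean"] <- mean(canopy)
  if (n >= 2) {
    out["Hsd"] <- stats::sd(canopy)
    out["Hcv"] <- out["Hsd"] / out["Hmean"]
    m2 <- mean((canopy - out["Hmean"])^2)
    m3 <- mean((canopy - out["Hmean"])^3)
    out["Hskewness"] <- if (m2 > 0) m3 / m2^1.5 else NA_real_
  }
  out
}

#' Full area-based metric vector for one plot
#'
#' Clips the cloud to the plot, pools echo classes, and computes height
#' percentiles, canopy densities and summary statistics for both the first
#' and last echo datasets: metric names carry the `.F` / `.L` suffix
#' (e.g. `H80.F`, `D1.L`, `Hsd.L`). Raw echo counts `n_first` and `n_last`
#' are recorded. Plots with no canopy echoes yield `NA` metrics.
#'
#' @param cloud An `echo_cloud`.
#' @param spec A [plot_spec()].
#' @param denominator Passed to [canopy_densities()].
#' @return One-row data.frame of 48 metrics plus `n_first`, `n_last`.
#' @export
metrics_for_plot <- function(cloud, spec, denominator = "all") {
  clipped <- echoes_in_plot(cloud, spec)
  pooled <- pool_echoes(clipped)
  one <- function(h, suf) {
    v <- c(height_percentiles(h), canopy_densities(h, denominator),
           summary_stats(h))
    names(v) <- paste0(names(v), suf)
    v
  }
  v <- c(one(pooled$first, ".F"), one(pooled$last, ".L"))
  out <- as.data.frame(as.list(v), check.names = FALSE)
  out$n_first <- pooled$n_first
  out$n_last <- pooled$n_last
  out
}
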