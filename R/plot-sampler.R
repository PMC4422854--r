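#' Radius of a circular plot of given area
#'
#' @param area Plot area in m², > 0. Vectorised.
#' @return Radius in m, `sqrt(area / pi)`; e.g. 7.98 m for 200 m² and
#'   30.90 m for 3000 m².
#' @export
plot_radius <- function(area) {
  if (!is.numeric(area) || any(!is.finite(area)) || any(area <= 0)) {
    stop("`area` must be > 0 (m^2)")
  }
  sqrt(area / pi)
}

#' Specify a circular field plot
#'
#' @param center Numeric length-2 plot center `(x, y)` in m.
#' @param area Plot area in m², > 0.
#' @return Object of class `plot_spec` with fields `center`, `area`,
#'   `radius` (= `sqrt(area/pi)`).
#' @export
plot_spec <- function(center, area) {
  stopifnot(is.numeric(center), length(center) == 2, all(is.finite(center)))
  structure(list(center = as.numeric(center), area = area,
                 radius = plot_radius(area)),
            class = "plot_spec")
}

#' Trees whose stem center falls inside a circular plot
#'
#' Follows the field convention that a tree belongs to the plot when its
#' stem center point is inside; stems exactly on the boundary
#' (distance == radius) count as inside.
#'
#' @param stand A [generate_stand()] result (or any list with a `trees`
#'   data.frame carrying `x`, `y`).
#' @param spec A [plot_spec()].
#' @return The subset of `stand$trees` inside the plot.
#' @export
trees_in_plot <- function(stand, spec) {
  stopifnot(inherits(spec, "plot_spec"))
  tr <- stand$trees
  d2 <- (tr$x - spec$center[1])^2 + (tr$y - spec$center[2])^2
  tr[d2 <= spec$radius^2, , drop = FALSE]
}

#' Field reference AGB density of a plot
#'
#' Sums per-tree biomass and scales to Mg per hectare:
#' `(sum(agb_kg) / 1000) / (area / 10000)`.
#'
#' @param trees Data frame with an `agb` column in kg (e.g. from
#'   [trees_in_plot()]).
#' @param area Plot area in m², > 0.
#' @param unit_scale Divisor converting the per-tree biomass unit to Mg;
#'   1000 for kg (the package convention).
#' @return AGB density in Mg per hectare.
#' @export
field_agb_density <- function(trees, area, unit_scale = 1000) {
  if (!is.numeric(area) || length(area) != 1 || !is.finite(area) || area <= 0) {
    stop("`area` must be > 0 (m^2)")
  }
  (sum(trees$agb) / unit_scale) / (area / 1e4)
}

#' Summarize biomass in an annular buffer outside a plot
#'
#' Boundary-effect indicators: trees with dbh > `dbh_min` whose stem lies in
#' the annulus `radius < distance <= radius + buffer_width` are tallied, and
#' their total (SAGB) and single-largest (MAGB) biomass are expressed per
#' hectare and then as ratios to the plot's field reference AGB. By default
#' the per-hectare scaling uses the plot area as reference area, which keeps
#' the ratios dimensionless and comparable across plot sizes;
#' `reference = "annulus"` scales by the buffer annulus area instead.
#'
#' @param stand A [generate_stand()] result.
#' @param spec A [plot_spec()].
#' @param buffer_width Annulus width in m (> 0); 3 and 6 m are the analysis
#'   defaults.
#' @param field_agb The plot's field reference AGB in Mg/ha (> 0).
#' @param dbh_min Buffer trees must have dbh strictly greater than this (cm).
#' @param reference Reference area for per-ha scaling: `"plot"` or
#'   `"annulus"`.
#' @param unit_scale Divisor converting per-tree biomass to Mg (1000 for kg).
#' @return Object of class `buffer_summary`: list with `buffer_width`,
#'   `sagb_ratio`, `magb_ratio` (both unitless, `magb_ratio <= sagb_ratio`).
#' @export
buffer_summary <- function(stand, spec, buffer_width, field_agb,
                           dbh_min = 10, reference = c("plot", "annulus"),
                           unit_scale = 1000) {
  stopifnot(inherits(spec, "plot_spec"))
  reference <- match.arg(reference)
  if (!is.finite(buffer_width) || buffer_width <= 0) {
    stop("`buffer_width` must be > 0 (m)")
  }
  if (!is.finite(field_agb) || field_agb <= 0) {
    stop("`field_agb` must be > 0 (Mg/ha)")
  }
  tr <- stand$trees
  d2 <- (tr$x - spec$center[1])^2 + (tr$y - spec$center[2])^2
  r <- spec$radius
  in_buf <- d2 > r^2 & d2 <= (r + buffer_width)^2 & tr$dbh > dbh_min
  buf <- tr[in_buf, , drop = FALSE]
  ref_area <- if (reference == "plot") spec$area else
    pi * ((r + buffer_width)^2 - r^2)
  per_ha <- function(kg) (kg / unit_scale) / (ref_area / 1e4)
  sagb <- if (nrow(buf)) per_ha(sum(buf$agb)) else 0
  magb <- if (nrow(buf)) per_ha(max(buf$agb)) else 0
  structure(list(buffer_width = buffer_width,
                 sagb_ratio = sagb / field_agb,
                 magb_ratio = magb / field_agb),
            class = "buffer_summary")
}

#' Clip an echo cloud to a circular plot
#'
#' Keeps echoes whose planimetric distance to the plot center is at most the
#' plot radius (boundary echoes included, matching the tree convention).
#' Echo class labels are preserved.
#'
#' @param cloud An [simulate_point_cloud()] result (or any `echo_cloud`).
#' @param spec A [plot_spec()].
#' @return An `echo_cloud` restricted to the plot.
#' @export
echoes_in_plot <- function(cloud, spec) {
  stopifnot(inherits(cloud, "echo_cloud"), inherits(spec, "plot_spec"))
  e <- cloud$echoes
  d2 <- (e$x - spec$center[1])^2 + (e$y - spec$center[2])^2
  structure(list(echoes = e[d2 <= spec$radius^2, , drop = FALSE],
                 source = cloud$source),
            class = "echo_cloud")
}
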