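#' Simulation configuration for a synthetic forest stand and its echo cloud
#'
#' Bundles every tunable of the stand and lidar simulator. Defaults describe
#' a dense tropical rain forest scanned at the acquisition settings assumed
#' throughout the package: 10.6 pulses per square metre and a plot-center
#' positioning error of 0.19 m.
#'
#' @param extent_m Numeric length-2, width and height of the simulated
#'   rectangle in m (a scalar is recycled to a square).
#' @param stem_density Stems per hectare with dbh >= 5 cm.
#' @param dbh_shape,dbh_scale Weibull shape and scale (cm) of the diameter
#'   distribution, left-truncated at `dbh_min`. The default (shape 1.1,
#'   scale 20) gives the reverse-J diameter distribution typical of natural
#'   tropical forest.
#' @param dbh_min Truncation diameter in cm; the field protocol tallies
#'   trees with dbh >= 5 cm.
#' @param crown_intercept,crown_slope Linear crown-radius model
#'   `crown_radius = crown_intercept + crown_slope * dbh` (m, m/cm).
#' @param crown_cap Maximum crown radius in m.
#' @param crown_gamma Crown envelope shape exponent; 0.5 gives rounded
#'   paraboloid crowns.
#' @param pulse_density Emitted lidar pulses per square metre.
#' @param ground_echo_fraction Fraction of pulses, in `[0, 1]`, returning a
#'   ground-level echo from canopy gaps.
#' @param height_noise_sd Gaussian sd (m) added to tree heights around the
#'   diameter-height curve and to first-echo heights around the crown
#'   envelope.
#' @param pos_error_sd Per-axis sd (m) of the plot-center positioning error.
#' @param agb_gradient Optional linear trend in expected stem density along
#'   the x axis, expressed as relative change per metre (0 disables it); a
#'   stand-level surrogate for the altitude-driven biomass gradient of
#'   mountainous field sites.
#' @param seed Integer seed; every stochastic operation that receives this
#'   config draws from a stream seeded deterministically from it.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(extent_m = c(100, 100),
                       stem_density = 500,
                       dbh_shape = 1.1,
                       dbh_scale = 20,
                       dbh_min = 5,
                       crown_intercept = 0.5,
                       crown_slope = 0.08,
                       crown_cap = 12,
                       crown_gamma = 0.5,
                       pulse_density = 10.6,
                       ground_echo_fraction = 0.2,
                       height_noise_sd = 0.5,
                       pos_error_sd = 0.19,
                       agb_gradient = 0,
                       seed = 1L) {
  extent_m <- rep(as.numeric(extent_m), length.out = 2)
  if (any(!is.finite(extent_m)) || any(extent_m <= 0)) {
    stop("`extent_m` must be positive")
  }
  if (!is.finite(stem_density) || stem_density <= 0) {
    stop("`stem_density` must be > 0")
  }
  if (!is.finite(pulse_density) || pulse_density <= 0) {
    stop("`pulse_density` must be > 0")
  }
  if (!is.finite(ground_echo_fraction) ||
      ground_echo_fraction < 0 || ground_echo_fraction > 1) {
    stop("`ground_echo_fraction` must be in [0, 1]")
  }
  if (height_noise_sd < 0) stop("`height_noise_sd` must be >= 0")
  if (pos_error_sd < 0) stop("`pos_error_sd` must be >= 0")
  structure(
    list(
      extent_m = extent_m, stem_density = stem_density,
      dbh_shape = dbh_shape, dbh_scale = dbh_scale, dbh_min = dbh_min,
      crown_intercept = crown_intercept, crown_slope = crown_slope,
      crown_cap = crown_cap, crown_gamma = crown_gamma,
      pulse_density = pulse_density,
      ground_echo_fraction = ground_echo_fraction,
      height_noise_sd = height_noise_sd, pos_error_sd = pos_error_sd,
      agb_gradient = agb_gradient, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Inverse-CDF draw from a Weibull left-truncated at `min`.
rtrunc_weibull <- function(n, shape, scale, min) {
  p0 <- stats::pweibull(min, shape, scale)
  u <- stats::runif(n, p0, 1)
  stats::qweibull(u, shape, scale)
}

#' Generate a synthetic forest stand
#'
#' Places stems by a homogeneous Poisson process over the configured
#' extent (optionally thinned along x when `agb_gradient` is non-zero),
#' draws diameters from the truncated Weibull distribution, derives heights
#' from the diameter-height curve ([predict_height()]) plus Gaussian noise,
#' crown radii from the linear crown model, and per-tree biomass from the
#' allometric model ([tree_agb()]).
#'
#' @param config A [sim_config()].
#' @return An object of class `stand`: list with `trees` (data.frame with
#'   columns `tree_id, x, y, dbh, height, crown_radius, agb`), `extent`
#'   (length-2 numeric) and `seed`.
#' @export
generate_stand <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  area_ha <- prod(config$extent_m) / 1e4
  n <- stats::rpois(1, config$stem_density * area_ha)
  x <- stats::runif(n, 0, config$extent_m[1])
  y <- stats::runif(n, 0, config$extent_m[2])
  if (config$agb_gradient != 0 && n > 0) {
    # thin the process so intensity rises linearly along x
    rel <- 1 + config$agb_gradient * (x - config$extent_m[1] / 2)
    keep <- stats::runif(n) < pmax(0, pmin(1, rel))
    x <- x[keep]; y <- y[keep]; n <- length(x)
  }
  dbh <- rtrunc_weibull(n, config$dbh_shape, config$dbh_scale, config$dbh_min)
  height <- predict_height(dbh)
  if (config$height_noise_sd > 0 && n > 0) {
    height <- height + stats::rnorm(n, 0, config$height_noise_sd)
    height <- pmax(height, 1.31)  # total height must exceed breast height
  }
  crown_radius <- pmin(config$crown_intercept + config$crown_slope * dbh,
                       config$crown_cap)
  trees <- data.frame(
    tree_id = seq_len(n), x = x, y = y, dbh = dbh, height = height,
    crown_radius = crown_radius, agb = tree_agb(dbh, height)
  )
  structure(list(trees = trees, extent = config$extent_m,
                 seed = config$seed),
            class = "stand")
}

#' Simulate a height-normalized lidar echo cloud over a stand
#'
#' Each tree intercepts a Poisson number of pulses proportional to its
#' crown disc area (`pulse_density * pi * crown_radius^2`), with echo
#' positions uniform in the disc so that crown echoes spill across any plot
#' boundary drawn later. A pulse hitting a crown returns either a `single`
#' echo at the crown envelope or a `first_of_many`/`last_of_many` pair; the
#' envelope is `z = h * (1 - (d/crown_radius)^2)^gamma` with Gaussian noise,
#' and last echoes fall uniformly between 0.3x and 1x the local envelope
#' height. A `ground_echo_fraction` of pulses over the whole extent return
#' ground-level echoes (z = 0) classified `single` or `last_of_many`.
#' Crowns act independently; overlap is not resolved.
#'
#' @param stand A [generate_stand()] result.
#' @param config The [sim_config()] used (its `seed + 1` seeds this step, so
#'   stand and cloud generation are independently reproducible).
#' @return Object of class `echo_cloud`: list with `echoes` (data.frame
#'   `x, y, z, echo_class`) and `source`.
#' @export
simulate_point_cloud <- function(stand, config) {
  stopifnot(inherits(stand, "stand"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  tr <- stand$trees
  if (nrow(tr) > 0) {
    n_pulse <- stats::rpois(nrow(tr), config$pulse_density * pi * tr$crown_radius^2)
    idx <- rep.int(seq_len(nrow(tr)), n_pulse)
    m <- length(idx)
    # uniform position in each crown disc
    theta <- stats::runif(m, 0, 2 * pi)
    d <- tr$crown_radius[idx] * sqrt(stats::runif(m))
    ex <- tr$x[idx] + d * cos(theta)
    ey <- tr$y[idx] + d * sin(theta)
    env <- tr$height[idx] *
      (1 - (d / tr$crown_radius[idx])^2)^config$crown_gamma
    z_first <- env
    if (config$height_noise_sd > 0) {
      z_first <- z_first + stats::rnorm(m, 0, config$height_noise_sd)
    }
    z_first <- pmax(z_first, 0)
    paired <- stats::runif(m) < 0.5
    canopy <- data.frame(
      x = c(ex, ex[paired]),
      y = c(ey, ey[paired]),
      z = c(z_first, stats::runif(sum(paired), 0.3, 1) * env[paired]),
      echo_class = c(ifelse(paired, "first_of_many", "single"),
                     rep("last_of_many", sum(paired)))
    )
  } else {
    canopy <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                         echo_class = character())
  }
  n_ground <- stats::rpois(1, config$pulse_density *
                              config$ground_echo_fraction *
                              prod(stand$extent))
  ground <- data.frame(
    x = stats::runif(n_ground, 0, stand$extent[1]),
    y = stats::runif(n_ground, 0, stand$extent[2]),
    z = numeric(n_ground),
    echo_class = c("single", "last_of_many")[(stats::runif(n_ground) >= 0.5) + 1L]
  )
  echoes <- rbind(canopy, ground)
  rownames(echoes) <- NULL
  structure(list(echoes = echoes, source = "simulated"),
            class = "echo_cloud")
}

#' Perturb a plot center with isotropic Gaussian positioning error
#'
#' Emulates the planimetric error of differentially corrected GNSS plot
#' coordinates: an independent N(0, sigma^2) displacement on each axis.
#'
#' @param center Numeric length-2 `(x, y)` in m.
#' @param sigma Per-axis standard deviation in m; 0 returns `center`
#'   unchanged.
#' @return Numeric length-2 perturbed center.
#' @export
perturb_plot_center <- function(center, sigma) {
  stopifnot(is.numeric(center), length(center) == 2)
  if (!is.finite(sigma) || sigma < 0) stop("`sigma` must be >= 0")
  if (sigma == 0) return(center)
  center + stats::rnorm(2, 0, sigma)
}
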