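#' Configuration of a full plot-size experiment
#'
#' @param sim A [sim_config()]; its extent is set per plot by the pipeline
#'   (a square just covering the largest plot radius plus the widest crown),
#'   other fields are used as given.
#' @param plot_sizes Circular plot areas in m², positive and strictly
#'   increasing; default 200 to 3000 in steps of 100.
#' @param n_plots Number of field plots (independent stands), >= 5.
#' @param buffer_widths Buffer annulus widths (m) for the boundary analysis.
#' @param buffer_size_max Named numeric: for each buffer width, the largest
#'   plot size (m²) whose plots enter that buffer's records; defaults 1500
#'   for 3 m and 1100 for 6 m.
#' @param max_radius_pool Pool of per-plot maximum measurable radii (m),
#'   sampled per plot; the default mirrors a field campaign where sight
#'   conditions limited most plots to 31 m and a few to 25-28 m, so plot
#'   sizes beyond a plot's maximum radius are missing for that plot.
#' @param loocv_selection_in_folds Rerun variable selection inside each
#'   cross-validation fold (default `FALSE`: labels fixed, coefficients
#'   refit).
#' @param residual_source Predictions entering the GREG variance:
#'   `"loocv"` (honest errors, default) or `"fullfit"`.
#' @param max_terms,vif_limit Subset-selection controls.
#' @param output_dir Directory for CSV/JSON outputs; `NULL` writes nothing.
#' @param seed Integer master seed for the whole experiment.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       plot_sizes = seq(200, 3000, by = 100),
                       n_plots = 30,
                       buffer_widths = c(3, 6),
                       buffer_size_max = c("3" = 1500, "6" = 1100),
                       max_radius_pool = c(rep(31, 22), rep(28, 2), 26,
                                           rep(25, 5)),
                       loocv_selection_in_folds = FALSE,
                       residual_source = c("loocv", "fullfit"),
                       max_terms = 3,
                       vif_limit = 10,
                       output_dir = NULL,
                       seed = 1L) {
  stopifnot(inherits(sim, "sim_config"))
  if (any(plot_sizes <= 0) || any(diff(plot_sizes) <= 0)) {
    stop("`plot_sizes` must be positive and strictly increasing")
  }
  if (n_plots < 5) stop("`n_plots` must be >= 5")
  if (!all(as.character(buffer_widths) %in% names(buffer_size_max))) {
    stop("`buffer_size_max` must name every buffer width")
  }
  residual_source <- match.arg(residual_source)
  sim$seed <- as.integer(seed)
  structure(list(
    sim = sim, plot_sizes = plot_sizes, n_plots = as.integer(n_plots),
    buffer_widths = buffer_widths, buffer_size_max = buffer_size_max,
    max_radius_pool = max_radius_pool,
    loocv_selection_in_folds = loocv_selection_in_folds,
    residual_source = residual_source, max_terms = max_terms,
    vif_limit = vif_limit, output_dir = output_dir, seed = as.integer(seed)
  ), class = "run_config")
}

# Simulate one plot's stand and cloud and extract everything the analysis
# needs at every measurable plot size. Field trees are tallied around the
# true plot center; ALS metrics are extracted around the GNSS-perturbed
# center. Returns list(field = data.frame, metrics = data.frame,
# buffers = data.frame).
sample_one_plot <- function(plot_id, plot_seed, max_radius, config) {
  sizes <- config$plot_sizes[plot_radius(config$plot_sizes) <= max_radius]
  if (!length(sizes)) stop("plot ", plot_id, ": no measurable plot size")
  r_need <- plot_radius(max(sizes))
  side <- 2 * (r_need + config$sim$crown_cap + 2)
  cfg <- config$sim
  cfg$extent_m <- c(side, side)
  cfg$seed <- plot_seed
  stand <- generate_stand(cfg)
  cloud <- simulate_point_cloud(stand, cfg)  # continues RNG at plot_seed + 1
  center <- c(side, side) / 2
  als_center <- perturb_plot_center(center, cfg$pos_error_sd)

  field <- metrics <- buffers <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    spec_field <- plot_spec(center, sizes[k])
    spec_als <- plot_spec(als_center, sizes[k])
    trees <- trees_in_plot(stand, spec_field)
    agb <- field_agb_density(trees, sizes[k])
    field[[k]] <- data.frame(plot_id = plot_id, plot_size = sizes[k],
                             n_trees = nrow(trees), field_agb = agb)
    metrics[[k]] <- cbind(plot_id = plot_id, plot_size = sizes[k],
                          metrics_for_plot(cloud, spec_als))
    bw <- config$buffer_widths[
      sizes[k] <= config$buffer_size_max[as.character(config$buffer_widths)]]
    if (length(bw) && agb > 0) {
      buffers[[k]] <- do.call(rbind, lapply(bw, function(w) {
        bs <- buffer_summary(stand, spec_field, w, agb)
        data.frame(plot_id = plot_id, plot_size = sizes[k], buffer_width = w,
                   sagb_ratio = bs$sagb_ratio, magb_ratio = bs$magb_ratio)
      }))
    }
  }
  list(field = do.call(rbind, field),
       metrics = do.call(rbind, metrics),
       buffers = do.call(rbind, buffers))
}

# Model fitting, LOOCV and design-based estimation for one plot size.
# `dat` holds field_agb and metric columns for the plots available at that
# size. Returns NULL (with a warning) when too few usable plots remain.
analyse_size <- function(size, field_agb, metrics, plot_ids, config) {
  ok <- is.finite(field_agb) & field_agb > 0
  if (any(!ok)) {
    warning("plot size ", size, ": dropped plot(s) ",
            paste(plot_ids[!ok], collapse = ", "), " with zero field AGB")
  }
  cand <- suppressWarnings(build_candidates(metrics[ok, , drop = FALSE]))
  keep_ids <- plot_ids[ok][cand$kept]
  y <- field_agb[ok][cand$kept]
  if (length(y) < config$max_terms + 3) {
    warning("plot size ", size, ": only ", length(y),
            " usable plots; size skipped")
    return(NULL)
  }
  fit <- select_model(log(y), cand, config$max_terms, config$vif_limit)
  cv <- loocv(y, cand, fit$selected,
              refit_selection = config$loocv_selection_in_folds,
              max_terms = config$max_terms, vif_limit = config$vif_limit)
  pred_full <- predict_agb(fit, cand$values)
  pred_greg <- if (config$residual_source == "loocv") cv$predictions else
    pred_full
  v_field <- variance_field(y)
  v_als <- variance_greg(y, pred_greg)
  mean_agb <- mean(y)
  list(
    plot_ids = keep_ids, field_agb = y,
    fit = fit, cv = cv, pred_full = pred_full,
    row = data.frame(
      plot_size = size, n = length(y),
      mean_agb = mean_agb, sd_agb = stats::sd(y),
      min_agb = min(y), max_agb = max(y),
      selected = paste(fit$selected, collapse = "+"),
      adj_r2 = fit$adj_r2, rmse_pct = cv$rmse_pct, mpe_pct = cv$mpe_pct,
      v_field = v_field, v_als = v_als,
      se_field = sqrt(v_field), se_als = sqrt(v_als),
      se_field_pct = se_percent(v_field, mean_agb),
      se_als_pct = se_percent(v_als, mean_agb),
      re = relative_efficiency(v_field, v_als)
    )
  )
}

#' Run the full plot-size experiment
#'
#' Simulates `n_plots` independent field plots (stand + echo cloud +
#' perturbed ALS extraction center), computes field reference AGB and ALS
#' metrics for every plot size, fits and cross-validates a best-subset
#' log-OLS biomass model per size, pools relative residuals for the
#' boundary-effect mixed models and the size trend, and compares the
#' field-based and model-assisted variance estimators per size.
#'
#' RNG order for a fixed `seed`: maximum radii are sampled first, then one
#' sub-seed per plot; each plot's stand, cloud and center perturbation draw
#' from its own sub-seeded stream, so results are reproducible and
#' insensitive to the number of sizes analysed.
#'
#' @param config A [run_config()].
#' @return Object of class `plot_size_experiment`: list with
#'   * `results`: one row per plot size (field AGB summary, selected
#'     variables, adjusted R², RMSE%, MPE%, SEs, relative efficiency);
#'   * `boundary`: `lme` (list of `lme_result` per predictor and buffer
#'     width), `size_trend` (a `size_trend`), `records` (pooled residual
#'     records);
#'   * `consistent_subset`: when sizes beyond 1900 m² are requested, the
#'     per-size results recomputed on the subset of plots measurable at the
#'     largest radius (`NULL` otherwise);
#'   * `field`, `metrics`: per-plot per-size tables; `config`.
#'   With `output_dir` set, writes `stands` are not retained but
#'   `metrics.csv`, `results.csv`, `boundary_records.csv` and
#'   `summary.json` are written there.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  max_radii <- sample(config$max_radius_pool, config$n_plots,
                      replace = config$n_plots > length(config$max_radius_pool))
  plot_seeds <- sample.int(2^30, config$n_plots)

  per_plot <- lapply(seq_len(config$n_plots), function(i) {
    sample_one_plot(i, plot_seeds[i], max_radii[i], config)
  })
  field <- do.call(rbind, lapply(per_plot, `[[`, "field"))
  metrics <- do.call(rbind, lapply(per_plot, `[[`, "metrics"))
  buffers <- do.call(rbind, lapply(per_plot, `[[`, "buffers"))
  metric_cols <- setdiff(names(metrics),
                         c("plot_id", "plot_size", "n_first", "n_last"))

  sizes <- config$plot_sizes
  analyses <- lapply(sizes, function(s) {
    sel <- field$plot_size == s
    if (!any(sel)) return(NULL)
    analyse_size(s, field$field_agb[sel],
                 metrics[metrics$plot_size == s, metric_cols, drop = FALSE],
                 field$plot_id[sel], config)
  })
  results <- do.call(rbind, lapply(analyses, function(a) a$row))
  message("fitted models for ", nrow(results), " plot size(s)")

  # pooled relative residuals (full-fit, bias-corrected predictions) joined
  # with buffer summaries for the boundary analysis
  records <- do.call(rbind, lapply(analyses, function(a) {
    if (is.null(a)) return(NULL)
    rr <- relative_residuals(a$field_agb, a$pred_full)
    cbind(plot_id = a$plot_ids, plot_size = a$row$plot_size, rr)
  }))
  boundary <- list(lme = list(), size_trend = NULL, records = records)
  if (!is.null(records)) {
    boundary$size_trend <- fit_absres_vs_size(records)
    for (w in config$buffer_widths) {
      pool <- merge(records,
                    buffers[buffers$buffer_width == w, , drop = FALSE],
                    by = c("plot_id", "plot_size"))
      for (pr in c("sagb_ratio", "magb_ratio")) {
        key <- paste0(pr, "_", w, "m")
        boundary$lme[[key]] <- tryCatch(
          fit_buffer_lme(pool, pr),
          error = function(e) {
            warning("boundary LME ", key, " not fitted: ",
                    conditionMessage(e))
            NULL
          })
      }
    }
  }

  consistent_subset <- NULL
  if (max(sizes) > 1900) {
    ids <- which(max_radii >= plot_radius(max(sizes)))
    if (length(ids) >= config$max_terms + 3) {
      sub <- lapply(sizes, function(s) {
        sel <- field$plot_size == s & field$plot_id %in% ids
        if (!any(sel)) return(NULL)
        msel <- metrics$plot_size == s & metrics$plot_id %in% ids
        a <- analyse_size(s, field$field_agb[sel],
                          metrics[msel, metric_cols, drop = FALSE],
                          field$plot_id[sel], config)
        a$row
      })
      consistent_subset <- do.call(rbind, sub)
    }
  }

  out <- structure(list(results = results, boundary = boundary,
                        consistent_subset = consistent_subset,
                        field = field, metrics = metrics, buffers = buffers,
                        config = config),
                   class = "plot_size_experiment")
  if (!is.null(config$output_dir)) write_experiment(out, config$output_dir)
  out
}

#' Write the machine-readable outputs of an experiment
#'
#' Emits `metrics.csv` (per plot and size: field AGB and all ALS metrics),
#' `results.csv` (the per-size results table), `boundary_records.csv`
#' (pooled relative residuals) and `summary.json` (headline numbers and the
#' boundary-model coefficients).
#'
#' @param experiment A [run_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "plot_size_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  merged <- merge(experiment$field, experiment$metrics,
                  by = c("plot_id", "plot_size"))
  utils::write.csv(merged, file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(experiment$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  if (!is.null(experiment$boundary$records)) {
    utils::write.csv(experiment$boundary$records,
                     file.path(dir, "boundary_records.csv"),
                     row.names = FALSE)
  }
  lme_summ <- lapply(experiment$boundary$lme, function(m) {
    if (is.null(m)) return(NULL)
    m[c("predictor", "intercept", "slope", "slope_p", "aic",
        "random_intercept_sd")]
  })
  summ <- list(
    seed = experiment$config$seed,
    n_plots = experiment$config$n_plots,
    plot_sizes = experiment$config$plot_sizes,
    size_trend = if (!is.null(experiment$boundary$size_trend)) {
      unclass(experiment$boundary$size_trend)
    },
    boundary_lme = lme_summ,
    re = stats::setNames(as.list(experiment$results$re),
                         experiment$results$plot_size)
  )
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
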