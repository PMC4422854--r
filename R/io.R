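#' Read and write stands, echo clouds and metrics tables as CSV
#'
#' Plain-text interchange formats. A stand table has columns
#' `tree_id,x,y,dbh,height,crown_radius,agb`; an echo table has
#' `x,y,z,echo_class` with `echo_class` one of `single`, `first_of_many`,
#' `last_of_many`. For point clouds delivered as LAS, the conventional
#' mapping onto these classes is: return 1 of 1 is `single`, return 1 of
#' k > 1 is `first_of_many`, return k of k > 1 is `last_of_many`, and
#' intermediate returns are dropped; this package consumes the resulting
#' CSV. Round trips preserve values to full double precision.
#'
#' @param stand,cloud Objects to write.
#' @param path File path.
#' @param extent For `read_stand`, the stand extent (length-2, m) to attach.
#' @return Readers return `stand` / `echo_cloud` objects; writers return
#'   `path` invisibly.
#' @name stand_io
NULL

#' @rdname stand_io
#' @export
write_stand <- function(stand, path) {
  stopifnot(inherits(stand, "stand"))
  utils::write.csv(format(stand$trees, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname stand_io
#' @export
read_stand <- function(path, extent = NULL) {
  tr <- utils::read.csv(path)
  need <- c("tree_id", "x", "y", "dbh", "height", "crown_radius", "agb")
  if (!all(need %in% names(tr))) {
    stop("stand CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(extent)) extent <- c(max(tr$x, 0), max(tr$y, 0))
  structure(list(trees = tr[need], extent = extent, seed = NA_integer_),
            class = "stand")
}

#' @rdname stand_io
#' @export
write_echoes <- function(cloud, path) {
  stopifnot(inherits(cloud, "echo_cloud"))
  utils::write.csv(format(cloud$echoes, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname stand_io
#' @export
read_echoes <- function(path) {
  e <- utils::read.csv(path)
  need <- c("x", "y", "z", "echo_class")
  if (!all(need %in% names(e))) {
    stop("echo CSV must have columns: ", paste(need, collapse = ", "))
  }
  bad <- !e$echo_class %in% c("single", "first_of_many", "last_of_many")
  if (any(bad)) {
    stop("unknown echo_class at data row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "),
         ": ", paste(unique(e$echo_class[bad]), collapse = ", "))
  }
  structure(list(echoes = e[need], source = path), class = "echo_cloud")
}

#' Read a run configuration from a flat YAML key-value file
#'
#' Keys mirror the arguments of [sim_config()] and [run_config()]:
#' simulator keys (e.g. `stem_density`, `pulse_density`, `pos_error_sd`)
#' and run keys (`plot_sizes`, `n_plots`, `buffer_widths`, `seed`, ...).
#' Unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  sim_keys <- setdiff(names(formals(sim_config)), "extent_m")
  run_keys <- setdiff(names(formals(run_config)), "sim")
  unknown <- setdiff(names(vals), c(sim_keys, run_keys, "extent_m"))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  sim <- do.call(sim_config, vals[names(vals) %in% c(sim_keys, "extent_m")])
  do.call(run_config, c(list(sim = sim), vals[names(vals) %in% run_keys]))
}
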