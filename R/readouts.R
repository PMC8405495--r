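#' gammaH2AX-positive fraction
#'
#' Percentage of agents carrying unrepaired replication-stress DNA damage:
#' residents of the D-S state plus repair-failed agents awaiting death (the
#' marker persists until the cell dies). The default denominator counts the
#' viable (non-dead) agents, as in assays that gate on intact cells; `"all"`
#' keeps dead cells (which persist on the monolayer lattice) in the
#' denominator.
#'
#' @param state Vector of agent state names or codes (agents on the lattice).
#' @param denominator `"viable"` or `"all"`.
#' @return Percentage in `[0, 100]`, or `NA` (with a warning) for an empty
#'   population.
#' @examples
#' gammah2ax_fraction(c("DS", "G1", "S", "G1"))  # 25
#' @export
gammah2ax_fraction <- function(state, denominator = c("viable", "all")) {
  denominator <- match.arg(denominator)
  code <- .state_code(state)
  if (denominator == "viable") code <- code[code != .STATES[["DEAD"]]]
  if (length(code) == 0) {
    warning("empty population: gammaH2AX fraction undefined")
    return(NA_real_)
  }
  pos <- code == .STATES[["DS"]] | code == .STATES[["LETHAL_PENDING"]]
  100 * sum(pos) / length(code)
}

#' Disc-to-spheroid volume extrapolation
#'
#' Extrapolates the simulated two-dimensional cross section to a spheroid:
#' the occupied area `A = n_occupied * dx^2` defines an effective disc radius
#' equal to `sqrt(A / pi)`, and the reported volume is that of the sphere of
#' the same radius, `(4/3) * pi * radius^3`.
#'
#' @param lattice An [new_lattice()] object, occupancy matrix, or a bare
#'   occupied-site count.
#' @param dx Lattice spacing in cm (taken from the lattice if available).
#' @return Volume in cm^3 (0 for an empty lattice).
#' @examples
#' spheroid_volume(1963, dx = 0.004)  # a disc of radius ~25 sites
#' @export
spheroid_volume <- function(lattice, dx = NULL) {
  if (inherits(lattice, "abm_lattice")) {
    if (is.null(dx)) dx <- lattice$spacing
    n_occ <- sum(lattice$occ != 0L)
  } else if (is.matrix(lattice)) {
    n_occ <- sum(lattice != 0L)
  } else {
    n_occ <- lattice
  }
  if (is.null(dx) || is.na(dx)) stop("spheroid_volume needs a spacing dx in cm")
  if (n_occ == 0) return(0)
  r <- sqrt(n_occ * dx^2 / pi)
  4 / 3 * pi * r^3
}

#' Root-mean-square error between two aligned series
#'
#' @param sim,data Numeric vectors of equal length (aligned time points).
#' @return `sqrt(mean((sim - data)^2))`.
#' @examples
#' rmse(c(1, 1), c(0, 2))  # 1
#' @export
rmse <- function(sim, data) {
  if (length(sim) != length(data) || length(sim) < 1)
    stop("rmse needs two non-empty series of equal length")
  if (anyNA(sim) || anyNA(data)) stop("rmse input contains missing values")
  sqrt(mean((sim - data)^2))
}

#' Write a readout series to long-format CSV
#'
#' One row per (time, metric) with columns `time`, `dose`, `replicate`,
#' `metric`, `value`.
#'
#' @param x An `abm_readouts` data frame from [run_replicate()] (or any data
#'   frame with a `time` column and numeric metric columns).
#' @param path Output file.
#' @param dose Dose label stored in the `dose` column (defaults to the dose
#'   recorded with the series).
#' @param replicate Replicate label.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path, dose = NULL, replicate = 1L) {
  if (is.null(dose)) {
    d <- attr(x, "dose")
    dose <- if (is.null(d)) NA else format(d)
  }
  metrics <- setdiff(names(x), "time")
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(time = x$time, dose = dose, replicate = replicate,
               metric = m, value = x[[m]])
  }))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format readout series written by [write_timeseries()]
#'
#' @param path CSV file.
#' @return A data frame with columns `time`, `dose`, `replicate`, `metric`,
#'   `value`.
#' @export
read_timeseries <- function(path) {
  x <- read.csv(path)
  need <- c("time", "dose", "replicate", "metric", "value")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("malformed time-series CSV; missing column(s): ",
         paste(miss, collapse = ", "))
  x
}

#' Load an experimental fixture table
#'
#' Reads a CSV of experimental reference time courses with columns `source`
#' (`invitro_monolayer` or `invivo_xenograft`), `dose`, `metric`, `time`,
#' `mean` and `dispersion` (standard deviation for in vitro, standard error
#' for in vivo data). Times must be strictly increasing within each
#' (dose, metric) series and dispersions non-negative.
#'
#' @param path CSV file.
#' @return A validated data frame of class `abm_fixture`.
#' @export
load_fixture <- function(path) {
  x <- read.csv(path)
  need <- c("source", "dose", "metric", "time", "mean", "dispersion")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("malformed fixture CSV; missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(x$source %in% c("invitro_monolayer", "invivo_xenograft")))
    stop("fixture source must be invitro_monolayer or invivo_xenograft")
  if (any(x$dispersion < 0)) stop("fixture dispersion must be non-negative")
  for (key in split(seq_len(nrow(x)), list(x$dose, x$metric), drop = TRUE)) {
    if (is.unsorted(x$time[key], strictly = TRUE))
      stop("fixture times must be strictly increasing within each series")
  }
  class(x) <- c("abm_fixture", class(x))
  x
}

#' Compare an experiment to a fixture table
#'
#' Computes the root-mean-square error between simulated mean readouts and
#' fixture means, per dose and metric. Simulated means are linearly
#' interpolated onto the fixture time points; fixture times outside the
#' simulated range raise an error.
#'
#' @param experiment An `abm_experiment` from [run_experiment()] (or its
#'   `summary` data frame with columns `time`, `metric`, `mean`).
#' @param fixture An `abm_fixture` from [load_fixture()].
#' @param metric_map Named character vector mapping fixture metric names to
#'   simulation metric names. Default maps `gammah2ax_pct` and `total` onto
#'   themselves and `volume_cm3` onto itself.
#' @return A data frame with columns `dose`, `metric`, `n` and `rmse`.
#' @export
compare_to_fixture <- function(experiment, fixture,
                               metric_map = c(gammah2ax_pct = "gammah2ax_pct",
                                              total = "n_total",
                                              volume_cm3 = "volume_cm3")) {
  summ <- if (inherits(experiment, "abm_experiment")) experiment$summary
          else experiment
  out <- list()
  for (dose in unique(fixture$dose)) {
    for (metric in unique(fixture$metric[fixture$dose == dose])) {
      fx <- fixture[fixture$dose == dose & fixture$metric == metric, ]
      sim_metric <- if (metric %in% names(metric_map)) metric_map[[metric]]
                    else metric
      sm <- summ[summ$metric == sim_metric, ]
      if (nrow(sm) == 0)
        stop("simulation summary has no metric '", sim_metric, "'")
      if (min(fx$time) < min(sm$time) - 1e-9 ||
          max(fx$time) > max(sm$time) + 1e-9)
        stop("fixture times outside the simulated range for ", metric)
      sim_at <- stats::approx(sm$time, sm$mean, xout = fx$time)$y
      out[[length(out) + 1L]] <-
        data.frame(dose = dose, metric = metric, n = nrow(fx),
                   rmse = rmse(sim_at, fx$mean))
    }
  }
  do.call(rbind, out)
}

#' Write a cell map (and optional fields) as legacy VTK image data
#'
#' ASCII `STRUCTURED_POINTS` file readable by ParaView: one integer array of
#' state-coded sites (0 empty, then the cell-cycle state codes) plus one
#' float array per extra field.
#'
#' @param path Output `.vtk` file.
#' @param states Integer matrix of state codes per site (0 = empty).
#' @param fields Named list of numeric matrices (e.g. oxygen, drug).
#' @param dx Lattice spacing (written as the VTK spacing; default 1).
#' @return `path`, invisibly.
#' @export
write_cellmap_vtk <- function(path, states, fields = list(), dx = 1) {
  n <- nrow(states)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "ddrabm cell map", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", n, ncol(states)),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g 1", dx, dx),
               sprintf("POINT_DATA %d", length(states)),
               "SCALARS cell_state int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(states), collapse = " "), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(paste(format(as.numeric(fields[[nm]]), trim = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' The file may hold two top-level maps, `config` (arguments of
#' [simulation_config()], with `dose` given as a nested map of
#' [dose_descriptor()] arguments) and `params` (arguments of
#' [model_params()]).
#'
#' @param path YAML file.
#' @return A list with elements `config` (`abm_config`) and `params`
#'   (`abm_params`).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- do.call(model_params, if (is.null(y$params)) list() else y$params)
  cfg_args <- if (is.null(y$config)) list() else y$config
  if (!is.null(cfg_args$dose))
    cfg_args$dose <- do.call(dose_descriptor, cfg_args$dose)
  config <- do.call(simulation_config, cfg_args)
  list(config = config, params = params)
}
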