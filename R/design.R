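# Design-space exploration: sweep multipliers of the baseline core
# radius and shell thickness, compute threshold metrics per cell, and
# locate the two "optimal" configurations (threshold intersection and
# maximum duration).

#' Design grid of geometry multipliers
#'
#' @param core_multipliers Multipliers applied to the baseline core
#'   radius (default 0.5-2.0 in steps of 0.1).
#' @param shell_multipliers Multipliers applied to the baseline shell
#'   thickness (default `c(0.5, 1, 2, 5, 10)`).
#' @param baseline Baseline [geometry()].
#' @return An object of class `cs_design_grid`.
#' @export
design_grid <- function(core_multipliers = seq(0.5, 2.0, by = 0.1),
                        shell_multipliers = c(0.5, 1, 2, 5, 10),
                        baseline = geometry(5.10, 1.25)) {
  stopifnot(all(core_multipliers > 0), all(shell_multipliers > 0),
            inherits(baseline, "cs_geometry"))
  structure(list(core_multipliers = as.numeric(core_multipliers),
                 shell_multipliers = as.numeric(shell_multipliers),
                 baseline = baseline),
            class = "cs_design_grid")
}

#' Sweep the design space against therapeutic thresholds
#'
#' For every (core multiplier, shell multiplier) cell: scale the baseline
#' geometry, solve the release model, and record the time to the
#' cumulative-release threshold, the duration above the release-rate
#' threshold (with its tolerance-band interval), and the cumulative
#' release at the horizon. The loaded dose is held fixed across cells
#' (the dose is renormalised to the same total amount whatever the
#' sphere size), so the rate depends only on `Q` and the dose.
#'
#' @param grid A [design_grid()] object.
#' @param params A [transport_params()] object.
#' @param dose A [dose_spec()] object.
#' @param q_threshold Cumulative-release threshold, percent (default 90).
#' @param rate_threshold Release-rate threshold, ug/day (default 2).
#' @param band Fractional tolerance band around the rate threshold.
#' @param horizon Simulation horizon, days (default 180).
#' @param n_core Core interval count of the solver grid.
#' @param dt Rate differencing interval, days.
#' @return An object of class `cs_design_metrics` with matrices (rows =
#'   core multipliers, columns = shell multipliers) `t_q_threshold`,
#'   `t_rate_threshold` (duration above the rate threshold),
#'   `band_enter`/`band_exit`, `q_at_horizon`; failed cells are recorded
#'   in `failures` and left `NA`.
#' @export
sweep_design <- function(grid, params, dose,
                         q_threshold = 90, rate_threshold = 2, band = 0.10,
                         horizon = 180, n_core = 100L, dt = 1) {
  stopifnot(inherits(grid, "cs_design_grid"), inherits(params, "cs_transport"),
            inherits(dose, "cs_dose"), horizon >= dt)
  cm <- grid$core_multipliers
  sm <- grid$shell_multipliers
  dims <- list(core = as.character(cm), shell = as.character(sm))
  empty <- matrix(NA_real_, length(cm), length(sm), dimnames = dims)
  out <- list(t_q_threshold = empty, t_rate_threshold = empty,
              band_enter = empty, band_exit = empty, q_at_horizon = empty)
  failures <- list()
  settings <- solver_settings(save_times = seq(0, horizon, by = dt))
  for (i in seq_along(cm)) {
    for (j in seq_along(sm)) {
      geom_ij <- geometry(grid$baseline$r_core * cm[i],
                          grid$baseline$delta_r * sm[j])
      cell <- try({
        prof <- solve_concentration(geom_ij, params, settings = settings,
                                    n_core = n_core)
        rel <- cumulative_release(prof)
        rates <- release_rate(rel, dose, dt = dt)
        dur <- duration_above_rate_threshold(rates, rate_threshold, band)
        list(tq = as.numeric(time_to_release_threshold(rel, q_threshold)),
             dur = dur$duration,
             enter = dur$band_interval[["upper"]],
             exit = dur$band_interval[["lower"]],
             q_end = rel$q[length(rel$q)])
      }, silent = TRUE)
      if (inherits(cell, "try-error")) {
        failures[[sprintf("%g x %g", cm[i], sm[j])]] <- as.character(cell)
      } else {
        out$t_q_threshold[i, j] <- cell$tq
        out$t_rate_threshold[i, j] <- cell$dur
        out$band_enter[i, j] <- cell$enter
        out$band_exit[i, j] <- cell$exit
        out$q_at_horizon[i, j] <- cell$q_end
      }
    }
  }
  structure(c(out,
              list(thresholds = list(q = q_threshold, rate = rate_threshold,
                                     band = band),
                   horizon = horizon, dt = dt,
                   grid = grid, params = params, dose = dose,
                   failures = failures)),
            class = "cs_design_metrics")
}

#' @export
print.cs_design_metrics <- function(x, ...) {
  cat(sprintf("design metrics: %d core x %d shell multipliers, horizon %g d\n",
              nrow(x$t_q_threshold), ncol(x$t_q_threshold), x$horizon))
  cat(sprintf("  thresholds: Q = %g%%, rate = %g ug/day (+/-%g%% band)\n",
              x$thresholds$q, x$thresholds$rate, 100 * x$thresholds$band))
  if (length(x$failures)) {
    cat(sprintf("  %d failed cells: %s\n", length(x$failures),
                paste(names(x$failures), collapse = ", ")))
  }
  invisible(x)
}

shell_column <- function(metrics, shell_multiplier) {
  j <- match(as.character(shell_multiplier),
             colnames(metrics$t_q_threshold))
  if (is.na(j)) stop("shell multiplier not present in the sweep", call. = FALSE)
  j
}

#' Where time-to-Q-threshold meets duration-above-rate-threshold
#'
#' Along the core-multiplier axis (at a fixed shell multiplier), finds
#' the configuration where the time to reach the cumulative-release
#' threshold equals the duration above the rate threshold, by linear
#' interpolation of the sign change of their difference.
#'
#' @param metrics A [sweep_design()] result.
#' @param shell_multiplier Which shell-multiplier column to use.
#' @return A list: `core_multiplier`, `time` (days, common metric value
#'   at the intersection), `degenerate` (TRUE when the two profiles
#'   coincide everywhere, in which case the smallest multiplier is
#'   returned), and the per-multiplier `difference` profile. `NULL`
#'   `core_multiplier` with the difference profile when no sign change is
#'   bracketed.
#' @export
find_threshold_intersection <- function(metrics, shell_multiplier = 1) {
  stopifnot(inherits(metrics, "cs_design_metrics"))
  j <- shell_column(metrics, shell_multiplier)
  cm <- metrics$grid$core_multipliers
  tq <- metrics$t_q_threshold[, j]
  td <- metrics$t_rate_threshold[, j]
  diff_prof <- tq - td
  ok <- is.finite(diff_prof)
  if (!any(ok)) {
    return(list(core_multiplier = NULL, time = NULL, degenerate = FALSE,
                difference = diff_prof))
  }
  if (all(abs(diff_prof[ok]) < 1e-9)) {
    return(list(core_multiplier = min(cm[ok]), time = tq[ok][which.min(cm[ok])],
                degenerate = TRUE, difference = diff_prof))
  }
  sgn <- sign(diff_prof)
  hit <- which(ok[-length(ok)] & ok[-1] &
                 sgn[-length(sgn)] * sgn[-1] <= 0 &
                 abs(diff_prof[-length(diff_prof)]) + abs(diff_prof[-1]) > 0)
  if (!length(hit)) {
    return(list(core_multiplier = NULL, time = NULL, degenerate = FALSE,
                difference = diff_prof))
  }
  k <- hit[1]
  w <- diff_prof[k] / (diff_prof[k] - diff_prof[k + 1L])
  core_star <- cm[k] + w * (cm[k + 1L] - cm[k])
  time_star <- tq[k] + w * (tq[k + 1L] - tq[k])
  list(core_multiplier = core_star, time = time_star,
       degenerate = FALSE, difference = diff_prof)
}

#' Core multiplier maximising the duration above the rate threshold
#'
#' Arg-max along the core-multiplier axis at a fixed shell multiplier;
#' ties (within `tie_tol` days) are broken toward the largest multiplier,
#' which holds the larger drug payload. A maximum at either end of the
#' grid is flagged as a boundary solution.
#'
#' @param metrics A [sweep_design()] result.
#' @param shell_multiplier Which shell-multiplier column to use.
#' @param tie_tol Durations within this many days of the maximum count as
#'   tied (default 1e-6).
#' @return A list: `core_multiplier`, `duration` (days), `boundary`.
#' @export
find_max_duration_config <- function(metrics, shell_multiplier = 1,
                                     tie_tol = 1e-6) {
  stopifnot(inherits(metrics, "cs_design_metrics"))
  j <- shell_column(metrics, shell_multiplier)
  cm <- metrics$grid$core_multipliers
  dur <- metrics$t_rate_threshold[, j]
  ok <- which(is.finite(dur))
  if (!length(ok)) stop("no finite durations in this column", call. = FALSE)
  dmax <- max(dur[ok])
  tied <- ok[dur[ok] >= dmax - tie_tol]
  pick <- tied[which.max(cm[tied])]
  list(core_multiplier = cm[pick], duration = dur[pick],
       boundary = pick == 1L || pick == length(cm))
}

#' Write the sweep metric matrices as CSV files
#'
#' One file per metric (`metrics_<name>.csv`), with core multipliers as
#' rows and shell multipliers as columns.
#'
#' @param metrics A [sweep_design()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_design_csv <- function(metrics, dir) {
  stopifnot(inherits(metrics, "cs_design_metrics"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  names_ <- c("t_q_threshold", "t_rate_threshold", "band_enter",
              "band_exit", "q_at_horizon")
  paths <- vapply(names_, function(nm) {
    df <- data.frame(core_multiplier = metrics$grid$core_multipliers,
                     metrics[[nm]], check.names = FALSE)
    names(df)[-1] <- paste0("shell_", colnames(metrics[[nm]]))
    p <- file.path(dir, paste0("metrics_", nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
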