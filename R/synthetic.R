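# Synthetic cumulative-release observations with known ground truth, so
# that estimation and uncertainty can be exercised without any external
# dataset. The default schedule is an 11-point stand-in over 180 days.

#' Default synthetic measurement schedule
#'
#' Eleven measurement times spanning 180 days, dense early (where the
#' burst and early diffusion shape the curve) and sparser late.
#'
#' @return Numeric vector of days.
#' @export
default_schedule <- function() {
  c(0.25, 1, 3, 7, 14, 28, 56, 84, 112, 140, 180)
}

#' Generate synthetic cumulative-release observations
#'
#' Forward-simulates the release model at the schedule times and adds
#' independent Gaussian measurement noise. Observations are clipped to
#' `[0, 100]`; clipping events are recorded. Deterministic for a fixed
#' seed.
#'
#' @param true_params A [transport_params()] object (the ground truth;
#'   its burst and `d_core` are what estimation should recover).
#' @param geom A [geometry()] object.
#' @param schedule Measurement times, days, strictly increasing.
#' @param noise_sd Measurement noise standard deviation, percent points
#'   (scalar or per-point; default 2).
#' @param seed Optional RNG seed.
#' @param n_core Core interval count of the solver grid.
#' @return An object of class `cs_synthetic` (also usable wherever a
#'   [observed_release()] object is expected): `times`, `q_obs`,
#'   `q_true`, `sd`, `true_params`, `seed`, `clipped`.
#' @export
generate_observations <- function(true_params, geom,
                                  schedule = default_schedule(),
                                  noise_sd = 2, seed = NULL,
                                  n_core = 100L) {
  stopifnot(inherits(true_params, "cs_transport"), inherits(geom, "cs_geometry"),
            length(schedule) >= 1L, all(noise_sd >= 0))
  if (any(diff(schedule) <= 0)) {
    stop("'schedule' must be strictly increasing", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sds <- rep_len(noise_sd, length(schedule))
  save_times <- sort(unique(c(0, schedule)))
  settings <- solver_settings(save_times = save_times)
  prof <- solve_concentration(geom, true_params, settings = settings,
                              n_core = n_core)
  rel <- cumulative_release(prof)
  q_true <- rel$q[match(schedule, save_times)]
  q_obs <- q_true + stats::rnorm(length(schedule), 0, sds)
  clipped <- q_obs < 0 | q_obs > 100
  q_obs <- pmin(100, pmax(0, q_obs))
  structure(list(times = schedule, q_obs = q_obs, q_true = q_true,
                 sd = sds, true_params = true_params,
                 seed = seed, clipped = clipped),
            class = c("cs_synthetic", "cs_observed"))
}

#' @export
print.cs_synthetic <- function(x, ...) {
  cat(sprintf("synthetic release data: %d points over [%g, %g] days, noise sd %g%%",
              length(x$times), min(x$times), max(x$times), x$sd[1]))
  if (any(x$clipped)) cat(sprintf(" (%d clipped)", sum(x$clipped)))
  cat("\n")
  invisible(x)
}

#' Write observed (or synthetic) release data as CSV
#'
#' Emits the dialect [read_observed_release()] reads: `time_days`,
#' `q_pct` and, when standard deviations are present, `sd_pct`.
#'
#' @param data A [observed_release()] or [generate_observations()]
#'   object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_observed_csv <- function(data, path) {
  stopifnot(inherits(data, "cs_observed"))
  df <- data.frame(time_days = data$times, q_pct = data$q_obs)
  if (!is.null(data$sd)) df$sd_pct <- data$sd
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
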