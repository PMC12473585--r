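# Release metrics: residual-mass quadrature, cumulative release Q(t),
# daily release rate, and the threshold metrics used for design.

# Composite Simpson on uniformly spaced samples; when the interval count
# is odd the final sub-interval falls back to the trapezoid rule.
simpson_uniform <- function(f, h) {
  n <- length(f) - 1L
  stopifnot(n >= 1L)
  if (n == 1L) return((f[1] + f[2]) * h / 2)
  simp <- function(g) {
    m <- length(g) - 1L # even
    s <- g[1] + g[m + 1L] + 4 * sum(g[seq(2L, m, 2L)])
    if (m > 2L) s <- s + 2 * sum(g[seq(3L, m - 1L, 2L)])
    s * h / 3
  }
  if (n %% 2L == 0L) simp(f) else simp(f[seq_len(n)]) + (f[n] + f[n + 1L]) * h / 2
}

#' Residual-mass integral of a state
#'
#' Evaluates `integral C(r) r^2 dr` over the normalised sphere by
#' composite Simpson quadrature, layer by layer. The two layers are
#' integrated separately because their spacings differ and the
#' concentration is discontinuous at the interface: the core integral
#' uses the core-side interface value (`kappa` times the shell-side
#' unknown) and the shell integral the shell-side value. The constant
#' angular prefactor `4*pi` is omitted - it cancels in the cumulative
#' release ratio.
#'
#' @param state A `cs_state` vector (see [initial_state()], [state_at()]).
#' @param grid,kappa Taken from the state attributes when omitted.
#' @return The dimensionless mass integral.
#' @export
shell_weighted_mass <- function(state, grid = attr(state, "grid"),
                                kappa = attr(state, "kappa")) {
  s <- split_state(state, grid, kappa)
  core <- s$core_values * grid$node_core^2
  shell <- s$shell_values * grid$node_shell^2
  simpson_uniform(core, grid$dr_core) + simpson_uniform(shell, grid$dr_shell)
}

#' Cumulative release curve
#'
#' `Q(t) = B + (100 - B) * (1 - M(t)/M(0))` where `M` is the residual
#' mass integral and `B` the burst percentage: the diffusion solution
#' evolves the post-burst load, and the burst re-enters only here.
#'
#' @param profile A [solve_concentration()] result (must include t = 0).
#' @param burst Burst percentage; defaults to the profile's transport
#'   parameters.
#' @return An object of class `cs_release`: `times` (days) and `q` (%).
#' @export
cumulative_release <- function(profile, burst = profile$params$burst) {
  stopifnot(inherits(profile, "cs_profile"))
  if (profile$times[1] != 0) stop("profile must include t = 0", call. = FALSE)
  stopifnot(burst >= 0, burst < 100)
  mass <- vapply(seq_along(profile$times),
                 function(k) shell_weighted_mass(state_at(profile, k)),
                 numeric(1))
  if (mass[1] <= 0) stop("zero initial mass: nothing to release", call. = FALSE)
  q <- burst + (100 - burst) * (1 - mass / mass[1])
  structure(list(times = profile$times, q = q, burst = burst),
            class = "cs_release")
}

#' @export
print.cs_release <- function(x, ...) {
  cat(sprintf("cumulative release: Q(0) = %.2f%%, Q(%g d) = %.2f%% over %d times\n",
              x$q[1], max(x$times), x$q[length(x$q)], length(x$times)))
  invisible(x)
}

#' Daily release rate curve
#'
#' Backward-difference release rate
#' `rate(t) = (Q(t) - Q(t - dt)) * a_load0 / 100 / dt` in ug/day.
#' The rate is undefined at t = 0 (the burst is instantaneous), so the
#' curve starts at the first spacing.
#'
#' @param curve A [cumulative_release()] result.
#' @param dose A [dose_spec()] object.
#' @param dt Differencing interval in days; must be representable on the
#'   saved time grid.
#' @return An object of class `cs_rate`: `times` (> 0), `rate` (ug/day),
#'   `dt`.
#' @export
release_rate <- function(curve, dose, dt = 1) {
  stopifnot(inherits(curve, "cs_release"), inherits(dose, "cs_dose"), dt > 0)
  t <- curve$times
  targets <- t[t >= dt]
  q_at <- function(tt) {
    i <- match(TRUE, abs(t - tt) < 1e-9)
    if (is.na(i)) NA_real_ else curve$q[i]
  }
  q_hi <- vapply(targets, q_at, numeric(1))
  q_lo <- vapply(targets - dt, q_at, numeric(1))
  if (anyNA(q_lo) || anyNA(q_hi)) {
    stop("'dt' is not representable on the saved time grid; ",
         "re-save the profile on a grid commensurate with dt", call. = FALSE)
  }
  structure(list(times = targets,
                 rate = (q_hi - q_lo) * dose$a_load0 / 100 / dt,
                 dt = dt),
            class = "cs_rate")
}

#' @export
print.cs_rate <- function(x, ...) {
  cat(sprintf("release rate (dt = %g d): %.3g ug/day at t = %g d down to %.3g ug/day at t = %g d\n",
              x$dt, x$rate[1], x$times[1],
              x$rate[length(x$rate)], max(x$times)))
  invisible(x)
}

#' First time the cumulative release crosses a threshold
#'
#' Linear interpolation between the bracketing saved times; `NA` when the
#' threshold is never reached within the saved horizon. The bracketing
#' integer-day pair is attached as attribute `"bracket"`.
#'
#' @param curve A [cumulative_release()] result.
#' @param q_threshold Threshold in percent, `0 < q_threshold <= 100`.
#' @return Crossing time in days (0 when the burst alone meets the
#'   threshold), or `NA_real_`.
#' @export
time_to_release_threshold <- function(curve, q_threshold) {
  stopifnot(inherits(curve, "cs_release"),
            q_threshold > 0, q_threshold <= 100)
  q <- curve$q
  t <- curve$times
  if (q[1] >= q_threshold) {
    return(structure(0, bracket = c(0, 0)))
  }
  idx <- match(TRUE, q >= q_threshold)
  if (is.na(idx)) return(NA_real_)
  t_cross <- t[idx - 1L] +
    (q_threshold - q[idx - 1L]) / (q[idx] - q[idx - 1L]) * (t[idx] - t[idx - 1L])
  structure(t_cross, bracket = c(t[idx - 1L], t[idx]))
}

#' Duration above a release-rate threshold
#'
#' Total time for which the daily release rate is at or above a
#' therapeutic threshold, with crossing times located by linear
#' interpolation between samples. The rate is undefined at t = 0 (the
#' burst is instantaneous), so the measure is taken over the sampled
#' domain `[dt, horizon]`. A tolerance band around the threshold (default
#' +/-10%) yields the interval between the downward crossings of
#' `(1+band)*threshold` and `(1-band)*threshold`.
#'
#' @param rates A [release_rate()] result.
#' @param threshold Rate threshold, ug/day (> 0).
#' @param band Fractional tolerance band (>= 0).
#' @return A list: `duration` (days), `band_interval` (times of the final
#'   downward crossings of the upper and lower band edges, days), and
#'   `crossings` (all threshold crossing times).
#' @export
duration_above_rate_threshold <- function(rates, threshold, band = 0.10) {
  stopifnot(inherits(rates, "cs_rate"), threshold > 0, band >= 0)
  t <- rates$times
  r <- rates$rate
  above_measure <- function(thr) {
    above <- r >= thr
    total <- 0
    crossings <- numeric(0)
    for (k in seq_len(length(t) - 1L)) {
      a <- above[k]
      b <- above[k + 1L]
      if (a && b) {
        total <- total + (t[k + 1L] - t[k])
      } else if (a != b) {
        tc <- t[k] + (thr - r[k]) / (r[k + 1L] - r[k]) * (t[k + 1L] - t[k])
        crossings <- c(crossings, tc)
        total <- total + if (a) tc - t[k] else t[k + 1L] - tc
      }
    }
    list(measure = total, crossings = crossings)
  }
  main <- above_measure(threshold)
  last_cross <- function(thr) {
    cr <- above_measure(thr)$crossings
    if (length(cr)) cr[length(cr)] else NA_real_
  }
  list(duration = main$measure,
       band_interval = c(upper = last_cross((1 + band) * threshold),
                         lower = last_cross((1 - band) * threshold)),
       crossings = main$crossings)
}

#' Write a release or rate curve as CSV
#'
#' @param x A `cs_release` or `cs_rate` object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_release_csv <- function(x, path) {
  df <- if (inherits(x, "cs_release")) {
    data.frame(time_days = x$times, Q_pct = x$q)
  } else if (inherits(x, "cs_rate")) {
    data.frame(time_days = x$times, rate_ug_per_day = x$rate)
  } else {
    stop("'x' must be a cs_release or cs_rate object", call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
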