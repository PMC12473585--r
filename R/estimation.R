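# Least-squares estimation of {burst, d_core} from observed cumulative
# release, with d_shell and kappa fixed (the identifiable reduction in
# the core-limited regime). Multi-start Levenberg-Marquardt with Latin
# hypercube initial guesses.

#' Observed cumulative-release data
#'
#' @param times Measurement times, days, strictly increasing.
#' @param q_obs Observed cumulative release, percent, in `[0, 100]`.
#' @param sd Optional per-point measurement standard deviations, percent.
#' @return An object of class `cs_observed`.
#' @export
observed_release <- function(times, q_obs, sd = NULL) {
  stopifnot(is.numeric(times), is.numeric(q_obs),
            length(times) == length(q_obs), length(times) >= 1L)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  if (any(q_obs < 0 | q_obs > 100)) stop("'q_obs' must lie in [0, 100]", call. = FALSE)
  if (!is.null(sd)) stopifnot(length(sd) == length(times), all(sd >= 0))
  structure(list(times = as.numeric(times), q_obs = as.numeric(q_obs), sd = sd),
            class = "cs_observed")
}

#' Read observed release data from CSV
#'
#' Expects columns `time_days`, `q_pct` and optionally `sd_pct` (the same
#' dialect [write_observed_csv()] emits).
#'
#' @param path CSV path.
#' @return A [observed_release()] object.
#' @export
read_observed_release <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_days", "q_pct") %in% names(df))) {
    stop("observed-release CSV must have columns 'time_days' and 'q_pct'",
         call. = FALSE)
  }
  observed_release(df$time_days, df$q_pct,
                   sd = if ("sd_pct" %in% names(df)) df$sd_pct else NULL)
}

#' Estimation context: everything held fixed during fitting
#'
#' The reduced two-parameter problem fixes the partition coefficient and
#' ties the shell diffusivity to the core one (`d_shell =
#' d_shell_ratio * d_core`); geometry, grid resolution and solver
#' tolerances are also frozen here.
#'
#' @param geom A [geometry()] object.
#' @param kappa Fixed partition coefficient.
#' @param d_shell_ratio Fixed ratio `d_shell / d_core`.
#' @param n_core Core interval count of the solver grid.
#' @param rel_tol,abs_tol Integrator tolerances.
#' @return An object of class `cs_context`.
#' @export
estimation_context <- function(geom, kappa = 1, d_shell_ratio = 1000,
                               n_core = 100L, rel_tol = 1e-6, abs_tol = 1e-9) {
  stopifnot(inherits(geom, "cs_geometry"), kappa > 0, d_shell_ratio > 0)
  structure(list(geom = geom, kappa = kappa, d_shell_ratio = d_shell_ratio,
                 n_core = as.integer(n_core),
                 rel_tol = rel_tol, abs_tol = abs_tol),
            class = "cs_context")
}

# Model cumulative release at the observation times for a (burst, d_core)
# fragment under a fixed context.
model_release_at <- function(fragment, times, context) {
  params <- transport_params(d_core = fragment[["d_core"]],
                             d_shell = context$d_shell_ratio * fragment[["d_core"]],
                             kappa = context$kappa,
                             burst = fragment[["burst"]])
  save_times <- sort(unique(c(0, times)))
  settings <- solver_settings(rel_tol = context$rel_tol, abs_tol = context$abs_tol,
                              save_times = save_times)
  prof <- solve_concentration(context$geom, params, settings = settings,
                              n_core = context$n_core)
  rel <- cumulative_release(prof)
  rel$q[match(times, save_times)]
}

#' Default parameter bounds for the reduced fit
#'
#' Burst in `[0, 20]` percent and core diffusivity in
#' `[1e-15, 1e-13]` cm^2/s.
#'
#' @return A list with elements `burst` and `d_core`, each `c(lower,
#'   upper)`.
#' @export
default_fit_bounds <- function() {
  list(burst = c(0, 20), d_core = c(1e-15, 1e-13))
}

#' Sum-of-squares objective of the reduced fit
#'
#' `sum_i (Q_model(t_i) - q_obs_i)^2` in squared percentage units, with
#' the model evaluated under the fixed context. Parameters outside the
#' bounds return a smooth penalty (optimiser-safe) instead of a model
#' evaluation.
#'
#' @param fragment Named vector or list with `burst` (%) and `d_core`
#'   (cm^2/s).
#' @param data A [observed_release()] object.
#' @param context A [estimation_context()] object.
#' @param bounds Parameter box, see [default_fit_bounds()].
#' @return Scalar sum of squared residuals.
#' @export
sse_objective <- function(fragment, data, context, bounds = default_fit_bounds()) {
  stopifnot(inherits(data, "cs_observed"), inherits(context, "cs_context"))
  fragment <- unlist(fragment)[c("burst", "d_core")]
  viol <- max(0, bounds$burst[1] - fragment[["burst"]],
              fragment[["burst"]] - bounds$burst[2]) / diff(bounds$burst) +
    max(0, bounds$d_core[1] - fragment[["d_core"]],
        fragment[["d_core"]] - bounds$d_core[2]) / diff(bounds$d_core)
  if (viol > 0) {
    warning("parameters outside bounds; returning penalty objective", call. = FALSE)
    return(1e8 * (1 + viol))
  }
  resid <- model_release_at(fragment, data$times, context) - data$q_obs
  sum(resid^2)
}

# One bound-constrained Levenberg-Marquardt start in scaled parameter
# space. Scaling: each parameter divided by its scale so that the range
# maximum maps to 1 ("range_max") or the range midpoint maps to 1
# ("midpoint"). If the search converges onto a bound it is restarted once
# from a point nudged into the interior: the projected LM update can pin
# a parameter against a box edge inside a correlated valley even when the
# objective still decreases inward.
lm_single_start <- function(start, data, context, bounds, scaling, ftol, maxfev) {
  scale_of <- function(b) if (scaling == "range_max") b[2] else mean(b)
  sc <- c(burst = scale_of(bounds$burst), d_core = scale_of(bounds$d_core))
  lo <- c(bounds$burst[1], bounds$d_core[1]) / sc
  hi <- c(bounds$burst[2], bounds$d_core[2]) / sc
  resid_fn <- function(theta) {
    frag <- c(burst = theta[[1]] * sc[["burst"]],
              d_core = theta[[2]] * sc[["d_core"]])
    model_release_at(frag, data$times, context) - data$q_obs
  }
  # epsfcn tells the finite-difference Jacobian about the noise floor of
  # the residuals (the ODE integration error); without it the default
  # machine-epsilon step sizes produce derivative estimates that are pure
  # integrator noise and the search stalls far from the optimum
  ctl <- minpack.lm::nls.lm.control(ftol = ftol, ptol = ftol, maxfev = maxfev,
                                    epsfcn = context$rel_tol)
  run_lm <- function(theta0) {
    try(minpack.lm::nls.lm(par = theta0, lower = lo, upper = hi,
                           fn = resid_fn, control = ctl),
        silent = TRUE)
  }
  fit <- run_lm(c(start[["burst"]], start[["d_core"]]) / sc)
  if (!inherits(fit, "try-error")) {
    on_bound <- fit$par <= lo + 1e-9 | fit$par >= hi - 1e-9
    if (any(on_bound)) {
      nudge <- pmin(hi - 0.05 * (hi - lo), pmax(lo + 0.05 * (hi - lo), fit$par))
      refit <- run_lm(nudge)
      if (!inherits(refit, "try-error") && refit$deviance < fit$deviance) {
        fit <- refit
      }
    }
  }
  if (inherits(fit, "try-error")) {
    return(list(converged = FALSE, burst = NA_real_, d_core = NA_real_,
                sse = NA_real_))
  }
  list(converged = fit$info %in% 1:4,
       burst = fit$par[1] * sc[["burst"]],
       d_core = fit$par[2] * sc[["d_core"]],
       sse = fit$deviance)
}

#' Multi-start least-squares fit of burst and core diffusivity
#'
#' Draws `n_starts` initial guesses by Latin hypercube sampling
#' (log-uniform in `d_core` over its bounds; log-uniform in burst over
#' `[max(0.1, lower), upper]`, since a log scale is undefined at a zero
#' lower bound - the optimiser may still move to 0), runs a
#' bound-constrained Levenberg-Marquardt fit from each, marks the starts
#' whose converged error is within 5% of the minimum as accepted, and
#' reports both the accepted-average and the best parameter sets.
#'
#' @param data A [observed_release()] object.
#' @param context A [estimation_context()] object.
#' @param bounds Parameter box, see [default_fit_bounds()].
#' @param n_starts Number of starts (>= 2, default 50).
#' @param seed Optional RNG seed.
#' @param scaling Parameter scaling convention: `"range_max"` (range
#'   maximum maps to 1, the default) or `"midpoint"`.
#' @param ftol Optimiser stopping tolerance (default 1e-3).
#' @param maxfev Maximum objective evaluations per start (default 800).
#' @param accept_tol Relative acceptance window around the minimum error
#'   (default 0.05).
#' @return An object of class `cs_fit`: `starts` (data frame of initial
#'   guesses, converged parameters and errors), `accepted` mask,
#'   `average_params`, `best_params`, `best_sse`, and the `fixed`
#'   quantities.
#' @export
multistart_fit <- function(data, context, bounds = default_fit_bounds(),
                           n_starts = 50L, seed = NULL,
                           scaling = c("range_max", "midpoint"),
                           ftol = 1e-3, maxfev = 800L, accept_tol = 0.05) {
  stopifnot(inherits(data, "cs_observed"), inherits(context, "cs_context"),
            n_starts >= 2L)
  scaling <- match.arg(scaling)
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(as.integer(n_starts), 2L)
  b_lo <- max(0.1, bounds$burst[1])
  starts <- data.frame(
    burst0 = 10^(log10(b_lo) + u[, 1] * (log10(bounds$burst[2]) - log10(b_lo))),
    d_core0 = 10^(log10(bounds$d_core[1]) +
                    u[, 2] * (log10(bounds$d_core[2]) - log10(bounds$d_core[1]))))
  res <- lapply(seq_len(nrow(starts)), function(i) {
    lm_single_start(c(burst = starts$burst0[i], d_core = starts$d_core0[i]),
                    data, context, bounds, scaling, ftol, maxfev)
  })
  starts$burst <- vapply(res, `[[`, numeric(1), "burst")
  starts$d_core <- vapply(res, `[[`, numeric(1), "d_core")
  starts$sse <- vapply(res, `[[`, numeric(1), "sse")
  starts$converged <- vapply(res, `[[`, logical(1), "converged")
  ok <- starts$converged & is.finite(starts$sse)
  if (!any(ok)) {
    stop("no start converged; inspect the data and bounds", call. = FALSE)
  }
  best_sse <- min(starts$sse[ok])
  accepted <- ok & starts$sse <= (1 + accept_tol) * best_sse
  best <- which(ok)[which.min(starts$sse[ok])]
  structure(
    list(starts = starts,
         accepted = accepted,
         average_params = c(burst = mean(starts$burst[accepted]),
                            d_core = mean(starts$d_core[accepted])),
         best_params = c(burst = starts$burst[best],
                         d_core = starts$d_core[best]),
         best_sse = best_sse,
         fixed = list(kappa = context$kappa,
                      d_shell_ratio = context$d_shell_ratio),
         bounds = bounds, scaling = scaling, n_starts = n_starts),
    class = "cs_fit")
}

#' @export
print.cs_fit <- function(x, ...) {
  cat(sprintf("multi-start fit: %d starts, %d accepted (error within 5%% of minimum)\n",
              x$n_starts, sum(x$accepted)))
  cat(sprintf("  best:    burst = %.3g%%, d_core = %.4g cm2/s (sse = %.4g)\n",
              x$best_params[["burst"]], x$best_params[["d_core"]], x$best_sse))
  cat(sprintf("  average: burst = %.3g%%, d_core = %.4g cm2/s\n",
              x$average_params[["burst"]], x$average_params[["d_core"]]))
  cat(sprintf("  fixed:   kappa = %g, d_shell = %g * d_core\n",
              x$fixed$kappa, x$fixed$d_shell_ratio))
  invisible(x)
}
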