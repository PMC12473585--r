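# Parameter sensitivity of cumulative release: local normalised
# one-at-a-time derivatives, Morris elementary-effects screening, and
# Saltelli/Jansen Sobol variance-based indices. The parameter vector is
# p = (burst, d_core, d_shell, kappa) throughout.

cs_param_names <- c("burst", "d_core", "d_shell", "kappa")

params_to_vector <- function(params) {
  stopifnot(inherits(params, "cs_transport"))
  c(burst = params$burst, d_core = params$d_core,
    d_shell = params$d_shell, kappa = params$kappa)
}

vector_to_params <- function(p) {
  transport_params(d_core = p[["d_core"]], d_shell = p[["d_shell"]],
                   kappa = p[["kappa"]], burst = p[["burst"]])
}

#' Build a cumulative-release model function for sensitivity analysis
#'
#' Returns a closure mapping a [transport_params()] object to the
#' cumulative release percentage `Q(target_time)` for a fixed geometry,
#' suitable as the `model_fn` argument of the sensitivity routines.
#'
#' @param geom A [geometry()] object.
#' @param target_time Evaluation time, days (default 28).
#' @param n_core Core interval count of the solver grid.
#' @param rel_tol,abs_tol Integrator tolerances.
#' @return `function(params) -> Q(target_time)` in percent.
#' @export
release_model_fn <- function(geom, target_time = 28, n_core = 100L,
                             rel_tol = 1e-6, abs_tol = 1e-9) {
  stopifnot(inherits(geom, "cs_geometry"), target_time > 0)
  settings <- solver_settings(rel_tol = rel_tol, abs_tol = abs_tol,
                              save_times = c(0, target_time))
  function(params) {
    prof <- solve_concentration(geom, params, settings = settings,
                                n_core = n_core)
    rel <- cumulative_release(prof)
    rel$q[length(rel$q)]
  }
}

#' Local normalised one-at-a-time sensitivity
#'
#' Perturbs each parameter upward by a fraction `perturbation` (default
#' 1%) and returns the normalised forward-difference sensitivity
#' `(f(p_k * (1 + d)) - f(p)) / (d * f(p))` per parameter. The sign is
#' kept; rank parameters by absolute value.
#'
#' @param model_fn A function mapping [transport_params()] to a scalar
#'   output (see [release_model_fn()]).
#' @param baseline Baseline [transport_params()].
#' @param perturbation Relative perturbation (> 0, default 0.01).
#' @return Named numeric vector over `burst`, `d_core`, `d_shell`,
#'   `kappa`.
#' @export
local_normalized_sensitivity <- function(model_fn, baseline, perturbation = 0.01) {
  stopifnot(is.function(model_fn), inherits(baseline, "cs_transport"),
            perturbation > 0)
  p0 <- params_to_vector(baseline)
  f0 <- model_fn(baseline)
  if (!is.finite(f0) || f0 == 0) {
    stop("baseline model output is zero or non-finite: normalised ",
         "sensitivity is undefined", call. = FALSE)
  }
  out <- vapply(cs_param_names, function(nm) {
    p <- p0
    p[nm] <- p[nm] * (1 + perturbation)
    (model_fn(vector_to_params(p)) - f0) / (perturbation * f0)
  }, numeric(1))
  setNames(out, cs_param_names)
}

#' Morris elementary-effects screening
#'
#' Standard Morris one-at-a-time screening over the hyperbox
#' `[(1 - rel_bound) * p, (1 + rel_bound) * p]` around the baseline
#' (default +/-1%). Each trajectory draws a base point on a uniform grid
#' of `levels` levels and perturbs each parameter once by
#' `delta = levels / (2 * (levels - 1))` in unit-cube coordinates; the
#' elementary effects are summarised by `mu_star` (mean absolute effect)
#' and `sigma` (their standard deviation).
#'
#' @inheritParams local_normalized_sensitivity
#' @param rel_bound Half-width of the relative parameter box (> 0).
#' @param n_trajectories Number of trajectories (>= 4).
#' @param levels Number of grid levels (even, >= 4).
#' @param seed Optional RNG seed for reproducibility.
#' @return A list with named vectors `mu_star` and `sigma` and the matrix
#'   of elementary effects.
#' @export
morris_screening <- function(model_fn, baseline, rel_bound = 0.01,
                             n_trajectories = 10L, levels = 4L, seed = NULL) {
  stopifnot(is.function(model_fn), inherits(baseline, "cs_transport"),
            n_trajectories >= 4L, levels >= 4L)
  if (rel_bound <= 0) stop("degenerate bounds: 'rel_bound' must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p0 <- params_to_vector(baseline)
  lo <- (1 - rel_bound) * p0
  hi <- (1 + rel_bound) * p0
  k <- length(p0)
  delta <- levels / (2 * (levels - 1))
  base_levels <- seq(0, 1 - delta, length.out = levels / 2) # grid points with room for +delta
  eval_unit <- function(x) {
    p <- lo + x * (hi - lo)
    model_fn(vector_to_params(setNames(p, cs_param_names)))
  }
  ee <- matrix(NA_real_, n_trajectories, k, dimnames = list(NULL, cs_param_names))
  for (tr in seq_len(n_trajectories)) {
    x <- setNames(sample(base_levels, k, replace = TRUE), cs_param_names)
    f_cur <- eval_unit(x)
    for (nm in sample(cs_param_names)) {
      x2 <- x
      x2[nm] <- x[nm] + delta
      f_new <- eval_unit(x2)
      ee[tr, nm] <- (f_new - f_cur) / delta
      x <- x2
      f_cur <- f_new
    }
  }
  list(mu_star = apply(abs(ee), 2, mean),
       sigma = apply(ee, 2, stats::sd),
       elementary_effects = ee)
}

#' Sobol variance-based sensitivity indices
#'
#' First-order and total Sobol indices of the model output with respect
#' to the four transport parameters, each sampled from an independent
#' normal distribution centred on its baseline with relative standard
#' deviation `rel_sd`, truncated to `+/- rel_bound` (defaults: 1% sd
#' truncated at +/-1%). Uniform Saltelli samples are mapped through the
#' truncated-normal inverse CDF; first-order indices use the Saltelli
#' (2010) estimator and total indices the Jansen estimator.
#'
#' @inheritParams morris_screening
#' @param rel_sd Relative standard deviation of the parameter
#'   distribution.
#' @param n_base_samples Saltelli base sample size (>= 128); the model is
#'   evaluated `n_base_samples * (k + 2)` times.
#' @return A list with named vectors `first` and `total`, the output
#'   variance, and `degenerate` (TRUE when the output variance is zero,
#'   in which case the indices are `NA`).
#' @export
sobol_indices <- function(model_fn, baseline, rel_sd = 0.01, rel_bound = 0.01,
                          n_base_samples = 128L, seed = NULL) {
  stopifnot(is.function(model_fn), inherits(baseline, "cs_transport"),
            n_base_samples >= 128L, rel_sd > 0, rel_bound > 0)
  if (!is.null(seed)) set.seed(seed)
  p0 <- params_to_vector(baseline)
  k <- length(p0)
  n <- as.integer(n_base_samples)

  # inverse CDF of a normal truncated at +/- rel_bound (in relative units)
  z <- rel_bound / rel_sd
  plo <- stats::pnorm(-z)
  phi <- stats::pnorm(z)
  map_unit <- function(u, nm) {
    rel <- stats::qnorm(plo + u * (phi - plo)) * rel_sd
    p0[[nm]] * (1 + rel)
  }
  eval_mat <- function(U) {
    apply(U, 1, function(u) {
      p <- vapply(seq_len(k), function(j) map_unit(u[j], cs_param_names[j]),
                  numeric(1))
      model_fn(vector_to_params(setNames(p, cs_param_names)))
    })
  }

  A <- matrix(stats::runif(n * k), n, k)
  B <- matrix(stats::runif(n * k), n, k)
  fA <- eval_mat(A)
  fB <- eval_mat(B)
  V <- stats::var(c(fA, fB))
  if (!is.finite(V) || V <= 0) {
    na <- setNames(rep(NA_real_, k), cs_param_names)
    return(list(first = na, total = na, variance = V, degenerate = TRUE))
  }
  # centre the outputs: the raw Saltelli first-order estimator is badly
  # biased when the output mean dwarfs its spread
  f0 <- mean(c(fA, fB))
  fAc <- fA - f0
  fBc <- fB - f0
  first <- total <- setNames(numeric(k), cs_param_names)
  for (j in seq_len(k)) {
    ABj <- A
    ABj[, j] <- B[, j]
    fABj <- eval_mat(ABj) - f0
    first[j] <- mean(fBc * (fABj - fAc)) / V
    total[j] <- mean((fAc - fABj)^2) / (2 * V)
  }
  list(first = first, total = total, variance = V, degenerate = FALSE)
}

#' Reference diffusivity regimes for sensitivity studies
#'
#' Three canonical regimes of the relative layer diffusivities (all with
#' burst 10% and kappa 1): `"core-limited"` (`d_core = 1e-15`,
#' `d_shell = 1000 * d_core`), `"equal"` (both `1e-14`), and
#' `"shell-limited"` (`d_core = 1e-12`, `d_shell = 0.001 * d_core`),
#' cm^2/s.
#'
#' @param regime Regime name.
#' @return A [transport_params()] object.
#' @export
regime_params <- function(regime = c("core-limited", "equal", "shell-limited")) {
  regime <- match.arg(regime)
  switch(regime,
         "core-limited" = transport_params(1e-15, 1e-12, kappa = 1, burst = 10),
         "equal" = transport_params(1e-14, 1e-14, kappa = 1, burst = 10),
         "shell-limited" = transport_params(1e-12, 1e-15, kappa = 1, burst = 10))
}
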