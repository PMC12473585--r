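# Frequentist uncertainty for the fitted parameters: finite-difference
# sensitivity matrix, sandwich covariance, Student-t intervals.

#' Finite-difference sensitivity matrix of the release curve
#'
#' Forward-difference Jacobian of the modelled cumulative release at the
#' observation times with respect to the estimated parameters (raw,
#' un-normalised `dQ/dp`), using a relative perturbation per parameter.
#'
#' @param fragment Named vector with `burst` and `d_core`.
#' @param times Observation times, days (nonempty).
#' @param context A [estimation_context()] object.
#' @param perturbation Relative perturbation (default 0.01).
#' @return Matrix of size `length(times) x 2` with columns `burst`,
#'   `d_core`.
#' @export
sensitivity_matrix_at <- function(fragment, times, context, perturbation = 0.01) {
  stopifnot(length(times) >= 1L, inherits(context, "cs_context"),
            perturbation > 0)
  fragment <- unlist(fragment)[c("burst", "d_core")]
  f0 <- model_release_at(fragment, times, context)
  if (any(!is.finite(f0))) stop("non-finite model output at baseline", call. = FALSE)
  S <- vapply(names(fragment), function(nm) {
    p <- fragment
    dp <- if (p[[nm]] != 0) p[[nm]] * perturbation else perturbation
    p[[nm]] <- p[[nm]] + dp
    f1 <- model_release_at(p, times, context)
    if (any(!is.finite(f1))) stop("non-finite model output at perturbed point",
                                  call. = FALSE)
    (f1 - f0) / dp
  }, numeric(length(times)))
  dimnames(S) <- list(NULL, names(fragment))
  S
}

#' Sandwich covariance of the estimated parameters
#'
#' `cov(p) = (S'S)^{-1} S' psi S (S'S)^{-1}` computed through a QR
#' factorisation of `S` (no explicit inverse), where `psi` is the
#' covariance of the observed release data.
#'
#' @param S Sensitivity matrix (`n_times x n_params`).
#' @param psi Data covariance matrix (`n_times x n_times`), symmetric
#'   positive semidefinite.
#' @return Parameter covariance matrix (`n_params x n_params`).
#' @export
parameter_covariance <- function(S, psi) {
  S <- as.matrix(S)
  psi <- as.matrix(psi)
  stopifnot(nrow(psi) == nrow(S), ncol(psi) == nrow(S))
  if (max(abs(psi - t(psi))) > 1e-8 * max(1, max(abs(psi)))) {
    stop("'psi' must be symmetric", call. = FALSE)
  }
  qrS <- qr(S)
  if (qrS$rank < ncol(S)) {
    stop("rank-deficient sensitivity matrix: the parameters are not ",
         "jointly identifiable from these observation times", call. = FALSE)
  }
  # P = (S'S)^{-1} S' as the least-squares solve S P' = I restricted to col space
  P <- qr.coef(qrS, diag(nrow(S)))
  cov <- P %*% psi %*% t(P)
  dimnames(cov) <- list(colnames(S), colnames(S))
  (cov + t(cov)) / 2
}

#' Student-t confidence half-widths
#'
#' Half-width per parameter: `t((1 + level)/2, dof) * sd` with
#' `dof = n_data - n_params`.
#'
#' @param cov Parameter covariance matrix.
#' @param n_data Number of observations.
#' @param n_params Number of estimated parameters.
#' @param level Confidence level (default 0.95).
#' @return Named vector of half-widths.
#' @export
confidence_intervals <- function(cov, n_data, n_params = ncol(cov), level = 0.95) {
  dof <- n_data - n_params
  if (dof <= 0) stop("degrees of freedom must be positive (n_data > n_params)",
                     call. = FALSE)
  sds <- sqrt(pmax(0, diag(as.matrix(cov))))
  stats::qt((1 + level) / 2, df = dof) * sds
}

#' Uncertainty report for a completed fit
#'
#' Builds the data covariance `psi` (diagonal, from per-point observed
#' standard deviations when supplied, else a constant variance estimated
#' from the fit residuals), the sensitivity matrix at the fitted
#' parameters, the sandwich covariance and the Student-t intervals.
#'
#' @param fit A [multistart_fit()] result.
#' @param data The [observed_release()] data that produced the fit.
#' @param context The [estimation_context()] used.
#' @param which Use the `"average"` (default) or `"best"` parameter set.
#' @param level Confidence level.
#' @return An object of class `cs_uncertainty`: `params`, `S`, `psi`,
#'   `cov`, `sd`, `ci_half_width`, `level`, `dof`.
#' @export
fit_uncertainty <- function(fit, data, context, which = c("average", "best"),
                            level = 0.95) {
  stopifnot(inherits(fit, "cs_fit"), inherits(data, "cs_observed"),
            inherits(context, "cs_context"))
  which <- match.arg(which)
  params <- if (which == "average") fit$average_params else fit$best_params
  n <- length(data$times)
  p <- length(params)
  S <- sensitivity_matrix_at(params, data$times, context)
  if (!is.null(data$sd)) {
    psi <- diag(data$sd^2, n)
  } else {
    resid <- model_release_at(params, data$times, context) - data$q_obs
    psi <- diag(rep(sum(resid^2) / max(1L, n - p), n), n)
  }
  cov <- parameter_covariance(S, psi)
  hw <- confidence_intervals(cov, n_data = n, n_params = p, level = level)
  structure(list(params = params, S = S, psi = psi, cov = cov,
                 sd = sqrt(pmax(0, diag(cov))),
                 ci_half_width = setNames(hw, names(params)),
                 level = level, dof = n - p),
            class = "cs_uncertainty")
}

#' @export
print.cs_uncertainty <- function(x, ...) {
  cat(sprintf("parameter uncertainty (%g%% CI, %d dof):\n", 100 * x$level, x$dof))
  for (nm in names(x$params)) {
    cat(sprintf("  %s = %.4g +/- %.4g\n", nm, x$params[[nm]], x$ci_half_width[[nm]]))
  }
  invisible(x)
}
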