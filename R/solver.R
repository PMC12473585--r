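#' Time-integration settings
#'
#' @param rel_tol,abs_tol Relative and absolute integrator tolerances.
#' @param save_times Output times in days; strictly increasing, starting
#'   at 0.
#' @param max_step Optional maximum internal step, days.
#' @return An object of class `cs_solver_settings`.
#' @export
solver_settings <- function(rel_tol = 1e-6, abs_tol = 1e-9,
                            save_times = 0:180, max_step = NULL) {
  stopifnot(rel_tol > 0, abs_tol > 0, length(save_times) >= 2L)
  if (save_times[1] != 0) stop("'save_times' must start at 0", call. = FALSE)
  if (any(diff(save_times) <= 0)) {
    stop("'save_times' must be strictly increasing", call. = FALSE)
  }
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 save_times = as.numeric(save_times), max_step = max_step),
            class = "cs_solver_settings")
}

#' Solve the two-layer diffusion model
#'
#' Integrates the method-of-lines system in time with `deSolve`'s `lsoda`
#' (automatic nonstiff/stiff switching; the shell layer makes the system
#' stiff whenever `d_shell >> d_core`), using the exact linear-operator
#' Jacobian. Time is integrated in days; the scaled rates are converted
#' from 1/s accordingly.
#'
#' @param geom A [geometry()] object.
#' @param params A [transport_params()] object.
#' @param grid A [build_grid()] result, or `NULL` for the default
#'   matched-spacing grid with `n_core` core intervals.
#' @param settings A [solver_settings()] object.
#' @param loading Initial loading, see [initial_state()].
#' @param n_core Core interval count used when `grid` is `NULL`.
#' @return An object of class `cs_profile`: `times` (days), `states`
#'   (matrix, one column of ODE unknowns per saved time), plus the
#'   `grid`, `params`, `geometry` and `loading` used.
#' @examples
#' geom <- geometry(5.10, 1.25)
#' par <- transport_params(2.6e-15, 2.6e-12, kappa = 1, burst = 10)
#' prof <- solve_concentration(geom, par,
#'                             settings = solver_settings(save_times = 0:30))
#' @export
solve_concentration <- function(geom, params, grid = NULL,
                                settings = solver_settings(),
                                loading = c("core", "uniform"),
                                n_core = 100L) {
  stopifnot(inherits(geom, "cs_geometry"), inherits(params, "cs_transport"),
            inherits(settings, "cs_solver_settings"))
  loading <- match.arg(loading)
  if (is.null(grid)) grid <- build_grid(geom, n_core = n_core)
  alpha <- alpha_field(geom, params, unit = "day")
  kappa <- params$kappa
  L <- bilayer_operator(grid, alpha, kappa)
  y0 <- initial_state(grid, params, loading = loading)

  rhs_fn <- function(t, y, parms) list(as.vector(L %*% y))
  jac_fn <- function(t, y, parms) L
  out <- deSolve::ode(y = as.numeric(y0), times = settings$save_times,
                      func = rhs_fn, parms = NULL,
                      jacfunc = jac_fn, jactype = "fullusr",
                      method = "lsoda",
                      rtol = settings$rel_tol, atol = settings$abs_tol,
                      hmax = if (is.null(settings$max_step)) Inf else settings$max_step)
  if (nrow(out) < length(settings$save_times) || any(!is.finite(out[, -1]))) {
    stop(sprintf(paste0("integration failed (d_core=%.3g, d_shell=%.3g, kappa=%.3g, ",
                        "Rcore=%.3g um, dR=%.3g um): incomplete or non-finite solution"),
                 params$d_core, params$d_shell, kappa, geom$r_core, geom$delta_r),
         call. = FALSE)
  }
  states <- t(unclass(out)[, -1, drop = FALSE])
  dimnames(states) <- NULL
  structure(
    list(times = settings$save_times, states = states,
         grid = grid, params = params, geometry = geom,
         loading = loading, settings = settings),
    class = "cs_profile")
}

#' @export
print.cs_profile <- function(x, ...) {
  cat(sprintf("concentration profile: %d saved times over [0, %g] days, %d+%d intervals\n",
              length(x$times), max(x$times), x$grid$n_core, x$grid$n_shell))
  print(x$params)
  invisible(x)
}

#' Extract the state at a saved time
#'
#' @param profile A [solve_concentration()] result.
#' @param index Index into `profile$times`.
#' @return A `cs_state` vector (with grid/kappa attributes).
#' @export
state_at <- function(profile, index) {
  stopifnot(inherits(profile, "cs_profile"),
            index >= 1L, index <= length(profile$times))
  structure(profile$states[, index], class = "cs_state",
            grid = profile$grid, kappa = profile$params$kappa,
            time = profile$times[index], loading = profile$loading)
}

#' Export a concentration profile as delimited text
#'
#' Writes columns `time_days`, `node_position_norm`, `concentration_norm`
#' with the interface position appearing twice per time (core side, then
#' shell side).
#'
#' @param profile A [solve_concentration()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "cs_profile"))
  grid <- profile$grid
  pos <- grid$node_positions
  rows <- lapply(seq_along(profile$times), function(k) {
    s <- split_state(state_at(profile, k))
    data.frame(time_days = profile$times[k],
               node_position_norm = pos,
               concentration_norm = c(s$core_values, s$shell_values))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Analytical release fraction from a uniformly loaded sphere
#'
#' Classical series solution for Fickian release from a uniformly loaded
#' homogeneous sphere with a perfect-sink surface:
#' `f(t) = 1 - (6/pi^2) * sum_n n^-2 exp(-n^2 pi^2 D t / R^2)`.
#' Used as the independent oracle for the numerical solver in its
#' single-layer limit.
#'
#' @param d Diffusion coefficient, cm^2/s.
#' @param r Sphere radius, micrometres.
#' @param t Time(s), days; must be >= 0.
#' @param n_terms Number of series terms (>= 50).
#' @return Release fraction(s) in `[0, 1]`.
#' @examples
#' single_layer_release_fraction(2.6e-15, 5.10, 180)
#' @export
single_layer_release_fraction <- function(d, r, t, n_terms = 200L) {
  stopifnot(d > 0, r > 0, n_terms >= 50L)
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  r_cm <- r * 1e-4
  tau <- d * 86400 * t / r_cm^2
  n <- seq_len(n_terms)
  vapply(tau, function(tt) {
    if (tt == 0) return(0)
    max(0, 1 - (6 / pi^2) * sum(exp(-n^2 * pi^2 * tt) / n^2))
  }, numeric(1))
}
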