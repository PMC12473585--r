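# Spatial discretisation of the normalised two-layer sphere.
#
# The domain is normalised by the outer radius, r/Rshell in [0, 1]. Each
# layer carries its own uniform spacing so that node n_core lands exactly
# on the interface r/Rshell = Rcore/Rshell and node n_shell of the shell
# lands exactly on 1. The interface position is therefore represented
# twice, once per layer, because the concentration is discontinuous there
# (core-side = kappa * shell-side).

#' Build the two-layer finite-difference grid
#'
#' Discretises the normalised sphere with `n_core` intervals in the core
#' and `n_shell` in the shell. When `n_shell` is omitted it is matched to
#' the core spacing (`n_shell ~ n_core * delta_r / r_core`, at least 3),
#' which keeps the spacings on either side of the interface close and
#' minimises interface truncation error.
#'
#' @param geom A [geometry()] object.
#' @param n_core Number of intervals in the core (>= 3).
#' @param n_shell Number of intervals in the shell (>= 3), or `NULL` for
#'   matched spacing.
#' @return An object of class `cs_grid`: `n_core`, `n_shell`, `dr_core`,
#'   `dr_shell`, `r_iface` (normalised interface position), `node_core`
#'   and `node_shell` (normalised node radii per layer) and
#'   `node_positions` (both layers concatenated; the interface position
#'   appears twice).
#' @examples
#' g <- build_grid(geometry(5.10, 1.25), n_core = 100)
#' g$dr_core   # (5.10/6.35)/100
#' @export
build_grid <- function(geom, n_core = 100L, n_shell = NULL) {
  stopifnot(inherits(geom, "cs_geometry"))
  n_core <- as.integer(n_core)
  if (is.null(n_shell)) n_shell <- matched_shell_intervals(geom, n_core)
  n_shell <- as.integer(n_shell)
  if (n_core < 3L || n_shell < 3L) {
    stop("'n_core' and 'n_shell' must both be >= 3", call. = FALSE)
  }
  r_iface <- geom$r_core / geom$r_shell
  dr_core <- r_iface / n_core
  dr_shell <- (geom$delta_r / geom$r_shell) / n_shell
  node_core <- seq(0, r_iface, length.out = n_core + 1L)
  node_shell <- seq(r_iface, 1, length.out = n_shell + 1L)
  structure(
    list(n_core = n_core, n_shell = n_shell,
         dr_core = dr_core, dr_shell = dr_shell,
         r_iface = r_iface,
         node_core = node_core, node_shell = node_shell,
         node_positions = c(node_core, node_shell)),
    class = "cs_grid")
}

#' Shell interval count that matches the core spacing
#'
#' @param geom A [geometry()] object.
#' @param n_core Core interval count.
#' @return Integer interval count for the shell, at least 3.
#' @export
matched_shell_intervals <- function(geom, n_core) {
  stopifnot(inherits(geom, "cs_geometry"))
  max(3L, as.integer(round(n_core * geom$delta_r / geom$r_core)))
}

#' @export
print.cs_grid <- function(x, ...) {
  cat(sprintf("two-layer grid: %d core + %d shell intervals, interface at r/Rshell = %.4f\n",
              x$n_core, x$n_shell, x$r_iface))
  cat(sprintf("  dr_core = %.6g, dr_shell = %.6g (normalised)\n", x$dr_core, x$dr_shell))
  invisible(x)
}

#' Scaled diffusion rates for the normalised domain
#'
#' Scales each layer's diffusion coefficient by the squared outer radius,
#' `alpha = D / Rshell^2`, giving the piecewise-constant rate field of the
#' normalised diffusion equation. Lengths are converted from micrometres
#' to centimetres internally.
#'
#' @param geom A [geometry()] object.
#' @param params A [transport_params()] object.
#' @param unit Time unit of the returned rates: per second (default) or
#'   per day.
#' @return An object of class `cs_alpha` with `alpha_core` and
#'   `alpha_shell`.
#' @examples
#' alpha_field(geometry(5.10, 1.25), transport_params(1e-15, 1e-12))
#' @export
alpha_field <- function(geom, params, unit = c("s", "day")) {
  stopifnot(inherits(geom, "cs_geometry"), inherits(params, "cs_transport"))
  unit <- match.arg(unit)
  r_shell_cm <- geom$r_shell * 1e-4
  scale <- if (unit == "day") 86400 else 1
  structure(
    list(alpha_core = params$d_core * scale / r_shell_cm^2,
         alpha_shell = params$d_shell * scale / r_shell_cm^2,
         unit = unit),
    class = "cs_alpha")
}

#' @export
print.cs_alpha <- function(x, ...) {
  cat(sprintf("alpha: core %.4g 1/%s, shell %.4g 1/%s\n",
              x$alpha_core, x$unit, x$alpha_shell, x$unit))
  invisible(x)
}

#' Interface weighting constants of the fictitious-node scheme
#'
#' The discrete flux-continuity condition at the core-shell interface is
#' imposed by eliminating one ghost node on each side, which produces two
#' dimensionless constants: `gamma`, the flux-weighting ratio
#' `(alpha_shell * dr_core) / (alpha_core * dr_shell)` that also sets the
#' consistent initial interface concentrations, and `Gamma`, the
#' geometric-and-transport weight entering the interface node's time
#' derivative,
#' `Gamma = ((n_core*dr_core + dr_core) / (n_core*dr_core - dr_shell)) * gamma`.
#'
#' @param grid A [build_grid()] result.
#' @param alpha An [alpha_field()] result.
#' @return A list with elements `gamma` and `Gamma`.
#' @examples
#' geom <- geometry(5.10, 1.25)
#' a <- alpha_field(geom, transport_params(1e-15, 1e-12))
#' interface_constants(build_grid(geom, 100, 25), a)
#' @export
interface_constants <- function(grid, alpha) {
  stopifnot(inherits(grid, "cs_grid"), inherits(alpha, "cs_alpha"))
  gamma <- (alpha$alpha_shell * grid$dr_core) / (alpha$alpha_core * grid$dr_shell)
  r_iface <- grid$n_core * grid$dr_core
  den <- r_iface - grid$dr_shell
  if (den <= 0 || abs(den) < 1e-12 * r_iface) {
    stop("degenerate interface weighting: n_core*dr_core is too close to dr_shell; ",
         "refine the grid (increase n_core or n_shell)", call. = FALSE)
  }
  Gamma <- ((r_iface + grid$dr_core) / den) * gamma
  list(gamma = gamma, Gamma = Gamma)
}
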