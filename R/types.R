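#' Core-shell microsphere geometry
#'
#' Describes a bi-layered sphere with a drug-loaded inner core and a
#' drug-free outer shell. A zero-thickness shell (a single-layered sphere)
#' is rejected: the two-layer interface scheme and the shell's protective
#' role both assume `delta_r > 0`.
#'
#' @param r_core_um Core radius in micrometres (> 0).
#' @param delta_r_um Shell thickness in micrometres (> 0).
#' @return An object of class `cs_geometry` with fields `r_core`,
#'   `r_shell` and `delta_r` (all in micrometres, `r_shell = r_core +
#'   delta_r`).
#' @examples
#' geometry(5.10, 1.25)
#' @export
geometry <- function(r_core_um, delta_r_um) {
  stopifnot(is.numeric(r_core_um), length(r_core_um) == 1L, is.finite(r_core_um),
            is.numeric(delta_r_um), length(delta_r_um) == 1L, is.finite(delta_r_um))
  if (r_core_um <= 0) stop("'r_core_um' must be > 0", call. = FALSE)
  if (delta_r_um <= 0) {
    stop("shell thickness must be > 0: the zero-thickness (single-layer, ",
         "delta_r = 0) case is excluded from the two-layer model", call. = FALSE)
  }
  structure(
    list(r_core = r_core_um,
         r_shell = r_core_um + delta_r_um,
         delta_r = delta_r_um),
    class = "cs_geometry")
}

#' @export
print.cs_geometry <- function(x, ...) {
  cat(sprintf("core-shell geometry: Rcore = %g um, dR = %g um (Rshell = %g um)\n",
              x$r_core, x$delta_r, x$r_shell))
  invisible(x)
}

#' Transport parameters of a core-shell device
#'
#' The parameter vector that governs diffusion-controlled release: the two
#' layer diffusion coefficients, the interface partition coefficient and
#' the burst release percentage. The burst never enters the diffusion
#' equation; concentrations are normalised to the post-burst load and the
#' burst re-enters only when cumulative release is assembled.
#'
#' @param d_core Drug diffusion coefficient in the core, cm^2/s (> 0).
#' @param d_shell Drug diffusion coefficient in the shell, cm^2/s (> 0).
#' @param kappa Partition coefficient, the equilibrium ratio of the
#'   core-side to shell-side interface concentrations (> 0).
#' @param burst Burst release as a percentage of the total load,
#'   `0 <= burst < 100`.
#' @return An object of class `cs_transport`.
#' @examples
#' transport_params(2.6e-15, 2.6e-12, kappa = 1, burst = 10)
#' @export
transport_params <- function(d_core, d_shell, kappa = 1, burst = 0) {
  vals <- c(d_core = d_core, d_shell = d_shell, kappa = kappa, burst = burst)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (d_core <= 0 || d_shell <= 0) stop("diffusion coefficients must be > 0", call. = FALSE)
  if (kappa <= 0) stop("'kappa' must be > 0", call. = FALSE)
  if (burst < 0 || burst >= 100) stop("'burst' must be in [0, 100)", call. = FALSE)
  structure(list(d_core = d_core, d_shell = d_shell,
                 kappa = kappa, burst = burst),
            class = "cs_transport")
}

#' @export
print.cs_transport <- function(x, ...) {
  cat(sprintf("transport: Dcore = %.3g cm2/s, Dshell = %.3g cm2/s, kappa = %g, burst = %g%%\n",
              x$d_core, x$d_shell, x$kappa, x$burst))
  invisible(x)
}

#' Dose specification
#'
#' The total drug amount loaded into one dose of (many identical)
#' microspheres. Release rates in mass units scale linearly with this
#' amount; a molecular weight may be attached for mole-based reporting.
#'
#' @param a_load0_ug Loaded amount in micrograms (> 0).
#' @param drug Drug label.
#' @param mw_g_mol Optional molecular weight, g/mol.
#' @return An object of class `cs_dose`.
#' @examples
#' dose_spec(1030, drug = "bevacizumab")
#' @export
dose_spec <- function(a_load0_ug, drug = "drug", mw_g_mol = NULL) {
  stopifnot(is.numeric(a_load0_ug), length(a_load0_ug) == 1L, is.finite(a_load0_ug))
  if (a_load0_ug <= 0) stop("'a_load0_ug' must be > 0", call. = FALSE)
  if (!is.null(mw_g_mol)) stopifnot(is.numeric(mw_g_mol), mw_g_mol > 0)
  structure(list(a_load0 = a_load0_ug, drug = as.character(drug),
                 molecular_weight = mw_g_mol),
            class = "cs_dose")
}

#' @export
print.cs_dose <- function(x, ...) {
  cat(sprintf("dose: %g ug of %s\n", x$a_load0, x$drug))
  invisible(x)
}
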