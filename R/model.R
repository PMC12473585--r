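# Method-of-lines discretisation of the two-layer spherical diffusion
# equation. State layout (the ODE unknowns):
#   [ c_core_0 .. c_core_{n_core-1} | c_iface_shell | c_shell_1 .. c_shell_{n_shell-1} ]
# The core-side interface value is slaved algebraically to the shell-side
# one (c_core at the interface = kappa * c_iface_shell): its time
# derivative in the scheme is exactly kappa times the shell-side
# derivative, so it is never carried as an independent unknown. The outer
# surface node is held at 0 (perfect sink) and not carried either.

#' Initial state of the core-loaded device
#'
#' Unit (post-burst normalised) concentration in the core, zero in the
#' shell and at the outer surface. The two interface values are the
#' flux-consistent weighted averages of the adjoining layers: shell-side
#' `c0/(kappa+gamma)`, core-side `kappa*c0/(kappa+gamma)`, so their ratio
#' is exactly `kappa` from the start. With `loading = "uniform"` the
#' whole sphere starts at unit concentration (a verification
#' configuration: with `kappa = 1` and equal diffusivities it admits the
#' classical single-sphere series solution).
#'
#' @param grid A [build_grid()] result.
#' @param params A [transport_params()] object.
#' @param gamma Interface flux-weighting ratio; computed from `grid` and
#'   `params` via [interface_constants()] when `NULL`.
#' @param loading `"core"` (drug in the core only, the physical device)
#'   or `"uniform"`.
#' @return An object of class `cs_state`: numeric vector of ODE unknowns
#'   with attributes `grid`, `kappa` and `time` (days).
#' @export
initial_state <- function(grid, params, gamma = NULL, loading = c("core", "uniform")) {
  stopifnot(inherits(grid, "cs_grid"), inherits(params, "cs_transport"))
  loading <- match.arg(loading)
  kappa <- params$kappa
  if (is.null(gamma)) {
    # unit of alpha cancels in the ratio
    a <- alpha_field(geometry_from_grid(grid), params, unit = "day")
    gamma <- interface_constants(grid, a)$gamma
  }
  core_val <- 1
  shell_val <- if (loading == "uniform") 1 else 0
  iface_shell <- (core_val + gamma * shell_val) / (kappa + gamma)
  y <- c(rep(core_val, grid$n_core),
         iface_shell,
         rep(shell_val, grid$n_shell - 1L))
  structure(y, class = "cs_state", grid = grid, kappa = kappa,
            time = 0, loading = loading)
}

# Reconstruct a geometry (up to overall scale) from a grid: gamma depends
# only on the diffusivity ratio and the spacings, so a unit outer radius
# serves. Used where a grid is at hand but the geometry object is not.
geometry_from_grid <- function(grid) {
  geometry(grid$r_iface, 1 - grid$r_iface)
}

#' Split a state vector into its per-layer pieces
#'
#' @param state A `cs_state` vector (or plain numeric laid out the same
#'   way) together with its grid and kappa.
#' @param grid,kappa Grid and partition coefficient; taken from the state
#'   attributes when omitted.
#' @return A list with `c_core` (core nodes 0..n_core-1),
#'   `c_iface_shell`, `c_iface_core` (= kappa * shell side), `c_shell`
#'   (shell interior nodes) and the full per-layer node value vectors
#'   `core_values` (0..n_core) and `shell_values` (0..n_shell, outer node
#'   0).
#' @export
split_state <- function(state, grid = attr(state, "grid"), kappa = attr(state, "kappa")) {
  stopifnot(!is.null(grid), !is.null(kappa))
  y <- as.numeric(state)
  n_c <- grid$n_core
  n_s <- grid$n_shell
  stopifnot(length(y) == n_c + n_s)
  c_core <- y[seq_len(n_c)]
  c_if <- y[n_c + 1L]
  c_shell <- if (n_s >= 2L) y[(n_c + 2L):(n_c + n_s)] else numeric(0)
  list(c_core = c_core,
       c_iface_shell = c_if,
       c_iface_core = kappa * c_if,
       c_shell = c_shell,
       core_values = c(c_core, kappa * c_if),
       shell_values = c(c_if, c_shell, 0))
}

# The spatial operator as a (dense) matrix L so that dy/dt = L y. The
# system is linear and time-invariant; building L once per solve gives
# both a fast right-hand side and an exact Jacobian for the implicit
# integrator.
bilayer_operator <- function(grid, alpha, kappa) {
  stopifnot(inherits(grid, "cs_grid"), inherits(alpha, "cs_alpha"))
  ic <- interface_constants(grid, alpha)
  n_c <- grid$n_core
  n_s <- grid$n_shell
  h1 <- grid$dr_core
  h2 <- grid$dr_shell
  ac <- alpha$alpha_core
  as_ <- alpha$alpha_shell
  n <- n_c + n_s
  L <- matrix(0, n, n)

  # centre node: dC0/dt = 6*ac/h1^2 * (C1 - C0)
  L[1L, 1L] <- -6 * ac / h1^2
  L[1L, 2L] <- 6 * ac / h1^2

  # core interior i = 1..n_c-1:
  # dCi/dt = ac/(i*h1^2) * ((i+1)C_{i+1} - 2i C_i + (i-1)C_{i-1})
  for (i in seq_len(n_c - 1L)) {
    row <- i + 1L
    cf <- ac / (i * h1^2)
    L[row, i] <- L[row, i] + cf * (i - 1)
    L[row, i + 1L] <- L[row, i + 1L] - cf * 2 * i
    if (i < n_c - 1L) {
      L[row, i + 2L] <- L[row, i + 2L] + cf * (i + 1)
    } else {
      # neighbour is the core-side interface value kappa * c_iface_shell
      L[row, n_c + 1L] <- L[row, n_c + 1L] + cf * (i + 1) * kappa
    }
  }

  # shell-side interface node (ghost nodes eliminated on both sides):
  # dCj0/dt = (2*Gamma*C_{j=1} - 2*(Gamma+kappa)*Cj0 + 2*C_{i=n_c-1})
  #           / (kappa*h1^2/ac + Gamma*h2^2/as)
  den <- kappa * h1^2 / ac + ic$Gamma * h2^2 / as_
  row <- n_c + 1L
  L[row, n_c] <- 2 / den
  L[row, n_c + 1L] <- -2 * (ic$Gamma + kappa) / den
  if (n_s >= 2L) L[row, n_c + 2L] <- 2 * ic$Gamma / den
  # (if n_s were 1 the neighbour is the sink node, identically 0)

  # shell interior j = 1..n_s-1 at r_j = r_iface + j*h2:
  # dCj/dt = as/(r_j*h2)*(C_{j+1}-C_{j-1}) + as/h2^2*(C_{j+1}-2Cj+C_{j-1})
  if (n_s >= 2L) {
    for (j in seq_len(n_s - 1L)) {
      row <- n_c + 1L + j
      rj <- grid$r_iface + j * h2
      a1 <- as_ / (rj * h2)
      a2 <- as_ / h2^2
      L[row, n_c + j] <- L[row, n_c + j] - a1 + a2
      L[row, n_c + 1L + j] <- L[row, n_c + 1L + j] - 2 * a2
      if (j < n_s - 1L) {
        L[row, n_c + 2L + j] <- L[row, n_c + 2L + j] + a1 + a2
      }
      # j = n_s-1: outer neighbour is the sink node, contributes 0
    }
  }
  L
}

#' Right-hand side of the method-of-lines system
#'
#' Evaluates the time derivative of the discretised two-layer diffusion
#' system at a given state: second-order central stencils in each layer,
#' the symmetry condition at the centre, the fictitious-node interface
#' scheme for the shell-side interface unknown, and a zero derivative at
#' the (eliminated) perfect-sink surface node. The core-side interface
#' derivative is `kappa` times the shell-side one by construction.
#'
#' @param state A [initial_state()]-style state vector.
#' @param grid,alpha,kappa Discretisation, scaled diffusion rates (see
#'   [alpha_field()]; the rate unit sets the derivative's time unit) and
#'   partition coefficient. Taken from `state` attributes when omitted
#'   (`alpha` has no default).
#' @return Numeric vector of derivatives, same layout as the state.
#' @export
bilayer_rhs <- function(state, grid = attr(state, "grid"), alpha,
                        kappa = attr(state, "kappa")) {
  y <- as.numeric(state)
  if (!all(is.finite(y))) stop("non-finite state entries", call. = FALSE)
  L <- bilayer_operator(grid, alpha, kappa)
  as.vector(L %*% y)
}
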