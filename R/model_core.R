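#' Tissue stiffness as a function of local osteoblast fraction
#'
#' Linear mixing closure between the mesenchyme stiffness \code{E_m} and the
#' osteoblast-tissue stiffness \code{E_o}: differentiated osteoblasts deposit
#' fibrillar collagen and stiffen their neighbourhood, so local stiffness
#' rises monotonically with the osteoblast fraction phi.
#'
#' @param phi osteoblast fraction(s) in \[0, 1\].
#' @param params a \code{\link{sim_params}} object.
#' @return Stiffness in kPa, same length as \code{phi}.
#' @export
stiffness_of_phi <- function(phi, params) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    stopf("phi must lie in [0, 1]")
  params$E_m + (params$E_o - params$E_m) * phi
}

#' Stiffness-dependent differentiation rate
#'
#' Rate at which undifferentiated mesenchyme converts to osteoblasts,
#' increasing with local stiffness: zero at the mesenchyme baseline
#' \code{E_m}, rising linearly to the coupling constant \code{beta} at the
#' osteoblast stiffness \code{E_o}, clamped beyond. \code{beta} is the single
#' fitted parameter of the model (see \code{\link{fit_beta}}).
#'
#' @param E local stiffness (kPa), \code{E >= 0}.
#' @param params a \code{\link{sim_params}} object.
#' @return Differentiation rate lambda(E) in 1/h.
#' @export
differentiation_rate <- function(E, params) {
  if (any(!is.finite(E)) || any(E < 0)) stopf("E must be non-negative")
  params$beta * clamp((E - params$E_m) / (params$E_o - params$E_m), 0, 1)
}

#' Composition-dependent homeostatic density
#'
#' Linear interpolation between the homeostatic densities of pure mesenchyme
#' and pure osteoblast tissue; the bone center is more densely packed.
#'
#' @param phi osteoblast fraction(s) in \[0, 1\].
#' @param params a \code{\link{sim_params}} object.
#' @return Homeostatic density rho0(phi) in cells/um.
#' @export
homeostatic_density <- function(phi, params) {
  params$rho0_m + (params$rho0_o - params$rho0_m) * phi
}

#' Tissue pressure equation of state
#'
#' Two contributions set the local pressure:
#' \deqn{P = E(\phi)\,(\rho - \rho_0(\phi))/\rho_0(\phi) +
#'   c_s\,(E(\phi) - E_m)\,\rho/\rho_0(\phi).}
#' The first term is a linear elastic-type crowding pressure — proportional
#' to the relative deviation of the total cell density from its
#' composition-dependent homeostatic value, with the local stiffness as
#' modulus; it vanishes at homeostasis and increases with density. The
#' second term is the matrix swelling stress: differentiated osteoblasts
#' deposit a hydrated, fibrillar collagen matrix that both stiffens the
#' tissue and occupies volume, so osteoblast-rich tissue carries a standing
#' compressive stress proportional to its stiffness excess over bare
#' mesenchyme, weighted by the relative packing of the matrix-producing
#' tissue (\code{c_swell} is the dimensionless swelling strain scale;
#' diluted tissue exerts proportionally less matrix stress). The gradient
#' of this term across the osteogenic front is what pushes tissue medially;
#' without it the differentiation wave would carry no pushing flow and
#' neither bone-center excision nor stiffness-gradient perturbations would
#' alter expansion.
#'
#' Pure mesenchyme at homeostatic density has zero pressure; homeostatic
#' bone retains the residual swelling pressure \code{c_swell (E_o - E_m)}.
#'
#' @param rho total cell density (cells/um), \code{rho >= 0}.
#' @param phi osteoblast fraction(s) in \[0, 1\].
#' @param params a \code{\link{sim_params}} object.
#' @return Pressure in kPa.
#' @export
tissue_pressure <- function(rho, phi, params) {
  if (any(!is.finite(rho)) || any(rho < 0)) stopf("rho must be non-negative")
  rho0 <- homeostatic_density(phi, params)
  E <- stiffness_of_phi(phi, params)
  E * (rho - rho0) / rho0 + params$c_swell * (E - params$E_m) * rho / rho0
}

# Cached symmetric positive-definite factorization of the interior force
# balance operator xi*I - eta*d^2/dx^2 (sign chosen to make it SPD).
force_balance_cache <- function(n, dx, params) {
  ni <- n - 2L
  a <- params$xi + 2 * params$eta / dx^2
  b <- -params$eta / dx^2
  A <- Matrix::bandSparse(ni, ni, k = c(0L, 1L),
                          diagonals = list(rep(a, ni), rep(b, ni - 1L)),
                          symmetric = TRUE)
  list(chol = Matrix::Cholesky(A, LDL = FALSE), n = n, dx = dx,
       eta = params$eta, xi = params$xi)
}

#' Solve the tissue force balance for the velocity profile
#'
#' Solves \code{eta v'' - xi v = dP/dx} on the uniform grid with no-slip
#' boundaries (\code{v = 0} at both domain ends), i.e. the balance between
#' pressure gradients, viscous stresses, and friction with the surrounding
#' tissue layers. Discretization: second-order centered differences, leading
#' to a symmetric tridiagonal system solved by a sparse Cholesky
#' factorization.
#'
#' @param P pressure profile (kPa) on the uniform grid.
#' @param dx grid spacing (um).
#' @param params a \code{\link{sim_params}} object; \code{eta} and \code{xi}
#'   must not both be zero.
#' @param cache optional factorization from a previous call on the same grid
#'   (used internally by \code{\link{simulate_wave}}).
#' @return Velocity profile v (um/h), same length as \code{P}; positive v
#'   points in the medial (+x) direction of expansion.
#' @export
solve_force_balance <- function(P, dx, params, cache = NULL) {
  n <- length(P)
  if (n < 3L) stopf("need at least 3 grid points")
  if (params$eta == 0 && params$xi == 0)
    stopf("singular force balance: eta and xi are both zero")
  if (is.null(cache) || cache$n != n || cache$dx != dx ||
      cache$eta != params$eta || cache$xi != params$xi)
    cache <- force_balance_cache(n, dx, params)
  dP <- (P[3:n] - P[1:(n - 2L)]) / (2 * dx)  # centered gradient, interior
  v <- numeric(n)
  v[2:(n - 1L)] <- as.numeric(Matrix::solve(cache$chol, -dP, system = "A"))
  v
}

#' Spatial state of the two-population tissue
#'
#' Builds a \code{"field_state"}: the densities of undifferentiated
#' mesenchyme (\code{rho_m}) and osteoblasts (\code{rho_o}), the net division
#' rate field \code{k}, and the time, on a uniform grid along the
#' medial-lateral axis (+x = medial, the direction of expansion; bone lies at
#' small x).
#'
#' @param params a \code{\link{sim_params}} object.
#' @param init \code{"step"} (osteoblasts at homeostatic density lateral of
#'   \code{x_front0}, mesenchyme medial of it), \code{"mesenchyme"} or
#'   \code{"bone"} (homogeneous homeostatic states), or a list with fields
#'   \code{rho_m}, \code{rho_o} and optionally \code{k} on the grid.
#' @param x_front0 initial front position (um) for the step preset.
#' @return A \code{"field_state"} list with \code{x}, \code{dx}, \code{t},
#'   \code{rho_m}, \code{rho_o}, \code{k}.
#' @export
field_state <- function(params, init = "step", x_front0 = params$x_front0) {
  n <- as.integer(params$n_grid)
  x <- seq(0, params$domain_length, length.out = n)
  zero <- numeric(n)
  if (is.list(init)) {
    rho_m <- init$rho_m; rho_o <- init$rho_o
    k <- if (is.null(init$k)) zero else init$k
    if (length(rho_m) != n || length(rho_o) != n || length(k) != n)
      stopf("initial fields must have length n_grid = %d", n)
  } else if (identical(init, "step")) {
    bone <- x < x_front0
    rho_o <- ifelse(bone, params$rho0_o, 0)
    rho_m <- ifelse(bone, 0, params$rho0_m)
    k <- zero
  } else if (identical(init, "mesenchyme")) {
    rho_m <- rep(params$rho0_m, n); rho_o <- zero; k <- zero
  } else if (identical(init, "bone")) {
    rho_o <- rep(params$rho0_o, n); rho_m <- zero; k <- zero
  } else stopf("unknown initial condition preset '%s'", init)
  if (any(rho_m < 0) || any(rho_o < 0)) stopf("initial densities must be >= 0")
  structure(list(x = x, dx = x[2] - x[1], t = 0,
                 rho_m = rho_m, rho_o = rho_o, k = k),
            class = "field_state")
}

#' Osteoblast fraction of a state
#'
#' \code{phi = rho_o / (rho_m + rho_o)}, defined as 0 where the total density
#' vanishes.
#'
#' @param state a \code{"field_state"}.
#' @return Numeric vector in \[0, 1\].
#' @export
state_phi <- function(state) {
  rho <- state$rho_m + state$rho_o
  ifelse(rho > 0, state$rho_o / rho, 0)
}

# upwind / van Leer flux-limited face values for the advective flux rho*v
advective_face_flux <- function(rho, v, scheme) {
  n <- length(rho)
  vf <- 0.5 * (v[-n] + v[-1])                   # faces i + 1/2, i = 1..n-1
  up <- ifelse(vf >= 0, rho[-n], rho[-1])       # first-order upwind
  if (scheme == "vanleer" && n >= 4L) {
    drho <- diff(rho)                           # drho[i] = rho[i+1] - rho[i]
    lim <- function(a, b) {                     # harmonic (van Leer) limiter
      ab <- a * b
      ifelse(ab > 0, 2 * ab / (a + b), 0)
    }
    corr <- numeric(n - 1L)
    i <- 2:(n - 2L)                             # interior faces with full stencil
    corr[i] <- ifelse(vf[i] >= 0,
                      0.5 * lim(drho[i - 1L], drho[i]),
                      -0.5 * lim(drho[i], drho[i + 1L]))
    up <- up + corr
  }
  vf * up
}

#' Advance the tissue state by one explicit time step
#'
#' One forward-Euler step of the coupled system: advection of both
#' populations by the tissue flow (first-order upwind or van Leer limited
#' fluxes), cell diffusion (centered), density-dependent net growth
#' \code{k rho}, stiffness-dependent conversion of mesenchyme to osteoblasts
#' \code{lambda(E) rho_m} (which conserves total cell number), and the
#' relaxation of the net division rate \code{k} toward
#' \code{alpha (1 - rho/rho0(phi))} with timescale \code{tau}, while being
#' advected with the flow. Density fluxes vanish at both boundaries, so with
#' growth switched off the total cell number is conserved to round-off.
#'
#' @param state a \code{"field_state"}.
#' @param params a \code{\link{sim_params}} object.
#' @param dt time step (h); must satisfy the explicit stability bound (see
#'   \code{\link{simulate_wave}}, which enforces it).
#' @param cache optional force-balance factorization (see
#'   \code{\link{solve_force_balance}}).
#' @param scheme advection scheme, \code{"upwind"} or \code{"vanleer"}.
#' @return The advanced \code{"field_state"}, with the velocity used stored
#'   as \code{$v}.
#' @export
step_state <- function(state, params, dt = params$dt, cache = NULL,
                       scheme = params$advection) {
  n <- length(state$x); dx <- state$dx
  rho_m <- state$rho_m; rho_o <- state$rho_o; k <- state$k
  rho <- rho_m + rho_o
  phi <- ifelse(rho > 0, rho_o / rho, 0)
  E <- stiffness_of_phi(phi, params)
  P <- tissue_pressure(rho, phi, params)
  v <- solve_force_balance(P, dx, params, cache)

  div_flux <- function(q) {
    f_adv <- advective_face_flux(q, v, scheme)
    f_dif <- -params$D * diff(q) / dx
    f <- c(0, f_adv + f_dif, 0)               # no-flux boundaries
    diff(f) / dx
  }
  lam <- differentiation_rate(E, params)
  rho_m_new <- rho_m + dt * (-div_flux(rho_m) + (k - lam) * rho_m)
  rho_o_new <- rho_o + dt * (-div_flux(rho_o) + k * rho_o + lam * rho_m)

  # net division rate: advected scalar relaxing toward its density target
  k_target <- params$alpha * (1 - rho / homeostatic_density(phi, params))
  if (params$tau > 0) {
    gradk <- numeric(n)
    gradk[2:(n - 1L)] <- ifelse(v[2:(n - 1L)] >= 0,
                                (k[2:(n - 1L)] - k[1:(n - 2L)]) / dx,
                                (k[3:n] - k[2:(n - 1L)]) / dx)
    gradk[1] <- (k[2] - k[1]) / dx
    gradk[n] <- (k[n] - k[n - 1L]) / dx
    k_new <- k + dt * (-v * gradk - (k - k_target) / params$tau)
  } else {
    k_new <- k_target
  }

  for (nm in c("rho_m", "rho_o")) {
    val <- if (nm == "rho_m") rho_m_new else rho_o_new
    if (any(!is.finite(val)))
      stopf("numerical instability: non-finite values in %s at t = %g", nm,
            state$t + dt)
    tol <- -1e-10 * max(val, 1)
    if (any(val < tol))
      stopf("numerical instability: negative density in %s at t = %g (min %g)",
            nm, state$t + dt, min(val))
  }
  rho_m_new[rho_m_new < 0] <- 0  # clip round-off-level negatives
  rho_o_new[rho_o_new < 0] <- 0

  structure(list(x = state$x, dx = dx, t = state$t + dt,
                 rho_m = rho_m_new, rho_o = rho_o_new, k = k_new, v = v),
            class = "field_state")
}
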