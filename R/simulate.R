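#' Simulate the osteoblast differentiation wave
#'
#' Integrates the two-population continuum model forward in time from a named
#' preset or explicit initial state, saving the fields at regular intervals.
#' The PDE system is deterministic: repeated runs with identical parameters
#' produce identical trajectories (only Lagrangian tracers, handled
#' separately by \code{\link{advect_tracers}}, are stochastic).
#'
#' The explicit time step is capped at
#' \code{0.4 min(dx^2/(2 D), dx/max|v|, 1/(alpha + beta + 1/tau))} and then
#' rounded down so that an integer number of steps fits in each save
#' interval; the advective part of the bound is asserted against the realized
#' flow at every step.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param init initial condition preset or explicit state
#'   (see \code{\link{field_state}}).
#' @param x_front0 initial front position for the step preset (um).
#' @param save_every interval between saved states (h).
#' @param scheme advection scheme, \code{"upwind"} (default) or
#'   \code{"vanleer"}.
#' @param check_margin assert that the detected front stays more than 100 um
#'   away from both domain boundaries at every save (default TRUE; the
#'   assertion is skipped at saves where no front crossing exists).
#' @return A \code{"wave_sim"} object: list with \code{params}, grid \code{x},
#'   save \code{times} (h) and matrices \code{rho_m}, \code{rho_o}, \code{k},
#'   \code{v} of dimension (saves x grid).
#' @export
#' @examples
#' p <- sim_params(domain_length = 300, n_grid = 301, t_end = 6, x_front0 = 150)
#' sim <- simulate_wave(p)
#' tail(front_trajectory(sim), 2)
simulate_wave <- function(params, init = "step", x_front0 = params$x_front0,
                          save_every = params$save_every,
                          scheme = params$advection, check_margin = TRUE) {
  params <- validate_params(params)
  state <- if (inherits(init, "field_state")) init
           else field_state(params, init, x_front0)
  n <- length(state$x); dx <- state$dx

  rate <- params$alpha + params$beta + if (params$tau > 0) 1 / params$tau else 0
  dt_max <- 0.4 * min(if (params$D > 0) dx^2 / (2 * params$D) else Inf,
                      if (rate > 0) 1 / rate else Inf)
  dt <- min(params$dt, dt_max)
  n_saves <- if (params$t_end > 0) ceiling(params$t_end / save_every) else 0L
  steps_per_save <- if (n_saves > 0) max(1L, ceiling(save_every / dt)) else 0L
  dt <- if (n_saves > 0) save_every / steps_per_save else dt

  cache <- force_balance_cache(n, dx, params)
  times <- numeric(n_saves + 1L)
  rho_m <- rho_o <- kk <- vv <- matrix(NA_real_, n_saves + 1L, n)
  snap <- function(s, row) {
    times[row] <<- s$t
    rho_m[row, ] <<- s$rho_m; rho_o[row, ] <<- s$rho_o
    kk[row, ] <<- s$k
    vv[row, ] <<- if (is.null(s$v))
      solve_force_balance(tissue_pressure(s$rho_m + s$rho_o,
                                          ifelse(s$rho_m + s$rho_o > 0,
                                                 s$rho_o / (s$rho_m + s$rho_o), 0),
                                          params), dx, params, cache)
    else s$v
  }
  snap(state, 1L)
  if (n_saves > 0) {
    for (s in seq_len(n_saves)) {
      for (i in seq_len(steps_per_save)) {
        state <- step_state(state, params, dt, cache, scheme)
        cfl <- max(abs(state$v)) * dt / dx
        if (cfl > 0.5)
          stopf("advective CFL violated (|v| dt / dx = %.3f) at t = %g",
                cfl, state$t)
      }
      state$t <- s * save_every  # avoid accumulated round-off in time
      snap(state, s + 1L)
      if (check_margin) {
        phi <- rho_o[s + 1L, ] / pmax(rho_m[s + 1L, ] + rho_o[s + 1L, ],
                                      .Machine$double.eps)
        fr <- tryCatch(detect_front(state$x, phi), error = function(e) NA_real_)
        if (is.finite(fr) &&
            (fr < 100 || fr > params$domain_length - 100))
          stopf("wave reached within 100 um of a domain boundary (front at %.1f um, t = %g h); enlarge the domain or shorten t_end",
                fr, state$t)
      }
    }
  }
  structure(list(params = params, x = state$x, dx = dx, times = times,
                 rho_m = rho_m, rho_o = rho_o, k = kk, v = vv,
                 dt = dt, scheme = scheme),
            class = "wave_sim")
}

#' @export
print.wave_sim <- function(x, ...) {
  cat(sprintf("<wave_sim> %d saves over %g h on %d-point grid (dx = %g um, dt = %g h, %s advection)\n",
              length(x$times), max(x$times), length(x$x), x$dx, x$dt, x$scheme))
  fr <- tryCatch(front_trajectory(x), error = function(e) NULL)
  if (!is.null(fr) && nrow(fr) > 2)
    cat(sprintf("  front: %.1f -> %.1f um\n",
                fr$front_um[1], fr$front_um[nrow(fr)]))
  invisible(x)
}

#' Osteoblast-fraction profiles of a simulation
#'
#' @param sim a \code{"wave_sim"}.
#' @return Matrix (saves x grid) of osteoblast fractions.
#' @export
sim_phi <- function(sim) {
  rho <- sim$rho_m + sim$rho_o
  out <- sim$rho_o / rho
  out[rho == 0] <- 0
  out
}

#' Long-format data frame of saved states
#'
#' @param x a \code{"wave_sim"}.
#' @param row.names,optional unused (S3 signature).
#' @param ... unused.
#' @return data.frame with columns \code{t_h}, \code{x_um}, \code{rho_m},
#'   \code{rho_o}, \code{phi}, \code{v_um_per_h}, \code{k_per_h}.
#' @export
as.data.frame.wave_sim <- function(x, row.names = NULL, optional = FALSE, ...) {
  phi <- sim_phi(x)
  data.frame(t_h = rep(x$times, each = length(x$x)),
             x_um = rep(x$x, times = length(x$times)),
             rho_m = as.vector(t(x$rho_m)),
             rho_o = as.vector(t(x$rho_o)),
             phi = as.vector(t(phi)),
             v_um_per_h = as.vector(t(x$v)),
             k_per_h = as.vector(t(x$k)))
}
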