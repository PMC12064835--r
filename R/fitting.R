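#' Fit the differentiation-stiffness coupling to displacement data
#'
#' Fits the single free parameter \code{beta} by minimizing the summed
#' squared residual between simulated and observed normalized displacement
#' curves of the osteogenic front and of the tracked cells (equal weights by
#' default), exactly the quantities measured in live imaging. The search is
#' a bracketing grid followed by golden-section refinement; the objective is
#' deterministic (tracked-cell curves are computed from the deterministic
#' mean tracer path, D = 0).
#'
#' @param observed data.frame with columns \code{t_h} (elapsed hours),
#'   \code{front}, \code{cells}: normalized displacement curves as produced
#'   by \code{\link{displacement_observables}}.
#' @param params a \code{\link{sim_params}} object; its \code{beta} entry is
#'   ignored.
#' @param interval search interval for beta (1/h); default
#'   \code{c(0, 10 * params$beta)}.
#' @param n_grid bracketing grid points; default 20.
#' @param tol absolute golden-section tolerance on beta; default
#'   \code{2e-4 * diff(interval)}.
#' @param weights length-2 weights for (front, cells) residuals.
#' @param t0 tracer release time passed to
#'   \code{\link{displacement_observables}}; default half the horizon.
#' @return List of class \code{"beta_fit"}: \code{beta_hat}, \code{objective}
#'   (value at the optimum), \code{grid} (data.frame beta/objective over the
#'   bracketing grid), \code{converged}, \code{n_evals}, \code{provenance}.
#' @export
fit_beta <- function(observed, params, interval = c(0, 10 * params$beta),
                     n_grid = 20, tol = 2e-4 * diff(interval),
                     weights = c(1, 1), t0 = params$t_end / 2) {
  stopifnot(all(c("t_h", "front", "cells") %in% names(observed)),
            diff(interval) > 0)
  duration <- max(observed$t_h)
  n_evals <- 0L
  objective <- function(beta) {
    p <- params; p$beta <- beta
    n_evals <<- n_evals + 1L
    obs_sim <- tryCatch({
      sim <- simulate_wave(p)
      displacement_observables(sim, t0 = t0, duration = duration,
                               n_tracers = 1L, D = 0)
    }, error = function(e) NULL)
    if (is.null(obs_sim)) return(NA_real_)
    fr <- interp_strict(obs_sim$curves$t_h, obs_sim$curves$front,
                        observed$t_h, "objective time")
    ce <- interp_strict(obs_sim$curves$t_h, obs_sim$curves$cells,
                        observed$t_h, "objective time")
    weights[1] * sum((fr - observed$front)^2) +
      weights[2] * sum((ce - observed$cells)^2)
  }
  grid <- seq(interval[1], interval[2], length.out = n_grid)
  grid_obj <- vapply(grid, objective, numeric(1))
  if (all(!is.finite(grid_obj)))
    stopf("objective non-finite across the whole search interval")
  i <- which.min(grid_obj)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(n_grid, i + 1L)]
  # golden-section refinement on the bracketing interval
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- objective(x1); f2 <- objective(x2)
  while (b - a > tol) {
    if (!is.finite(f1) || (is.finite(f2) && f2 < f1)) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- objective(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- objective(x1)
    }
  }
  cand <- rbind(data.frame(beta = grid, obj = grid_obj),
                data.frame(beta = c(x1, x2), obj = c(f1, f2)))
  cand <- cand[is.finite(cand$obj), ]
  best <- cand[which.min(cand$obj), ]
  structure(list(beta_hat = best$beta, objective = best$obj,
                 grid = data.frame(beta = grid, objective = grid_obj),
                 converged = (b - a) <= tol, n_evals = n_evals,
                 provenance = list(interval = interval, n_grid = n_grid,
                                   tol = tol, weights = weights,
                                   t0 = t0, duration = duration)),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf("<beta_fit> beta_hat = %.4f 1/h (objective %.3g, %d simulations, %s)\n",
              x$beta_hat, x$objective, x$n_evals,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Post-fit model predictions
#'
#' The three observables used to confront the fitted model with imaging
#' data, computed with no further fitting: the late-time cell-velocity
#' profile, the osteoblast-fraction profile, and the front expansion speed.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return List with \code{velocity_profile} and \code{phi_profile}
#'   (data.frames over x at the final save), \code{front_speed} (um/h), and
#'   the \code{sim}.
#' @export
predicted_observables <- function(params) {
  sim <- simulate_wave(params)
  last <- length(sim$times)
  phi <- sim_phi(sim)
  list(velocity_profile = data.frame(x_um = sim$x, v_um_per_h = sim$v[last, ]),
       phi_profile = data.frame(x_um = sim$x, phi = phi[last, ]),
       front_speed = front_speed(front_trajectory(sim))$speed,
       sim = sim)
}
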