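#' Advect Lagrangian tracers through a simulated flow field
#'
#' Tracers are material points of the tissue flow plus cell-scale diffusion;
#' they model individually tracked nuclei. The update is Euler-Maruyama,
#' \code{x <- x + v(x, t) dt + sqrt(2 D dt) N(0, 1)}, with the velocity
#' interpolated bilinearly in space and time from the saved states and
#' reflection at the domain boundaries. Runs are reproducible given the seed.
#'
#' @param sim a \code{"wave_sim"} whose saved velocity history covers the
#'   requested time window.
#' @param initial_positions tracer start positions (um), inside the domain.
#' @param t_start,t_end tracked time window (h); defaults to the full record.
#' @param dt tracer time step (h); default 0.1.
#' @param D tracer diffusivity (um^2/h); defaults to the simulation's
#'   \code{D}.
#' @param seed RNG seed (ignored when \code{D = 0}).
#' @param region optional region labels, one per tracer.
#' @return data.frame of class \code{"tracer_tracks"} with columns
#'   \code{track_id}, \code{t_h}, \code{x_um} (and \code{region} if given).
#' @export
advect_tracers <- function(sim, initial_positions, t_start = sim$times[1],
                           t_end = max(sim$times), dt = 0.1,
                           D = sim$params$D, seed = sim$params$seed,
                           region = NULL) {
  L <- sim$x[length(sim$x)]
  if (any(initial_positions < 0 | initial_positions > L))
    stopf("tracer initial position outside the domain [0, %g]", L)
  if (t_start < sim$times[1] - 1e-9 || t_end > max(sim$times) + 1e-9)
    stopf("velocity history does not cover [%g, %g] h", t_start, t_end)
  if (D < 0) stopf("D must be >= 0")
  nt <- max(1L, ceiling((t_end - t_start) / dt))
  dt <- (t_end - t_start) / nt
  n <- length(initial_positions)

  v_at <- function(xq, tq) {
    # bilinear interpolation of the saved velocity field
    it <- findInterval(tq, sim$times, rightmost.closed = TRUE)
    it <- clamp(it, 1L, length(sim$times) - 1L)
    w <- (tq - sim$times[it]) / (sim$times[it + 1L] - sim$times[it])
    v1 <- stats::approx(sim$x, sim$v[it, ], xout = xq, rule = 2)$y
    v2 <- stats::approx(sim$x, sim$v[it + 1L, ], xout = xq, rule = 2)$y
    (1 - w) * v1 + w * v2
  }
  reflect <- function(x) {
    x <- ifelse(x < 0, -x, x)
    ifelse(x > L, 2 * L - x, x)
  }
  run <- function() {
    pos <- matrix(NA_real_, nt + 1L, n)
    pos[1L, ] <- initial_positions
    xc <- initial_positions
    for (s in seq_len(nt)) {
      tq <- t_start + (s - 1L) * dt
      xc <- xc + v_at(xc, tq) * dt
      if (D > 0) xc <- xc + sqrt(2 * D * dt) * stats::rnorm(n)
      xc <- reflect(xc)
      pos[s + 1L, ] <- xc
    }
    pos
  }
  pos <- if (D > 0) with_seed(seed, run()) else run()
  out <- data.frame(track_id = rep(seq_len(n), each = nt + 1L),
                    t_h = rep(t_start + (0:nt) * dt, times = n),
                    x_um = as.vector(pos))
  if (!is.null(region)) out$region <- rep(region, each = nt + 1L)
  class(out) <- c("tracer_tracks", "data.frame")
  out
}

#' Region-labelled tracer ensemble mirroring the live-imaging design
#'
#' Releases tracers at the osteogenic front and at stated distances toward
#' the bone center ("lateral" direction, -x), labelled \code{front},
#' \code{intermediate} (200 um lateral) and \code{lateral} (400 um lateral)
#' at release time.
#'
#' @param sim a \code{"wave_sim"}.
#' @param t0 release time (h); choose after the wave-formation transient.
#' @param duration tracked duration (h).
#' @param offsets named lateral offsets from the front at \code{t0} (um).
#' @param n_per_region tracers per region.
#' @param D,dt,seed passed to \code{\link{advect_tracers}}.
#' @return A \code{"tracer_tracks"} data.frame with a \code{region} column.
#' @export
tracer_ensemble <- function(sim, t0, duration,
                            offsets = c(front = 0, intermediate = 200,
                                        lateral = 400),
                            n_per_region = 30, D = sim$params$D, dt = 0.1,
                            seed = sim$params$seed) {
  f0 <- interp_strict(sim$times, front_trajectory(sim)$front_um, t0, "t0")
  x0 <- rep(f0 - offsets, each = n_per_region)
  region <- rep(names(offsets), each = n_per_region)
  advect_tracers(sim, x0, t_start = t0, t_end = t0 + duration, dt = dt,
                 D = D, seed = seed, region = region)
}

#' Relative displacement of the front versus tracked cells
#'
#' Both displacements are normalized by the total displacement of the
#' osteogenic front at the reference time, as in live-imaging analyses: the
#' front curve ends at exactly 1, and a cell curve ending below 1 means the
#' front outruns the tracked cells (newly differentiated osteoblasts are
#' added at the front).
#'
#' @param front a \code{"front_trajectory"} (absolute times) covering the
#'   tracer record.
#' @param tracks a \code{"tracer_tracks"} data.frame.
#' @param t_ref reference duration after the first tracked time (h),
#'   default 6.
#' @return data.frame with columns \code{t_h} (elapsed), \code{front},
#'   \code{cells}.
#' @export
relative_displacement_curve <- function(front, tracks, t_ref = 6) {
  tt <- sort(unique(tracks$t_h))
  t0 <- tt[1]
  if (max(tt) < t0 + t_ref - 1e-9)
    stopf("records do not reach t_ref = %g h", t_ref)
  f <- interp_strict(front$t_h, front$front_um, tt, "front trajectory time")
  f_ref <- interp_strict(front$t_h, front$front_um, t0 + t_ref, "t_ref")
  denom <- f_ref - f[1]
  if (denom == 0) stopf("zero front displacement at t_ref: normalization undefined")
  ids <- sort(unique(tracks$track_id))
  x0 <- tracks$x_um[tracks$t_h == t0][order(tracks$track_id[tracks$t_h == t0])]
  rel <- tracks$x_um - x0[match(tracks$track_id, ids)]
  disp <- tapply(rel, tracks$t_h, mean)  # factor levels sort numerically = tt
  data.frame(t_h = tt - t0,
             front = (f - f[1]) / denom,
             cells = as.numeric(disp) / denom)
}

#' Front and mean-cell displacement observables of a simulation
#'
#' Convenience wrapper used for model fitting and for the front-versus-cells
#' comparison: releases tracers at the front at \code{t0} and returns the
#' normalized displacement curves together with the front and mean tracer
#' speeds over the window.
#'
#' @param sim a \code{"wave_sim"}.
#' @param t0 release time (h); default half of the record (after the
#'   formation transient).
#' @param duration observation window (h), default 6.
#' @param t_ref normalization time (h), default \code{duration}.
#' @param n_tracers tracers released at the front.
#' @param D tracer diffusivity; 0 gives the deterministic mean path.
#' @param dt,seed passed to \code{\link{advect_tracers}}.
#' @return List with \code{curves} (data.frame \code{t_h}, \code{front},
#'   \code{cells}), \code{front_speed}, \code{cell_speed} (um/h), and
#'   \code{speed_ratio}.
#' @export
displacement_observables <- function(sim, t0 = max(sim$times) / 2,
                                     duration = 6, t_ref = duration,
                                     n_tracers = 30, D = sim$params$D,
                                     dt = 0.1, seed = sim$params$seed) {
  traj <- front_trajectory(sim)
  f0 <- interp_strict(traj$t_h, traj$front_um, t0, "t0")
  tracks <- advect_tracers(sim, rep(f0, n_tracers), t_start = t0,
                           t_end = t0 + duration, dt = dt, D = D, seed = seed)
  curves <- relative_displacement_curve(traj, tracks, t_ref = t_ref)
  f_disp <- interp_strict(traj$t_h, traj$front_um, t0 + duration, "window") - f0
  final <- tracks$t_h == max(tracks$t_h)
  first <- tracks$t_h == min(tracks$t_h)
  c_disp <- mean(tracks$x_um[final]) - mean(tracks$x_um[first])
  list(curves = curves,
       front_speed = f_disp / duration,
       cell_speed = c_disp / duration,
       speed_ratio = f_disp / c_disp)
}
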