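#' Reporter-intensity profiles predicted from a simulation
#'
#' Maps a simulated differentiation wave to synthetic GFP-reporter intensity
#' profiles. Reporter signal grows with osteoblast maturity, so the local
#' intensity is modelled as a saturating function of the time since the
#' front passed: \code{I(x) = baseline + (plateau - baseline)
#' min(age(x) / maturation_h, 1)}, with \code{age} derived from the front
#' trajectory (linearly extrapolated into the pre-existing bone, where the
#' signal is saturated anyway). Because the age gradient behind the front is
#' \code{1/c}, a faster wave produces a shallower intensity slope — the
#' readout used to compare control and crosslinking-perturbed tissue.
#' Per-sample jitter and multiplicative log-normal noise mirror
#' \code{\link{generate_profiles}}.
#'
#' @param sim a \code{"wave_sim"}.
#' @param time_h evaluation time (h); default the final save.
#' @param maturation_h reporter maturation time (h); default 60 (the reporter
#'   accumulates over days, so intensity rises across the full imaged depth).
#' @param plateau,baseline intensity levels (a.u.).
#' @param n_samples number of synthetic samples.
#' @param noise_sd multiplicative log-normal noise (sdlog); default 0.01,
#'   reflecting transverse-averaged intensity profiles.
#' @param jitter_sd_um per-sample offset jitter (um).
#' @param seed RNG seed.
#' @return data.frame compatible with \code{\link{align_intensity_profiles}}.
#' @export
simulate_gfp_profiles <- function(sim, time_h = max(sim$times),
                                  maturation_h = 60, plateau = 100,
                                  baseline = 20, n_samples = 6,
                                  noise_sd = 0.01, jitter_sd_um = 5,
                                  seed = sim$params$seed) {
  traj <- front_trajectory(sim)
  sp <- front_speed(traj)
  # time at which the front passed position x (linear extrapolation outside)
  t_front <- function(x) {
    inside <- x >= min(traj$front_um) & x <= max(traj$front_um)
    out <- numeric(length(x))
    out[inside] <- stats::approx(traj$front_um, traj$t_h, xout = x[inside],
                                 ties = "ordered")$y
    out[!inside] <- (x[!inside] - sp$intercept) / sp$speed
    out
  }
  x <- sim$x
  age <- time_h - t_front(x)
  maturity <- clamp(age / maturation_h, 0, 1)
  mu0 <- baseline + (plateau - baseline) * maturity
  f_now <- interp_strict(traj$t_h, traj$front_um, time_h, "evaluation time")
  with_seed(seed, {
    out <- lapply(seq_len(n_samples), function(s) {
      off <- stats::rnorm(1, 0, jitter_sd_um)
      mu <- stats::approx(x + off, mu0, xout = x, rule = 2)$y
      noise <- if (noise_sd > 0) exp(stats::rnorm(length(x), 0, noise_sd)) else 1
      data.frame(sample_id = sprintf("s%02d", s), time_h = time_h,
                 x_um = x, intensity = mu * noise,
                 is_baseline = x >= f_now + 60)
    })
    do.call(rbind, out)
  })
}
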