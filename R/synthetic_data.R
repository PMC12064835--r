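#' Specification for synthetic cell tracks
#'
#' Parameters of a persistent-random-walk generator emulating live-imaging
#' nuclei tracks in three medial-lateral regions: persistent (near-ballistic)
#' motion at the osteogenic front, progressively more diffusive motion
#' toward the dense bone center.
#'
#' @param n_tracks named counts per region (\code{front},
#'   \code{intermediate}, \code{lateral}).
#' @param frame_h frame interval (h); default 1/6 (10 min).
#' @param duration_h track duration (h); default 12.
#' @param speed_um_h cell speed scale (um/h); default 2.
#' @param tau_p_h named persistence times per region (h); \code{Inf} gives
#'   straight tracks.
#' @param d_floor_um2_h diffusion floor added to all regions (um^2/h).
#' @param drift_um_h named medial (+x) drift per region (um/h).
#' @param region_x0_um named initial x offsets per region (um); front at 0,
#'   bone center at negative x.
#' @param y_extent_um transverse extent over which tracks start (um).
#' @param seed RNG seed.
#' @return List of class \code{"track_spec"}.
#' @export
track_spec <- function(n_tracks = c(front = 60, intermediate = 60, lateral = 60),
                       frame_h = 1 / 6, duration_h = 12, speed_um_h = 2,
                       tau_p_h = c(front = 6, intermediate = 3, lateral = 0.4),
                       d_floor_um2_h = 0.05,
                       drift_um_h = c(front = 1, intermediate = 0.4,
                                      lateral = 0.1),
                       region_x0_um = c(front = 0, intermediate = -200,
                                        lateral = -400),
                       y_extent_um = 300, seed = 1) {
  regions <- c("front", "intermediate", "lateral")
  stopifnot(all(regions %in% names(n_tracks)),
            all(regions %in% names(tau_p_h)),
            all(regions %in% names(drift_um_h)),
            frame_h > 0, duration_h > 0, speed_um_h >= 0,
            d_floor_um2_h >= 0, all(tau_p_h >= 0))
  structure(list(n_tracks = n_tracks, frame_h = frame_h,
                 duration_h = duration_h, speed_um_h = speed_um_h,
                 tau_p_h = tau_p_h, d_floor_um2_h = d_floor_um2_h,
                 drift_um_h = drift_um_h, region_x0_um = region_x0_um,
                 y_extent_um = y_extent_um, seed = seed),
            class = "track_spec")
}

#' Generate persistent-random-walk cell tracks
#'
#' 2D persistent random walk: the heading angle diffuses with rotational
#' relaxation time \code{tau_p}, positions advance with the region's speed
#' and medial drift plus a Gaussian diffusion floor. Pure functions of spec
#' and seed: identical bytes on re-run.
#'
#' @param spec a \code{\link{track_spec}}.
#' @return data.frame with \code{track_id}, \code{t_h}, \code{x_um},
#'   \code{y_um}, \code{region}.
#' @export
generate_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_spec"))
  nt <- round(spec$duration_h / spec$frame_h)
  times <- (0:nt) * spec$frame_h
  with_seed(spec$seed, {
    out <- list(); id0 <- 0L
    for (rg in names(spec$n_tracks)) {
      n <- spec$n_tracks[[rg]]
      if (n == 0) next
      tp <- spec$tau_p_h[[rg]]
      x <- matrix(NA_real_, nt + 1L, n); y <- x
      x[1L, ] <- spec$region_x0_um[[rg]] + stats::runif(n, -10, 10)
      y[1L, ] <- stats::runif(n, 0, spec$y_extent_um)
      th <- stats::runif(n, 0, 2 * pi)
      sig_th <- if (is.infinite(tp)) 0 else sqrt(2 * spec$frame_h / max(tp, 1e-12))
      sig_d <- sqrt(2 * spec$d_floor_um2_h * spec$frame_h)
      for (s in seq_len(nt)) {
        if (tp == 0) th <- stats::runif(n, 0, 2 * pi)
        else if (sig_th > 0) th <- th + sig_th * stats::rnorm(n)
        x[s + 1L, ] <- x[s, ] +
          (spec$speed_um_h * cos(th) + spec$drift_um_h[[rg]]) * spec$frame_h +
          sig_d * stats::rnorm(n)
        y[s + 1L, ] <- y[s, ] + spec$speed_um_h * sin(th) * spec$frame_h +
          sig_d * stats::rnorm(n)
      }
      out[[rg]] <- data.frame(
        track_id = rep(id0 + seq_len(n), each = nt + 1L),
        t_h = rep(times, times = n),
        x_um = as.vector(x), y_um = as.vector(y), region = rg)
      id0 <- id0 + n
    }
    do.call(rbind, out)
  })
}

#' Specification for synthetic intensity profiles
#'
#' Sigmoidal reporter-intensity wavefront along the medial-lateral axis,
#' translating with the stated center trajectory, with per-sample alignment
#' jitter and multiplicative log-normal (fluorescence-like) noise.
#'
#' @param center_um_h data.frame with \code{t_h} and \code{center_um}, or a
#'   single center position.
#' @param width_um sigmoid width (um).
#' @param plateau,baseline plateau (bone) and baseline (mesenchyme)
#'   intensities (a.u.), \code{plateau > baseline > 0}.
#' @param noise_sd multiplicative log-normal noise (sdlog); default 0.02.
#'   Profiles represent transverse-averaged intensities, so per-point noise
#'   is small; it must stay well below the alignment threshold fraction or
#'   the first-exceedance alignment scan triggers on baseline noise.
#' @param jitter_sd_um per-sample offset jitter (um).
#' @param n_samples samples per time point.
#' @param x_um sampled positions (um).
#' @param baseline_margin_um distance medial of the nominal center beyond
#'   which the baseline region is annotated.
#' @param seed RNG seed.
#' @return List of class \code{"profile_spec"}.
#' @export
profile_spec <- function(center_um_h = 500, width_um = 15, plateau = 100,
                         baseline = 20, noise_sd = 0.02, jitter_sd_um = 5,
                         n_samples = 6, x_um = seq(0, 1000, by = 2),
                         baseline_margin_um = 80, seed = 1) {
  if (is.numeric(center_um_h))
    center_um_h <- data.frame(t_h = 0, center_um = center_um_h)
  stopifnot(plateau > baseline, baseline > 0, width_um > 0,
            noise_sd >= 0, jitter_sd_um >= 0, n_samples >= 1)
  structure(list(center = center_um_h, width_um = width_um, plateau = plateau,
                 baseline = baseline, noise_sd = noise_sd,
                 jitter_sd_um = jitter_sd_um, n_samples = n_samples,
                 x_um = x_um, baseline_margin_um = baseline_margin_um,
                 seed = seed),
            class = "profile_spec")
}

#' Generate synthetic sigmoidal intensity profiles
#'
#' \code{intensity(x, t) = baseline + (plateau - baseline)
#' logistic((center(t) - x) / width)} (high on the bone side, decaying to the
#' mesenchyme baseline medially), per-sample offset jitter, multiplicative
#' log-normal noise. The baseline region is annotated medial of the nominal
#' front.
#'
#' @param spec a \code{\link{profile_spec}}.
#' @return data.frame with \code{sample_id}, \code{time_h}, \code{x_um},
#'   \code{intensity}, \code{is_baseline}.
#' @export
generate_profiles <- function(spec) {
  stopifnot(inherits(spec, "profile_spec"))
  with_seed(spec$seed, {
    out <- list()
    for (i in seq_len(nrow(spec$center))) {
      ctr <- spec$center$center_um[i]; tt <- spec$center$t_h[i]
      for (s in seq_len(spec$n_samples)) {
        off <- stats::rnorm(1, 0, spec$jitter_sd_um)
        mu <- spec$baseline + (spec$plateau - spec$baseline) *
          stats::plogis((ctr + off - spec$x_um) / spec$width_um)
        noise <- if (spec$noise_sd > 0)
          exp(stats::rnorm(length(spec$x_um), 0, spec$noise_sd)) else 1
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sprintf("t%g_s%02d", tt, s), time_h = tt,
          x_um = spec$x_um, intensity = mu * noise,
          is_baseline = spec$x_um >= ctr + spec$baseline_margin_um)
      }
    }
    do.call(rbind, out)
  })
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler; used for synthetic division angles.
#'
#' @param n sample size.
#' @param mu_deg mean direction (degrees).
#' @param kappa concentration (>= 0); 0 gives the uniform circle.
#' @return Angles in degrees in \[0, 360).
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  th <- numeric(n); got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nn <- sum(ok)
    if (nn) {
      th[got + seq_len(nn)] <- mu + sign(u3[ok] - 0.5) * acos(f[ok])
      got <- got + nn
    }
  }
  (th * 180 / pi) %% 360
}

#' Generate synthetic division angles and daughter-displacement events
#'
#' Von Mises division angles concentrated around the expansion-parallel
#' orientation, and paired daughter displacements with a medial bias: medial
#' and lateral daughters displace \code{d + bias/2} and \code{d - bias/2}
#' (plus Gaussian noise) in opposite directions along the expansion axis.
#'
#' @param n number of divisions.
#' @param mu_deg mean division angle (degrees); default 90 (parallel to the
#'   medial-lateral axis).
#' @param kappa von Mises concentration.
#' @param bias_um medial displacement bias (um).
#' @param d_um mean daughter displacement magnitude (um); default 5.
#' @param noise_sd_um Gaussian displacement noise (um); default 1.
#' @param seed RNG seed.
#' @return List with \code{angles_deg} and \code{events} (data.frame ready
#'   for \code{\link{daughter_displacement}}).
#' @export
generate_division_data <- function(n, mu_deg = 90, kappa = 2, bias_um = 1,
                                   d_um = 5, noise_sd_um = 1, seed = 1) {
  with_seed(seed, {
    angles <- rvonmises(n, mu_deg, kappa)
    plate_x <- stats::runif(n, 0, 500); plate_y <- stats::runif(n, 0, 300)
    dm <- d_um + bias_um / 2 + stats::rnorm(n, 0, noise_sd_um)
    dl <- d_um - bias_um / 2 + stats::rnorm(n, 0, noise_sd_um)
    events <- data.frame(event_id = seq_len(n),
                         plate_x = plate_x, plate_y = plate_y,
                         d1_x = plate_x + dm, d1_y = plate_y,
                         d2_x = plate_x - dl, d2_y = plate_y)
    list(angles_deg = angles, events = events)
  })
}

#' Generate a synthetic bone image with known area
#'
#' Ellipse (or rectangle) of plateau intensity on a darker background with
#' additive Gaussian noise; returns the ground-truth foreground area for
#' segmentation checks. Optionally adds a second, smaller blob.
#'
#' @param nrow,ncol raster size (pixels).
#' @param shape \code{"ellipse"} or \code{"rectangle"}.
#' @param center blob center (row, col).
#' @param semiaxes blob semi-axes (pixels).
#' @param fg,bg foreground/background intensities.
#' @param noise_sd additive Gaussian noise sd.
#' @param second_blob optional list(center, semiaxes) for a second blob.
#' @param seed RNG seed.
#' @return List with \code{image} (matrix), \code{true_area_px},
#'   \code{true_mask}.
#' @export
generate_bone_image <- function(nrow = 120, ncol = 160, shape = "ellipse",
                                center = c(60, 70), semiaxes = c(30, 45),
                                fg = 200, bg = 50, noise_sd = 0,
                                second_blob = NULL, seed = 1) {
  rr <- row(matrix(0, nrow, ncol)); cc <- col(matrix(0, nrow, ncol))
  blob <- function(ctr, ax) {
    if (shape == "rectangle")
      abs(rr - ctr[1]) <= ax[1] & abs(cc - ctr[2]) <= ax[2]
    else ((rr - ctr[1]) / ax[1])^2 + ((cc - ctr[2]) / ax[2])^2 <= 1
  }
  mask <- blob(center, semiaxes)
  if (!is.null(second_blob)) mask2 <- blob(second_blob$center, second_blob$semiaxes)
  else mask2 <- mask & FALSE
  img <- matrix(bg, nrow, ncol)
  img[mask | mask2] <- fg
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(nrow * ncol, 0, noise_sd),
                                        nrow, ncol))
  list(image = img, true_area_px = sum(mask), true_mask = mask)
}

#' Synthetic nuclei with mitosis labels for regional proliferation
#'
#' Uniform nuclei positions with independent PH3-positive labels at a fixed
#' rate; used to validate the regional counting procedure.
#'
#' @param n nuclei count.
#' @param rate PH3-positive probability.
#' @param x_range positions range (um).
#' @param seed RNG seed.
#' @return data.frame with \code{x_um}, \code{ph3}.
#' @export
generate_nuclei <- function(n, rate, x_range = c(0, 600), seed = 1) {
  with_seed(seed, data.frame(
    x_um = stats::runif(n, x_range[1], x_range[2]),
    ph3 = stats::runif(n) < rate))
}
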