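#' Mean squared displacement of cell tracks
#'
#' From-origin definition used for live-imaging nuclei: for each elapsed time
#' T, \code{MSD(T) = mean_i |x_i(T) - x_i(0)|^2}, averaged over tracks (not
#' over reference times). Tracks must share a common time base; interpolation
#' is deliberately not performed. With a \code{region} column, per-region
#' curves are returned alongside the pooled curve.
#'
#' @param tracks data.frame with columns \code{track_id}, \code{t_h},
#'   \code{x_um} and optionally \code{y_um} (2D) and \code{region}.
#' @return data.frame with columns \code{region} ("all" plus any labels),
#'   \code{t_h} (elapsed time), \code{msd} (um^2), \code{n_tracks}.
#' @export
msd <- function(tracks) {
  split_tracks <- split(tracks, tracks$track_id)
  bases <- lapply(split_tracks, function(tr) tr$t_h - tr$t_h[1])
  base <- bases[[1]]
  same <- vapply(bases, function(b)
    length(b) == length(base) && all(abs(b - base) < 1e-9), logical(1))
  if (!all(same))
    stopf("tracks do not share a common time base (interpolation is not performed)")
  has_y <- "y_um" %in% names(tracks)
  sq <- vapply(split_tracks, function(tr) {
    d2 <- (tr$x_um - tr$x_um[1])^2
    if (has_y) d2 <- d2 + (tr$y_um - tr$y_um[1])^2
    d2
  }, numeric(length(base)))
  sq <- matrix(sq, nrow = length(base))
  regions <- if ("region" %in% names(tracks))
    vapply(split_tracks, function(tr) as.character(tr$region[1]), character(1))
  else NULL
  one <- function(cols, label) data.frame(
    region = label, t_h = base,
    msd = rowMeans(sq[, cols, drop = FALSE]), n_tracks = length(cols))
  out <- one(seq_len(ncol(sq)), "all")
  if (!is.null(regions))
    for (r in unique(regions)) out <- rbind(out, one(which(regions == r), r))
  out
}

#' Scaling exponent of an MSD curve
#'
#' Least-squares slope of \code{log MSD} versus \code{log T} on a time
#' window: 2 indicates ballistic, 1 diffusive motion. Cells at the osteogenic
#' front stay ballistic far longer than cells in the dense bone center.
#'
#' @param curve data.frame with \code{t_h} and \code{msd} (one region).
#' @param window time range \code{c(tmin, tmax)} (h).
#' @return The fitted exponent.
#' @export
msd_scaling_exponent <- function(curve, window = range(curve$t_h[curve$t_h > 0])) {
  use <- curve$t_h >= window[1] - 1e-12 & curve$t_h <= window[2] + 1e-12 &
    curve$t_h > 0
  if (sum(use) < 3L) stopf("need at least 3 positive-lag points in the window")
  if (any(curve$msd[use] <= 0)) stopf("msd must be positive in the window")
  unname(stats::coef(stats::lm(log(curve$msd[use]) ~ log(curve$t_h[use])))[2])
}

#' Spatial correlation of cell velocity directions
#'
#' For every pair of cells with finite velocity at time \code{t}, the dot
#' product of their unit velocity vectors is averaged within bins of the
#' transverse (y) distance \code{|y_i - y_j|}: collective, aligned motion
#' gives correlations near 1. Velocities are centered finite differences at
#' interior frames and one-sided at the track ends; zero-velocity cells are
#' excluded.
#'
#' @param tracks data.frame with \code{track_id}, \code{t_h}, \code{x_um},
#'   \code{y_um}.
#' @param t evaluation time (h); the nearest frame is used.
#' @param bin_width distance bin width (um), default 20.
#' @return data.frame with \code{dist_um} (bin centers), \code{C},
#'   \code{n_pairs}.
#' @export
velocity_spatial_correlation <- function(tracks, t, bin_width = 20) {
  per <- split(tracks, tracks$track_id)
  vel <- lapply(per, function(tr) {
    i <- which.min(abs(tr$t_h - t))
    n <- nrow(tr)
    if (n < 2L) return(NULL)
    j1 <- if (i == 1L) 1L else i - 1L
    j2 <- if (i == n) n else i + 1L
    dtt <- tr$t_h[j2] - tr$t_h[j1]
    c(vx = (tr$x_um[j2] - tr$x_um[j1]) / dtt,
      vy = (tr$y_um[j2] - tr$y_um[j1]) / dtt,
      y = tr$y_um[i])
  })
  vel <- do.call(rbind, vel[!vapply(vel, is.null, logical(1))])
  sp <- sqrt(vel[, "vx"]^2 + vel[, "vy"]^2)
  keep <- is.finite(sp) & sp > 0
  if (sum(keep) < 2L) stopf("need at least 2 cells with non-zero finite velocity")
  ux <- vel[keep, "vx"] / sp[keep]; uy <- vel[keep, "vy"] / sp[keep]
  y <- vel[keep, "y"]
  pr <- utils::combn(seq_along(y), 2L)
  dd <- abs(y[pr[1, ]] - y[pr[2, ]])
  cc <- ux[pr[1, ]] * ux[pr[2, ]] + uy[pr[1, ]] * uy[pr[2, ]]
  bin <- floor(dd / bin_width)
  agg <- tapply(cc, bin, mean)
  cnt <- tapply(cc, bin, length)
  data.frame(dist_um = (as.numeric(names(agg)) + 0.5) * bin_width,
             C = as.numeric(agg), n_pairs = as.integer(cnt))
}
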