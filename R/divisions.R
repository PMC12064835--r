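#' Circular statistics of division orientation
#'
#' Summary of division angles on the circle, in the imaging convention where
#' 90 degrees means a division parallel to the medial-lateral axis of
#' expansion: mean angle (direction of the resultant), mean resultant length
#' \code{R}, the Rayleigh statistic \code{z = n R^2}, and the standard
#' Rayleigh approximation for the p-value,
#' \code{p = exp(sqrt(1 + 4n + 4(n^2 - z n)) - (1 + 2n))}.
#'
#' Angles are treated as plain circular data by default (the convention in
#' which a mean angle near 90 degrees is reported); set \code{axial = TRUE}
#' to double the angles for orientation-only (axial) data.
#'
#' @param angles_deg division angles in degrees.
#' @param axial treat the data as axial (default FALSE).
#' @return List of class \code{"circular_summary"} with \code{mean_deg},
#'   \code{R}, \code{z}, \code{p}, \code{n}.
#' @export
circular_stats <- function(angles_deg, axial = FALSE) {
  if (!length(angles_deg)) stopf("empty angle input")
  mult <- if (axial) 2 else 1
  th <- angles_deg * pi / 180 * mult
  Cbar <- mean(cos(th)); Sbar <- mean(sin(th))
  R <- sqrt(Cbar^2 + Sbar^2)
  n <- length(th)
  mean_deg <- (atan2(Sbar, Cbar) * 180 / pi / mult) %% (360 / mult)
  z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - z * n)) - (1 + 2 * n))
  structure(list(mean_deg = mean_deg, R = R, z = z, p = min(p, 1), n = n,
                 axial = axial),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("Mean angle %.1f deg, R = %.3f, Rayleigh z = %.1f (n = %d), p = %.3g%s\n",
              x$mean_deg, x$R, x$z, x$n, x$p, if (x$axial) " [axial]" else ""))
  invisible(x)
}

#' Medial/lateral displacement of daughter nuclei after division
#'
#' Projects each daughter centroid onto the expansion axis relative to the
#' metaphase-plate centroid; per division the daughter with the larger
#' signed projection is the medial one. The paired table feeds a paired test
#' downstream (delegated to standard routines).
#'
#' @param events data.frame with columns \code{plate_x}, \code{plate_y},
#'   \code{d1_x}, \code{d1_y}, \code{d2_x}, \code{d2_y} and optionally
#'   \code{event_id}.
#' @param axis expansion-axis vector (default \code{c(1, 0)}, the +x medial
#'   direction).
#' @return data.frame with \code{event_id}, \code{medial}, \code{lateral}
#'   (signed um along the axis), \code{bias}
#'   (\code{|medial| - |lateral|}, the paired displacement difference), and
#'   \code{coincident} flag.
#' @export
daughter_displacement <- function(events, axis = c(1, 0)) {
  u <- axis / sqrt(sum(axis^2))
  p1 <- (events$d1_x - events$plate_x) * u[1] + (events$d1_y - events$plate_y) * u[2]
  p2 <- (events$d2_x - events$plate_x) * u[1] + (events$d2_y - events$plate_y) * u[2]
  coincident <- events$d1_x == events$d2_x & events$d1_y == events$d2_y
  medial <- pmax(p1, p2); lateral <- pmin(p1, p2)
  medial[coincident] <- 0; lateral[coincident] <- 0
  data.frame(event_id = if ("event_id" %in% names(events)) events$event_id
             else seq_len(nrow(events)),
             medial = medial, lateral = lateral,
             bias = abs(medial) - abs(lateral),
             coincident = coincident)
}
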