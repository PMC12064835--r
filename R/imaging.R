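#' Segment the frontal bone and measure its area
#'
#' Thresholds a grayscale image at a common intensity value and returns the
#' area of the largest 8-connected component, the procedure used to measure
#' frontal-bone sizes from fixed reporter images.
#'
#' @param image numeric matrix (grayscale raster) or path to a
#'   single-channel TIFF (read via the \pkg{tiff} package).
#' @param threshold intensity threshold; pixels with \code{image >=
#'   threshold} are foreground.
#' @param pixel_size pixel edge length (um); default 1.
#' @return List with \code{area_um2}, \code{n_pixels}, \code{mask} (logical
#'   matrix of the largest component), \code{n_components}, and \code{empty}
#'   flag (TRUE with a warning when no pixel passes the threshold).
#' @export
segment_bone_area <- function(image, threshold, pixel_size = 1) {
  if (is.character(image)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stopf("reading TIFF files requires the 'tiff' package")
    image <- tiff::readTIFF(image)
    if (length(dim(image)) == 3L) image <- image[, , 1L]
  }
  if (!is.matrix(image)) stopf("image must be a 2D raster")
  mask <- image >= threshold
  if (!any(mask)) {
    warning("empty mask: no pixel reaches the threshold", call. = FALSE)
    return(list(area_um2 = 0, n_pixels = 0L,
                mask = mask, n_components = 0L, empty = TRUE))
  }
  lab <- label_components8(mask)
  sizes <- tabulate(lab[mask])
  big <- which.max(sizes)
  list(area_um2 = sizes[big] * pixel_size^2, n_pixels = sizes[big],
       mask = lab == big, n_components = length(sizes), empty = FALSE)
}

# 8-connected component labelling via a vectorized pixel graph
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, nr, nc))
  pos <- matrix(0L, nr, nc); pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- pos[cbind(r2[ok], c2[ok])]
    hit <- nb > 0L
    edges[[length(edges) + 1L]] <-
      cbind(pos[cbind(r[ok], cc[ok])][hit], nb[hit])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges) || nrow(edges) == 0L) {
    out <- matrix(0L, nr, nc)
    out[idx] <- seq_along(idx)
    return(out)
  }
  g <- igraph::graph_from_edgelist(matrix(as.numeric(edges), ncol = 2),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out <- matrix(0L, nr, nc)
  out[idx] <- as.integer(comp[seq_along(idx)])
  out
}

#' Regional proliferation fractions from stained sections
#'
#' Percentage of PH3-positive (mitotic) nuclei in three 100-um regions
#' defined around the osteogenic front: the undifferentiated mesenchyme just
#' ahead (medial) of the front, the bone just behind it, and a box in the
#' bone center.
#'
#' @param nuclei data.frame with \code{x_um} and logical \code{ph3}.
#' @param front_x front position (um).
#' @param center_x bone-center reference position (um).
#' @param box_um region width (um), default 100.
#' @return data.frame with \code{region}, \code{n}, \code{n_positive},
#'   \code{pct} (NA with a warning for empty regions).
#' @export
regional_proliferation <- function(nuclei, front_x, center_x, box_um = 100) {
  regions <- list(
    um_ahead = c(front_x, front_x + box_um),
    bone_behind = c(front_x - box_um, front_x),
    bone_center = c(center_x - box_um / 2, center_x + box_um / 2))
  out <- do.call(rbind, lapply(names(regions), function(rn) {
    rg <- regions[[rn]]
    inr <- nuclei$x_um >= rg[1] & nuclei$x_um < rg[2]
    n <- sum(inr); np <- sum(nuclei$ph3[inr])
    data.frame(region = rn, n = n, n_positive = np,
               pct = if (n > 0) 100 * np / n else NA_real_)
  }))
  if (any(is.na(out$pct)))
    warning("empty region(s): ", paste(out$region[is.na(out$pct)],
                                       collapse = ", "), call. = FALSE)
  out
}
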