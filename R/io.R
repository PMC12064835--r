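#' Read and write the package's tabular dialects
#'
#' Thin, validating wrappers around CSV for the file dialects used
#' throughout: cell tracks (\code{track_id, t_h, x_um[, y_um][, region]}),
#' intensity profiles (\code{sample_id, x_um, intensity, is_baseline}),
#' division events (\code{event_id, plate_x, plate_y, d1_x, d1_y, d2_x,
#' d2_y}), and per-save simulation state tables (\code{x_um, rho_m, rho_o,
#' v_um_per_h, phi}).
#'
#' @param path file path.
#' @param x object to write.
#' @return The validated data.frame (readers); \code{path} invisibly
#'   (writers).
#' @name io_dialects
NULL

read_checked <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  df
}

#' @rdname io_dialects
#' @export
read_tracks <- function(path) read_checked(path, c("track_id", "t_h", "x_um"))

#' @rdname io_dialects
#' @export
write_tracks <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_dialects
#' @export
read_profiles <- function(path)
  read_checked(path, c("sample_id", "x_um", "intensity", "is_baseline"))

#' @rdname io_dialects
#' @export
write_profiles <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_dialects
#' @export
read_division_events <- function(path)
  read_checked(path, c("plate_x", "plate_y", "d1_x", "d1_y", "d2_x", "d2_y"))

#' Write per-save state tables of a simulation
#'
#' One CSV per saved state (columns \code{x_um, rho_m, rho_o, v_um_per_h,
#' phi}) plus a front-trajectory CSV.
#'
#' @param sim a \code{"wave_sim"}.
#' @param dir output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_states <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  phi <- sim_phi(sim)
  paths <- vapply(seq_along(sim$times), function(i) {
    p <- file.path(dir, sprintf("state_t%07.2fh.csv", sim$times[i]))
    utils::write.csv(data.frame(x_um = sim$x, rho_m = sim$rho_m[i, ],
                                rho_o = sim$rho_o[i, ],
                                v_um_per_h = sim$v[i, ], phi = phi[i, ]),
                     p, row.names = FALSE)
    p
  }, character(1))
  fp <- file.path(dir, "front_trajectory.csv")
  utils::write.csv(front_trajectory(sim), fp, row.names = FALSE)
  invisible(c(paths, fp))
}
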