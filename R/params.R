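#' Model parameters for the calvarial differentiation-wave model
#'
#' Constructs the full parameter set of the 1D two-population continuum model:
#' stiffnesses of the two tissue types, homeostatic densities, viscosity,
#' friction, cell diffusivity, division-rate relaxation time, maximal net
#' growth rate, the differentiation-stiffness coupling \code{beta} (the single
#' free parameter of the model), and the numerical grid/run controls. Defaults
#' are read from the versioned configuration file shipped in
#' \code{inst/extdata/default_params.yaml}.
#'
#' @param ... named overrides of any default parameter. Unknown names are an
#'   error. Key fields: \code{E_m}, \code{E_o} (kPa, with \code{E_o > E_m}),
#'   \code{rho0_m}, \code{rho0_o} (cells/um, \code{rho0_o > rho0_m}),
#'   \code{eta} (kPa h), \code{xi} (kPa h/um^2), \code{D} (um^2/h),
#'   \code{tau} (h), \code{alpha} (1/h), \code{beta} (1/h), \code{c_swell}
#'   (dimensionless matrix swelling strain),
#'   \code{domain_length} (um), \code{n_grid}, \code{dt} (h), \code{t_end} (h),
#'   \code{x_front0} (um), \code{save_every} (h), \code{advection}
#'   (\code{"upwind"} or \code{"vanleer"}), \code{seed}.
#' @return A validated list of class \code{"sim_params"}.
#' @export
#' @examples
#' p <- sim_params(beta = 0.25, t_end = 12)
#' p$E_o / p$E_m
sim_params <- function(...) {
  defaults <- default_params()
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stopf("all parameter overrides must be named")
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      stopf("unknown parameter key(s): %s", paste(unknown, collapse = ", "))
    defaults[names(over)] <- over
  }
  validate_params(defaults)
}

default_params <- function() {
  path <- system.file("extdata", "default_params.yaml", package = "osteowave")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "default_params.yaml")
  yaml::read_yaml(path)
}

#' @rdname sim_params
#' @param params a parameter list to validate.
#' @export
validate_params <- function(params) {
  errs <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  num1 <- function(key) {
    v <- params[[key]]
    ok <- is.numeric(v) && length(v) == 1L && is.finite(v)
    need(ok, sprintf("%s must be a single finite number", key))
    ok
  }
  keys <- c("E_m", "E_o", "rho0_m", "rho0_o", "eta", "xi", "D", "tau",
            "alpha", "beta", "c_swell", "domain_length", "n_grid", "dt",
            "t_end", "x_front0", "save_every", "seed")
  ok <- vapply(keys, num1, logical(1))
  if (all(ok[c("E_m", "E_o")]))
    need(params$E_o > params$E_m && params$E_m > 0, "E_o > E_m > 0")
  if (all(ok[c("rho0_m", "rho0_o")]))
    need(params$rho0_o > params$rho0_m && params$rho0_m > 0,
         "rho0_o > rho0_m > 0")
  for (k in c("eta", "xi", "D", "tau", "alpha", "beta", "c_swell"))
    if (ok[[k]]) need(params[[k]] >= 0, sprintf("%s >= 0", k))
  for (k in c("dt", "domain_length", "save_every"))
    if (ok[[k]]) need(params[[k]] > 0, sprintf("%s > 0", k))
  if (ok[["t_end"]]) need(params$t_end >= 0, "t_end >= 0")
  if (ok[["n_grid"]])
    need(params$n_grid >= 8 && params$n_grid == round(params$n_grid),
         "n_grid must be an integer >= 8")
  if (ok[["x_front0"]] && ok[["domain_length"]])
    need(params$x_front0 > 0 && params$x_front0 < params$domain_length,
         "x_front0 inside (0, domain_length)")
  if (all(ok[c("eta", "xi")]))
    need(params$eta > 0 || params$xi > 0, "eta and xi cannot both be zero")
  need(is.character(params$advection) &&
         params$advection %in% c("upwind", "vanleer"),
       "advection must be 'upwind' or 'vanleer'")
  if (length(errs))
    stopf("invalid parameters:\n  - %s", paste(errs, collapse = "\n  - "))
  structure(params, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> two-population calvarial wave model\n")
  cat(sprintf("  stiffness  E_m = %g, E_o = %g kPa  (ratio %.2f)\n",
              x$E_m, x$E_o, x$E_o / x$E_m))
  cat(sprintf("  densities  rho0_m = %g, rho0_o = %g cells/um\n",
              x$rho0_m, x$rho0_o))
  cat(sprintf("  mechanics  eta = %g kPa h, xi = %g kPa h/um^2 (l_h = %.1f um)\n",
              x$eta, x$xi, sqrt(x$eta / max(x$xi, .Machine$double.eps))))
  cat(sprintf("  kinetics   D = %g um^2/h, alpha = %g, beta = %g, tau = %g h, c_swell = %g\n",
              x$D, x$alpha, x$beta, x$tau, x$c_swell))
  cat(sprintf("  numerics   L = %g um, n = %d, dt = %g h, t_end = %g h (%s)\n",
              x$domain_length, as.integer(x$n_grid), x$dt, x$t_end,
              x$advection))
  invisible(x)
}

#' Load and validate a model configuration file
#'
#' Reads a flat YAML (or JSON) configuration holding \code{\link{sim_params}}
#' keys, fills unspecified keys from the package defaults, rejects unknown
#' keys by name, and reports every violated invariant at once.
#'
#' @param path path to a YAML or JSON configuration file.
#' @return A validated \code{"sim_params"} object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(cfg)) stopf("config must be a mapping of parameter keys")
  do.call(sim_params, cfg)
}

#' Write a configuration in canonical form
#'
#' Writes the parameter set as flat YAML with keys in canonical (default
#' file) order, so that validated round trips are byte-identical.
#'
#' @param params a \code{"sim_params"} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(params, path) {
  params <- validate_params(params)
  ord <- names(default_params())
  yaml::write_yaml(params[ord], path, precision = 15)
  invisible(path)
}
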