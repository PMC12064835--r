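#' In-silico bone-center excision
#'
#' Reproduces the explant experiment in which the stiff bone center is cut
#' away before live imaging. The protocol mirrors the experiment: a wave is
#' first established (the explant has a developed bone at dissection), then
#' the osteoblast bulk lateral of the front is removed, retaining only a
#' thin band of partially differentiated tissue at the front, and both the
#' intact control and the excised tissue are observed over a short imaging
#' window. The cavity is left empty and refills only by flow, diffusion and
#' proliferation; with the matrix-bearing bulk gone its swelling push
#' vanishes and the retained band is drawn laterally into the cavity, so
#' the front barely advances.
#'
#' The default band width (10 um) is the width of the partially
#' differentiated front zone of the model (osteoblast fraction still rising
#' toward 1); a wider band retains mature bone, which still pushes.
#'
#' @param params a \code{\link{sim_params}} object; \code{t_end} is used for
#'   the wave-establishment phase.
#' @param band_width width (um) of retained tissue lateral of the front;
#'   default 10.
#' @param observe_h imaging window after excision (h); default 6.
#' @param save_every_h save interval in the observation window (h).
#' @return List with \code{control} and \code{excised} front trajectories
#'   over the observation window (same time base), the displacement ratio
#'   \code{excised_displacement / control_displacement}, and the
#'   \code{"wave_sim"} objects.
#' @export
scenario_excision <- function(params, band_width = 10, observe_h = 6,
                              save_every_h = 0.5) {
  params <- validate_params(params)
  establish <- simulate_wave(params)
  last <- length(establish$times)
  st0 <- structure(list(x = establish$x, dx = establish$dx, t = 0,
                        rho_m = establish$rho_m[last, ],
                        rho_o = establish$rho_o[last, ],
                        k = establish$k[last, ]),
                   class = "field_state")
  f0 <- detect_front(establish$x, sim_phi(establish)[last, ])
  obs_params <- params
  obs_params$t_end <- observe_h; obs_params$save_every <- save_every_h
  control <- simulate_wave(obs_params, init = st0, check_margin = FALSE)
  st <- st0
  cut <- st$x < f0 - band_width
  st$rho_m[cut] <- 0; st$rho_o[cut] <- 0; st$k[cut] <- 0
  excised <- simulate_wave(obs_params, init = st, check_margin = FALSE)
  tc <- front_trajectory(control); te <- front_trajectory(excised)
  disp <- function(tr) tr$front_um[nrow(tr)] - tr$front_um[1]
  list(control = tc, excised = te,
       displacement_ratio = disp(te) / disp(tc),
       sims = list(establish = establish, control = control,
                   excised = excised))
}

#' In-silico stiffness-gradient steepening (collagen-crosslinking block)
#'
#' Emulates BAPN treatment, which softens the tissue at the osteogenic front
#' while mildly stiffening the bone center, thereby steepening the stiffness
#' gradient across the front: the treated run multiplies \code{E_m} by
#' \code{front_softening} (< 1) and \code{E_o} by \code{center_stiffening}
#' (>= 1). Returns the paired front trajectories and the final size of the
#' osteoblast domain (the region with phi >= 0.5).
#'
#' @param params a \code{\link{sim_params}} object (control).
#' @param front_softening multiplicative factor on \code{E_m}; default 0.5.
#' @param center_stiffening multiplicative factor on \code{E_o}; default 1.1.
#' @return List with \code{control}, \code{treated} front trajectories,
#'   \code{domain_control}, \code{domain_treated} (um), and both sims.
#' @export
scenario_gradient_steepening <- function(params, front_softening = 0.5,
                                         center_stiffening = 1.1) {
  params <- validate_params(params)
  if (front_softening <= 0 || center_stiffening <= 0)
    stopf("softening/stiffening factors must be positive")
  treated_params <- params
  treated_params$E_m <- params$E_m * front_softening
  treated_params$E_o <- params$E_o * center_stiffening
  if (treated_params$E_o <= treated_params$E_m)
    stopf("perturbed stiffnesses violate E_o > E_m")
  control <- simulate_wave(params)
  treated <- simulate_wave(treated_params)
  dom <- function(sim) {
    phi <- sim_phi(sim)
    sum(phi[nrow(phi), ] >= 0.5) * sim$dx
  }
  list(control = front_trajectory(control),
       treated = front_trajectory(treated),
       domain_control = dom(control), domain_treated = dom(treated),
       sims = list(control = control, treated = treated))
}
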