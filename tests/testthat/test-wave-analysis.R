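test_that("front detection interpolates the medial-most level crossing", {
  x <- seq(0, 100, by = 2)
  # step dropping from 1 to 0 between grid points: midpoint at level 0.5
  phi <- as.numeric(x < 50)          # 1 up to 48, 0 from 50
  expect_equal(detect_front(x, phi), 49)
  # logistic centered at x0 recovered within one grid spacing
  phi2 <- stats::plogis((37.3 - x) / 4)
  expect_lt(abs(detect_front(x, phi2) - 37.3), 2)
  # no crossing is an error
  expect_error(detect_front(x, rep(0.9, length(x))), "front not in domain")
})

test_that("noisy multi-crossing profiles agree with a brute-force scan", {
  set.seed(21)
  x <- seq(0, 200, by = 1)
  for (rep in 1:20) {
    phi <- stats::plogis((100 - x) / 8) + stats::rnorm(length(x), 0, 0.15)
    phi <- clamp_profile <- pmin(pmax(phi, 0), 1)
    s <- phi - 0.5
    idx <- which(s[-length(s)] * s[-1] <= 0 & !(s[-length(s)] == 0 & s[-1] == 0))
    if (!length(idx)) next
    i <- max(idx)  # exhaustive scan: largest-x bracketing pair
    oracle <- x[i] + (0.5 - phi[i]) / (phi[i + 1] - phi[i]) * (x[i + 1] - x[i])
    expect_equal(detect_front(x, phi), oracle)
  }
})

test_that("front detection is translation-equivariant", {
  x <- seq(0, 300, by = 1.5)
  phi <- stats::plogis((120 - x) / 10)
  f0 <- detect_front(x, phi)
  for (dx in c(-31.7, 12.25, 80)) {
    expect_equal(detect_front(x + dx, phi), f0 + dx)
  }
})

test_that("front speed fits discard the transient and flag short records", {
  t <- 0:20
  expect_equal(front_speed(t, 5 + 2.5 * t)$speed, 2.5)
  expect_equal(front_speed(t, rep(7, 21))$speed, 0)
  expect_error(front_speed(0:3, c(0, 1, 2, 3), transient_fraction = 0.9),
               "at least 3")
  # slope of a noisy linear record lies inside its own 95% CI
  set.seed(5)
  t <- seq(0, 10, length.out = 50)
  fit <- front_speed(t, 3 * t + stats::rnorm(50), transient_fraction = 0)
  expect_gt(3, fit$ci[1]); expect_lt(3, fit$ci[2])
})

test_that("tracers follow the flow exactly when deterministic", {
  sim <- flow_sim(function(x) rep(1.7, length(x)))
  tr <- advect_tracers(sim, c(50, 100), t_end = 20, dt = 0.5, D = 0)
  final <- tr[tr$t_h == 20, ]
  expect_equal(final$x_um, c(50, 100) + 1.7 * 20)
  expect_error(advect_tracers(sim, 600, D = 0), "outside the domain")
})

test_that("tracer integration error halves with the time step (D = 0)", {
  sim <- flow_sim(function(x) 0.02 * x)   # linear shear flow, exact: x0*exp(0.02 t)
  exact <- 100 * exp(0.02 * 20)
  err <- vapply(c(0.4, 0.2, 0.1), function(dt) {
    tr <- advect_tracers(sim, 100, t_end = 20, dt = dt, D = 0)
    abs(tr$x_um[which.max(tr$t_h)] - exact)
  }, numeric(1))
  ratios <- err[-length(err)] / err[-1]
  expect_true(all(ratios > 1.6 & ratios < 2.4))  # first-order convergence
})

test_that("diffusing tracers reproduce the 1D diffusion law and are seeded", {
  sim <- flow_sim(function(x) rep(0, length(x)), L = 4000, n = 401)
  D <- 2
  tr <- advect_tracers(sim, rep(2000, 2000), t_end = 10, dt = 0.25, D = D,
                       seed = 42)
  msd_t <- tapply((tr$x_um - 2000)^2, tr$t_h, mean)
  tt <- as.numeric(names(msd_t))
  expect_lt(max(abs(msd_t[tt > 2] / (2 * D * tt[tt > 2]) - 1)), 0.05)
  tr2 <- advect_tracers(sim, rep(2000, 2000), t_end = 10, dt = 0.25, D = D,
                        seed = 42)
  expect_identical(tr, tr2)
})

test_that("relative displacement normalizes to the front at t_ref", {
  front <- structure(data.frame(t_h = 0:10, front_um = 100 + 2 * (0:10)),
                     class = c("front_trajectory", "data.frame"))
  # tracers moving identically to the front
  tracks <- data.frame(track_id = rep(1:3, each = 11),
                       t_h = rep(0:10, 3),
                       x_um = rep(100 + 2 * (0:10), 3))
  rc <- relative_displacement_curve(front, tracks, t_ref = 6)
  expect_equal(rc$front, rc$cells)
  expect_equal(rc$front[rc$t_h == 6], 1)
  # stationary tracers give a zero cell curve
  tracks$x_um <- 100
  rc0 <- relative_displacement_curve(front, tracks, t_ref = 6)
  expect_equal(rc0$cells, rep(0, nrow(rc0)))
  # zero front displacement is an error
  still <- structure(data.frame(t_h = 0:10, front_um = rep(100, 11)),
                     class = c("front_trajectory", "data.frame"))
  expect_error(relative_displacement_curve(still, tracks), "normalization")
})

test_that("front roughness follows the RMS definition", {
  times <- 1:50
  flat <- matrix(100, 50, 8)
  expect_equal(front_fluctuations(flat, times)$W, rep(0, 50))
  # sinusoidal front line of amplitude A: W = A / sqrt(2)
  A <- 3
  y <- seq(0, 2 * pi * 16, length.out = 4000)  # many periods
  sine <- matrix(rep(A * sin(y), each = 50), 50, length(y), byrow = FALSE)
  sine <- t(matrix(A * sin(y), length(y), 50))
  W <- front_fluctuations(sine, times)$W
  expect_lt(max(abs(W - A / sqrt(2))), 0.01)
  # independent Gaussian jitter: W ~ sigma, no growth
  set.seed(9)
  sigma <- 2
  jit <- matrix(stats::rnorm(60 * 400, 0, sigma), 60, 400)
  fl <- front_fluctuations(jit, 1:60)
  expect_lt(abs(mean(fl$W) - sigma) / sigma, 0.05)
  expect_lt(abs(fl$growth_slope), 0.05)
  expect_error(front_fluctuations(matrix(1, 5, 1), 1:5), "transverse")
})

test_that("tracers released at the front outrun tracers in the bone center", {
  sim <- default_sim()
  tr <- tracer_ensemble(sim, t0 = 24, duration = 6, n_per_region = 80,
                        seed = 3)
  net <- tapply(tr$x_um, list(tr$region, tr$t_h), mean)
  disp <- net[, ncol(net)] - net[, 1]
  expect_gt(disp[["front"]], disp[["lateral"]])
})

test_that("excising the bone center halts expansion; a full-width band does not", {
  p <- sim_params(t_end = 24)
  ex <- memo("excision", scenario_excision(p))
  dc <- ex$control$front_um[nrow(ex$control)] - ex$control$front_um[1]
  de <- ex$excised$front_um[nrow(ex$excised)] - ex$excised$front_um[1]
  expect_gt(dc, 0)
  expect_lte(de, 0.2 * dc)
  # keeping the whole bone reproduces the control
  ex_full <- scenario_excision(p, band_width = p$x_front0 + p$t_end * 3)
  expect_lt(max(abs(ex_full$excised$front_um - ex_full$control$front_um)),
            1e-9)
})

test_that("steepening the stiffness gradient accelerates expansion", {
  p <- sim_params(t_end = 24)
  gs0 <- scenario_gradient_steepening(p, 1, 1)   # identity perturbation
  expect_equal(gs0$treated$front_um, gs0$control$front_um)
  gs <- scenario_gradient_steepening(p)
  expect_gt(gs$domain_treated, gs$domain_control)
  # monotone response to front softening
  sp <- vapply(c(1, 0.8, 0.6), function(fs)
    front_speed(scenario_gradient_steepening(p, fs, 1)$treated)$speed,
    numeric(1))
  expect_true(all(diff(sp) > 0))
  expect_error(scenario_gradient_steepening(p, 2, 0.5), "E_o > E_m")
})
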