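make_tracks <- function(pos_list, times, y_list = NULL) {
  do.call(rbind, lapply(seq_along(pos_list), function(i) {
    data.frame(track_id = i, t_h = times, x_um = pos_list[[i]],
               y_um = if (is.null(y_list)) 0 else y_list[[i]])
  }))
}

test_that("msd follows the from-origin definition", {
  times <- seq(0, 10, by = 0.5)
  # stationary track
  m <- msd(make_tracks(list(rep(3, 21)), times))
  expect_equal(m$msd, rep(0, 21))
  # ballistic track at speed s: msd = s^2 T^2 exactly
  s <- 1.7
  m2 <- msd(make_tracks(list(5 + s * times), times))
  expect_equal(m2$msd, s^2 * times^2)
  # mismatched time bases are an error, not interpolated
  bad <- rbind(data.frame(track_id = 1, t_h = times, x_um = 0, y_um = 0),
               data.frame(track_id = 2, t_h = times * 2, x_um = 0, y_um = 0))
  expect_error(msd(bad), "common time base")
})

test_that("msd and circular statistics match brute-force re-implementations", {
  set.seed(31)
  times <- seq(0, 5, by = 0.25)
  pos <- lapply(1:50, function(i) cumsum(stats::rnorm(length(times))))
  ys <- lapply(1:50, function(i) cumsum(stats::rnorm(length(times))))
  tracks <- make_tracks(pos, times, ys)
  m <- msd(tracks)
  # naive double loop
  brute <- sapply(seq_along(times), function(ti) {
    acc <- 0
    for (i in 1:50)
      acc <- acc + (pos[[i]][ti] - pos[[i]][1])^2 + (ys[[i]][ti] - ys[[i]][1])^2
    acc / 50
  })
  expect_lt(max(abs(m$msd - brute)), 1e-12)

  ang <- stats::runif(50, 0, 360)
  cs <- circular_stats(ang)
  Cb <- 0; Sb <- 0
  for (a in ang) { Cb <- Cb + cos(a * pi / 180); Sb <- Sb + sin(a * pi / 180) }
  R_brute <- sqrt((Cb / 50)^2 + (Sb / 50)^2)
  expect_lt(abs(cs$R - R_brute), 1e-12)
  expect_equal(cs$z, 50 * cs$R^2)
})

test_that("diffusive ensembles reproduce the 2D diffusion law", {
  set.seed(7)
  D <- 1.5; dt <- 0.25; nt <- 40; n <- 2000
  times <- (0:nt) * dt
  sig <- sqrt(2 * D * dt)
  pos <- lapply(1:n, function(i) c(0, cumsum(stats::rnorm(nt, 0, sig))))
  ys <- lapply(1:n, function(i) c(0, cumsum(stats::rnorm(nt, 0, sig))))
  m <- msd(make_tracks(pos, times, ys))
  sel <- m$t_h > 1
  expect_lt(max(abs(m$msd[sel] / (4 * D * m$t_h[sel]) - 1)), 0.05)
})

test_that("msd scaling exponents separate ballistic from diffusive motion", {
  tt <- seq(0.1, 10, by = 0.1)
  ball <- data.frame(t_h = tt, msd = 4 * tt^2)
  diff_ <- data.frame(t_h = tt, msd = 3 * tt)
  expect_lt(abs(msd_scaling_exponent(ball) - 2), 1e-9)
  expect_lt(abs(msd_scaling_exponent(diff_) - 1), 1e-9)
  expect_error(msd_scaling_exponent(data.frame(t_h = tt, msd = 0 * tt)),
               "positive")
})

test_that("velocity correlations distinguish aligned, opposed and random motion", {
  times <- 0:10
  # all cells moving the same direction: C = 1 in every occupied bin
  aligned <- make_tracks(lapply(1:6, function(i) times * 2), times,
                         lapply(1:6, function(i) rep(10 * i, 11)))
  cc <- velocity_spatial_correlation(aligned, t = 5, bin_width = 15)
  expect_equal(cc$C, rep(1, nrow(cc)))
  expect_equal(sum(cc$n_pairs), choose(6, 2))
  # two opposed cells: C = -1
  opposed <- make_tracks(list(times, -times), times, list(rep(0, 11), rep(5, 11)))
  expect_equal(velocity_spatial_correlation(opposed, 5, 20)$C, -1)
  # isotropic headings decorrelate
  set.seed(12)
  th <- stats::runif(500, 0, 2 * pi)
  iso <- make_tracks(lapply(1:500, function(i) times * cos(th[i])), times,
                     lapply(1:500, function(i) 0.4 * i + times * sin(th[i])))
  ci <- velocity_spatial_correlation(iso, 5, bin_width = 20)
  expect_true(all(abs(ci$C[ci$n_pairs >= 50]) < 0.1))
})

test_that("circular summaries are exact in degenerate cases", {
  cs <- circular_stats(rep(90, 10))
  expect_equal(cs$mean_deg, 90)
  expect_equal(cs$R, 1)
  expect_equal(cs$z, 10)
  cs0 <- circular_stats(c(0, 90, 180, 270))
  expect_lt(cs0$R, 1e-12)
  expect_lt(cs0$z, 1e-12)
  expect_error(circular_stats(numeric(0)), "empty")
  # axial option: orientations 10 and 190 are the same axis
  expect_equal(circular_stats(c(10, 190), axial = TRUE)$R, 1)
})

test_that("von Mises samples recover the Bessel-ratio resultant length", {
  kappa <- 2
  A_kappa <- besselI(kappa, 1) / besselI(kappa, 0)  # analytic mean resultant
  set.seed(2)
  ang <- rvonmises(500, 90, kappa)
  cs <- circular_stats(ang)
  expect_lt(abs(cs$R - A_kappa), 0.05)
  expect_lt(abs(cs$mean_deg - 90), 10)
})

test_that("daughter displacements project onto the expansion axis", {
  # event 2: both daughters displaced +4 along x (transversely separated);
  # event 3: coincident daughter centroids
  ev <- data.frame(plate_x = 0, plate_y = 0,
                   d1_x = c(4, 4, 1), d1_y = c(0, 1, 0),
                   d2_x = c(-4, 4, 1), d2_y = c(0, -1, 0))
  dd <- daughter_displacement(ev)
  expect_equal(dd$medial[1], 4); expect_equal(dd$lateral[1], -4)
  expect_equal(dd$medial[2], 4); expect_equal(dd$lateral[2], 4)
  expect_equal(dd$bias[2], 0)
  expect_true(dd$coincident[3])
  expect_equal(dd$medial[3], 0)
  # axis projection is direction-normalized
  ev2 <- data.frame(plate_x = 0, plate_y = 0, d1_x = 3, d1_y = 3,
                    d2_x = -3, d2_y = -3)
  dd2 <- daughter_displacement(ev2, axis = c(2, 2))
  expect_equal(dd2$medial, sqrt(18))
})

test_that("synthetic division data recover their generating bias", {
  gen <- generate_division_data(400, kappa = 8, bias_um = 1.2, seed = 5)
  dd <- daughter_displacement(gen$events)
  ci <- stats::t.test(dd$bias)$conf.int
  expect_gt(1.2, ci[1]); expect_lt(1.2, ci[2])
  cs <- circular_stats(gen$angles_deg)
  expect_lt(abs(cs$mean_deg - 90), 5)
})

test_that("profile alignment finds the baseline-threshold crossing exactly", {
  x <- seq(0, 200, by = 1)
  b <- 10
  # flat baseline stepping to 1.2 b at position p (bone side: small x)
  intens <- ifelse(x <= 80, 1.2 * b, b)
  pr <- data.frame(sample_id = "a", x_um = x, intensity = intens,
                   is_baseline = x >= 150)
  al <- align_intensity_profiles(pr)
  expect_equal(unname(al$alignment["a"]), 80)
  # two identical profiles shifted by 50 um align to identical curves, sd 0
  pr2 <- rbind(pr,
               data.frame(sample_id = "b", x_um = x + 50, intensity = intens,
                          is_baseline = x >= 150))
  al2 <- align_intensity_profiles(pr2)
  expect_equal(al2$curve$sd, rep(0, nrow(al2$curve)))
  expect_equal(unname(al2$alignment), c(80, 130))
  # no crossing reports the failing sample
  flat <- data.frame(sample_id = "bad", x_um = x, intensity = b,
                     is_baseline = x >= 150)
  expect_error(align_intensity_profiles(flat), "bad")
})

test_that("scaling a profile moves the slope, not the alignment point", {
  x <- seq(0, 300, by = 1)
  intens <- 20 + 80 * stats::plogis((100 - x) / 12)
  mk <- function(f) data.frame(sample_id = "s", x_um = x,
                               intensity = f * intens, is_baseline = x >= 220)
  a1 <- align_intensity_profiles(mk(1))
  a5 <- align_intensity_profiles(mk(5))
  expect_identical(unname(a1$alignment), unname(a5$alignment))
  s1 <- front_intensity_slope(a1)$slope
  s5 <- front_intensity_slope(a5)$slope
  expect_equal(s5, 5 * s1)
})

test_that("front intensity slope recovers exact ramps", {
  curve <- data.frame(dist_um = 0:120, mean = 5 + 0.37 * (0:120))
  expect_lt(abs(front_intensity_slope(curve)$slope - 0.37), 1e-9)
  flat <- data.frame(dist_um = 0:120, mean = rep(4, 121))
  expect_equal(front_intensity_slope(flat)$slope, 0)
  expect_error(front_intensity_slope(curve, window = c(0, 1)), "3 bins")
})

test_that("generated sigmoid profiles align back to their analytic shape", {
  spec <- profile_spec(center_um_h = 500, width_um = 15, plateau = 100,
                       baseline = 20, noise_sd = 0, jitter_sd_um = 8,
                       n_samples = 6, seed = 3)
  al <- align_intensity_profiles(generate_profiles(spec))
  # analytic aligned curve: same logistic expressed around its own
  # 10%-above-baseline crossing
  x <- seq(0, 1000, by = 2)
  ideal <- 20 + 80 * stats::plogis((500 - x) / 15)
  x0 <- max(x[ideal > 1.1 * 20])
  ideal_curve <- stats::approx(x0 - x, ideal, xout = al$curve$dist_um,
                               rule = 2)$y
  sel <- al$curve$dist_um >= 0 & al$curve$dist_um <= 100
  expect_lt(sqrt(mean((al$curve$mean[sel] - ideal_curve[sel])^2)), 1.5)
  # with multiplicative noise the aligned mean stays near truth (CLT)
  spec_n <- profile_spec(noise_sd = 0.02, jitter_sd_um = 8, n_samples = 8,
                         seed = 4)
  al_n <- align_intensity_profiles(generate_profiles(spec_n))
  sel_n <- al_n$curve$dist_um >= 0 & al_n$curve$dist_um <= 100
  ideal_n <- stats::approx(x0 - x, ideal, xout = al_n$curve$dist_um[sel_n],
                           rule = 2)$y
  rms <- sqrt(mean((al_n$curve$mean[sel_n] - ideal_n)^2))
  expect_lt(rms, 2.5 * 0.02 * 100 / sqrt(8))
})

test_that("more samples shrink the uncertainty band of the aligned mean", {
  # the standard-error band of the across-sample mean scales as 1/sqrt(n):
  # quadrupling the sample count halves it
  sem_of <- function(n, seed) {
    sp <- profile_spec(noise_sd = 0.02, jitter_sd_um = 0, n_samples = n,
                       seed = seed)
    al <- align_intensity_profiles(generate_profiles(sp))
    sel <- al$curve$dist_um >= 0 & al$curve$dist_um <= 100 &
      al$curve$n_samples == n
    mean(al$curve$sd[sel] / sqrt(n))
  }
  ratios <- vapply(1:20, function(s) sem_of(20, s) / sem_of(5, s + 100),
                   numeric(1))
  # approximate: the alignment-point spread grows slightly with n
  expect_lt(abs(mean(ratios) - 0.5), 0.15)
})

test_that("cohorts generated with different slopes keep their order", {
  # two cohorts of simulated reporter fronts whose generating waves differ
  slope_of <- function(width, seed) {
    sp <- profile_spec(width_um = width, noise_sd = 0.03, jitter_sd_um = 5,
                       n_samples = 6, seed = seed)
    front_intensity_slope(align_intensity_profiles(generate_profiles(sp)))$slope
  }
  ok <- sum(vapply(1:20, function(s) slope_of(12, s) > slope_of(30, s + 500),
                   logical(1)))
  expect_gte(ok, 19)
})

test_that("bone-area segmentation counts the largest 8-connected component", {
  img <- matrix(0, 60, 80)
  img[11:30, 21:50] <- 10      # 20 x 30 rectangle
  seg <- segment_bone_area(img, threshold = 5, pixel_size = 1)
  expect_equal(seg$area_um2, 600)
  # pixel size scales the area quadratically
  expect_equal(segment_bone_area(img, 5, pixel_size = 0.5)$area_um2, 150)
  # two blobs: the larger one wins
  img[45:54, 5:14] <- 10       # 100 px blob
  seg2 <- segment_bone_area(img, 5)
  expect_equal(seg2$n_pixels, 600)
  expect_equal(seg2$n_components, 2L)
  # salt noise does not perturb the largest component
  set.seed(8)
  salt <- img
  idx <- sample(which(salt == 0), 50)
  salt[idx] <- 10
  # drop any salt pixel 8-adjacent to the blobs to keep components separate
  near <- which(salt == 10 & img == 0)
  for (i in near) {
    r <- (i - 1) %% 60 + 1; cc <- (i - 1) %/% 60 + 1
    if (any(img[max(1, r - 1):min(60, r + 1),
                max(1, cc - 1):min(80, cc + 1)] == 10)) salt[i] <- 0
  }
  expect_equal(segment_bone_area(salt, 5)$n_pixels, 600)
  # diagonal touch merges under 8-connectivity
  dg <- matrix(0, 10, 10); dg[2, 2] <- 1; dg[3, 3] <- 1
  expect_equal(segment_bone_area(dg, 0.5)$n_pixels, 2)
  # empty mask warns and returns zero area
  expect_warning(z <- segment_bone_area(matrix(0, 5, 5), 1), "empty")
  expect_equal(z$area_um2, 0)
})

test_that("segmentation ignores the values of sub-threshold pixels", {
  set.seed(14)
  img <- matrix(stats::runif(2500, 0, 4), 50, 50)
  img[20:35, 10:30] <- 9
  s1 <- segment_bone_area(img, 5)
  below <- which(img < 5)
  img2 <- img
  img2[below] <- img[sample(below)]   # permute sub-threshold values
  s2 <- segment_bone_area(img2, 5)
  expect_identical(s1$mask, s2$mask)
  expect_equal(s1$area_um2, s2$area_um2)
})

test_that("synthetic bone images segment back to their true area", {
  g <- generate_bone_image(noise_sd = 0)
  expect_equal(segment_bone_area(g$image, 125)$n_pixels, g$true_area_px)
  gn <- generate_bone_image(noise_sd = 15, seed = 2)  # 10% of contrast
  expect_lt(abs(segment_bone_area(gn$image, 125)$n_pixels - g$true_area_px) /
              g$true_area_px, 0.02)
  g2 <- generate_bone_image(second_blob = list(center = c(30, 130),
                                               semiaxes = c(8, 10)))
  expect_equal(segment_bone_area(g2$image, 125)$n_pixels, g2$true_area_px)
})

test_that("regional proliferation fractions count PH3 labels per window", {
  nuc <- data.frame(x_um = c(runif(10, 300, 400)), ph3 = FALSE)
  out <- suppressWarnings(
    regional_proliferation(nuc, front_x = 300, center_x = 100))
  expect_equal(out$pct[out$region == "um_ahead"], 0)
  # 3 of 6 positive in one region
  nuc2 <- data.frame(x_um = c(seq(310, 360, by = 10), 150, 150),
                     ph3 = c(rep(c(TRUE, FALSE), 3), TRUE, FALSE))
  out2 <- suppressWarnings(
    regional_proliferation(nuc2, front_x = 300, center_x = 150))
  expect_equal(out2$pct[out2$region == "um_ahead"], 50)
  expect_equal(out2$pct[out2$region == "bone_center"], 50)
  expect_warning(regional_proliferation(nuc, front_x = 300, center_x = 700),
                 "empty")
  # randomized labels land inside the binomial confidence band
  q <- 0.15
  nuc3 <- generate_nuclei(1200, q, x_range = c(200, 500), seed = 6)
  out3 <- regional_proliferation(nuc3, front_x = 300, center_x = 250)
  for (i in which(out3$n > 100)) {
    ci <- stats::binom.test(out3$n_positive[i], out3$n[i])$conf.int * 100
    expect_gt(100 * q, ci[1]); expect_lt(100 * q, ci[2])
  }
})
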