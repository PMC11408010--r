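small_geom <- function(n = 48)
  detector_geometry(wavelength_nm = 0.1, distance_mm = 50, pixel_mm = 0.2,
                    center_x_px = (n + 1) / 2, center_y_px = (n + 1) / 2)

test_that("pattern1d validates its contract", {
  expect_error(pattern1d(c(1, 2), c(1, 2, 3)), "lengths differ")
  expect_error(pattern1d(c(0, 1), c(1, 1)), "positive")
  expect_error(pattern1d(c(2, 1), c(1, 1)), "strictly increasing")
  expect_error(pattern1d(c(1, 2), c(-1, 1)), "non-negative")
})

test_that("azimuthal integration matches per-pixel brute force exactly", {
  set.seed(21)
  n <- 48
  geom <- small_geom(n)
  img <- detector_image(matrix(runif(n * n, 0, 100), n, n), geom)
  for (nb in c(16, 40)) {
    got <- azimuthal_integrate(img, n_bins = nb)
    want <- bf_azimuthal(img$counts, geom, nb)
    expect_equal(got$q, want$q, tolerance = 1e-12)
    expect_equal(got$intensity, want$I, tolerance = 1e-12)
  }
})

test_that("integration: flat image, ring position, monitor, masking, sum mode", {
  n <- 64
  geom <- small_geom(n)
  flat <- detector_image(matrix(5, n, n), geom)
  p <- azimuthal_integrate(flat, n_bins = 24)
  expect_true(all(abs(p$intensity - 5) < 1e-12))
  # synthetic ring: peak within half a bin of q(r0)
  r0 <- 15
  dx <- matrix(seq_len(n) - geom$center_x_px, n, n, byrow = TRUE)
  dy <- matrix(seq_len(n) - geom$center_y_px, n, n)
  rr <- sqrt(dx^2 + dy^2)
  img <- detector_image(exp(-(rr - r0)^2 / 2) * 100, geom)
  pr <- azimuthal_integrate(img, n_bins = 48)
  q0 <- (4 * pi / geom$wavelength_nm) *
    sin(atan(r0 * geom$pixel_mm / geom$distance_mm) / 2)
  binw <- diff(pr$q[1:2])
  expect_lt(abs(pr$q[which.max(pr$intensity)] - q0), binw / 2 + 1e-12)
  # doubling the monitor halves normalized intensity
  img2 <- detector_image(img$counts, geom, monitor = 2)
  p2 <- azimuthal_integrate(img2, n_bins = 48)
  expect_equal(p2$intensity, pr$intensity / 2, tolerance = 1e-12)
  # masked pixels are excluded
  msk <- matrix(FALSE, n, n); msk[rr > r0 - 1 & rr < r0 + 1] <- TRUE
  p3 <- azimuthal_integrate(detector_image(img$counts, geom, mask = msk),
                            n_bins = 48)
  expect_lt(max(p3$intensity), max(pr$intensity) / 2)
  # sum mode conserves total unmasked counts
  ps <- azimuthal_integrate(img, n_bins = 48, mode = "sum")
  expect_equal(sum(ps$intensity), sum(img$counts), tolerance = 1e-9)
  # beam centre outside the image errors
  bad <- detector_geometry(center_x_px = 500, center_y_px = 2)
  expect_error(azimuthal_integrate(detector_image(matrix(1, 8, 8), bad)),
               "outside")
})

test_that("fit_peak recovers a noiseless Gaussian to 4 significant digits", {
  q <- seq(19, 23, by = 0.01)
  s <- 0.5 / 2.3548
  y <- 80 * exp(-(q - 21)^2 / (2 * s^2)) + 3
  pf <- fit_peak(pattern1d(q, y), window_q = c(20, 22))
  expect_equal(pf$center_q, 21, tolerance = 1e-4)
  expect_equal(pf$fwhm_q, 0.5, tolerance = 1e-4)
  # sloped baseline does not shift the centre
  y2 <- y + 2 + 0.8 * (q - 19)
  pf2 <- fit_peak(pattern1d(q, y2), window_q = c(20, 22))
  expect_lt(abs(pf2$center_q - 21) / 21, 0.001)
  # symmetric data about the centre: zero fitted slope (to fit precision)
  expect_lt(abs(pf$baseline[["slope"]]), 1e-4)
  # window without an interior maximum errors
  expect_error(fit_peak(pattern1d(q, y), window_q = c(19, 20.5)),
               "local maximum")
})

test_that("bragg_d: closed forms, identity, monotonicity", {
  expect_equal(bragg_d(13.80, 0.082656, input_kind = "two_theta_deg"),
               0.344, tolerance = 1e-3)
  # q = 2 pi / d identity
  expect_equal(bragg_d(2 * pi / 0.344, 0.082656, input_kind = "q"), 0.344,
               tolerance = 1e-12)
  d1 <- bragg_d(10, 0.0826, input_kind = "two_theta_deg")
  d2 <- bragg_d(20, 0.0826, input_kind = "two_theta_deg")
  expect_gt(d1, d2)
  expect_error(bragg_d(0, 0.0826, input_kind = "two_theta_deg"), "2-theta")
  expect_error(bragg_d(-1, 0.0826, input_kind = "q"), "center")
})

test_that("scherrer_size: closed form, proportionality, conversions", {
  expect_equal(scherrer_size(0.010, 6.90 * pi / 180, 0.082656), 8.33,
               tolerance = 1e-3)
  expect_equal(scherrer_size(0.005, 0.1, 0.0826),
               2 * scherrer_size(0.010, 0.1, 0.0826))
  expect_error(scherrer_size(0, 0.1, 0.08), "beta")
  expect_error(scherrer_size(0.01, 1.6, 0.08), "theta")
  # quadrature subtraction of instrumental width
  tau_raw <- scherrer_size(0.010, 0.1, 0.0826)
  tau_cor <- scherrer_size(0.010, 0.1, 0.0826,
                           instrumental_beta_rad = 0.006)
  expect_equal(tau_cor, scherrer_size(0.008, 0.1, 0.0826))
  expect_gt(tau_cor, tau_raw)
  # fwhm_q -> beta converter: consistent with the exact 2 pi K / tau law
  tau <- 20
  fq <- 2 * pi / tau
  cv <- fwhm_q_to_beta(fq, 2 * pi / 0.344, 0.082656)
  expect_equal(scherrer_size(cv$beta_rad, cv$theta_rad, 0.082656), tau,
               tolerance = 1e-10)
})

test_that("fit_kratky_T: recovery, exact scale invariance, truncation, guards", {
  sp <- make_saxs_pattern(T_true_nm = 3, noise_sd = 0)
  kt <- fit_kratky_T(sp$pattern)
  expect_lt(abs(kt$T_nm - 3) / 3, 0.05)
  # exact invariance under intensity rescaling
  p2 <- pattern1d(sp$pattern$q, sp$pattern$intensity * 37.5)
  kt2 <- fit_kratky_T(p2)
  expect_equal(kt2$T_nm, kt$T_nm, tolerance = 1e-12)
  expect_equal(kt2$P_porod, kt$P_porod * 37.5, tolerance = 1e-9)
  # truncating qmax by 20 %: analytic tail compensates (< 3 % change)
  keep <- sp$pattern$q <= 0.8 * max(sp$pattern$q)
  kt3 <- fit_kratky_T(pattern1d(sp$pattern$q[keep],
                                sp$pattern$intensity[keep]))
  expect_lt(abs(kt3$T_nm - kt$T_nm) / kt$T_nm, 0.03)
  # pattern that never reaches the plateau errors
  q <- seq(0.05, 8, length.out = 300)
  expect_error(fit_kratky_T(pattern1d(q, 100 * exp(-q^2 * 3))),
               "Porod")
})

test_that("q-scale calibration from calibrant rings", {
  ref <- c(10, 14.14, 17.32)
  obs <- ref / 1.02
  k <- q_scale_calibration(obs, ref)
  expect_equal(k, 1.02, tolerance = 1e-12)
  expect_error(q_scale_calibration(1:3, 1:2), "matching")
})

test_that("ultrastructure_report: per-point fits and group contrast", {
  pts <- lapply(1:4, function(i)
    make_saxs_pattern(T_true_nm = 3, noise_sd = 0.02, seed = i)$pattern)
  geom <- detector_geometry()
  waxs <- lapply(1:4, function(i) {
    fr <- make_waxs_frame(d_true_nm = 0.344, tau_true_nm = 20,
                          geometry = geom, shape_px = c(1024, 1024),
                          noise_model = list(type = "gaussian", sd = 30),
                          seed = i)
    azimuthal_integrate(fr, n_bins = 400)
  })
  res <- ultrastructure_report(saxs = pts, waxs = waxs,
                               lambda_nm = geom$wavelength_nm,
                               waxs_window_q = 2 * pi / 0.344 + c(-0.55, 0.55))
  expect_equal(nrow(res$points), 4)
  expect_lt(abs(res$summary["T_nm", "median"] - 3) / 3, 0.1)
  expect_lt(abs(res$summary["d002_nm", "median"] - 0.344) / 0.344, 0.005)
  expect_lt(abs(res$summary["tau002_nm", "median"] - 20) / 20, 0.1)
  expect_error(ultrastructure_report(), "empty ROI")
  expect_error(ultrastructure_report(saxs = pts, waxs = waxs[1:2]),
               "point counts differ")
})
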