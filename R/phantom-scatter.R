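# Scattering phantoms.
#
# WAXS: a Debye-Scherrer ring on a flat area detector. The radial centre
# encodes the lattice spacing via Bragg's law (q0 = 2*pi/d) and the
# Gaussian radial width encodes the crystallite size via the Scherrer
# relation: a FWHM of beta in 2-theta maps to fwhm_q = beta*(2*pi/lambda)*
# cos(theta) = 2*pi*K/tau, independent of angle.
#
# SAXS: a smooth two-phase intensity whose Porod constant P and invariant
# Q = int I q^2 dq satisfy the stack-of-cards identity T = 4Q/(pi*P)
# exactly; (A, Rg) are chosen in closed form from that identity.

#' Detector geometry descriptor
#'
#' @param wavelength_nm X-ray wavelength (default 0.082656, i.e. 15 keV).
#' @param distance_mm sample-detector distance.
#' @param pixel_mm detector pixel pitch.
#' @param center_x_px,center_y_px beam centre (pixel units, 1-based grid).
#' @return named list of class `detector_geometry`.
#' @export
detector_geometry <- function(wavelength_nm = 0.082656, distance_mm = 150,
                              pixel_mm = 0.075, center_x_px = 512.5,
                              center_y_px = 512.5) {
  check_scalar(wavelength_nm, "wavelength_nm", 0, strict_lower = TRUE)
  check_scalar(distance_mm, "distance_mm", 0, strict_lower = TRUE)
  check_scalar(pixel_mm, "pixel_mm", 0, strict_lower = TRUE)
  structure(list(wavelength_nm = wavelength_nm, distance_mm = distance_mm,
                 pixel_mm = pixel_mm, center_x_px = center_x_px,
                 center_y_px = center_y_px),
            class = "detector_geometry")
}

#' 2D area-detector frame
#'
#' @param counts numeric matrix of detector counts (rows = detector rows).
#' @param geometry a [detector_geometry()].
#' @param mask optional logical matrix of bad pixels (`TRUE` = masked).
#' @param monitor upstream beam-monitor value used for normalization.
#' @return object of class `detector_image`.
#' @export
detector_image <- function(counts, geometry, mask = NULL, monitor = 1) {
  stopifnot(inherits(geometry, "detector_geometry"))
  if (!is.matrix(counts)) stop_oq("`counts` must be a matrix")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(counts), ncol(counts))
  if (!identical(dim(mask), dim(counts)))
    stop_oq("bad-pixel mask shape does not match counts")
  if (any(counts[!mask] < 0)) stop_oq("negative counts in unmasked pixels")
  check_scalar(monitor, "monitor", 0, strict_lower = TRUE)
  structure(list(counts = counts, geometry = geometry, mask = mask,
                 monitor = monitor),
            class = "detector_image")
}

# q (nm^-1) at radius r_px pixels from the beam centre
q_of_radius <- function(r_px, geom) {
  two_theta <- atan(r_px * geom$pixel_mm / geom$distance_mm)
  (4 * pi / geom$wavelength_nm) * sin(two_theta / 2)
}

radius_of_q <- function(q, geom) {
  two_theta <- 2 * asin(q * geom$wavelength_nm / (4 * pi))
  geom$distance_mm * tan(two_theta) / geom$pixel_mm
}

#' Synthetic WAXS detector frame with a Debye-Scherrer ring
#'
#' The ring's radial centre corresponds to `d_true_nm` through Bragg's law
#' and its Gaussian radial FWHM in q is `2*pi*K/tau_true_nm` (Scherrer
#' broadening with zero instrumental width, shape factor K = 1).
#'
#' @param d_true_nm lattice spacing of the simulated reflection.
#' @param tau_true_nm crystallite size.
#' @param geometry a [detector_geometry()].
#' @param shape_px detector shape `c(nrows, ncols)`.
#' @param intensity peak intensity (counts) at the ring centre.
#' @param background flat background level (counts).
#' @param noise_model `list(type = "gaussian", sd = ...)` or
#'   `list(type = "none")`. Counts are floored at zero.
#' @param seed RNG seed.
#' @return a [detector_image()].
#' @export
make_waxs_frame <- function(d_true_nm = 0.344, tau_true_nm = 20,
                            geometry = detector_geometry(),
                            shape_px = c(1024, 1024), intensity = 1000,
                            background = 20,
                            noise_model = list(type = "none"), seed = 1L) {
  check_scalar(d_true_nm, "d_true_nm", 0, strict_lower = TRUE)
  check_scalar(tau_true_nm, "tau_true_nm", 0, strict_lower = TRUE)
  q0 <- 2 * pi / d_true_nm
  qmax_det <- q_of_radius(min(
    geometry$center_x_px - 1, shape_px[2] - geometry$center_x_px,
    geometry$center_y_px - 1, shape_px[1] - geometry$center_y_px), geometry)
  if (q0 >= qmax_det)
    stop_oq("ring at q = %.3f nm^-1 falls outside the detector (edge q = %.3f)",
            q0, qmax_det)
  sigma_q <- (2 * pi / tau_true_nm) / (2 * sqrt(2 * log(2)))
  nr <- shape_px[1]; nc <- shape_px[2]
  dx <- matrix((seq_len(nc) - geometry$center_x_px), nr, nc, byrow = TRUE)
  dy <- matrix((seq_len(nr) - geometry$center_y_px), nr, nc)
  qpix <- q_of_radius(sqrt(dx^2 + dy^2), geometry)
  counts <- intensity * exp(-(qpix - q0)^2 / (2 * sigma_q^2)) + background
  counts <- with_seed(seed, {
    if (identical(noise_model$type, "gaussian") && noise_model$sd > 0)
      counts + matrix(rnorm(nr * nc, 0, noise_model$sd), nr, nc)
    else if (identical(noise_model$type, "poisson"))
      matrix(rpois(nr * nc, pmax(counts, 0)), nr, nc)
    else counts
  })
  detector_image(pmax(counts, 0), geometry)
}

#' Synthetic SAXS pattern with exact stack-of-cards truth
#'
#' Intensity model
#' `I(q) = A*exp(-q^2*Rg^2/3) + (P/q^4)*(1 - exp(-q^2*Rg^2/3))`
#' with `Rg = T_true_nm/2` and `A` solved in closed form so that the
#' invariant `Q = int_0^inf I q^2 dq` and the Porod constant `P` satisfy
#' `T_true = 4Q/(pi*P)` exactly (both integrals have closed forms for this
#' model). Multiplicative Gaussian noise models counting statistics.
#'
#' @param T_true_nm platelet thickness, must lie in `[0.5, 20]` nm.
#' @param porod_constant Porod constant `P` (intensity * q^4 units).
#' @param qmin,qmax q-range of the sampled pattern, nm^-1. `qmax` must be
#'   deep in the Porod regime.
#' @param n_points number of (linearly spaced) q samples.
#' @param noise_sd relative Gaussian noise (fraction of clean intensity).
#' @param seed RNG seed.
#' @return list with `pattern` (a [pattern1d()]) and `truth`
#'   ([phantom_truth()] with `T_true`, `Q_true`, `P_true`).
#' @export
make_saxs_pattern <- function(T_true_nm = 3, porod_constant = 1,
                              qmin = 0.05, qmax = 8, n_points = 500,
                              noise_sd = 0, seed = 1L) {
  check_scalar(T_true_nm, "T_true_nm", 0, strict_lower = TRUE)
  if (T_true_nm < 0.5 || T_true_nm > 20)
    stop_oq("T_true_nm = %g outside the model validity range [0.5, 20] nm",
            T_true_nm)
  check_scalar(porod_constant, "porod_constant", 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  P <- porod_constant
  Rg <- T_true_nm / 2
  a <- Rg^2 / 3
  # closed forms: int_0^inf q^2 exp(-a q^2) dq = sqrt(pi)/(4 a^{3/2});
  # int_0^inf (1 - exp(-a q^2))/q^2 dq = sqrt(pi * a)
  Q_target <- pi * P * T_true_nm / 4
  A <- (Q_target - P * sqrt(pi * a)) * 4 * a^1.5 / sqrt(pi)
  if (A <= 0) stop_oq("degenerate model: knee amplitude non-positive")
  # Porod-regime precondition: the exponential term must have died off well
  # before qmax so that I*q^4 plateaus
  if (exp(-a * qmax^2) > 1e-3)
    stop_oq("qmax = %g too small: Porod regime not reached for T = %g nm",
            qmax, T_true_nm)
  q <- seq(qmin, qmax, length.out = as.integer(n_points))
  intens <- A * exp(-a * q^2) + (P / q^4) * (1 - exp(-a * q^2))
  intens <- with_seed(seed, {
    if (noise_sd > 0) intens * (1 + rnorm(length(q), 0, noise_sd))
    else intens
  })
  pat <- pattern1d(q, pmax(intens, 0))
  truth <- phantom_truth(T_true = T_true_nm, Q_true = Q_target, P_true = P,
                         Rg_model = Rg, A_model = A, seed = seed)
  list(pattern = pat, truth = truth)
}
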