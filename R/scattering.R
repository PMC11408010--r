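# Scattering analysis: azimuthal integration of area-detector frames,
# stack-of-cards platelet thickness from the Kratky/Porod representation,
# Gaussian (002) peak fitting, Bragg d-spacing and Scherrer crystallite
# size.

#' Azimuthally integrated 1D scattering pattern
#'
#' @param q scattering vector, nm^-1, strictly increasing and positive.
#' @param intensity non-negative intensities (monitor-normalized).
#' @param sigma optional per-point uncertainties.
#' @param normalization monitor value the intensities were divided by.
#' @return object of class `pattern1d`.
#' @export
pattern1d <- function(q, intensity, sigma = NULL, normalization = 1) {
  if (length(q) != length(intensity))
    stop_oq("q and intensity lengths differ")
  if (any(!is.finite(q)) || any(q <= 0)) stop_oq("q must be positive and finite")
  if (any(diff(q) <= 0)) stop_oq("q must be strictly increasing")
  if (any(intensity < 0)) stop_oq("intensities must be non-negative")
  if (!is.null(sigma) && length(sigma) != length(q))
    stop_oq("sigma length differs")
  structure(list(q = as.numeric(q), intensity = as.numeric(intensity),
                 sigma = sigma, normalization = normalization),
            class = "pattern1d")
}

#' @export
print.pattern1d <- function(x, ...) {
  cat(sprintf("pattern1d: %d points, q in [%.4g, %.4g] nm^-1\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Azimuthal integration of a detector frame
#'
#' Radial binning around the beam centre:
#' `q(r) = (4*pi/lambda) * sin(atan(r * pixel / distance) / 2)`, mean (or
#' sum) of unmasked pixel intensities per q-bin, divided by the monitor.
#'
#' @param img a [detector_image()].
#' @param n_bins number of q-bins (default 512).
#' @param mode `"mean"` (intensity per pixel) or `"sum"` (conserves total
#'   counts).
#' @return a [pattern1d()]; bins with no unmasked pixel are dropped.
#' @export
azimuthal_integrate <- function(img, n_bins = 512, mode = c("mean", "sum")) {
  stopifnot(inherits(img, "detector_image"))
  mode <- match.arg(mode)
  g <- img$geometry
  nr <- nrow(img$counts); nc <- ncol(img$counts)
  if (g$center_x_px < 1 || g$center_x_px > nc ||
      g$center_y_px < 1 || g$center_y_px > nr)
    stop_oq("beam centre (%.1f, %.1f) outside the %d x %d image",
            g$center_x_px, g$center_y_px, nr, nc)
  dx <- matrix(seq_len(nc) - g$center_x_px, nr, nc, byrow = TRUE)
  dy <- matrix(seq_len(nr) - g$center_y_px, nr, nc)
  qpix <- q_of_radius(sqrt(dx^2 + dy^2), g)
  keep <- !img$mask
  qv <- qpix[keep]
  iv <- img$counts[keep]
  qlo <- min(qv); qhi <- max(qv)
  edges <- seq(qlo, qhi, length.out = n_bins + 1)
  bin <- findInterval(qv, edges, rightmost.closed = TRUE, all.inside = TRUE)
  n_per <- tabulate(bin, n_bins)
  s_per <- numeric(n_bins)
  agg <- rowsum(iv, bin)
  s_per[as.integer(rownames(agg))] <- agg[, 1]
  used <- n_per > 0
  val <- if (mode == "mean") s_per[used] / n_per[used] else s_per[used]
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  pattern1d(centers[used], val / img$monitor,
            normalization = img$monitor)
}

#' Stack-of-cards platelet thickness from a SAXS pattern
#'
#' `T = 4Q/(pi*P)` with the Porod constant `P` estimated as the mean of
#' `I*q^4` over the plateau (`q >= porod_qmin`) and the invariant
#' `Q = int I q^2 dq` assembled from (i) a low-q closure: quadratic fit of
#' `I*q^2` in `q^2` over `knee_window`, integrated analytically from 0 to
#' qmin, (ii) the trapezoidal integral over the data, and (iii) the
#' analytic Porod tail `P/qmax` beyond the data.
#'
#' @param p a [pattern1d()].
#' @param porod_qmin start of the Porod plateau (default 4 nm^-1).
#' @param knee_window q-window for the low-q closure fit; default the
#'   lowest 15 % of the q-range.
#' @param plateau_tol maximum allowed relative drift of `I*q^4` across the
#'   plateau (linear-fit change / mean) before erroring.
#' @return list: `T_nm`, `Q_invariant`, `P_porod`.
#' @export
fit_kratky_T <- function(p, porod_qmin = 4, knee_window = NULL,
                         plateau_tol = 0.2) {
  stopifnot(inherits(p, "pattern1d"))
  q <- p$q; I <- p$intensity
  if (max(q) <= porod_qmin)
    stop_oq("pattern ends at q = %.3g before the Porod region (%.3g)",
            max(q), porod_qmin)
  pl <- q >= porod_qmin
  if (sum(pl) < 5) stop_oq("too few points in the Porod region")
  iq4 <- I[pl] * q[pl]^4
  P <- mean(iq4)
  if (P <= 0) stop_oq("non-positive Porod constant")
  drift <- unname(coef(lm(iq4 ~ q[pl]))[2]) * (max(q) - porod_qmin)
  if (abs(drift) / P > plateau_tol)
    stop_oq("Porod regime not reached: I*q^4 drifts %.0f%% across [%g, %g]",
            100 * abs(drift) / P, porod_qmin, max(q))
  # low-q closure: I*q^2 ~ c0 + c2 q^2 (even, smooth at 0)
  if (is.null(knee_window)) knee_window <- c(min(q), min(q) + 0.15 * diff(range(q)))
  kn <- q >= knee_window[1] & q <= knee_window[2]
  if (sum(kn) < 3) stop_oq("knee window contains < 3 points")
  iq2 <- I * q^2
  cf <- coef(lm(iq2[kn] ~ I(q[kn]^2)))
  qmin <- min(q); qmax <- max(q)
  Q_low <- cf[1] * qmin + cf[2] * qmin^3 / 3
  Q_data <- sum(diff(q) * (iq2[-1] + iq2[-length(q)]) / 2)
  Q_tail <- P / qmax
  Q <- unname(Q_low + Q_data + Q_tail)
  list(T_nm = 4 * Q / (pi * P), Q_invariant = Q, P_porod = P)
}

#' Gaussian + linear-baseline peak fit
#'
#' Least-squares fit of `a * exp(-(q - c)^2 / (2 s^2)) + b0 + b1 * q`
#' within `window_q`. FWHM = `2 * sqrt(2 * log 2) * s`.
#'
#' @param p a [pattern1d()].
#' @param window_q `c(qlo, qhi)` fitting window containing a local
#'   maximum; default the full pattern.
#' @return object of class `peak_fit`: center_q, fwhm_q, amplitude,
#'   baseline (intercept, slope), residual_norm, below_resolution flag.
#' @export
fit_peak <- function(p, window_q = NULL) {
  stopifnot(inherits(p, "pattern1d"))
  if (is.null(window_q)) window_q <- range(p$q)
  inw <- p$q >= window_q[1] & p$q <= window_q[2]
  if (sum(inw) < 6) stop_oq("fit window contains < 6 points")
  q <- p$q[inw]; y <- p$intensity[inw]
  imax <- which.max(y)
  if (imax == 1 || imax == length(y))
    stop_oq("no interior local maximum in the fit window")
  # start values: centre at max; sigma from half-max crossing width
  base0 <- (y[1] + y[length(y)]) / 2
  amp0 <- y[imax] - base0
  half <- base0 + amp0 / 2
  above <- which(y >= half)
  w0 <- max(q[max(above)] - q[min(above)], 2 * mean(diff(q)))
  s0 <- w0 / 2.3548
  dat <- data.frame(q = q, y = y)
  fit <- tryCatch(
    nls(y ~ a * exp(-(q - cc)^2 / (2 * s^2)) + b0 + b1 * q, data = dat,
        start = list(a = amp0, cc = q[imax], s = s0, b0 = base0, b1 = 0),
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    obj <- function(th) {
      mu <- th[1] * exp(-(q - th[2])^2 / (2 * th[3]^2)) + th[4] + th[5] * q
      sum((y - mu)^2)
    }
    op <- optim(c(amp0, q[imax], s0, base0, 0), obj,
                control = list(maxit = 5000, reltol = 1e-12))
    if (op$convergence != 0)
      stop_oq("peak fit failed to converge (optim code %d, value %.3g)",
              op$convergence, op$value)
    th <- op$par
    resid <- sqrt(obj(th))
  } else {
    th <- coef(fit)[c("a", "cc", "s", "b0", "b1")]
    resid <- sqrt(sum(residuals(fit)^2))
  }
  s_abs <- abs(th[[3]])
  fwhm <- 2 * sqrt(2 * log(2)) * s_abs
  center <- th[[2]]
  if (center < window_q[1] || center > window_q[2])
    stop_oq("fitted centre %.4g escaped the window [%g, %g]",
            center, window_q[1], window_q[2])
  structure(list(center_q = center, fwhm_q = fwhm, amplitude = th[[1]],
                 baseline = c(intercept = th[[4]], slope = th[[5]]),
                 residual_norm = resid,
                 below_resolution = fwhm < mean(diff(q))),
            class = "peak_fit")
}

#' Bragg's law: lattice spacing from a peak position
#'
#' `n * lambda = 2 * d * sin(theta)`, equivalently `d = 2 * pi * n / q`.
#'
#' @param center peak position: q (nm^-1) or the scattering angle 2-theta.
#' @param lambda_nm X-ray wavelength.
#' @param n diffraction order (default 1).
#' @param input_kind `"q"`, `"two_theta_deg"` or `"two_theta_rad"`.
#' @return d-spacing, nm.
#' @export
bragg_d <- function(center, lambda_nm,  n = 1,
                    input_kind = c("q", "two_theta_deg", "two_theta_rad")) {
  input_kind <- match.arg(input_kind)
  check_scalar(lambda_nm, "lambda_nm", 0, strict_lower = TRUE)
  if (input_kind == "q") {
    check_scalar(center, "center", 0, strict_lower = TRUE)
    return(2 * pi * n / center)
  }
  tt <- if (input_kind == "two_theta_deg") center * pi / 180 else center
  if (tt <= 0 || tt >= pi) stop_oq("2-theta must lie in (0, pi)")
  st <- sin(tt / 2)
  if (st == 0) stop_oq("sin(theta) = 0")
  n * lambda_nm / (2 * st)
}

#' Scherrer crystallite size
#'
#' `tau = K * lambda / (beta * cos(theta))`, with `beta` the peak FWHM in
#' 2-theta radians. An instrumental width may optionally be removed in
#' quadrature before applying the formula.
#'
#' @param beta_rad fitted Gaussian FWHM in 2-theta, radians.
#' @param theta_rad glancing (half-scattering) angle, radians.
#' @param lambda_nm X-ray wavelength.
#' @param K shape factor (default 1).
#' @param instrumental_beta_rad instrumental FWHM removed in quadrature
#'   (default 0 = no deconvolution).
#' @return crystallite size tau, nm.
#' @export
scherrer_size <- function(beta_rad, theta_rad, lambda_nm, K = 1,
                          instrumental_beta_rad = 0) {
  check_scalar(beta_rad, "beta_rad", 0, strict_lower = TRUE)
  if (theta_rad <= 0 || theta_rad >= pi / 2)
    stop_oq("theta must lie in (0, pi/2)")
  check_scalar(lambda_nm, "lambda_nm", 0, strict_lower = TRUE)
  if (instrumental_beta_rad > 0) {
    if (instrumental_beta_rad >= beta_rad)
      stop_oq("instrumental width exceeds the observed width")
    beta_rad <- sqrt(beta_rad^2 - instrumental_beta_rad^2)
  }
  K * lambda_nm / (beta_rad * cos(theta_rad))
}

#' Convert a FWHM in q to the Scherrer broadening in 2-theta
#'
#' Uses `dq/d(2theta) = (2*pi/lambda) * cos(theta)`, with theta from the
#' peak position `q = (4*pi/lambda) * sin(theta)`.
#'
#' @param fwhm_q peak FWHM in q, nm^-1.
#' @param center_q peak centre in q, nm^-1.
#' @param lambda_nm X-ray wavelength.
#' @return list: `beta_rad` (FWHM in 2-theta) and `theta_rad`.
#' @export
fwhm_q_to_beta <- function(fwhm_q, center_q, lambda_nm) {
  st <- center_q * lambda_nm / (4 * pi)
  if (st <= 0 || st >= 1) stop_oq("center_q outside the physical range")
  theta <- asin(st)
  list(beta_rad = fwhm_q * lambda_nm / (2 * pi * cos(theta)),
       theta_rad = theta)
}

#' Multiplicative q-scale calibration from calibrant rings
#'
#' Fits a single scale factor `k` minimising
#' `sum (k * observed - reference)^2` (through the origin), reproducing a
#' calibrant-based q calibration (e.g. lanthanum hexaboride).
#'
#' @param observed_q measured ring positions.
#' @param reference_q known ring positions, same order.
#' @return scale factor to multiply q by.
#' @export
q_scale_calibration <- function(observed_q, reference_q) {
  if (length(observed_q) != length(reference_q) || length(observed_q) < 1)
    stop_oq("need matching, non-empty ring position vectors")
  sum(observed_q * reference_q) / sum(observed_q^2)
}

#' Per-point ultrastructure parameters for a scanned ROI
#'
#' For each scan point: platelet thickness from its SAXS pattern and
#' d-spacing plus crystallite size from the Gaussian (002) fit of its WAXS
#' pattern. Medians and quartiles across points summarise the ROI.
#'
#' @param saxs list of [pattern1d()] (one per scan point); may be `NULL`.
#' @param waxs list of [pattern1d()]; may be `NULL`.
#' @param lambda_nm X-ray wavelength for the WAXS conversion.
#' @param waxs_window_q fit window for the (002) peak.
#' @param porod_qmin,knee_window passed to [fit_kratky_T()].
#' @param K Scherrer shape factor.
#' @return list of class `ultrastructure_result`: `points` (per-point
#'   data.frame with T_nm, d002_nm, tau002_nm, Q_invariant, P_porod) and
#'   `summary` (median and quartiles per parameter).
#' @export
ultrastructure_report <- function(saxs = NULL, waxs = NULL,
                                  lambda_nm = 0.082656,
                                  waxs_window_q = NULL, porod_qmin = 4,
                                  knee_window = NULL, K = 1) {
  ns <- length(saxs); nw <- length(waxs)
  if (ns == 0 && nw == 0) stop_oq("empty ROI: no patterns supplied")
  n <- max(ns, nw)
  if (ns > 0 && nw > 0 && ns != nw)
    stop_oq("SAXS (%d) and WAXS (%d) point counts differ", ns, nw)
  rows <- lapply(seq_len(n), function(i) {
    T_nm <- Qv <- Pv <- d_nm <- tau_nm <- NA_real_
    if (ns > 0) {
      kt <- fit_kratky_T(saxs[[i]], porod_qmin, knee_window)
      T_nm <- kt$T_nm; Qv <- kt$Q_invariant; Pv <- kt$P_porod
    }
    if (nw > 0) {
      pf <- fit_peak(waxs[[i]], waxs_window_q)
      d_nm <- bragg_d(pf$center_q, lambda_nm, input_kind = "q")
      cv <- fwhm_q_to_beta(pf$fwhm_q, pf$center_q, lambda_nm)
      tau_nm <- scherrer_size(cv$beta_rad, cv$theta_rad, lambda_nm, K)
    }
    data.frame(point = i, T_nm = T_nm, d002_nm = d_nm, tau002_nm = tau_nm,
               Q_invariant = Qv, P_porod = Pv)
  })
  pts <- do.call(rbind, rows)
  qs <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(c(q25 = NA, median = NA, q75 = NA))
    setNames(quantile(v, c(0.25, 0.5, 0.75), names = FALSE),
             c("q25", "median", "q75"))
  }
  summ <- rbind(T_nm = qs(pts$T_nm), d002_nm = qs(pts$d002_nm),
                tau002_nm = qs(pts$tau002_nm))
  structure(list(points = pts, summary = summ),
            class = "ultrastructure_result")
}
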