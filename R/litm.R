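# LA-ICP-TOF-MS quantification: gelatin-standard calibration (static or
# drift-corrected), CPS -> ppm conversion, control-area limit of detection
# (LOD = mean + 3*s), percentile-rule region classification, and per-region
# reporting.

LITM_CHANNELS <- c("26Mg", "44Ca", "31P", "47Ti", "56Fe", "155Gd")

channel_element <- function(channel) gsub("^[0-9]+", "", channel)

#' Multi-channel LA-ICP-TOF-MS scan
#'
#' @param channels named list of CPS matrices (e.g. `"26Mg"`, `"44Ca"`,
#'   `"31P"`, `"47Ti"`, `"56Fe"`, `"155Gd"`), all the same shape.
#' @param pixel_um laser spot / pixel size, micrometres.
#' @param time_h per-pixel acquisition timestamps in hours; must be
#'   non-decreasing along scan order (row-major raster). Default: a uniform
#'   raster over `scan_hours`.
#' @param scan_hours total scan duration used to build the default
#'   timeline.
#' @return object of class `litm_scan`.
#' @export
litm_scan <- function(channels, pixel_um, time_h = NULL, scan_hours = 2) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop_oq("`channels` must be a named list of matrices")
  dm <- dim(channels[[1]])
  for (nm in names(channels)) {
    if (!is.matrix(channels[[nm]]) || !identical(dim(channels[[nm]]), dm))
      stop_oq("channel '%s' shape differs", nm)
    if (any(channels[[nm]] < 0)) stop_oq("channel '%s' has negative CPS", nm)
  }
  check_scalar(pixel_um, "pixel_um", 0, strict_lower = TRUE)
  if (is.null(time_h)) {
    n <- prod(dm)
    # row-major raster: row 1 scanned first
    tt <- matrix(seq(0, scan_hours, length.out = n), dm[1], dm[2],
                 byrow = TRUE)
    time_h <- tt
  } else {
    if (!identical(dim(time_h), dm)) stop_oq("`time_h` shape differs")
    ord <- as.vector(t(time_h))
    if (any(diff(ord) < 0))
      stop_oq("timestamps must be non-decreasing along scan order")
  }
  structure(list(channels = channels, pixel_um = pixel_um, time_h = time_h),
            class = "litm_scan")
}

#' Gelatin calibration standards
#'
#' @param standards data.frame with columns `element`, `ppm`, `cps`,
#'   `time_h`: mean CPS of each standard at each standard-scan time.
#' @param blank named numeric vector of blank (0 ppm gelatin) CPS per
#'   element.
#' @return object of class `standard_set`.
#' @export
standard_set <- function(standards, blank) {
  need <- c("element", "ppm", "cps", "time_h")
  if (!is.data.frame(standards) || !all(need %in% names(standards)))
    stop_oq("`standards` needs columns %s", paste(need, collapse = ", "))
  if (any(standards$ppm <= 0)) stop_oq("standard concentrations must be > 0")
  if (is.null(blank) || is.null(names(blank)))
    stop_oq("a named `blank` CPS record is required")
  for (el in unique(standards$element))
    if (length(unique(standards$ppm[standards$element == el])) < 2)
      stop_oq("element '%s' has fewer than 2 standard concentrations", el)
  structure(list(standards = standards, blank = blank),
            class = "standard_set")
}

#' Fit the CPS-vs-concentration calibration
#'
#' Static model: one ordinary-least-squares line per element over all
#' standard scans. Drift model: an OLS line per standard-scan time with the
#' slope/intercept interpolated piecewise-linearly in time (standards are
#' scanned at the start, middle and end of the tissue scan, so sample
#' pixels are always bracketed).
#'
#' @param std a [standard_set()].
#' @param model `"static"` or `"drift"`.
#' @param blank_subtract subtract the blank CPS from standard CPS before
#'   fitting (the sample-side counterpart happens in [cps_to_ppm()]).
#' @return object of class `calibration_model`.
#' @export
build_calibration <- function(std, model = c("static", "drift"),
                              blank_subtract = TRUE) {
  stopifnot(inherits(std, "standard_set"))
  model <- match.arg(model)
  df <- std$standards
  elements <- unique(df$element)
  fits <- list()
  for (el in elements) {
    d <- df[df$element == el, ]
    bl <- if (blank_subtract && el %in% names(std$blank)) std$blank[[el]] else 0
    d$cps <- d$cps - bl
    rsq <- function(fit, y) {
      ss <- sum((y - mean(y))^2)
      if (ss == 0) 1 else 1 - sum(residuals(fit)^2) / ss
    }
    if (model == "static") {
      fit <- lm(cps ~ ppm, data = d)
      slope <- unname(coef(fit)[2]); icpt <- unname(coef(fit)[1])
      if (slope <= 0) stop_oq("inverted calibration for '%s'", el)
      r2 <- rsq(fit, d$cps)
      fits[[el]] <- list(times = NA_real_, slope = slope, intercept = icpt,
                         r_squared = r2)
    } else {
      times <- sort(unique(d$time_h))
      if (length(times) < 2)
        stop_oq("drift model needs >= 2 standard scan times for '%s'", el)
      sl <- ic <- r2 <- numeric(length(times))
      for (i in seq_along(times)) {
        di <- d[d$time_h == times[i], ]
        if (nrow(di) < 2)
          stop_oq("standard scan at t = %g h has < 2 concentrations for '%s'",
                  times[i], el)
        fit <- lm(cps ~ ppm, data = di)
        sl[i] <- unname(coef(fit)[2]); ic[i] <- unname(coef(fit)[1])
        r2[i] <- rsq(fit, di$cps)
      }
      if (any(sl <= 0)) stop_oq("inverted calibration for '%s'", el)
      fits[[el]] <- list(times = times, slope = sl, intercept = ic,
                         r_squared = r2)
    }
  }
  structure(list(model = model, fits = fits, blank = std$blank,
                 blank_subtract = blank_subtract),
            class = "calibration_model")
}

cal_slope_at <- function(fit, t) {
  if (length(fit$times) == 1 && is.na(fit$times)) rep(fit$slope, length(t))
  else approx(fit$times, fit$slope, xout = t, rule = 2)$y
}
cal_intercept_at <- function(fit, t) {
  if (length(fit$times) == 1 && is.na(fit$times)) rep(fit$intercept, length(t))
  else approx(fit$times, fit$intercept, xout = t, rule = 2)$y
}

#' Convert CPS maps to concentration maps
#'
#' `ppm = (CPS - blank - intercept(t)) / slope(t)` per pixel; negative
#' results are floored at zero (the floored-pixel count is reported as an
#' attribute). Channels without a calibration (e.g. 31P, which cannot be
#' quantified against gelatin) pass through unchanged, flagged `"cps"`.
#'
#' @param scan a [litm_scan()].
#' @param cal a [calibration_model()] from [build_calibration()].
#' @param passthrough channels allowed to pass through uncalibrated.
#' @return named list of maps; each map carries attributes `unit`
#'   (`"ppm"` or `"cps"`) and, for calibrated maps, `n_floored`.
#' @export
cps_to_ppm <- function(scan, cal, passthrough = c("31P", "56Fe")) {
  stopifnot(inherits(scan, "litm_scan"), inherits(cal, "calibration_model"))
  out <- list()
  for (ch in names(scan$channels)) {
    el <- channel_element(ch)
    m <- scan$channels[[ch]]
    if (el %in% names(cal$fits)) {
      fit <- cal$fits[[el]]
      tt <- as.vector(scan$time_h)
      bl <- if (cal$blank_subtract && el %in% names(cal$blank))
        cal$blank[[el]] else 0
      ppm <- (as.vector(m) - bl - cal_intercept_at(fit, tt)) /
        cal_slope_at(fit, tt)
      nfl <- sum(ppm < 0)
      ppm <- matrix(pmax(ppm, 0), nrow(m), ncol(m))
      attr(ppm, "unit") <- "ppm"
      attr(ppm, "n_floored") <- nfl
      out[[ch]] <- ppm
    } else if (ch %in% passthrough || el %in% passthrough) {
      attr(m, "unit") <- "cps"
      out[[ch]] <- m
    } else {
      stop_oq("channel '%s' has no calibration and is not in the pass-through list", ch)
    }
  }
  out
}

#' Limit of detection of a channel
#'
#' `LOD = mean + 3 * s` over a control area close to, but excluding, the
#' tissue, where `s` is the sample standard deviation.
#'
#' @param scan a [litm_scan()] (or a named list of maps, e.g. ppm maps).
#' @param control_mask logical matrix selecting the control area (>= 30
#'   pixels).
#' @param channel channel name.
#' @return scalar LOD in the channel's units.
#' @export
compute_lod <- function(scan, control_mask, channel) {
  maps <- if (inherits(scan, "litm_scan")) scan$channels else scan
  if (!channel %in% names(maps)) stop_oq("channel '%s' not present", channel)
  m <- maps[[channel]]
  if (!identical(dim(control_mask), dim(m)))
    stop_oq("control mask shape differs from channel maps")
  v <- m[control_mask]
  if (length(v) < 30)
    stop_oq("control area has %d pixels; >= 30 required", length(v))
  mean(v) + 3 * sd(v)
}

#' Classify degradation / interface / control regions
#'
#' Applies the percentile rules: with per-channel cutoffs `c` at the 99.9th
#' percentile (linear interpolation between order statistics), a pixel is
#' degradation when the implant channel (155Gd or 47Ti) is visible
#' (`>= visibility_fraction * c_implant`), Ca and P are below 50 % of their
#' cutoffs, and Fe is below 20 % of its cutoff. Tail-streak artefacts are
#' not auto-detected; supply them as `exclude_mask`. Interface bands are
#' built from the degradation mask by Euclidean distance.
#'
#' @param scan a [litm_scan()].
#' @param implant_channel `"155Gd"` or `"47Ti"`.
#' @param visibility_fraction fraction of the implant-channel cutoff above
#'   which the implant signal counts as visible. No published value exists;
#'   it is the most consequential free parameter (default 0.10).
#' @param ca_fraction,p_fraction,fe_fraction cutoff fractions for the Ca, P
#'   and Fe criteria (defaults 0.5, 0.5, 0.2).
#' @param band_edges_um interface-band distance edges from the degradation
#'   boundary, micrometres (default `c(0, 50, 150, Inf)`).
#' @param exclude_mask optional logical matrix of manually excluded pixels
#'   (tail streaks).
#' @param control_mask optional logical matrix defining the control bone
#'   tissue region; excluded pixels are removed from it.
#' @return named list of disjoint logical masks: `degradation`, one
#'   `interface_<lo>_<hi>` per band, and `control` when supplied. Cutoffs
#'   are attached as attribute `cutoffs`.
#' @export
classify_regions <- function(scan, implant_channel = c("155Gd", "47Ti"),
                             visibility_fraction = 0.10,
                             ca_fraction = 0.5, p_fraction = 0.5,
                             fe_fraction = 0.2,
                             band_edges_um = c(0, 50, 150, Inf),
                             exclude_mask = NULL, control_mask = NULL) {
  stopifnot(inherits(scan, "litm_scan"))
  implant_channel <- match.arg(implant_channel)
  need <- c(implant_channel, "44Ca", "31P", "56Fe")
  miss <- setdiff(need, names(scan$channels))
  if (length(miss)) stop_oq("missing channel(s): %s", paste(miss, collapse = ", "))
  cut <- vapply(need, function(ch) {
    m <- scan$channels[[ch]]
    if (max(m) == min(m))
      stop_oq("channel '%s' is constant; 99.9th percentile degenerate", ch)
    percentile(m, 0.999)
  }, numeric(1))
  dm <- dim(scan$channels[[1]])
  if (is.null(exclude_mask)) exclude_mask <- matrix(FALSE, dm[1], dm[2])
  deg <- scan$channels[[implant_channel]] >= visibility_fraction * cut[[implant_channel]] &
    scan$channels[["44Ca"]] < ca_fraction * cut[["44Ca"]] &
    scan$channels[["31P"]] < p_fraction * cut[["31P"]] &
    scan$channels[["56Fe"]] < fe_fraction * cut[["56Fe"]] &
    !exclude_mask
  regions <- list(degradation = deg)
  if (any(deg)) {
    d_um <- distance_transform(deg) * scan$pixel_um
    for (i in seq_len(length(band_edges_um) - 1)) {
      lo <- band_edges_um[i]; hi <- band_edges_um[i + 1]
      nm <- sprintf("interface_%s_%s", format(lo), if (is.finite(hi))
        format(hi) else "inf")
      regions[[nm]] <- d_um > lo & d_um <= hi & !deg & !exclude_mask
    }
  }
  if (!is.null(control_mask)) {
    for (nm in names(regions)) regions[[nm]] <- regions[[nm]] & !control_mask
    regions$control <- control_mask & !exclude_mask
  }
  attr(regions, "cutoffs") <- cut
  regions
}

#' Per-region statistics report
#'
#' For every region x channel: mean, SD, median, pixel count and the
#' percentage of pixels above that channel's LOD.
#'
#' @param maps named list of maps (ppm or CPS, e.g. from [cps_to_ppm()]).
#' @param regions named list of disjoint logical masks (e.g. from
#'   [classify_regions()]).
#' @param lods named numeric vector of LODs per channel (same units as the
#'   corresponding map); channels absent from `lods` get `NA` percentages.
#' @return `data.frame` with columns region, channel, unit, mean, sd,
#'   median, n, pct_above_lod.
#' @export
region_report <- function(maps, regions, lods = NULL) {
  nms <- names(regions)
  for (i in seq_along(regions))
    for (j in seq_len(i - 1))
      if (any(regions[[i]] & regions[[j]]))
        stop_oq("regions '%s' and '%s' overlap", nms[i], nms[j])
  rows <- list()
  for (rg in nms) {
    msk <- regions[[rg]]
    for (ch in names(maps)) {
      v <- maps[[ch]][msk]
      unit <- attr(maps[[ch]], "unit")
      if (is.null(unit)) unit <- "ppm"
      lod <- if (!is.null(lods) && ch %in% names(lods)) lods[[ch]] else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        region = rg, channel = ch, unit = unit,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) sd(v) else NA_real_,
        median = if (length(v)) median(v) else NA_real_,
        n = length(v),
        pct_above_lod = if (length(v) && is.finite(lod))
          100 * mean(v > lod) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Per-pixel scatter export for two channels in a region
#'
#' @param maps named list of maps.
#' @param region logical mask.
#' @param channel_x,channel_y channel names.
#' @return `data.frame` with columns `x`, `y` (one row per region pixel).
#' @export
region_scatter <- function(maps, region, channel_x, channel_y) {
  data.frame(x = maps[[channel_x]][region], y = maps[[channel_y]][region])
}
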