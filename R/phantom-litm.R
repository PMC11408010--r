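# LITM phantom: piecewise-constant ppm regions rendered to CPS maps with a
# linear sensitivity drift and Poisson counting noise, plus gelatin
# standards scanned at the start, middle and end of the timeline.

litm_default_sensitivity <- c(Mg = 120, Ca = 80, P = 60, Ti = 100,
                              Fe = 90, Gd = 150) # CPS per ppm at t = 0
litm_default_baseline <- c(Mg = 60, Ca = 50, P = 40, Ti = 30,
                           Fe = 50, Gd = 20)     # blank CPS

#' Synthetic LA-ICP-TOF-MS phantom with known concentrations
#'
#' Renders rectangular regions of known concentration (mg/kg) into CPS maps
#' via `CPS = sensitivity * ppm * (1 + drift_slope * t) + baseline
#' (+ noise)`, with per-pixel timestamps from a row-major raster over
#' `scan_hours`. Gelatin standards (the same linear response, no noise:
#' they are averaged over many pixels in practice) are recorded at the
#' start, middle and end of the timeline.
#'
#' @param region_layout named list of pixel rectangles
#'   `c(row0, row1, col0, col1)` (inclusive, 1-based); must not overlap.
#'   Pixels in no rectangle form the background region `"other"`.
#' @param ppm_true named list: region -> named vector element -> ppm. The
#'   `"other"` entry (default all zero) covers background pixels.
#' @param channels channel names to render.
#' @param drift_slope_per_hour relative sensitivity drift per hour (e.g.
#'   0.1 = +10 %/h).
#' @param noise_model `list(type = "poisson")`, `list(type = "gaussian",
#'   sd = ...)` (additive CPS noise) or `list(type = "none")`.
#' @param standards_ppm concentrations of the gelatin standard series; must
#'   span roughly 10-1000 ppm.
#' @param shape_px map shape `c(nrows, ncols)`.
#' @param pixel_um pixel size (laser spot), micrometres.
#' @param scan_hours total scan duration.
#' @param seed RNG seed.
#' @return list with `scan` ([litm_scan()]), `standards`
#'   ([standard_set()]), and `truth` ([phantom_truth()] whose `ppm_true`
#'   maps region -> element -> ppm; region masks under `region_masks`).
#' @export
make_litm_phantom <- function(region_layout, ppm_true,
                              channels = LITM_CHANNELS,
                              drift_slope_per_hour = 0,
                              noise_model = list(type = "none"),
                              standards_ppm = c(10, 30, 100, 300, 1000),
                              shape_px = c(128, 128), pixel_um = 15,
                              scan_hours = 2, seed = 1L) {
  if (min(standards_ppm) > 10 || max(standards_ppm) < 1000)
    stop_oq("standards_ppm must span approximately 10-1000 ppm")
  nr <- shape_px[1]; nc <- shape_px[2]
  masks <- list()
  occupied <- matrix(FALSE, nr, nc)
  for (nm in names(region_layout)) {
    rc <- region_layout[[nm]]
    if (length(rc) != 4 || rc[1] > rc[2] || rc[3] > rc[4] ||
        rc[1] < 1 || rc[2] > nr || rc[3] < 1 || rc[4] > nc)
      stop_oq("region '%s': invalid rectangle", nm)
    m <- matrix(FALSE, nr, nc)
    m[rc[1]:rc[2], rc[3]:rc[4]] <- TRUE
    if (any(m & occupied)) stop_oq("region '%s' overlaps another region", nm)
    occupied <- occupied | m
    masks[[nm]] <- m
  }
  masks$other <- !occupied
  if (is.null(ppm_true$other)) ppm_true$other <- c()

  elements <- unique(channel_element(channels))
  sens <- litm_default_sensitivity
  base <- litm_default_baseline
  miss <- setdiff(elements, names(sens))
  if (length(miss)) stop_oq("no sensitivity defined for element(s): %s",
                            paste(miss, collapse = ", "))

  # per-pixel ppm fields
  ppm_field <- lapply(elements, function(el) {
    f <- matrix(0, nr, nc)
    for (nm in names(masks)) {
      conc <- ppm_true[[nm]]
      if (!is.null(conc) && el %in% names(conc)) f[masks[[nm]]] <- conc[[el]]
    }
    f
  })
  names(ppm_field) <- elements

  # only Mg, Ca, Gd and Ti salts go into the gelatin standards; P and Fe
  # cannot be quantified against them and stay CPS-only downstream
  std_elements <- intersect(elements, c("Mg", "Ca", "Gd", "Ti"))

  tt <- matrix(seq(0, scan_hours, length.out = nr * nc), nr, nc, byrow = TRUE)
  drift <- 1 + drift_slope_per_hour * tt
  chans <- with_seed(seed, {
    out <- list()
    for (ch in channels) {
      el <- channel_element(ch)
      mu <- sens[[el]] * ppm_field[[el]] * drift + base[[el]]
      cps <- if (identical(noise_model$type, "poisson"))
        matrix(rpois(nr * nc, as.vector(mu)), nr, nc)
      else if (identical(noise_model$type, "gaussian"))
        pmax(mu + matrix(rnorm(nr * nc, 0, noise_model$sd), nr, nc), 0)
      else mu
      out[[ch]] <- cps
    }
    out
  })
  scan <- litm_scan(chans, pixel_um = pixel_um, time_h = tt)

  std_times <- c(0, scan_hours / 2, scan_hours)
  std <- expand.grid(element = std_elements, ppm = standards_ppm,
                     time_h = std_times, stringsAsFactors = FALSE)
  std$cps <- mapply(function(el, p, t)
    sens[[el]] * p * (1 + drift_slope_per_hour * t) + base[[el]],
    std$element, std$ppm, std$time_h)
  stds <- standard_set(std[, c("element", "ppm", "cps", "time_h")],
                       blank = base[std_elements])
  truth <- phantom_truth(ppm_true = ppm_true, region_masks = masks,
                         sensitivity = sens[elements],
                         baseline = base[elements],
                         drift_slope_per_hour = drift_slope_per_hour,
                         seed = seed)
  list(scan = scan, standards = stds, truth = truth)
}
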