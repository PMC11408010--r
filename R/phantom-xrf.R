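# XRF phantom: co-registered Ca / P / Gd maps with a vertical
# degradation-layer band (Gd-positive) on the left and bone to its right.
# The imposed Ca/P ratio at each bone pixel is a function of the
# centre-to-centre distance to the nearest band pixel, matching the
# convention of distance_map(), so profile recovery is exact at zero noise.

#' Synthetic XRF element-map phantom
#'
#' Generates Ca, P and Gd maps (`size_px` x `size_px`) in which Gd is
#' nonzero only inside a left-edge band of width `gd_layer_width_um` (the
#' degradation layer) and every bone pixel carries
#' `Ca/P = ca_p_profile(d)` with `d` the distance (micrometres,
#' centre-to-centre) to the nearest band pixel. Gaussian noise of absolute
#' standard deviation `noise_sd` is added to the Ca and P maps
#' independently.
#'
#' @param size_px image side length in pixels.
#' @param pixel_um pixel size, micrometres.
#' @param ca_p_profile function distance_um -> dimensionless Ca/P ratio,
#'   defined on `[0, size_px * pixel_um]`.
#' @param gd_layer_width_um width of the Gd band.
#' @param noise_sd Gaussian noise SD on intensities (the clean P level is
#'   `p_level`, so SNR = p_level / noise_sd).
#' @param seed RNG seed.
#' @param p_level clean P intensity in bone (default 100).
#' @param gd_level clean Gd intensity in the band (default 500).
#' @param ca_band_level clean Ca intensity inside the band (default 60;
#'   corrosion layers take up calcium).
#' @return list with `maps` (an [element_map_set()] carrying the true class
#'   mask) and `truth` ([phantom_truth()] with
#'   `capratio_profile_true`).
#' @export
make_xrf_phantom <- function(size_px = 256, pixel_um = 0.5,
                             ca_p_profile = function(d) rep(2.0, length(d)),
                             gd_layer_width_um = 10, noise_sd = 0,
                             seed = 1L, p_level = 100, gd_level = 500,
                             ca_band_level = 60) {
  check_scalar(size_px, "size_px", 2)
  check_scalar(pixel_um, "pixel_um", 0, strict_lower = TRUE)
  check_scalar(gd_layer_width_um, "gd_layer_width_um", 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  wpx <- as.integer(round(gd_layer_width_um / pixel_um))
  if (wpx < 1) stop_oq("gd_layer_width_um is below one pixel")
  if (wpx >= size_px) stop_oq("Gd band (%d px) wider than image (%d px)",
                              wpx, size_px)
  n <- as.integer(size_px)
  col_idx <- matrix(seq_len(n), n, n, byrow = TRUE)
  band <- col_idx <= wpx
  # centre-to-centre distance to the nearest band pixel (straight band:
  # purely horizontal)
  dist_um <- pmax(0, col_idx - wpx) * pixel_um
  ratio <- matrix(ca_p_profile(as.vector(dist_um)), n, n)
  if (any(!is.finite(ratio[!band])))
    stop_oq("ca_p_profile returned non-finite values inside the image")
  ca <- ifelse(band, ca_band_level, ratio * p_level)
  p <- matrix(p_level, n, n)
  gd <- ifelse(band, gd_level, 0)
  with_seed(seed, {
    if (noise_sd > 0) {
      ca <- ca + matrix(rnorm(n * n, 0, noise_sd), n, n)
      p <- p + matrix(rnorm(n * n, 0, noise_sd), n, n)
      gd <- gd + ifelse(band, matrix(rnorm(n * n, 0, noise_sd), n, n), 0)
    }
  })
  ca <- pmax(ca, 0); p <- pmax(p, 0); gd <- pmax(gd, 0)
  mask <- matrix(XRF_BONE, n, n)
  mask[band] <- XRF_DEGRADATION
  ems <- element_map_set(list(Ca = ca, P = p, Gd = gd), pixel_um = pixel_um,
                         mask = mask)
  truth <- phantom_truth(capratio_profile_true = ca_p_profile,
                         band_width_px = wpx, seed = seed)
  list(maps = ems, truth = truth)
}
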