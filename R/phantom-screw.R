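# Screw phantom: a cylinder-with-thread implant, uniformly eroded, wrapped
# in a concentric degradation shell, with partial bone apposition. The
# thread is a sinusoidal radial modulation (M2 pitch, 0.4 mm) so that the
# continuous geometry stays integrable and truth values are exact.
#
# Bone occupies 18 narrow azimuthal sectors. 6-connectivity face counting
# overestimates lateral area by a factor |cos phi| + |sin phi| (period
# pi/2); with a sector count not divisible by 4 the sector centres sample
# that weight uniformly over its period, so the weighted bone-face fraction
# converges to the plain azimuthal fill fraction and the continuum BIC
# (= fill fraction) is also the face-count limit.

#' Ground truth attached to synthetic phantoms
#'
#' @param ... named truth fields (dr_true, bic_true, bvtv_true,
#'   capratio_profile_true, d_true, tau_true, T_true, ppm_true, ...).
#' @param seed the generator seed.
#' @return object of class `phantom_truth`.
#' @export
phantom_truth <- function(..., seed) {
  fields <- list(...)
  for (nm in c("bic_true", "bvtv_true"))
    if (!is.null(fields[[nm]]))
      check_scalar(fields[[nm]], nm, 0, 100)
  for (nm in c("d_true", "tau_true", "T_true"))
    if (!is.null(fields[[nm]]))
      check_scalar(fields[[nm]], nm, 0, strict_lower = TRUE)
  fields$seed <- seed
  structure(fields, class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.function(v)) cat(sprintf("  %s: <function>\n", nm))
    else if (is.list(v)) cat(sprintf("  %s: <%d regions>\n", nm, length(v)))
    else cat(sprintf("  %s: %s\n", nm, paste(signif(unlist(v), 6), collapse = " ")))
  }
  invisible(x)
}

screw_radius_fun <- function(radius_mm, thread_depth_mm, pitch_mm) {
  a <- radius_mm - thread_depth_mm / 2
  b <- thread_depth_mm / 2
  function(z) a + b * sin(2 * pi * z / pitch_mm)
}

#' Synthetic eroded-screw phantom with analytic morphometry truth
#'
#' Builds a labeled volume (background / bone / degradation layer / residual
#' metal) of a threaded screw eroded uniformly by `erosion_depth_um`, with a
#' degradation shell of `layer_thickness_um` on the residual surface and
#' bone apposed to the shell over an azimuthal fraction
#' `bone_fill_fraction`. Truth values come from the continuous geometry:
#' volumes and lateral surface area by quadrature of the closed-form radius
#' profile, BIC and BV/TV exactly `100 * bone_fill_fraction` by
#' construction (zero-width gap, bone and background proportioned
#' identically at every radius).
#'
#' @param length_mm screw length (spans the full grid in z).
#' @param radius_mm outer thread radius.
#' @param thread_depth_mm radial depth of the sinusoidal thread.
#' @param erosion_depth_um uniform radial erosion of the screw surface.
#' @param layer_thickness_um degradation-shell thickness on the residual
#'   metal.
#' @param bone_fill_fraction fraction of the peri-implant space (and hence
#'   of the shell surface) occupied by bone, in `[0, 1]`.
#' @param voxel_um isotropic voxel size; must be at most half the erosion
#'   depth when erosion is nonzero.
#' @param t_years simulated residence time used for the degradation-rate
#'   truth (default 0.5).
#' @param pitch_mm thread pitch (default 0.4, M2).
#' @param seed recorded in the truth (the generator itself is
#'   deterministic).
#' @return list with `volume` ([label_volume()]), `reference`
#'   ([screw_reference()]) and `truth` ([phantom_truth()]).
#' @export
make_screw_phantom <- function(length_mm = 0.4, radius_mm = 0.25,
                               thread_depth_mm = 0.05,
                               erosion_depth_um = 30,
                               layer_thickness_um = 40,
                               bone_fill_fraction = 0.6,
                               voxel_um = 5, t_years = 0.5,
                               pitch_mm = 0.4, seed = 1L) {
  check_scalar(length_mm, "length_mm", 0, strict_lower = TRUE)
  check_scalar(radius_mm, "radius_mm", 0, strict_lower = TRUE)
  check_scalar(thread_depth_mm, "thread_depth_mm", 0, radius_mm)
  check_scalar(erosion_depth_um, "erosion_depth_um", 0)
  check_scalar(layer_thickness_um, "layer_thickness_um", 0)
  check_scalar(bone_fill_fraction, "bone_fill_fraction", 0, 1)
  check_scalar(voxel_um, "voxel_um", 0, strict_lower = TRUE)
  check_scalar(t_years, "t_years", 0, strict_lower = TRUE)
  if (erosion_depth_um > 0 && voxel_um > erosion_depth_um / 2)
    stop_oq("voxel_um (%g) must be <= erosion_depth_um/2 (%g)",
            voxel_um, erosion_depth_um / 2)
  e_mm <- erosion_depth_um / 1000
  lay_mm <- layer_thickness_um / 1000
  r_ref <- screw_radius_fun(radius_mm, thread_depth_mm, pitch_mm)
  r_min_res <- radius_mm - thread_depth_mm - e_mm
  if (r_min_res <= 0) stop_oq("fully degraded phantom")

  # continuum truth: quadrature of the closed-form profiles
  quad <- function(f) integrate(f, 0, length_mm, rel.tol = 1e-10,
                                subdivisions = 2000L)$value
  Vi <- pi * quad(function(z) r_ref(z)^2)
  Vr <- pi * quad(function(z) (r_ref(z) - e_mm)^2)
  drdz <- function(z) (thread_depth_mm / 2) * (2 * pi / pitch_mm) *
    cos(2 * pi * z / pitch_mm)
  Ai <- 2 * pi * quad(function(z) r_ref(z) * sqrt(1 + drdz(z)^2))
  dr_true <- (Vi - Vr) / (Ai * t_years)

  # grid: screw axis along z, spanning full z extent
  h <- voxel_um / 1000
  pad_mm <- max(0, lay_mm - e_mm) + 0.24
  half_w <- radius_mm + pad_mm
  nx <- 2L * as.integer(ceiling(half_w / h))
  nz <- max(1L, as.integer(round(length_mm / h)))
  xc <- (seq_len(nx) - 0.5) * h - nx * h / 2
  rho <- sqrt(outer(xc^2, xc^2, `+`))
  phi <- atan2(matrix(xc, nx, nx, byrow = TRUE), matrix(xc, nx, nx))
  # bone sectors: 18 sectors (centres sample the face-count weight
  # uniformly; see header note), each filled to the stated azimuthal
  # fraction
  nsec <- 18L
  sec_half <- bone_fill_fraction * pi / nsec
  ang <- (phi %% (2 * pi / nsec)) - pi / nsec
  in_bone_sector <- abs(ang) <= sec_half
  if (bone_fill_fraction == 1) in_bone_sector[] <- TRUE

  labels <- array(LABEL_BACKGROUND, dim = c(nx, nx, nz))
  refmask <- array(FALSE, dim = c(nx, nx, nz))
  for (k in seq_len(nz)) {
    z <- (k - 0.5) * h
    rr <- r_ref(z)
    rres <- rr - e_mm
    rlay <- rres + lay_mm
    sl <- matrix(LABEL_BACKGROUND, nx, nx)
    sl[in_bone_sector & rho > rlay] <- LABEL_BONE
    sl[rho <= rlay] <- LABEL_DEGRADATION
    sl[rho <= rres] <- LABEL_METAL
    labels[, , k] <- sl
    refmask[, , k] <- rho <= rr
  }
  vol <- label_volume(labels, voxel_um)
  ref <- screw_reference(refmask, voxel_um, Vi = Vi, Ai = Ai)
  truth <- phantom_truth(dr_true = dr_true,
                         bic_true = 100 * bone_fill_fraction,
                         bvtv_true = 100 * bone_fill_fraction,
                         Vi_true = Vi, Vr_true = Vr, Ai_true = Ai,
                         t_years = t_years, seed = seed)
  list(volume = vol, reference = ref, truth = truth)
}
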