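# Run configuration and the end-to-end (all-synthetic) pipeline.

config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "oq_out",
    stages = c("morpho", "xrf", "scattering", "litm"),
    morpho = list(voxel_um = 5, margin_um = 200, t_days = 183,
                  erosion_depth_um = 30, layer_thickness_um = 40,
                  bone_fill_fraction = 0.6),
    xrf = list(size_px = 256, pixel_um = 0.5, gd_layer_width_um = 10,
               noise_sd = 5, bin_um = 1, max_um = 30),
    scattering = list(T_true_nm = 3, d_true_nm = 0.344, tau_true_nm = 20,
                      noise_sd = 50, porod_qmin = 4, K = 1),
    litm = list(drift_slope_per_hour = 0.1, visibility_fraction = 0.10,
                band_edges_um = c(0, 50, 150, Inf))
  )
}

#' Build a validated run configuration
#'
#' Defaults for every stage parameter (documented units: um for
#' pixels/voxels/distances, nm for d/tau/T, nm^-1 for q, mm/year for DR,
#' ppm for concentrations); unknown keys are rejected.
#'
#' @param ... overrides, possibly nested lists (e.g.
#'   `morpho = list(voxel_um = 10)`).
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- config_defaults()
  over <- list(...)
  merge_checked <- function(base, upd, prefix = "") {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown))
      stop_oq("unknown config key(s): %s",
              paste0(prefix, unknown, collapse = ", "))
    for (k in names(upd)) {
      if (is.list(base[[k]]) && is.list(upd[[k]]))
        base[[k]] <- merge_checked(base[[k]], upd[[k]], paste0(prefix, k, "$"))
      else base[[k]] <- upd[[k]]
    }
    base
  }
  cfg <- merge_checked(defaults, over)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' @param path JSON file with (possibly partial) configuration.
#' @return a [run_config()].
#' @export
read_config <- function(path) {
  kv <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, kv)
}

stage_seed <- function(seed, k) (as.integer(seed) * 13L + k * 101L) %% 2147483647L

#' Run the all-synthetic end-to-end pipeline
#'
#' Executes the enabled stages in order (morphometry, XRF, scattering,
#' LITM), each on a phantom generated from the stage parameters and the
#' run seed, writes per-stage outputs under `config$out_dir`, and writes a
#' `manifest.json` (config echo, seed, package version, per-file MD5
#' checksums) sufficient to reproduce the run.
#'
#' @param config a [run_config()].
#' @return named list of per-stage result objects, invisibly; side effect:
#'   files under `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  outputs <- character(0)
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop_oq("stage %s: %s", name, conditionMessage(e)))
  }
  emit <- function(path) outputs <<- c(outputs, path)

  if ("morpho" %in% config$stages) {
    results$morpho <- run_stage("morpho", function() {
      pc <- config$morpho
      ph <- make_screw_phantom(voxel_um = pc$voxel_um,
                               erosion_depth_um = pc$erosion_depth_um,
                               layer_thickness_um = pc$layer_thickness_um,
                               bone_fill_fraction = pc$bone_fill_fraction,
                               t_years = pc$t_days / 365.25,
                               seed = stage_seed(config$seed, 1L))
      rep <- morphometry_report(ph$volume, ph$reference, pc$t_days,
                                pc$margin_um)
      f <- file.path(config$out_dir, "morphometry.csv")
      write_results(cbind(sample_id = "phantom", rep), f); emit(f)
      fv <- file.path(config$out_dir, "labels.tif")
      write_volume(ph$volume, fv); emit(fv)
      ft <- file.path(config$out_dir, "morpho_truth.txt")
      write_truth(ph$truth, ft); emit(ft)
      list(report = rep, truth = ph$truth)
    })
  }
  if ("xrf" %in% config$stages) {
    results$xrf <- run_stage("xrf", function() {
      pc <- config$xrf
      ph <- make_xrf_phantom(size_px = pc$size_px, pixel_um = pc$pixel_um,
                             gd_layer_width_um = pc$gd_layer_width_um,
                             noise_sd = pc$noise_sd,
                             seed = stage_seed(config$seed, 2L))
      mask <- segment_xrf(ph$maps)
      prof <- ratio_profile(ph$maps, mask, bin_um = pc$bin_um,
                            max_um = pc$max_um)
      lr <- layer_ratios(ph$maps, mask)
      fm <- file.path(config$out_dir, "xrf_mask.tif")
      write_tiff(mask, fm, "uint8"); emit(fm)
      fp <- file.path(config$out_dir, "xrf_profile.csv")
      write_results(as.data.frame(prof), fp); emit(fp)
      fl <- file.path(config$out_dir, "xrf_layer_ratios.csv")
      write_results(lr, fl); emit(fl)
      list(mask = mask, profile = prof, layer = lr, truth = ph$truth)
    })
  }
  if ("scattering" %in% config$stages) {
    results$scattering <- run_stage("scattering", function() {
      pc <- config$scattering
      sp <- make_saxs_pattern(T_true_nm = pc$T_true_nm,
                              seed = stage_seed(config$seed, 3L))
      kt <- fit_kratky_T(sp$pattern, porod_qmin = pc$porod_qmin)
      fr <- make_waxs_frame(d_true_nm = pc$d_true_nm,
                            tau_true_nm = pc$tau_true_nm,
                            noise_model = list(type = "gaussian",
                                               sd = pc$noise_sd),
                            seed = stage_seed(config$seed, 4L))
      pat <- azimuthal_integrate(fr)
      q0 <- 2 * pi / pc$d_true_nm
      pf <- fit_peak(pat, window_q = q0 + c(-0.55, 0.55))
      d <- bragg_d(pf$center_q, fr$geometry$wavelength_nm, input_kind = "q")
      cv <- fwhm_q_to_beta(pf$fwhm_q, pf$center_q, fr$geometry$wavelength_nm)
      tau <- scherrer_size(cv$beta_rad, cv$theta_rad,
                           fr$geometry$wavelength_nm, pc$K)
      fitdf <- data.frame(roi = "phantom", point = 1L, T_nm = kt$T_nm,
                          d002_nm = d, tau002_nm = tau,
                          Q_invariant = kt$Q_invariant,
                          P_porod = kt$P_porod,
                          peak_residual = pf$residual_norm)
      fs <- file.path(config$out_dir, "saxs_pattern.dat")
      write_pattern(sp$pattern, fs); emit(fs)
      fw <- file.path(config$out_dir, "waxs_pattern.dat")
      write_pattern(pat, fw); emit(fw)
      ff <- file.path(config$out_dir, "ultrastructure.csv")
      write_results(fitdf, ff); emit(ff)
      list(fits = fitdf, saxs_truth = sp$truth)
    })
  }
  if ("litm" %in% config$stages) {
    results$litm <- run_stage("litm", function() {
      pc <- config$litm
      layout <- list(degradation = c(10, 50, 10, 50),
                     interface = c(10, 50, 55, 80),
                     control = c(80, 120, 80, 120))
      ppm <- list(degradation = c(Gd = 1316.3, Mg = 5000, Ca = 100),
                  interface = c(Gd = 60, Mg = 900, Ca = 3000, P = 2000),
                  control = c(Mg = 800, Ca = 3000, P = 2000),
                  other = c(Fe = 300, Ca = 100, P = 80))
      ph <- make_litm_phantom(layout, ppm,
                              drift_slope_per_hour = pc$drift_slope_per_hour,
                              noise_model = list(type = "poisson"),
                              seed = stage_seed(config$seed, 5L))
      cal <- build_calibration(ph$standards,
                               if (pc$drift_slope_per_hour != 0) "drift"
                               else "static")
      maps <- cps_to_ppm(ph$scan, cal)
      regs <- classify_regions(ph$scan,
                               visibility_fraction = pc$visibility_fraction,
                               band_edges_um = pc$band_edges_um,
                               control_mask = ph$truth$region_masks$control)
      lods <- vapply(names(maps), function(ch)
        compute_lod(maps, ph$truth$region_masks$other, ch), numeric(1))
      rep <- region_report(maps, regs, lods)
      fr <- file.path(config$out_dir, "litm_report.csv")
      write_results(rep, fr); emit(fr)
      list(calibration = cal, report = rep, truth = ph$truth)
    })
  }
  manifest <- list(
    package = "osseoquant",
    version = as.character(utils::packageVersion("osseoquant")),
    seed = config$seed,
    stages = config$stages,
    config = unclass(config),
    files = lapply(setNames(nm = basename(outputs)), function(b) {
      f <- outputs[basename(outputs) == b][1]
      list(md5 = unname(tools::md5sum(f)), bytes = unname(file.size(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
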