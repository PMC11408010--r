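test_that("containers validate their contracts", {
  m <- matrix(1, 8, 8)
  expect_error(litm_scan(list(m, m), 10), "named list")
  expect_error(litm_scan(list(`26Mg` = m, `44Ca` = matrix(1, 4, 4)), 10),
               "shape differs")
  tt <- matrix(seq(1, 0, length.out = 64), 8, 8, byrow = TRUE)
  expect_error(litm_scan(list(`26Mg` = m), 10, time_h = tt),
               "non-decreasing")
  std <- data.frame(element = "Gd", ppm = c(10, 100), cps = c(500, 5000),
                    time_h = 0)
  expect_s3_class(standard_set(std, blank = c(Gd = 20)), "standard_set")
  expect_error(standard_set(std[1, ], blank = c(Gd = 20)),
               "fewer than 2")
  expect_error(standard_set(data.frame(element = "Gd", ppm = c(-1, 10),
                                       cps = c(1, 2), time_h = 0),
                            blank = c(Gd = 0)), "> 0")
})

test_that("noiseless calibration is exact; guards fire", {
  ph <- make_litm_phantom(litm_test_layout(), litm_test_ppm())
  cal <- build_calibration(ph$standards, "static")
  tr <- ph$truth
  for (el in names(cal$fits)) {
    expect_equal(cal$fits[[el]]$slope, unname(tr$sensitivity[el]),
                 tolerance = 1e-9)
    # blank-subtracted: intercept collapses to zero
    expect_lt(abs(cal$fits[[el]]$intercept), 1e-8)
    expect_equal(cal$fits[[el]]$r_squared, 1, tolerance = 1e-12)
  }
  # inverted calibration detected
  bad <- ph$standards
  bad$standards$cps <- max(bad$standards$cps) - bad$standards$cps
  expect_error(build_calibration(bad, "static"), "inverted")
})

test_that("cps_to_ppm: recovery, floor, pass-through", {
  ph <- make_litm_phantom(litm_test_layout(), litm_test_ppm())
  cal <- build_calibration(ph$standards, "static")
  maps <- cps_to_ppm(ph$scan, cal)
  msk <- ph$truth$region_masks$degradation
  expect_equal(mean(maps[["155Gd"]][msk]), 1316.3, tolerance = 0.02)
  expect_equal(mean(maps[["26Mg"]][msk]), 5000, tolerance = 0.02)
  # CPS equal to blank+intercept maps to 0 ppm
  expect_true(all(maps[["155Gd"]][ph$truth$region_masks$control] < 1e-8))
  # 31P passes through in CPS with a unit flag
  expect_identical(attr(maps[["31P"]], "unit"), "cps")
  expect_equal(unclass(maps[["31P"]]), unclass(ph$scan$channels[["31P"]]),
               ignore_attr = TRUE)
  # unknown uncalibrated channel errors
  expect_error(cps_to_ppm(ph$scan, cal, passthrough = character(0)),
               "pass-through")
})

test_that("drift model quantifies a drifting scan within 2 %", {
  ph <- make_litm_phantom(litm_test_layout(), litm_test_ppm(),
                          drift_slope_per_hour = 0.10)
  cal <- build_calibration(ph$standards, "drift")
  maps <- cps_to_ppm(ph$scan, cal)
  for (rg in c("degradation", "interface")) {
    msk <- ph$truth$region_masks[[rg]]
    want <- ph$truth$ppm_true[[rg]][["Gd"]]
    got <- mean(maps[["155Gd"]][msk])
    expect_lt(abs(got - want) / want, 0.02)
  }
  # the static model on the same scan is visibly biased
  cal_s <- build_calibration(ph$standards, "static")
  maps_s <- cps_to_ppm(ph$scan, cal_s)
  err_s <- abs(mean(maps_s[["155Gd"]][ph$truth$region_masks$degradation]) -
                 1316.3) / 1316.3
  err_d <- abs(mean(maps[["155Gd"]][ph$truth$region_masks$degradation]) -
                 1316.3) / 1316.3
  expect_gt(err_s, err_d)
  # drift model demands multiple scan times
  std1 <- ph$standards
  std1$standards <- std1$standards[std1$standards$time_h == 0, ]
  expect_error(build_calibration(std1, "drift"), ">= 2 standard scan times")
})

test_that("compute_lod: arithmetic, equivariance, normal-tail oracle", {
  # control with sample mean 120 and sample SD exactly 10 -> LOD 150
  set.seed(5)
  z <- as.vector(scale(rnorm(100)))
  v <- matrix(120 + 10 * z, 10, 10)
  maps <- list(ch = v)
  ctrl <- matrix(TRUE, 10, 10)
  expect_equal(compute_lod(maps, ctrl, "ch"), 150, tolerance = 1e-12)
  # zero-variance control: LOD = mean
  expect_equal(compute_lod(list(ch = matrix(7, 6, 6)), matrix(TRUE, 6, 6),
                           "ch"), 7)
  # translation equivariance
  expect_equal(compute_lod(list(ch = v + 13), ctrl, "ch"),
               compute_lod(maps, ctrl, "ch") + 13, tolerance = 1e-12)
  expect_error(compute_lod(maps, matrix(c(TRUE, rep(FALSE, 99)), 10, 10),
                           "ch"), ">= 30")
  # Gaussian control: expected exceedance of mean + 3s is ~0.135 %
  fr <- vapply(1:50, function(s) {
    set.seed(s)
    x <- matrix(rnorm(50 * 50, 100, 10), 50, 50)
    lod <- compute_lod(list(ch = x), matrix(TRUE, 50, 50), "ch")
    mean(x > lod)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.00135), 5e-4)
})

test_that("classify_regions: rules, disjointness, monotonicity, guards", {
  ph <- make_litm_phantom(litm_test_layout(), litm_test_ppm())
  regs <- classify_regions(ph$scan, "155Gd")
  expect_identical(regs$degradation, ph$truth$region_masks$degradation)
  nms <- names(regs)
  for (i in seq_along(regs)) for (j in seq_len(i - 1))
    expect_false(any(regs[[i]] & regs[[j]]))
  # Fe at 25 % of its cutoff excludes a pixel from degradation
  scan2 <- ph$scan
  cut_fe <- quantile(scan2$channels[["56Fe"]], 0.999, names = FALSE)
  idx <- which(ph$truth$region_masks$degradation, arr.ind = TRUE)[1, ]
  scan2$channels[["56Fe"]][idx[1], idx[2]] <- 0.25 * cut_fe
  regs2 <- classify_regions(scan2, "155Gd")
  expect_false(regs2$degradation[idx[1], idx[2]])
  # raising the Fe threshold fraction can only grow the mask
  regs3 <- classify_regions(scan2, "155Gd", fe_fraction = 0.5)
  expect_true(all(regs2$degradation <= regs3$degradation))
  # manual exclusion mask removes pixels
  excl <- matrix(FALSE, 128, 128); excl[10:50, 10:20] <- TRUE
  regs4 <- classify_regions(ph$scan, "155Gd", exclude_mask = excl)
  expect_false(any(regs4$degradation & excl))
  # constant channel: degenerate percentile
  scan3 <- ph$scan
  scan3$channels[["56Fe"]][] <- 5
  expect_error(classify_regions(scan3, "155Gd"), "degenerate")
  # Poisson noise: pixel accuracy >= 95 %
  phn <- make_litm_phantom(litm_test_layout(), litm_test_ppm(),
                           noise_model = list(type = "poisson"), seed = 3)
  regsn <- classify_regions(phn$scan, "155Gd")
  expect_gte(mean(regsn$degradation == phn$truth$region_masks$degradation),
             0.95)
})

test_that("region_report: stats, LOD percentages, empty regions", {
  ph <- make_litm_phantom(litm_test_layout(), litm_test_ppm(),
                          noise_model = list(type = "poisson"), seed = 6)
  cal <- build_calibration(ph$standards, "static")
  maps <- cps_to_ppm(ph$scan, cal)
  masks <- ph$truth$region_masks
  # LOD applied in signal (CPS) space, before the ppm zero-floor distorts
  # the baseline distribution
  lod_gd <- compute_lod(ph$scan, masks$other, "155Gd")
  rr <- region_report(list(`155Gd` = ph$scan$channels[["155Gd"]]),
                      list(degradation = masks$degradation,
                           control = masks$control,
                           empty = matrix(FALSE, 128, 128)),
                      lods = c(`155Gd` = lod_gd))
  gd <- rr[rr$channel == "155Gd", ]
  expect_equal(gd$pct_above_lod[gd$region == "degradation"], 100)
  expect_lt(gd$pct_above_lod[gd$region == "control"], 1)
  expect_equal(gd$n[gd$region == "empty"], 0)
  expect_true(is.na(gd$mean[gd$region == "empty"]))
  rr_ppm <- region_report(maps, list(degradation = masks$degradation))
  expect_equal(rr_ppm$mean[rr_ppm$channel == "155Gd"], 1316.3,
               tolerance = 0.02)
  # overlapping regions are rejected
  expect_error(region_report(maps, list(a = masks$degradation,
                                        b = masks$degradation)),
               "overlap")
  # scatter export has one row per region pixel
  sc <- region_scatter(maps, masks$degradation, "44Ca", "31P")
  expect_equal(nrow(sc), sum(masks$degradation))
})
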