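flat_phantom <- function(noise_sd = 0, seed = 1)
  make_xrf_phantom(size_px = 128, pixel_um = 0.5,
                   ca_p_profile = function(d) rep(2, length(d)),
                   noise_sd = noise_sd, seed = seed)

test_that("segmentation: noiseless exactness, Gd precedence, idempotence", {
  ph <- flat_phantom()
  m <- segment_xrf(ph$maps)
  expect_identical(m, ph$maps$mask)
  # pixel with both Ca and Gd above threshold -> degradation
  maps <- ph$maps
  maps$maps$Ca[5, 5] <- max(maps$maps$Ca)
  maps$maps$Gd[5, 5] <- max(maps$maps$Gd)
  m2 <- segment_xrf(maps)
  expect_equal(m2[5, 5], 2L)
  # classes partition the image
  expect_true(all(m %in% 0:2))
  # noisy segmentation accuracy >= 95 % (SNR 10)
  phn <- flat_phantom(noise_sd = 10, seed = 4)
  mn <- segment_xrf(phn$maps)
  expect_gte(mean(mn == phn$maps$mask), 0.95)
})

test_that("small-object removal cleans salt noise", {
  ph <- flat_phantom()
  maps <- ph$maps
  maps$maps$Gd[100, 100] <- max(maps$maps$Gd)  # isolated false Gd pixel
  m_raw <- segment_xrf(maps)
  expect_equal(m_raw[100, 100], 2L)
  m_clean <- segment_xrf(maps, min_area = 5)
  expect_equal(m_clean[100, 100], 0L)  # empty there (Ca below threshold too)
  # the genuine band survives
  expect_true(all(m_clean[, 1:19] == 2L))
})

test_that("distance_map: adjacency, linear interface, zeros on class", {
  mask <- matrix(1L, 10, 10)
  mask[, 1:3] <- 2L
  d <- distance_map(mask, 2, pixel_um = 2)
  expect_true(all(d[, 1:3] == 0))
  expect_equal(d[5, 4], 2)             # 4-neighbour of the layer
  expect_equal(d[1, 4:10], (1:7) * 2)  # linear growth with column
  expect_error(distance_map(matrix(1L, 4, 4), 2), "absent")
})

test_that("ratio_profile: flat field, scale invariance, denominator floor", {
  ph <- flat_phantom()
  rp <- ratio_profile(ph$maps, bin_um = 2, max_um = 20)
  expect_true(all(abs(rp$mean - 2) < 1e-12, na.rm = TRUE))
  expect_s3_class(rp, "ratio_profile")
  # rescaling both maps leaves the profile unchanged
  maps2 <- ph$maps
  maps2$maps$Ca <- maps2$maps$Ca * 7.3
  maps2$maps$P <- maps2$maps$P * 7.3
  rp2 <- ratio_profile(maps2, bin_um = 2, max_um = 20)
  expect_equal(rp2$mean, rp$mean, tolerance = 1e-12)
  # denominator-zero pixels drop out of the counts
  maps3 <- ph$maps
  bone_cols <- which(ph$maps$mask[1, ] == 1)
  maps3$maps$P[1:10, bone_cols[1]] <- 0
  rp3 <- ratio_profile(maps3, bin_um = 2, max_um = 20)
  expect_equal(sum(rp$n_pixels) - sum(rp3$n_pixels), 10)
  # CI shrinks as n grows: noisy phantom, wide vs narrow bins
  phn <- flat_phantom(noise_sd = 5, seed = 2)
  rp_narrow <- ratio_profile(phn$maps, bin_um = 1, max_um = 20)
  rp_wide <- ratio_profile(phn$maps, bin_um = 10, max_um = 20)
  expect_lt(mean(rp_wide$ci_halfwidth), mean(rp_narrow$ci_halfwidth))
})

test_that("imposed linear gradient is recovered within 2 CI", {
  prof <- function(d) 1.5 + 0.5 * pmin(d, 30) / 30
  ph <- make_xrf_phantom(size_px = 256, pixel_um = 0.5,
                         ca_p_profile = prof, noise_sd = 5, seed = 3)
  m <- segment_xrf(ph$maps)
  rp <- ratio_profile(ph$maps, m)
  mid <- (rp$bin_lo + rp$bin_hi) / 2
  ok <- abs(rp$mean - prof(mid)) <= 2 * rp$ci_halfwidth
  expect_gte(mean(ok, na.rm = TRUE), 0.95)
})

test_that("layer_ratios: arithmetic, pixelwise identity, particle contrast", {
  n <- 32
  mask <- matrix(2L, n, n)
  maps <- element_map_set(list(Ca = matrix(2, n, n), P = matrix(2, n, n),
                               Gd = matrix(4, n, n)), 1, mask)
  lr <- layer_ratios(maps)
  expect_equal(lr$mean[lr$ratio == "Ca/P"], 1.0)
  expect_equal(lr$mean[lr$ratio == "Gd/P"], 2.0)
  expect_equal(lr$mean[lr$ratio == "Gd/Ca"], 2.0)
  # pixelwise identity Gd/Ca * Ca/P = Gd/P
  set.seed(8)
  mr <- element_map_set(list(Ca = matrix(runif(n^2, 1, 3), n),
                             P = matrix(runif(n^2, 1, 3), n),
                             Gd = matrix(runif(n^2, 1, 3), n)), 1, mask)
  gdca <- mr$maps$Gd / mr$maps$Ca
  cap <- mr$maps$Ca / mr$maps$P
  expect_equal(gdca * cap, mr$maps$Gd / mr$maps$P, tolerance = 1e-12)
  # bright Gd particles raise the layer SD
  mp <- mr
  idx <- sample(n^2, 20)
  mp$maps$Gd[idx] <- mp$maps$Gd[idx] * 20
  expect_gt(layer_ratios(mp)$sd[2], layer_ratios(mr)$sd[2])
  expect_error(layer_ratios(element_map_set(list(Ca = matrix(1, 2, 2),
                                                 P = matrix(1, 2, 2),
                                                 Gd = matrix(1, 2, 2)), 1,
                                            matrix(1L, 2, 2))),
               "layer empty")
})

test_that("vessel_profile: flat equals control; imposed dip recovered", {
  n <- 128
  px <- 0.5
  ctr <- c(64, 64)
  rad <- sqrt(outer((seq_len(n) - ctr[1])^2, (seq_len(n) - ctr[2])^2, `+`))
  vessel <- rad <= 6          # ~3 um vessel lumen
  dist_um <- pmax(rad - 6, 0) * px
  mask <- matrix(1L, n, n)
  mask[vessel] <- 0L
  control <- matrix(FALSE, n, n); control[1:20, 1:20] <- TRUE
  # flat ratio field
  maps <- element_map_set(list(Ca = matrix(200, n, n), P = matrix(100, n, n),
                               Gd = matrix(0, n, n)), px, mask)
  vp <- vessel_profile(maps, vessel, control, bin_um = 2, max_um = 20)
  expect_true(all(abs(vp$mean - attr(vp, "control_mean")) < 1e-12,
                  na.rm = TRUE))
  # dip: 1.8 at the wall rising to 2.0 at 15 um
  dipfun <- function(d) 2.0 - 0.2 * pmax(0, 1 - d / 15)
  set.seed(10)
  ca <- (dipfun(dist_um) * 100) + matrix(rnorm(n^2, 0, 3), n, n)
  mapsd <- element_map_set(list(Ca = pmax(ca, 0), P = matrix(100, n, n),
                                Gd = matrix(0, n, n)), px, mask)
  vpd <- vessel_profile(mapsd, vessel, control, bin_um = 2, max_um = 20)
  mid <- (vpd$bin_lo + vpd$bin_hi) / 2
  ok <- abs(vpd$mean - dipfun(mid)) <= 2 * vpd$ci_halfwidth
  expect_gte(mean(ok, na.rm = TRUE), 0.9)
  expect_lt(vpd$mean[1], vpd$mean[nrow(vpd)])
  # vessel overlapping the degradation class errors
  mask2 <- mask; mask2[70, 70] <- 2L
  v2 <- vessel; v2[70, 70] <- TRUE
  mapse <- element_map_set(list(Ca = matrix(1, n, n), P = matrix(1, n, n),
                                Gd = matrix(0, n, n)), px, mask2)
  expect_error(vessel_profile(mapse, v2, control), "overlaps")
})

test_that("compare_ratio_groups: degeneracies, symmetry, power", {
  expect_equal(compare_ratio_groups(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  expect_equal(compare_ratio_groups(c(2, 2, 2), c(2, 2, 2))$statistic, 0)
  a <- c(1.9, 2.0, 2.1, 2.0, 1.95)
  b <- c(2.15, 2.2, 2.25, 2.18, 2.21)
  f <- compare_ratio_groups(a, b)
  r <- compare_ratio_groups(b, a)
  expect_equal(abs(f$statistic), abs(r$statistic))
  expect_equal(f$p_value, r$p_value)
  expect_error(compare_ratio_groups(1, c(1, 2)), ">= 2 samples")
  # N(2.0, 0.01) vs N(2.2, 0.01), n = 5: significant in >= 99 % of seeds
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    compare_ratio_groups(rnorm(5, 2.0, 0.01),
                         rnorm(5, 2.2, 0.01))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
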