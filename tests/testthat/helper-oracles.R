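# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately use naive triple loops / per-pixel loops so they share
# no code path with the package implementation.

# voxel count of a code, by explicit loop
bf_class_count <- function(labels, code) {
  n <- 0L
  dm <- dim(labels)
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1]))
    if (labels[i, j, k] %in% code) n <- n + 1L
  n
}

# exposed faces of a code-set, and faces touching `contact`, by explicit
# neighbour enumeration (6-connectivity, domain-boundary faces not counted)
bf_faces <- function(labels, codes, contact = -1L) {
  dm <- dim(labels)
  exposed <- 0L
  hit <- 0L
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    if (!(labels[i, j, k] %in% codes)) next
    for (m in 1:6) {
      ii <- i + nb[m, 1]; jj <- j + nb[m, 2]; kk <- k + nb[m, 3]
      if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] ||
          kk < 1 || kk > dm[3]) next
      v <- labels[ii, jj, kk]
      if (!(v %in% codes)) {
        exposed <- exposed + 1L
        if (v == contact) hit <- hit + 1L
      }
    }
  }
  c(exposed = exposed, contact = hit)
}

# random labeled grid for oracle-equivalence checks
random_label_grid <- function(seed, max_dim = 12) {
  set.seed(seed)
  dm <- sample(4:max_dim, 3, replace = TRUE)
  array(sample(0:3, prod(dm), replace = TRUE), dim = dm)
}

# brute-force azimuthal integration: per-pixel loop into q bins
bf_azimuthal <- function(counts, geom, n_bins) {
  nr <- nrow(counts); nc <- ncol(counts)
  qpx <- matrix(0, nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    r <- sqrt((j - geom$center_x_px)^2 + (i - geom$center_y_px)^2)
    tth <- atan(r * geom$pixel_mm / geom$distance_mm)
    qpx[i, j] <- (4 * pi / geom$wavelength_nm) * sin(tth / 2)
  }
  edges <- seq(min(qpx), max(qpx), length.out = n_bins + 1)
  sums <- numeric(n_bins); ns <- integer(n_bins)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    b <- findInterval(qpx[i, j], edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
    sums[b] <- sums[b] + counts[i, j]
    ns[b] <- ns[b] + 1L
  }
  used <- ns > 0
  list(q = ((edges[-1] + edges[-(n_bins + 1)]) / 2)[used],
       I = sums[used] / ns[used])
}

# standard LITM phantom layout/concentrations used across tests
litm_test_layout <- function() {
  list(degradation = c(10, 50, 10, 50),
       interface = c(10, 50, 55, 80),
       control = c(80, 120, 80, 120))
}

litm_test_ppm <- function(gd_layer = 1316.3) {
  list(degradation = c(Gd = gd_layer, Mg = 5000, Ca = 100),
       interface = c(Gd = 60, Mg = 900, Ca = 3000, P = 2000),
       control = c(Mg = 800, Ca = 3000, P = 2000),
       other = c(Fe = 300, Ca = 100, P = 80))
}

# fresh scratch directory per test, cleaned up by the session tempdir
withr_like_tempdir <- function() {
  d <- tempfile("oqtest")
  dir.create(d)
  d
}
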