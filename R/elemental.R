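# XRF elemental-map analysis: presence-based segmentation into
# bone / degradation layer / empty space, distance-resolved elemental-ratio
# profiles from the implant interface or from blood-vessel walls, and
# degradation-layer ratio statistics.

XRF_EMPTY <- 0L
XRF_BONE <- 1L
XRF_DEGRADATION <- 2L

#' Co-registered XRF element maps
#'
#' @param maps named list of non-negative intensity matrices (at least
#'   `Ca`, `P`, `Gd` for the standard workflow), all the same shape.
#' @param pixel_um pixel size, micrometres.
#' @param mask optional class matrix (0 empty, 1 bone, 2 degradation).
#' @return object of class `element_map_set`.
#' @export
element_map_set <- function(maps, pixel_um, mask = NULL) {
  if (!is.list(maps) || is.null(names(maps)) || any(!nzchar(names(maps))))
    stop_oq("`maps` must be a named list of matrices")
  dm <- dim(maps[[1]])
  for (nm in names(maps)) {
    if (!is.matrix(maps[[nm]]) || !identical(dim(maps[[nm]]), dm))
      stop_oq("map '%s' shape differs", nm)
    if (any(maps[[nm]] < 0)) stop_oq("map '%s' has negative intensities", nm)
  }
  check_scalar(pixel_um, "pixel_um", 0, strict_lower = TRUE)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dm)) stop_oq("mask shape differs from maps")
    bad <- setdiff(unique(as.vector(mask)), c(XRF_EMPTY, XRF_BONE, XRF_DEGRADATION))
    if (length(bad)) stop_oq("invalid mask code(s): %s", paste(bad, collapse = ", "))
    mask <- matrix(as.integer(mask), dm[1], dm[2])
  }
  structure(list(maps = maps, pixel_um = pixel_um, mask = mask),
            class = "element_map_set")
}

# Otsu threshold from a 256-bin histogram: maximises between-class variance.
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + as.integer((x - r[1]) / (r[2] - r[1]) * nb)), nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(nb) - 0.5) / nb * (r[2] - r[1])
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, nb)
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  mids[which.max(sigma_b)]
}

# Two-pass 4-connectivity connected-component labelling (union-find).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j]) next
    up <- if (i > 1 && mask[i - 1, j]) lab[i - 1, j] else 0L
    left <- if (j > 1 && mask[i, j - 1]) lab[i, j - 1] else 0L
    if (up == 0L && left == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i, j] <- nxt
    } else if (up != 0L && left != 0L) {
      ru <- find(up); rl <- find(left)
      lab[i, j] <- ru
      if (ru != rl) parent[rl] <- ru
    } else lab[i, j] <- max(up, left)
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    ids <- match(roots, unique(roots))
    lab[mask] <- ids[lab[mask]]
  }
  lab
}

remove_small_objects <- function(mask, min_area) {
  if (min_area <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask)
  keep <- which(tabulate(lab[mask]) >= min_area)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

resolve_threshold <- function(map, rule) {
  if (is.numeric(rule)) return(rule)
  method <- if (is.null(rule$method)) "otsu" else rule$method
  if (method == "otsu") {
    k <- if (is.null(rule$k)) 1 else rule$k
    k * otsu_threshold(map)
  } else if (method == "abs") rule$value
  else stop_oq("unknown threshold rule method '%s'", method)
}

#' Segment XRF maps into bone / degradation layer / empty space
#'
#' Presence-based rules: a pixel is degradation layer when Gd exceeds its
#' threshold (Gd takes precedence), else bone when Ca exceeds its
#' threshold, else empty. Thresholds default to `k * Otsu` per element.
#' Optional small-object removal cleans each non-empty class.
#'
#' @param maps an [element_map_set()] containing `Ca` and `Gd`.
#' @param ca_rule,gd_rule either a numeric threshold or a list
#'   `list(method = "otsu", k = 1)` / `list(method = "abs", value = v)`.
#' @param min_area minimum connected-component area in pixels (0 disables
#'   cleaning).
#' @return integer class matrix (0 empty, 1 bone, 2 degradation).
#' @export
segment_xrf <- function(maps, ca_rule = list(method = "otsu", k = 1),
                        gd_rule = list(method = "otsu", k = 1),
                        min_area = 0) {
  stopifnot(inherits(maps, "element_map_set"))
  if (!all(c("Ca", "Gd") %in% names(maps$maps)))
    stop_oq("segmentation needs Ca and Gd maps")
  thr_ca <- resolve_threshold(maps$maps$Ca, ca_rule)
  thr_gd <- resolve_threshold(maps$maps$Gd, gd_rule)
  deg <- maps$maps$Gd > thr_gd
  bone <- !deg & maps$maps$Ca > thr_ca
  if (min_area > 1) {
    deg <- remove_small_objects(deg, min_area)
    bone <- remove_small_objects(bone & !deg, min_area)
  }
  mask <- matrix(XRF_EMPTY, nrow(deg), ncol(deg))
  mask[bone] <- XRF_BONE
  mask[deg] <- XRF_DEGRADATION
  if (!any(mask != XRF_EMPTY)) warn_oq("segmentation produced no bone or degradation pixels")
  mask
}

#' Distance map to a mask class
#'
#' Per-pixel Euclidean distance (micrometres, centre-to-centre) to the
#' nearest pixel of `from_class`.
#'
#' @param mask integer class matrix.
#' @param from_class class code to measure from (default 2, degradation).
#' @param pixel_um pixel size, micrometres.
#' @return numeric matrix of distances (0 on `from_class` pixels).
#' @export
distance_map <- function(mask, from_class = XRF_DEGRADATION, pixel_um = 1) {
  src <- mask == from_class
  if (!any(src)) stop_oq("class %d absent from mask", from_class)
  distance_transform(src) * pixel_um
}

new_ratio_profile <- function(bin_lo, bin_hi, mean, ci, n) {
  out <- data.frame(bin_lo = bin_lo, bin_hi = bin_hi, mean = mean,
                    ci_halfwidth = ci, n_pixels = n,
                    flagged = n == 0)
  class(out) <- c("ratio_profile", class(out))
  out
}

profile_from_distances <- function(num, den, sel, dist_um, bin_um, max_um,
                                   denom_floor, n_min = 1) {
  edges <- seq(0, max_um, by = bin_um)
  if (edges[length(edges)] < max_um) edges <- c(edges, max_um)
  ok <- sel & den > denom_floor & dist_um <= max_um
  r <- num[ok] / den[ok]
  d <- dist_um[ok]
  bin <- findInterval(d, edges, rightmost.closed = TRUE, left.open = TRUE)
  bin[d == 0] <- 1L
  nb <- length(edges) - 1
  m <- ci <- rep(NA_real_, nb)
  n <- integer(nb)
  for (b in seq_len(nb)) {
    v <- r[bin == b]
    n[b] <- length(v)
    if (n[b] >= n_min) {
      m[b] <- mean(v)
      ci[b] <- if (n[b] > 1) 1.96 * sd(v) / sqrt(n[b]) else NA_real_
    }
  }
  new_ratio_profile(edges[-length(edges)], edges[-1], m, ci, n)
}

#' Elemental-ratio profile versus distance from the implant interface
#'
#' For bone-class pixels only: the per-pixel ratio
#' `numerator / denominator` (denominator pixels at or below `denom_floor`
#' excluded), binned by Euclidean distance to the degradation layer, with
#' per-bin mean and a normal-approximation 95 % confidence halfwidth
#' `1.96 * SD / sqrt(n)`. Empty bins are kept and flagged.
#'
#' @param maps an [element_map_set()].
#' @param mask class matrix (e.g. from [segment_xrf()]); defaults to the
#'   mask stored in `maps`.
#' @param numerator,denominator map names (defaults `Ca`, `P`).
#' @param bin_um bin width (default 1).
#' @param max_um maximum distance (default 30).
#' @param denom_floor exclude pixels whose denominator is at or below this.
#' @param exclusion_um optional near-interface exclusion margin for
#'   segmentation artefacts (default 0 = off).
#' @return a `ratio_profile` data.frame: bin_lo, bin_hi, mean,
#'   ci_halfwidth, n_pixels, flagged.
#' @export
ratio_profile <- function(maps, mask = NULL, numerator = "Ca",
                          denominator = "P", bin_um = 1, max_um = 30,
                          denom_floor = 0, exclusion_um = 0) {
  stopifnot(inherits(maps, "element_map_set"))
  if (is.null(mask)) mask <- maps$mask
  if (is.null(mask)) stop_oq("no class mask available; run segment_xrf() first")
  dist_um <- distance_map(mask, XRF_DEGRADATION, maps$pixel_um)
  sel <- mask == XRF_BONE & dist_um > exclusion_um
  if (!any(sel & dist_um <= max_um))
    stop_oq("no bone pixels within %g um of the interface", max_um)
  profile_from_distances(maps$maps[[numerator]], maps$maps[[denominator]],
                         sel, dist_um, bin_um, max_um, denom_floor)
}

#' Elemental ratios inside the degradation layer
#'
#' Pixelwise Ca/P, Gd/P and Gd/Ca over degradation-layer pixels
#' (denominator floor applied), reported as mean, SD and n.
#'
#' @param maps an [element_map_set()] with Ca, P, Gd.
#' @param mask class matrix; defaults to the stored mask.
#' @param denom_floor exclude pixels whose denominator is at or below this.
#' @return `data.frame` with one row per ratio: ratio, mean, sd, n.
#' @export
layer_ratios <- function(maps, mask = NULL, denom_floor = 0) {
  stopifnot(inherits(maps, "element_map_set"))
  if (is.null(mask)) mask <- maps$mask
  if (is.null(mask)) stop_oq("no class mask available")
  lay <- mask == XRF_DEGRADATION
  if (!any(lay)) stop_oq("degradation layer empty")
  one <- function(num, den) {
    ok <- lay & maps$maps[[den]] > denom_floor
    v <- maps$maps[[num]][ok] / maps$maps[[den]][ok]
    data.frame(ratio = paste0(num, "/", den),
               mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
               n = length(v))
  }
  rbind(one("Ca", "P"), one("Gd", "P"), one("Gd", "Ca"))
}

#' Elemental-ratio profile around a blood vessel
#'
#' Same computation as [ratio_profile()], but distances are measured from
#' the vessel-wall pixels, and the mean ratio over a caller-supplied
#' control region is attached for reference.
#'
#' @param maps an [element_map_set()].
#' @param vessel_mask logical matrix of vessel(-wall) pixels; must not
#'   overlap the degradation class.
#' @param control_mask logical matrix of the control bone region.
#' @param mask class matrix; defaults to the stored mask.
#' @param numerator,denominator map names.
#' @param bin_um,max_um,denom_floor as in [ratio_profile()].
#' @return a `ratio_profile` with attribute `control_mean`.
#' @export
vessel_profile <- function(maps, vessel_mask, control_mask = NULL,
                           mask = NULL, numerator = "Ca",
                           denominator = "P", bin_um = 1, max_um = 30,
                           denom_floor = 0) {
  stopifnot(inherits(maps, "element_map_set"))
  if (is.null(mask)) mask <- maps$mask
  if (is.null(mask)) stop_oq("no class mask available")
  if (!any(vessel_mask)) stop_oq("vessel mask is empty")
  if (any(vessel_mask & mask == XRF_DEGRADATION))
    stop_oq("vessel mask overlaps the degradation layer")
  dist_um <- distance_transform(vessel_mask) * maps$pixel_um
  sel <- mask == XRF_BONE & !vessel_mask
  prof <- profile_from_distances(maps$maps[[numerator]],
                                 maps$maps[[denominator]], sel, dist_um,
                                 bin_um, max_um, denom_floor)
  if (!is.null(control_mask)) {
    ok <- control_mask & maps$maps[[denominator]] > denom_floor
    attr(prof, "control_mean") <-
      mean(maps$maps[[numerator]][ok] / maps$maps[[denominator]][ok])
  }
  prof
}

#' Two-sample comparison of per-sample mean ratios
#'
#' Two-sided two-sample Welch t-test on per-sample means (the experimental
#' unit is the sample, not the pixel). Zero-variance degeneracies are
#' handled explicitly and flagged.
#'
#' @param a,b numeric vectors of per-sample mean ratios (>= 2 each).
#' @return list: statistic, p_value, n_a, n_b, degenerate flag.
#' @export
compare_ratio_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_oq("each group needs >= 2 samples")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, p_value = 1, n_a = length(a),
                  n_b = length(b), degenerate = TRUE))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                n_a = length(a), n_b = length(b), degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       n_a = length(a), n_b = length(b), degenerate = FALSE)
}
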