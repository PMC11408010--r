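#' @useDynLib osseoquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef integrate lm median nls optim pnorm
#'   predict qnorm quantile residuals rnorm rpois sd setNames t.test var
#' @importFrom utils read.csv write.csv modifyList
"_PACKAGE"

# Evaluate expr with a temporary RNG seed; restores the caller's RNG state so
# generators are deterministic without clobbering the session stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_oq <- function(...) stop(sprintf(...), call. = FALSE)
warn_oq <- function(...) warning(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_oq("`%s` must be a finite numeric scalar", name)
  if (strict_lower && x <= lower)
    stop_oq("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_oq("`%s` must be >= %g (got %g)", name, lower, x)
  if (x > upper) stop_oq("`%s` must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

#' Squared / plain Euclidean distance transform of a binary mask
#'
#' Distance (in grid units) from every element of a 2D or 3D logical array to
#' the nearest `TRUE` element, using the exact separable algorithm of
#' Felzenszwalb and Huttenlocher. Multiply by the pixel/voxel size to get
#' physical distances.
#'
#' @param mask logical matrix or 3D array with at least one `TRUE`.
#' @param squared return squared distances (default `FALSE`).
#' @return numeric array of the same shape as `mask`.
#' @export
distance_transform <- function(mask, squared = FALSE) {
  dm <- dim(mask)
  if (is.null(dm) || !(length(dm) %in% c(2L, 3L)))
    stop_oq("`mask` must be a 2D or 3D array")
  if (!any(mask)) stop_oq("`mask` has no TRUE element; distance undefined")
  d2 <- .edt_sq_cpp(as.logical(mask), as.integer(dm))
  out <- if (squared) d2 else sqrt(d2)
  array(out, dim = dm)
}

# Percentile with linear interpolation between order statistics
# (quantile type 7) -- the fixed, documented definition used by the
# region-classification rules.
percentile <- function(x, p) {
  stats::quantile(x, probs = p, type = 7, names = FALSE, na.rm = TRUE)
}
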