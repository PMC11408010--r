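# File-format boundary: TIFF images/volumes with plain-text key-value
# sidecars for physical metadata, two-column text for 1D patterns,
# key-value text for detector geometry, CSV for tabular results. All unit
# conversions happen here; internal code uses um, nm, nm^-1, mm/year, ppm.

sidecar_path <- function(path) paste0(path, ".meta")

write_keyvals <- function(kv, path) {
  lines <- vapply(names(kv), function(k) {
    v <- kv[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 17, scientific = FALSE,
                                       trim = TRUE), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_keyvals <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop_oq("'%s': malformed key-value line: %s", path, ln)
    key <- trimws(parts[1])
    vals <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(vals))
    kv[[key]] <- if (any(is.na(num))) vals else num
  }
  kv
}

#' Write / read a labeled volume as multi-page TIFF
#'
#' The label field goes into an unsigned 8-bit multi-page TIFF; the voxel
#' size into a plain-text sidecar (`<path>.meta`).
#'
#' @param vol a [label_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  write_tiff(vol$labels, path, "uint8")
  write_keyvals(list(voxel_um = vol$voxel_um), sidecar_path(path))
  invisible(path)
}

#' @rdname write_volume
#' @param voxel_um voxel size override when no sidecar exists.
#' @return for `read_volume`: a [label_volume()].
#' @export
read_volume <- function(path, voxel_um = NULL) {
  if (!file.exists(path)) stop_oq("'%s': no such file", path)
  arr <- read_tiff(path, pages_as_array = TRUE)
  sc <- sidecar_path(path)
  if (is.null(voxel_um)) {
    if (!file.exists(sc))
      stop_oq("'%s': voxel size unknown; provide `voxel_um` or a sidecar %s",
              path, sc)
    voxel_um <- read_keyvals(sc)$voxel_um
    if (is.null(voxel_um)) stop_oq("'%s': sidecar lacks voxel_um", sc)
  }
  label_volume(arr, voxel_um)
}

#' Write / read a 2D intensity map as float32 TIFF
#'
#' @param map numeric matrix.
#' @param path TIFF path.
#' @param pixel_um pixel size recorded in the sidecar.
#' @return `path` / the matrix with attribute `pixel_um`.
#' @export
write_map <- function(map, path, pixel_um = NULL) {
  write_tiff(map, path, "float32")
  if (!is.null(pixel_um))
    write_keyvals(list(pixel_um = pixel_um), sidecar_path(path))
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path, pixel_um = NULL) {
  if (!file.exists(path)) stop_oq("'%s': no such file", path)
  m <- read_tiff(path)
  if (length(dim(m)) == 3L) stop_oq("'%s': expected a single-page map", path)
  sc <- sidecar_path(path)
  if (is.null(pixel_um) && file.exists(sc))
    pixel_um <- read_keyvals(sc)$pixel_um
  attr(m, "pixel_um") <- pixel_um
  m
}

#' Write / read a 1D pattern as two-column text
#'
#' Whitespace-delimited `q intensity` rows (q in nm^-1), `#` comment
#' header. Locale-independent: decimal points and exponent notation are
#' parsed with C conventions.
#'
#' @param p a [pattern1d()].
#' @param path output file.
#' @return `path` / a [pattern1d()].
#' @export
write_pattern <- function(p, path) {
  stopifnot(inherits(p, "pattern1d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# q_nm^-1  intensity",
               sprintf("# normalization = %.17g", p$normalization)), con)
  writeLines(sprintf("%.10e %.10e", p$q, p$intensity), con)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  if (!file.exists(path)) stop_oq("'%s': no such file", path)
  lines <- readLines(path, warn = FALSE)
  norm <- 1
  hdr <- grep("^#\\s*normalization\\s*=", lines, value = TRUE)
  if (length(hdr))
    norm <- as.numeric(sub(".*=\\s*", "", hdr[1]))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop_oq("'%s': no data rows", path)
  fields <- strsplit(lines, "\\s+")
  if (any(lengths(fields) < 2)) stop_oq("'%s': rows need two columns", path)
  q <- as.numeric(vapply(fields, `[`, character(1), 1))
  I <- as.numeric(vapply(fields, `[`, character(1), 2))
  if (any(is.na(q)) || any(is.na(I))) stop_oq("'%s': non-numeric data", path)
  pattern1d(q, I, normalization = norm)
}

#' Write / read a detector geometry file
#'
#' Plain text with keys `wavelength_nm`, `distance_mm`, `pixel_mm`,
#' `center_x_px`, `center_y_px`.
#'
#' @param geom a [detector_geometry()].
#' @param path file path.
#' @return `path` / a [detector_geometry()].
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "detector_geometry"))
  write_keyvals(unclass(geom), path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  kv <- read_keyvals(path)
  need <- c("wavelength_nm", "distance_mm", "pixel_mm", "center_x_px",
            "center_y_px")
  miss <- setdiff(need, names(kv))
  if (length(miss)) stop_oq("'%s': missing geometry key(s): %s", path,
                            paste(miss, collapse = ", "))
  do.call(detector_geometry, kv[need])
}

#' Write a results table as CSV with stable column order
#'
#' @param records data.frame.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop_oq("`records` must be a non-empty data.frame")
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a phantom-truth sidecar (scalar fields only)
#'
#' @param truth a [phantom_truth()].
#' @param path output file.
#' @return `path` / a named list.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  scal <- Filter(function(v) is.numeric(v) && length(v) == 1, unclass(truth))
  write_keyvals(scal, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) read_keyvals(path)
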