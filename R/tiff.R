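# Minimal baseline TIFF 6.0 codec: uncompressed, single-sample grayscale,
# little-endian, uint8 / uint16 / float32, one or more pages. This exists
# because no TIFF package ships with the supported R stack; the subset
# covers label volumes (uint8) and intensity maps (float32) and is
# round-trip compatible with common scientific TIFF readers.
#
# In-memory convention: a page is a numeric matrix whose rows are image
# scanlines (row 1 = top); a multi-page file becomes a 3D array with the
# page index third.

TIFF_UINT8 <- "uint8"
TIFF_UINT16 <- "uint16"
TIFF_FLOAT32 <- "float32"

tiff_dtype_info <- function(dtype) {
  switch(dtype,
    uint8   = list(bits = 8L,  fmt = 1L, size = 1L),
    uint16  = list(bits = 16L, fmt = 1L, size = 2L),
    float32 = list(bits = 32L, fmt = 3L, size = 4L),
    stop_oq("unsupported TIFF dtype '%s'", dtype)
  )
}

#' Write a grayscale TIFF (single- or multi-page)
#'
#' @param x numeric matrix (one page) or 3D array (pages along dim 3). Rows
#'   are image scanlines.
#' @param path output file.
#' @param dtype `"uint8"`, `"uint16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path, dtype = c("float32", "uint8", "uint16")) {
  dtype <- match.arg(dtype)
  info <- tiff_dtype_info(dtype)
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop_oq("`x` must be a matrix or 3D array")
  h <- dim(x)[1]; w <- dim(x)[2]; np <- dim(x)[3]
  if (dtype %in% c("uint8", "uint16")) {
    rng <- range(x)
    maxv <- if (dtype == "uint8") 255 else 65535
    if (rng[1] < 0 || rng[2] > maxv)
      stop_oq("values outside [0, %d] cannot be stored as %s", maxv, dtype)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(c(42L), con, size = 2, endian = "little")
  # first IFD offset placeholder; pages laid out as [data][IFD] blocks
  data_bytes <- as.double(w) * h * info$size
  ifd_bytes <- 2 + 10 * 12 + 4
  first_ifd <- 8 + data_bytes
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  offset <- 8
  for (p in seq_len(np)) {
    page <- x[, , p]
    # scanline order: row-major
    v <- as.vector(t(page))
    if (dtype == "float32") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(round(v)), con, size = info$size, endian = "little")
    }
    strip_offset <- offset
    ifd_offset <- offset + data_bytes
    next_ifd <- if (p < np) ifd_offset + ifd_bytes + data_bytes else 0
    ent <- function(tag, type, count, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      if (type == 3L) { # SHORT inlined, left-justified
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(value), con, size = 4, endian = "little")
      }
    }
    writeBin(10L, con, size = 2, endian = "little") # entry count
    ent(256L, 4L, 1L, w)                 # ImageWidth
    ent(257L, 4L, 1L, h)                 # ImageLength
    ent(258L, 3L, 1L, info$bits)         # BitsPerSample
    ent(259L, 3L, 1L, 1L)                # Compression: none
    ent(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
    ent(273L, 4L, 1L, strip_offset)      # StripOffsets (single strip)
    ent(277L, 3L, 1L, 1L)                # SamplesPerPixel
    ent(278L, 4L, 1L, h)                 # RowsPerStrip
    ent(279L, 4L, 1L, data_bytes)        # StripByteCounts
    ent(339L, 3L, 1L, info$fmt)          # SampleFormat
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    offset <- offset + data_bytes + ifd_bytes
  }
  invisible(path)
}

read_tiff_tagvals <- function(raw, pos, type, count, endian) {
  tsize <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)[[as.character(type)]]
  nbytes <- tsize * count
  valfield <- raw[pos:(pos + 3)]
  bytes <- if (nbytes <= 4) {
    valfield[seq_len(nbytes)]
  } else {
    off <- readBin(valfield, "integer", 1, 4, endian = endian)
    raw[(off + 1):(off + nbytes)]
  }
  if (type == 3L) readBin(bytes, "integer", count, 2, signed = FALSE, endian = endian)
  else if (type == 4L) readBin(bytes, "integer", count, 4, endian = endian)
  else readBin(bytes, "integer", count, 1, signed = FALSE, endian = endian)
}

#' Read a grayscale TIFF into a matrix or 3D array
#'
#' Supports the uncompressed single-sample subset written by [write_tiff()]
#' (plus multi-strip layouts). Multi-page files return a 3D array with the
#' page index third.
#'
#' @param path TIFF file.
#' @param pages_as_array return a 3D array even for a single page.
#' @return numeric matrix or 3D array.
#' @export
read_tiff <- function(path, pages_as_array = FALSE) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stop_oq("'%s': not a TIFF (too short)", path)
  byte_order <- rawToChar(raw[1:2])
  endian <- if (byte_order == "II") "little" else if (byte_order == "MM") "big"
    else stop_oq("'%s': not a TIFF (bad byte-order mark)", path)
  magic <- readBin(raw[3:4], "integer", 1, 2, endian = endian)
  if (magic != 42L) stop_oq("'%s': not a TIFF (magic != 42)", path)
  ifd_off <- readBin(raw[5:8], "integer", 1, 4, endian = endian)
  pages <- list()
  while (ifd_off != 0) {
    n_ent <- readBin(raw[(ifd_off + 1):(ifd_off + 2)], "integer", 1, 2,
                     endian = endian)
    tags <- list()
    for (i in seq_len(n_ent)) {
      base <- ifd_off + 2 + (i - 1) * 12
      tag <- readBin(raw[(base + 1):(base + 2)], "integer", 1, 2,
                     signed = FALSE, endian = endian)
      type <- readBin(raw[(base + 3):(base + 4)], "integer", 1, 2,
                      endian = endian)
      count <- readBin(raw[(base + 5):(base + 8)], "integer", 1, 4,
                       endian = endian)
      if (type %in% c(1L, 3L, 4L))
        tags[[as.character(tag)]] <- read_tiff_tagvals(raw, base + 9, type,
                                                       count, endian)
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop_oq("'%s': missing TIFF tag %d", path, tag)
        default
      } else v
    }
    w <- need(256); h <- need(257)
    bits <- need(258, 8L); comp <- need(259, 1L)
    fmt <- need(339, 1L)
    spp <- need(277, 1L)
    if (comp != 1L) stop_oq("'%s': compressed TIFF not supported", path)
    if (spp != 1L) stop_oq("'%s': only single-sample grayscale supported", path)
    offs <- need(273); counts <- need(279)
    bsize <- bits %/% 8
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      nb <- counts[s]
      bytes <- raw[(offs[s] + 1):(offs[s] + nb)]
      vals <- c(vals, if (fmt == 3L && bits == 32L) {
        readBin(bytes, "double", nb %/% 4, 4, endian = endian)
      } else if (fmt %in% c(1L, 2L)) {
        readBin(bytes, "integer", nb %/% bsize, bsize,
                signed = (fmt == 2L || bits == 32L), endian = endian)
      } else stop_oq("'%s': unsupported sample format %d/%d bits",
                     path, fmt, bits))
    }
    if (length(vals) != w * h)
      stop_oq("'%s': strip data does not match %d x %d page", path, w, h)
    pages[[length(pages) + 1]] <- matrix(vals, nrow = h, ncol = w,
                                         byrow = TRUE)
    ifd_off <- readBin(raw[(ifd_off + 2 + n_ent * 12 + 1):
                           (ifd_off + 2 + n_ent * 12 + 4)],
                       "integer", 1, 4, endian = endian)
  }
  if (length(pages) == 0) stop_oq("'%s': no pages", path)
  if (length(pages) == 1 && !pages_as_array) return(pages[[1]])
  dm <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), dm), logical(1))))
    stop_oq("'%s': pages differ in shape", path)
  array(unlist(pages), dim = c(dm, length(pages)))
}
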