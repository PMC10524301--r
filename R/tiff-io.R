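# Minimal multi-page grayscale TIFF codec (uncompressed, little-endian,
# single sample per pixel, one strip per page). No TIFF package ships with
# the analysis stack, and movies only need a lossless grayscale round trip,
# so the baseline subset of the format is implemented here directly.
# Supported on read: uint 8/16/32 and float 32/64, compression "none".

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

write_u <- function(con, x, size) {
  writeBin(as.integer(x), con, size = size, endian = "little")
}

#' Write a stack of frames as a multi-page TIFF
#'
#' @param frames numeric array `time x rows x cols` (or a single matrix).
#' @param path output file path.
#' @param type `"float64"` (lossless for R doubles), `"float32"`, or
#'   `"uint16"` (requires integer-valued data in \[0, 65535\]).
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(frames, path, type = c("float64", "float32", "uint16")) {
  type <- match.arg(type)
  if (is.matrix(frames)) frames <- array(frames, c(1L, dim(frames)))
  stopifnot(length(dim(frames)) == 3L)
  nT <- dim(frames)[1]; H <- dim(frames)[2]; W <- dim(frames)[3]
  bits <- switch(type, float64 = 64L, float32 = 32L, uint16 = 16L)
  fmt <- switch(type, float64 = 3L, float32 = 3L, uint16 = 1L)
  bpp <- bits / 8L
  if (type == "uint16") {
    if (any(frames != round(frames)) || any(frames < 0 | frames > 65535)) {
      stop_param("uint16 TIFF requires integer pixel values in [0, 65535]")
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  write_u(con, 42L, 2L)
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  data_bytes <- H * W * bpp
  # layout: header(8) then per page [pixel data, IFD]
  first_ifd <- 8L + data_bytes
  write_u(con, first_ifd, 4L)
  entry <- function(tag, typ, count, value) {
    write_u(con, tag, 2L); write_u(con, typ, 2L); write_u(con, count, 4L)
    if (typ == 3L && count == 1L) {  # SHORT packed into 4-byte slot
      write_u(con, value, 2L); write_u(con, 0L, 2L)
    } else {
      write_u(con, value, 4L)
    }
  }
  offset <- 8L
  for (p in seq_len(nT)) {
    fr <- t(frames[p, , , drop = TRUE])  # row-major pixel order
    if (type == "uint16") {
      writeBin(as.integer(fr), con, size = 2L, endian = "little")
    } else {
      writeBin(as.double(fr), con, size = bpp, endian = "little")
    }
    ifd_off <- offset + data_bytes
    write_u(con, n_entries, 2L)
    entry(TIFF_TAGS["width"], 3L, 1L, W)
    entry(TIFF_TAGS["height"], 3L, 1L, H)
    entry(TIFF_TAGS["bits"], 3L, 1L, bits)
    entry(TIFF_TAGS["compression"], 3L, 1L, 1L)
    entry(TIFF_TAGS["photometric"], 3L, 1L, 1L)
    entry(TIFF_TAGS["strip_offsets"], 4L, 1L, offset)
    entry(TIFF_TAGS["spp"], 3L, 1L, 1L)
    entry(TIFF_TAGS["rows_per_strip"], 3L, 1L, H)
    entry(TIFF_TAGS["strip_bytes"], 4L, 1L, data_bytes)
    entry(TIFF_TAGS["sample_format"], 3L, 1L, fmt)
    next_ifd <- if (p < nT) ifd_off + ifd_size + data_bytes else 0L
    write_u(con, next_ifd, 4L)
    offset <- ifd_off + ifd_size
  }
  invisible(path)
}

read_u <- function(raw, at, size) {
  v <- 0
  for (i in seq_len(size)) v <- v + as.numeric(raw[at + i - 1L]) * 256^(i - 1L)
  v
}

#' Read a multi-page grayscale TIFF into an array
#'
#' @param path TIFF file path.
#' @return numeric array `time x rows x cols`.
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop_param("TIFF file does not exist: %s", path)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L || rawToChar(raw[1:2]) != "II" || read_u(raw, 3L, 2L) != 42) {
    stop_param("not a little-endian TIFF file: %s", path)
  }
  ifd <- read_u(raw, 5L, 4L)
  pages <- list()
  while (ifd != 0) {
    n <- read_u(raw, ifd + 1L, 2L)
    tags <- list()
    for (e in seq_len(n)) {
      at <- ifd + 2L + (e - 1L) * 12L + 1L
      tag <- read_u(raw, at, 2L)
      typ <- read_u(raw, at + 2L, 2L)
      val <- if (typ == 3L) read_u(raw, at + 8L, 2L) else read_u(raw, at + 8L, 4L)
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[[tag]])]]
      if (is.null(v)) {
        if (is.null(default)) stop_param("TIFF missing required tag %s: %s", tag, path)
        default
      } else v
    }
    if (g("compression", 1) != 1) stop_param("compressed TIFF not supported: %s", path)
    if (g("spp", 1) != 1) stop_param("multi-sample TIFF not supported: %s", path)
    W <- g("width"); H <- g("height")
    bits <- g("bits"); fmt <- g("sample_format", 1)
    off <- g("strip_offsets")
    npix <- H * W
    dat <- if (fmt == 3) {
      readBin(raw[(off + 1L):(off + npix * bits / 8)], "double",
              n = npix, size = bits / 8, endian = "little")
    } else {
      readBin(raw[(off + 1L):(off + npix * bits / 8)], "integer",
              n = npix, size = bits / 8, signed = !(bits %in% c(8, 16)),
              endian = "little")
    }
    pages[[length(pages) + 1L]] <- t(matrix(dat, W, H))  # stored row-major
    ifd <- read_u(raw, ifd + 2L + n * 12L + 1L, 4L)
  }
  dims <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), dims), TRUE))) {
    stop_param("TIFF pages differ in shape: %s", path)
  }
  out <- array(0, c(length(pages), dims))
  for (p in seq_along(pages)) out[p, , ] <- pages[[p]]
  out
}
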