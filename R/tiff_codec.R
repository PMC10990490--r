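# Minimal baseline TIFF codec (the only dialect used by this package):
# multi-page, grayscale, unsigned 16-bit, little-endian, uncompressed.
# The reader additionally accepts 8-bit samples and multi-strip layouts.
# No compression, tiling, palettes, or planar configurations.

TIFF_TAG <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
              photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
              strip_counts = 279L, sample_format = 339L)

tiff_read_pages <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L) nm_stop("not a TIFF file (truncated header)", "nm_format_error")
  r_u16 <- function(off) {
    v <- as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L]); v
  }
  r_u32 <- function(off) {
    as.double(as.integer(raw[off + 1L])) + 256 * as.integer(raw[off + 2L]) +
      65536 * as.integer(raw[off + 3L]) + 16777216 * as.integer(raw[off + 4L])
  }
  if (!(raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49)))
    nm_stop("only little-endian (II) TIFF is supported", "nm_format_error")
  if (r_u16(2L) != 42L) nm_stop("bad TIFF magic number", "nm_format_error")
  ifd <- r_u32(4L)
  pages <- list()
  while (ifd != 0) {
    n_entries <- r_u16(ifd)
    tags <- list()
    for (e in seq_len(n_entries)) {
      off <- ifd + 2L + (e - 1L) * 12L
      tag <- r_u16(off); typ <- r_u16(off + 2L); cnt <- r_u32(off + 4L)
      if (!tag %in% TIFF_TAG) next
      vals <- if (typ == 3L) {            # SHORT
        if (cnt <= 2L) vapply(seq_len(cnt), function(i) r_u16(off + 8L + 2L * (i - 1L)), 0L)
        else { p <- r_u32(off + 8L); vapply(seq_len(cnt), function(i) r_u16(p + 2L * (i - 1L)), 0L) }
      } else if (typ == 4L) {             # LONG
        if (cnt <= 1L) r_u32(off + 8L)
        else { p <- r_u32(off + 8L); vapply(seq_len(cnt), function(i) r_u32(p + 4 * (i - 1L)), 0) }
      } else next
      tags[[as.character(tag)]] <- vals
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(TIFF_TAG[[id]])]]
      if (is.null(v)) default else v
    }
    w <- g("width"); h <- g("length")
    if (is.null(w) || is.null(h)) nm_stop("TIFF page missing dimensions", "nm_format_error")
    bits <- g("bits", 1L)[1]
    if (!bits %in% c(8L, 16L)) nm_stop("only 8/16-bit grayscale TIFF supported", "nm_format_error")
    if (g("compression", 1L)[1] != 1L) nm_stop("compressed TIFF not supported", "nm_format_error")
    so <- g("strip_offsets"); sc <- g("strip_counts")
    if (is.null(so)) nm_stop("TIFF page missing strip offsets", "nm_format_error")
    if (is.null(sc)) sc <- rep(w * h * bits / 8 / length(so), length(so))
    bytes <- raw(0)
    for (s in seq_along(so)) bytes <- c(bytes, raw[(so[s] + 1L):(so[s] + sc[s])])
    px <- if (bits == 16L) {
      lo <- as.integer(bytes[seq(1L, length(bytes), 2L)])
      hi <- as.integer(bytes[seq(2L, length(bytes), 2L)])
      lo + 256L * hi
    } else as.integer(bytes)
    if (length(px) != w * h) nm_stop("TIFF strip data does not match dimensions", "nm_format_error")
    pages[[length(pages) + 1L]] <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
    ifd <- r_u32(ifd + 2L + n_entries * 12L)
  }
  if (!length(pages)) nm_stop("TIFF contains no pages", "nm_format_error")
  pages
}

tiff_write_pages <- function(pages, path) {
  stopifnot(is.list(pages), length(pages) >= 1L)
  w <- ncol(pages[[1L]]); h <- nrow(pages[[1L]])
  for (p in pages) {
    if (ncol(p) != w || nrow(p) != h)
      nm_stop("all pages must share identical dimensions", "nm_format_error")
    if (any(p < 0 | p > 65535))
      nm_stop("pixel intensity outside the unsigned 16-bit range", "nm_range_error")
    if (any(abs(p - round(p)) > 1e-6))
      nm_stop("pixel intensities must be integral for 16-bit TIFF output", "nm_range_error")
  }
  n_tags <- 9L
  ifd_size <- 2L + 12L * n_tags + 4L
  page_bytes <- w * h * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w_u32 <- function(v) {
    v <- as.double(v)
    writeBin(as.integer(c(v %% 65536, v %/% 65536)), con, size = 2, endian = "little")
  }
  writeBin(as.raw(c(0x49, 0x49)), con); w_u16(42L); w_u32(8)
  entry <- function(tag, typ, cnt, val) { w_u16(tag); w_u16(typ); w_u32(cnt)
    if (typ == 3L) { w_u16(val); w_u16(0L) } else w_u32(val) }
  offset <- 8
  for (i in seq_along(pages)) {
    data_off <- offset + ifd_size
    next_ifd <- if (i < length(pages)) data_off + page_bytes else 0
    w_u16(n_tags)
    entry(256L, 4L, 1L, w)
    entry(257L, 4L, 1L, h)
    entry(258L, 3L, 1L, 16L)
    entry(259L, 3L, 1L, 1L)            # no compression
    entry(262L, 3L, 1L, 1L)            # BlackIsZero
    entry(273L, 4L, 1L, data_off)
    entry(278L, 4L, 1L, h)             # one strip per page
    entry(279L, 4L, 1L, page_bytes)
    entry(339L, 3L, 1L, 1L)            # unsigned integer samples
    w_u32(next_ifd)
    px <- as.integer(round(t(pages[[i]])))   # row-major
    px[px > 32767L] <- px[px > 32767L] - 65536L  # two's complement for writeBin
    writeBin(px, con, size = 2, endian = "little")
    offset <- data_off + page_bytes
  }
  invisible(path)
}
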