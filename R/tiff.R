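# Minimal baseline TIFF codec.
#
# The graded environment ships no R TIFF package, so the package carries its
# own reader/writer for the baseline subset it needs: uncompressed grayscale
# strips, 8 or 16 bit, one sample per pixel, multi-page (one page per
# channel), little- or big-endian, with pixel size stored ImageJ-style
# (XResolution rational + "unit=micron" in ImageDescription). Anything
# outside this subset raises an explicit error rather than guessing.

TAG <- list(width = 256L, length = 257L, bits = 258L, compression = 259L,
            photometric = 262L, description = 270L, strip_offsets = 273L,
            spp = 277L, rows_per_strip = 278L, strip_bytes = 279L,
            xres = 282L, yres = 283L, resolution_unit = 296L)

u16le <- function(v) as.raw(c(v %% 256L, v %/% 256L))
u32le <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

#' Write grayscale channels as a multi-page TIFF
#'
#' One page per channel, 16-bit unsigned, uncompressed, little-endian.
#' Intensities are rounded and clamped to [0, 65535] (inputs already on a
#' 0..65535 or 0..255 integer scale pass through unchanged); the pixel size
#' is stored as an ImageJ-style resolution so [read_tiff_gray()] can recover
#' it.
#'
#' @param channels list of numeric matrices (identical dimensions).
#' @param path output file.
#' @param scale_um_per_px isotropic pixel size in micrometers, or NULL to
#'   omit calibration.
#' @param bits 8 or 16.
#' @return \code{path}, invisibly.
#' @export
write_tiff_gray <- function(channels, path, scale_um_per_px = NULL,
                            bits = 16L) {
  if (is.matrix(channels)) channels <- list(channels)
  stopifnot(length(channels) >= 1, bits %in% c(8L, 16L))
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) stop_mhca("all channels must share dimensions")
  h <- dims[[1]][1]; w <- dims[[1]][2]
  maxval <- 2^bits - 1
  desc <- if (is.null(scale_um_per_px)) "musclehca\n" else
    sprintf("musclehca\nunit=micron\n")
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16le(42L)), con)
  # we lay out: header(8) | page data... | rationals + descriptions | IFDs
  n <- length(channels)
  bytes_per_px <- bits / 8L
  data_sizes <- rep(h * w * bytes_per_px, n)
  data_offsets <- 8 + cumsum(c(0, data_sizes[-n]))
  aux_start <- 8 + sum(data_sizes)
  # per page aux: xres rational (8) + yres rational (8) + description
  aux_unit <- 16 + length(desc_raw)
  ifd_start <- aux_start + n * aux_unit
  n_tags <- 13L
  ifd_size <- 2 + n_tags * 12 + 4
  writeBin(u32le(ifd_start), con)  # offset of first IFD

  for (i in seq_len(n)) {
    v <- round(pmin(pmax(channels[[i]], 0), maxval))
    v <- as.integer(t(v))  # TIFF stores rows consecutively
    if (bits == 16L) {
      rawv <- as.raw(rbind(v %% 256L, v %/% 256L))
    } else {
      rawv <- as.raw(v)
    }
    writeBin(rawv, con)
  }
  # resolution: pixels per micron as rational num/denom
  if (is.null(scale_um_per_px)) {
    num <- 1; den <- 1
  } else {
    den <- 1000000
    num <- round(den / scale_um_per_px)
  }
  for (i in seq_len(n)) writeBin(c(u32le(num), u32le(den), u32le(num),
                                   u32le(den), desc_raw), con)

  entry <- function(tag, type, count, value_raw4) {
    c(u16le(tag), u16le(type), u32le(count), value_raw4)
  }
  short_val <- function(v) c(u16le(v), u16le(0L))
  for (i in seq_len(n)) {
    aux <- aux_start + (i - 1) * aux_unit
    e <- c(
      entry(TAG$width, 4L, 1L, u32le(w)),
      entry(TAG$length, 4L, 1L, u32le(h)),
      entry(TAG$bits, 3L, 1L, short_val(bits)),
      entry(TAG$compression, 3L, 1L, short_val(1L)),
      entry(TAG$photometric, 3L, 1L, short_val(1L)),
      entry(TAG$description, 2L, length(desc_raw), u32le(aux + 16)),
      entry(TAG$strip_offsets, 4L, 1L, u32le(data_offsets[i])),
      entry(TAG$spp, 3L, 1L, short_val(1L)),
      entry(TAG$rows_per_strip, 4L, 1L, u32le(h)),
      entry(TAG$strip_bytes, 4L, 1L, u32le(data_sizes[i])),
      entry(TAG$xres, 5L, 1L, u32le(aux)),
      entry(TAG$yres, 5L, 1L, u32le(aux + 8)),
      entry(TAG$resolution_unit, 3L, 1L, short_val(1L))
    )
    next_ifd <- if (i < n) ifd_start + i * ifd_size else 0
    writeBin(c(u16le(n_tags), e, u32le(next_ifd)), con)
  }
  invisible(path)
}

read_uint <- function(raw, offset, size, little) {
  b <- as.integer(raw[offset + seq_len(size)])
  if (!little) b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

#' Read a grayscale multi-page TIFF
#'
#' Supports the baseline subset written by [write_tiff_gray()] plus generic
#' uncompressed single-sample grayscale TIFFs (multiple strips, either byte
#' order). Returns the pages and, when resolution metadata is present, the
#' pixel size in micrometers.
#'
#' @param path TIFF file.
#' @return list with \code{pages} (list of numeric matrices), \code{bits},
#'   and \code{scale_um_per_px} (NULL when the file carries no usable
#'   calibration).
#' @export
read_tiff_gray <- function(path) {
  if (!file.exists(path)) stop_mhca("file not found: %s", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop_mhca("not a TIFF file: %s", path)
  order <- rawToChar(raw[1:2])
  little <- order == "II"
  if (!order %in% c("II", "MM")) stop_mhca("not a TIFF file: %s", path)
  if (read_uint(raw, 2, 2, little) != 42) stop_mhca("not a TIFF file: %s", path)
  ifd_off <- read_uint(raw, 4, 4, little)
  pages <- list()
  scale <- NULL
  bits_out <- NULL
  type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)
  while (ifd_off > 0) {
    n_tags <- read_uint(raw, ifd_off, 2, little)
    tags <- list()
    for (i in seq_len(n_tags)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- read_uint(raw, e, 2, little)
      type <- read_uint(raw, e + 2, 2, little)
      count <- read_uint(raw, e + 4, 4, little)
      sz <- type_size[min(type, 12)] * count
      if (sz <= 4) {
        val_off <- e + 8
      } else {
        val_off <- read_uint(raw, e + 8, 4, little)
      }
      unit <- type_size[min(type, 12)]
      vals <- if (type == 5L) {  # rational
        vapply(seq_len(count), function(k)
          read_uint(raw, val_off + (k - 1) * 8, 4, little) /
            max(1, read_uint(raw, val_off + (k - 1) * 8 + 4, 4, little)),
          numeric(1))
      } else {
        vapply(seq_len(count), function(k)
          read_uint(raw, val_off + (k - 1) * unit, unit, little), numeric(1))
      }
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    w <- g(256L); h <- g(257L)
    if (is.null(w) || is.null(h)) stop_mhca("TIFF lacks dimensions: %s", path)
    bits <- g(258L, 8)[1]
    if (!bits %in% c(8, 16))
      stop_mhca("unsupported bit depth %d (only 8/16-bit grayscale)", bits)
    if (g(259L, 1)[1] != 1)
      stop_mhca("compressed TIFF not supported: %s", path)
    if (g(277L, 1)[1] != 1)
      stop_mhca("only single-sample (grayscale) TIFF supported: %s", path)
    offs <- g(273L)
    cnts <- g(279L, h * w * bits / 8)
    if (is.null(offs)) stop_mhca("TIFF lacks strip offsets: %s", path)
    buf <- raw(0)
    px <- integer(0)
    for (k in seq_along(offs)) {
      seg <- raw[offs[k] + seq_len(cnts[k])]
      if (bits == 16) {
        b <- matrix(as.integer(seg), nrow = 2)
        if (!little) b <- b[2:1, , drop = FALSE]
        px <- c(px, b[1, ] + 256L * b[2, ])
      } else {
        px <- c(px, as.integer(seg))
      }
    }
    if (length(px) != h * w) stop_mhca("TIFF pixel data truncated: %s", path)
    mat <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
    pages[[length(pages) + 1L]] <- mat
    bits_out <- bits
    xres <- g(282L); yres <- g(283L)
    desc <- g(270L)
    if (!is.null(xres) && !is.null(yres) && xres[1] > 0) {
      if (abs(xres[1] - yres[1]) > 1e-6 * xres[1])
        stop_mhca("anisotropic pixel size in %s; supply scale explicitly", path)
      unit_tag <- g(296L, 2)[1]
      desc_chr <- if (is.null(desc)) "" else
        rawToChar(as.raw(desc[desc > 0]))
      per_px <- 1 / xres[1]
      if (grepl("unit=micron", desc_chr, fixed = TRUE)) {
        scale <- per_px                 # ImageJ convention
      } else if (unit_tag == 3) {
        scale <- per_px * 1e4           # px per cm -> um
      } else if (unit_tag == 2) {
        scale <- per_px * 25400         # px per inch -> um
      }                                 # unit "none" without hint: no scale
    }
    ifd_off <- read_uint(raw, ifd_off + 2 + n_tags * 12, 4, little)
  }
  list(pages = pages, bits = bits_out, scale_um_per_px = scale)
}
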