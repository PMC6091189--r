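# Minimal PNG writer (8-bit grayscale or RGB, no interlace). Deflate comes
# from base R's memCompress gzip stream, re-wrapped as the zlib stream PNG
# expects; CRC-32/Adler-32 via the compiled helpers.

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- cpp_crc32(body)
  c(u32be(length(data)), body, u32be(crc))
}

u32be <- function(v) {
  v <- as.numeric(v)
  as.raw(c((v %/% 16777216) %% 256, (v %/% 65536) %% 256,
           (v %/% 256) %% 256, v %% 256))
}

# zlib stream for PNG IDAT. R's memCompress(type = "gzip") emits an RFC
# 1950 zlib stream (0x78 header) on this platform; if a build ever returns
# a true gzip container instead, re-wrap its deflate payload as zlib.
zlib_stream <- function(data) {
  z <- memCompress(data, type = "gzip")
  if (as.integer(z[1]) == 0x78) return(z)
  if (as.integer(z[1]) == 0x1f && as.integer(z[2]) == 0x8b) {
    if (as.integer(z[4]) != 0L)
      stop_mhca("unexpected gzip flags from memCompress")
    defl <- z[11:(length(z) - 8L)]
    return(c(as.raw(c(0x78, 0x01)), defl, u32be(cpp_adler32(data))))
  }
  stop_mhca("unrecognized memCompress output")
}

#' Write an 8-bit PNG
#'
#' @param img numeric array: \code{h x w} (grayscale) or \code{h x w x 3}
#'   (RGB), values 0-255.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_png <- function(img, path) {
  d <- dim(img)
  rgb <- length(d) == 3L
  h <- d[1]; w <- d[2]
  v <- as.integer(round(pmin(pmax(img, 0), 255)))
  if (rgb) {
    a <- array(v, d)
    # scanlines: filter byte 0 + interleaved RGB, row-major
    sl <- array(0L, c(3L, w, h))
    for (k in 1:3) sl[k, , ] <- t(a[, , k])
    stream <- raw(h * (1L + 3L * w))
    rowlen <- 1L + 3L * w
    for (r in seq_len(h))
      stream[(r - 1L) * rowlen + 1L + seq_len(3L * w)] <-
        as.raw(sl[, , r])
    colortype <- 2L
  } else {
    m <- matrix(v, h, w)
    rowlen <- 1L + w
    stream <- raw(h * rowlen)
    tm <- t(m)
    for (r in seq_len(h))
      stream[(r - 1L) * rowlen + 1L + seq_len(w)] <- as.raw(tm[, r])
    colortype <- 0L
  }
  zlib <- zlib_stream(stream)
  ihdr <- c(u32be(w), u32be(h), as.raw(c(8L, colortype, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
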