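`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mhca <- function(...) stop(sprintf(...), call. = FALSE)

assert_matrix2d <- function(x, what = "input") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_mhca("%s must be a 2-D numeric matrix", what)
  invisible(x)
}

#' Otsu's automatic threshold
#'
#' Maximizes between-class variance on a fixed-bin histogram. Returns the
#' intensity value separating the two classes; pixels strictly above the
#' returned value belong to the bright class.
#'
#' @param x numeric vector or matrix of intensities.
#' @param nbins number of histogram bins.
#' @return threshold on the intensity scale of \code{x}.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop_mhca("otsu_threshold: no finite values")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(nbins, floor((x - lo) / (hi - lo) * nbins) + 1L), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  lo + k / nbins * (hi - lo)
}

# Histogram mode of a vector: center of the fullest fixed-width bin.
mode_estimate <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop_mhca("mode_estimate: no finite values")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  b <- pmin(nbins, floor((x - lo) / (hi - lo) * nbins) + 1L)
  k <- which.max(tabulate(b, nbins))
  lo + (k - 0.5) / nbins * (hi - lo)
}

# Binary morphology with a Euclidean disc via the exact distance transform.
binary_erode <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  cpp_edt(mask) > radius_px
}

binary_dilate <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  mask | (cpp_edt(!mask) <= radius_px)
}

binary_close <- function(mask, radius_px) {
  if (radius_px <= 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  pad <- radius_px + 2L
  big <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  big[pad + seq_len(h), pad + seq_len(w)] <- mask
  big <- binary_erode(binary_dilate(big, radius_px), radius_px)
  big[pad + seq_len(h), pad + seq_len(w)]
}

fill_holes <- function(mask) {
  bg <- cpp_label_components(!mask, 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  # holes = background components not touching the image border
  hole <- bg > 0 & !matrix(bg %in% border, nrow(bg), ncol(bg))
  mask | hole
}

# Centroids (row, col, 1-based) of each label in an integer label matrix.
label_centroids <- function(labels, n = max(labels)) {
  if (n < 1) return(matrix(numeric(0), 0, 2))
  out <- matrix(NA_real_, n, 2)
  idx <- which(labels > 0)
  if (!length(idx)) return(out)
  l <- labels[idx]
  r <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  cnt <- tabulate(l, n)
  sr <- rowsum(as.numeric(r), l)
  sc <- rowsum(as.numeric(cc), l)
  ids <- as.integer(rownames(sr))
  out[ids, 1] <- sr[, 1] / cnt[ids]
  out[ids, 2] <- sc[, 1] / cnt[ids]
  out
}

# Crop a logical/integer matrix to the bounding box of TRUE/positive pixels,
# with padding; returns list(crop, r0, c0) where (r0, c0) is the offset such
# that crop[i, j] corresponds to full[(r0 + i - 1), (c0 + j - 1)].
crop_to_bbox <- function(mask, pad = 0L) {
  idx <- which(mask)
  if (!length(idx)) stop_mhca("crop_to_bbox: empty mask")
  h <- nrow(mask)
  r <- (idx - 1L) %% h + 1L
  c <- (idx - 1L) %/% h + 1L
  r0 <- max(1L, min(r) - pad); r1 <- min(h, max(r) + pad)
  c0 <- max(1L, min(c) - pad); c1 <- min(ncol(mask), max(c) + pad)
  list(crop = mask[r0:r1, c0:c1, drop = FALSE], r0 = r0, c0 = c0)
}
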