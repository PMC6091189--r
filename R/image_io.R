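VALID_ROLES <- c("laminin", "dapi", "pax7", "cd31", "stain1", "stain2",
                 "stain3")

#' Calibrated multichannel section
#'
#' Container for one muscle cross-section: per-role intensity matrices, the
#' isotropic pixel size, and the source identifier. The laminin role is
#' mandatory (it drives fiber segmentation); at most four roles may be
#' mapped, mirroring the four-channel acquisition limit.
#'
#' @param channels named list of numeric matrices; names are roles from
#'   \code{laminin, dapi, pax7, cd31, stain1, stain2, stain3}.
#' @param scale_um_per_px positive isotropic pixel size, um/px.
#' @param source identifier of the origin file (informational).
#' @return object of class \code{calibrated_section}.
#' @export
calibrated_section <- function(channels, scale_um_per_px, source = "memory") {
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop_mhca("channels must be a named list (role = matrix)")
  bad <- setdiff(names(channels), VALID_ROLES)
  if (length(bad))
    stop_mhca("unknown channel role(s): %s", paste(bad, collapse = ", "))
  if (!"laminin" %in% names(channels))
    stop_mhca("a laminin channel is required")
  if (length(channels) > 4L)
    stop_mhca("at most 4 channel roles can be mapped (got %d)",
              length(channels))
  for (nm in names(channels)) assert_matrix2d(channels[[nm]], nm)
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1)
    stop_mhca("all channels must share identical height x width")
  if (!is.numeric(scale_um_per_px) || length(scale_um_per_px) != 1 ||
      !is.finite(scale_um_per_px) || scale_um_per_px <= 0)
    stop_mhca("scale_um_per_px must be a single positive number")
  structure(list(channels = channels,
                 scale_um_per_px = as.numeric(scale_um_per_px),
                 source = source),
            class = "calibrated_section")
}

#' @export
print.calibrated_section <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("calibrated_section: %d x %d px, %.4g um/px, roles: %s\n",
              d[1], d[2], x$scale_um_per_px,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Read a section from TIFF
#'
#' Reads a single multi-page TIFF (pages = channels) or a series of
#' per-channel TIFF files, binds the requested channels to their biological
#' roles and attaches the physical calibration. The pixel size comes either
#' from \code{scale_um_per_px} or, when that is \code{"from metadata"}, from
#' the file's resolution tags; a file without usable calibration is an
#' error, never a silent default. Intensities are passed through unchanged
#' (bit depth preserved).
#'
#' @param path one TIFF path (multichannel) or a character vector of
#'   per-channel TIFF paths.
#' @param channel_map named list/vector, role -> channel index (1-based page
#'   index for a multichannel file, file index for a series).
#' @param scale_um_per_px number, or \code{"from metadata"}.
#' @return [calibrated_section()].
#' @export
read_section <- function(path, channel_map,
                         scale_um_per_px = "from metadata") {
  channel_map <- as.list(channel_map)
  for (p in path) if (!file.exists(p)) stop_mhca("file not found: %s", p)
  if (length(path) == 1L) {
    tf <- read_tiff_gray(path)
    pages <- tf$pages
    meta_scale <- tf$scale_um_per_px
  } else {
    tfs <- lapply(path, read_tiff_gray)
    pages <- lapply(tfs, function(t) {
      if (length(t$pages) != 1L)
        stop_mhca("per-channel series must contain single-page TIFFs")
      t$pages[[1]]
    })
    scales <- unique(unlist(lapply(tfs, `[[`, "scale_um_per_px")))
    meta_scale <- if (length(scales) == 1L) scales else NULL
  }
  n <- length(pages)
  idx <- vapply(channel_map, function(i) as.integer(i), integer(1))
  if (any(idx < 1L | idx > n))
    stop_mhca("channel index out of range: file has %d channel(s), map asks for %s",
              n, paste(idx[idx < 1L | idx > n], collapse = ", "))
  scale <- if (identical(scale_um_per_px, "from metadata")) {
    if (is.null(meta_scale))
      stop_mhca("no pixel-size metadata in %s; pass scale_um_per_px explicitly",
                paste(path, collapse = ", "))
    meta_scale
  } else scale_um_per_px
  channels <- setNames(lapply(idx, function(i) pages[[i]]), names(channel_map))
  calibrated_section(channels, scale, source = paste(path, collapse = ";"))
}

#' Maximum-intensity projection of a z-stack
#'
#' Per-pixel, per-channel maximum over a list of sections acquired at
#' different focal planes. All slices must share geometry, roles and scale.
#'
#' @param stack list of [calibrated_section()] z-slices.
#' @return a single projected [calibrated_section()].
#' @export
max_project <- function(stack) {
  if (!length(stack)) stop_mhca("max_project: empty stack")
  roles <- names(stack[[1]]$channels)
  d <- dim(stack[[1]]$channels[[1]])
  for (s in stack) {
    if (!identical(sort(names(s$channels)), sort(roles)) ||
        !identical(dim(s$channels[[1]]), d))
      stop_mhca("max_project: slices differ in geometry or roles")
  }
  channels <- setNames(lapply(roles, function(r) {
    Reduce(pmax, lapply(stack, function(s) s$channels[[r]]))
  }), roles)
  calibrated_section(channels, stack[[1]]$scale_um_per_px,
                     source = stack[[1]]$source)
}
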