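# Shared blob pipeline for nuclei (DAPI), satellite-cell (Pax7) and vessel
# (CD31) channels: background subtraction, automatic threshold,
# distance-transform watershed to split touching blobs, area filter.

default_area_bounds <- list(dapi = c(10, 200), pax7 = c(8, 120),
                            cd31 = c(5, 400))

detect_blobs <- function(channel, scale_um_per_px, role,
                         min_area_um2 = NULL, max_area_um2 = NULL,
                         bg_radius_px = 25L, threshold = NULL) {
  assert_matrix2d(channel, role)
  bounds <- default_area_bounds[[role]] %||% c(5, 500)
  min_area <- min_area_um2 %||% bounds[1]
  max_area <- max_area_um2 %||% bounds[2]
  empty <- list(objects = data.frame(object_id = integer(0),
                                     role = character(0),
                                     area_um2 = numeric(0),
                                     gc_x_um = numeric(0),
                                     gc_y_um = numeric(0),
                                     mean_intensity = numeric(0),
                                     stringsAsFactors = FALSE),
                labels = matrix(0L, nrow(channel), ncol(channel)))
  bg <- cpp_max_filter(cpp_min_filter(channel, as.integer(bg_radius_px)),
                       as.integer(bg_radius_px))
  sub <- pmax(channel - bg, 0)
  if (max(sub) <= 0) return(empty)
  thr <- threshold %||% otsu_threshold(sub)
  mask <- sub > thr
  if (!any(mask)) return(empty)
  sep_px <- max(2L, round(sqrt(min_area) / scale_um_per_px))
  labels <- split_touching(mask, sep_px)
  n <- max(labels)
  if (n == 0L) return(empty)
  area_px <- tabulate(labels[labels > 0L], n)
  keep <- which(area_px * scale_um_per_px^2 >= min_area &
                area_px * scale_um_per_px^2 <= max_area)
  if (!length(keep)) return(empty)
  labels[matrix(!(labels %in% keep) & labels > 0L, nrow(labels),
                ncol(labels))] <- 0L
  labels <- relabel_consecutive(labels)
  n <- max(labels)
  cent <- label_centroids(labels, n)
  area_px <- tabulate(labels[labels > 0L], n)
  mean_int <- as.numeric(rowsum(channel[labels > 0L],
                                labels[labels > 0L])[, 1]) / area_px
  objects <- data.frame(object_id = seq_len(n),
                        role = role,
                        area_um2 = area_px * scale_um_per_px^2,
                        gc_x_um = (cent[, 2] - 1) * scale_um_per_px,
                        gc_y_um = (cent[, 1] - 1) * scale_um_per_px,
                        mean_intensity = mean_int,
                        stringsAsFactors = FALSE)
  list(objects = objects, labels = labels)
}

#' Detect nuclei in the DAPI channel
#'
#' Background subtraction, automatic (Otsu) threshold, and a
#' distance-transform watershed that splits touching nuclei; blobs outside
#' the plausible nucleus area range are discarded.
#'
#' @param dapi DAPI intensity matrix.
#' @param scale_um_per_px pixel size, um/px.
#' @param min_area_um2,max_area_um2 nucleus area bounds (defaults 10-200).
#' @param bg_radius_px background-opening window radius.
#' @return list: \code{objects} (data.frame \code{object_id, role,
#'   area_um2, gc_x_um, gc_y_um, mean_intensity}) and \code{labels}
#'   (integer matrix of blob ids). An empty channel yields zero objects.
#' @export
detect_nuclei <- function(dapi, scale_um_per_px, min_area_um2 = 10,
                          max_area_um2 = 200, bg_radius_px = 25L) {
  detect_blobs(dapi, scale_um_per_px, "dapi", min_area_um2, max_area_um2,
               bg_radius_px)
}

#' Detect Pax7 or CD31 marker blobs
#'
#' Same pipeline as [detect_nuclei()] with role-specific area bounds
#' (Pax7 8-120 um^2, CD31 5-400 um^2).
#'
#' @param channel intensity matrix.
#' @param scale_um_per_px pixel size, um/px.
#' @param role \code{"pax7"} or \code{"cd31"}.
#' @param min_area_um2,max_area_um2 optional overrides.
#' @param bg_radius_px background-opening window radius.
#' @return same shape as [detect_nuclei()].
#' @export
detect_marker_objects <- function(channel, scale_um_per_px,
                                  role = c("pax7", "cd31"),
                                  min_area_um2 = NULL, max_area_um2 = NULL,
                                  bg_radius_px = 25L) {
  role <- match.arg(role)
  detect_blobs(channel, scale_um_per_px, role, min_area_um2, max_area_um2,
               bg_radius_px)
}
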