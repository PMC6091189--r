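# Satellite-cell calling (Pax7/DAPI overlap rule) and vessel metrics.

#' Call Pax7-positive satellite cells
#'
#' A Pax7 blob is accepted as a satellite cell iff at least
#' \code{overlap_min} of its area is covered by the nuclei mask (Pax7/DAPI
#' double positivity) and its centroid lies in some fiber's sub-laminal
#' annulus (between fiber and basal lamina). The owning fiber is the one
#' whose annulus contains the centroid.
#'
#' @param pax7 [detect_marker_objects()] output for the Pax7 channel.
#' @param nuclei_mask logical matrix of detected nuclei (e.g.
#'   \code{detect_nuclei(...)$labels > 0}).
#' @param rois [build_all_rois()] output.
#' @param map [segment_fibers()] output.
#' @param overlap_min minimum covered fraction (default 0.90).
#' @return data.frame, one row per Pax7 blob: \code{object_id,
#'   overlap_fraction, fiber_id} (NA when sub-laminal position fails),
#'   \code{accepted}, plus centroid and area columns carried over.
#' @export
call_satellites <- function(pax7, nuclei_mask, rois, map,
                            overlap_min = 0.90) {
  obj <- pax7$objects
  scale <- map$scale_um_per_px
  n <- nrow(obj)
  out <- cbind(obj,
               data.frame(overlap_fraction = numeric(n) * NA,
                          fiber_id = rep(NA_integer_, n),
                          accepted = logical(n)))
  if (!n) return(out)
  lab <- pax7$labels
  inter <- tabulate(lab[lab > 0L & nuclei_mask], n)
  size <- tabulate(lab[lab > 0L], n)
  out$overlap_fraction <- inter / size
  r <- pmin(pmax(round(obj$gc_y_um / scale) + 1L, 1L), nrow(map$labels))
  c <- pmin(pmax(round(obj$gc_x_um / scale) + 1L, 1L), ncol(map$labels))
  owner <- rois$sc_map[cbind(r, c)]
  out$fiber_id <- ifelse(owner > 0L, owner, NA_integer_)
  out$accepted <- out$overlap_fraction >= overlap_min & owner > 0L
  out
}

#' Vessel metrics from CD31 blobs
#'
#' Three readouts: per-fiber counts (a CD31 object counts for a fiber when
#' its centroid lies in that fiber's peri-fiber band; bands of adjacent
#' fibers overlap, so one object may count for several fibers), the density
#' of unique CD31 objects per square millimeter of tissue, and the
#' percentage of the section area occupied by the CD31 mask.
#'
#' @param cd31 [detect_marker_objects()] output for the CD31 channel.
#' @param rois [build_all_rois()] output.
#' @param map [segment_fibers()] output.
#' @return list of class \code{vessel_metrics}: \code{per_fiber_counts}
#'   (data.frame \code{fiber_id, n_vessels}), \code{density_per_mm2},
#'   \code{pct_area}.
#' @export
quantify_vessels <- function(cd31, rois, map) {
  scale <- map$scale_um_per_px
  sect_px <- sum(map$section_mask)
  if (sect_px == 0) stop_mhca("quantify_vessels: zero section area")
  area_mm2 <- sect_px * (scale / 1000)^2
  obj <- cd31$objects
  counts <- integer(map$n_fibers)
  if (nrow(obj)) {
    r <- round(obj$gc_y_um / scale) + 1L
    c <- round(obj$gc_x_um / scale) + 1L
    for (k in seq_len(map$n_fibers)) {
      rs <- rois$rois[[k]]
      counts[k] <- sum(vapply(seq_len(nrow(obj)), function(i)
        point_in_roi(rs, "v", r[i], c[i]), logical(1)))
    }
  }
  pct_area <- 100 * sum(cd31$labels > 0L & map$section_mask) / sect_px
  structure(list(per_fiber_counts = data.frame(fiber_id = seq_len(map$n_fibers),
                                               n_vessels = counts),
                 density_per_mm2 = nrow(obj) / area_mm2,
                 pct_area = pct_area),
            class = "vessel_metrics")
}

#' Minimum satellite-to-vessel distances
#'
#' Euclidean centroid-to-centroid minimum distance from each accepted
#' satellite cell to any vessel, in micrometers.
#'
#' @param satellites [call_satellites()] output (accepted rows are used).
#' @param vessels CD31 objects data.frame with \code{gc_x_um, gc_y_um}.
#' @return data.frame \code{object_id, min_dist_um} (NA when no vessels).
#' @export
satellite_vessel_distances <- function(satellites, vessels) {
  sat <- satellites[satellites$accepted, , drop = FALSE]
  if (!nrow(sat))
    return(data.frame(object_id = integer(0), min_dist_um = numeric(0)))
  if (is.list(vessels) && !is.data.frame(vessels)) vessels <- vessels$objects
  if (is.null(vessels) || !nrow(vessels))
    return(data.frame(object_id = sat$object_id, min_dist_um = NA_real_))
  d <- vapply(seq_len(nrow(sat)), function(i) {
    min(sqrt((vessels$gc_x_um - sat$gc_x_um[i])^2 +
             (vessels$gc_y_um - sat$gc_y_um[i])^2))
  }, numeric(1))
  data.frame(object_id = sat$object_id, min_dist_um = d)
}
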