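# Centronucleation: locate each detected nucleus in the per-fiber central
# zone (cnf) or sub-laminal annulus (sc) by centroid containment.

#' Classify fibers by centronucleation
#'
#' A nucleus belongs to a region iff its centroid pixel lies in that
#' region's mask; since the central zone and the annulus partition each
#' fiber, every nucleus is assigned to at most one fiber and one region.
#' Nuclei whose centroid falls on wall pixels (outside every fiber) are
#' interstitial and only counted globally.
#'
#' @param nuclei [detect_nuclei()] output.
#' @param rois [build_all_rois()] output.
#' @param map [segment_fibers()] output (for the fiber count and scale).
#' @return data.frame, one row per fiber: \code{fiber_id, n_centronuclei,
#'   n_peripheral, is_cnf}; number of interstitial nuclei in
#'   \code{attr(, "n_interstitial")}.
#' @export
classify_cnf <- function(nuclei, rois, map) {
  n <- map$n_fibers
  scale <- map$scale_um_per_px
  out <- data.frame(fiber_id = seq_len(n),
                    n_centronuclei = 0L,
                    n_peripheral = 0L,
                    is_cnf = logical(n))
  interstitial <- 0L
  obj <- nuclei$objects
  if (nrow(obj)) {
    r <- pmin(pmax(round(obj$gc_y_um / scale) + 1L, 1L), nrow(map$labels))
    c <- pmin(pmax(round(obj$gc_x_um / scale) + 1L, 1L), ncol(map$labels))
    idx <- cbind(r, c)
    in_cnf <- rois$cnf_map[idx]
    in_sc <- rois$sc_map[idx]
    for (i in seq_len(nrow(obj))) {
      if (in_cnf[i] > 0L) {
        out$n_centronuclei[in_cnf[i]] <- out$n_centronuclei[in_cnf[i]] + 1L
      } else if (in_sc[i] > 0L) {
        out$n_peripheral[in_sc[i]] <- out$n_peripheral[in_sc[i]] + 1L
      } else {
        interstitial <- interstitial + 1L
      }
    }
  }
  out$is_cnf <- out$n_centronuclei >= 1L
  attr(out, "n_interstitial") <- interstitial
  out
}

#' Four-bin centronuclei distribution
#'
#' Percentage of fibers with 0, 1, 2, and 3-or-more centronuclei.
#'
#' @param results [classify_cnf()] output.
#' @return named numeric vector \code{c("0", "1", "2", "3+")} summing
#'   to 100.
#' @export
cnf_distribution <- function(results) {
  if (!nrow(results)) stop_mhca("cnf_distribution: empty fiber set")
  bins <- pmin(results$n_centronuclei, 3L)
  pct <- 100 * tabulate(bins + 1L, 4L) / nrow(results)
  stats::setNames(pct, c("0", "1", "2", "3+"))
}
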