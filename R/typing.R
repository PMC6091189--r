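# Intrafiber staining quantification: robust per-channel thresholds from
# the non-fiber tissue background, per-fiber positivity and type labels.

#' Signal-to-noise threshold for one intrafiber channel
#'
#' Background is the modal intensity of the non-fiber tissue pixels (walls
#' and interstitium inside the section mask); spread is the scaled median
#' absolute deviation of those pixels; the threshold is
#' \code{mode + snr_factor * sigma}. The mode/MAD pair stays valid whatever
#' fraction of fibers is positive, which is why it is preferred over Otsu
#' here.
#'
#' @param channel intensity matrix.
#' @param map [segment_fibers()] output (provides section mask and labels).
#' @param snr_factor multiplier on sigma (default 3).
#' @return list of class \code{typing_threshold}: \code{threshold},
#'   \code{background_mode}, \code{sigma}, \code{snr_factor}.
#' @export
compute_threshold <- function(channel, map, snr_factor = 3) {
  assert_matrix2d(channel, "typing channel")
  bgpx <- channel[map$section_mask & map$labels == 0L]
  if (!length(bgpx)) stop_mhca("compute_threshold: empty background region")
  mode <- mode_estimate(bgpx)
  sigma <- stats::mad(bgpx, constant = 1.4826)
  structure(list(threshold = mode + snr_factor * sigma,
                 background_mode = mode, sigma = sigma,
                 snr_factor = snr_factor),
            class = "typing_threshold")
}

TYPE_NAME_DEFAULT <- c(stain1 = "I", stain2 = "IIA", stain3 = "IIB")

# label from the set of positive type names, ordered I < IIA < IIB
type_label <- function(pos_types) {
  ord <- c("I", "IIA", "IIB")
  pos <- ord[ord %in% pos_types]
  if (length(pos) == 0L) "IIX"
  else if (length(pos) == 1L) pos
  else if (length(pos) == 2L) paste(pos, collapse = "-")
  else "ND"
}

#' Assign a fiber type to every fiber
#'
#' A fiber is positive for a channel iff its mean intensity over the fiber
#' mask exceeds that channel's threshold. Zero positives is the deduced
#' type IIX (unlabeled); one is the matching pure type; two is a hybrid
#' (I-IIA, I-IIB, IIA-IIB); three is not determined (ND).
#'
#' @param channels named list of up to three intensity matrices
#'   (\code{stain1}, \code{stain2}, \code{stain3}).
#' @param thresholds named list of [compute_threshold()] results (or bare
#'   numbers), same names.
#' @param map [segment_fibers()] output.
#' @param type_names channel-to-type mapping (default stain1 = I,
#'   stain2 = IIA, stain3 = IIB).
#' @param statistic \code{"mean"} (default) or \code{"median"} positivity
#'   statistic over the fiber mask.
#' @return data.frame, one row per fiber: per-channel mean intensities
#'   (\code{mean_<stain>}), positivity flags (\code{pos_<stain>}) and
#'   \code{label}.
#' @export
call_types <- function(channels, thresholds, map,
                       type_names = TYPE_NAME_DEFAULT,
                       statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (!length(channels)) stop_mhca("call_types: at least one typing channel")
  stopifnot(!is.null(names(channels)))
  n <- map$n_fibers
  lab <- map$labels
  idx <- which(lab > 0L)
  l <- lab[idx]
  out <- data.frame(fiber_id = seq_len(n))
  pos <- matrix(FALSE, n, length(channels),
                dimnames = list(NULL, names(channels)))
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    thr <- thresholds[[nm]]
    if (is.list(thr)) thr <- thr$threshold
    if (statistic == "mean") {
      stat <- as.numeric(rowsum(ch[idx], l)[, 1]) / tabulate(l, n)
    } else {
      stat <- vapply(split(ch[idx], l), stats::median, numeric(1))
    }
    out[[paste0("mean_", nm)]] <- stat
    pos[, nm] <- stat > thr
  }
  out$label <- vapply(seq_len(n), function(i)
    type_label(type_names[names(channels)[pos[i, ]]]), character(1))
  for (nm in names(channels)) out[[paste0("pos_", nm)]] <- pos[, nm]
  out
}

TYPE_LEVELS <- c("I", "IIA", "IIB", "IIX", "I-IIA", "I-IIB", "IIA-IIB", "ND")

#' Fiber-type distribution
#'
#' @param calls [call_types()] output.
#' @return named percentages over all typed fibers (levels I, IIA, IIB,
#'   IIX, the three hybrids, ND), summing to 100.
#' @export
type_distribution <- function(calls) {
  if (!nrow(calls)) stop_mhca("type_distribution: empty fiber set")
  tab <- table(factor(calls$label, levels = TYPE_LEVELS))
  stats::setNames(100 * as.numeric(tab) / nrow(calls), TYPE_LEVELS)
}
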