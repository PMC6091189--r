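# Fiber segmentation from the pretreated laminin channel, plus the two
# section-level quality controls.

#' Pretreat the laminin channel
#'
#' Background reduction followed by local contrast enhancement, the standard
#' preparation before thresholding a basal-lamina stain. Background is a
#' grayscale morphological opening (running min then max over a square
#' window, a rolling-ball-style estimator exact under constant offsets);
#' contrast is tile-based contrast-limited adaptive equalization. Output is
#' normalized to [0, 1].
#'
#' @param laminin 2-D numeric matrix.
#' @param rolling_ball_radius_px background window radius, px.
#' @param clahe_clip clip limit (>= 1; larger = stronger equalization).
#' @param clahe_tiles tiles per image side.
#' @param clahe_bins histogram bins.
#' @return matrix in [0, 1], same dimensions.
#' @export
pretreat <- function(laminin, rolling_ball_radius_px = 50L, clahe_clip = 2,
                     clahe_tiles = 8L, clahe_bins = 256L) {
  assert_matrix2d(laminin, "laminin")
  bg <- cpp_max_filter(cpp_min_filter(laminin, as.integer(rolling_ball_radius_px)),
                       as.integer(rolling_ball_radius_px))
  sub <- pmax(laminin - bg, 0)
  cpp_clahe(sub, as.integer(clahe_tiles), as.integer(clahe_bins), clahe_clip)
}

# Split touching objects in a binary mask: seeds are local maxima of the
# (lightly smoothed) distance transform with minimum separation sep_px;
# seed pairs whose connecting line never drops below saddle_ratio times the
# smaller peak are merged (no real neck between them). Components with a
# single surviving seed are kept whole, so clean objects are never cut.
# Returns an integer label matrix.
split_touching <- function(mask, sep_px, saddle_ratio = 0.65,
                           smooth_sigma = 1) {
  comp <- cpp_label_components(mask, 4L)
  n_comp <- max(comp)
  if (n_comp == 0L) return(comp)
  edt <- cpp_edt(mask)
  sm <- if (smooth_sigma > 0) cpp_gaussian_blur(edt, smooth_sigma) else edt
  sm[!mask] <- 0
  mx <- cpp_max_filter(sm, as.integer(max(1L, sep_px)))
  peaks <- mask & sm >= mx - 1e-9 & edt > 1
  seed_lab <- cpp_label_components(peaks, 8L)
  n_seed <- max(seed_lab)
  if (n_seed == 0L) return(comp)
  seed_cent <- label_centroids(seed_lab, n_seed)
  sidx <- which(seed_lab > 0L)
  sl <- seed_lab[sidx]
  seed_peak <- numeric(n_seed)
  mx_by_seed <- vapply(split(edt[sidx], sl), max, numeric(1))
  seed_peak[as.integer(names(mx_by_seed))] <- mx_by_seed
  seed_comp <- integer(n_seed)
  seed_comp[sl] <- comp[sidx]

  # union-find over seeds of the same component
  parent <- seq_len(n_seed)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  sample_line_min <- function(p, q) {
    n <- max(2L, ceiling(2 * sqrt(sum((p - q)^2))))
    rr <- pmin(pmax(round(seq(p[1], q[1], length.out = n)), 1L), nrow(mask))
    cc <- pmin(pmax(round(seq(p[2], q[2], length.out = n)), 1L), ncol(mask))
    min(edt[cbind(rr, cc)])
  }
  for (cmp in unique(seed_comp)) {
    ids <- which(seed_comp == cmp)
    if (length(ids) < 2) next
    for (a in seq_along(ids)) for (b in seq_len(a - 1L)) {
      i <- ids[a]; j <- ids[b]
      saddle <- sample_line_min(seed_cent[i, ], seed_cent[j, ])
      if (saddle > saddle_ratio * min(seed_peak[i], seed_peak[j])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  group <- vapply(seq_len(n_seed), find, integer(1))
  groups <- sort(unique(group))
  gid <- match(group, groups)

  # components with a single group keep their component label; components
  # with several groups are flooded by watershed on -distance
  group_comp <- vapply(groups, function(g)
    seed_comp[which(group == g)[1]], integer(1))
  comp_ngroups <- tabulate(group_comp, n_comp)
  multi <- which(comp_ngroups > 1L)
  out <- comp
  if (length(multi)) {
    markers <- matrix(0L, nrow(mask), ncol(mask))
    markers[seed_lab > 0] <- gid[seed_lab[seed_lab > 0]]
    in_multi <- matrix(comp %in% multi, nrow(mask), ncol(mask)) & mask
    ws <- cpp_watershed(-edt, markers, in_multi)
    # offset watershed labels past existing component labels; pixels the
    # flood could not reach (none in practice) fall back to non-fiber
    out[in_multi] <- ifelse(ws[in_multi] > 0L, ws[in_multi] + n_comp, 0L)
  }
  # compact to consecutive labels (deterministic scan order)
  relabel_consecutive(out)
}

relabel_consecutive <- function(labels) {
  u <- sort(unique(labels[labels > 0L]))
  if (!length(u)) return(labels)
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  out <- labels
  out[out > 0L] <- lut[out[out > 0L]]
  out
}

#' Segment all muscle fibers
#'
#' Thresholds the pretreated laminin (walls) with Otsu's method, takes the
#' connected components of the complement inside the tissue mask as fiber
#' interiors, splits merged interiors by marker-based watershed on the
#' distance transform, and discards components below the minimum fiber area
#' or touching the image border.
#'
#' @param pretreated output of [pretreat()].
#' @param scale_um_per_px pixel size, um/px.
#' @param min_fiber_area_um2 smallest object kept as a fiber (um^2).
#' @param wall_threshold override for the automatic wall threshold.
#' @param close_radius_px morphological closing radius used to build the
#'   section (tissue) mask.
#' @return object of class \code{fiber_label_map}: \code{labels} (integer
#'   matrix, 0 = non-fiber), \code{n_fibers}, \code{section_mask},
#'   \code{excluded} (QC removals), \code{scale_um_per_px}.
#' @export
segment_fibers <- function(pretreated, scale_um_per_px,
                           min_fiber_area_um2 = 50,
                           wall_threshold = NULL,
                           close_radius_px = NULL) {
  assert_matrix2d(pretreated, "pretreated laminin")
  if (max(pretreated) <= min(pretreated))
    stop_mhca("no tissue: laminin channel is constant")
  thr <- wall_threshold %||% otsu_threshold(pretreated)
  wall <- pretreated > thr
  if (sum(wall) < 0.001 * length(wall))
    stop_mhca("no tissue: nothing above the wall threshold")
  close_r <- as.integer(close_radius_px %||% max(2L, round(1.5 / scale_um_per_px)))
  section_mask <- fill_holes(binary_close(wall, close_r))
  interiors <- section_mask & !wall
  sep_px <- max(3L, round(sqrt(min_fiber_area_um2) / scale_um_per_px))
  labels <- split_touching(interiors, sep_px)

  # Half-maximum boundary refinement: a global histogram threshold lands on
  # the shoulder of the blurred wall profile, so the raw wall mask is wider
  # than the wall's half-maximum and fiber areas come out biased low. Wall
  # pixels below the midpoint between the interior and wall levels are
  # reassigned to their adjacent fiber by ascending-intensity flooding; the
  # wall ridge itself stays above the midpoint and keeps fibers separated.
  if (any(interiors)) {
    wall_level <- stats::median(pretreated[wall])
    int_level <- stats::median(pretreated[interiors])
    half_level <- (wall_level + int_level) / 2
    skirt <- wall & pretreated < half_level
    if (any(skirt)) {
      flood <- cpp_watershed(pretreated, labels, (labels > 0L) | skirt)
      labels[skirt] <- flood[skirt]
    }
  }

  # area filter + border filter
  n <- max(labels)
  if (n > 0L) {
    area_px <- tabulate(labels[labels > 0L], n)
    min_px <- min_fiber_area_um2 / scale_um_per_px^2
    border_ids <- unique(c(labels[1, ], labels[nrow(labels), ],
                           labels[, 1], labels[, ncol(labels)]))
    drop <- which(area_px < min_px)
    drop <- union(drop, border_ids[border_ids > 0L])
    if (length(drop)) {
      labels[matrix(labels %in% drop, nrow(labels), ncol(labels))] <- 0L
      labels <- relabel_consecutive(labels)
    }
  }
  if (max(labels) == 0L)
    stop_mhca("no tissue: no fiber interiors found")
  structure(list(labels = labels,
                 n_fibers = max(labels),
                 section_mask = section_mask,
                 excluded = data.frame(fiber_id = integer(0),
                                       reason = character(0),
                                       stringsAsFactors = FALSE),
                 scale_um_per_px = scale_um_per_px,
                 wall_threshold = thr),
            class = "fiber_label_map")
}

#' @export
print.fiber_label_map <- function(x, ...) {
  cat(sprintf("fiber_label_map: %d fibers, %d x %d px, %d excluded by QC\n",
              x$n_fibers, nrow(x$labels), ncol(x$labels), nrow(x$excluded)))
  invisible(x)
}

#' Section-level quality control
#'
#' Compares the summed area of segmented fibers with the area of the whole
#' tissue section; a section whose unsegmented fraction exceeds the
#' user-accepted artifact tolerance is rejected (the batch layer routes it
#' to the Artefacts folder).
#'
#' @param map [segment_fibers()] output.
#' @param artifact_tolerance accepted unsegmented fraction, in [0, 1].
#' @return object of class \code{qc_report} with \code{fiber_area_ratio},
#'   \code{accepted}, \code{artifact_tolerance}.
#' @export
qc_section <- function(map, artifact_tolerance = 0.1) {
  sect <- sum(map$section_mask)
  if (sect == 0) stop_mhca("qc_section: zero section area")
  ratio <- sum(map$labels > 0L) / sect
  structure(list(fiber_area_ratio = ratio,
                 accepted = (1 - ratio) <= artifact_tolerance,
                 artifact_tolerance = artifact_tolerance),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: fiber/section area ratio %.3f, tolerance %.2f -> %s\n",
              x$fiber_area_ratio, x$artifact_tolerance,
              if (x$accepted) "accepted" else "REJECTED"))
  invisible(x)
}

#' Fiber-level quality control (CSA outliers)
#'
#' Removes, in a single pass, every fiber whose cross-sectional area exceeds
#' the section mean plus three standard deviations — the standard guard
#' against under-segmented fiber clumps. Removed ids are recorded in
#' \code{excluded} with reason \code{"csa_outlier"} and the surviving labels
#' are compacted.
#'
#' @param map [segment_fibers()] output.
#' @param csa_um2 per-fiber CSA, ordered by fiber id (e.g. from
#'   [measure_all_fibers()]).
#' @param n_sd number of standard deviations above the mean.
#' @return updated \code{fiber_label_map}; the applied cutoff and CSA
#'   mean/SD are stored in \code{$qc_csa}.
#' @export
qc_fibers <- function(map, csa_um2, n_sd = 3) {
  if (length(csa_um2) != map$n_fibers)
    stop_mhca("qc_fibers: need one CSA per fiber (%d != %d)",
              length(csa_um2), map$n_fibers)
  if (map$n_fibers < 2L) {
    warning("qc_fibers: fewer than 2 fibers; no outlier removal performed")
    map$qc_csa <- list(mean = mean(csa_um2), sd = NA_real_,
                       cutoff = NA_real_, n_removed = 0L)
    return(map)
  }
  m <- mean(csa_um2)
  s <- stats::sd(csa_um2)  # sample SD
  cutoff <- m + n_sd * s
  drop <- which(csa_um2 > cutoff)
  if (length(drop)) {
    map$labels[matrix(map$labels %in% drop, nrow(map$labels),
                      ncol(map$labels))] <- 0L
    map$labels <- relabel_consecutive(map$labels)
    map$excluded <- rbind(map$excluded,
                          data.frame(fiber_id = drop, reason = "csa_outlier",
                                     stringsAsFactors = FALSE))
    map$n_fibers <- max(map$labels)
  }
  map$qc_csa <- list(mean = m, sd = s, cutoff = cutoff,
                     n_removed = length(drop))
  map
}
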