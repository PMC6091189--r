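# Per-fiber morphometry: CSA, Feret diameters (rotating calipers on the
# convex hull of pixel corners), perimeter (chain code with corner
# correction), circularity and gravity center.

# Convex hull of the corner points of the given pixels; pixels are treated
# as unit squares so a w x h pixel rectangle measures exactly w x h.
# Returns an n x 2 matrix (x = col, y = row), counter-clockwise.
pixel_hull <- function(rows, cols) {
  pts <- rbind(cbind(cols - 0.5, rows - 0.5), cbind(cols + 0.5, rows - 0.5),
               cbind(cols - 0.5, rows + 0.5), cbind(cols + 0.5, rows + 0.5))
  pts[grDevices::chull(pts), , drop = FALSE]
}

# Rotating-calipers Feret diameters of a convex polygon (n x 2, x/y).
# min Feret = smallest width over directions normal to hull edges;
# max Feret = largest pairwise vertex distance.
feret_from_hull <- function(hull) {
  n <- nrow(hull)
  if (n == 1L) return(c(min = 0, max = 0))
  if (n == 2L) {
    d <- sqrt(sum((hull[1, ] - hull[2, ])^2))
    return(c(min = 0, max = d))
  }
  e <- hull[c(2:n, 1L), ] - hull
  len <- sqrt(rowSums(e^2))
  keep <- len > 1e-12
  nx <- -e[keep, 2] / len[keep]
  ny <- e[keep, 1] / len[keep]
  # width for each edge direction: extent of all vertices along the normal
  proj <- hull %*% rbind(nx, ny)  # n x n_edges
  widths <- apply(proj, 2, max) - apply(proj, 2, min)
  dmat <- as.matrix(stats::dist(hull))
  c(min = min(widths), max = max(dmat))
}

# Chain-code perimeter with the Vossepoel-Smeulders corner correction.
chain_perimeter <- function(mask) {
  path <- cpp_trace_boundary(mask)
  n <- nrow(path)
  if (n <= 1L) return(4)  # isolated pixel: unit square
  nxt <- rbind(path[-1, , drop = FALSE], path[1, , drop = FALSE])
  dr <- nxt[, 1] - path[, 1]
  dc <- nxt[, 2] - path[, 2]
  diag <- abs(dr) == 1 & abs(dc) == 1
  code <- atan2(dr, dc)
  corners <- sum(abs(diff(c(code, code[1]))) > 1e-9)
  0.980 * sum(!diag) + 1.406 * sum(diag) - 0.091 * corners
}

#' Morphometry of one fiber mask
#'
#' Computes cross-sectional area (pixel count times scale squared), minimum
#' and maximum Feret diameters (rotating calipers on the convex hull of
#' boundary pixel corners), perimeter (boundary following with corner
#' correction), circularity \eqn{4\pi A / P^2} (clamped to 1) and the
#' gravity center (unweighted pixel centroid, um).
#'
#' @param mask logical matrix, one connected nonempty fiber.
#' @param scale_um_per_px pixel size, um/px.
#' @param fiber_id id stored in the result.
#' @param check_connected verify the mask is a single connected component.
#' @return one-row data.frame: \code{fiber_id, csa_um2, min_feret_um,
#'   max_feret_um, circularity, perimeter_um, gc_x_um, gc_y_um}.
#' @export
measure_fiber <- function(mask, scale_um_per_px, fiber_id = 1L,
                          check_connected = TRUE) {
  idx <- which(mask)
  if (!length(idx)) stop_mhca("measure_fiber: empty mask")
  if (check_connected && max(cpp_label_components(mask, 8L)) != 1L)
    stop_mhca("measure_fiber: mask is not a single connected component")
  h <- nrow(mask)
  rows <- (idx - 1L) %% h + 1L
  cols <- (idx - 1L) %/% h + 1L
  # boundary pixels suffice for the hull
  inner <- binary_erode(mask, 1)
  bidx <- which(mask & !inner)
  if (!length(bidx)) bidx <- idx
  br <- (bidx - 1L) %% h + 1L
  bc <- (bidx - 1L) %/% h + 1L
  fer <- feret_from_hull(pixel_hull(br, bc)) * scale_um_per_px
  per <- chain_perimeter(mask) * scale_um_per_px
  csa <- length(idx) * scale_um_per_px^2
  circ <- min(1, 4 * pi * csa / per^2)
  data.frame(fiber_id = fiber_id,
             csa_um2 = csa,
             min_feret_um = unname(fer["min"]),
             max_feret_um = unname(fer["max"]),
             circularity = circ,
             perimeter_um = per,
             gc_x_um = (mean(cols) - 1) * scale_um_per_px,
             gc_y_um = (mean(rows) - 1) * scale_um_per_px)
}

#' Morphometry of every fiber in a label map
#'
#' @param map [segment_fibers()] output.
#' @return data.frame with one [measure_fiber()] row per fiber, ordered by
#'   fiber id.
#' @export
measure_all_fibers <- function(map) {
  scale <- map$scale_um_per_px
  out <- vector("list", map$n_fibers)
  for (k in seq_len(map$n_fibers)) {
    cb <- crop_to_bbox(map$labels == k, pad = 1L)
    m <- measure_fiber(cb$crop, scale, fiber_id = k, check_connected = FALSE)
    m$gc_x_um <- m$gc_x_um + (cb$c0 - 1L) * scale
    m$gc_y_um <- m$gc_y_um + (cb$r0 - 1L) * scale
    out[[k]] <- m
  }
  do.call(rbind, out)
}

#' Build the four Feret-proportional regions of interest for one fiber
#'
#' The central zone \code{cnf} is the fiber eroded by a disc of radius
#' \code{round(min_feret * cnf_fraction / scale)} px; the sub-laminal
#' annulus \code{sc} is the exact set difference fiber minus central zone;
#' the peri-fiber band \code{v} is the dilation of the fiber by
#' \code{round(min_feret * v_fraction / scale)} px minus the fiber itself
#' (and minus every other fiber when \code{other_fibers} is given). When
#' erosion would empty the central zone, the ultimate-erosion pixel set
#' (distance-transform maxima) is used so every fiber keeps a defined
#' center.
#'
#' @param mask logical fiber mask (full frame or crop).
#' @param morph one-row data.frame from [measure_fiber()].
#' @param scale_um_per_px pixel size, um/px.
#' @param cnf_fraction,v_fraction margins as fractions of the minimum Feret
#'   diameter (defaults 1/5 inward and 1/8 outward).
#' @param other_fibers optional logical mask of all *other* fibers, same
#'   geometry as \code{mask}; excluded from the \code{v} band.
#' @return object of class \code{roi_set}: logical masks \code{f, cnf, sc,
#'   v} on the same grid as \code{mask}, plus the radii used
#'   (\code{erosion_px}, \code{dilation_px}).
#' @export
build_rois <- function(mask, morph, scale_um_per_px, cnf_fraction = 1 / 5,
                       v_fraction = 1 / 8, other_fibers = NULL) {
  er_px <- round(morph$min_feret_um * cnf_fraction / scale_um_per_px)
  dil_px <- round(morph$min_feret_um * v_fraction / scale_um_per_px)
  edt_in <- cpp_edt(mask)
  cnf <- edt_in > er_px
  if (!any(cnf)) cnf <- mask & edt_in >= max(edt_in) - 1e-9
  sc <- mask & !cnf
  v <- (cpp_edt(!mask) <= dil_px) & !mask
  if (!is.null(other_fibers)) v <- v & !other_fibers
  structure(list(f = mask, cnf = cnf, sc = sc, v = v,
                 erosion_px = er_px, dilation_px = dil_px,
                 fiber_id = morph$fiber_id),
            class = "roi_set")
}

#' Build ROI sets for every fiber of a section
#'
#' Runs [build_rois()] per fiber on padded crops and assembles, in
#' addition, two full-frame integer lookup maps (\code{cnf_map},
#' \code{sc_map}: pixel to owning fiber id, mutually disjoint) used for
#' fast centroid-containment queries. The \code{v} band of each fiber
#' excludes every fiber's pixels.
#'
#' @param map [segment_fibers()] output.
#' @param morpho [measure_all_fibers()] output.
#' @param cnf_fraction,v_fraction see [build_rois()].
#' @return list of class \code{roi_collection}: \code{rois} (per-fiber crop
#'   records with bbox offsets), \code{cnf_map}, \code{sc_map}.
#' @export
build_all_rois <- function(map, morpho, cnf_fraction = 1 / 5,
                           v_fraction = 1 / 8) {
  scale <- map$scale_um_per_px
  h <- nrow(map$labels); w <- ncol(map$labels)
  any_fiber <- map$labels > 0L
  cnf_map <- matrix(0L, h, w)
  rois <- vector("list", map$n_fibers)
  for (k in seq_len(map$n_fibers)) {
    mk <- morpho[morpho$fiber_id == k, ]
    pad <- round(mk$min_feret_um * v_fraction / scale) + 2L
    cb <- crop_to_bbox(map$labels == k, pad = pad)
    rr <- cb$r0 + seq_len(nrow(cb$crop)) - 1L
    cc <- cb$c0 + seq_len(ncol(cb$crop)) - 1L
    rs <- build_rois(cb$crop, mk, scale, cnf_fraction, v_fraction,
                     other_fibers = any_fiber[rr, cc, drop = FALSE] & !cb$crop)
    rs$r0 <- cb$r0; rs$c0 <- cb$c0
    rois[[k]] <- rs
    sub <- cnf_map[rr, cc]
    sub[rs$cnf] <- k
    cnf_map[rr, cc] <- sub
  }
  sc_map <- map$labels
  sc_map[cnf_map > 0L] <- 0L
  structure(list(rois = rois, cnf_map = cnf_map, sc_map = sc_map),
            class = "roi_collection")
}

# Does physical/pixel point (r, c) fall inside a given crop-stored roi mask?
point_in_roi <- function(rs, which_mask, r, c) {
  m <- rs[[which_mask]]
  ri <- round(r) - rs$r0 + 1L
  ci <- round(c) - rs$c0 + 1L
  ri >= 1L && ri <= nrow(m) && ci >= 1L && ci <= ncol(m) && m[ri, ci]
}
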