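# Seeded synthetic muscle sections with complete per-fiber ground truth.
#
# Fiber geometry is a Lloyd-relaxed random tessellation clipped to an
# elliptical "section", which mimics the near-convex space-filling packing
# of real transverse muscle sections. Laminin walls are drawn along cell
# boundaries; nuclei, Pax7 and CD31 blobs are planted in geometrically
# correct zones (central nuclei in the fiber-center zone, peripheral nuclei
# and satellites in the sub-laminal band, vessels on walls); typing
# channels are filled per true label. Every placement respects margins so
# the planted truth is recoverable by the measurement definitions.

sample_in_ellipse <- function(n, cy, cx, b, a) {
  out <- matrix(0, 0, 2)
  while (nrow(out) < n) {
    r <- runif(2 * n, -1, 1); c <- runif(2 * n, -1, 1)
    keep <- r^2 + c^2 <= 1
    out <- rbind(out, cbind(cy + r[keep] * b, cx + c[keep] * a))
  }
  out[seq_len(n), , drop = FALSE]
}

# pick up to n pixels from candidate indices with pairwise min separation
place_points <- function(cand_r, cand_c, n, min_sep_px, existing = NULL) {
  pr <- numeric(0); pc <- numeric(0)
  if (!is.null(existing) && nrow(existing)) {
    pr <- existing[, 1]; pc <- existing[, 2]
  }
  n_existing <- length(pr)
  ord <- sample.int(length(cand_r))
  for (i in ord) {
    if (length(pr) - n_existing >= n) break
    r <- cand_r[i]; c <- cand_c[i]
    if (!length(pr) || all((pr - r)^2 + (pc - c)^2 >= min_sep_px^2)) {
      pr <- c(pr, r); pc <- c(pc, c)
    }
  }
  k <- length(pr) - n_existing
  if (k <= 0) return(matrix(numeric(0), 0, 2))
  cbind(pr[n_existing + seq_len(k)], pc[n_existing + seq_len(k)])
}

draw_disc <- function(img, r0, c0, radius_px, value) {
  rr <- max(1, floor(r0 - radius_px)):min(nrow(img), ceiling(r0 + radius_px))
  cc <- max(1, floor(c0 - radius_px)):min(ncol(img), ceiling(c0 + radius_px))
  sub <- img[rr, cc, drop = FALSE]
  d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
  sub[d2 <= radius_px^2] <- pmax(sub[d2 <= radius_px^2], value)
  img[rr, cc] <- sub
  img
}

finish_channel <- function(img, blur_px, noise_sigma, base = 0) {
  img <- img + base
  if (blur_px > 0) img <- cpp_gaussian_blur(img, blur_px)
  if (noise_sigma > 0)
    img <- img + matrix(rnorm(length(img), 0, noise_sigma), nrow(img))
  round(pmin(pmax(img, 0), 1) * 65535)
}

#' Generate a synthetic calibrated section with ground truth
#'
#' All randomness flows through \code{seed}; the same call is
#' pixel-identical across runs. Defaults describe a healthy mouse
#' hind-limb-like section: ~1500 um^2 fibers, ~5 peripheral myonuclei and
#' ~4 planted wall vessels per fiber, sparse satellite cells, and a
#' IIB-dominant type mix.
#'
#' @param n_fibers number of tessellation cells.
#' @param mean_csa_um2 target mean fiber CSA (wall-corrected), um^2.
#' @param csa_cv advisory CSA spread; lower values run more Lloyd
#'   relaxation steps (the tessellation sets the exact distribution).
#' @param cnf_fraction fraction of fibers given >= 1 central nucleus.
#' @param centronuclei_dist named probabilities of 1, 2, 3, ... central
#'   nuclei for a centronucleated fiber.
#' @param peripheral_mean Poisson mean of peripheral myonuclei per fiber.
#' @param satellites_per_fiber_dist named probabilities of 0, 1, 2, ...
#'   satellite cells per fiber.
#' @param vessels_per_fiber_mean Poisson mean of planted wall vessels per
#'   fiber.
#' @param interstitial_rate expected interstitial (wall) nuclei per fiber.
#' @param type_mix named probabilities over fiber types (pure types and
#'   optionally hybrids).
#' @param channels roles to render (max 4, must include laminin).
#' @param noise_sigma additive Gaussian noise, fraction of full scale.
#' @param blur_sigma_um optical blur sigma, um.
#' @param scale_um_per_px pixel size (default the AxioScan-like 0.325).
#' @param wall_um full laminin wall thickness, um.
#' @param seed integer seed; recorded in the truth.
#' @return list: \code{section} ([calibrated_section()], 16-bit scale) and
#'   \code{truth} (class \code{synthetic_truth}: \code{fibers} data.frame,
#'   \code{objects} data.frame, \code{labels} truth label matrix,
#'   \code{params}).
#' @export
generate_section <- function(n_fibers = 150, mean_csa_um2 = 1500,
                             csa_cv = 0.25, cnf_fraction = 0,
                             centronuclei_dist = c("1" = 0.6, "2" = 0.25,
                                                   "3" = 0.1, "4" = 0.05),
                             peripheral_mean = 5,
                             satellites_per_fiber_dist = c("0" = 0.7,
                                                           "1" = 0.25,
                                                           "2" = 0.05),
                             vessels_per_fiber_mean = 4,
                             interstitial_rate = 0.1,
                             type_mix = c(I = 0.05, IIA = 0.35, IIB = 0.45,
                                          IIX = 0.15),
                             channels = c("laminin", "dapi"),
                             noise_sigma = 0.02, blur_sigma_um = 0.5,
                             scale_um_per_px = 0.325, wall_um = 2,
                             seed = 1) {
  if (!"laminin" %in% channels) stop_mhca("laminin channel is required")
  if (length(channels) > 4) stop_mhca("at most 4 channels")
  if (any(c("dapi", "pax7") %in% channels) && mean_csa_um2 < 400)
    stop_mhca(paste("infeasible parameters: ~2.5 um radius nuclei cannot be",
                    "placed with margins in fibers of mean CSA %g um2"),
              mean_csa_um2)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  scale <- scale_um_per_px
  half_wall_um <- wall_um / 2
  half_wall_px <- max(1L, round(half_wall_um / scale))
  blur_px <- blur_sigma_um / scale

  # cell area compensating for the wall the interior loses
  s <- sqrt(pi) * half_wall_um + sqrt(pi * half_wall_um^2 + mean_csa_um2)
  cell_px <- s^2 / scale^2
  aspect <- 1.4
  b <- sqrt(n_fibers * cell_px / (pi * aspect))
  a <- aspect * b
  margin <- 16L
  H <- as.integer(ceiling(2 * b) + 2 * margin)
  W <- as.integer(ceiling(2 * a) + 2 * margin)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rg <- matrix(seq_len(H), H, W)
  cg <- matrix(seq_len(W), H, W, byrow = TRUE)
  ellipse <- ((rg - cy) / b)^2 + ((cg - cx) / a)^2 <= 1

  pts <- sample_in_ellipse(n_fibers, cy, cx, b * 0.97, a * 0.97)
  n_lloyd <- if (csa_cv <= 0.25) 3L else if (csa_cv <= 0.4) 1L else 0L
  for (it in seq_len(n_lloyd + 1L)) {
    lab_full <- cpp_nearest_label(H, W, pts[, 1] - 1, pts[, 2] - 1)
    lab_full[!ellipse] <- 0L
    if (it <= n_lloyd) {
      cent <- label_centroids(lab_full, n_fibers)
      ok <- !is.na(cent[, 1])
      pts[ok, ] <- cent[ok, , drop = FALSE]
    }
  }

  # walls along cell boundaries and the section rim
  shift_ne <- function(m, dr, dc) {
    out <- matrix(-1L, H, W)
    rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
    okr <- rs >= 1 & rs <= H; okc <- cs >= 1 & cs <= W
    out[which(okr), which(okc)] <- m[rs[okr], cs[okc]]
    out
  }
  boundary <- ellipse & (lab_full != shift_ne(lab_full, 1L, 0L) |
                         lab_full != shift_ne(lab_full, 0L, 1L) |
                         lab_full != shift_ne(lab_full, -1L, 0L) |
                         lab_full != shift_ne(lab_full, 0L, -1L))
  wall <- binary_dilate(boundary, half_wall_px) & ellipse
  truth_labels <- lab_full
  truth_labels[wall] <- 0L

  # truth morphometry per fiber (on the rendered interior masks)
  fibers <- vector("list", n_fibers)
  crops <- vector("list", n_fibers)
  for (k in seq_len(n_fibers)) {
    mk <- truth_labels == k
    if (!any(mk)) next
    cb <- crop_to_bbox(mk, pad = 2L)
    comp <- cpp_label_components(cb$crop, 8L)
    if (max(comp) > 1L) {  # keep largest piece only
      big <- which.max(tabulate(comp[comp > 0L], max(comp)))
      cb$crop <- comp == big
      full <- matrix(FALSE, H, W)
      full[cb$r0 + seq_len(nrow(cb$crop)) - 1L,
           cb$c0 + seq_len(ncol(cb$crop)) - 1L] <- cb$crop
      truth_labels[truth_labels == k & !full] <- 0L
    }
    m <- measure_fiber(cb$crop, scale, fiber_id = k, check_connected = FALSE)
    m$gc_x_um <- m$gc_x_um + (cb$c0 - 1L) * scale
    m$gc_y_um <- m$gc_y_um + (cb$r0 - 1L) * scale
    fibers[[k]] <- m
    crops[[k]] <- cb
  }
  fib <- do.call(rbind, fibers)
  fib$n_central <- 0L; fib$n_peripheral <- 0L
  fib$n_satellites <- 0L; fib$n_vessels <- 0L
  fib$type <- NA_character_

  want <- function(role) role %in% channels
  objects <- list()
  add_obj <- function(kind, fiber_id, pos_px, radius_um) {
    if (!nrow(pos_px)) return()
    objects[[length(objects) + 1L]] <<-
      data.frame(kind = kind, fiber_id = fiber_id,
                 r_px = pos_px[, 1], c_px = pos_px[, 2],
                 x_um = (pos_px[, 2] - 1) * scale,
                 y_um = (pos_px[, 1] - 1) * scale,
                 radius_um = radius_um[seq_len(nrow(pos_px))],
                 stringsAsFactors = FALSE)
  }

  # --- nuclei, satellites ---------------------------------------------------
  if (want("dapi")) {
    is_cnf_fiber <- runif(nrow(fib)) < cnf_fraction
    cn_counts <- as.integer(names(centronuclei_dist))
    for (i in seq_len(nrow(fib))) {
      k <- fib$fiber_id[i]
      cb <- crops[[k]]
      edt_um <- cpp_edt(cb$crop) * scale
      er_um <- fib$min_feret_um[i] / 5
      r_nuc <- function(n) runif(n, 2.2, 2.8)
      # central zone with safety margin so detected centroids stay central
      cen_cand <- which(edt_um > er_um + 1.5)
      if (!length(cen_cand)) cen_cand <- which(edt_um >= max(edt_um) - scale)
      # sub-laminal band, clear of both wall and central zone
      lo <- min(1.8, 0.35 * er_um); hi <- max(min(er_um - 1.5, 5), 0.6 * er_um)
      per_cand <- which(edt_um >= lo & edt_um <= hi)
      ci <- cbind((cen_cand - 1L) %% nrow(cb$crop) + 1L,
                  (cen_cand - 1L) %/% nrow(cb$crop) + 1L)
      pi_ <- cbind((per_cand - 1L) %% nrow(cb$crop) + 1L,
                   (per_cand - 1L) %/% nrow(cb$crop) + 1L)
      n_cen <- if (is_cnf_fiber[i])
        cn_counts[sample.int(length(cn_counts), 1L,
                             prob = centronuclei_dist)] else 0L
      cap <- max(2L, floor(pi * fib$min_feret_um[i] / (2.6 * 2.5)))
      n_per <- min(rpois(1, peripheral_mean), cap)
      sep_px <- 2.6 * 2.5 / scale
      placed_c <- place_points(ci[, 1], ci[, 2], n_cen, sep_px)
      placed_p <- place_points(pi_[, 1], pi_[, 2], n_per, sep_px,
                               existing = placed_c)
      off <- c(cb$r0 - 1L, cb$c0 - 1L)
      if (nrow(placed_c)) {
        pc <- sweep(placed_c, 2, -off)
        add_obj("nucleus_central", k, pc, r_nuc(nrow(pc)))
        fib$n_central[i] <- nrow(pc)
      }
      if (nrow(placed_p)) {
        pp <- sweep(placed_p, 2, -off)
        rr <- r_nuc(nrow(pp))
        add_obj("nucleus_peripheral", k, pp, rr)
        fib$n_peripheral[i] <- nrow(pp)
        if (want("pax7")) {
          s_counts <- as.integer(names(satellites_per_fiber_dist))
          n_sat <- min(s_counts[sample.int(length(s_counts), 1L,
                                           prob = satellites_per_fiber_dist)],
                       nrow(pp))
          if (n_sat > 0) {
            sel <- sample.int(nrow(pp), n_sat)
            add_obj("pax7", k, pp[sel, , drop = FALSE], 0.75 * rr[sel])
            fib$n_satellites[i] <- n_sat
          }
        }
      }
    }
    # interstitial nuclei on walls
    n_int <- rpois(1, interstitial_rate * n_fibers)
    if (n_int > 0) {
      wi <- which(wall & cpp_edt(wall) * scale > 0.8)
      if (length(wi)) {
        wp <- place_points((wi - 1L) %% H + 1L, (wi - 1L) %/% H + 1L,
                           n_int, 3 / scale)
        add_obj("nucleus_interstitial", NA_integer_, wp,
                runif(nrow(wp), 2.2, 2.8))
      }
    }
  }

  # --- vessels on walls -----------------------------------------------------
  if (want("cd31")) {
    placed_v <- matrix(numeric(0), 0, 2)
    for (i in seq_len(nrow(fib))) {
      k <- fib$fiber_id[i]
      cb <- crops[[k]]
      h2 <- nrow(cb$crop); w2 <- ncol(cb$crop)
      rr <- cb$r0 + seq_len(h2) - 1L
      cc <- cb$c0 + seq_len(w2) - 1L
      wall_crop <- wall[rr, cc, drop = FALSE]
      dist_um <- cpp_edt(!cb$crop) * scale  # distance to this fiber
      band_um <- fib$min_feret_um[i] / 8
      cand <- which(wall_crop & dist_um > 0.2 &
                    dist_um < max(band_um - 2.5, 1.2))
      if (!length(cand)) next
      n_v <- min(rpois(1, vessels_per_fiber_mean), 12L)
      if (n_v == 0) next
      cr <- (cand - 1L) %% h2 + cb$r0
      cccol <- (cand - 1L) %/% h2 + cb$c0
      pv <- place_points(cr, cccol, n_v, 3.5 / scale, existing = placed_v)
      if (nrow(pv)) {
        placed_v <- rbind(placed_v, pv)
        add_obj("cd31", k, pv, runif(nrow(pv), 1.2, 1.9))
        fib$n_vessels[i] <- nrow(pv)
      }
    }
  }

  # --- fiber types ----------------------------------------------------------
  stains <- intersect(channels, c("stain1", "stain2", "stain3"))
  if (length(stains)) {
    fib$type <- sample(names(type_mix), nrow(fib), replace = TRUE,
                       prob = type_mix)
  }

  obj <- if (length(objects)) do.call(rbind, objects) else
    data.frame(kind = character(0), fiber_id = integer(0), r_px = numeric(0),
               c_px = numeric(0), x_um = numeric(0), y_um = numeric(0),
               radius_um = numeric(0), stringsAsFactors = FALSE)

  # --- render channels ------------------------------------------------------
  chan <- list()
  lam <- matrix(0, H, W)
  lam[wall] <- 0.75
  chan$laminin <- finish_channel(lam, blur_px, noise_sigma, base = 0.04)
  stamp <- function(df, value) {
    img <- matrix(0, H, W)
    if (!nrow(df)) return(img)
    cpp_draw_discs(img, df$r_px, df$c_px, df$radius_um / scale,
                   rep(value, nrow(df)))
  }
  if (want("dapi")) {
    nuc <- obj[grepl("^nucleus", obj$kind), , drop = FALSE]
    chan$dapi <- finish_channel(stamp(nuc, 0.85), blur_px, noise_sigma,
                                base = 0.03)
  }
  if (want("pax7")) {
    chan$pax7 <- finish_channel(stamp(obj[obj$kind == "pax7", , drop = FALSE],
                                      0.8), blur_px, noise_sigma, base = 0.03)
  }
  if (want("cd31")) {
    chan$cd31 <- finish_channel(stamp(obj[obj$kind == "cd31", , drop = FALSE],
                                      0.8), blur_px, noise_sigma, base = 0.03)
  }
  if (length(stains)) {
    pos_for <- function(type, stain) {
      if (is.na(type) || type %in% c("IIX")) return(FALSE)
      if (type == "ND") return(TRUE)
      parts <- strsplit(type, "-")[[1]]
      TYPE_NAME_DEFAULT[[stain]] %in% parts
    }
    for (st in stains) {
      m <- matrix(0, H, W)
      lvl <- ifelse(vapply(fib$type, pos_for, logical(1), stain = st),
                    0.7, 0.10)
      lut <- rep(0, n_fibers)
      lut[fib$fiber_id] <- lvl
      inside <- truth_labels > 0L
      m[inside] <- lut[truth_labels[inside]]
      m[wall] <- pmax(m[wall], 0.06)
      chan[[st]] <- finish_channel(m, blur_px, noise_sigma, base = 0.04)
    }
  }
  chan <- chan[intersect(c("laminin", "dapi", "pax7", "cd31",
                           "stain1", "stain2", "stain3"), names(chan))]

  section <- calibrated_section(chan, scale, source = sprintf("synthetic_seed%d", seed))
  truth <- structure(list(fibers = fib, objects = obj, labels = truth_labels,
                          section_mask = ellipse,
                          params = list(n_fibers = n_fibers,
                                        mean_csa_um2 = mean_csa_um2,
                                        csa_cv = csa_cv,
                                        cnf_fraction = cnf_fraction,
                                        scale_um_per_px = scale,
                                        wall_um = wall_um,
                                        noise_sigma = noise_sigma,
                                        blur_sigma_um = blur_sigma_um,
                                        seed = seed)),
                     class = "synthetic_truth")
  list(section = section, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d fibers, seed %d, %.3g um/px\n",
              nrow(x$fibers), x$params$seed, x$params$scale_um_per_px))
  invisible(x)
}

#' Controlled degradation of a synthetic section
#'
#' Produces corrupted inputs for exercising the quality-control path.
#' \code{broken_walls} replaces patches (totaling \code{severity} of the
#' tissue area) with bright unstructured signal, making them
#' unsegmentable; \code{uneven_illumination} multiplies every channel by a
#' left-right ramp of amplitude \code{severity}; \code{debris} adds
#' off-tissue bright blobs to the laminin channel without touching fibers.
#'
#' @param section [calibrated_section()] (16-bit scale, as generated).
#' @param mode \code{"broken_walls"}, \code{"uneven_illumination"} or
#'   \code{"debris"}.
#' @param severity in [0, 1]; 0 returns the input unchanged.
#' @param seed RNG seed for patch placement.
#' @return degraded [calibrated_section()] with attribute \code{degrade}
#'   recording mode, severity and (for \code{broken_walls}) the expected
#'   unsegmentable area fraction.
#' @export
degrade <- function(section, mode = c("broken_walls", "uneven_illumination",
                                      "debris"),
                    severity, seed = 1) {
  mode <- match.arg(mode)
  if (severity < 0 || severity > 1) stop_mhca("severity must be in [0, 1]")
  if (severity == 0) return(section)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed + 7919L)
  lam <- section$channels$laminin
  H <- nrow(lam); W <- ncol(lam)
  thr <- otsu_threshold(lam)
  tissue <- fill_holes(binary_close(lam > thr,
                                    max(2L, round(1.5 / section$scale_um_per_px))))
  t_idx <- which(tissue)
  if (mode == "broken_walls") {
    target <- severity * length(t_idx)
    patched <- matrix(FALSE, H, W)
    radius <- round(sqrt(500 / pi) / section$scale_um_per_px)  # ~500 um2 discs
    guard <- 0L
    while (sum(patched & tissue) < target && guard < 10000L) {
      guard <- guard + 1L
      ctr <- t_idx[sample.int(length(t_idx), 1L)]
      r0 <- (ctr - 1L) %% H + 1L; c0 <- (ctr - 1L) %/% H + 1L
      rr <- max(1, r0 - radius):min(H, r0 + radius)
      cc <- max(1, c0 - radius):min(W, c0 + radius)
      d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
      sub <- patched[rr, cc]; sub[d2 <= radius^2] <- TRUE
      patched[rr, cc] <- sub
    }
    patched <- patched & tissue
    wall_level <- stats::quantile(lam[lam > thr], 0.5)
    lam[patched] <- wall_level * runif(sum(patched), 0.85, 1.1)
    section$channels$laminin <- lam
    attr(section, "degrade") <- list(mode = mode, severity = severity,
                                     unsegmentable_fraction =
                                       sum(patched) / length(t_idx))
  } else if (mode == "uneven_illumination") {
    ramp <- matrix(1 - severity + 2 * severity * (seq_len(W) - 1) / (W - 1),
                   H, W, byrow = TRUE)
    for (nm in names(section$channels))
      section$channels[[nm]] <- section$channels[[nm]] * ramp
    attr(section, "degrade") <- list(mode = mode, severity = severity)
  } else {  # debris
    n_blob <- ceiling(severity * 20)
    off <- which(!binary_dilate(tissue, 10L))
    for (j in seq_len(min(n_blob, length(off)))) {
      ctr <- off[sample.int(length(off), 1L)]
      r0 <- (ctr - 1L) %% H + 1L; c0 <- (ctr - 1L) %/% H + 1L
      lam <- draw_disc(lam, r0, c0, runif(1, 6, 14), 50000)
    }
    section$channels$laminin <- lam
    attr(section, "degrade") <- list(mode = mode, severity = severity)
  }
  section
}

#' Match predicted labels to truth labels by IoU
#'
#' Greedy one-to-one matching on intersection-over-union between two label
#' matrices of identical size, used to score segmentation recall and
#' precision against planted truth.
#'
#' @param truth,pred integer label matrices (0 = background).
#' @param iou_min minimum IoU for a match.
#' @return list: \code{matches} (data.frame \code{truth_id, pred_id, iou}),
#'   \code{recall}, \code{precision}.
#' @export
match_labels <- function(truth, pred, iou_min = 0.5) {
  nt <- max(truth); np <- max(pred)
  both <- truth > 0L & pred > 0L
  if (!any(both) || nt == 0L || np == 0L)
    return(list(matches = data.frame(truth_id = integer(0),
                                     pred_id = integer(0), iou = numeric(0)),
                recall = 0, precision = 0))
  key <- (as.numeric(truth[both]) - 1) * np + as.numeric(pred[both])
  tab <- table(key)
  ks <- as.numeric(names(tab))
  ti <- floor((ks - 1) / np) + 1
  pj <- ks - (ti - 1) * np
  inter <- as.numeric(tab)
  at <- tabulate(truth[truth > 0L], nt)
  ap <- tabulate(pred[pred > 0L], np)
  iou <- inter / (at[ti] + ap[pj] - inter)
  ord <- order(iou, decreasing = TRUE)
  used_t <- logical(nt); used_p <- logical(np)
  keep <- logical(length(ord))
  for (i in ord) {
    if (iou[i] < iou_min) break
    if (!used_t[ti[i]] && !used_p[pj[i]]) {
      keep[i] <- TRUE
      used_t[ti[i]] <- TRUE
      used_p[pj[i]] <- TRUE
    }
  }
  m <- data.frame(truth_id = ti[keep], pred_id = pj[keep], iou = iou[keep])
  # denominator: truth labels that actually exist
  nt_eff <- sum(at > 0)
  list(matches = m, recall = nrow(m) / nt_eff, precision = nrow(m) / np)
}
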