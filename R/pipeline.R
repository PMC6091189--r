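# Single-section orchestration: pretreatment -> segmentation -> QC ->
# morphometry -> ROIs -> requested features, assembled into per-fiber,
# per-object and per-section summaries.

#' Default pipeline parameters
#'
#' Every tunable of the analysis with its default: pretreatment
#' (\code{rolling_ball_radius_px} 50, \code{clahe_clip} 2), segmentation
#' (\code{min_fiber_area_um2} 50), QC (\code{artifact_tolerance} 0.10,
#' \code{csa_outlier_sd} 3), ROI geometry (\code{cnf_fraction} 1/5 inward,
#' \code{v_fraction} 1/8 outward of the minimum Feret diameter), detection
#' area bounds per marker, the satellite \code{overlap_min} 0.90 and the
#' typing \code{snr_factor} 3.
#'
#' @param ... overrides.
#' @return named list of parameters.
#' @export
default_params <- function(...) {
  p <- list(rolling_ball_radius_px = 50L, clahe_clip = 2,
            min_fiber_area_um2 = 50, artifact_tolerance = 0.10,
            csa_outlier_sd = 3, cnf_fraction = 1 / 5, v_fraction = 1 / 8,
            nucleus_area_um2 = c(10, 200), pax7_area_um2 = c(8, 120),
            cd31_area_um2 = c(5, 400), overlap_min = 0.90, snr_factor = 3,
            type_names = TYPE_NAME_DEFAULT)
  ov <- list(...)
  p[names(ov)] <- ov
  p
}

ALL_FEATURES <- c("morphometry", "cnf", "satellites", "vessels", "typing")

#' Analyze one calibrated section
#'
#' Runs the full pipeline for the requested features and returns all
#' intermediate and final products. A section failing the area-ratio
#' quality control is returned immediately with \code{accepted = FALSE}
#' and no feature results (the batch layer routes it to Artefacts).
#'
#' @param section [calibrated_section()].
#' @param features subset of \code{morphometry, cnf, satellites, vessels,
#'   typing} (morphometry always runs).
#' @param params [default_params()].
#' @return object of class \code{section_analysis}: \code{map}, \code{qc},
#'   \code{morpho}, \code{rois}, per-feature results, \code{fibers}
#'   (merged per-fiber table), \code{objects} (per-object table),
#'   \code{summary} (named list, one global row).
#' @export
analyze_section <- function(section, features = ALL_FEATURES,
                            params = default_params()) {
  features <- match.arg(features, ALL_FEATURES, several.ok = TRUE)
  need <- function(role, feat) {
    if (feat %in% features && is.null(section$channels[[role]]))
      stop_mhca("feature '%s' requires a '%s' channel", feat, role)
  }
  need("dapi", "cnf"); need("dapi", "satellites")
  need("pax7", "satellites"); need("cd31", "vessels")
  stains <- intersect(names(section$channels), c("stain1", "stain2", "stain3"))
  if ("typing" %in% features && !length(stains))
    stop_mhca("feature 'typing' requires at least one stain channel")
  scale <- section$scale_um_per_px

  pre <- pretreat(section$channels$laminin,
                  rolling_ball_radius_px = params$rolling_ball_radius_px,
                  clahe_clip = params$clahe_clip)
  map <- segment_fibers(pre, scale,
                        min_fiber_area_um2 = params$min_fiber_area_um2)
  qc <- qc_section(map, params$artifact_tolerance)
  res <- structure(list(section = section$source, map = map, qc = qc),
                   class = "section_analysis")
  if (!qc$accepted) {
    res$summary <- list(image = section$source, n_fibers = NA_integer_,
                        qc_ratio = qc$fiber_area_ratio, accepted = FALSE)
    return(res)
  }
  morpho <- measure_all_fibers(map)
  map <- qc_fibers(map, morpho$csa_um2, n_sd = params$csa_outlier_sd)
  if (map$qc_csa$n_removed > 0) morpho <- measure_all_fibers(map)
  res$map <- map
  res$morpho <- morpho
  rois <- build_all_rois(map, morpho, cnf_fraction = params$cnf_fraction,
                         v_fraction = params$v_fraction)
  res$rois <- rois
  fibers <- morpho
  objects <- list()
  area_mm2 <- sum(map$section_mask) * (scale / 1000)^2

  nuclei <- NULL
  if (any(c("cnf", "satellites") %in% features)) {
    nuclei <- detect_nuclei(section$channels$dapi, scale,
                            min_area_um2 = params$nucleus_area_um2[1],
                            max_area_um2 = params$nucleus_area_um2[2])
    res$nuclei <- nuclei
  }
  if ("cnf" %in% features) {
    cnf <- classify_cnf(nuclei, rois, map)
    res$cnf <- cnf
    res$cnf_dist <- cnf_distribution(cnf)
    fibers$NbCentroNuclei <- cnf$n_centronuclei
    fibers$NbPeripheralNuclei <- cnf$n_peripheral
    fibers$IsCNF <- cnf$is_cnf
  }
  if ("satellites" %in% features) {
    pax7 <- detect_marker_objects(section$channels$pax7, scale, "pax7",
                                  min_area_um2 = params$pax7_area_um2[1],
                                  max_area_um2 = params$pax7_area_um2[2])
    sat <- call_satellites(pax7, nuclei$labels > 0L, rois, map,
                           overlap_min = params$overlap_min)
    res$satellites <- sat
    objects$satellites <- data.frame(
      ObjectId = sat$object_id, Role = "pax7", Area_um2 = sat$area_um2,
      MeanIntensity = sat$mean_intensity, GC_X = sat$gc_x_um,
      GC_Y = sat$gc_y_um, FiberId = sat$fiber_id, Accepted = sat$accepted)
    n_sat <- tabulate(sat$fiber_id[sat$accepted], map$n_fibers)
    fibers$NbSatellites <- n_sat
    res$satellites_per_mm2 <- sum(sat$accepted) / area_mm2
  }
  if ("vessels" %in% features) {
    cd31 <- detect_marker_objects(section$channels$cd31, scale, "cd31",
                                  min_area_um2 = params$cd31_area_um2[1],
                                  max_area_um2 = params$cd31_area_um2[2])
    ves <- quantify_vessels(cd31, rois, map)
    res$cd31 <- cd31
    res$vessels <- ves
    objects$vessels <- data.frame(
      ObjectId = cd31$objects$object_id, Role = "cd31",
      Area_um2 = cd31$objects$area_um2,
      MeanIntensity = cd31$objects$mean_intensity,
      GC_X = cd31$objects$gc_x_um, GC_Y = cd31$objects$gc_y_um,
      FiberId = NA_integer_, Accepted = TRUE)
    fibers$NbVessels <- ves$per_fiber_counts$n_vessels
    if ("satellites" %in% features)
      res$sat_vessel_dist <- satellite_vessel_distances(res$satellites,
                                                        cd31$objects)
  }
  if ("typing" %in% features) {
    thr <- lapply(stains, function(st)
      compute_threshold(section$channels[[st]], map,
                        snr_factor = params$snr_factor))
    names(thr) <- stains
    calls <- call_types(section$channels[stains], thr, map,
                        type_names = params$type_names)
    res$thresholds <- thr
    res$typing <- calls
    res$type_dist <- type_distribution(calls)
    for (st in stains) {
      fibers[[paste0("MeanIntensity_", st)]] <- calls[[paste0("mean_", st)]]
      fibers[[paste0("Pos_", st)]] <- calls[[paste0("pos_", st)]]
    }
    fibers$Type <- calls$label
  }
  res$fibers <- fibers
  res$objects <- if (length(objects)) do.call(rbind, unname(objects)) else NULL

  smry <- list(image = section$source, n_fibers = map$n_fibers,
               qc_ratio = qc$fiber_area_ratio, accepted = TRUE,
               mean_csa_um2 = mean(morpho$csa_um2),
               median_csa_um2 = stats::median(morpho$csa_um2))
  if ("cnf" %in% features) {
    smry$pct_cnf <- 100 * mean(res$cnf$is_cnf)
    d <- res$cnf_dist
    smry$pct_cn0 <- d[["0"]]; smry$pct_cn1 <- d[["1"]]
    smry$pct_cn2 <- d[["2"]]; smry$pct_cn3plus <- d[["3+"]]
    smry$mean_peripheral_nuclei <- mean(res$cnf$n_peripheral)
  }
  if ("satellites" %in% features)
    smry$satellites_per_mm2 <- res$satellites_per_mm2
  if ("vessels" %in% features) {
    smry$vessels_per_mm2 <- res$vessels$density_per_mm2
    smry$vessel_pct_area <- res$vessels$pct_area
  }
  if ("typing" %in% features) {
    td <- res$type_dist
    for (lv in TYPE_LEVELS)
      smry[[paste0("pct_type_", lv)]] <- td[[lv]]
    for (st in stains)
      smry[[paste0("threshold_", st)]] <- res$thresholds[[st]]$threshold
  }
  res$summary <- smry
  res
}

#' @export
print.section_analysis <- function(x, ...) {
  cat(sprintf("section_analysis of %s: %d fibers, QC ratio %.3f (%s)\n",
              x$summary$image %||% "?", x$map$n_fibers,
              x$qc$fiber_area_ratio,
              if (x$qc$accepted) "accepted" else "rejected"))
  invisible(x)
}
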