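# hand-built scene: one disc fiber, constructed Pax7 blobs with exact
# overlap fractions against a synthetic nuclei mask
local_scene <- function() {
  cached("cell_scene", {
    d <- disc_mask(161, 70)
    map <- toy_map(matrix(as.integer(d), 161, 161))
    morpho <- measure_all_fibers(map)
    rois <- build_all_rois(map, morpho)
    list(map = map, rois = rois)
  })
}

mk_pax7 <- function(scene, r0, c0, blob_px = 100L) {
  labels <- matrix(0L, 161, 161)
  # 10 x 10 px blob
  labels[r0:(r0 + 9), c0:(c0 + 9)] <- 1L
  cent <- c(r0 + 4.5, c0 + 4.5)
  objects <- data.frame(object_id = 1L, role = "pax7", area_um2 = 25,
                        gc_x_um = (cent[2] - 1) * TEST_SCALE,
                        gc_y_um = (cent[1] - 1) * TEST_SCALE,
                        mean_intensity = 1)
  list(objects = objects, labels = labels)
}

test_that("the 90% Pax7/DAPI overlap rule decides acceptance", {
  sc <- local_scene()
  # blob sits in the sub-laminal annulus (radius ~60 px from center 81,81)
  pax <- mk_pax7(sc, 76, 136)
  nmask95 <- pax$labels > 0L
  nmask95[76, 136:140] <- FALSE  # cover 95 of 100 px
  out <- call_satellites(pax, nmask95, sc$rois, sc$map)
  expect_equal(out$overlap_fraction, 0.95)
  expect_true(out$accepted)
  expect_equal(out$fiber_id, 1L)

  nmask80 <- pax$labels > 0L
  nmask80[76:79, 136:140] <- FALSE  # cover 80 of 100 px
  out80 <- call_satellites(pax, nmask80, sc$rois, sc$map)
  expect_equal(out80$overlap_fraction, 0.80)
  expect_false(out80$accepted)

  # full overlap but centroid in the central zone: not sub-laminal
  pax_c <- mk_pax7(sc, 77, 77)
  outc <- call_satellites(pax_c, pax_c$labels > 0L, sc$rois, sc$map)
  expect_equal(outc$overlap_fraction, 1)
  expect_false(outc$accepted)
  expect_true(is.na(outc$fiber_id))
})

an_cells <- function() {
  cached("an_cells", {
    g <- std_section(41, n_fibers = 80,
                     channels = c("laminin", "dapi", "pax7", "cd31"))
    analyze_section(g$section,
                    features = c("morphometry", "cnf", "satellites",
                                 "vessels"),
                    params = TEST_PARAMS())
  })
}

test_that("lowering the overlap threshold never loses satellites", {
  an <- an_cells()
  pax <- list(objects = an$satellites[names(an$satellites) %in%
                                        c("object_id", "role", "area_um2",
                                          "gc_x_um", "gc_y_um",
                                          "mean_intensity")],
              labels = NULL)
  prev <- -1
  for (thr in c(0.99, 0.9, 0.5, 0.1)) {
    n_acc <- sum(an$satellites$overlap_fraction >= thr &
                 !is.na(an$satellites$fiber_id))
    expect_gte(n_acc, prev)
    prev <- n_acc
  }
})

test_that("planted satellite and vessel densities are recovered", {
  g <- std_section(41, n_fibers = 80,
                   channels = c("laminin", "dapi", "pax7", "cd31"))
  an <- an_cells()
  area_mm2 <- sum(an$map$section_mask) * (TEST_SCALE / 1000)^2
  sat_truth <- sum(g$truth$fibers$n_satellites) / area_mm2
  ves_truth <- sum(g$truth$fibers$n_vessels) / area_mm2
  expect_lt(abs(an$summary$satellites_per_mm2 - sat_truth) / sat_truth, 0.1)
  expect_lt(abs(an$summary$vessels_per_mm2 - ves_truth) / ves_truth, 0.1)
})

test_that("vessel pct_area recovers a painted fraction within 0.5 points", {
  g <- std_section(21, n_fibers = 60, channels = "laminin")
  an <- std_analysis(21, n_fibers = 60, channels = "laminin",
                     features = "morphometry")
  set.seed(99)
  cd <- matrix(0, nrow(an$map$labels), ncol(an$map$labels))
  idx <- which(an$map$section_mask)
  ctr <- idx[sample.int(length(idx), 120)]
  cd <- musclehca:::cpp_draw_discs(cd, (ctr - 1) %% nrow(cd) + 1,
                                   (ctr - 1) %/% nrow(cd) + 1,
                                   rep(3.2, 120), rep(0.9, 120))
  painted <- cd > 0
  truth_pct <- 100 * sum(painted & an$map$section_mask) /
    sum(an$map$section_mask)
  det <- detect_marker_objects(round(cd * 65535), TEST_SCALE, "cd31")
  vm <- quantify_vessels(det, an$rois, an$map)
  expect_lt(abs(vm$pct_area - truth_pct), 0.5)
  expect_gte(vm$density_per_mm2, 0)
})

test_that("vessels count per fiber via the peri-fiber band", {
  # three isolated disc fibers, 4 CD31 blobs ringed around each
  n <- 300
  lab <- matrix(0L, n, n)
  centers <- list(c(70, 70), c(70, 210), c(200, 140))
  for (k in 1:3) lab[disc_mask(n, 45, centers[[k]][1], centers[[k]][2])] <-
    as.integer(k)
  map <- toy_map(lab)
  morpho <- measure_all_fibers(map)
  rois <- build_all_rois(map, morpho)
  cd <- matrix(0, n, n)
  rr <- numeric(0); cc <- numeric(0)
  for (k in 1:3) for (a in c(0, pi / 2, pi, 3 * pi / 2)) {
    rr <- c(rr, centers[[k]][1] + 49 * sin(a))
    cc <- c(cc, centers[[k]][2] + 49 * cos(a))
  }
  cd <- musclehca:::cpp_draw_discs(cd, rr, cc, rep(3, 12), rep(0.9, 12))
  det <- detect_marker_objects(round(cd * 65535), TEST_SCALE, "cd31")
  expect_equal(nrow(det$objects), 12L)
  vm <- quantify_vessels(det, rois, map)
  expect_equal(vm$per_fiber_counts$n_vessels, rep(4L, 3))
  # an object inside a fiber contributes to density but no per-fiber count
  cd2 <- musclehca:::cpp_draw_discs(cd, centers[[1]][1], centers[[1]][2],
                                    3, 0.9)
  det2 <- detect_marker_objects(round(cd2 * 65535), TEST_SCALE, "cd31")
  vm2 <- quantify_vessels(det2, rois, map)
  expect_equal(nrow(det2$objects), 13L)
  expect_equal(vm2$per_fiber_counts$n_vessels, rep(4L, 3))
  expect_gt(vm2$density_per_mm2, vm$density_per_mm2)
})

test_that("marker blobs below the area floor are excluded", {
  img <- matrix(0, 100, 100)
  img <- musclehca:::cpp_draw_discs(img, c(30, 70), c(30, 70), c(4, 1.5),
                                    c(0.9, 0.9))
  det <- detect_marker_objects(round(img * 65535), TEST_SCALE, "pax7",
                               min_area_um2 = 8)
  expect_equal(nrow(det$objects), 1L)  # the 1.5 px blob is ~1.8 um2
  expect_equal(nrow(detect_marker_objects(matrix(0, 50, 50), TEST_SCALE,
                                          "cd31")$objects), 0L)
})

test_that("satellite-vessel distances match the brute-force minimum", {
  sat <- data.frame(object_id = 1L, gc_x_um = 0, gc_y_um = 0,
                    accepted = TRUE)
  ves <- data.frame(gc_x_um = c(3, 10), gc_y_um = c(4, 0))
  expect_equal(satellite_vessel_distances(sat, ves)$min_dist_um, 5)
  ves0 <- data.frame(gc_x_um = 0, gc_y_um = 0)
  expect_equal(satellite_vessel_distances(sat, ves0)$min_dist_um, 0)
  expect_true(is.na(satellite_vessel_distances(
    sat, data.frame(gc_x_um = numeric(0), gc_y_um = numeric(0)))$min_dist_um))
  set.seed(5)
  sats <- data.frame(object_id = 1:20, gc_x_um = runif(20, 0, 500),
                     gc_y_um = runif(20, 0, 500), accepted = TRUE)
  vess <- data.frame(gc_x_um = runif(30, 0, 500),
                     gc_y_um = runif(30, 0, 500))
  got <- satellite_vessel_distances(sats, vess)$min_dist_um
  brute <- vapply(1:20, function(i)
    min(sqrt((vess$gc_x_um - sats$gc_x_um[i])^2 +
             (vess$gc_y_um - sats$gc_y_um[i])^2)), numeric(1))
  expect_equal(got, brute)
})
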