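test_that("detect_nuclei on a blank channel returns an empty list", {
  out <- detect_nuclei(matrix(3, 100, 100), TEST_SCALE)
  expect_equal(nrow(out$objects), 0L)
  expect_true(all(out$labels == 0L))
})

test_that("planted nuclei are recovered in count and position", {
  g <- std_section(22, n_fibers = 100, cnf_fraction = 0.3)
  nuc <- detect_nuclei(g$section$channels$dapi, TEST_SCALE)
  truth <- g$truth$objects[grepl("^nucleus", g$truth$objects$kind), ]
  expect_gt(nrow(truth), 300)
  expect_lt(abs(nrow(nuc$objects) - nrow(truth)) / nrow(truth), 0.02)
  # nearest-planted centroid error below 1 um
  err <- vapply(seq_len(nrow(nuc$objects)), function(i) {
    min(sqrt((truth$x_um - nuc$objects$gc_x_um[i])^2 +
             (truth$y_um - nuc$objects$gc_y_um[i])^2))
  }, numeric(1))
  expect_lt(stats::median(err), 1)
  expect_lt(mean(err > 1), 0.02)
})

test_that("a dumbbell of two fused nuclei is split by the watershed", {
  img <- matrix(0, 80, 80)
  img <- musclehca:::cpp_draw_discs(img, c(40, 40), c(30, 48), c(6, 6),
                                    c(0.9, 0.9))
  img <- round(pmin(img, 1) * 65535)
  out <- detect_nuclei(img, TEST_SCALE, min_area_um2 = 5)
  expect_equal(nrow(out$objects), 2L)
})

test_that("classify_cnf assigns nuclei by centroid containment", {
  # one disc fiber; nuclei planted by hand in each zone
  d <- disc_mask(161, 70)
  map <- toy_map(matrix(as.integer(d), 161, 161))
  morpho <- measure_all_fibers(map)
  rois <- build_all_rois(map, morpho)
  mk_obj <- function(r, c) data.frame(object_id = 1L, role = "dapi",
                                      area_um2 = 20,
                                      gc_x_um = (c - 1) * TEST_SCALE,
                                      gc_y_um = (r - 1) * TEST_SCALE,
                                      mean_intensity = 1)
  nuc_center <- list(objects = mk_obj(81, 81))
  nuc_edge <- list(objects = mk_obj(81, 81 + 65))   # annulus, inside fiber
  nuc_out <- list(objects = mk_obj(5, 5))           # outside every fiber
  r1 <- classify_cnf(nuc_center, rois, map)
  expect_equal(r1$n_centronuclei, 1L)
  expect_true(r1$is_cnf)
  r2 <- classify_cnf(nuc_edge, rois, map)
  expect_equal(r2$n_peripheral, 1L)
  expect_equal(r2$n_centronuclei, 0L)
  expect_false(r2$is_cnf)
  r3 <- classify_cnf(nuc_out, rois, map)
  expect_equal(attr(r3, "n_interstitial"), 1L)
  expect_equal(r3$n_centronuclei + r3$n_peripheral, 0L)
})

test_that("planted centronucleation fraction is recovered", {
  fracs <- numeric(0)
  for (seed in 23:27) {
    g <- std_section(seed, n_fibers = 60, cnf_fraction = 0.3)
    an <- std_analysis(seed, n_fibers = 60, cnf_fraction = 0.3)
    truth_frac <- mean(g$truth$fibers$n_central > 0)
    m <- match_labels(g$truth$labels, an$map$labels)
    fracs <- c(fracs, mean(an$cnf$is_cnf) - truth_frac)
  }
  expect_lt(max(abs(fracs)), 0.02)
})

test_that("cnf_distribution tallies the four bins", {
  mk <- function(counts) data.frame(fiber_id = seq_along(counts),
                                    n_centronuclei = counts,
                                    n_peripheral = 0L,
                                    is_cnf = counts >= 1)
  expect_equal(unname(cnf_distribution(mk(rep(0L, 8)))), c(100, 0, 0, 0))
  expect_equal(unname(cnf_distribution(mk(c(0L, 1L, 1L, 2L, 5L)))),
               c(20, 40, 20, 20))
  expect_equal(sum(cnf_distribution(mk(c(0L, 3L, 7L)))), 100)
  empty <- data.frame(fiber_id = integer(0), n_centronuclei = integer(0),
                      n_peripheral = integer(0), is_cnf = logical(0))
  expect_error(cnf_distribution(empty), "empty")
})

test_that("assigned nuclei never exceed detected nuclei", {
  an <- std_analysis(22, n_fibers = 100, cnf_fraction = 0.3)
  expect_lte(sum(an$cnf$n_centronuclei) + sum(an$cnf$n_peripheral),
             nrow(an$nuclei$objects))
})

test_that("percent CNF is invariant under 90-degree rotation", {
  g <- std_section(28, n_fibers = 40, cnf_fraction = 0.4)
  an <- analyze_section(g$section, features = c("morphometry", "cnf"),
                        params = TEST_PARAMS())
  an_rot <- analyze_section(rot90_section(g$section),
                            features = c("morphometry", "cnf"),
                            params = TEST_PARAMS())
  expect_equal(an_rot$map$n_fibers, an$map$n_fibers)
  expect_equal(mean(an_rot$cnf$is_cnf), mean(an$cnf$is_cnf))
  expect_equal(sum(an_rot$cnf$n_centronuclei), sum(an$cnf$n_centronuclei))
})
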