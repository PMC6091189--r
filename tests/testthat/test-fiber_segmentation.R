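test_that("pretreat removes flat background and is offset-invariant", {
  expect_equal(pretreat(matrix(5, 60, 60)), matrix(0, 60, 60))
  expect_error(pretreat(array(0, c(3, 3, 3))), "2-D")
  set.seed(11)
  img <- matrix(runif(90 * 90), 90, 90)
  img[40:44, ] <- img[40:44, ] + 3  # a bright wall
  # constant offsets vanish in the background subtraction, exactly
  expect_equal(pretreat(img, rolling_ball_radius_px = 20),
               pretreat(img + 137.5, rolling_ball_radius_px = 20))
})

test_that("pretreat increases wall/interior contrast under uneven light", {
  # vertical walls every 30 px + strong left-right illumination gradient
  n <- 180
  img <- matrix(0.1, n, n)
  wall <- (seq_len(n) %% 30) < 3
  img[, wall] <- 0.5
  grad <- matrix(seq(0.2, 1, length.out = n), n, n, byrow = TRUE)
  raw <- img * grad + 0.3
  michelson <- function(m) {
    wv <- mean(m[, wall]); iv <- mean(m[, !wall])
    (wv - iv) / (wv + iv)
  }
  out <- pretreat(raw, rolling_ball_radius_px = 10)
  expect_gt(michelson(out), michelson(raw))
})

test_that("segment_fibers recovers a single drawn rectangular fiber", {
  img <- matrix(0, 200, 200)
  img[60:140, 50:150] <- 1     # filled wall block
  img[64:136, 54:146] <- 0.02  # interior carved out; 4 px wall
  map <- segment_fibers(pretreat(img, rolling_ball_radius_px = 60),
                        scale_um_per_px = 0.5)
  expect_equal(map$n_fibers, 1L)
  interior_px <- 73 * 93
  expect_lt(abs(sum(map$labels == 1L) - interior_px) / interior_px, 0.15)
  # deterministic
  map2 <- segment_fibers(pretreat(img, rolling_ball_radius_px = 60),
                         scale_um_per_px = 0.5)
  expect_identical(map$labels, map2$labels)
})

test_that("segment_fibers errors on empty input", {
  expect_error(segment_fibers(matrix(0, 50, 50), 0.5), "no tissue")
})

test_that("clean synthetic tessellation is segmented one-to-one", {
  g <- std_section(21, n_fibers = 60, channels = "laminin")
  an <- std_analysis(21, n_fibers = 60, channels = "laminin",
                     features = "morphometry")
  m <- match_labels(g$truth$labels, an$map$labels, iou_min = 0.8)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
  # every matched fiber overlaps its truth cell strongly
  expect_gte(min(m$matches$iou), 0.8)
})

test_that("qc_section applies the area-ratio rule", {
  lab <- matrix(0L, 40, 40)
  lab[1:38, 1:40] <- 1L   # 95% of the frame
  map <- toy_map(lab, section_mask = matrix(TRUE, 40, 40))
  qc <- qc_section(map, artifact_tolerance = 0.10)
  expect_equal(qc$fiber_area_ratio, 0.95)
  expect_true(qc$accepted)
  lab2 <- matrix(0L, 40, 40)
  lab2[1:32, 1:40] <- 1L  # 80%
  expect_false(qc_section(toy_map(lab2, matrix(TRUE, 40, 40)), 0.10)$accepted)
  empty <- toy_map(matrix(0L, 4, 4), matrix(FALSE, 4, 4))
  expect_error(qc_section(empty), "zero section area")
})

test_that("qc_fibers removes mean + 3 SD outliers (direct arithmetic)", {
  # 100 fibers of 100 um2 + one of 5000: mean 148.51, SD 487.57,
  # cutoff 1611.23 -> only the 5000 um2 fiber goes
  csa <- c(rep(100, 100), 5000)
  expect_equal(mean(csa) + 3 * sd(csa), 1611.235, tolerance = 1e-4)
  lab <- matrix(0L, 30, 500)
  for (k in seq_along(csa)) lab[5:14, (4 * (k - 1) + 1):(4 * k - 1)] <- k
  map <- toy_map(lab)
  out <- qc_fibers(map, csa)
  expect_equal(out$excluded$fiber_id, 101L)
  expect_equal(out$excluded$reason, "csa_outlier")
  expect_equal(out$n_fibers, 100L)
  expect_equal(out$qc_csa$cutoff, 1611.235, tolerance = 1e-4)
  # labels are compacted and consecutive
  expect_equal(sort(unique(as.vector(out$labels[out$labels > 0]))), 1:100)
})

test_that("qc_fibers keeps homogeneous sections intact", {
  lab <- matrix(0L, 20, 40)
  for (k in 1:5) lab[3:10, (7 * (k - 1) + 1):(7 * k - 2)] <- k
  map <- toy_map(lab)
  # zero variance: nothing exceeds mean + 3 * 0
  expect_equal(qc_fibers(map, rep(100, 5))$n_fibers, 5L)
  # spec's five-fiber case: cutoff 138.5 exceeds the max of 120
  out <- qc_fibers(map, c(100, 110, 90, 105, 120))
  expect_equal(out$n_fibers, 5L)
  expect_equal(nrow(out$excluded), 0L)
  # fewer than 2 fibers: warning, no-op
  one <- toy_map(matrix(c(0L, 1L), 2, 2))
  expect_warning(qc_fibers(one, 100), "fewer than 2")
})

test_that("qc_fibers never removes a fiber at or below the section mean", {
  set.seed(7)
  for (i in 1:25) {
    csa <- rlnorm(50, log(1000), 0.8)
    n <- length(csa)
    lab <- matrix(0L, 10, 3 * n + 2)
    for (k in seq_len(n)) lab[2:8, (3 * (k - 1) + 1):(3 * k - 1)] <- k
    out <- qc_fibers(toy_map(lab), csa)
    if (nrow(out$excluded)) expect_true(all(csa[out$excluded$fiber_id] >
                                              mean(csa)))
  }
})
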