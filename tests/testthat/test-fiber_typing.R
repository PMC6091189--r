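# eight-square toy section: fiber k gets the k-th positivity subset
eight_fiber_scene <- function() {
  cached("typing_scene", {
    lab <- matrix(0L, 40, 330)
    for (k in 1:8) lab[11:30, (40 * (k - 1) + 11):(40 * (k - 1) + 30)] <-
      as.integer(k)
    map <- toy_map(lab, section_mask = matrix(TRUE, 40, 330))
    subsets <- list(integer(0), 1L, 2L, 3L, c(1L, 2L), c(1L, 3L),
                    c(2L, 3L), c(1L, 2L, 3L))
    channels <- lapply(1:3, function(ch) {
      m <- matrix(100, 40, 330)
      for (k in 1:8) if (ch %in% subsets[[k]])
        m[lab == k] <- 1000
      m
    })
    names(channels) <- c("stain1", "stain2", "stain3")
    list(map = map, channels = channels, subsets = subsets)
  })
}

test_that("compute_threshold is mode + k * MAD-sigma of the background", {
  lab <- matrix(0L, 60, 60)
  lab[20:40, 20:40] <- 1L
  map <- toy_map(lab, section_mask = matrix(TRUE, 60, 60))
  set.seed(8)
  ch <- matrix(100, 60, 60)
  bg <- map$section_mask & lab == 0L
  ch[bg] <- 100 + round(rnorm(sum(bg), 0, 10))
  thr <- compute_threshold(ch, map, snr_factor = 3)
  expect_s3_class(thr, "typing_threshold")
  bgpx <- ch[bg]
  expect_equal(thr$sigma, mad(bgpx), tolerance = 1e-9)
  expect_equal(thr$threshold, thr$background_mode + 3 * thr$sigma)
  expect_lt(abs(thr$background_mode - 100), 3)
  # uniform channel: sigma 0, threshold equals the mode
  u <- matrix(50, 60, 60)
  tu <- compute_threshold(u, map)
  expect_equal(tu$sigma, 0)
  expect_equal(tu$threshold, tu$background_mode)
})

test_that("all 8 positivity subsets map to the right type label", {
  sc <- eight_fiber_scene()
  thr <- list(stain1 = 500, stain2 = 500, stain3 = 500)
  calls <- call_types(sc$channels, thr, sc$map)
  expect_equal(calls$label,
               c("IIX", "I", "IIA", "IIB", "I-IIA", "I-IIB", "IIA-IIB",
                 "ND"))
  # labels partition the fibers
  expect_equal(sum(type_distribution(calls)), 100)
  # per-channel means are reported for every fiber
  expect_true(all(c("mean_stain1", "mean_stain2", "mean_stain3") %in%
                    names(calls)))
})

test_that("raising snr_factor shrinks (or keeps) each positive set", {
  an <- cached("an_typing", {
    g <- std_section(44, n_fibers = 80,
                     channels = c("laminin", "stain1", "stain2", "stain3"))
    analyze_section(g$section, features = c("morphometry", "typing"),
                    params = TEST_PARAMS())
  })
  map <- an$map
  g <- std_section(44, n_fibers = 80,
                   channels = c("laminin", "stain1", "stain2", "stain3"))
  for (st in c("stain1", "stain2", "stain3")) {
    prev <- NULL
    for (k in c(1, 3, 6, 12)) {
      thr <- compute_threshold(g$section$channels[[st]], map, snr_factor = k)
      calls <- call_types(g$section$channels[st], setNames(list(thr), st),
                          map)
      pos <- sum(calls[[paste0("pos_", st)]])
      if (!is.null(prev)) expect_lte(pos, prev)
      prev <- pos
    }
  }
})

test_that("typing is invariant to a constant channel offset", {
  sc <- eight_fiber_scene()
  shifted <- lapply(sc$channels, function(m) m + 500)
  thr <- lapply(sc$channels, function(m) compute_threshold(m, sc$map))
  thr_s <- lapply(shifted, function(m) compute_threshold(m, sc$map))
  c1 <- call_types(sc$channels, thr, sc$map)
  c2 <- call_types(shifted, thr_s, sc$map)
  expect_equal(c1$label, c2$label)
})

test_that("type_distribution tallies percentages", {
  calls <- data.frame(fiber_id = 1:100,
                      label = rep(c("I", "IIA", "IIB", "IIX"),
                                  c(10, 30, 40, 20)))
  td <- type_distribution(calls)
  expect_equal(unname(td[c("I", "IIA", "IIB", "IIX")]), c(10, 30, 40, 20))
  expect_equal(sum(td), 100)
  all_iix <- data.frame(fiber_id = 1:5, label = rep("IIX", 5))
  expect_equal(unname(type_distribution(all_iix)["IIX"]), 100)
  expect_error(type_distribution(calls[0, ]), "empty")
})

test_that("planted type mix is recovered through the full pipeline", {
  an <- cached("an_typing", {
    g <- std_section(44, n_fibers = 80,
                     channels = c("laminin", "stain1", "stain2", "stain3"))
    analyze_section(g$section, features = c("morphometry", "typing"),
                    params = TEST_PARAMS())
  })
  g <- std_section(44, n_fibers = 80,
                   channels = c("laminin", "stain1", "stain2", "stain3"))
  m <- match_labels(g$truth$labels, an$map$labels)
  idx <- match(m$matches$truth_id, g$truth$fibers$fiber_id)
  agree <- mean(g$truth$fibers$type[idx] ==
                  an$typing$label[m$matches$pred_id])
  expect_gte(agree, 0.98)
  # thresholds are logged per channel for the summary table
  expect_named(an$thresholds, c("stain1", "stain2", "stain3"))
})
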