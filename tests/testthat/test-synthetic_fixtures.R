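test_that("generation is seed-deterministic and leaves the RNG alone", {
  g1 <- generate_section(n_fibers = 25, channels = c("laminin", "dapi"),
                         cnf_fraction = 0.4, scale_um_per_px = 0.6,
                         seed = 12)
  set.seed(1234)
  expected_draw <- runif(1)
  set.seed(1234)
  g2 <- generate_section(n_fibers = 25, channels = c("laminin", "dapi"),
                         cnf_fraction = 0.4, scale_um_per_px = 0.6,
                         seed = 12)
  expect_identical(g1$section$channels, g2$section$channels)
  expect_identical(g1$truth$fibers, g2$truth$fibers)
  expect_identical(g1$truth$objects, g2$truth$objects)
  # caller's RNG stream is restored around the seeded generator
  expect_equal(runif(1), expected_draw)
})

test_that("cnf_fraction 0 plants no central nuclei", {
  g <- std_section(45, n_fibers = 30, cnf_fraction = 0)
  expect_equal(sum(g$truth$fibers$n_central), 0L)
  expect_false(any(g$truth$objects$kind == "nucleus_central"))
})

test_that("truth is self-consistent", {
  g <- std_section(22, n_fibers = 100, cnf_fraction = 0.3)
  obj <- g$truth$objects
  fib <- g$truth$fibers
  expect_equal(sum(fib$n_central), sum(obj$kind == "nucleus_central"))
  expect_equal(sum(fib$n_peripheral), sum(obj$kind == "nucleus_peripheral"))
  # per-fiber planted nuclei + interstitial = total planted nuclei
  expect_equal(sum(fib$n_central) + sum(fib$n_peripheral) +
                 sum(obj$kind == "nucleus_interstitial"),
               sum(grepl("^nucleus", obj$kind)))
  # planted objects respect their geometric roles
  lab_at <- g$truth$labels[cbind(round(obj$r_px), round(obj$c_px))]
  central <- obj$kind == "nucleus_central"
  expect_true(all(lab_at[central] == obj$fiber_id[central]))
  periph <- obj$kind == "nucleus_peripheral"
  expect_true(all(lab_at[periph] == obj$fiber_id[periph]))
  expect_true(all(lab_at[obj$kind == "cd31"] == 0))  # vessels on walls
})

test_that("planted mean CSA tracks the requested mean at n >= 100", {
  g <- cached("sec_csa150", generate_section(n_fibers = 150,
                                             mean_csa_um2 = 1500,
                                             channels = "laminin",
                                             scale_um_per_px = TEST_SCALE,
                                             seed = 77))
  expect_lt(abs(mean(g$truth$fibers$csa_um2) - 1500) / 1500, 0.05)
})

test_that("infeasible parameters are refused", {
  expect_error(generate_section(n_fibers = 10, mean_csa_um2 = 100,
                                channels = c("laminin", "dapi")),
               "infeasible")
  expect_error(generate_section(channels = c("dapi")), "laminin")
})

test_that("degrade severity 0 is the identity", {
  g <- std_section(45, n_fibers = 30, cnf_fraction = 0)
  expect_identical(degrade(g$section, "broken_walls", 0), g$section)
})

test_that("broken walls lower the QC ratio by about the severity", {
  g <- std_section(46, n_fibers = 80, channels = "laminin")
  bad <- degrade(g$section, "broken_walls", 0.20, seed = 3)
  an_ok <- analyze_section(g$section, features = "morphometry",
                           params = TEST_PARAMS())
  map_bad <- segment_fibers(pretreat(bad$channels$laminin), TEST_SCALE)
  qc_bad <- qc_section(map_bad, 0.25)
  drop <- an_ok$qc$fiber_area_ratio - qc_bad$fiber_area_ratio
  # patches destroy fiber area in proportion to the fiber fraction of the
  # tissue, so the expected ratio drop is severity x baseline ratio
  expect_lt(abs(drop - 0.20 * an_ok$qc$fiber_area_ratio), 0.05)
})

test_that("debris does not change the fiber count", {
  g <- std_section(45, n_fibers = 30, cnf_fraction = 0)
  deb <- degrade(g$section, "debris", 0.5, seed = 2)
  an0 <- analyze_section(g$section, features = "morphometry",
                         params = TEST_PARAMS())
  an1 <- analyze_section(deb, features = "morphometry",
                         params = TEST_PARAMS(artifact_tolerance = 0.5))
  expect_equal(an1$map$n_fibers, an0$map$n_fibers)
  expect_error(degrade(g$section, "nonsense", 0.1))
})

test_that("uneven illumination is survivable by the pretreatment", {
  g <- std_section(45, n_fibers = 30, cnf_fraction = 0)
  un <- degrade(g$section, "uneven_illumination", 0.4, seed = 2)
  an0 <- analyze_section(g$section, features = "morphometry",
                         params = TEST_PARAMS())
  an1 <- analyze_section(un, features = "morphometry",
                         params = TEST_PARAMS())
  expect_lt(abs(an1$map$n_fibers - an0$map$n_fibers), 3)
})
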