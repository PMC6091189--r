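# three-square toy map reused for color tests; pixel at each fiber's
# center is sampled from the rendered RGB array
carto_map <- function(n_fib = 3) {
  lab <- matrix(0L, 30, 40 * n_fib)
  for (k in seq_len(n_fib))
    lab[8:22, (40 * (k - 1) + 10):(40 * (k - 1) + 30)] <- as.integer(k)
  toy_map(lab, section_mask = lab >= 0L)
}

center_rgb <- function(img, k) img[15, 40 * (k - 1) + 20, ]

hex2rgb <- function(hex) as.numeric(grDevices::col2rgb(hex))

test_that("centronuclei classes follow the 0/1/2/3+ color scale", {
  map <- carto_map(5)
  spec <- cartography_spec("centronuclei", legend = FALSE)
  img <- render_cartography(map, c(0, 1, 2, 3, 7), spec)
  pal <- spec$palette
  for (k in 1:4) expect_equal(center_rgb(img, k), hex2rgb(pal[k]))
  expect_equal(center_rgb(img, 5), hex2rgb(pal[4]))  # >= 3 stays red
})

test_that("vessel classes cover 0-1 / 2-3 / 4-5 / 6-7 / 8-9 / >9", {
  map <- carto_map(6)
  spec <- cartography_spec("vessels", legend = FALSE)
  vals <- c(0, 1, 2, 3, 4, 5)
  img <- render_cartography(map, c(0, 2, 4, 7, 9, 12), spec)
  expect_equal(center_rgb(img, 1), hex2rgb(spec$palette[1]))
  expect_equal(center_rgb(img, 2), hex2rgb(spec$palette[2]))
  expect_equal(center_rgb(img, 3), hex2rgb(spec$palette[3]))
  expect_equal(center_rgb(img, 4), hex2rgb(spec$palette[4]))  # 7 -> 6-7
  expect_equal(center_rgb(img, 5), hex2rgb(spec$palette[5]))  # 9 -> 8-9
  expect_equal(center_rgb(img, 6), hex2rgb(spec$palette[6]))  # 12 -> >9
  # boundary: 1 is still class 1, 10 is class 6
  img2 <- render_cartography(map, c(1, 3, 5, 6, 8, 10), spec)
  expect_equal(center_rgb(img2, 1), hex2rgb(spec$palette[1]))
  expect_equal(center_rgb(img2, 4), hex2rgb(spec$palette[4]))
  expect_equal(center_rgb(img2, 6), hex2rgb(spec$palette[6]))
})

test_that("satellite classes are 0 / 1 / more-than-one", {
  map <- carto_map(4)
  spec <- cartography_spec("satellites", legend = FALSE)
  img <- render_cartography(map, c(0, 1, 2, 5), spec)
  expect_equal(center_rgb(img, 1), hex2rgb(spec$palette[1]))
  expect_equal(center_rgb(img, 2), hex2rgb(spec$palette[2]))
  expect_equal(center_rgb(img, 3), hex2rgb(spec$palette[3]))
  expect_equal(center_rgb(img, 4), hex2rgb(spec$palette[3]))
})

test_that("equal CSA means equal green; missing values go no-data gray", {
  map <- carto_map(3)
  spec <- cartography_spec("csa", legend = FALSE)
  img <- render_cartography(map, c(800, 800, 2000), spec)
  expect_equal(center_rgb(img, 1), center_rgb(img, 2))
  expect_warning(img2 <- render_cartography(map, c(800, NA, 2000), spec),
                 "no-data")
  expect_equal(center_rgb(img2, 2), hex2rgb("#BDBDBD"))
})

test_that("fiber types render categorically; walls and background differ", {
  map <- carto_map(3)
  spec <- cartography_spec("fibertype", legend = FALSE)
  img <- render_cartography(map, c("I", "IIX", "ND"), spec)
  expect_equal(center_rgb(img, 1), hex2rgb(spec$palette[["I"]]))
  expect_equal(center_rgb(img, 2), hex2rgb(spec$palette[["IIX"]]))
  expect_equal(center_rgb(img, 3), hex2rgb(spec$palette[["ND"]]))
  expect_equal(img[2, 2, ], hex2rgb("#303030"))  # in-section non-fiber
})

test_that("rendering is deterministic and the legend matches the classes", {
  an <- std_analysis(21, n_fibers = 60, channels = "laminin",
                     features = "morphometry")
  spec <- cartography_spec("csa", legend = TRUE)
  img1 <- render_cartography(an$map, an$morpho$csa_um2, spec)
  img2 <- render_cartography(an$map, an$morpho$csa_um2, spec)
  expect_identical(img1, img2)
  sw <- attr(img1, "legend_swatches")
  expect_equal(nrow(sw), length(spec$palette))
  for (i in seq_len(nrow(sw))) {
    if (is.na(sw$r[i])) next
    expect_equal(img1[round(sw$r[i]), round(sw$c[i]), ],
                 hex2rgb(spec$palette[i]))
  }
  # written PNG round-trips bit-identically on re-render
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_cartography(img1, p1)
  write_cartography(img2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  magic <- readBin(p1, "raw", 8)
  expect_identical(magic, as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A,
                                   0x1A, 0x0A)))
})

test_that("cartography_spec validates class edges and palette override", {
  expect_error(cartography_spec("csa", class_edges = c(3, 2, 1)),
               "increasing")
  sp <- cartography_spec("centronuclei",
                         palette = c("#000000", "#111111", "#222222",
                                     "#333333"), legend = FALSE)
  map <- carto_map(1)
  img <- render_cartography(map, 2, sp)
  expect_equal(center_rgb(img, 1), hex2rgb("#222222"))
})
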