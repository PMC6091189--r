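# In situ cartographies: the section repainted so each fiber's color
# encodes a measured class, with optional burned-in legend.

#' Cartography palettes
#'
#' Fixed default palettes per cartography kind: an 8-step light-to-dark
#' green scale for CSA octiles; white/yellow/orange/red for 0/1/2/3+
#' centronuclei; six light-to-dark purples for the vessel classes
#' (0-1, 2-3, 4-5, 6-7, 8-9, >9); white/light-pink/dark-pink for 0/1/>1
#' satellite cells; a categorical palette over fiber types. Overridable via
#' [cartography_spec()].
#' @name cartography_palettes
NULL

PALETTES <- list(
  csa = c("#E9F7E6", "#CDEBC6", "#AEDCA4", "#8CCB82", "#68B763",
          "#45A047", "#2A7F32", "#145A20"),
  centronuclei = c("#FFFFFF", "#FFE633", "#FF9A1F", "#D92B1C"),
  vessels = c("#F4E9F7", "#DDC3E7", "#C099D4", "#9F6BBE", "#7B3FA4",
              "#4E1778"),
  satellites = c("#FFFFFF", "#F7BBD3", "#C2176B"),
  fibertype = c(I = "#2C4EA0", IIA = "#3FA0C8", IIB = "#D92B1C",
                IIX = "#E8E8E8", `I-IIA` = "#7DC87D", `I-IIB` = "#F2A03C",
                `IIA-IIB` = "#B05CC6", ND = "#606060")
)

NO_DATA_COL <- "#BDBDBD"
WALL_COL <- "#303030"
BG_COL <- "#FFFFFF"

#' Cartography specification
#'
#' @param kind one of \code{csa}, \code{centronuclei}, \code{vessels},
#'   \code{satellites}, \code{fibertype}.
#' @param palette optional color vector overriding the default; length must
#'   equal the number of classes.
#' @param legend burn a legend strip with one swatch per class.
#' @param class_edges for \code{kind = "csa"} only: explicit increasing bin
#'   edges; by default the within-section octiles are used.
#' @return object of class \code{cartography_spec}.
#' @export
cartography_spec <- function(kind = c("csa", "centronuclei", "vessels",
                                      "satellites", "fibertype"),
                             palette = NULL, legend = TRUE,
                             class_edges = NULL) {
  kind <- match.arg(kind)
  palette <- palette %||% PALETTES[[kind]]
  if (!is.null(class_edges) && any(diff(class_edges) <= 0))
    stop_mhca("class_edges must be strictly increasing")
  structure(list(kind = kind, palette = palette, legend = legend,
                 class_edges = class_edges),
            class = "cartography_spec")
}

# class index (1-based into palette) of each value; NA -> no-data
carto_class <- function(values, spec) {
  switch(spec$kind,
    centronuclei = ifelse(is.na(values), NA, pmin(values, 3) + 1),
    vessels = ifelse(is.na(values), NA, pmin(values %/% 2, 5) + 1),
    satellites = ifelse(is.na(values), NA, pmin(values, 2) + 1),
    csa = {
      edges <- spec$class_edges %||%
        unique(stats::quantile(values, probs = seq(0, 1, 1 / 8),
                               na.rm = TRUE, names = FALSE))
      if (length(edges) < 2) edges <- c(edges, edges + 1)
      findInterval(values, edges, rightmost.closed = TRUE,
                   all.inside = TRUE)
    },
    fibertype = {
      i <- match(values, names(spec$palette))
      i
    })
}

carto_class_labels <- function(spec, values = NULL) {
  switch(spec$kind,
    centronuclei = c("0", "1", "2", "3+"),
    vessels = c("0-1", "2-3", "4-5", "6-7", "8-9", ">9"),
    satellites = c("0", "1", ">1"),
    csa = paste0("Q", seq_len(length(spec$palette))),
    fibertype = names(spec$palette))
}

# ---------------------------------------------------------------------------
# 5x7 bitmap font for legend labels (digits, the letters used by class
# labels, and separators). '#' = on.
FONT5x7 <- list(
  "0" = c("01110","10001","10011","10101","11001","10001","01110"),
  "1" = c("00100","01100","00100","00100","00100","00100","01110"),
  "2" = c("01110","10001","00001","00010","00100","01000","11111"),
  "3" = c("11110","00001","00001","01110","00001","00001","11110"),
  "4" = c("00010","00110","01010","10010","11111","00010","00010"),
  "5" = c("11111","10000","11110","00001","00001","10001","01110"),
  "6" = c("00110","01000","10000","11110","10001","10001","01110"),
  "7" = c("11111","00001","00010","00100","01000","01000","01000"),
  "8" = c("01110","10001","10001","01110","10001","10001","01110"),
  "9" = c("01110","10001","10001","01111","00001","00010","01100"),
  "A" = c("01110","10001","10001","11111","10001","10001","10001"),
  "B" = c("11110","10001","10001","11110","10001","10001","11110"),
  "D" = c("11110","10001","10001","10001","10001","10001","11110"),
  "I" = c("01110","00100","00100","00100","00100","00100","01110"),
  "N" = c("10001","11001","10101","10011","10001","10001","10001"),
  "Q" = c("01110","10001","10001","10001","10101","10010","01101"),
  "X" = c("10001","10001","01010","00100","01010","10001","10001"),
  "-" = c("00000","00000","00000","01110","00000","00000","00000"),
  "+" = c("00000","00100","00100","11111","00100","00100","00000"),
  ">" = c("01000","00100","00010","00100","01000","00000","00000"),
  " " = c("00000","00000","00000","00000","00000","00000","00000")
)

draw_text <- function(img, text, r0, c0, col_rgb) {
  chars <- strsplit(toupper(text), "")[[1]]
  c_at <- c0
  for (ch in chars) {
    glyph <- FONT5x7[[ch]]
    if (!is.null(glyph)) {
      for (gr in 1:7) {
        bits <- strsplit(glyph[gr], "")[[1]] == "1"
        for (gc in which(bits)) {
          rr <- r0 + gr - 1L; cc <- c_at + gc - 1L
          if (rr >= 1 && rr <= dim(img)[1] && cc >= 1 && cc <= dim(img)[2])
            img[rr, cc, ] <- col_rgb
        }
      }
    }
    c_at <- c_at + 6L
  }
  img
}

#' Render an in situ cartography
#'
#' Repaints the section so each fiber's mask takes the color of its class;
#' walls and interstitium are dark gray, the area outside the section is
#' white, and fibers with a missing value are painted a distinct no-data
#' gray (and reported via a warning). When \code{spec$legend} is TRUE a
#' legend strip with one labeled swatch per class is appended on the right;
#' swatch positions are returned in \code{attr(, "legend_swatches")}.
#'
#' Color lookup is a pure function of (value, spec), so re-rendering is
#' bit-identical.
#'
#' @param map [segment_fibers()] output.
#' @param values per-fiber values ordered by fiber id: counts for
#'   \code{centronuclei}/\code{vessels}/\code{satellites}, um^2 for
#'   \code{csa}, type labels for \code{fibertype}.
#' @param spec [cartography_spec()].
#' @return \code{h x w' x 3} numeric array of 0-255 RGB values, with
#'   attributes \code{classes} (per-fiber class index) and, if legended,
#'   \code{legend_swatches}.
#' @export
render_cartography <- function(map, values, spec) {
  if (length(values) != map$n_fibers)
    stop_mhca("need one value per fiber (%d != %d)", length(values),
              map$n_fibers)
  cls <- carto_class(values, spec)
  if (anyNA(cls))
    warning(sprintf("%d fiber(s) without a value painted no-data gray",
                    sum(is.na(cls))))
  pal_rgb <- t(grDevices::col2rgb(spec$palette))
  nd_rgb <- as.numeric(grDevices::col2rgb(NO_DATA_COL))
  wall_rgb <- as.numeric(grDevices::col2rgb(WALL_COL))
  bg_rgb <- as.numeric(grDevices::col2rgb(BG_COL))
  h <- nrow(map$labels); w <- ncol(map$labels)
  img <- array(0, c(h, w, 3))
  lab <- map$labels
  # per-label color lookup, 0 = non-fiber
  for (k in 1:3) {
    lut <- ifelse(is.na(cls), nd_rgb[k], pal_rgb[cls, k])
    plane <- matrix(bg_rgb[k], h, w)
    plane[map$section_mask] <- wall_rgb[k]
    fib <- lab > 0L
    plane[fib] <- lut[lab[fib]]
    img[, , k] <- plane
  }
  if (isTRUE(spec$legend)) {
    labels <- carto_class_labels(spec)
    n_cls <- length(spec$palette)
    strip_w <- 24L + 6L * (max(nchar(labels)) + 1L)
    leg <- array(255, c(h, strip_w, 3))
    sw <- 14L; gap <- 6L
    swatches <- data.frame(class = seq_len(n_cls), r = NA_real_, c = NA_real_)
    for (i in seq_len(n_cls)) {
      r0 <- gap + (i - 1L) * (sw + gap) + 1L
      if (r0 + sw - 1L > h) break
      leg[r0:(r0 + sw - 1L), 3:(2L + sw), ] <-
        rep(pal_rgb[i, ], each = sw * sw)
      swatches$r[i] <- r0 + sw / 2
      swatches$c[i] <- w + 2L + sw / 2
      leg <- draw_text(leg, labels[i], r0 + 3L, sw + 6L, c(0, 0, 0))
    }
    full <- array(0, c(h, w + strip_w, 3))
    full[, seq_len(w), ] <- img
    full[, w + seq_len(strip_w), ] <- leg
    img <- full
    attr(img, "legend_swatches") <- swatches
  }
  attr(img, "classes") <- cls
  img
}

#' Write a cartography to PNG
#'
#' @param img [render_cartography()] output.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cartography <- function(img, path) write_png(img, path)
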