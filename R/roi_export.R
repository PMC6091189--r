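# Export per-fiber ROIs as ImageJ-compatible polygon records inside a
# stored (uncompressed) zip archive, plus a plain-text CSV index.
# Ring-shaped regions (the sub-laminal annulus and the peri-fiber band) are
# stored by their outer outline; the CSV index records the set-difference
# partner needed to reconstruct them exactly.

u16be <- function(v) as.raw(c((v %/% 256) %% 256, v %% 256))

# ImageJ .roi binary record, polygon type, version 227, big-endian header.
imagej_roi_polygon <- function(xs, ys) {
  n <- length(xs)
  left <- min(xs); top <- min(ys)
  header <- c(charToRaw("Iout"),
              u16be(227L),            # version
              as.raw(c(0L, 0L)),      # type 0 = polygon
              u16be(top), u16be(left),
              u16be(max(ys) + 1L), u16be(max(xs) + 1L),
              u16be(n),
              raw(64 - 18))
  coords <- c(unlist(lapply(xs - left, u16be)),
              unlist(lapply(ys - top, u16be)))
  c(header, coords)
}

# outline (0-based x = col-1, y = row-1) of the largest component of a mask
mask_outline <- function(mask) {
  comp <- cpp_label_components(mask, 8L)
  if (max(comp) == 0L) return(NULL)
  biggest <- which.max(tabulate(comp[comp > 0L], max(comp)))
  path <- cpp_trace_boundary(comp == biggest)
  list(x = path[, 2] - 1L, y = path[, 1] - 1L)
}

# minimal stored (method 0) zip writer; fixed timestamp for determinism
write_zip_store <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  pos <- 0L
  crcs <- numeric(length(entries))
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crcs[i] <- cpp_crc32(data)
    offsets[i] <- pos
    rec <- c(as.raw(c(0x50, 0x4B, 0x03, 0x04)), u16le(20L), u16le(0L),
             u16le(0L), u16le(0L), u16le(0x21L),  # fixed DOS time/date
             u32le(crcs[i]), u32le(length(data)), u32le(length(data)),
             u16le(length(name)), u16le(0L), name)
    writeBin(c(rec, data), con)
    pos <- pos + length(rec) + length(data)
  }
  cd_start <- pos
  cd_len <- 0L
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    rec <- c(as.raw(c(0x50, 0x4B, 0x01, 0x02)), u16le(20L), u16le(20L),
             u16le(0L), u16le(0L), u16le(0L), u16le(0x21L),
             u32le(crcs[i]), u32le(length(data)), u32le(length(data)),
             u16le(length(name)), u16le(0L), u16le(0L), u16le(0L),
             u16le(0L), u32le(0L), u32le(offsets[i]), name)
    writeBin(rec, con)
    cd_len <- cd_len + length(rec)
  }
  end <- c(as.raw(c(0x50, 0x4B, 0x05, 0x06)), u16le(0L), u16le(0L),
           u16le(length(entries)), u16le(length(entries)),
           u32le(cd_len), u32le(cd_start), u16le(0L))
  writeBin(end, con)
  invisible(path)
}

#' Export all fiber ROIs to a zip archive
#'
#' One ImageJ-compatible polygon record per (fiber, roi kind) — kinds F,
#' CNF, SC, V — plus \code{index.csv} listing every entry with its fiber
#' id, kind, outline length and reconstruction note.
#'
#' @param rois [build_all_rois()] output.
#' @param path output \code{.zip} path.
#' @return \code{path}, invisibly.
#' @export
export_rois <- function(rois, path) {
  entries <- list()
  index <- list()
  for (rs in rois$rois) {
    for (kind in c("f", "cnf", "sc", "v")) {
      ol <- mask_outline(rs[[kind]])
      if (is.null(ol)) next
      xs <- ol$x + rs$c0 - 1L
      ys <- ol$y + rs$r0 - 1L
      nm <- sprintf("%04d_%s.roi", rs$fiber_id, toupper(kind))
      entries[[nm]] <- imagej_roi_polygon(xs, ys)
      note <- switch(kind, f = "", cnf = "",
                     sc = "outer outline; region = F minus CNF",
                     v = "outer outline; region = outline minus all F")
      index[[length(index) + 1L]] <-
        data.frame(fiber_id = rs$fiber_id, roi_kind = toupper(kind),
                   file = nm, n_points = length(xs), note = note,
                   stringsAsFactors = FALSE)
    }
  }
  idx <- do.call(rbind, index)
  csv <- paste(c(paste(names(idx), collapse = ","),
                 apply(idx, 1, function(r)
                   paste(trimws(r), collapse = ","))),
               collapse = "\n")
  entries[["index.csv"]] <- charToRaw(paste0(csv, "\n"))
  write_zip_store(entries, path)
}
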