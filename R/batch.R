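# Batch driver: multi-image runs with the standard output folder layout
# (Artefacts / Cartography / "Results by file" / ROI + RunGlobalResult
# table), headless configuration, and per-image failure quarantine.

#' Read a run configuration file
#'
#' Plain \code{key = value} lines (TOML-like; \code{[section]} headers
#' prefix the keys with \code{section.}). Values are coerced: logicals,
#' numbers, comma-separated lists; \code{channels.<role>} keys build the
#' channel map.
#'
#' @param path config file.
#' @return named list of raw keys plus \code{channel_map}.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  section <- ""
  out <- list()
  for (ln in lines[nzchar(lines)]) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    if (nzchar(section)) key <- paste(section, key, sep = ".")
    val <- trimws(paste(kv[-1], collapse = "="))
    val <- gsub('^"|"$', "", val)
    if (grepl(",", val)) {
      val <- trimws(strsplit(val, ",")[[1]])
    }
    num <- suppressWarnings(as.numeric(val))
    if (all(!is.na(num))) val <- num
    else if (all(toupper(val) %in% c("TRUE", "FALSE"))) val <- as.logical(val)
    out[[key]] <- val
  }
  ch <- grep("^channels\\.", names(out), value = TRUE)
  if (length(ch)) {
    out$channel_map <- stats::setNames(as.list(as.integer(unlist(out[ch]))),
                                       sub("^channels\\.", "", ch))
  }
  out
}

batch_folders <- c("Artefacts", "Cartography", "Results by file", "ROI")

fmt_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 6,
                                                 format = "g"))
  df
}

write_txt_table <- function(df, path) {
  utils::write.table(fmt_table(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
}

#' Run a batch analysis
#'
#' Processes every TIFF in \code{input_dir}, reproducing the standard
#' output layout: four folders (\code{Artefacts}, \code{Cartography},
#' \code{Results by file}, \code{ROI}), one tab-delimited per-fiber table
#' and one per-object table per image, ROI zip archives, the requested
#' cartography PNGs, a global \code{RunGlobalResult_<run id>.txt} summary
#' (one row per image) and a run log recording every configuration value
#' and the per-channel typing thresholds. QC-rejected images are copied to
#' Artefacts and flagged in the global table; a per-image failure
#' quarantines that image (error recorded) and the batch continues.
#'
#' @param config list (or path to a [read_run_config()] file) with at
#'   least \code{input_dir}, \code{output_dir}, \code{channel_map}; optional
#'   \code{scale_um_per_px} (default "from metadata"), \code{features},
#'   \code{cartographies}, \code{artifact_tolerance}, \code{zstack} +
#'   \code{n_channels}, \code{run_id}, \code{seed}, and any
#'   [default_params()] override.
#' @return invisibly, the global summary data.frame.
#' @export
run_batch <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  input_dir <- config$input_dir %||% stop_mhca("config needs input_dir")
  output_dir <- config$output_dir %||% stop_mhca("config needs output_dir")
  channel_map <- config$channel_map %||% stop_mhca("config needs channel_map")
  features <- config$features %||% ALL_FEATURES
  features <- intersect(ALL_FEATURES, features)
  cartos <- config$cartographies %||% character(0)
  scale <- config$scale_um_per_px %||% "from metadata"
  run_id <- config$run_id %||% format(Sys.time(), "%Y%m%d_%H%M%S")
  if (!is.null(config$seed)) set.seed(config$seed)

  files <- list.files(input_dir, pattern = "\\.tiff?$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop_mhca("no TIFF images in %s", input_dir)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in batch_folders)
    dir.create(file.path(output_dir, f), showWarnings = FALSE)

  par_names <- intersect(names(config), names(default_params()))
  params <- do.call(default_params, config[par_names])
  if (!is.null(config$artifact_tolerance))
    params$artifact_tolerance <- config$artifact_tolerance

  log_lines <- c(sprintf("run_id\t%s", run_id),
                 vapply(sort(setdiff(names(config), "channel_map")),
                        function(k) sprintf("config.%s\t%s", k,
                                            paste(config[[k]], collapse = ",")),
                        character(1)),
                 vapply(names(channel_map), function(r)
                   sprintf("channel.%s\t%d", r, channel_map[[r]]),
                   character(1)))
  rows <- list()
  for (f in files) {
    img <- tools::file_path_sans_ext(basename(f))
    row <- tryCatch({
      section <- read_batch_image(f, channel_map, scale, config)
      an <- analyze_section(section, features = features, params = params)
      an$summary$image <- img
      if (!an$qc$accepted) {
        file.copy(f, file.path(output_dir, "Artefacts", basename(f)))
        writeLines(sprintf("rejected: fiber/section area ratio %.4f below tolerance %.3f",
                           an$qc$fiber_area_ratio, params$artifact_tolerance),
                   file.path(output_dir, "Artefacts",
                             paste0(img, "_reason.txt")))
      } else {
        write_txt_table(an$fibers,
                        file.path(output_dir, "Results by file",
                                  paste0(img, "_results.txt")))
        if (!is.null(an$objects))
          write_txt_table(an$objects,
                          file.path(output_dir, "Results by file",
                                    paste0(img, "_objects.txt")))
        export_rois(an$rois, file.path(output_dir, "ROI",
                                       paste0(img, "_ROI.zip")))
        for (kind in cartos) {
          vals <- switch(kind,
            csa = an$morpho$csa_um2,
            centronuclei = an$cnf$n_centronuclei,
            vessels = an$vessels$per_fiber_counts$n_vessels,
            satellites = an$fibers$NbSatellites,
            fibertype = an$typing$label,
            stop_mhca("unknown cartography kind '%s'", kind))
          carto <- render_cartography(an$map, vals, cartography_spec(kind))
          write_cartography(carto,
                            file.path(output_dir, "Cartography",
                                      paste0(img, "_", kind, ".png")))
        }
        if (!is.null(an$thresholds))
          log_lines <- c(log_lines, vapply(names(an$thresholds), function(st)
            sprintf("threshold.%s.%s\t%.6g", img, st,
                    an$thresholds[[st]]$threshold), character(1)))
      }
      an$summary
    }, error = function(e) {
      writeLines(conditionMessage(e),
                 file.path(output_dir, "Artefacts",
                           paste0(img, "_error.txt")))
      list(image = img, n_fibers = NA_integer_, qc_ratio = NA_real_,
           accepted = FALSE)
    })
    rows[[img]] <- row
  }
  # global table: union of all summary fields, one row per image
  all_names <- unique(unlist(lapply(rows, names)))
  global <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(all_names, names(r))
    r[miss] <- NA
    as.data.frame(r[all_names], stringsAsFactors = FALSE)
  }))
  rownames(global) <- NULL
  write_txt_table(global, file.path(output_dir,
                                    paste0("RunGlobalResult_", run_id,
                                           ".txt")))
  writeLines(log_lines, file.path(output_dir,
                                  paste0("RunLog_", run_id, ".txt")))
  invisible(global)
}

# read one batch image, honoring the z-stack option: with zstack = TRUE the
# file's pages are [channel fastest] z-planes and are max-projected first
read_batch_image <- function(path, channel_map, scale, config) {
  if (isTRUE(config$zstack)) {
    nc <- config$n_channels %||%
      stop_mhca("zstack = TRUE requires n_channels in the config")
    tf <- read_tiff_gray(path)
    np <- length(tf$pages)
    if (np %% nc != 0)
      stop_mhca("%s: %d pages not divisible by n_channels = %d",
                path, np, nc)
    nz <- np %/% nc
    sc <- if (identical(scale, "from metadata")) {
      tf$scale_um_per_px %||%
        stop_mhca("no pixel-size metadata in %s", path)
    } else scale
    slices <- lapply(seq_len(nz), function(z) {
      chans <- lapply(channel_map, function(i)
        tf$pages[[(z - 1L) * nc + as.integer(i)]])
      calibrated_section(chans, sc, source = path)
    })
    max_project(slices)
  } else {
    read_section(path, channel_map, scale)
  }
}
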