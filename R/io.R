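## File interchange: multi-page TIFF stacks, label masks, dataset CSVs.
## Counts are stored as 16-bit TIFF (scaled to [0,1] as value/65535, the
## format's convention), one file per ion channel with pages as planes,
## plus a JSON sidecar for raster metadata.

TIFF_MAX <- 65535

#' Write a NanoSIMS stack to multi-page TIFFs
#'
#' @param stack an [nsims_stack()].
#' @param prefix path prefix; files `<prefix>_mass24.tif` ...
#'   `<prefix>_mass27.tif` and `<prefix>.json` are written.
#' @return Invisibly, the written file paths.
#' @export
write_stack_tiff <- function(stack, prefix) {
  stopifnot(inherits(stack, "nsims_stack"))
  if (max(stack$counts) > TIFF_MAX)
    stop("counts exceed 16-bit TIFF range")
  d <- dim(stack$counts)
  paths <- character(0)
  for (ch in dimnames(stack$counts)[[3]]) {
    pages <- lapply(seq_len(d[4]), function(p)
      stack$counts[, , ch, p] / TIFF_MAX)
    f <- paste0(prefix, "_", ch, ".tif")
    tiff::writeTIFF(pages, f, bits.per.sample = 16)
    paths <- c(paths, f)
  }
  meta <- list(raster_um = stack$raster_um, dwell_ms = stack$dwell_ms,
               species = stack$species, treatment = stack$treatment,
               is_control = stack$is_control, planes = d[4],
               shape = d[1:2])
  jf <- paste0(prefix, ".json")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null"), jf)
  invisible(c(paths, jf))
}

#' Read a NanoSIMS stack written by [write_stack_tiff()]
#'
#' @param prefix path prefix used at write time.
#' @return An [nsims_stack()].
#' @export
read_stack_tiff <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, ".json"))
  chans <- c("mass24", "mass25", "mass26", "mass27")
  arr <- array(0L, c(meta$shape[1], meta$shape[2], 4, meta$planes))
  for (k in seq_along(chans)) {
    pages <- tiff::readTIFF(paste0(prefix, "_", chans[k], ".tif"), all = TRUE)
    for (p in seq_along(pages))
      arr[, , k, p] <- as.integer(round(pages[[p]] * TIFF_MAX))
  }
  nsims_stack(arr, raster_um = meta$raster_um, dwell_ms = meta$dwell_ms,
              species = meta$species, treatment = meta$treatment,
              is_control = meta$is_control)
}

#' Write an ROI set as a 16-bit label TIFF plus JSON table
#'
#' @param rois a [roi_set()].
#' @param prefix path prefix; writes `<prefix>_labels.tif` and
#'   `<prefix>_rois.json`.
#' @return Invisibly, the written paths.
#' @export
write_roi_tiff <- function(rois, prefix) {
  stopifnot(inherits(rois, "roi_set"))
  if (max(rois$labels) > TIFF_MAX) stop("too many ROI labels for 16-bit")
  f <- paste0(prefix, "_labels.tif")
  tiff::writeTIFF(rois$labels / TIFF_MAX, f, bits.per.sample = 16)
  jf <- paste0(prefix, "_rois.json")
  writeLines(jsonlite::toJSON(rois$table, dataframe = "rows"), jf)
  invisible(c(f, jf))
}

#' Read an ROI set written by [write_roi_tiff()]
#'
#' @param prefix path prefix used at write time.
#' @param pixel_um passed to [roi_set()] (default skips size checks).
#' @return A [roi_set()].
#' @export
read_roi_tiff <- function(prefix, pixel_um = NA) {
  lab <- tiff::readTIFF(paste0(prefix, "_labels.tif"))
  lab <- matrix(as.integer(round(lab * TIFF_MAX)), nrow(lab), ncol(lab))
  tab <- jsonlite::fromJSON(paste0(prefix, "_rois.json"))
  roi_set(lab, tab, pixel_um = pixel_um)
}

#' Write a simulated tracer dataset to CSV files
#'
#' Writes `bulk.csv`, `fractions.csv`, `counts.csv`, `filters.csv` and
#' `ground_truth.json` into a directory, making a self-contained dataset
#' that [run_full_analysis()] can consume after reading back.
#'
#' @param dataset list from [simulate_tracer_experiment()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_tracer_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("bulk", "fractions", "counts", "filters"))
    write.csv(dataset[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  writeLines(jsonlite::toJSON(dataset$truth, auto_unbox = TRUE, digits = NA,
                              force = TRUE),
             file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Read a tracer dataset directory written by [write_tracer_dataset()]
#'
#' @param dir dataset directory.
#' @param foods named list of [food_source()] objects (food definitions
#'   are configuration, not data, so they are supplied separately).
#' @return List with `bulk`, `fractions`, `counts`, `filters`, `foods`.
#' @export
read_tracer_dataset <- function(dir, foods) {
  out <- lapply(c(bulk = "bulk", fractions = "fractions",
                  counts = "counts", filters = "filters"),
                function(nm) read.csv(file.path(dir, paste0(nm, ".csv"))))
  out$foods <- foods
  out
}

#' Diagnostic plot of a summed acquisition
#'
#' Shows the carbon or nitrogen isotope-ratio map of an accumulated
#' stack on a terrain palette; masked pixels are blank.
#'
#' @param x an `nsims_summed` object.
#' @param element `"C"` or `"N"`.
#' @param min_counts per-pixel denominator mask.
#' @param ... passed to [graphics::image()].
#' @export
plot.nsims_summed <- function(x, element = c("C", "N"), min_counts = 20,
                              ...) {
  element <- match.arg(element)
  rm <- ratio_maps(x, min_counts = min_counts)
  r <- if (element == "C") rm$r_c else rm$r_n
  graphics::image(t(r[nrow(r):1, ]), axes = FALSE, useRaster = TRUE,
                  col = grDevices::terrain.colors(64),
                  main = sprintf("%s ratio map", element), ...)
  invisible(x)
}
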