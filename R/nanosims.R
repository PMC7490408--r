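#' NanoSIMS ion-count image stack
#'
#' Container for a raster acquisition: repeated raster planes of four
#' simultaneously collected ion channels (mass 24 = 12C2-, mass 25 =
#' 13C12C-, mass 26 = 12C14N-, mass 27 = 12C15N-) as non-negative
#' integer counts.
#'
#' @param counts integer array with dim `c(H, W, 4, planes)`; the third
#'   dimension is the channel, ordered mass24, mass25, mass26, mass27.
#' @param raster_um physical raster edge length in micrometres
#'   (default 30; with 256 px this gives ~0.117 um pixels).
#' @param dwell_ms beam dwell time per pixel in ms (metadata).
#' @param species,treatment,is_control sample metadata.
#' @return Object of class `nsims_stack`.
#' @export
nsims_stack <- function(counts, raster_um = 30, dwell_ms = 5,
                        species = NA_character_, treatment = NA_character_,
                        is_control = FALSE) {
  stopifnot(is.array(counts), length(dim(counts)) == 4, dim(counts)[3] == 4)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("ion counts must be non-negative integers")
  dimnames(counts)[[3]] <- c("mass24", "mass25", "mass26", "mass27")
  structure(list(counts = counts, raster_um = raster_um, dwell_ms = dwell_ms,
                 species = species, treatment = treatment,
                 is_control = is_control),
            class = "nsims_stack")
}

#' @export
print.nsims_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(paste0("NanoSIMS stack: %d x %d px, %d planes, 4 channels ",
                     "(%.0f x %.0f um raster)\n"),
              d[1], d[2], d[4], x$raster_um, x$raster_um))
  cat(sprintf("  total counts: mass24 %.3g, mass25 %.3g, mass26 %.3g, mass27 %.3g\n",
              sum(x$counts[, , 1, ]), sum(x$counts[, , 2, ]),
              sum(x$counts[, , 3, ]), sum(x$counts[, , 4, ])))
  invisible(x)
}

#' Region-of-interest set over an ion image
#'
#' Labelled pixel regions (cells) with a type annotation. Cell types
#' follow the equivalent-diameter size classes used when ROIs are drawn:
#' bacteria 0.2-2 um, choanocytes 3-10 um, other mesohyl/pinacoderm cells
#' 7-30 um; out-of-class sizes draw a warning, not an error.
#'
#' @param labels integer matrix, 0 = background, k > 0 = ROI k.
#' @param cell_type data.frame with columns `roi_id`, `cell_type`
#'   (bacteria, choanocyte, choanocyte_hotspot or mesohyl_other), and
#'   optionally extra columns carried through.
#' @param pixel_um pixel edge length in micrometres, used for the size
#'   check (default `30/256`); `NA` skips the check.
#' @return Object of class `roi_set` with the label matrix and a table
#'   including `pixel_count`.
#' @export
roi_set <- function(labels, cell_type, pixel_um = 30 / 256) {
  stopifnot(is.matrix(labels), is.data.frame(cell_type),
            all(c("roi_id", "cell_type") %in% names(cell_type)))
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0L]))
  if (!all(ids %in% cell_type$roi_id))
    stop("label matrix contains ROI ids missing from the cell-type table")
  bad <- !cell_type$cell_type %in%
    c("bacteria", "choanocyte", "choanocyte_hotspot", "mesohyl_other")
  if (any(bad)) stop("unknown cell type: ",
                     paste(unique(cell_type$cell_type[bad]), collapse = ", "))
  tab <- cell_type[cell_type$roi_id %in% ids, , drop = FALSE]
  npx <- table(factor(labels[labels > 0L], levels = tab$roi_id))
  tab$pixel_count <- as.integer(npx[as.character(tab$roi_id)])
  if (!is.na(pixel_um)) {
    eqd <- 2 * sqrt(tab$pixel_count * pixel_um^2 / pi)
    lims <- list(bacteria = c(0.2, 2), choanocyte = c(3, 10),
                 mesohyl_other = c(7, 30),
                 choanocyte_hotspot = c(0, Inf))
    for (i in seq_len(nrow(tab))) {
      l <- lims[[tab$cell_type[i]]]
      if (eqd[i] < l[1] || eqd[i] > l[2])
        warning(sprintf("ROI %d (%s): equivalent diameter %.2f um outside %g-%g um",
                        tab$roi_id[i], tab$cell_type[i], eqd[i], l[1], l[2]))
    }
  }
  structure(list(labels = labels, table = tab), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("ROI set:", nrow(x$table), "regions\n")
  print(table(x$table$cell_type))
  invisible(x)
}

## circular integer cross-correlation peak between two matrices (FFT);
## returns the shift s = (dy, dx) such that img[i, j] ~ ref[i - dy, j - dx]
xcorr_peak <- function(ref, img) {
  cc <- Re(fft(Conj(fft(ref)) * fft(img), inverse = TRUE))
  k <- which.max(cc)
  H <- nrow(ref)
  dy <- (k - 1L) %% H
  dx <- (k - 1L) %/% H
  if (dy > H / 2) dy <- dy - H
  if (dx > ncol(ref) / 2) dx <- dx - ncol(ref)
  c(dy = as.integer(dy), dx = as.integer(dx))
}

## translate matrix by (-dy, -dx) filling with NA: out[i,j] = m[i+dy, j+dx]
translate_na <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(NA_real_, H, W)
  ri <- intersect(seq_len(H), seq_len(H) + dy) # source rows
  ci <- intersect(seq_len(W), seq_len(W) + dx)
  out[ri - dy, ci - dx] <- m[ri, ci]
  out
}

#' Drift-correct the planes of a stack
#'
#' Lateral stage/beam drift between repeated planes is estimated per
#' plane as the integer pixel shift maximising the cross-correlation of
#' its 12C14N channel (the highest-count channel) against plane 1. The
#' same shift is applied to all four channels and the stack is cropped to
#' the region covered by every plane, so counts stay integer and no pixel
#' is interpolated.
#'
#' @param stack an [nsims_stack()].
#' @param max_shift_frac maximum tolerated shift as a fraction of the
#'   frame (default 0.25); beyond this the alignment is declared failed.
#' @return List: `stack` (aligned, cropped [nsims_stack()]), `shifts`
#'   (planes x 2 integer matrix of estimated (dy, dx)), `window` (row and
#'   column ranges kept).
#' @export
align_planes <- function(stack, max_shift_frac = 0.25) {
  stopifnot(inherits(stack, "nsims_stack"))
  cnt <- stack$counts
  d <- dim(cnt)
  P <- d[4]
  ref <- cnt[, , "mass26", 1]
  shifts <- matrix(0L, P, 2, dimnames = list(NULL, c("dy", "dx")))
  for (p in seq_len(P)[-1])
    shifts[p, ] <- xcorr_peak(ref, cnt[, , "mass26", p])
  if (any(abs(shifts[, 1]) > max_shift_frac * d[1]) ||
      any(abs(shifts[, 2]) > max_shift_frac * d[2]))
    stop("alignment failure: estimated drift exceeds ",
         round(100 * max_shift_frac), "% of the frame")
  rows <- seq.int(max(1, 1 - min(shifts[, 1])), min(d[1], d[1] - max(shifts[, 1])))
  cols <- seq.int(max(1, 1 - min(shifts[, 2])), min(d[2], d[2] - max(shifts[, 2])))
  out <- array(0L, c(length(rows), length(cols), 4, P))
  for (p in seq_len(P)) {
    for (ch in 1:4) {
      shifted <- translate_na(cnt[, , ch, p], shifts[p, 1], shifts[p, 2])
      out[, , ch, p] <- as.integer(shifted[rows, cols])
    }
  }
  aligned <- nsims_stack(out, raster_um = stack$raster_um * length(rows) / d[1],
                         dwell_ms = stack$dwell_ms, species = stack$species,
                         treatment = stack$treatment,
                         is_control = stack$is_control)
  list(stack = aligned, shifts = shifts,
       window = list(rows = range(rows), cols = range(cols)))
}

#' Accumulate planes into summed channel images
#'
#' Pixelwise sum of an (aligned) stack across planes; counts are
#' conserved over the common region.
#'
#' @param stack an [nsims_stack()] (typically the aligned stack from
#'   [align_planes()]).
#' @return Object of class `nsims_summed`: a list of four integer count
#'   matrices (`mass24`, `mass25`, `mass26`, `mass27`) plus the stack
#'   metadata and `pixel_um`.
#' @export
accumulate_planes <- function(stack) {
  stopifnot(inherits(stack, "nsims_stack"))
  d <- dim(stack$counts)
  ch <- lapply(1:4, function(k) {
    m <- apply(stack$counts[, , k, , drop = FALSE], c(1, 2), sum)
    storage.mode(m) <- "integer"
    m
  })
  names(ch) <- dimnames(stack$counts)[[3]]
  structure(c(ch, list(pixel_um = stack$raster_um / d[1],
                       species = stack$species, treatment = stack$treatment,
                       is_control = stack$is_control)),
            class = "nsims_summed")
}

#' Isotope-ratio maps from summed channel images
#'
#' Per-pixel carbon (13C12C- / 12C2-) and nitrogen (12C15N- / 12C14N-)
#' ratio maps. Pixels whose denominator holds fewer than `min_counts`
#' accumulated counts are masked (`NA`): a ratio of a handful of counts is
#' dominated by shot noise.
#'
#' @param summed an `nsims_summed` object from [accumulate_planes()].
#' @param min_counts minimum denominator counts per pixel (default 20).
#' @return List with matrices `r_c`, `r_n` (NA where masked) and logical
#'   masks `valid_c`, `valid_n`.
#' @export
ratio_maps <- function(summed, min_counts = 20) {
  stopifnot(inherits(summed, "nsims_summed"))
  vc <- summed$mass24 >= min_counts
  vn <- summed$mass26 >= min_counts
  r_c <- ifelse(vc, summed$mass25 / summed$mass24, NA_real_)
  r_n <- ifelse(vn, summed$mass27 / summed$mass26, NA_real_)
  list(r_c = r_c, r_n = r_n, valid_c = vc, valid_n = vn)
}

#' Control calibration for NanoSIMS delta values
#'
#' Delta values of labelled samples are referenced to the measured
#' isotope ratios of unlabelled control acquisitions, not to the
#' international standards: the instrument's relative-ratio accuracy is
#' far better than its absolute accuracy. Also records, per cell type
#' and element, the mean and SD of control ROI deltas used by the
#' enrichment classifier.
#'
#' @param control_summed a single `nsims_summed` or a list of them, from
#'   control acquisitions.
#' @param control_rois matching [roi_set()] (or list of them).
#' @param pool_types logical; pool control ROI statistics across cell
#'   types instead of keeping them per type (default `FALSE`).
#' @param min_rois minimum control ROIs per cell type (default 2).
#' @param pixel_smooth mean-filter window used for the pixel-level
#'   statistics (default 3); match the `smooth` argument of
#'   [extract_hotspots()].
#' @param min_counts per-pixel denominator mask for the pixel-level
#'   statistics.
#' @return Object of class `nsims_calibration`: `r_c`, `r_n` (measured
#'   control ratios, ratio of total counts over the control frames),
#'   `stats`, a data.frame (cell_type, element, mean, sd, n) of
#'   ROI-level control deltas driving [classify_enriched()], and
#'   `pixel_stats`, the same summaries of the smoothed per-pixel delta
#'   maps, which set the (much wider, shot-noise dominated) thresholds
#'   for [extract_hotspots()].
#' @export
control_calibration <- function(control_summed, control_rois,
                                pool_types = FALSE, min_rois = 2,
                                pixel_smooth = 3, min_counts = 20) {
  if (inherits(control_summed, "nsims_summed")) {
    control_summed <- list(control_summed)
    control_rois <- list(control_rois)
  }
  stopifnot(length(control_summed) == length(control_rois))
  tot <- sapply(control_summed, function(s)
    c(sum(s$mass24), sum(s$mass25), sum(s$mass26), sum(s$mass27)))
  r_c <- sum(tot[2, ]) / sum(tot[1, ])
  r_n <- sum(tot[4, ]) / sum(tot[3, ])
  cal0 <- structure(list(r_c = r_c, r_n = r_n, stats = NULL),
                    class = "nsims_calibration")
  dd <- do.call(rbind, Map(function(s, r) roi_deltas(s, r, cal0),
                           control_summed, control_rois))
  type <- if (pool_types) rep("all", nrow(dd)) else dd$cell_type
  stats <- do.call(rbind, lapply(split(dd, type), function(g) {
    data.frame(cell_type = g$cell_type[1], element = c("C", "N"),
               mean = c(mean(g$delta13C, na.rm = TRUE),
                        mean(g$delta15N, na.rm = TRUE)),
               sd = c(sd(g$delta13C, na.rm = TRUE),
                      sd(g$delta15N, na.rm = TRUE)),
               n = c(sum(!is.na(g$delta13C)), sum(!is.na(g$delta15N))))
  }))
  if (pool_types) stats$cell_type <- "all"
  rownames(stats) <- NULL
  low <- stats$n < min_rois
  if (any(low))
    warning("fewer than ", min_rois, " control ROIs for: ",
            paste(unique(stats$cell_type[low]), collapse = ", "))
  ## per-pixel (smoothed) control delta statistics, for hotspot thresholds
  px <- list()
  for (i in seq_along(control_summed)) {
    s <- control_summed[[i]]
    r <- control_rois[[i]]
    rm <- ratio_maps(s, min_counts = min_counts)
    d_c <- smooth_mean((rm$r_c / r_c - 1) * 1000, pixel_smooth)
    d_n <- smooth_mean((rm$r_n / r_n - 1) * 1000, pixel_smooth)
    inroi <- r$labels > 0L
    ty <- r$table$cell_type[match(r$labels[inroi], r$table$roi_id)]
    if (pool_types) ty <- rep("all", length(ty))
    px[[i]] <- data.frame(cell_type = ty, d_c = d_c[inroi], d_n = d_n[inroi])
  }
  px <- do.call(rbind, px)
  pixel_stats <- do.call(rbind, lapply(split(px, px$cell_type), function(g) {
    data.frame(cell_type = g$cell_type[1], element = c("C", "N"),
               mean = c(mean(g$d_c, na.rm = TRUE), mean(g$d_n, na.rm = TRUE)),
               sd = c(sd(g$d_c, na.rm = TRUE), sd(g$d_n, na.rm = TRUE)),
               n = c(sum(!is.na(g$d_c)), sum(!is.na(g$d_n))))
  }))
  rownames(pixel_stats) <- NULL
  structure(list(r_c = r_c, r_n = r_n, stats = stats,
                 pixel_stats = pixel_stats, pixel_smooth = pixel_smooth,
                 pool_types = pool_types),
            class = "nsims_calibration")
}

#' @export
print.nsims_calibration <- function(x, ...) {
  cat(sprintf("NanoSIMS control calibration: r_C = %.5g, r_N = %.5g\n",
              x$r_c, x$r_n))
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

cal_stats <- function(calibration, cell_type, element, pixel = FALSE) {
  st <- if (pixel) calibration$pixel_stats else calibration$stats
  if (is.null(st)) return(NULL)
  if (isTRUE(calibration$pool_types)) cell_type <- "all"
  # hotspots are judged against the stats of their parent cell type
  if (cell_type == "choanocyte_hotspot") cell_type <- "choanocyte"
  row <- st[st$cell_type == cell_type & st$element == element, , drop = FALSE]
  if (nrow(row) == 0L) return(NULL)
  row
}

#' ROI delta values from summed channel images
#'
#' For each ROI the isotope ratio is the ratio of summed counts,
#' numerator counts over denominator counts within the ROI (not the mean
#' of per-pixel ratios, which is biased at low counts), converted to
#' per-mil delta against the measured control ratio. ROIs whose
#' denominator total falls below `min_counts` are excluded with a reason
#' code rather than reported.
#'
#' @param summed an `nsims_summed` object.
#' @param rois a [roi_set()].
#' @param calibration an `nsims_calibration` (only `r_c`/`r_n` are used
#'   here).
#' @param min_counts minimum denominator counts per ROI (default 20).
#' @return data.frame: roi_id, cell_type, pixel_count, counts per
#'   channel, `delta13C`, `delta15N` (NA when excluded) and
#'   `exclude_reason` (`""`, `"low_C_counts"`, `"low_N_counts"` or both).
#' @export
roi_deltas <- function(summed, rois, calibration, min_counts = 20) {
  stopifnot(inherits(summed, "nsims_summed"), inherits(rois, "roi_set"))
  lab <- as.vector(rois$labels)
  keep <- lab > 0L
  f <- factor(lab[keep], levels = rois$table$roi_id)
  sums <- sapply(c("mass24", "mass25", "mass26", "mass27"), function(ch)
    as.vector(rowsum(as.vector(summed[[ch]])[keep], f, na.rm = TRUE)))
  sums <- matrix(sums, ncol = 4,
                 dimnames = list(NULL, c("mass24", "mass25", "mass26", "mass27")))
  ok_c <- sums[, "mass24"] >= min_counts
  ok_n <- sums[, "mass26"] >= min_counts
  d13 <- ifelse(ok_c,
                (sums[, "mass25"] / sums[, "mass24"] / calibration$r_c - 1) * 1000,
                NA_real_)
  d15 <- ifelse(ok_n,
                (sums[, "mass27"] / sums[, "mass26"] / calibration$r_n - 1) * 1000,
                NA_real_)
  reason <- paste0(ifelse(ok_c, "", "low_C_counts;"),
                   ifelse(ok_n, "", "low_N_counts;"))
  data.frame(roi_id = rois$table$roi_id, cell_type = rois$table$cell_type,
             pixel_count = rois$table$pixel_count, sums,
             delta13C = d13, delta15N = d15,
             exclude_reason = sub(";$", "", reason))
}

#' Classify ROIs as isotopically enriched
#'
#' An ROI is called enriched in an element when its delta value lies more
#' than two standard deviations above the mean of a comparable set of
#' control ROIs (same cell type, one-sided rule).
#'
#' @param deltas data.frame from [roi_deltas()].
#' @param calibration an `nsims_calibration` carrying per-type control
#'   statistics.
#' @param k number of control SDs above the control mean (default 2).
#' @return The input with logical columns `enriched_c`, `enriched_n`
#'   appended (NA where the delta was excluded).
#' @export
classify_enriched <- function(deltas, calibration, k = 2) {
  stopifnot(is.data.frame(deltas), inherits(calibration, "nsims_calibration"))
  thr <- function(type, el) {
    st <- cal_stats(calibration, type, el)
    if (is.null(st))
      stop("no control statistics for cell type '", type, "', element ", el)
    st$mean + k * st$sd
  }
  deltas$enriched_c <- mapply(function(d, ty)
    if (is.na(d)) NA else d > thr(ty, "C"), deltas$delta13C, deltas$cell_type)
  deltas$enriched_n <- mapply(function(d, ty)
    if (is.na(d)) NA else d > thr(ty, "N"), deltas$delta15N, deltas$cell_type)
  deltas
}

## 8-connected component labelling of a logical matrix (0 = background)
label_components8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  mask[is.na(mask)] <- FALSE
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- (p - 1L) %% H + 1L
      j <- (p - 1L) %/% H + 1L
      for (jj in max(1L, j - 1L):min(W, j + 1L)) {
        base <- (jj - 1L) * H
        for (ii in max(1L, i - 1L):min(H, i + 1L)) {
          q <- base + ii
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  lab
}

## NA-aware 3x3 (or n x n) mean filter
smooth_mean <- function(m, size = 3) {
  if (size <= 1) return(m)
  half <- (size - 1) %/% 2
  H <- nrow(m); W <- ncol(m)
  acc <- matrix(0, H, W); n <- matrix(0, H, W)
  for (dy in -half:half) for (dx in -half:half) {
    sh <- translate_na(m, dy, dx)
    ok <- !is.na(sh)
    acc[ok] <- acc[ok] + sh[ok]
    n <- n + ok
  }
  out <- acc / n
  out[n == 0] <- NA_real_
  out
}

#' Extract enrichment hotspots within choanocyte ROIs
#'
#' Sub-cellular hotspots of tracer enrichment inside host choanocytes are
#' segmented from the per-pixel delta map: after a small mean smoothing,
#' pixels exceeding the pixel-level control mean by more than `k`
#' pixel-level control SDs (which are dominated by counting noise, so the
#' threshold sits far above whole-cell enrichment) are grouped into
#' 8-connected components, and components of at least `min_area` pixels
#' inside a choanocyte ROI become hotspot ROIs.
#' The criteria (`k = 5`, `min_area = 10`, 3x3 smoothing) are package
#' defaults, exposed as parameters.
#'
#' @param summed an `nsims_summed` object.
#' @param rois a [roi_set()]; only choanocyte ROIs are searched.
#' @param calibration an `nsims_calibration`.
#' @param element `"C"` or `"N"`.
#' @param k threshold in control SDs above the control mean (default 5).
#' @param min_area minimum component size in pixels (default 10).
#' @param smooth mean-filter window (default 3; 1 disables).
#' @param min_counts per-pixel denominator mask (default 20).
#' @return A [roi_set()] of `choanocyte_hotspot` ROIs whose table has a
#'   `parent_roi` column; empty table if no hotspot is found.
#' @export
extract_hotspots <- function(summed, rois, calibration, element = c("C", "N"),
                             k = 5, min_area = 10, smooth = 3,
                             min_counts = 20) {
  element <- match.arg(element)
  rm <- ratio_maps(summed, min_counts = min_counts)
  r <- if (element == "C") rm$r_c else rm$r_n
  r0 <- if (element == "C") calibration$r_c else calibration$r_n
  dmap <- smooth_mean((r / r0 - 1) * 1000, smooth)
  st <- cal_stats(calibration, "choanocyte", element, pixel = TRUE)
  if (is.null(st))
    stop("no choanocyte pixel-level control statistics in calibration")
  thr <- st$mean + k * st$sd

  choan <- rois$table$roi_id[rois$table$cell_type == "choanocyte"]
  out_lab <- matrix(0L, nrow(rois$labels), ncol(rois$labels))
  tab <- list()
  nid <- 0L
  for (id in choan) {
    inroi <- rois$labels == id
    mask <- inroi & !is.na(dmap) & dmap > thr
    if (!any(mask)) next
    comp <- label_components8(mask)
    for (cid in seq_len(max(comp))) {
      px <- comp == cid
      if (sum(px) < min_area) next
      nid <- nid + 1L
      out_lab[px] <- nid
      tab[[nid]] <- data.frame(roi_id = nid,
                               cell_type = "choanocyte_hotspot",
                               parent_roi = id)
    }
  }
  tab <- if (nid > 0L) do.call(rbind, tab)
         else data.frame(roi_id = integer(), cell_type = character(),
                         parent_roi = integer())
  roi_set(out_lab, tab, pixel_um = NA)
}

#' Summarise ROI enrichment by cell type
#'
#' @param deltas data.frame from [classify_enriched()].
#' @param probs quantiles of the delta distribution to report.
#' @param min_n warn when a cell type has fewer ROIs than this
#'   (default 20, the usual per-type minimum when drawing ROIs).
#' @return data.frame per cell type x element: n, n_enriched,
#'   prop_enriched and delta quantiles.
#' @export
enrichment_summary <- function(deltas, probs = c(0.25, 0.5, 0.75),
                               min_n = 20) {
  stopifnot(all(c("enriched_c", "enriched_n") %in% names(deltas)))
  out <- list()
  for (ty in unique(deltas$cell_type)) {
    g <- deltas[deltas$cell_type == ty, ]
    if (nrow(g) < min_n)
      warning("cell type '", ty, "' has only ", nrow(g), " ROIs")
    for (el in c("C", "N")) {
      d <- if (el == "C") g$delta13C else g$delta15N
      enr <- if (el == "C") g$enriched_c else g$enriched_n
      ok <- !is.na(d)
      val <- !is.na(enr)
      q <- quantile(d[ok], probs = probs, names = FALSE)
      out[[paste(ty, el)]] <- data.frame(
        cell_type = ty, element = el, n = sum(ok),
        n_enriched = sum(enr[val]),
        prop_enriched = if (any(val)) mean(enr[val]) else NA_real_,
        t(setNames(q, paste0("q", probs * 100))))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' NanoSIMS-route host/symbiont partition
#'
#' Single-cell counterpart of the cell-fraction route: each compartment's
#' specific enrichment is the mean excess atom fraction of its ROIs
#' (derived from ROI deltas and the measured control ratio), combined
#' with compartment biomass exactly as in [partition_uptake()].
#'
#' @param deltas data.frame from [roi_deltas()] (one or several scenes
#'   row-bound together).
#' @param calibration an `nsims_calibration`.
#' @param biomass_host,biomass_microbe compartment element biomass.
#' @param element `"C"` or `"N"`.
#' @param host_types,microbe_types cell types pooled into each
#'   compartment; hotspots belong to their parent choanocytes and are
#'   excluded by default to avoid double counting.
#' @return A `partition_result` (status `"no_estimate"` if a compartment
#'   has no usable ROI).
#' @export
nanosims_partition <- function(deltas, calibration,
                               biomass_host, biomass_microbe,
                               element = c("C", "N"),
                               host_types = c("choanocyte", "mesohyl_other"),
                               microbe_types = "bacteria") {
  element <- match.arg(element)
  dcol <- if (element == "C") "delta13C" else "delta15N"
  r0 <- if (element == "C") calibration$r_c else calibration$r_n
  f0 <- atom_fraction(r0)
  mean_excess <- function(types) {
    d <- deltas[[dcol]][deltas$cell_type %in% types]
    d <- d[!is.na(d)]
    if (length(d) == 0L) return(NA_real_)
    mean(atom_fraction(ratio_from_delta(d, r0)) - f0)
  }
  eh <- mean_excess(host_types)
  em <- mean_excess(microbe_types)
  if (is.na(eh) || is.na(em)) {
    res <- list(element = element, pct_host = NA_real_, pct_microbe = NA_real_,
                status = "no_estimate",
                biomass_pct_microbe =
                  100 * biomass_microbe / (biomass_host + biomass_microbe),
                diagnostics = list(e_host = eh, e_microbe = em))
    class(res) <- "partition_result"
    return(res)
  }
  partition_uptake(eh, em, biomass_host, biomass_microbe, element)
}
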