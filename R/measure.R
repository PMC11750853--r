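#' Scan candidate columns near the ROI centre and measure the diameters
#'
#' Every pixel column within the central `center_fraction` of the ROI
#' width is scanned left to right; each column's intensity profile (rows
#' inside the ROI) goes through the FWHM chain ([profile_edges()]). The
#' per-column outer and lumen extents (in pixels) of the valid columns are
#' aggregated -- by default their median, which is robust to the odd
#' mis-segmented column; `"best-quality"` instead keeps the single column
#' with the highest edge quality. Pixel extents are converted to
#' micrometres with the cross-section's calibration.
#'
#' Columns away from the exact vessel centre measure chords slightly
#' shorter than the diameter, which is why the scan is confined to a
#' narrow central band.
#'
#' @param roi a `roi_result` from [extract_roi()] (its `enhanced` image is
#'   the intensity source).
#' @param cross the [vessel_cross_section()] the ROI came from (supplies
#'   the calibration and metadata).
#' @param center_fraction fraction (0, 1] of the ROI width scanned, centred
#'   on the ROI's horizontal middle.
#' @param noise_floor forwarded to [segment_groups()].
#' @param aggregate `"median"` or `"best-quality"`.
#' @return a [diameter_measurement()]; its `columns` element is a data
#'   frame with one row per valid column (column index, the four edges in
#'   image coordinates, extents, quality).
#' @export
scan_columns <- function(roi, cross, center_fraction = 0.2, noise_floor = 2,
                         aggregate = c("median", "best-quality")) {
  stopifnot(inherits(roi, "roi_result"),
            inherits(cross, "vessel_cross_section"))
  aggregate <- match.arg(aggregate)
  if (!(center_fraction > 0 && center_fraction <= 1)) {
    stop("center_fraction must lie in (0, 1]")
  }
  b <- roi$roi_bounds
  img <- roi$enhanced
  w <- b[4] - b[2] + 1L
  mid <- (b[2] + b[4]) / 2
  half <- center_fraction * w / 2
  cols <- seq(max(b[2], ceiling(mid - half)), min(b[4], floor(mid + half)))
  if (length(cols) == 0L) cols <- round(mid)

  rows <- b[1]:b[3]
  res <- vector("list", length(cols))
  fails <- character(0)
  for (i in seq_along(cols)) {
    cl <- cols[i]
    es <- tryCatch(
      profile_edges(img[rows, cl], noise_floor = noise_floor,
                    column_index = cl),
      error = function(e) conditionMessage(e))
    if (is.character(es)) {
      fails <- c(fails, sprintf("col %d: %s", cl, es))
      next
    }
    off <- b[1] - 1
    res[[i]] <- data.frame(
      column = cl,
      outer_top = es$outer_top + off, lumen_top = es$lumen_top + off,
      lumen_bottom = es$lumen_bottom + off,
      outer_bottom = es$outer_bottom + off,
      outer_extent = es$outer_bottom - es$outer_top,
      lumen_extent = es$lumen_bottom - es$lumen_top,
      quality = es$quality, polarity = es$polarity)
  }
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0L) {
    stop_octvessel(
      paste0("measurement failed: no column yielded a valid edge set\n",
             paste(utils::head(fails, 10), collapse = "\n")),
      "octvessel_measurement_failed", diagnostics = fails)
  }
  if (aggregate == "median") {
    outer_px <- stats::median(res$outer_extent)
    lumen_px <- stats::median(res$lumen_extent)
  } else {
    best <- which.max(res$quality)
    outer_px <- res$outer_extent[best]
    lumen_px <- res$lumen_extent[best]
  }
  diameter_measurement(
    outer_diameter = outer_px * cross$um_per_px,
    lumen_diameter = lumen_px * cross$um_per_px,
    vessel_class = cross$vessel_class,
    n_columns_used = nrow(res),
    image_id = cross$image_id,
    columns = res, aggregate = aggregate)
}

#' Measure a vessel cross-section end to end
#'
#' Full measurement chain on a raw grayscale crop: [standardize()] to a
#' 512 x 512 isotropic frame, [enhance_contrast()] (CLAHE),
#' [detect_edges()] (Canny), [extract_roi()], then [scan_columns()] over
#' the FWHM edge detector.
#'
#' CLAHE conditions the Canny edge map that localizes the vessel, but the
#' intensity profiles scanned by the FWHM stage default to the *raw*
#' standardized image within the ROI bounds (`intensity = "raw"`):
#' adaptive equalization amplifies speckle inside the homogeneous lumen
#' until noise spikes can out-compete the true wall-lumen transition in
#' the pairing step, whereas the raw profiles keep the wall bands
#' dominant. Set `intensity = "enhanced"` to scan the CLAHE output
#' instead; the report records the choice either way.
#'
#' @param image raw grayscale matrix (or `EBImage::Image`), any size.
#' @param um_per_px input calibration, um/px (scalar or `(row, col)`).
#' @param vessel_class `"artery"` or `"vein"`.
#' @param size standardized frame side (pixels).
#' @param clip_limit,tile_grid CLAHE settings ([enhance_contrast()]).
#' @param canny_sigma,canny_low,canny_high Canny settings
#'   ([detect_edges()]).
#' @param roi_margin ROI dilation in pixels ([extract_roi()]).
#' @param center_fraction,noise_floor,aggregate column-scan settings
#'   ([scan_columns()]).
#' @param intensity `"raw"` (default) or `"enhanced"`: which image the
#'   FWHM column scan reads.
#' @param ... metadata forwarded to [standardize()].
#' @return a list of class `vessel_measurement`: `measurement` (a
#'   [diameter_measurement()]), plus the intermediates `cross`,
#'   `enhanced`, `edge_map`, `roi` and a `settings` record.
#' @export
measure_vessel <- function(image, um_per_px, vessel_class = c("artery", "vein"),
                           size = 512L, clip_limit = 2, tile_grid = c(8L, 8L),
                           canny_sigma = 1.4, canny_low = NULL,
                           canny_high = NULL, roi_margin = 10L,
                           center_fraction = 0.2, noise_floor = 2,
                           aggregate = "median",
                           intensity = c("raw", "enhanced"), ...) {
  vessel_class <- match.arg(vessel_class)
  intensity <- match.arg(intensity)
  cross <- standardize(image, um_per_px, size = size,
                       vessel_class = vessel_class, ...)
  enhanced <- enhance_contrast(cross, clip_limit = clip_limit,
                               tile_grid = tile_grid)
  edges <- detect_edges(enhanced, low = canny_low, high = canny_high,
                        sigma = canny_sigma)
  roi <- extract_roi(cross, edges, margin = roi_margin,
                     enhanced = if (intensity == "enhanced") enhanced
                                else cross$pixels)
  meas <- scan_columns(roi, cross, center_fraction = center_fraction,
                       noise_floor = noise_floor, aggregate = aggregate)
  structure(
    list(measurement = meas, cross = cross, enhanced = enhanced,
         edge_map = edges, roi = roi,
         settings = list(intensity_source = intensity,
                         clip_limit = clip_limit, tile_grid = tile_grid,
                         canny_sigma = canny_sigma,
                         center_fraction = center_fraction,
                         noise_floor = noise_floor, aggregate = aggregate)),
    class = "vessel_measurement"
  )
}

#' @export
print.vessel_measurement <- function(x, ...) {
  print(x$measurement)
  b <- x$roi$roi_bounds
  cat(sprintf("  ROI rows %d..%d cols %d..%d; %s intensity\n",
              b[1], b[3], b[2], b[4], x$settings$intensity_source))
  invisible(x)
}
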