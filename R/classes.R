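#' Vessel cross-section container
#'
#' A single grayscale OCT crop of one vessel together with its physical
#' calibration and bookkeeping metadata. Pixel values live on the 8-bit
#' scale `[0, 255]` (stored as doubles); pixel centres sit at integer
#' coordinates `1..nrow` / `1..ncol`, so a pixel spans half a pixel to
#' either side of its centre.
#'
#' @param pixels numeric matrix in `[0, 255]`.
#' @param um_per_px physical pixel pitch, micrometres per pixel (> 0).
#' @param vessel_class `"artery"`, `"vein"`, or `NA` when not yet known.
#' @param eye `"left"`, `"right"`, or `NA`.
#' @param subject_id,image_id free-form identifiers.
#' @return an object of class `vessel_cross_section`.
#' @export
vessel_cross_section <- function(pixels, um_per_px, vessel_class = NA_character_,
                                 eye = NA_character_, subject_id = NA_character_,
                                 image_id = NA_character_) {
  pixels <- as_pixel_matrix(pixels)
  if (length(pixels) == 0L) stop("zero-sized image")
  stopifnot(is.numeric(um_per_px), length(um_per_px) == 1L)
  if (!is.finite(um_per_px) || um_per_px <= 0) {
    stop("um_per_px must be a positive number")
  }
  if (!is.na(vessel_class)) {
    vessel_class <- match.arg(vessel_class, c("artery", "vein"))
  }
  if (!is.na(eye)) eye <- match.arg(eye, c("left", "right"))
  structure(
    list(pixels = pixels, um_per_px = um_per_px, vessel_class = vessel_class,
         eye = eye, subject_id = subject_id, image_id = image_id),
    class = "vessel_cross_section"
  )
}

#' @export
print.vessel_cross_section <- function(x, ...) {
  cat(sprintf("<vessel_cross_section> %d x %d px, %.4g um/px, class=%s, eye=%s\n",
              nrow(x$pixels), ncol(x$pixels), x$um_per_px,
              x$vessel_class, x$eye))
  invisible(x)
}

#' Four vessel-edge positions along one pixel column
#'
#' Sub-pixel row positions of the four wall boundaries met when walking
#' down a column: entry into the top wall band (`outer_top`), wall-to-lumen
#' transition (`lumen_top`), lumen-to-wall transition (`lumen_bottom`) and
#' exit from the bottom wall band (`outer_bottom`). An edge detected
#' between samples `i` and `i + 1` is reported at `i + 0.5`.
#'
#' @param outer_top,lumen_top,lumen_bottom,outer_bottom strictly increasing
#'   sub-pixel row positions.
#' @param column_index pixel column the profile was taken from.
#' @param quality non-negative score: the sum of the four absolute
#'   first-difference maxima at the edges.
#' @param polarity `"bright"` for hyperreflective walls (the usual OCT
#'   appearance), `"dark"` for the inverted pattern.
#' @return an object of class `edge_set`.
#' @export
edge_set <- function(outer_top, lumen_top, lumen_bottom, outer_bottom,
                     column_index = NA_integer_, quality = NA_real_,
                     polarity = NA_character_) {
  e <- c(outer_top, lumen_top, lumen_bottom, outer_bottom)
  if (any(!is.finite(e)) || any(diff(e) <= 0)) {
    stop("edges must satisfy outer_top < lumen_top < lumen_bottom < outer_bottom")
  }
  structure(
    list(outer_top = outer_top, lumen_top = lumen_top,
         lumen_bottom = lumen_bottom, outer_bottom = outer_bottom,
         column_index = column_index, quality = quality, polarity = polarity),
    class = "edge_set"
  )
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf(
    "<edge_set> col %s: outer [%.1f, %.1f], lumen [%.1f, %.1f] (quality %.3g)\n",
    format(x$column_index), x$outer_top, x$outer_bottom,
    x$lumen_top, x$lumen_bottom, x$quality))
  invisible(x)
}

#' One vessel's diameters measured on one image
#'
#' @param outer_diameter,lumen_diameter diameters in micrometres,
#'   `0 < lumen < outer`.
#' @param vessel_class `"artery"` or `"vein"` (or `NA`).
#' @param n_columns_used number of candidate columns that produced a valid
#'   edge set and entered the aggregate.
#' @param image_id identifier of the source image.
#' @param columns optional per-column diagnostics data frame.
#' @param aggregate how the per-column extents were combined.
#' @return an object of class `diameter_measurement`.
#' @export
diameter_measurement <- function(outer_diameter, lumen_diameter,
                                 vessel_class = NA_character_,
                                 n_columns_used = NA_integer_,
                                 image_id = NA_character_,
                                 columns = NULL, aggregate = NA_character_) {
  stopifnot(is.numeric(outer_diameter), is.numeric(lumen_diameter))
  if (!(lumen_diameter > 0 && outer_diameter > lumen_diameter)) {
    stop("require 0 < lumen_diameter < outer_diameter")
  }
  structure(
    list(outer_diameter = outer_diameter, lumen_diameter = lumen_diameter,
         vessel_class = vessel_class, n_columns_used = n_columns_used,
         image_id = image_id, columns = columns, aggregate = aggregate),
    class = "diameter_measurement"
  )
}

#' @export
print.diameter_measurement <- function(x, ...) {
  cat(sprintf(
    "<diameter_measurement> %s: outer %.2f um, lumen %.2f um (%s over %s columns)\n",
    x$vessel_class, x$outer_diameter, x$lumen_diameter,
    x$aggregate, format(x$n_columns_used)))
  invisible(x)
}
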