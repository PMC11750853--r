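#' Specification of a synthetic OCT vessel phantom
#'
#' Describes an annular vessel cross-section rendered into a speckle-noisy
#' grayscale frame: a bright wall ring of thickness
#' `(outer_diameter - lumen_diameter) / 2` around a darker lumen on a dark
#' background, optionally Gaussian-blurred (a stand-in for the imaging
#' point-spread function) and corrupted by additive Gaussian speckle.
#'
#' Eccentricity and tilt are stress parameters for the edge detector and
#' default to zero: scan lines are normally set perpendicular to the vessel,
#' so the nominal cross-section is circular.
#'
#' @param outer_diameter,lumen_diameter physical diameters in micrometres;
#'   `0 < lumen_diameter < outer_diameter`.
#' @param image_size frame side length in pixels (default 512).
#' @param center `(row, col)` centre of the annulus in pixel coordinates;
#'   defaults to `image_size / 2`.
#' @param wall_intensity,lumen_intensity,background_intensity gray levels in
#'   `[0, 255]`; the wall must be brighter than both lumen and background
#'   (hyperreflective wall).
#' @param speckle_sigma standard deviation of the additive Gaussian noise,
#'   gray levels.
#' @param blur_sigma Gaussian blur sigma in pixels (0 = no blur).
#' @param um_per_px physical pixel pitch in micrometres per pixel.
#' @param eccentricity horizontal squeeze of the annulus in `[0, 0.9]`;
#'   0 gives a circle.
#' @param tilt_deg rotation of the (possibly eccentric) annulus in degrees.
#' @param seed integer seed; the same seed and spec give a bit-identical
#'   image.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(outer_diameter, lumen_diameter, image_size = 512L,
                         center = NULL, wall_intensity = 200,
                         lumen_intensity = 60, background_intensity = 20,
                         speckle_sigma = 0, blur_sigma = 0, um_per_px = 1,
                         eccentricity = 0, tilt_deg = 0, seed = NULL) {
  stopifnot(is.numeric(outer_diameter), is.numeric(lumen_diameter),
            is.numeric(image_size), image_size >= 8)
  if (!(lumen_diameter > 0 && outer_diameter > lumen_diameter)) {
    stop("require 0 < lumen_diameter < outer_diameter")
  }
  if (!(wall_intensity > lumen_intensity &&
        wall_intensity > background_intensity)) {
    stop("wall_intensity must exceed both lumen and background intensity")
  }
  if (um_per_px <= 0) stop("um_per_px must be positive")
  if (speckle_sigma < 0 || blur_sigma < 0) stop("sigmas must be non-negative")
  if (eccentricity < 0 || eccentricity > 0.9) {
    stop("eccentricity must lie in [0, 0.9]")
  }
  center <- center %||% c(image_size / 2, image_size / 2)
  stopifnot(length(center) == 2L)
  structure(
    list(image_size = as.integer(image_size),
         outer_diameter = outer_diameter, lumen_diameter = lumen_diameter,
         center = as.numeric(center), wall_intensity = wall_intensity,
         lumen_intensity = lumen_intensity,
         background_intensity = background_intensity,
         speckle_sigma = speckle_sigma, blur_sigma = blur_sigma,
         um_per_px = um_per_px, eccentricity = eccentricity,
         tilt_deg = tilt_deg, seed = seed),
    class = "phantom_spec"
  )
}

#' Render a synthetic vessel phantom with known ground truth
#'
#' Rasterizes the annulus described by `spec` (a pixel belongs to a region
#' when its centre lies inside that region's boundary), applies Gaussian
#' blur and additive speckle, and records the exact edge positions on the
#' central column.
#'
#' Two flavours of truth are reported. `ground_truth` holds the sub-pixel
#' transition positions actually present in the rasterized image (half-way
#' between the last pixel outside and the first pixel inside a region) --
#' this is what a perfect edge detector recovers. The attribute
#' `nominal` holds the continuous-geometry positions `center_row +- radius`
#' and the nominal diameters in micrometres; rasterization makes the two
#' differ by at most one pixel.
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `vessel_phantom` with elements
#'   `cross` (a [vessel_cross_section()]), `ground_truth` (an
#'   [edge_set()] on the central column, with attribute `nominal`),
#'   and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(160, 136, um_per_px = 0.5, seed = 1))
#' ph$ground_truth
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  r_out <- spec$outer_diameter / 2 / spec$um_per_px
  r_lum <- spec$lumen_diameter / 2 / spec$um_per_px
  if (spec$outer_diameter / spec$um_per_px >= n ||
      spec$center[1] - r_out < 1 || spec$center[1] + r_out > n ||
      spec$center[2] - r_out < 1 || spec$center[2] + r_out > n) {
    stop("vessel does not fit in frame: reduce outer_diameter or um_per_px")
  }
  dr <- matrix(seq_len(n) - spec$center[1], n, n)
  dc <- matrix(seq_len(n) - spec$center[2], n, n, byrow = TRUE)
  if (spec$tilt_deg != 0) {
    th <- spec$tilt_deg * pi / 180
    dr2 <- cos(th) * dr - sin(th) * dc
    dc <- sin(th) * dr + cos(th) * dc
    dr <- dr2
  }
  if (spec$eccentricity > 0) dc <- dc / (1 - spec$eccentricity)
  dist <- sqrt(dr^2 + dc^2)

  img <- matrix(spec$background_intensity, n, n)
  img[dist <= r_out] <- spec$wall_intensity
  img[dist <= r_lum] <- spec$lumen_intensity

  col0 <- round(spec$center[2])
  in_out <- which(dist[, col0] <= r_out)
  in_lum <- which(dist[, col0] <= r_lum)
  if (length(in_lum) == 0L || length(in_out) <= length(in_lum)) {
    stop("lumen or wall unresolved on the central column at this calibration")
  }
  gt <- edge_set(outer_top = min(in_out) - 0.5,
                 lumen_top = min(in_lum) - 0.5,
                 lumen_bottom = max(in_lum) + 0.5,
                 outer_bottom = max(in_out) + 0.5,
                 column_index = col0, polarity = "bright")
  attr(gt, "nominal") <- list(
    outer_rows = spec$center[1] + c(-1, 1) * r_out,
    lumen_rows = spec$center[1] + c(-1, 1) * r_lum,
    outer_diameter_um = spec$outer_diameter,
    lumen_diameter_um = spec$lumen_diameter)

  if (spec$blur_sigma > 0) {
    img <- EBImage::imageData(EBImage::gblur(img, sigma = spec$blur_sigma))
  }
  if (spec$speckle_sigma > 0) {
    noise <- if (is.null(spec$seed)) {
      stats::rnorm(n * n, 0, spec$speckle_sigma)
    } else {
      withr::with_seed(spec$seed, stats::rnorm(n * n, 0, spec$speckle_sigma))
    }
    img <- img + matrix(noise, n, n)
  }
  img <- clamp(img, 0, 255)

  cross <- vessel_cross_section(img, um_per_px = spec$um_per_px,
                                image_id = sprintf("phantom_seed%s",
                                                   spec$seed %||% "NA"))
  structure(list(cross = cross, ground_truth = gt, spec = spec),
            class = "vessel_phantom")
}

#' Write a phantom to disk as 8-bit PNG plus JSON sidecar
#'
#' The sidecar records the calibration, the generating spec and both the
#' rasterized and nominal ground-truth edges, so a phantom on disk is fully
#' self-describing.
#'
#' @param phantom a `vessel_phantom` from [generate_phantom()].
#' @param png_path,json_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_phantom <- function(phantom, png_path, json_path = NULL) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  json_path <- json_path %||% sub("\\.png$", ".json", png_path)
  png::writePNG(phantom$cross$pixels / 255, png_path)
  gt <- phantom$ground_truth
  sidecar <- list(
    um_per_px = phantom$cross$um_per_px,
    ground_truth = gt[c("outer_top", "lumen_top", "lumen_bottom",
                        "outer_bottom", "column_index")],
    nominal = attr(gt, "nominal"),
    spec = unclass(phantom$spec))
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(png = png_path, json = json_path))
}

#' Read a phantom written by [write_phantom()]
#'
#' @param png_path path to the PNG written by [write_phantom()]; the JSON
#'   sidecar is expected next to it unless given explicitly.
#' @param json_path optional explicit sidecar path.
#' @return a list with elements `cross` and `ground_truth`.
#' @export
read_phantom <- function(png_path, json_path = NULL) {
  json_path <- json_path %||% sub("\\.png$", ".json", png_path)
  px <- png::readPNG(png_path)
  if (length(dim(px)) > 2) px <- apply(px, c(1, 2), mean)
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  gt <- side$ground_truth
  es <- edge_set(gt$outer_top, gt$lumen_top, gt$lumen_bottom,
                 gt$outer_bottom, column_index = gt$column_index)
  attr(es, "nominal") <- side$nominal
  list(cross = vessel_cross_section(px * 255, um_per_px = side$um_per_px),
       ground_truth = es)
}
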