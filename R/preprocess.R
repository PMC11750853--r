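#' Standardize a raw OCT crop to a 512 x 512 isotropic frame
#'
#' Reproduces the conditioning every crop goes through before edge
#' analysis: anisotropic pixel pitches are first resampled to a 1:1 um
#' aspect, the frame is then scaled uniformly so its longer side is `size`
#' pixels and padded (edge-median gray) to `size x size`, and the
#' calibration is updated so physical distances are preserved. Intensity
#' is interpolated bilinearly; pixel centres sit at integer coordinates,
#' i.e. pixel `(1, 1)` is centred at physical
#' `(0.5 * um_per_px, 0.5 * um_per_px)` from the frame corner.
#'
#' An input that is already `size x size` with a scalar calibration is
#' returned unchanged.
#'
#' @param image numeric matrix (any gray range; values are clamped to
#'   `[0, 255]`), or an `EBImage::Image`.
#' @param um_per_px input pixel pitch in um/px: a scalar for isotropic
#'   input, or `c(row_pitch, col_pitch)` for anisotropic input.
#' @param size output side length in pixels.
#' @param ... metadata forwarded to [vessel_cross_section()]
#'   (`vessel_class`, `eye`, `subject_id`, `image_id`).
#' @return a [vessel_cross_section()] of shape `size x size`.
#' @export
standardize <- function(image, um_per_px, size = 512L, ...) {
  image <- as_pixel_matrix(image)
  if (length(image) == 0L || any(dim(image) == 0L)) stop("zero-sized input")
  if (!is.numeric(um_per_px) || !length(um_per_px) %in% c(1L, 2L) ||
      any(um_per_px <= 0) || any(!is.finite(um_per_px))) {
    stop("um_per_px must be one or two positive numbers")
  }
  um <- rep_len(as.numeric(um_per_px), 2L)

  if (all(dim(image) == size) && um[1] == um[2]) {
    return(vessel_cross_section(clamp(image, 0, 255), um_per_px = um[1], ...))
  }

  resize2 <- function(x, d1, d2) {
    EBImage::imageData(EBImage::resize(x, w = d1, h = d2,
                                       filter = "bilinear"))
  }

  # step 1: isotropic resample at the finer of the two pitches
  if (um[1] != um[2]) {
    p <- min(um)
    newdim <- pmax(1L, as.integer(round(dim(image) * um / p)))
    image <- resize2(image, newdim[1], newdim[2])
    um <- c(p, p)
  }

  # step 2: uniform scale so the longer side is `size`, then pad square
  f <- size / max(dim(image))
  if (f != 1) {
    newdim <- pmax(1L, as.integer(round(dim(image) * f)))
    image <- resize2(image, newdim[1], newdim[2])
    um <- um / f
  }
  if (!all(dim(image) == size)) {
    border <- c(image[c(1, nrow(image)), ], image[, c(1, ncol(image))])
    out <- matrix(stats::median(border), size, size)
    r0 <- floor((size - nrow(image)) / 2)
    c0 <- floor((size - ncol(image)) / 2)
    out[r0 + seq_len(nrow(image)), c0 + seq_len(ncol(image))] <- image
    image <- out
  }
  vessel_cross_section(clamp(image, 0, 255), um_per_px = um[1], ...)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Applies CLAHE per tile to boost local contrast ahead of edge detection.
#' Output stays on the `[0, 255]` scale. A constant image is returned
#' unchanged (there is no contrast to amplify).
#'
#' @param img a [vessel_cross_section()] or numeric matrix in `[0, 255]`.
#' @param clip_limit contrast clip limit (> 0); higher values allow more
#'   amplification.
#' @param tile_grid integer `(nx, ny)` number of tiles in each direction.
#' @return numeric matrix in `[0, 255]`, same shape as the input.
#' @export
enhance_contrast <- function(img, clip_limit = 2, tile_grid = c(8L, 8L)) {
  x <- as_pixel_matrix(img)
  if (!is.numeric(clip_limit) || clip_limit <= 0) {
    stop("clip_limit must be positive")
  }
  tile_grid <- rep_len(as.integer(tile_grid), 2L)
  if (any(tile_grid < 1L)) stop("tile counts must be positive integers")
  if (diff(range(x)) == 0) return(x)
  y <- EBImage::clahe(x / 255, nx = tile_grid[1], ny = tile_grid[2],
                      limit = clip_limit)
  clamp(EBImage::imageData(y) * 255, 0, 255)
}

gaussian_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  outer(k, k)
}

shift_mat <- function(x, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(x), ncol(x))
  rs <- seq_len(nrow(x)) - dr
  cs <- seq_len(ncol(x)) - dc
  ok_r <- rs >= 1 & rs <= nrow(x)
  ok_c <- cs >= 1 & cs <= ncol(x)
  out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
  out
}

#' Canny edge detection
#'
#' Standard Canny chain: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, and double-threshold
#' hysteresis (weak edge pixels survive only when 8-connected to a strong
#' one). Deterministic; no RNG involved.
#'
#' When `low`/`high` are `NULL` the thresholds are picked automatically
#' from the gradient-magnitude histogram: `high` is Otsu's threshold on
#' the magnitudes and `low = high / 2`.
#'
#' @param enhanced numeric matrix (typically the output of
#'   [enhance_contrast()]).
#' @param low,high hysteresis thresholds on gradient magnitude,
#'   `0 <= low < high`, or `NULL` for automatic selection.
#' @param sigma Gaussian smoothing sigma in pixels (0 disables smoothing).
#' @return logical matrix marking edge pixels.
#' @export
detect_edges <- function(enhanced, low = NULL, high = NULL, sigma = 1.4) {
  x <- as_pixel_matrix(enhanced)
  if (!is.null(low) && !is.null(high) && low >= high) {
    stop("require low < high")
  }
  if (sigma > 0) {
    x <- EBImage::imageData(
      EBImage::filter2(x, gaussian_kernel(sigma), boundary = "replicate"))
  }
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # Sobel, d/d(col)
  gx <- EBImage::imageData(EBImage::filter2(x, kx, boundary = "replicate"))
  gy <- EBImage::imageData(EBImage::filter2(x, t(kx), boundary = "replicate"))
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  # FFT round-off leaves ~1e-13 residuals on flat input; anything below a
  # millionth of a gray level is no gradient
  if (mmax < 1e-6) return(matrix(FALSE, nrow(x), ncol(x)))

  if (is.null(high)) {
    high <- as.numeric(EBImage::otsu(EBImage::Image(mag / mmax),
                                     range = c(0, 1))) * mmax
    low <- low %||% (high / 2)
  } else {
    low <- low %||% (high / 2)
  }

  # non-maximum suppression in 4 quantized directions; gradient vector is
  # (d_row, d_col) = (gy, gx)
  ang <- atan2(gy, gx) %% pi
  sector <- (floor(ang / (pi / 4) + 0.5) %% 4)
  neigh <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(-1L, 1L))
  nms <- matrix(FALSE, nrow(x), ncol(x))
  for (s in 0:3) {
    d <- neigh[[s + 1L]]
    sel <- sector == s
    keep <- mag >= shift_mat(mag, d[1], d[2]) &
            mag >= shift_mat(mag, -d[1], -d[2])
    nms[sel & keep] <- TRUE
  }

  strong <- nms & mag >= high
  weak <- nms & mag >= low
  if (!any(strong)) return(matrix(FALSE, nrow(x), ncol(x)))
  lab <- label_components(weak)
  keep_labels <- unique(lab[strong])
  weak & matrix(lab %in% keep_labels, nrow(x), ncol(x))
}

#' Region-of-interest extraction from an edge map
#'
#' The ROI is the bounding box of the largest 8-connected edge structure
#' (in a single-vessel crop the vessel dominates the edge map), dilated by
#' `margin` pixels and clipped to the frame. The box is annotated, not
#' cropped: downstream column scans index the full standardized image with
#' these bounds.
#'
#' @param cross a [vessel_cross_section()].
#' @param edge_map logical matrix from [detect_edges()], same shape as the
#'   image.
#' @param margin dilation of the bounding box in pixels.
#' @param enhanced optional contrast-enhanced image to carry along for the
#'   intensity analysis; defaults to the cross-section's pixels.
#' @return a list of class `roi_result` with elements `enhanced`,
#'   `edge_map` and `roi_bounds = c(row0, col0, row1, col1)` (1-based,
#'   inclusive).
#' @export
extract_roi <- function(cross, edge_map, margin = 10L, enhanced = NULL) {
  stopifnot(inherits(cross, "vessel_cross_section"))
  edge_map <- edge_map != 0
  if (!any(edge_map)) {
    stop_octvessel("no vessel found: empty edge map", "octvessel_no_vessel")
  }
  if (!all(dim(edge_map) == dim(cross$pixels))) {
    stop("edge map shape does not match the image")
  }
  lab <- label_components(edge_map)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  idx <- which(lab == big)
  nr <- nrow(edge_map)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  b <- c(max(1L, min(r) - margin), max(1L, min(cc) - margin),
         min(nr, max(r) + margin), min(ncol(edge_map), max(cc) + margin))
  structure(
    list(enhanced = enhanced %||% cross$pixels, edge_map = edge_map,
         roi_bounds = as.integer(b)),
    class = "roi_result"
  )
}

#' @export
print.roi_result <- function(x, ...) {
  b <- x$roi_bounds
  cat(sprintf("<roi_result> rows %d..%d, cols %d..%d (%d edge px)\n",
              b[1], b[3], b[2], b[4], sum(x$edge_map)))
  invisible(x)
}
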