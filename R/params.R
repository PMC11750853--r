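#' Derive the eleven vessel-wall parameters from the four diameters
#'
#' Given retinal arteriolar outer/lumen diameters (RAOD/RALD) and venular
#' outer/lumen diameters (RVOD/RVLD), all in micrometres, computes
#'
#' \describe{
#'   \item{AWT, VWT}{wall thickness, `(outer - lumen) / 2` (um)}
#'   \item{AWLR, VWLR}{wall-to-lumen ratio, `WT / lumen` (dimensionless)}
#'   \item{AWCSA, VWCSA}{wall cross-sectional area of the annulus,
#'     `(outer^2 - lumen^2) * pi_tilde / 4` (um^2)}
#'   \item{AVR}{arteriovenous ratio, `RAOD / RVOD` (dimensionless)}
#' }
#'
#' `pi_tilde` defaults to 3.14 exactly, reproducing the convention the
#' reference values were computed with; pass `pi` for the true circle
#' constant. Values are stored at full precision; rounding to four
#' decimals happens only at report time.
#'
#' A zero-thickness wall (`outer == lumen`) is accepted as a degenerate
#' case (WT, WLR and WCSA all 0); `outer < lumen` is rejected with a
#' message naming the offending pair.
#'
#' @param raod,rald,rvod,rvld numeric vectors of diameters in um, recycled
#'   to a common length; require `raod >= rald > 0` and `rvod >= rvld > 0`.
#' @param pi_tilde circle constant used in the wall-area formula.
#' @return a data frame with columns `RAOD, RALD, RVOD, RVLD, AWT, VWT,
#'   AWLR, VWLR, AWCSA, VWCSA, AVR`.
#' @examples
#' compute_params(122.0836, 94.5531, 168.2741, 142.9281)
#' @export
compute_params <- function(raod, rald, rvod, rvld, pi_tilde = 3.14) {
  n <- max(length(raod), length(rald), length(rvod), length(rvld))
  raod <- rep_len(raod, n); rald <- rep_len(rald, n)
  rvod <- rep_len(rvod, n); rvld <- rep_len(rvld, n)
  if (!all(is.finite(c(raod, rald, rvod, rvld)))) {
    stop("diameters must be finite numbers")
  }
  if (any(rald <= 0) || any(rvld <= 0)) {
    stop("lumen diameters must be positive")
  }
  bad_a <- which(raod < rald)
  if (length(bad_a)) {
    stop(sprintf("artery pair violates outer >= lumen at index %d (%.4f < %.4f)",
                 bad_a[1], raod[bad_a[1]], rald[bad_a[1]]))
  }
  bad_v <- which(rvod < rvld)
  if (length(bad_v)) {
    stop(sprintf("vein pair violates outer >= lumen at index %d (%.4f < %.4f)",
                 bad_v[1], rvod[bad_v[1]], rvld[bad_v[1]]))
  }
  awt <- (raod - rald) / 2
  vwt <- (rvod - rvld) / 2
  data.frame(
    RAOD = raod, RALD = rald, RVOD = rvod, RVLD = rvld,
    AWT = awt, VWT = vwt,
    AWLR = awt / rald, VWLR = vwt / rvld,
    AWCSA = (raod^2 - rald^2) * pi_tilde / 4,
    VWCSA = (rvod^2 - rvld^2) * pi_tilde / 4,
    AVR = raod / rvod)
}

#' Average repeat measurements of one vessel
#'
#' A vessel is scanned on several repeat images (the protocol asks for at
#' least five clear ones); the per-subject diameters are the arithmetic
#' means across images. Fewer than five supplied measurements triggers a
#' warning, not an error.
#'
#' @param measurements a list of [diameter_measurement()]s of one vessel,
#'   or a 2-column numeric matrix/data frame `(outer, lumen)` in um.
#' @return named numeric vector `c(outer = , lumen = )` in um.
#' @export
average_repeats <- function(measurements) {
  if (inherits(measurements, "diameter_measurement")) {
    measurements <- list(measurements)
  }
  if (is.list(measurements) && !is.data.frame(measurements)) {
    stopifnot(length(measurements) >= 1L)
    cls <- unique(stats::na.omit(vapply(measurements, `[[`, character(1),
                                        "vessel_class")))
    if (length(cls) > 1L) {
      stop("measurements mix vessel classes: ", paste(cls, collapse = ", "))
    }
    m <- cbind(vapply(measurements, `[[`, numeric(1), "outer_diameter"),
               vapply(measurements, `[[`, numeric(1), "lumen_diameter"))
  } else {
    m <- as.matrix(measurements)
    if (ncol(m) != 2L || nrow(m) < 1L) {
      stop("expected a non-empty 2-column (outer, lumen) table")
    }
  }
  if (nrow(m) < 5L) {
    warning(sprintf("only %d repeat image(s) supplied; the protocol asks for >= 5",
                    nrow(m)))
  }
  c(outer = mean(m[, 1]), lumen = mean(m[, 2]))
}

#' Choose which eye enters the per-subject analysis
#'
#' The right eye is used whenever it carries complete artery and vein
#' measurements; otherwise the left eye is used. An eye is complete when
#' both an artery and a vein entry are present (non-NULL).
#'
#' @param right,left per-eye data: a list with elements `artery` and
#'   `vein` (each anything non-NULL, typically measurement lists), or
#'   `NULL` when the eye was not imaged.
#' @return a list with elements `eye` (`"right"` or `"left"`) and `data`
#'   (the chosen eye's input).
#' @export
select_eye <- function(right = NULL, left = NULL) {
  complete <- function(e) {
    !is.null(e) && !is.null(e$artery) && !is.null(e$vein)
  }
  if (complete(right)) return(list(eye = "right", data = right))
  if (complete(left)) return(list(eye = "left", data = left))
  stop("neither eye has complete artery and vein measurements")
}
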