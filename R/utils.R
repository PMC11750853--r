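`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_octvessel <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "octvessel_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

as_pixel_matrix <- function(image) {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (inherits(image, "vessel_cross_section")) image <- image$pixels
  if (is.array(image) && length(dim(image)) > 2) {
    # collapse colour planes to grayscale by averaging
    image <- apply(image, c(1, 2), mean)
  }
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("expected a 2-D numeric grayscale image")
  }
  image
}

#' Label connected components of a binary mask (8-connectivity)
#'
#' Foreground pixels that touch horizontally, vertically or diagonally share
#' a label. Used for Canny hysteresis and for picking the dominant edge
#' structure when locating the region of interest.
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @return integer matrix of the same shape; 0 is background, components are
#'   numbered from 1.
#' @keywords internal
label_components <- function(mask) {
  mask <- mask != 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  m <- length(idx)
  if (m == 0L) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  pos <- integer(nr * nc)
  pos[idx] <- seq_len(m)
  # forward half of the 8-neighbourhood is enough for an undirected graph
  offs <- list(c(1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L))
  el <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    rn <- r + offs[[k]][1L]; cn <- cc + offs[[k]][2L]
    ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    if (!any(ok)) next
    nidx <- (cn[ok] - 1L) * nr + rn[ok]
    hit <- pos[nidx] > 0L
    if (any(hit)) el[[k]] <- cbind(which(ok)[hit], pos[nidx[hit]])
  }
  el <- do.call(rbind, el)
  if (is.null(el) || nrow(el) == 0L) {
    lab[idx] <- seq_len(m)
    return(lab)
  }
  g <- igraph::make_graph(edges = as.vector(t(el)), n = m, directed = FALSE)
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

round4 <- function(x) round(x, 4)

fmt4 <- function(x) formatC(x, digits = 4, format = "f")
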