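#' First-difference sequence of a grayscale profile
#'
#' Element `i` is `gray[i + 1] - gray[i]`; the sequence is one element
#' shorter than the profile and reflects the local rate of change of the
#' gray values, which is what highlights edges.
#'
#' @param gray numeric vector of gray values, length >= 2.
#' @return numeric vector of first differences.
#' @examples
#' difference_sequence(c(10, 10, 100, 100, 10))
#' @export
difference_sequence <- function(gray) {
  gray <- as.numeric(gray)
  if (length(gray) < 2L) stop("profile must have at least 2 samples")
  diff(gray)
}

#' Segment a difference sequence into signed groups
#'
#' Maximal runs of same-signed differences become groups; runs of zeros
#' are the zero points that separate them (a zero marks a turning point of
#' the gray values). Values with `|diff| < noise_floor` are suppressed
#' (treated as zero) first, and same-signed groups separated *only by
#' suppressed values* are merged back together -- without this, speckle
#' fragments every profile into micro-groups. Same-signed groups
#' separated by exact zeros (a true gray-value plateau) remain distinct:
#' an exact zero is a genuine turning point, not noise.
#'
#' @param d numeric difference sequence (from [difference_sequence()]).
#' @param noise_floor magnitude below which a difference counts as zero
#'   (gray levels); 0 keeps every non-zero value.
#' @return an object of class `fwhm_groups`: a list with
#'   `groups` (data frame with columns `sign`, `start`, `end`, index
#'   ranges into `d`), `zero_points` (positions treated as zero) and
#'   `n_diff` (length of `d`). A flat profile yields zero groups.
#' @examples
#' segment_groups(c(0, 90, 0, -90))
#' @export
segment_groups <- function(d, noise_floor = 0) {
  stopifnot(is.numeric(d), length(d) >= 1L, noise_floor >= 0)
  s <- sign(d)
  if (noise_floor > 0) s[abs(d) < noise_floor] <- 0
  zero_points <- which(s == 0)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  g <- data.frame(sign = r$values[keep], start = starts[keep],
                  end = ends[keep])
  # merge same-signed neighbours separated only by suppressed (sub-floor,
  # non-zero) values; an exact-zero plateau keeps groups apart
  if (nrow(g) > 1L) {
    merged <- g[1, ]
    for (i in 2:nrow(g)) {
      last <- nrow(merged)
      has_gap <- g$start[i] - merged$end[last] > 1L
      gap <- if (has_gap) (merged$end[last] + 1L):(g$start[i] - 1L) else integer(0)
      mergeable <- g$sign[i] == merged$sign[last] &&
        has_gap && all(d[gap] != 0)
      if (mergeable) {
        merged$end[last] <- g$end[i]
      } else {
        merged <- rbind(merged, g[i, ])
      }
    }
    g <- merged
  }
  rownames(g) <- NULL
  structure(list(groups = g, zero_points = zero_points,
                 n_diff = length(d)),
            class = "fwhm_groups")
}

#' @export
print.fwhm_groups <- function(x, ...) {
  cat(sprintf("<fwhm_groups> %d group(s) over %d differences\n",
              nrow(x$groups), x$n_diff))
  if (nrow(x$groups)) {
    cat(paste0(sprintf("  %s [%d..%d]",
                       ifelse(x$groups$sign > 0, "+", "-"),
                       x$groups$start, x$groups$end),
               collapse = "\n"), "\n")
  }
  invisible(x)
}

has_pattern <- function(signs, pattern) {
  j <- 1L
  for (s in signs) {
    if (s == pattern[j]) {
      j <- j + 1L
      if (j > length(pattern)) return(TRUE)
    }
  }
  FALSE
}

#' Discard leading/trailing background groups
#'
#' A profile whose very first difference is positive, or whose very last
#' difference is negative, starts or ends mid-gradient: those boundary
#' groups typically belong to the image background or non-feature regions
#' rather than to the wall bands. They are removed -- but only when at
#' least four alternating-signed groups (a wall-band pattern of either
#' polarity) survive the removal, otherwise the groups are returned
#' unchanged.
#'
#' @param groups an `fwhm_groups` object from [segment_groups()].
#' @return an `fwhm_groups` object.
#' @export
discard_background_groups <- function(groups) {
  stopifnot(inherits(groups, "fwhm_groups"))
  g <- groups$groups
  if (nrow(g) < 2L) return(groups)
  drop <- integer(0)
  if (g$sign[1] > 0 && g$start[1] == 1L) drop <- c(drop, 1L)
  if (g$sign[nrow(g)] < 0 && g$end[nrow(g)] == groups$n_diff) {
    drop <- c(drop, nrow(g))
  }
  if (length(drop)) {
    kept <- g[-drop, , drop = FALSE]
    if (has_pattern(kept$sign, c(1, -1, 1, -1)) ||
        has_pattern(kept$sign, c(-1, 1, -1, 1))) {
      groups$groups <- kept
      rownames(groups$groups) <- NULL
    }
  }
  groups
}

# maximum-total-weight subsequence of groups matching a sign pattern;
# weights are each group's peak |difference|
best_pattern_groups <- function(g, peaks, pattern) {
  m <- nrow(g); k <- length(pattern)
  if (m < k) return(NULL)
  score <- matrix(-Inf, m + 1L, k + 1L)
  score[, 1L] <- 0
  pick <- array(FALSE, c(m + 1L, k + 1L))
  for (i in seq_len(m)) {
    for (j in seq_len(k)) {
      skip <- score[i, j + 1L]
      take <- if (g$sign[i] == pattern[j]) score[i, j] + peaks[i] else -Inf
      if (take > skip) {
        score[i + 1L, j + 1L] <- take
        pick[i + 1L, j + 1L] <- TRUE
      } else {
        score[i + 1L, j + 1L] <- skip
      }
    }
  }
  if (!is.finite(score[m + 1L, k + 1L])) return(NULL)
  idx <- integer(k); i <- m; j <- k
  while (j > 0L) {
    if (pick[i + 1L, j + 1L]) {
      idx[j] <- i; j <- j - 1L; i <- i - 1L
    } else {
      i <- i - 1L
    }
  }
  list(indices = idx, score = score[m + 1L, k + 1L])
}

#' Pair groups and locate the four vessel edges
#'
#' With hyperreflective (bright) walls, walking down a column crosses
#' background -> wall -> lumen -> wall -> background, so the expected sign
#' pattern of the difference groups is `+, -, +, -`: rise into the top
#' wall band, fall into the lumen, rise into the bottom band, fall back to
#' background. The four groups realizing that alternating pattern with
#' the greatest total |difference| are selected (the inverted pattern is
#' tried too, to cover dark-walled profiles, and the higher-quality
#' interpretation wins). Within each selected group the edge sits at the
#' position of maximum |difference|, reported at `i + 0.5` -- a first
#' difference lives between samples -- with ties broken toward the profile
#' centre.
#'
#' @param groups an `fwhm_groups` object (after
#'   [discard_background_groups()], typically).
#' @param gray the grayscale profile the groups came from.
#' @param column_index recorded in the returned [edge_set()].
#' @return an [edge_set()]; `quality` is the sum of the four absolute
#'   difference maxima. Fails with a `"no vessel in column"` error when
#'   fewer than four usable alternating groups exist.
#' @export
pair_and_locate_edges <- function(groups, gray, column_index = NA_integer_) {
  stopifnot(inherits(groups, "fwhm_groups"))
  gray <- as.numeric(gray)
  d <- diff(gray)
  if (length(d) != groups$n_diff) {
    stop("profile length does not match the segmented difference sequence")
  }
  g <- groups$groups
  if (nrow(g) < 4L) {
    stop_octvessel("no vessel in column: fewer than 4 signed groups",
                   "octvessel_no_vessel")
  }
  centre <- (length(gray) + 1) / 2
  peak_of <- function(i) {
    idx <- g$start[i]:g$end[i]
    idx <- idx[sign(d[idx]) == g$sign[i]]
    a <- abs(d[idx])
    cand <- idx[a == max(a)]
    cand[order(abs(cand + 0.5 - centre), cand)][1L]
  }
  peak_idx <- vapply(seq_len(nrow(g)), peak_of, numeric(1))
  peak_abs <- abs(d[peak_idx])

  bright <- best_pattern_groups(g, peak_abs, c(1, -1, 1, -1))
  dark <- best_pattern_groups(g, peak_abs, c(-1, 1, -1, 1))
  if (is.null(bright) && is.null(dark)) {
    stop_octvessel("no vessel in column: no alternating wall-band pattern",
                   "octvessel_no_vessel")
  }
  use_bright <- !is.null(bright) &&
    (is.null(dark) || bright$score >= dark$score)
  sel <- if (use_bright) bright else dark
  e <- peak_idx[sel$indices] + 0.5
  edge_set(outer_top = e[1], lumen_top = e[2], lumen_bottom = e[3],
           outer_bottom = e[4], column_index = column_index,
           quality = sel$score,
           polarity = if (use_bright) "bright" else "dark")
}

#' Locate the four vessel edges on one grayscale profile
#'
#' Convenience wrapper chaining [difference_sequence()],
#' [segment_groups()], [discard_background_groups()] and
#' [pair_and_locate_edges()].
#'
#' @param gray numeric profile.
#' @param noise_floor see [segment_groups()]; default 2 gray levels.
#' @param discard_background apply [discard_background_groups()]?
#' @param column_index recorded in the result.
#' @return an [edge_set()].
#' @export
profile_edges <- function(gray, noise_floor = 2, discard_background = TRUE,
                          column_index = NA_integer_) {
  d <- difference_sequence(gray)
  gr <- segment_groups(d, noise_floor = noise_floor)
  if (discard_background) gr <- discard_background_groups(gr)
  pair_and_locate_edges(gr, gray, column_index = column_index)
}
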