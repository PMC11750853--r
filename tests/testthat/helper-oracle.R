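# Independent oracles and fixture builders shared across the tests.
# Everything here is deliberately written from first principles (loops and
# enumeration), not by calling the package's own code paths.

# Build a piecewise-constant profile from a band table.
# bands: data.frame(end = last index of each band, value = gray level);
# bands partition 1..max(end).
make_band_profile <- function(bands) {
  gray <- numeric(max(bands$end))
  start <- 1L
  for (i in seq_len(nrow(bands))) {
    gray[start:bands$end[i]] <- bands$value[i]
    start <- bands$end[i] + 1L
  }
  gray
}

# Canonical bright-wall fixture: background / wall / lumen / wall /
# background, with the four transitions at known sub-pixel positions.
make_vessel_profile <- function(n = 220, wall_top = c(100, 110),
                                wall_bot = c(150, 160),
                                bg = 20, wall = 200, lumen = 60) {
  bands <- data.frame(
    end = c(wall_top[1] - 1L, wall_top[2], wall_bot[1] - 1L, wall_bot[2], n),
    value = c(bg, wall, lumen, wall, bg))
  list(gray = make_band_profile(bands),
       edges = c(wall_top[1] - 0.5, wall_top[2] + 0.5,
                 wall_bot[1] - 0.5, wall_bot[2] + 0.5))
}

# Brute-force edge oracle: enumerate every selection of four same-sign
# difference runs matching the bright (+,-,+,-) or dark (-,+,-,+) pattern,
# score each by the sum of its per-run |difference| maxima, and return the
# best selection's edge positions. Runs are found by a plain scan loop.
brute_force_edges <- function(gray, noise_floor = 0) {
  n <- length(gray)
  d <- numeric(n - 1)
  for (i in seq_len(n - 1)) d[i] <- gray[i + 1] - gray[i]
  s <- ifelse(abs(d) < max(noise_floor, .Machine$double.eps), 0, sign(d))
  runs <- list()
  i <- 1L
  while (i <= length(s)) {
    if (s[i] != 0) {
      j <- i
      while (j < length(s) && s[j + 1] == s[i]) j <- j + 1L
      runs[[length(runs) + 1L]] <- list(sign = s[i], idx = i:j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(runs) < 4L) return(NULL)
  centre <- (n + 1) / 2
  peak <- function(run) {
    a <- abs(d[run$idx])
    cand <- run$idx[a == max(a)]
    cand <- cand[order(abs(cand + 0.5 - centre), cand)]
    list(pos = cand[1] + 0.5, score = max(a))
  }
  best <- NULL
  for (sel in utils::combn(length(runs), 4, simplify = FALSE)) {
    signs <- vapply(runs[sel], `[[`, numeric(1), "sign")
    if (!identical(signs, c(1, -1, 1, -1)) &&
        !identical(signs, c(-1, 1, -1, 1))) next
    pk <- lapply(runs[sel], peak)
    score <- sum(vapply(pk, `[[`, numeric(1), "score"))
    if (is.null(best) || score > best$score) {
      best <- list(edges = vapply(pk, `[[`, numeric(1), "pos"), score = score)
    }
  }
  best
}

# Classical one-way F statistic from the sums-of-squares definition.
fstat_direct <- function(y, g) {
  g <- as.integer(factor(g))
  m <- tapply(y, g, mean)
  n <- tabulate(g)
  ssb <- sum(n * (m - mean(y))^2)
  ssw <- sum((y - m[g])^2)
  (ssb / (length(n) - 1)) / (ssw / (length(y) - length(n)))
}

# Exact permutation p value of the F statistic for three groups of the
# given sizes (full enumeration of group assignments).
exact_perm_p <- function(y, sizes) {
  stopifnot(length(sizes) == 3, sum(sizes) == length(y))
  N <- length(y)
  g0 <- rep(1:3, sizes)
  f0 <- fstat_direct(y, g0)
  ids <- seq_len(N)
  cnt <- 0L; tot <- 0L
  for (a in utils::combn(N, sizes[1], simplify = FALSE)) {
    rest <- setdiff(ids, a)
    for (b in utils::combn(length(rest), sizes[2], simplify = FALSE)) {
      g <- integer(N); g[a] <- 1L; g[rest[b]] <- 2L; g[g == 0L] <- 3L
      tot <- tot + 1L
      if (fstat_direct(y, g) >= f0 - 1e-12) cnt <- cnt + 1L
    }
  }
  cnt / tot
}

# ROI around a phantom's ground-truth annulus, built from the sidecar
# geometry rather than from the edge-detection chain.
phantom_roi <- function(phantom, margin = 5L) {
  gt <- phantom$ground_truth
  ctr <- phantom$spec$center
  r_out <- phantom$spec$outer_diameter / 2 / phantom$spec$um_per_px
  n <- phantom$spec$image_size
  b <- as.integer(c(
    max(1, floor(gt$outer_top) - margin),
    max(1, floor(ctr[2] - r_out) - margin),
    min(n, ceiling(gt$outer_bottom) + margin),
    min(n, ceiling(ctr[2] + r_out) + margin)))
  structure(list(enhanced = phantom$cross$pixels, edge_map = NULL,
                 roi_bounds = b),
            class = "roi_result")
}

# Random bright-wall profile generator for property-style tests; returns
# the profile plus the construction's transition positions. Optionally
# appends a dimmer distractor ring so the pattern search has competing
# candidates.
random_vessel_profile <- function(n = 200, distractor = FALSE) {
  bg <- runif(1, 5, 40)
  wall <- runif(1, 150, 240)
  lumen <- runif(1, bg + 10, wall - 40)
  t1 <- sample(20:60, 1)
  w1 <- sample(5:15, 1)
  lum <- sample(20:60, 1)
  w2 <- sample(5:15, 1)
  top <- c(t1, t1 + w1 - 1)
  bot <- c(t1 + w1 + lum, t1 + w1 + lum + w2 - 1)
  prof <- make_vessel_profile(n, top, bot, bg = bg, wall = wall,
                              lumen = lumen)
  if (distractor) {
    # shallow second ring in the trailing background
    s <- bot[2] + sample(10:20, 1)
    e <- s + sample(4:8, 1)
    if (e < n - 5) prof$gray[s:e] <- bg + runif(1, 8, 25)
  }
  prof
}
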