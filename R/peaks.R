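# Internal 1-D signal helpers: running min/max morphology, peak picking with
# prominences, FWHM estimation and parabolic sub-pixel refinement.

run_extremum <- function(x, width, fun) {
  # centered running window; truncated windows at the edges are equivalent to
  # padding with +Inf (min) / -Inf (max), i.e. replicate-free morphology
  zoo::rollapply(x, width = width, FUN = fun, partial = TRUE, align = "center")
}

# Morphological opening: erosion then dilation. Removes features narrower
# than `width` while following slow baseline trends (offsets, ramps).
open_profile <- function(x, width) {
  run_extremum(run_extremum(x, width, min), width, max)
}

running_mean <- function(x, width) {
  zoo::rollapply(x, width = width, FUN = mean, partial = TRUE, align = "center")
}

# Local maxima with prominences. Returns a tibble sorted by position with
# columns pos, height, prominence. Plateaus report their first index.
find_peaks <- function(x, min_prominence = 0, min_spacing = 1) {
  n <- length(x)
  if (n < 3L) return(tibble(pos = integer(), height = numeric(),
                            prominence = numeric()))
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand)) return(tibble(pos = integer(), height = numeric(),
                                   prominence = numeric()))
  prom <- vapply(cand, function(p) {
    h <- x[p]
    # walk left until a higher point or the edge; track the minimum
    lmin <- h
    k <- p - 1L
    while (k >= 1L && x[k] <= h) { lmin <- min(lmin, x[k]); k <- k - 1L }
    if (k < 1L) lmin <- min(lmin, min(x[1:p]))
    rmin <- h
    k <- p + 1L
    while (k <= n && x[k] <= h) { rmin <- min(rmin, x[k]); k <- k + 1L }
    if (k > n) rmin <- min(rmin, min(x[p:n]))
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(tibble(pos = integer(), height = numeric(),
                                   prominence = numeric()))
  # enforce spacing greedily, strongest peaks first
  ord <- order(-prom, cand)
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(cand[p] - cand[kept]) >= min_spacing)) {
      kept <- c(kept, p)
    }
  }
  kept <- kept[order(cand[kept])]
  tibble(pos = cand[kept], height = x[cand[kept]], prominence = prom[kept])
}

# Full width at half maximum around peak index p, by linear interpolation of
# the half-height crossings. Falls back to the distance to the profile edge.
fwhm_at <- function(x, p) {
  half <- x[p] / 2
  n <- length(x)
  left <- 1
  if (p > 1L) {
    for (k in (p - 1L):1L) {
      if (x[k] <= half) {
        left <- k + (half - x[k]) / (x[k + 1L] - x[k])
        break
      }
    }
  }
  right <- n
  if (p < n) {
    for (k in (p + 1L):n) {
      if (x[k] <= half) {
        right <- k - (half - x[k]) / (x[k - 1L] - x[k])
        break
      }
    }
  }
  max(right - left, .Machine$double.eps)
}

# 3-point parabolic interpolation of a peak center (sub-pixel).
subpixel_center <- function(x, p) {
  if (p <= 1L || p >= length(x)) return(as.numeric(p))
  denom <- x[p - 1L] - 2 * x[p] + x[p + 1L]
  if (denom >= 0) return(as.numeric(p))   # not locally concave
  delta <- 0.5 * (x[p - 1L] - x[p + 1L]) / denom
  p + max(min(delta, 0.5), -0.5)
}
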