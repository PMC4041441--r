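# Blot densitometry: lane detection, profile extraction, background
# correction, marker-band calling, size calibration, smear measurement.

#' Detect lanes on a blot image
#'
#' Lanes are found as peaks of the smoothed column-sum projection, with a
#' minimum prominence (relative to the projection maximum) and a minimum
#' spacing. Manual lane centers in the config override detection, keeping
#' the pipeline semi-automated. Lane column spans are half-open:
#' `[left_col, right_col)` in 1-based column indices.
#'
#' @param image A [gel_image()].
#' @param config A [telka_config()].
#' @return A tibble with one row per lane: `lane`, `center_col`, `left_col`,
#'   `right_col`, ordered left to right. Zero rows (with a warning) when no
#'   lane-like column peak exists.
#' @export
detect_lanes <- function(image, config = telka_config()) {
  stopifnot(inherits(image, "gel_image"))
  px <- image$pixels
  if (!is.null(config$lanes)) {
    centers <- sort(as.integer(config$lanes))
    if (any(centers < 1 | centers > ncol(px))) {
      abort("manual lane centers outside image columns",
            class = "telka_error_bounds")
    }
  } else {
    proj <- running_mean(colSums(px), config$lane_smooth_px)
    if (max(proj) <= 0) {
      warn("no signal in column projection; no lanes detected",
           class = "telka_warning_no_lanes")
      return(tibble(lane = integer(), center_col = integer(),
                    left_col = integer(), right_col = integer()))
    }
    pk <- find_peaks(proj,
                     min_prominence = config$lane_prominence_fraction * max(proj),
                     min_spacing = config$lane_min_spacing)
    if (!nrow(pk)) {
      warn("no column-projection peak above the prominence threshold",
           class = "telka_warning_no_lanes")
      return(tibble(lane = integer(), center_col = integer(),
                    left_col = integer(), right_col = integer()))
    }
    # refine each center as the local centroid: lanes are near flat-topped,
    # so the raw argmax wanders under noise while the centroid does not
    centers <- vapply(pk$pos, function(p) {
      win <- max(1L, p - config$lane_halfwidth):min(length(proj),
                                                    p + config$lane_halfwidth)
      w <- proj[win] - min(proj[win])
      if (sum(w) <= 0) return(as.numeric(p))
      sum(win * w) / sum(w)
    }, numeric(1))
    centers <- as.integer(round(centers))
  }
  n <- length(centers)
  hw <- config$lane_halfwidth
  left <- right <- integer(n)
  for (i in seq_len(n)) {
    hw_l <- if (i > 1) min(hw, floor((centers[i] - centers[i - 1]) / 2)) else hw
    hw_r <- if (i < n) min(hw, ceiling((centers[i + 1] - centers[i]) / 2)) else hw
    left[i] <- max(1L, centers[i] - as.integer(hw_l))
    right[i] <- min(ncol(px) + 1L, centers[i] + as.integer(hw_r) + 1L)
  }
  tibble(lane = seq_len(n), center_col = as.integer(centers),
         left_col = left, right_col = right)
}

#' Extract a lane's migration profile
#'
#' @param image A [gel_image()].
#' @param lane One row of the [detect_lanes()] table (or any list with
#'   `left_col`/`right_col`).
#' @param stat `"sum"` (default) or `"mean"` across the lane's columns.
#' @return A tibble with columns `row`, `intensity` and (zero until
#'   [subtract_background()] is applied) `background`.
#' @export
extract_profile <- function(image, lane, stat = c("sum", "mean")) {
  stopifnot(inherits(image, "gel_image"))
  stat <- match.arg(stat)
  l <- lane$left_col[1]
  r <- lane$right_col[1]
  if (is.na(l) || is.na(r) || l < 1 || r > ncol(image$pixels) + 1L || l >= r) {
    abort("lane columns outside image bounds", class = "telka_error_bounds")
  }
  block <- image$pixels[, l:(r - 1L), drop = FALSE]
  intensity <- if (stat == "sum") rowSums(block) else rowMeans(block)
  tibble(row = seq_along(intensity), intensity = intensity,
         background = 0)
}

#' Subtract the baseline from a lane profile
#'
#' The baseline (autoradiogram fog, ramps from uneven exposure) is estimated
#' by 1-D morphological opening with a structuring element wider than the
#' widest genuine feature, then subtracted with clipping at zero.
#'
#' @param profile A profile tibble from [extract_profile()].
#' @param width Structuring-element width in rows; must be shorter than the
#'   profile and wider than the smear (see [telka_config()]).
#' @return The profile tibble with `intensity` background-corrected and
#'   `background` holding the subtracted baseline.
#' @export
subtract_background <- function(profile, width = telka_config()$background_width) {
  x <- profile$intensity
  if (width >= length(x)) {
    abort("background structuring width must be smaller than the profile",
          class = "telka_error_config")
  }
  baseline <- open_profile(x, width)
  tibble(row = profile$row,
         intensity = pmax(x - baseline, 0),
         background = baseline)
}

#' Detect the two restriction-marker bands
#'
#' Marker bands are narrow (FWHM at most `marker_fwhm_max` rows) in contrast
#' to the broad telomeric smear, because markers and telomere probe
#' hybridize on the same blot. The two most prominent narrow peaks are
#' returned, ordered by migration row, with sub-pixel centers from 3-point
#' parabolic interpolation.
#'
#' @param profile A background-corrected profile tibble.
#' @param config A [telka_config()].
#' @return A two-row tibble: `center_row`, `width_rows`, `peak_intensity`.
#' @export
detect_marker_bands <- function(profile, config = telka_config()) {
  x <- profile$intensity
  pk <- find_peaks(x, min_prominence = 0.05 * max(x, 0), min_spacing = 3)
  if (nrow(pk)) {
    pk$fwhm <- vapply(pk$pos, function(p) fwhm_at(x, p), numeric(1))
    pk <- pk[pk$fwhm <= config$marker_fwhm_max, , drop = FALSE]
  }
  if (nrow(pk) < 2) {
    abort(glue::glue(
      "expected 2 narrow marker bands but found {nrow(pk)}"),
      class = "telka_error_marker_detection", n_found = nrow(pk))
  }
  if (nrow(pk) > 2) {
    warn(glue::glue("{nrow(pk)} narrow bands found; keeping the 2 most ",
                    "prominent"),
         class = "telka_warning_extra_bands")
    pk <- pk[order(-pk$prominence)[1:2], , drop = FALSE]
  }
  pk <- pk[order(pk$pos), , drop = FALSE]
  tibble(center_row = vapply(pk$pos, function(p) subpixel_center(x, p),
                             numeric(1)),
         width_rows = pk$fwhm,
         peak_intensity = pk$height)
}

#' Fit the two-point log-linear size calibration
#'
#' Electrophoretic migration is modelled as linear in `log10(size)`:
#' `row = a - b * log10(size_bp)`. Two marker anchors determine the model
#' exactly; `rows[i]` is paired with `sizes[i]`, so passing the rows in
#' ascending order together with the sizes in descending order encodes the
#' physical orientation (large fragments migrate least).
#'
#' @param rows Numeric length-2: detected marker band centers (rows).
#' @param sizes Numeric length-2: marker fragment sizes in bp (default
#'   2044 and 779).
#' @return A `tel_calibration` object with coefficients `a`, `b`.
#' @export
#' @examples
#' cal <- fit_calibration(c(100, 400), c(2044, 779))
#' size_at(cal, 250)  # geometric mean of the marker sizes
fit_calibration <- function(rows, sizes = c(2044, 779)) {
  stopifnot(length(rows) == 2, length(sizes) == 2)
  if (any(sizes <= 0)) {
    abort("marker sizes must be positive", class = "telka_error_calibration")
  }
  if (rows[1] == rows[2] || sizes[1] == sizes[2]) {
    abort("degenerate calibration: marker rows and sizes must be distinct",
          class = "telka_error_degenerate_calibration")
  }
  b <- (rows[2] - rows[1]) / (log10(sizes[1]) - log10(sizes[2]))
  if (b <= 0) {
    abort(paste("calibration slope is not positive; the image is probably",
                "not oriented well-side-up (try flip)"),
          class = "telka_error_orientation")
  }
  a <- rows[1] + b * log10(sizes[1])
  structure(list(a = a, b = b, marker_rows = as.numeric(rows),
                 marker_sizes = as.numeric(sizes)),
            class = "tel_calibration")
}

#' @export
print.tel_calibration <- function(x, ...) {
  cat(sprintf("<tel_calibration> row = %.3f - %.3f * log10(bp); anchors %g bp @ row %.2f, %g bp @ row %.2f\n",
              x$a, x$b, x$marker_sizes[1], x$marker_rows[1],
              x$marker_sizes[2], x$marker_rows[2]))
  invisible(x)
}

#' Convert between migration row and fragment size
#'
#' `size_at()` and `row_at()` are mutually inverse monotone maps under the
#' fitted log-linear model; sizes strictly decrease with migration row.
#'
#' @param model A `tel_calibration` from [fit_calibration()].
#' @param row Migration row(s).
#' @param size_bp Fragment size(s) in bp, strictly positive.
#' @return Numeric vector of sizes (bp) or rows.
#' @export
size_at <- function(model, row) {
  stopifnot(inherits(model, "tel_calibration"))
  10^((model$a - row) / model$b)
}

#' @rdname size_at
#' @export
row_at <- function(model, size_bp) {
  stopifnot(inherits(model, "tel_calibration"))
  if (any(size_bp <= 0)) {
    abort("fragment sizes must be positive", class = "telka_error_domain")
  }
  model$a - model$b * log10(size_bp)
}

#' @rdname size_at
#' @param ... Unused.
#' @export
is_extrapolated <- function(model, row, ...) {
  row < min(model$marker_rows) | row > max(model$marker_rows)
}

#' Locate the terminal restriction fragment smear
#'
#' Marker-band windows (center +/- `marker_mask_fwhm` x FWHM) are masked
#' out; the smear is the maximal contiguous run of rows whose corrected
#' intensity reaches `smear_threshold_fraction` of the remaining maximum
#' (masked rows may sit inside the run but never contribute intensity).
#'
#' @param profile A background-corrected profile tibble.
#' @param markers The two-row tibble from [detect_marker_bands()].
#' @param config A [telka_config()].
#' @return A `smear_region` list: `start_row`, `end_row` (half-open),
#'   `masked_intervals` tibble.
#' @export
detect_smear <- function(profile, markers, config = telka_config()) {
  x <- profile$intensity
  n <- length(x)
  masked <- rep(FALSE, n)
  m_int <- NULL
  if (!is.null(markers) && nrow(markers)) {
    half <- config$marker_mask_fwhm * markers$width_rows
    lo <- pmax(1L, floor(markers$center_row - half))
    hi <- pmin(n, ceiling(markers$center_row + half))
    for (i in seq_along(lo)) masked[lo[i]:hi[i]] <- TRUE
    m_int <- tibble(start_row = as.integer(lo), end_row = as.integer(hi) + 1L)
  } else {
    m_int <- tibble(start_row = integer(), end_row = integer())
  }
  peak <- max(x[!masked], 0)
  if (peak <= 0) {
    abort("no unmasked signal left in the profile",
          class = "telka_error_no_smear")
  }
  thr <- config$smear_threshold_fraction * peak
  qualifies <- masked | (x >= thr)
  runs <- rle(qualifies)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  best <- NULL
  for (ci in cand) {
    s <- starts[ci]; e <- ends[ci]
    # trim to unmasked, above-threshold endpoints
    while (s <= e && (masked[s] || x[s] < thr)) s <- s + 1L
    while (e >= s && (masked[e] || x[e] < thr)) e <- e - 1L
    if (s > e) next
    if (is.null(best) || (e - s) > (best[2] - best[1])) best <- c(s, e)
  }
  if (is.null(best) || (best[2] - best[1] + 1L) < config$smear_min_width) {
    abort("no smear-like run of rows wide enough above threshold",
          class = "telka_error_no_smear")
  }
  structure(list(start_row = best[1], end_row = best[2] + 1L,
                 masked_intervals = m_int),
            class = "smear_region")
}

#' @export
print.smear_region <- function(x, ...) {
  cat(sprintf("<smear_region> rows [%d, %d), %d masked interval(s)\n",
              x$start_row, x$end_row, nrow(x$masked_intervals)))
  invisible(x)
}

smear_rows <- function(profile, region) {
  rows <- region$start_row:(region$end_row - 1L)
  if (nrow(region$masked_intervals)) {
    for (i in seq_len(nrow(region$masked_intervals))) {
      mi <- region$masked_intervals[i, ]
      rows <- rows[rows < mi$start_row | rows >= mi$end_row]
    }
  }
  rows
}

#' Intensity-weighted median row of the smear
#'
#' The smallest row in the (unmasked) smear whose cumulative intensity
#' reaches half of the total. Invariant under global intensity scaling, and
#' equivariant under monotone remapping of the row axis, which is why the
#' median — unlike the mean — can be computed in row space and mapped
#' through the calibration afterwards.
#'
#' @param profile A background-corrected profile tibble.
#' @param region A `smear_region`.
#' @return Integer row.
#' @export
weighted_median_row <- function(profile, region) {
  rows <- smear_rows(profile, region)
  w <- profile$intensity[rows]
  tot <- sum(w)
  if (tot <= 0) {
    abort("zero total intensity in the smear region",
          class = "telka_error_no_smear")
  }
  rows[which(cumsum(w) >= tot / 2)[1]]
}

#' Measure telomere length for one lane
#'
#' The median TRF size is `size_at()` of the intensity-weighted median row
#' (valid because a monotone size map commutes with the weighted median);
#' the mean TRF is the intensity-weighted mean of per-row sizes, computed in
#' size space because the mean does not commute. Telomere length is the
#' median TRF minus the constant subtelomeric offset.
#'
#' @param profile A background-corrected profile tibble.
#' @param model A `tel_calibration`.
#' @param region A `smear_region`.
#' @param offset_bp Subtelomeric offset in bp (see [telka_config()]).
#' @param lane_id,sample_id Labels carried into the output.
#' @return One-row tibble: `lane_id`, `sample_id`, `median_trf_bp`,
#'   `mean_trf_bp`, `telomere_length_bp`, `median_row`, `extrapolated`,
#'   `qc_flag`.
#' @export
measure_telomere <- function(profile, model, region,
                             offset_bp = telka_config()$subtelomere_offset_bp,
                             lane_id = 1L, sample_id = paste0("lane-", lane_id)) {
  med_row <- weighted_median_row(profile, region)
  rows <- smear_rows(profile, region)
  w <- profile$intensity[rows]
  sizes <- size_at(model, rows)
  median_trf <- size_at(model, med_row)
  mean_trf <- sum(w * sizes) / sum(w)
  tibble(lane_id = as.integer(lane_id), sample_id = sample_id,
         median_trf_bp = median_trf, mean_trf_bp = mean_trf,
         telomere_length_bp = median_trf - offset_bp,
         median_row = as.integer(med_row),
         extrapolated = is_extrapolated(model, med_row),
         qc_flag = "ok")
}

#' Quantify every lane of a blot image
#'
#' Runs the full densitometry pipeline per lane: profile extraction,
#' background subtraction, marker-band detection, calibration fit, smear
#' detection and telomere measurement. Per-lane failures are recorded as
#' flagged rows (`qc_flag` holds the error class), never aborts, so a blot
#' with one bad lane still yields the other measurements. Deterministic
#' given image and config.
#'
#' @param image A [gel_image()].
#' @param config A [telka_config()].
#' @param blot_id Label copied into every row.
#' @return A tibble with one row per detected lane (possibly zero rows with
#'   a warning for an empty image): `blot_id`, `lane_id`, `sample_id`,
#'   `median_trf_bp`, `mean_trf_bp`, `telomere_length_bp`, `extrapolated`,
#'   `qc_flag`.
#' @export
process_blot <- function(image, config = telka_config(), blot_id = "blot-1") {
  lanes <- detect_lanes(image, config)
  empty <- tibble(blot_id = character(), lane_id = integer(),
                  sample_id = character(), median_trf_bp = numeric(),
                  mean_trf_bp = numeric(), telomere_length_bp = numeric(),
                  extrapolated = logical(), qc_flag = character())
  if (!nrow(lanes)) return(empty)
  ids <- config$sample_ids
  if (is.null(ids)) ids <- paste0("lane-", lanes$lane)
  purrr::map_dfr(seq_len(nrow(lanes)), function(i) {
    res <- tryCatch({
      prof <- extract_profile(image, lanes[i, ], stat = config$profile_stat)
      prof <- subtract_background(prof, config$background_width)
      markers <- detect_marker_bands(prof, config)
      cal <- fit_calibration(markers$center_row, sort(config$marker_sizes,
                                                      decreasing = TRUE))
      region <- detect_smear(prof, markers, config)
      measure_telomere(prof, cal, region,
                       offset_bp = config$subtelomere_offset_bp,
                       lane_id = lanes$lane[i], sample_id = ids[i])
    }, error = function(e) {
      flag <- setdiff(class(e), c("rlang_error", "error", "condition"))[1]
      if (is.na(flag)) flag <- conditionMessage(e)
      tibble(lane_id = lanes$lane[i], sample_id = ids[i],
             median_trf_bp = NA_real_, mean_trf_bp = NA_real_,
             telomere_length_bp = NA_real_, median_row = NA_integer_,
             extrapolated = NA, qc_flag = flag)
    })
    dplyr::bind_cols(tibble(blot_id = blot_id), res)
  }) |>
    dplyr::select(-dplyr::any_of("median_row"))
}
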