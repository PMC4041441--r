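#' Densitometry configuration
#'
#' Collects every tunable of the blot-quantification pipeline with documented
#' defaults. Unknown keys are rejected so that typos in a config file cannot
#' silently fall back to defaults.
#'
#' @param ... Named overrides of the defaults listed below.
#'
#' @details Defaults (units in parentheses):
#' \describe{
#'   \item{marker_sizes}{`c(2044, 779)` (bp). Fragment sizes of the two
#'     restriction-marker bands; the larger size is assigned to the band
#'     nearer the wells.}
#'   \item{subtelomere_offset_bp}{`950` (bp). Constant subtelomeric portion of
#'     the terminal restriction fragment subtracted to report telomeric-repeat
#'     length. A laboratory constant of the probe/digest combination.}
#'   \item{profile_stat}{`"sum"`. Per-row aggregation across a lane's columns
#'     (`"sum"` or `"mean"`).}
#'   \item{background_width}{`201` (rows). Structuring-element width of the
#'     1-D morphological opening used as baseline. Must exceed the widest
#'     genuine feature in a profile (the smear), otherwise the baseline
#'     follows the smear itself and subtraction removes the signal.}
#'   \item{marker_fwhm_max}{`12` (rows). A detected peak counts as a marker
#'     band only if its full width at half maximum is at most this; the
#'     telomeric smear is far broader.}
#'   \item{marker_mask_fwhm}{`2`. Marker windows of center +/- this multiple
#'     of the band FWHM are excluded from smear statistics.}
#'   \item{smear_threshold_fraction}{`0.1`. The smear is the maximal
#'     contiguous run of rows at or above this fraction of the maximum
#'     unmasked intensity.}
#'   \item{smear_min_width}{`10` (rows). Minimum row span of an acceptable
#'     smear region.}
#'   \item{lane_prominence_fraction}{`0.2`. Minimum peak prominence for lane
#'     detection, as a fraction of the maximum of the smoothed column
#'     projection.}
#'   \item{lane_min_spacing}{`15` (px). Minimum horizontal distance between
#'     lane centers.}
#'   \item{lane_smooth_px}{`5` (px). Running-mean window applied to the
#'     column projection before peak picking.}
#'   \item{lane_halfwidth}{`14` (px). Half-width of the column span
#'     integrated per lane (narrowed where lanes would overlap).}
#'   \item{lanes}{`NULL`. Optional integer vector of manual lane center
#'     columns; overrides detection (the assay is semi-automated by design).}
#'   \item{sample_ids}{`NULL`. Optional character vector of per-lane sample
#'     labels; defaults to `lane-1..n`.}
#' }
#'
#' @return A named list with class `telka_config`.
#' @export
#' @examples
#' telka_config(subtelomere_offset_bp = 900)
telka_config <- function(...) {
  defaults <- list(
    marker_sizes = c(2044, 779),
    subtelomere_offset_bp = 950,
    profile_stat = "sum",
    background_width = 201,
    marker_fwhm_max = 12,
    marker_mask_fwhm = 2,
    smear_threshold_fraction = 0.1,
    smear_min_width = 10,
    lane_prominence_fraction = 0.2,
    lane_min_spacing = 15,
    lane_smooth_px = 5,
    lane_halfwidth = 14,
    lanes = NULL,
    sample_ids = NULL
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      abort("all configuration overrides must be named",
            class = "telka_error_config")
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      abort(glue::glue("unknown configuration key(s): ",
                       "{paste(unknown, collapse = ', ')}"),
            class = "telka_error_config")
    }
    defaults[names(overrides)] <- overrides
  }
  structure(defaults, class = "telka_config")
}

#' Read a YAML configuration file
#'
#' @param path Path to a YAML file whose top-level keys are
#'   [telka_config()] keys.
#' @return A `telka_config` list.
#' @export
read_telka_config <- function(path) {
  if (!file.exists(path)) {
    abort(glue::glue("config file not found: {path}"), class = "telka_error_io")
  }
  telka_config(yaml::read_yaml(path))
}

#' @export
print.telka_config <- function(x, ...) {
  cat("<telka_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-26s %s\n", nm,
                if (is.null(val)) "NULL" else paste(format(val), collapse = ", ")))
  }
  invisible(x)
}
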