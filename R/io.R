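# Tabular I/O with provenance comment headers.

provenance_lines <- function(seed = NULL, config = NULL) {
  ver <- as.character(utils::packageVersion("telka"))
  out <- c(sprintf("# telka %s", ver))
  if (!is.null(seed)) out <- c(out, sprintf("# seed: %s", seed))
  if (!is.null(config)) {
    out <- c(out, sprintf("# config_hash: %s", rlang::hash(config)))
  }
  out
}

#' Write a results table as CSV with a provenance header
#'
#' Output starts with `#`-prefixed comment lines (package version, seed,
#' config hash) that [read_telka_csv()] and standard `comment = "#"`
#' readers tolerate.
#'
#' @param df A data frame.
#' @param path Output CSV path.
#' @param seed,config Optional provenance: the run seed and the resolved
#'   [telka_config()] (hashed).
#' @return `path`, invisibly.
#' @export
write_telka_csv <- function(df, path, seed = NULL, config = NULL) {
  writeLines(provenance_lines(seed, config), path)
  con <- file(path, open = "a")
  on.exit(close(con))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by this package
#'
#' @param path CSV path; `#` comment lines are skipped.
#' @return A tibble.
#' @export
read_telka_csv <- function(path) {
  if (!file.exists(path)) {
    abort(glue::glue("file not found: {path}"), class = "telka_error_io")
  }
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Read a kinetics table from CSV
#'
#' Accepts either the wide form (`mutant` + `streak_*` columns, as written
#' by this package) or the long form (`mutant`, `streak`, `length_bp`),
#' which is returned as-is for [build_kinetics_matrix()].
#'
#' @param path CSV path.
#' @return A tibble in the form found, with attribute `"form"` set to
#'   `"wide"` or `"long"`.
#' @export
read_kinetics <- function(path) {
  df <- read_telka_csv(path)
  if (length(grep("^streak_[0-9]+$", names(df)))) {
    attr(df, "form") <- "wide"
  } else if (all(c("mutant", "streak", "length_bp") %in% names(df))) {
    attr(df, "form") <- "long"
  } else {
    abort(paste("unrecognised kinetics table: need either streak_* columns",
                "or (mutant, streak, length_bp)"),
          class = "telka_error_input")
  }
  df
}
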