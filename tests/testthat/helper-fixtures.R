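# Shared fixture builders; everything is generated in code.

make_kin <- function(m, ids = sprintf("m%02d", seq_len(nrow(m)))) {
  colnames(m) <- paste0("streak_", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(mutant = ids), tibble::as_tibble(m))
}

# a profile tibble from a bare intensity vector
make_profile <- function(intensity) {
  tibble::tibble(row = seq_along(intensity), intensity = intensity,
                 background = 0)
}

# smear region covering given rows, no masking
region_over <- function(rows) {
  structure(list(start_row = min(rows), end_row = max(rows) + 1L,
                 masked_intervals = tibble::tibble(start_row = integer(),
                                                   end_row = integer())),
            class = "smear_region")
}

quiet_lane_spec <- function(...) {
  lane_spec(noise_sd = 0, background = c(0, 0), ...)
}

six_lane_blot <- function(noise = TRUE, seed = 1) {
  specs <- replicate(6, if (noise) wt_lane_spec() else quiet_lane_spec(),
                     simplify = FALSE)
  render_blot(blot_spec(specs), seed = seed)
}
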