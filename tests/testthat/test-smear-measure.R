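# Smear detection, weighted median and telomere measurement.

test_that("smear region brackets a rendered broad smear", {
  rows <- 1:600
  narrow <- function(c0) 8 * exp(-(rows - c0)^2 / (2 * 2^2))
  smear <- 5 * exp(-(rows - 300)^2 / (2 * 35^2))
  prof <- make_profile(narrow(150) + narrow(450) + smear)
  bands <- detect_marker_bands(prof)
  reg <- detect_smear(prof, bands)
  # 10% threshold support of a Gaussian: center +/- sigma * sqrt(2 ln 10)
  half_supp <- 35 * sqrt(2 * log(10))
  expect_lt(abs(reg$start_row - (300 - half_supp)), 3)
  expect_lt(abs(reg$end_row - (300 + half_supp)), 3)
})

test_that("an empty profile after masking raises the no-smear condition", {
  prof <- make_profile(rep(0, 300))
  expect_error(detect_smear(prof, NULL), class = "telka_error_no_smear")
})

test_that("a smear overlapping a marker window stays contiguous but masked rows carry no weight", {
  rows <- 1:600
  smear <- 5 * exp(-(rows - 300)^2 / (2 * 40^2))
  marker <- 9 * exp(-(rows - 290)^2 / (2 * 2^2))
  prof <- make_profile(smear + marker)
  bands <- detect_marker_bands(make_profile(marker + 8 * exp(-(rows - 500)^2 / 8)))
  reg <- detect_smear(prof, bands, telka_config())
  expect_s3_class(reg, "smear_region")
  expect_gt(nrow(reg$masked_intervals), 0)
  expect_true(reg$start_row < 290 && reg$end_row > 310)
  # masked rows do not contribute: zeroing them changes nothing
  masked_rows <- unlist(purrr::map2(reg$masked_intervals$start_row,
                                    reg$masked_intervals$end_row - 1L, seq))
  prof0 <- prof; prof0$intensity[masked_rows] <- 0
  expect_equal(weighted_median_row(prof0, reg), weighted_median_row(prof, reg))
})

test_that("weighted median follows the smallest-row tie rule", {
  # equal weights on rows 10..13: cumulative reaches half at row 11
  prof <- make_profile(replace(rep(0, 20), 10:13, 1))
  expect_equal(weighted_median_row(prof, region_over(10:13)), 11)

  # weights 1 and 3 on rows 5 and 6: brute-force cumulative crosses at 6
  prof2 <- make_profile(replace(rep(0, 10), 5:6, c(1, 3)))
  expect_equal(weighted_median_row(prof2, region_over(5:6)), 6)

  # symmetric triangle centered at 50
  tri <- pmax(0, 10 - abs((1:100) - 50))
  expect_equal(weighted_median_row(make_profile(tri), region_over(41:59)), 50)

  expect_error(weighted_median_row(make_profile(rep(0, 30)), region_over(5:20)),
               class = "telka_error_no_smear")
})

test_that("the weighted median is equivariant under the monotone size map (property)", {
  set.seed(7)
  cal <- fit_calibration(c(100, 400), c(2044, 779))
  for (i in 1:25) {
    n <- 300
    w <- runif(n)
    prof <- make_profile(replace(rep(0, 500), 101:400, w))
    reg <- region_over(101:400)
    r_med <- weighted_median_row(prof, reg)
    via_rows <- size_at(cal, r_med)
    # direct size-space weighted median with the same smallest-value rule
    sizes <- size_at(cal, 101:400)
    ord <- order(sizes)
    direct <- sizes[ord][which(cumsum(w[ord]) >= sum(w) / 2)[1]]
    expect_equal(via_rows, direct, tolerance = 1e-12)
  }
})

test_that("measurement is invariant to intensity scaling and honours the offset", {
  r <- render_blot(blot_spec(list(quiet_lane_spec())), seed = 5)
  m1 <- process_blot(r$image)
  img2 <- gel_image(r$image$pixels * 2, bit_depth = 16)
  m2 <- process_blot(img2)
  expect_equal(m1$median_trf_bp, m2$median_trf_bp, tolerance = 1e-12)
  expect_equal(m1$mean_trf_bp, m2$mean_trf_bp, tolerance = 1e-12)

  # offset enters the telomere length exactly
  expect_equal(m1$telomere_length_bp, m1$median_trf_bp - 950)
  cfg0 <- telka_config(subtelomere_offset_bp = 0)
  m0 <- process_blot(r$image, cfg0)
  expect_equal(m0$telomere_length_bp, m0$median_trf_bp)
})

test_that("a whole-lane shift leaves sizes unchanged when markers shift equally", {
  rows <- 1:600
  narrow <- function(c0) 8 * exp(-(rows - c0)^2 / (2 * 2^2))
  smear <- 5 * exp(-(rows - 280)^2 / (2 * 30^2))
  measure <- function(shift) {
    prof <- make_profile(narrow(150 + shift) + narrow(450 + shift) +
                           5 * exp(-(rows - 280 - shift)^2 / (2 * 30^2)))
    bands <- detect_marker_bands(prof)
    cal <- fit_calibration(bands$center_row, c(2044, 779))
    reg <- detect_smear(prof, bands)
    measure_telomere(prof, cal, reg)$median_trf_bp
  }
  expect_equal(measure(0), measure(17), tolerance = 1e-6)
})

test_that("a zero-noise wild-type lane measures 352 bp within quantization", {
  r <- render_blot(blot_spec(list(quiet_lane_spec())), seed = 1)
  m <- process_blot(r$image)
  expect_equal(m$qc_flag, "ok")
  expect_lt(abs(m$median_trf_bp - 1302), 3)
  expect_lt(abs(m$telomere_length_bp - 352), 3)
})

test_that("per-lane failures are flagged rows, not aborts", {
  specs <- replicate(6, wt_lane_spec(), simplify = FALSE)
  specs[[3]] <- wt_lane_spec(marker_amplitude = 0)
  r <- render_blot(blot_spec(specs), seed = 9)
  res <- process_blot(r$image)
  expect_equal(nrow(res), 6)
  expect_equal(res$qc_flag[3], "telka_error_marker_detection")
  expect_true(all(res$qc_flag[-3] == "ok"))
  expect_true(all(is.na(res$telomere_length_bp[3])))
  expect_true(all(abs(res$telomere_length_bp[-3] - 352) < 20))
})

test_that("an empty image gives an empty measurement table", {
  img <- gel_image(matrix(0, 60, 30))
  expect_warning(res <- process_blot(img), class = "telka_warning_no_lanes")
  expect_equal(nrow(res), 0)
})
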