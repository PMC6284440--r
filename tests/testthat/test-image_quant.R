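# Segmentation, geminin calling and band-limited focus detection against
# the generator's ground truth.

test_that("well-separated synthetic nuclei segment one label each", {
  spec <- field_spec(field_shape = c(400L, 400L), n_nuclei = 5, seed = 21,
                     overlap_cap = 0)
  out <- synthesize_field(spec)
  lab <- segment_nuclei(out$field)
  expect_equal(max(lab), 5)
  # each truth center carries a distinct label
  at <- lab[cbind(round(out$truth$nuclei$row) + 1,
                  round(out$truth$nuclei$col) + 1)]
  expect_equal(sort(at), 1:5)
})

test_that("blank and background-only nuclear channels give zero labels", {
  blank <- field_image(list(nuclear = matrix(0.2, 64, 64),
                            geminin = matrix(0.2, 64, 64),
                            RAD51 = matrix(0.2, 64, 64)), pixel_size = 0.11)
  expect_warning(lab <- segment_nuclei(blank), "blank")
  expect_equal(max(lab), 0)
})

test_that("touching nuclei are split into two labels", {
  # two overlapping disks at the default 10% overlap cap
  spec <- field_spec(field_shape = c(300L, 300L), n_nuclei = 2, seed = 1,
                     overlap_cap = 0.1)
  found <- vapply(1:8, function(s) {
    sp <- field_spec(field_shape = c(300L, 300L), n_nuclei = 2, seed = s,
                     overlap_cap = 0.1)
    max(segment_nuclei(synthesize_field(sp)$field))
  }, numeric(1))
  expect_true(all(found == 2))
})

test_that("geminin calls match the rendered ground truth", {
  spec <- field_spec(field_shape = c(400L, 400L), n_nuclei = 12, seed = 7)
  out <- synthesize_field(spec)
  lab <- segment_nuclei(out$field)
  gem <- call_geminin_positive(lab, out$field$channels$geminin)
  tr <- out$truth$nuclei
  at <- lab[cbind(round(tr$row) + 1, round(tr$col) + 1)]
  expect_equal(unname(gem[as.character(at)]), tr$geminin)
})

test_that("geminin calling is all-negative on degenerate inputs", {
  lab <- matrix(0L, 50, 50); lab[10:20, 10:20] <- 1L
  flat <- matrix(0.1, 50, 50)
  expect_false(any(call_geminin_positive(lab, flat + rnorm(2500, 0, 1e-3))))
  # single nucleus: no bimodality to threshold
  expect_false(any(call_geminin_positive(lab, flat + 0.5)))
  lab2 <- lab; lab2[30:40, 30:40] <- 2L
  expect_error(call_geminin_positive(lab2, matrix(0.1, 10, 10)), "shape")
})

test_that("fixed-threshold geminin policy compares nucleus means", {
  lab <- matrix(0L, 40, 40)
  lab[5:10, 5:10] <- 1L; lab[25:30, 25:30] <- 2L
  ch <- matrix(0.1, 40, 40); ch[25:30, 25:30] <- 0.8
  calls <- call_geminin_positive(lab, ch, policy = "fixed", threshold = 0.4)
  expect_equal(unname(calls), c(FALSE, TRUE))
})

test_that("in-band foci are detected and out-of-band blobs rejected", {
  out <- one_nucleus_field(c(rep(0.7, 6), rep(1.5, 2)))
  mask <- segment_nuclei(out$field) > 0
  f <- detect_foci(out$field$channels$RAD51, mask, 0.11)
  expect_equal(nrow(f), 6)
  expect_true(all(f$diameter_um >= 0.42 & f$diameter_um <= 1.15))
  m <- match_foci(out$truth$foci[out$truth$foci$diameter_um <= 1.15, ], f)
  expect_equal(unname(m), c(6, 0, 0))
})

test_that("a zero-intensity marker channel yields no foci", {
  mask <- matrix(FALSE, 64, 64); mask[20:40, 20:40] <- TRUE
  f <- detect_foci(matrix(0, 64, 64), mask, 0.11)
  expect_equal(nrow(f), 0)
  expect_error(detect_foci(matrix(0, 64, 64), matrix(FALSE, 64, 64), 0.11),
               "empty")
})

test_that("the diameter band is inclusive at both bounds", {
  p <- foci_params()
  expect_true(rad51score:::in_diameter_band(0.42, p))
  expect_true(rad51score:::in_diameter_band(1.15, p))
  expect_false(rad51score:::in_diameter_band(0.42 - 1e-9, p))
  expect_false(rad51score:::in_diameter_band(1.15 + 1e-9, p))
})

test_that("a coarse pixel size is flagged in QC metadata", {
  mask <- matrix(FALSE, 64, 64); mask[20:40, 20:40] <- TRUE
  f <- detect_foci(matrix(0, 64, 64), mask, pixel_size = 0.3)
  expect_match(attr(f, "qc_warnings"), "coarse")
})

test_that("detection is monotone in sensitivity and band width", {
  out <- one_nucleus_field(c(rep(0.5, 3), rep(0.8, 4), rep(1.4, 2)),
                           seed = 6, noise_sd = 0.02, snr = 5)
  mask <- segment_nuclei(out$field) > 0
  base <- foci_params()
  counts <- vapply(c(1, 2, 3, 5, 8), function(s) {
    p <- base; p$detection_sensitivity <- s
    nrow(detect_foci(out$field$channels$RAD51, mask, 0.11, p))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  narrow <- base; narrow$diameter_min <- 0.6; narrow$diameter_max <- 0.9
  wide <- base; wide$diameter_min <- 0.3; wide$diameter_max <- 1.6
  n_narrow <- nrow(detect_foci(out$field$channels$RAD51, mask, 0.11, narrow))
  n_base <- nrow(detect_foci(out$field$channels$RAD51, mask, 0.11, base))
  n_wide <- nrow(detect_foci(out$field$channels$RAD51, mask, 0.11, wide))
  expect_lte(n_narrow, n_base)
  expect_lte(n_base, n_wide)
})

test_that("noise-free fields recover ground-truth counts exactly", {
  spec <- field_spec(field_shape = c(400L, 400L), n_nuclei = 6, seed = 11,
                     noise_sd = 0,
                     markers = list(RAD51 = marker_model(
                       forming_fraction = 1, count = 6, diameters = 0.7)))
  out <- synthesize_field(spec)
  rec <- quantify_field(out$field)
  expect_equal(nrow(rec), 6)
  expect_true(all(rec$RAD51_foci == 6))
  expect_true(all(rec$RAD51_pos))
})

test_that("records are invariant to positive intensity rescaling", {
  spec <- field_spec(field_shape = c(256L, 256L), n_nuclei = 4, seed = 13)
  out <- synthesize_field(spec)
  f2 <- out$field
  f2$channels <- lapply(f2$channels, function(ch) 3.7 * ch)
  expect_equal(quantify_field(out$field), quantify_field(f2))
})

test_that("per-nucleus focus counts match ground truth at default SNR", {
  hits <- 0; total <- 0
  for (s in 2:4) {
    spec <- field_spec(field_shape = c(512L, 512L), n_nuclei = 8, seed = s,
                       focus_peak_snr = 5,
                       markers = list(RAD51 = marker_model(
                         forming_fraction = 1, lambda_forming = 8)))
    out <- synthesize_field(spec)
    lab <- segment_nuclei(out$field)
    rec <- quantify_field(out$field)
    tr <- out$truth
    at <- lab[cbind(round(tr$nuclei$row) + 1, round(tr$nuclei$col) + 1)]
    truth_counts <- vapply(tr$nuclei$nucleus_id, function(i)
      sum(tr$foci$nucleus_id == i &
          tr$foci$diameter_um >= 0.42 & tr$foci$diameter_um <= 1.15),
      numeric(1))
    det_counts <- rec$RAD51_foci[match(at, rec$nucleus_id)]
    hits <- hits + sum(truth_counts == det_counts, na.rm = TRUE)
    total <- total + length(truth_counts)
  }
  expect_gte(hits / total, 0.95)
})

test_that("fields round-trip through TIFF plus sidecar", {
  spec <- field_spec(field_shape = c(128L, 128L), n_nuclei = 2, seed = 5)
  out <- synthesize_field(spec)
  path <- file.path(withr::local_tempdir(), "field.tif")
  write_field_tiff(out$field, path, truth = out$truth)
  back <- read_field_tiff(path)
  expect_equal(names(back$channels), names(out$field$channels))
  expect_equal(back$pixel_size, out$field$pixel_size)
  expect_lt(max(abs(back$channels$nuclear - out$field$channels$nuclear)),
            2 / 65535)
  truth_csv <- read.csv(sub("\\.tif$", "_truth.csv", path))
  expect_equal(nrow(truth_csv), nrow(out$truth$foci))
})
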