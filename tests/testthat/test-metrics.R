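test_that("area fraction counts suprathreshold pixels", {
  d <- c(10, 10)
  blank <- image_field(list(carrier = array(0, d)), 1)
  expect_equal(as.numeric(area_fraction(blank)), 0)

  x <- array(0, d)
  x[sample(100, 7)] <- 50
  f <- image_field(list(carrier = x), 1)
  expect_equal(as.numeric(area_fraction(f, threshold = 10)), 7)
})

test_that("phantom area fractions are recovered by the default threshold rule", {
  sp <- small_spec_2d(seed = 20, target_area_fraction = 2.5)
  g <- generate_field(sp)
  af <- as.numeric(area_fraction(g$field))
  expect_equal(af, 2.5, tolerance = 0.3)
})

test_that("ring positivity finds exactly the haloed vessels", {
  sp <- small_spec_2d(seed = 21, n_vessels = 3L)
  g <- generate_field(sp)
  seg <- truth_segmentation(g$truth, c(0.3, 0.3))
  dm <- distance_map(seg)
  sh <- build_shells(dm, edges = c(5, 10))
  # paint halos around vessels 1 and 2 only
  halo <- array(0, dim(dm$values))
  sel <- dm$values > 0 & dm$values <= 5 & dm$nearest_label %in% c(1L, 2L)
  halo[sel] <- 400 * exp(-dm$values[sel] / 3)
  set.seed(1)
  ch <- array(pmax(round(halo + 100 + rnorm(length(halo), 0, 20)), 0),
              dim(halo))
  f <- image_field(list(vessel = g$field$channels$vessel, probe = ch),
                   c(0.3, 0.3))
  n <- count_extravasation_positive_vessels(seg, sh, f, channel = "probe")
  expect_identical(as.integer(n), 2L)
  tab <- attr(n, "per_vessel")
  expect_identical(tab$positive, c(TRUE, TRUE, FALSE))
})

test_that("positivity decisions are invariant to uniform gain", {
  sp <- small_spec_2d(seed = 22, leaky_vessel_fraction = 0.5)
  g <- generate_field(sp)
  seg <- truth_segmentation(g$truth, c(0.3, 0.3))
  sh <- build_shells(distance_map(seg), edges = c(5, 10))
  n1 <- count_extravasation_positive_vessels(seg, sh, g$field,
                                             channel = "igg")
  f2 <- g$field
  f2$channels$igg <- f2$channels$igg * 6
  n2 <- count_extravasation_positive_vessels(seg, sh, f2, channel = "igg")
  expect_identical(attr(n1, "per_vessel")$positive,
                   attr(n2, "per_vessel")$positive)
})

test_that("no segmented vessels yields zero positives with a warning", {
  d <- c(32, 32)
  f <- image_field(list(vessel = array(0, d), carrier = array(0, d),
                        igg = array(0, d)), 1)
  seg <- suppressWarnings(segment_vessels(f))
  sh <- NULL
  expect_warning(n <- count_extravasation_positive_vessels(seg, sh, f),
                 "no vessels")
  expect_identical(as.integer(n), 0L)
  expect_warning(p <- igg_positive_vessel_pct(seg, sh, f), "no vessels")
  expect_true(is.na(p))
})

test_that("IgG-positive percentage saturates and nulls correctly", {
  sp <- small_spec_2d(seed = 23, leaky_vessel_fraction = 1)
  g <- generate_field(sp)
  seg <- truth_segmentation(g$truth, c(0.3, 0.3))
  sh <- build_shells(distance_map(seg), edges = c(5, 10))
  expect_equal(as.numeric(igg_positive_vessel_pct(seg, sh, g$field)), 100)

  # null phantoms: false-positive rate below 5% of vessels over fields
  pos <- 0; tot <- 0
  for (seed in 31:34) {
    g0 <- generate_field(small_spec_2d(seed = seed,
                                       leaky_vessel_fraction = 0))
    seg0 <- truth_segmentation(g0$truth, c(0.3, 0.3))
    sh0 <- build_shells(distance_map(seg0), edges = c(5, 10))
    n0 <- count_extravasation_positive_vessels(seg0, sh0, g0$field,
                                               channel = "igg")
    pos <- pos + as.integer(n0)
    tot <- tot + seg0$n_vessels
  }
  expect_lt(pos / tot, 0.05)
})

test_that("percent injected dose follows the linear calibration", {
  cal <- dose_calibration(injected_dose = 4, fluorescence_per_amount = 10,
                          roi_volume_mm3 = 500)
  expect_equal(percent_id(40, cal), 100)           # full dose in 500 mm³
  cal2 <- dose_calibration(4, 10, 250)
  expect_equal(percent_id(20, cal2), 100)          # half dose in 250 mm³
  # forward-constructed ROI holding 5.1 %ID per 500 mm³
  cal3 <- dose_calibration(4, 25, 500)
  signal <- 0.051 * 4 * 25
  expect_equal(percent_id(signal, cal3), 5.1)
  expect_error(dose_calibration(0, 1, 1), "positive")
})

test_that("enhancement percentages match the printed arithmetic", {
  e <- enhancement_pct(5.1, 3.1)
  expect_equal(e$enhancement_pct, 100 * 2 / 3.1)
  expect_equal(e$enhancement_pct_rounded, 65)  # 64.5 rounds half-up
  expect_equal(enhancement_pct(2, 2)$enhancement_pct, 0)
  expect_equal(enhancement_pct(3, 1.5)$enhancement_pct, 100)
  expect_error(enhancement_pct(1, 0), "positive")
  expect_gt(enhancement_pct(0.01, 100)$enhancement_pct, -100)
})
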