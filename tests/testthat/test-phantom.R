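test_that("a fixed seed reproduces every channel bit-exactly", {
  g1 <- generate_field(small_spec_2d(seed = 11))
  g2 <- generate_field(small_spec_2d(seed = 11))
  expect_identical(g1$field$channels, g2$field$channels)
  expect_identical(g1$truth$lumen_mask, g2$truth$lumen_mask)
  g3 <- generate_field(small_spec_2d(seed = 12))
  expect_false(identical(g1$field$channels, g3$field$channels))
})

test_that("a lumen-only profile places all carrier signal inside the lumen", {
  sp <- small_spec_2d(seed = 2)
  sp$profile <- two_shell_profile(c(100, 0, 0))
  g <- generate_field(sp)
  seg <- truth_segmentation(g$truth, sp$pixel_size)
  shells <- build_shells(distance_map(seg), edges = c(5, 10))
  prof <- penetration_profile(shells, g$field)
  expect_gt(profile_fractions(prof)[1], 99)
  expect_equal(g$truth$true_profile$raw_sum[2:3], c(0, 0))
})

test_that("zero leaky fraction leaves the IgG channel at background", {
  g <- generate_field(small_spec_2d(seed = 3, leaky_vessel_fraction = 0))
  expect_identical(g$truth$true_leaky_count, 0L)
  igg <- g$field$channels$igg
  # background ~ Poisson/Gaussian noise around the camera baseline
  expect_lt(max(igg), 100 + 8 * mad(igg))
})

test_that("IgG halos surround exactly the leaky vessels", {
  sp <- small_spec_2d(seed = 4, leaky_vessel_fraction = 0.5)
  g <- generate_field(sp)
  truth <- g$truth
  expect_identical(truth$true_leaky_count, sum(truth$per_vessel$leaky))
  seg <- truth_segmentation(truth, sp$pixel_size)
  dm <- distance_map(seg)
  ring <- dm$values > 0 & dm$values <= 5
  for (l in truth$per_vessel$label) {
    sel <- ring & dm$nearest_label == l
    m <- mean(g$field$channels$igg[sel]) - 100
    if (truth$per_vessel$leaky[l]) expect_gt(m, 100) else expect_lt(m, 30)
  }
})

test_that("realized profiles match the request within 1% per compartment", {
  # measured on the noisy field against ground-truth shells
  sp <- phantom_spec(shape = c(256, 256), pixel_size = 0.3,
                     profile = make_profile_preset("polymer_US_2D"),
                     n_vessels = c(4L, 6L), vessel_radius_range = c(3, 6),
                     seed = 17)
  g <- generate_field(sp)
  seg <- truth_segmentation(g$truth, sp$pixel_size)
  shells <- build_shells(distance_map(seg), edges = profile_edges(sp$profile))
  measured <- profile_fractions(penetration_profile(shells, g$field))
  requested <- profile_fractions(sp$profile)
  expect_true(all(abs(measured - requested) < 1))
  # and the recorded pre-noise truth is exact
  expect_equal(profile_fractions(g$truth$true_profile), requested,
               tolerance = 1e-9)
})

test_that("carrier intensity mass is conserved across compartments", {
  g <- generate_field(small_spec_2d(seed = 5))
  expect_equal(sum(g$truth$true_profile$raw_sum), g$truth$carrier_total,
               tolerance = 1e-6)
})

test_that("cohorts are reproducible and seeded per field", {
  sp <- small_spec_2d()
  c1 <- generate_cohort(sp, n_fields = 3, base_seed = 21)
  c2 <- generate_cohort(sp, n_fields = 3, base_seed = 21)
  expect_identical(lapply(c1$fields, `[[`, "channels"),
                   lapply(c2$fields, `[[`, "channels"))
  expect_identical(c1$cohort, c2$cohort)
  # field 1 of a cohort == generate_field at the base seed
  single <- generate_field(small_spec_2d(seed = 21))
  expect_identical(c1$fields[[1]]$channels, single$field$channels)
  expect_identical(c1$cohort$seed, 21:23)
  expect_equal(nrow(c1$cohort), 3)
  expect_error(generate_cohort(sp, n_fields = 0), ">= 1")
})

test_that("impossible vessel layouts fail with a clear error", {
  expect_error(
    phantom_spec(shape = c(64, 64), pixel_size = 0.3,
                 profile = two_shell_profile()),
    "cannot fit")
  sp <- small_spec_2d(seed = 6, n_vessels = 60L,
                      tuning = list(max_retries = 2L))
  expect_error(generate_field(sp), "could not place")
})

test_that("target area fractions are realized in the support", {
  sp <- small_spec_2d(seed = 7, target_area_fraction = 3)
  g <- generate_field(sp)
  expect_equal(g$truth$true_area_fraction, 3, tolerance = 0.2)
})
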