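test_that("leaf image generator is deterministic and honours its contract", {
  g1 <- gen_leaf_image(seed = 42, stain_saturation = 90)
  g2 <- gen_leaf_image(seed = 42, stain_saturation = 90)
  expect_identical(g1$image, g2$image)
  expect_equal(dim(g1$image), c(512, 512, 3))
  # blob pixels carry the programmed saturation (up to 8-bit rounding)
  sat <- saturation_channel(g1$image)
  expect_lt(max(abs(sat[g1$mask] - 90)), 1.5)
  expect_true(all(sat[!g1$mask] == 0))
  # zero blobs: nothing to quantify
  empty <- gen_leaf_image(seed = 1, blob_count = 0)
  expect_equal(quantify(empty$image)$corrected_mean, 0)
  expect_error(gen_leaf_image(seed = 1, height = 150, width = 150,
                              blob_radius = 75), "fit")
  expect_error(gen_leaf_image(seed = 1, stain_saturation = 300), "255")
})

test_that("weight series generator inverts the RWC formula", {
  g <- gen_weight_series(seed = 1, rwc_target = 35.6, noise_sd = 0)
  tc <- rwc_time_course(g$time_min, g$fresh, g$turgid, g$dry)
  expect_equal(tc$rwc[nrow(tc)], 35.6, tolerance = 1e-12)
  expect_equal(tc$rwc[1], 100)
  g100 <- gen_weight_series(seed = 1, rwc_target = 100)
  expect_equal(g100$fresh[length(g100$fresh)], g100$turgid)
  expect_error(gen_weight_series(seed = 1, rwc_target = 120), "\\[0, 100\\]")
  # noisy series stay near the target on average
  finals <- vapply(1:100, function(s) {
    g <- gen_weight_series(seed = s, rwc_target = 70, noise_sd = 0.01)
    tc <- rwc_time_course(g$time_min, g$fresh, g$turgid, g$dry)
    tc$rwc[nrow(tc)]
  }, numeric(1))
  expect_lt(abs(mean(finals) - 70), 3 * sd(finals) / sqrt(100) + 1e-9)
})

test_that("conductivity generator inverts the leakage formulas exactly", {
  for (target in c(0, 1.78, 8.0)) {
    g <- gen_conductivity(seed = 1, eli_target = target, el_c = 0.1)
    el_c <- electrolyte_leakage(g$control$cond_treatment,
                                g$control$cond_positive_control)
    el_h <- electrolyte_leakage(g$heat$cond_treatment,
                                g$heat$cond_positive_control)
    expect_equal(suppressWarnings(eli(el_h, el_c)), target,
                 tolerance = 1e-12)
  }
  g <- gen_conductivity(seed = 1, eli_target = 8.0, el_c = 0.1)
  expect_equal(g$el_h, 0.9, tolerance = 1e-12)
  expect_error(gen_conductivity(eli_target = 2, el_c = 0), "> 0")
  expect_error(gen_conductivity(eli_target = -1.5), "-1")
})

test_that("DAB series generator realizes the programmed kinetics", {
  # tolerant: clearance exactly at the target phase, zero noise
  for (ph in c("H", "J", "M", "N")) {
    g <- gen_dab_series(seed = 1, profile = "tolerant",
                        clearance_phase = ph, replicate_noise_sd = 0)
    expect_equal(clearance_time(g$series)$phase, ph)
  }
  # sensitive: never clears
  s <- gen_dab_series(seed = 1, profile = "sensitive")
  expect_true(is.na(clearance_time(s$series)$phase))
  # degenerate kinetics: flat at baseline
  flat <- gen_dab_series(seed = 1, profile = "tolerant", baseline = 10,
                         peak = 10)
  expect_equal(flat$series$mean, rep(10, 14))
  expect_error(gen_dab_series(seed = 1, clearance_phase = "C"), "H, I")
  # replicate table round-trips through the dab_series schema
  g <- gen_dab_series(seed = 2, replicate_noise_sd = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements_csv(g$replicates, path, "dab_series")
  back <- read_measurements_csv(path, "dab_series")
  expect_equal(back$value, g$replicates$value, tolerance = 1e-12)
})

test_that("cohort generator plants recoverable classes and is seeded", {
  ch1 <- gen_cohort(seed = 5, separation = 4)
  ch2 <- gen_cohort(seed = 5, separation = 4)
  expect_identical(ch1, ch2)
  expect_equal(nrow(ch1$pairs), 27)
  # high separation: classes fall on opposite sides of the cohort means
  tol <- ch1$labels == "tolerant"
  expect_true(min(ch1$pairs$rwc[tol]) > max(ch1$pairs$rwc[!tol]))
  expect_true(max(ch1$pairs$eli[tol]) < min(ch1$pairs$eli[!tol]))
  # two species edge case still standardizes
  ch3 <- gen_cohort(seed = 1, n_species = 2, separation = 3)
  std <- standardize(ch3$pairs)
  expect_equal(mean(std$z_rwc), 0, tolerance = 1e-9)
  expect_equal(sd(std$z_eli), 1, tolerance = 1e-9)
  expect_error(gen_cohort(seed = 1, tolerant_fraction = 1), "between 0 and 1")
})

test_that("replicate generator is seeded and hits the zero-noise limit", {
  r1 <- gen_replicates(c(a = 1, b = 5), sd = 1, n = 3, seed = 3)
  r2 <- gen_replicates(c(a = 1, b = 5), sd = 1, n = 3, seed = 3)
  expect_identical(r1, r2)
  r0 <- gen_replicates(c(a = 1, b = 5), sd = 0, n = 3, seed = 3)
  expect_equal(r0$a, rep(1, 3))
  expect_equal(r0$b, rep(5, 3))
  expect_error(gen_replicates(c(a = 1), sd = -1), "non-negative")
})

test_that("generator randomness does not leak into the global RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_cohort(seed = 1))
  invisible(gen_leaf_image(seed = 1, pixel_noise_sd = 3))
  invisible(gen_replicates(c(a = 1, b = 2), sd = 1, seed = 1))
  expect_identical(.Random.seed, before)
})
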