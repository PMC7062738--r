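test_that("a spec with no oscillation and no noise yields an all-zero recording", {
  rec <- simulate_resting(silent_spec(), 1, "pre")
  expect_true(all(rec$data == 0))
  expect_equal(rec$fs, 250)
})

test_that("a planted theta component dominates the Welch PSD at that channel", {
  sp <- silent_spec(n_channels = 4, rest_duration = 20)
  rec <- simulate_resting(sp, 1, "pre")
  n <- ncol(rec$data)
  # plant a 10-uV 6-Hz jittered component on channel 1 only
  set.seed(42)
  t <- seq_len(n) / 250
  rec$data[1, ] <- 10 * sin(2 * pi * 6 * t + cumsum(rnorm(n, 0, 0.05)))
  # direct FFT oracle on the generated series
  spec <- Mod(fft(rec$data[1, ]))^2
  freq <- (seq_len(n) - 1) * 250 / n
  half <- freq > 0.5 & freq < 125
  peak <- freq[half][which.max(spec[half])]
  expect_gt(peak, 4); expect_lt(peak, 8)
})

test_that("cohorts are byte-identical under a fixed seed", {
  sp <- cohort_spec(n_rplus = 2, n_rminus = 2, n_channels = 4,
                    rest_duration = 4, n_trials = 5, noise_sd = 3, seed = 7)
  c1 <- simulate_cohort(sp, recordings = "rest")
  c2 <- simulate_cohort(sp, recordings = "rest")
  expect_identical(c1, c2)
  # and different seeds differ
  sp$seed <- 8L
  c3 <- simulate_cohort(sp, recordings = "rest")
  expect_false(identical(c1$rest_pre[[1]]$data, c3$rest_pre[[1]]$data))
})

test_that("CRS-R scores are in range and consistent with the response label", {
  sp <- cohort_spec(n_rplus = 5, n_rminus = 7, n_channels = 4, seed = 3)
  coh <- simulate_cohort(sp, recordings = character())
  expect_true(all(coh$crsr_pre >= 0 & coh$crsr_pre <= 23))
  expect_true(all(coh$crsr_post >= 0 & coh$crsr_post <= 23))
  expect_equal(classify_response(coh$crsr_pre, coh$crsr_post), coh$group)
})

test_that("task trials carry the exact deviant proportion and seeded order", {
  sp <- silent_spec(n_channels = 4)
  sp$n_trials <- 100
  rec <- simulate_task(sp, 1, "pre")
  expect_equal(sum(rec$events$code == "deviant"), 20)
  expect_equal(nrow(rec$events), 100)
  rec2 <- simulate_task(sp, 1, "pre")
  expect_identical(rec$events, rec2$events)
})

test_that("zero P3 amplitude leaves no deviant-standard ERP difference", {
  sp <- silent_spec(n_channels = 4)
  sp$n_trials <- 40; sp$mmn_amplitude <- 0; sp$p3_amplitude <- 0
  rec <- simulate_task(sp, 1, "pre")
  ep <- epoch_task(rec)
  dev <- erp_average(ep, "deviant"); std <- erp_average(ep, "standard")
  expect_lt(max(abs(dev$data - std$data)), 1e-9)
})

test_that("planted deviant components appear only after stimulus onset", {
  sp <- silent_spec(n_channels = 4)
  sp$n_trials <- 20; sp$p3_amplitude <- 5
  rec <- simulate_task(sp, 1, "pre")
  ep <- epoch_task(rec)
  dev <- erp_average(ep, "deviant")
  pre_onset <- dev$time_ms < 0
  late <- dev$time_ms >= 300 & dev$time_ms <= 600
  expect_lt(max(abs(dev$data[, pre_onset])), 1e-9)
  expect_gt(max(dev$data[, late]), 1)
})

test_that("reference database separation drives a theta-power difference", {
  sp <- silent_spec(n_channels = 4, rest_duration = 10)
  sp$band_amplitudes[] <- c(2, 2, 2, 1, 1)
  ref <- simulate_reference_database(5, 5, separation = 1, seed = 2, spec = sp)
  expect_equal(table(ref$label)[["MCS"]], 5)
  pow <- vapply(ref$recording, function(r) mean(r$data[1, ]^2), numeric(1))
  expect_gt(mean(pow[ref$label == "MCS"]), mean(pow[ref$label == "VS"]))
})

test_that("field maps honour the grid, hotspot magnitude and planted correlation", {
  fm <- simulate_field_maps(10, c(8, 8, 8), hotspot_mean = 0.8,
                            corr_strength = 1, seed = 4)
  expect_length(fm$maps, 10)
  expect_true(all(vapply(fm$maps, function(a) all(a >= 0), logical(1))))
  # noiseless planted correlation: voxelwise r = 1 inside the hotspot
  mask <- fm$hotspot
  V <- vapply(fm$maps, function(a) a[mask], numeric(sum(mask)))
  rs <- apply(V, 1, function(v) cor(v, fm$outcomes))
  expect_true(all(rs > 0.999))
  # hotspot below the masking threshold is excluded
  fm2 <- simulate_field_maps(10, c(8, 8, 8), hotspot_mean = 0.4,
                             corr_strength = 0, background_mean = 0.1, seed = 5)
  expect_false(any(field_mask(fm2, 0.5)[fm2$hotspot]))
  fm3 <- simulate_field_maps(10, c(8, 8, 8), hotspot_mean = 0.6,
                             corr_strength = 0, background_mean = 0.1, seed = 5)
  expect_true(mean(field_mask(fm3, 0.5)[fm3$hotspot]) > 0.9)
})
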