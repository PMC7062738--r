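sine_epochs <- function(freq, amp = 1, ne = 4, nc = 2, ns = 200, fs = 250) {
  data <- array(0, c(ne, nc, ns))
  for (e in seq_len(ne)) for (c in seq_len(nc)) {
    data[e, c, ] <- amp * sin(2 * pi * freq * (seq_len(ns) / fs) + e + c)
  }
  make_epochs(data, fs = fs)
}

test_that("Welch PSD peaks at the planted frequency and is zero for silence", {
  sp <- welch_psd(sine_epochs(10))
  peak_bin <- which.max(sp$power[1, 1, ])
  expect_lt(abs(sp$freq[peak_bin] - 10), 250 / 128) # within one bin
  sp0 <- welch_psd(make_epochs(array(0, c(2, 2, 200))))
  expect_true(all(sp0$power == 0))
})

test_that("white-noise PSD is flat across 1-45 Hz", {
  set.seed(21)
  sp <- welch_psd(make_epochs(array(rnorm(100 * 2 * 200), c(100, 2, 200))))
  idx <- sp$freq >= 2 & sp$freq <= 45
  prof <- colMeans(sp$power[, 1, idx]) # averaged over 100 epochs
  expect_lt(max(prof) / min(prof), 1.5)
})

test_that("band powers follow the five-band definition and normalize to one", {
  bp <- band_powers(welch_psd(sine_epochs(6)))
  expect_equal(dimnames(bp$raw)[[3]], c("delta", "theta", "alpha", "beta", "gamma"))
  expect_gt(bp$norm[1, 1, "theta"], 0.85) # leakage-bounded: Hann sidelobes
  expect_lt(max(bp$norm[1, 1, c("beta", "gamma")]), 0.02)
  expect_equal(sum(bp$norm[1, 1, ]), 1, tolerance = 1e-6)
  # flat spectrum: normalized powers proportional to band bin counts
  sp <- welch_psd(sine_epochs(10))
  sp$power[] <- 1
  bpf <- band_powers(sp)
  widths <- c(sum(sp$freq >= 1 & sp$freq < 4), sum(sp$freq >= 4 & sp$freq < 8),
              sum(sp$freq >= 8 & sp$freq < 12), sum(sp$freq >= 12 & sp$freq < 30),
              sum(sp$freq >= 30 & sp$freq <= 45))
  expect_equal(as.numeric(bpf$norm[1, 1, ]), widths / sum(widths), tolerance = 1e-9)
})

test_that("spectral summaries behave for line, flat and two-line spectra", {
  sp <- welch_psd(sine_epochs(10))
  idx <- which(sp$freq >= 1 & sp$freq <= 45)
  # single-line spectrum
  sp1 <- sp; sp1$power[] <- 0; sp1$power[, , idx[5]] <- 1
  ss1 <- spectral_summaries(sp1)
  expect_equal(ss1$SE[1, 1], 0)
  expect_equal(ss1$MSF[1, 1], sp$freq[idx[5]], tolerance = 1e-9)
  # flat spectrum
  sp2 <- sp; sp2$power[] <- 1
  ss2 <- spectral_summaries(sp2)
  expect_equal(ss2$SE[1, 1], 1, tolerance = 1e-9)
  f <- sp$freq[idx]
  expect_lt(abs(ss2$MSF[1, 1] - mean(range(f))), 2)
  # two equal lines at 4 and 40 Hz
  sp3 <- sp; sp3$power[] <- 0
  b4 <- idx[which.min(abs(sp$freq[idx] - 4))]
  b40 <- idx[which.min(abs(sp$freq[idx] - 40))]
  sp3$power[, , b4] <- 1; sp3$power[, , b40] <- 1
  ss3 <- spectral_summaries(sp3)
  expect_gt(ss3$MSF[1, 1], 4); expect_lt(ss3$MSF[1, 1], 40)
  expect_gte(ss3$SEF95[1, 1], 39)
})

test_that("compression complexity ranks constant < periodic < random", {
  set.seed(22)
  ns <- 200
  data <- array(0, c(1, 3, ns))
  data[1, 1, ] <- 5 # constant
  data[1, 2, ] <- rep(c(1, 4, 2, 8), length.out = ns) # short period
  data[1, 3, ] <- runif(ns) # incompressible
  K <- kolmogorov_complexity(make_epochs(data))
  expect_lt(K[1, 1], 0.2)
  expect_lt(K[1, 2], K[1, 3])
  # 32-level uniform symbols carry 5 bits/byte: the deflate floor sits near
  # 5/8 plus container overhead
  expect_gt(K[1, 3], 0.65); expect_lte(K[1, 3], 1.15)
})

test_that("ordinal symbolization matches a brute-force pattern oracle", {
  # monotone ramps map to a single symbol each
  up <- ordinal_symbols(1:30, fs = 250, tau_ms = 4)
  dn <- ordinal_symbols(30:1, fs = 250, tau_ms = 4)
  expect_length(unique(up), 1)
  expect_length(unique(dn), 1)
  expect_false(up[1] == dn[1])

  # exhaustive oracle with ties broken by order of occurrence
  brute <- function(x, tau) {
    perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    vapply(seq_len(length(x) - 2 * tau), function(t) {
      r <- rank(c(x[t], x[t + tau], x[t + 2 * tau]), ties.method = "first")
      which(apply(perms, 1, function(p) all(p == r))) - 1L
    }, integer(1))
  }
  x <- c(1, 3, 2, 5, 4, 4, 6, 1, 2, 2, 7, 0)
  expect_identical(ordinal_symbols(x, fs = 250, tau_ms = 4), brute(x, 1))
  set.seed(23)
  y <- rnorm(50)
  expect_identical(ordinal_symbols(y, fs = 250, tau_ms = 8), brute(y, 2))
  expect_error(ordinal_symbols(y, fs = 250, tau_ms = 5), "integer")
})

test_that("permutation entropy is 0 for ramps and approaches 1 for noise", {
  ns <- 400
  data <- array(0, c(2, 2, ns))
  data[, 1, ] <- matrix(rep(seq_len(ns), 2), 2, byrow = TRUE) # ramps
  set.seed(24)
  data[1, 2, ] <- rnorm(ns); data[2, 2, ] <- rnorm(ns)
  pe <- permutation_entropy(make_epochs(data), tau_ms = 4)
  expect_equal(pe[, 1], c(0, 0))
  expect_gt(min(pe[, 2]), 0.9)
  expect_true(all(pe >= 0 & pe <= 1))
  # frequency invariance: duplicated epochs keep the same entropy
  dup <- array(data[c(1, 1), , ], c(2, 2, ns))
  pe2 <- permutation_entropy(make_epochs(dup), tau_ms = 4)
  expect_equal(pe2[1, ], pe2[2, ])
})

test_that("wSMI is zero for duplicated channels and detects lagged coupling", {
  set.seed(25)
  ne <- 30; ns <- 200
  shared <- lapply(seq_len(ne), function(e) bl_noise(ns + 10))
  data <- array(0, c(ne, 4, ns))
  for (e in seq_len(ne)) {
    z <- shared[[e]]
    data[e, 1, ] <- z[11:(ns + 10)]
    data[e, 2, ] <- z[1:ns]     # lag-coupled with channel 1
    data[e, 3, ] <- data[e, 1, ] # exact copy of channel 1
    data[e, 4, ] <- bl_noise(ns) # independent
  }
  w <- wsmi(make_epochs(data))
  expect_true(isSymmetric(unname(w$values)))
  expect_equal(w$values[1, 3], 0) # identical patterns carry zero weight
  expect_gt(w$values[1, 2], w$values[1, 4])
  expect_gt(w$values[1, 2], w$values[2, 4])
  # coupled pair exceeds an empirical independent-pair null
  null_vals <- replicate(30, {
    d2 <- array(0, c(10, 2, ns))
    for (e in 1:10) { d2[e, 1, ] <- bl_noise(ns); d2[e, 2, ] <- bl_noise(ns) }
    wsmi(make_epochs(d2))$values[1, 2]
  })
  expect_gt(w$values[1, 2], quantile(null_vals, 0.95))
})

test_that("trimmed mean and topography summaries match the sort-and-slice oracle", {
  expect_equal(trimmed_mean80(1:10), 5.5)
  expect_equal(trimmed_mean80(rep(3, 7)), 3)
  x <- c(rnorm(19), 1e6)
  expect_lt(abs(trimmed_mean80(x)), 2) # outlier trimmed away
  expect_equal(trimmed_mean80(x), mean(sort(x)[3:18]))
  m <- matrix(c(1:10, rep(2, 10)), 10, 2)
  expect_equal(summarize_topography(m), c(5.5, 2))
})

test_that("pair degree reduces matrices to channel medians", {
  m <- matrix(0.3, 4, 4); diag(m) <- NA
  expect_equal(pair_degree(m), rep(0.3, 4))
  m2 <- matrix(0.1, 4, 4); diag(m2) <- NA
  m2[1, -1] <- m2[-1, 1] <- 0.8 # hub channel
  deg <- pair_degree(m2)
  expect_equal(which.max(deg), 1L)
  expect_equal(deg[2], median(m2[2, -2]))
})

test_that("the marker set has 17 members with valid ranges on real-ish data", {
  set.seed(26)
  data <- array(rnorm(6 * 4 * 200, 0, 10), c(6, 4, 200))
  mv <- marker_epoch_values(make_epochs(data))
  expect_length(mv, 17)
  expect_true(all(mv$SE >= 0 & mv$SE <= 1))
  expect_true(all(mv$PE_theta >= 0 & mv$PE_theta <= 1))
  norm_sum <- mv$delta_norm + mv$theta_norm + mv$alpha_norm +
    mv$beta_norm + mv$gamma_norm
  expect_equal(as.numeric(norm_sum), rep(1, length(norm_sum)), tolerance = 1e-6)
})
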