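make_rec <- function(data, fs = 250, events = NULL, kind = "rest") {
  structure(list(data = data, fs = fs,
                 layout = make_layout(max(nrow(data), 3), "ring", "k-nearest", k = 2),
                 events = events %||% data.frame(sample = integer(), code = character()),
                 meta = list(subject = 1, session = "pre", kind = kind)),
            class = "eeg_recording")
}

test_that("the filter cascade removes DC and mains while preserving the passband", {
  t <- seq_len(7500) / 250
  data <- rbind(100 + 50 * sin(2 * pi * 50 * t),
                10 * sin(2 * pi * 10 * t),
                sin(2 * pi * 1 * t))
  out <- filter_continuous(make_rec(data), "rest_task_common")
  mid <- 1000:6500
  # DC + 50 Hz channel: both components removed
  expect_lt(mean(abs(out$data[1, mid])), 2)
  atten_db <- 20 * log10(sd(out$data[1, mid]) / sd(50 * sin(2 * pi * 50 * t)))
  expect_lt(atten_db, -20)
  # 10-Hz passband amplitude preserved within 5%
  gain <- sd(out$data[2, mid]) / sd(data[2, mid])
  expect_gt(gain, 0.95); expect_lt(gain, 1.05)
})

test_that("the task filter suppresses 30-Hz content passed by the common filter", {
  t <- seq_len(7500) / 250
  data <- rbind(10 * sin(2 * pi * 30 * t), 10 * sin(2 * pi * 30 * t),
                10 * sin(2 * pi * 30 * t))
  common <- filter_continuous(make_rec(data), "rest_task_common")
  task <- filter_continuous(make_rec(data), "task_extra")
  mid <- 1000:6500
  expect_gt(sd(common$data[1, mid]), 5)   # 30 Hz survives the 45-Hz low-pass
  expect_lt(sd(task$data[1, mid]), 0.5)   # but not the 20-Hz task low-pass
})

test_that("resting epoch counts respect the jitter bounds on a 5-min recording", {
  rec <- make_rec(matrix(0, 3, 5 * 60 * 250))
  sets <- epoch_resting(rec, seed = 1, n_iterations = 5)
  counts <- vapply(sets, function(s) dim(s$data)[1], integer(1))
  # spacing in [800 + 550, 800 + 850] ms over a 300-s recording
  expect_true(all(counts >= floor(300000 / 1650)))
  expect_true(all(counts <= ceiling(300000 / 1350) + 1))
  # seeded onsets reproduce
  sets2 <- epoch_resting(rec, seed = 1, n_iterations = 5)
  expect_identical(lapply(sets, `[[`, "onsets"), lapply(sets2, `[[`, "onsets"))
})

test_that("a collapsed jitter range gives deterministic regular epoching", {
  rec <- make_rec(matrix(0, 3, 20000))
  sets <- epoch_resting(rec, seed = 3, n_iterations = 2, jitter_ms = c(700, 700))
  on <- sets[[1]]$onsets
  expect_true(all(diff(on) == diff(on)[1]))
  expect_equal(diff(on)[1], 200 + 175) # 800 ms epoch + 700 ms gap at 250 Hz
  expect_identical(sets[[1]]$onsets, sets[[2]]$onsets)
})

test_that("task epochs use half-open [-800, +740) windows and baseline correction", {
  n <- 3000
  data <- matrix(0, 3, n)
  data[1, ] <- seq_len(n) # ramp encodes the sample index (0-based value i-1)
  rec <- make_rec(data, events = data.frame(sample = 1000, code = "deviant"),
                  kind = "task")
  ep <- epoch_task(rec)
  expect_equal(dim(ep$data)[3], 385)
  raw <- ep$data[1, 1, ] # baseline-corrected ramp: still a ramp, mean-shifted
  # epoch covers 0-based samples [800, 1185): values 801..1185 pre-baseline
  base <- mean(801:1000)
  expect_equal(raw, 801:1185 - base)
  expect_equal(ep$labels, "deviant")
  # constant voltage -> exactly zero after baseline correction
  rec2 <- make_rec(matrix(7, 3, n),
                   events = data.frame(sample = 1000, code = "standard"))
  expect_true(all(epoch_task(rec2)$data == 0))
})

test_that("the rejection cascade flags the right channels and epochs in order", {
  set.seed(11)
  ne <- 20; nc <- 10; ns <- 200
  base <- array(rnorm(ne * nc * ns, 0, 5), c(ne, nc, ns))
  # channel 2: 200-uV transients in 60% of epochs -> step (a)
  bad_ep <- 1:12
  data <- base
  data[bad_ep, 2, 50] <- 200
  res <- reject_cascade(make_epochs(data))
  expect_true(res$epochs$rejected_channels[2])
  expect_equal(res$report$n_rejected[res$report$step == "channel_ptp"], 1)
  # epoch 5 with transients on 20% of retained channels -> step (c)
  data2 <- base
  data2[5, c(3, 6), 100] <- 200
  res2 <- reject_cascade(make_epochs(data2))
  expect_true(res2$epochs$rejected_epochs[5])
  expect_false(any(res2$epochs$rejected_channels[c(3, 6)]))
  # clean data: nothing rejected
  res3 <- reject_cascade(make_epochs(base))
  expect_equal(sum(res3$report$n_rejected), 0)
})

test_that("the rejection cascade is idempotent", {
  set.seed(12)
  data <- array(rnorm(15 * 8 * 200, 0, 10), c(15, 8, 200))
  data[1:9, 3, 77] <- 250
  r1 <- reject_cascade(make_epochs(data))
  r2 <- reject_cascade(r1$epochs)
  expect_identical(r1$epochs$rejected_channels, r2$epochs$rejected_channels)
  expect_identical(r1$epochs$rejected_epochs, r2$epochs$rejected_epochs)
  expect_equal(sum(r2$report$n_rejected), 0)
})

test_that("finalize applies an average reference and the 75%/30% quality gate", {
  set.seed(13)
  data <- array(rnorm(10 * 8 * 100, 0, 5), c(10, 8, 100))
  ep <- make_epochs(data)
  fin <- finalize_epochs(ep)
  expect_false(fin$failed)
  for (e in c(1, 5)) {
    expect_lt(max(abs(colMeans(fin$data[e, , ]))), 1e-9)
  }
  # 3 of 10 channels rejected (70% retained) -> gate failure
  data2 <- array(rnorm(10 * 10 * 100), c(10, 10, 100))
  ep2 <- make_epochs(data2)
  ep2$rejected_channels[1:3] <- TRUE
  expect_true(finalize_epochs(ep2)$failed)
})

test_that("interpolation reproduces a spatially uniform field exactly", {
  # all channels carry the same signal; a rejected channel must get it back
  ns <- 80
  sig <- sin(seq_len(ns) / 5)
  data <- array(rep(rep(sig, each = 6), 4), c(4, 6, ns))
  for (e in 1:4) for (c in 1:6) data[e, c, ] <- sig
  ep <- make_epochs(data)
  ep$rejected_channels[4] <- TRUE
  fin <- finalize_epochs(ep)
  # after average reference the uniform field is zero everywhere, and the
  # interpolated channel must equal its (zero) neighbours
  expect_lt(max(abs(fin$data[1, 4, ])), 1e-9)
  # without re-referencing: interpolate from neighbours directly
  ep2 <- make_epochs(data)
  ep2$rejected_channels[4] <- TRUE
  ep2$data[, 4, ] <- 999 # corrupt; must be replaced by neighbour value
  fin2 <- finalize_epochs(ep2)
  expect_equal(fin2$data[2, 4, ], fin2$data[2, 3, ], tolerance = 1e-9)
})
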