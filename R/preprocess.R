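#' @importFrom signal butter filtfilt
NULL

# causal direct-form ARMA filter over the columns of a matrix,
# zero initial conditions
arma_filter_mat <- function(f, X) {
  b <- f$b / f$a[1]; a <- f$a / f$a[1]
  p <- length(b)
  n <- nrow(X); m <- ncol(X)
  Xp <- rbind(matrix(0, p, m), X)
  Y <- stats::filter(Xp, b, method = "convolution", sides = 1)
  Y <- matrix(as.numeric(Y), n + p, m)[(p + 1):(p + n), , drop = FALSE]
  if (length(a) > 1) {
    Y <- matrix(as.numeric(stats::filter(Y, -a[-1], method = "recursive")), n, m)
  }
  Y
}

# zero-phase IIR application: reflect-pad, filter forward and backward.
# X: samples x series matrix (or a vector).
zp_filter <- function(f, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, length(x), 1) else x
  n <- nrow(X)
  pad <- min(n - 1L, 3L * max(length(f$b), length(f$a)) * 10L)
  XX <- rbind(2 * X[rep(1, pad), , drop = FALSE] - X[(pad + 1):2, , drop = FALSE],
              X,
              2 * X[rep(n, pad), , drop = FALSE] - X[(n - 1):(n - pad), , drop = FALSE])
  Y <- arma_filter_mat(f, XX)
  Y <- arma_filter_mat(f, Y[nrow(Y):1, , drop = FALSE])
  Y <- Y[nrow(Y):1, , drop = FALSE][(pad + 1):(pad + n), , drop = FALSE]
  if (vec) as.numeric(Y) else Y
}

#' Band-pass, notch and task filtering of a continuous recording
#'
#' Applies the study's filter cascade: a 6th-order Butterworth high-pass at
#' 0.5 Hz, an 8th-order Butterworth low-pass at 45 Hz, and band-stop notches
#' at 50 and 100 Hz. `mode = "task_extra"` additionally applies a 20-Hz
#' low-pass used for event-related-potential analysis. All filters are run
#' forward-backward (zero phase) so component latencies are preserved; each
#' channel is demeaned first to suppress edge transients.
#'
#' @param rec An `eeg_recording`.
#' @param mode `"rest_task_common"` or `"task_extra"`.
#' @return The filtered `eeg_recording`.
#' @export
filter_continuous <- function(rec, mode = c("rest_task_common", "task_extra")) {
  mode <- match.arg(mode)
  fs <- rec$fs
  if (fs <= 2 * 45) stop("sampling rate too low for the 45-Hz low-pass", call. = FALSE)
  nyq <- fs / 2
  filters <- list(
    signal::butter(6, 0.5 / nyq, "high"),
    signal::butter(8, 45 / nyq, "low"),
    signal::butter(4, c(48, 52) / nyq, "stop")
  )
  if (nyq > 102) {
    filters <- c(filters, list(signal::butter(4, c(98, 102) / nyq, "stop")))
  }
  if (mode == "task_extra") {
    filters <- c(filters, list(signal::butter(8, 20 / nyq, "low")))
  }
  X <- t(rec$data) - rep(rowMeans(rec$data), each = ncol(rec$data))
  for (f in filters) X <- zp_filter(f, X)
  rec$data <- t(X)
  rec$meta$filtered <- mode
  rec
}

new_epochs <- function(data, fs, layout, labels, reference = "vertex") {
  structure(list(
    data = data, fs = fs, layout = layout, labels = labels,
    rejected_channels = rep(FALSE, dim(data)[2]),
    rejected_epochs = rep(FALSE, dim(data)[1]),
    interpolated_channels = integer(), reference = reference,
    failed = FALSE
  ), class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epochs x %d ch x %d samples @ %g Hz (%d ch, %d ep rejected%s)\n",
              d[1], d[2], d[3], x$fs, sum(x$rejected_channels),
              sum(x$rejected_epochs), if (x$failed) ", FAILED" else ""))
  invisible(x)
}

#' Cut resting-state EEG into jittered 800-ms epochs
#'
#' Segments a continuous resting recording into 800-ms epochs separated by a
#' random inter-epoch jitter drawn uniformly in \[550, 850\] ms. Because the
#' placement is random, the segmentation is repeated `n_iterations` times;
#' downstream markers are computed per iteration and averaged.
#'
#' @param rec An `eeg_recording`.
#' @param seed Integer seed driving the jitters.
#' @param n_iterations Number of independent segmentations (study default
#'   100; desk-scale analyses use fewer).
#' @param jitter_ms Length-2 jitter range in ms.
#' @param epoch_ms Epoch length in ms.
#' @return A list of `eeg_epochs`, one per iteration. If the recording is too
#'   short for two epochs the single returned element has `failed = TRUE`.
#' @export
epoch_resting <- function(rec, seed = 1L, n_iterations = 100,
                          jitter_ms = c(550, 850), epoch_ms = 800) {
  fs <- rec$fs
  ep_len <- round(epoch_ms * fs / 1000)
  n <- ncol(rec$data)
  if (n < 2 * ep_len) {
    ep <- new_epochs(array(0, c(0, nrow(rec$data), ep_len)), fs, rec$layout,
                     character())
    ep$failed <- TRUE
    return(list(ep))
  }
  set.seed(as.integer(seed) %% 2147483629)
  lapply(seq_len(n_iterations), function(it) {
    onsets <- integer(); pos <- 1L
    repeat {
      if (pos + ep_len - 1L > n) break
      onsets <- c(onsets, pos)
      gap <- round(stats::runif(1, jitter_ms[1], jitter_ms[2]) * fs / 1000)
      pos <- pos + ep_len + gap
    }
    data <- array(0, c(length(onsets), nrow(rec$data), ep_len))
    for (e in seq_along(onsets)) {
      data[e, , ] <- rec$data[, onsets[e]:(onsets[e] + ep_len - 1L)]
    }
    ep <- new_epochs(data, fs, rec$layout, rep("rest", length(onsets)))
    ep$onsets <- onsets
    ep
  })
}

#' Epoch an oddball task recording around the fifth sound
#'
#' Cuts epochs spanning \[-800, +740) ms around each fifth-sound onset event
#' (half-open, 0-based sample indexing) and baseline-corrects each epoch by
#' subtracting its mean over the pre-onset \[-800, 0) ms window. Labels come
#' from the event codes.
#'
#' @param rec An `eeg_recording` with events.
#' @return An `eeg_epochs` with `labels` in `standard`/`deviant`; `failed` is
#'   set when no usable event exists.
#' @export
epoch_task <- function(rec) {
  fs <- rec$fs
  pre <- round(0.8 * fs); post <- round(0.74 * fs)
  ev <- rec$events
  nc <- nrow(rec$data); n <- ncol(rec$data)
  ok <- ev$sample - pre >= 0 & ev$sample + post <= n
  ev <- ev[ok, , drop = FALSE]
  if (nrow(ev) == 0) {
    ep <- new_epochs(array(0, c(0, nc, pre + post)), fs, rec$layout, character())
    ep$failed <- TRUE
    return(ep)
  }
  data <- array(0, c(nrow(ev), nc, pre + post))
  for (e in seq_len(nrow(ev))) {
    i0 <- ev$sample[e] - pre + 1L # event 0-based -> R 1-based
    slab <- rec$data[, i0:(i0 + pre + post - 1L), drop = FALSE]
    data[e, , ] <- slab - rowMeans(slab[, seq_len(pre), drop = FALSE])
  }
  ep <- new_epochs(data, fs, rec$layout, ev$code)
  ep$time_ms <- (seq_len(pre + post) - 1 - pre) / fs * 1000
  ep
}

ptp <- function(ep_data) {
  # peak-to-peak per epoch x channel over the full window
  apply(ep_data, c(1, 2), function(v) diff(range(v)))
}

var_z <- function(v) {
  (v - mean(v)) / stats::sd(v)
}

# mean over epochs of the per-epoch sample variance for one channel
mean_epoch_var <- function(data, ep_keep, ch) {
  slab <- matrix(data[ep_keep, ch, ], sum(ep_keep))
  mean(rowSums((slab - rowMeans(slab))^2) / (ncol(slab) - 1))
}

#' Hierarchical automated artifact-rejection cascade
#'
#' Applies, in order: (a) channels whose peak-to-peak amplitude exceeds
#' 150 uV in more than 50% of epochs are rejected; (b) channels whose mean
#' variance across epochs is an outlier (z > 4 across channels) are rejected,
#' twice, recomputing z each pass; (c) epochs exceeding 150 uV peak-to-peak in
#' more than 10% of retained channels are rejected; (d) the variance-z rule is
#' re-applied twice on 25-Hz high-passed data. The order is part of the
#' contract. Rejections accumulate in the epoch set's masks.
#'
#' @param ep An `eeg_epochs`.
#' @param ptp_uv Peak-to-peak threshold (uV).
#' @param z_thresh Variance z-score threshold.
#' @return A list `(epochs, report)`: the updated `eeg_epochs` plus a tibble
#'   of per-step rejection counts.
#' @export
reject_cascade <- function(ep, ptp_uv = 150, z_thresh = 4) {
  d <- dim(ep$data)
  if (d[1] < 2 || d[2] < 2) stop("need >= 2 epochs and >= 2 channels", call. = FALSE)
  ch_keep <- !ep$rejected_channels
  ep_keep <- !ep$rejected_epochs
  steps <- list()
  p <- ptp(ep$data)

  # (a) channel peak-to-peak rule
  frac_bad <- colMeans(p[ep_keep, , drop = FALSE] > ptp_uv)
  rej_a <- ch_keep & frac_bad > 0.5
  ch_keep <- ch_keep & !rej_a
  steps$channel_ptp <- sum(rej_a)

  # (b) channel variance z-rule, two passes
  for (pass in 1:2) {
    idx <- which(ch_keep)
    if (length(idx) > 2) {
      mv <- vapply(idx, function(c) mean_epoch_var(ep$data, ep_keep, c), 0)
      z <- var_z(mv)
      bad <- idx[z > z_thresh]
      ch_keep[bad] <- FALSE
      steps[[paste0("channel_var_z", pass)]] <- length(bad)
    } else steps[[paste0("channel_var_z", pass)]] <- 0L
  }

  # (c) epoch peak-to-peak rule over retained channels
  frac_bad_ep <- rowMeans(p[, ch_keep, drop = FALSE] > ptp_uv)
  rej_c <- ep_keep & frac_bad_ep > 0.1
  ep_keep <- ep_keep & !rej_c
  steps$epoch_ptp <- sum(rej_c)

  # (d) variance z-rule on 25-Hz high-passed data, two passes
  hp <- signal::butter(4, 25 / (ep$fs / 2), "high")
  ns <- dim(ep$data)[3]; ne <- dim(ep$data)[1]; nch <- dim(ep$data)[2]
  flat <- matrix(aperm(ep$data, c(3, 1, 2)), ns, ne * nch)
  flat <- zp_filter(hp, flat)
  hp_data <- aperm(array(flat, c(ns, ne, nch)), c(2, 3, 1))
  for (pass in 1:2) {
    idx <- which(ch_keep)
    if (length(idx) > 2) {
      mv <- vapply(idx, function(c) mean_epoch_var(hp_data, ep_keep, c), 0)
      z <- var_z(mv)
      bad <- idx[z > z_thresh]
      ch_keep[bad] <- FALSE
      steps[[paste0("channel_hf_z", pass)]] <- length(bad)
    } else steps[[paste0("channel_hf_z", pass)]] <- 0L
  }

  ep$rejected_channels <- !ch_keep
  ep$rejected_epochs <- !ep_keep
  if (!any(ch_keep)) ep$failed <- TRUE
  report <- tibble::tibble(
    step = names(steps),
    n_rejected = unlist(steps, use.names = FALSE)
  )
  list(epochs = ep, report = report)
}

#' Re-reference, interpolate and quality-gate an epoch set
#'
#' Transforms retained channels to an average reference, interpolates
#' rejected channels by inverse-distance weighting over their layout
#' neighbors, and applies the quality gate: the set fails unless at least 75%
#' of channels and 30% of epochs survive. Failed sets are flagged, not
#' raised, and should be excluded downstream.
#'
#' @param ep An `eeg_epochs` after [reject_cascade()].
#' @param min_channel_frac,min_epoch_frac Quality-gate fractions.
#' @return The finalized `eeg_epochs` (`$failed` reflects the gate).
#' @export
finalize_epochs <- function(ep, min_channel_frac = 0.75, min_epoch_frac = 0.30) {
  ch_keep <- !ep$rejected_channels
  ep_keep <- !ep$rejected_epochs
  nc <- length(ch_keep)
  if (mean(ch_keep) < min_channel_frac || mean(ep_keep) < min_epoch_frac) {
    ep$failed <- TRUE
  }
  if (!any(ch_keep) || !any(ep_keep)) {
    ep$failed <- TRUE
    return(ep)
  }
  # average reference over retained channels only
  ns <- dim(ep$data)[3]
  for (e in which(ep_keep)) {
    slab <- matrix(ep$data[e, ch_keep, ], sum(ch_keep), ns)
    ep$data[e, ch_keep, ] <- sweep(slab, 2, colMeans(slab))
  }
  ep$reference <- "average"
  # inverse-distance interpolation of rejected channels from retained neighbors
  pos <- ep$layout$positions_3d
  for (c in which(!ch_keep)) {
    nb <- which(ep$layout$adjacency[c, ] & ch_keep)
    if (length(nb) == 0) nb <- which(ch_keep)
    w <- 1 / pmax(sqrt(rowSums((pos[nb, , drop = FALSE] -
                                  matrix(pos[c, ], length(nb), 3, byrow = TRUE))^2)), 1e-9)
    w <- w / sum(w)
    for (e in which(ep_keep)) {
      nbdat <- matrix(ep$data[e, nb, ], length(nb), ns)
      ep$data[e, c, ] <- as.numeric(crossprod(nbdat, w))
    }
  }
  ep$interpolated_channels <- which(!ch_keep)
  ep
}

#' Run the full preprocessing chain on one recording
#'
#' Convenience wrapper: filter, epoch (resting iterations or task), reject
#' and finalize. Returns finalized epoch sets plus the per-step report of the
#' first iteration.
#'
#' @param rec An `eeg_recording`.
#' @param seed Seed for resting epoch placement.
#' @param n_iterations Resting segmentation iterations.
#' @return A list with `epoch_sets` (list of finalized `eeg_epochs`),
#'   `report`, and `passed` (quality gate over the first iteration).
#' @export
preprocess_recording <- function(rec, seed = 1L, n_iterations = 5) {
  if (rec$meta$kind == "rest") {
    filt <- filter_continuous(rec, "rest_task_common")
    sets <- epoch_resting(filt, seed = seed, n_iterations = n_iterations)
  } else {
    filt <- filter_continuous(rec, "task_extra")
    sets <- list(epoch_task(filt))
  }
  out <- vector("list", length(sets))
  report <- NULL
  for (i in seq_along(sets)) {
    if (sets[[i]]$failed || dim(sets[[i]]$data)[1] < 2) {
      sets[[i]]$failed <- TRUE
      out[[i]] <- sets[[i]]
      next
    }
    rc <- reject_cascade(sets[[i]])
    out[[i]] <- finalize_epochs(rc$epochs)
    if (is.null(report)) report <- rc$report
  }
  list(epoch_sets = out, report = report,
       passed = !out[[1]]$failed)
}
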