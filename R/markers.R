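#' Welch power spectral density of an epoch set
#'
#' Per epoch and channel, averages modified periodograms of 512-ms Hann-
#' tapered segments with 400-ms overlap (128-sample segments, 100-sample
#' overlap at 250 Hz). One-sided density in uV^2/Hz.
#'
#' @param ep An `eeg_epochs`.
#' @param seg_ms,overlap_ms Welch segment length and overlap (ms).
#' @return A list of class `eeg_spectrum`: `freq` (Hz) and `power`
#'   (epochs x channels x frequencies, retained epochs only).
#' @export
welch_psd <- function(ep, seg_ms = 512, overlap_ms = 400) {
  fs <- ep$fs
  nper <- round(seg_ms * fs / 1000)
  nover <- round(overlap_ms * fs / 1000)
  step <- nper - nover
  keep_e <- which(!ep$rejected_epochs)
  ns <- dim(ep$data)[3]
  if (ns < nper) stop("epochs shorter than the Welch segment", call. = FALSE)
  nc <- dim(ep$data)[2]
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1)) # Hann
  u <- sum(w^2)
  nf <- nper %/% 2 + 1
  freq <- (seq_len(nf) - 1) * fs / nper
  starts <- seq(1, ns - nper + 1, by = step)

  power <- array(0, c(length(keep_e), nc, nf))
  for (ei in seq_along(keep_e)) {
    e <- keep_e[ei]
    for (ch in seq_len(nc)) {
      x <- ep$data[e, ch, ]
      acc <- numeric(nf)
      for (s0 in starts) {
        seg <- (x[s0:(s0 + nper - 1)] - mean(x[s0:(s0 + nper - 1)])) * w
        sp <- abs(stats::fft(seg))^2 / (fs * u)
        half <- sp[seq_len(nf)]
        half[2:(nf - 1)] <- 2 * half[2:(nf - 1)]
        acc <- acc + half
      }
      power[ei, ch, ] <- acc / length(starts)
    }
  }
  structure(list(freq = freq, power = power, nper = nper, nover = nover),
            class = "eeg_spectrum")
}

#' Frequency-band definitions (Hz)
#'
#' Delta 1-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-45. Band bins are
#' assigned half-open `[low, high)` except gamma which includes 45 Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 45))
}

band_bins <- function(freq, band, last = FALSE) {
  if (last) which(freq >= band[1] & freq <= band[2])
  else which(freq >= band[1] & freq < band[2])
}

#' Raw and normalized spectral band powers
#'
#' Raw band power sums the PSD bins of the band; normalized band power is the
#' raw power divided by the total over the five bands, so the five normalized
#' values sum to one per epoch and channel.
#'
#' @param sp An `eeg_spectrum`.
#' @return A list with `raw` and `norm`, each epochs x channels x 5 arrays
#'   with band names on the third dimension.
#' @export
band_powers <- function(sp) {
  bands <- eeg_bands()
  nb <- length(bands)
  d <- dim(sp$power)
  raw <- array(0, c(d[1], d[2], nb), dimnames = list(NULL, NULL, names(bands)))
  for (b in seq_len(nb)) {
    idx <- band_bins(sp$freq, bands[[b]], last = (b == nb))
    raw[, , b] <- apply(sp$power[, , idx, drop = FALSE], c(1, 2), sum)
  }
  tot <- apply(raw, c(1, 2), sum)
  norm <- raw
  for (b in seq_len(nb)) norm[, , b] <- ifelse(tot > 0, raw[, , b] / tot, NA_real_)
  list(raw = raw, norm = norm)
}

#' Spectral entropy, median frequency and spectral edges
#'
#' Treats the 1-45-Hz PSD as a probability distribution per epoch x channel.
#' Spectral entropy is its Shannon entropy normalized by `log(#bins)` (0 for
#' a single line, 1 for a flat spectrum). The median spectral frequency and
#' 90/95% spectral edges are the frequencies below which 50/90/95% of the
#' total band power lies, linearly interpolated between bins.
#'
#' @param sp An `eeg_spectrum`.
#' @return List of epochs x channels matrices: `SE`, `MSF`, `SEF90`, `SEF95`.
#' @export
spectral_summaries <- function(sp) {
  idx <- which(sp$freq >= 1 & sp$freq <= 45)
  f <- sp$freq[idx]
  d <- dim(sp$power)
  SE <- MSF <- SEF90 <- SEF95 <- matrix(NA_real_, d[1], d[2])
  for (e in seq_len(d[1])) for (ch in seq_len(d[2])) {
    p <- sp$power[e, ch, idx]
    tot <- sum(p)
    if (tot <= 0) stop("zero total power: spectral summaries undefined", call. = FALSE)
    pr <- p / tot
    nz <- pr > 0
    SE[e, ch] <- -sum(pr[nz] * log(pr[nz])) / log(length(pr))
    cs <- cumsum(pr)
    df <- if (length(f) > 1) f[2] - f[1] else 0
    # inverse CDF treating each bin's mass as uniform over its width, so a
    # single-line spectrum returns exactly that bin's frequency
    edge <- function(q) {
      i <- which(cs >= q)[1]
      prev <- if (i == 1) 0 else cs[i - 1]
      f[i] - df / 2 + (q - prev) / pr[i] * df
    }
    MSF[e, ch] <- edge(0.5)
    SEF90[e, ch] <- edge(0.9)
    SEF95[e, ch] <- edge(0.95)
  }
  list(SE = SE, MSF = MSF, SEF90 = SEF90, SEF95 = SEF95)
}

#' Kolmogorov-Chaitin complexity proxy by lossless compression
#'
#' Per epoch x channel, the signal is quantized to 32 equal-width amplitude
#' bins between its minimum and maximum, serialized to one byte per sample,
#' and compressed with a deflate (gzip) compressor. Complexity is the ratio
#' of compressed to uncompressed size: low for redundant signals, around one
#' (slightly above, due to container overhead) for incompressible ones.
#'
#' @param ep An `eeg_epochs`.
#' @param n_bins Quantization levels.
#' @return Epochs x channels matrix of compression ratios.
#' @export
kolmogorov_complexity <- function(ep, n_bins = 32) {
  keep_e <- which(!ep$rejected_epochs)
  d <- dim(ep$data)
  out <- matrix(NA_real_, length(keep_e), d[2])
  for (ei in seq_along(keep_e)) for (ch in seq_len(d[2])) {
    x <- ep$data[keep_e[ei], ch, ]
    rng <- range(x)
    q <- if (diff(rng) == 0) rep(0L, length(x)) else {
      pmin(n_bins - 1L, as.integer((x - rng[1]) / diff(rng) * n_bins))
    }
    raw <- as.raw(q)
    out[ei, ch] <- length(memCompress(raw, "gzip")) / length(raw)
  }
  out
}

# ---- ordinal patterns --------------------------------------------------

perm_table <- local({
  p <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
             c(3, 1, 2), c(3, 2, 1))
  code <- (p[, 1] - 1) * 9 + (p[, 2] - 1) * 3 + (p[, 3] - 1)
  lut <- integer(27); lut[code + 1] <- seq_len(6) - 1L
  # sign-opposite pattern: ranks mirrored r -> 4 - r
  opp <- integer(6)
  for (i in 1:6) {
    r <- 4 - p[i, ]
    opp[i] <- lut[(r[1] - 1) * 9 + (r[2] - 1) * 3 + (r[3] - 1) + 1]
  }
  list(lut = lut, opposite = opp)
})

#' Ordinal-pattern symbolization of a single-channel signal
#'
#' At each start index t, the symbol is the permutation ranking of
#' `(x[t], x[t + tau], x[t + 2 tau])` with `tau = tau_ms * fs / 1000` samples
#' (k = 3, six possible symbols, 0-5). Ties are broken by order of
#' occurrence. `tau` must be an integer number of samples.
#'
#' @param x Numeric vector (one channel of one epoch).
#' @param fs Sampling rate (Hz).
#' @param tau_ms Pattern lag in ms (default 32 ms, the theta-alpha range).
#' @return Integer vector of symbols in `0:5`, length `length(x) - 2 * tau`.
#' @export
ordinal_symbols <- function(x, fs = 250, tau_ms = 32) {
  tau <- tau_ms * fs / 1000
  if (abs(tau - round(tau)) > 1e-9) {
    stop("tau_ms does not correspond to an integer number of samples", call. = FALSE)
  }
  tau <- as.integer(round(tau))
  n <- length(x) - 2L * tau
  if (n < 1) stop("signal too short for the requested tau", call. = FALSE)
  a <- x[seq_len(n)]
  b <- x[seq_len(n) + tau]
  c <- x[seq_len(n) + 2L * tau]
  ra <- 1L + (b < a) + (c < a)
  rb <- 1L + (a <= b) + (c < b)
  rc <- 1L + (a <= c) + (b <= c)
  perm_table$lut[(ra - 1L) * 9L + (rb - 1L) * 3L + (rc - 1L) + 1L]
}

#' Permutation entropy map
#'
#' Shannon entropy of the six ordinal-pattern frequencies within each epoch,
#' normalized by `log(6)` to lie in \[0, 1\]. The default 32-ms lag tunes the
#' patterns to the theta-alpha range.
#'
#' @param ep An `eeg_epochs`.
#' @param tau_ms Pattern lag (ms).
#' @return Epochs x channels matrix of normalized entropies.
#' @export
permutation_entropy <- function(ep, tau_ms = 32) {
  keep_e <- which(!ep$rejected_epochs)
  d <- dim(ep$data)
  out <- matrix(NA_real_, length(keep_e), d[2])
  for (ei in seq_along(keep_e)) for (ch in seq_len(d[2])) {
    s <- ordinal_symbols(ep$data[keep_e[ei], ch, ], ep$fs, tau_ms)
    p <- tabulate(s + 1L, 6) / length(s)
    nz <- p > 0
    out[ei, ch] <- -sum(p[nz] * log(p[nz])) / log(6)
  }
  out
}

#' Weighted symbolic mutual information between all channel pairs
#'
#' For each channel pair, forms the joint distribution of simultaneous
#' ordinal patterns and computes
#' `sum_{s,s'} w(s,s') p(s,s') log( p(s,s') / (p(s) p(s')) )`,
#' with weight 0 for identical and sign-opposite pattern pairs and 1
#' otherwise, which discounts common-source and volume-conduction coupling.
#' Computed per epoch, then combined across epochs with the 80% trimmed mean.
#'
#' @param ep An `eeg_epochs`.
#' @param tau_ms Pattern lag (ms); 32 ms targets the 4-10-Hz theta-alpha
#'   range.
#' @return A list of class `wsmi_matrix`: `values` (symmetric channels x
#'   channels, diagonal `NA`), `per_epoch` (epochs x n_pairs matrix),
#'   `pairs` (n_pairs x 2 index matrix), `tau_ms`.
#' @export
wsmi <- function(ep, tau_ms = 32) {
  keep_e <- which(!ep$rejected_epochs)
  d <- dim(ep$data)
  nc <- d[2]
  if (nc < 2) stop("need >= 2 channels", call. = FALSE)
  pairs <- electrode_pairs(nc)
  np <- nrow(pairs)

  opp <- perm_table$opposite
  W <- matrix(1, 6, 6)
  diag(W) <- 0
  for (s in 1:6) W[s, opp[s] + 1] <- 0

  per_epoch <- matrix(0, length(keep_e), np)
  for (ei in seq_along(keep_e)) {
    e <- keep_e[ei]
    S <- matrix(0L, nc, 0)
    symlist <- lapply(seq_len(nc), function(ch) {
      ordinal_symbols(ep$data[e, ch, ], ep$fs, tau_ms)
    })
    L <- length(symlist[[1]])
    marg <- lapply(symlist, function(s) tabulate(s + 1L, 6) / L)
    for (pi in seq_len(np)) {
      i <- pairs[pi, 1]; j <- pairs[pi, 2]
      joint <- tabulate(symlist[[i]] * 6L + symlist[[j]] + 1L, 36) / L
      jm <- matrix(joint, 6, 6, byrow = TRUE) # rows: symbol of i
      pij <- outer(marg[[i]], marg[[j]])
      ok <- jm > 0 & pij > 0
      per_epoch[ei, pi] <- sum(W[ok] * jm[ok] * log(jm[ok] / pij[ok]))
    }
  }
  vals <- tm80_cols(per_epoch)
  m <- matrix(NA_real_, nc, nc)
  m[pairs] <- vals
  m[pairs[, c(2, 1), drop = FALSE]] <- vals
  structure(list(values = m, per_epoch = per_epoch, pairs = pairs,
                 tau_ms = tau_ms), class = "wsmi_matrix")
}

#' 80% trimmed mean
#'
#' Mean after discarding the lowest 10% and highest 10% of values (counts
#' floored), the study's robust estimator of central tendency.
#' @param x Numeric vector.
#' @return Scalar.
#' @export
trimmed_mean80 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(NA_real_)
  k <- floor(0.1 * n)
  mean(sort(x)[(k + 1):(n - k)])
}

# column-wise 80% trimmed mean via one global order() pass
tm80_cols <- function(m) {
  n <- nrow(m)
  if (n == 1) return(as.numeric(m))
  k <- floor(0.1 * n)
  s <- matrix(m[order(col(m), m)], n)
  colMeans(s[(k + 1):(n - k), , drop = FALSE])
}

#' Summarize per-epoch marker values into a topography
#'
#' Per channel, the 80% trimmed mean across epochs. For multi-iteration
#' resting epoching, call per iteration and average the topographies.
#'
#' @param values Epochs x channels matrix.
#' @return Named numeric vector (one value per channel).
#' @export
summarize_topography <- function(values) {
  if (anyNA(values)) return(apply(values, 2, trimmed_mean80))
  tm80_cols(values)
}

#' Channel degree of a wSMI pair matrix
#'
#' Reduces the 3-D pairwise structure to a topography: per channel, the
#' median of its wSMI values with all other channels, highlighting
#' connectivity hubs.
#'
#' @param pm A `wsmi_matrix` (or plain symmetric matrix).
#' @return Numeric vector, one value per channel.
#' @export
pair_degree <- function(pm) {
  m <- if (inherits(pm, "wsmi_matrix")) pm$values else pm
  apply(m, 1, function(v) stats::median(v, na.rm = TRUE))
}

marker_ids <- c("delta_raw", "delta_norm", "theta_raw", "theta_norm",
                "alpha_raw", "alpha_norm", "beta_raw", "beta_norm",
                "gamma_raw", "gamma_norm", "SE", "MSF", "SEF90", "SEF95",
                "K", "PE_theta", "wSMI_theta_degree")

#' Per-epoch values of all seventeen resting-state markers
#'
#' Computes, for one finalized epoch set, the ten raw/normalized band powers,
#' the four spectral summaries, Kolmogorov complexity, theta-alpha
#' permutation entropy and the wSMI degree, each as an epochs x channels
#' matrix (wSMI degree is the per-epoch channel median of pair values).
#'
#' @param ep A finalized `eeg_epochs`.
#' @param tau_ms Ordinal-pattern lag for PE and wSMI.
#' @return Named list of 17 epochs x channels matrices plus attribute
#'   `wsmi` carrying the full `wsmi_matrix`.
#' @export
marker_epoch_values <- function(ep, tau_ms = 32) {
  sp <- welch_psd(ep)
  bp <- band_powers(sp)
  ss <- spectral_summaries(sp)
  K <- kolmogorov_complexity(ep)
  PE <- permutation_entropy(ep, tau_ms)
  wm <- wsmi(ep, tau_ms)
  nc <- dim(ep$data)[2]
  # per-epoch degree from the per-epoch pair values
  deg <- t(apply(wm$per_epoch, 1, function(v) {
    m <- matrix(NA_real_, nc, nc)
    m[wm$pairs] <- v
    m[wm$pairs[, c(2, 1), drop = FALSE]] <- v
    apply(m, 1, function(r) stats::median(r, na.rm = TRUE))
  }))
  out <- list(
    delta_raw = bp$raw[, , "delta"], delta_norm = bp$norm[, , "delta"],
    theta_raw = bp$raw[, , "theta"], theta_norm = bp$norm[, , "theta"],
    alpha_raw = bp$raw[, , "alpha"], alpha_norm = bp$norm[, , "alpha"],
    beta_raw = bp$raw[, , "beta"], beta_norm = bp$norm[, , "beta"],
    gamma_raw = bp$raw[, , "gamma"], gamma_norm = bp$norm[, , "gamma"],
    SE = ss$SE, MSF = ss$MSF, SEF90 = ss$SEF90, SEF95 = ss$SEF95,
    K = K, PE_theta = PE, wSMI_theta_degree = deg
  )
  out <- lapply(out, function(m) matrix(m, nrow = dim(ep$data)[1] - sum(ep$rejected_epochs), ncol = nc))
  attr(out, "wsmi") <- wm
  out
}

#' Marker topographies for one subject/session
#'
#' Runs [marker_epoch_values()] over each resting iteration, summarizes each
#' marker with the trimmed mean across epochs, and averages over iterations.
#'
#' @param epoch_sets List of finalized `eeg_epochs` (iterations). Failed sets
#'   are skipped.
#' @param tau_ms Ordinal-pattern lag.
#' @return A tibble `marker`, `channel`, `value` (class
#'   `marker_topography`), with the averaged `wsmi_matrix` values in
#'   attribute `wsmi`.
#' @export
compute_markers <- function(epoch_sets, tau_ms = 32) {
  sets <- Filter(function(s) !s$failed, epoch_sets)
  if (length(sets) == 0) stop("no usable epoch set", call. = FALSE)
  topos <- NULL; wsum <- NULL
  per_iter <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    mv <- marker_epoch_values(sets[[i]], tau_ms)
    per_iter[[i]] <- mv
    tp <- vapply(mv, summarize_topography, numeric(ncol(mv[[1]])))
    topos <- if (is.null(topos)) tp else topos + tp
    wv <- attr(mv, "wsmi")$values
    wsum <- if (is.null(wsum)) wv else wsum + wv
  }
  topos <- topos / length(sets)
  wsum <- wsum / length(sets)
  out <- tibble::tibble(
    marker = rep(colnames(topos), each = nrow(topos)),
    channel = rep(seq_len(nrow(topos)), ncol(topos)),
    value = as.numeric(topos)
  )
  class(out) <- c("marker_topography", class(out))
  attr(out, "wsmi") <- wsum
  attr(out, "per_iteration") <- per_iter
  out
}
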