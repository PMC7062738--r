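#' Specify a synthetic tDCS cohort
#'
#' Bundles every knob of the synthetic-cohort generator: group sizes,
#' recording geometry, the oscillatory/noise signal model, artifact rates and
#' the planted post-stimulation effects that responders (`R+`) receive.
#' Amplitudes are in microvolts; planted sinusoid power is analytically
#' `amplitude^2 / 2` which anchors the calibration tests.
#'
#' @param n_rplus,n_rminus Subjects per behavioral-response group.
#' @param n_channels,geometry,neighbor_rule Layout passed to [make_layout()].
#' @param fs Sampling rate (Hz).
#' @param rest_duration Resting recording length (s).
#' @param n_trials Oddball trials per task recording.
#' @param p_deviant Deviant-trial proportion (exact allocation, then shuffled).
#' @param band_amplitudes Named baseline amplitudes (uV) of the five
#'   band-limited components (delta, theta, alpha, beta, gamma).
#' @param noise_sd Broadband pink-noise standard deviation (uV); 0 disables.
#' @param pink_exponent Spectral slope of the 1/f background.
#' @param sensor_noise_sd White sensor-noise SD (uV).
#' @param coupling_pairs Two-column matrix of channel index pairs sharing a
#'   lagged latent theta-alpha oscillator.
#' @param coupling_amplitude Baseline amplitude (uV) of the shared oscillator.
#' @param coupling_lag_ms Lag of the second channel of each pair (ms).
#' @param effect_theta,effect_alpha Post-session amplitude increments (uV)
#'   added to the theta and alpha components of `R+` subjects.
#' @param effect_coupling Post-session increment of the shared-oscillator
#'   amplitude in `R+`.
#' @param mmn_amplitude,p3_amplitude Deviant-trial component amplitudes (uV).
#' @param effect_p3 Post-session P3 amplitude increment in `R+`.
#' @param artifact_rate Per-epoch-equivalent probability of a high-amplitude
#'   (>=150 uV) rectangular transient.
#' @param bad_channel_rate Probability that a channel is replaced by
#'   high-variance noise for a whole recording.
#' @param seed Integer master seed; fixes the whole cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_rplus = 12, n_rminus = 48,
                        n_channels = 32, geometry = "spherical-cap",
                        neighbor_rule = "delaunay",
                        fs = 250, rest_duration = 95, n_trials = 150,
                        p_deviant = 0.2,
                        band_amplitudes = c(delta = 8, theta = 4, alpha = 5,
                                            beta = 2, gamma = 1),
                        noise_sd = 10, pink_exponent = 1, sensor_noise_sd = 2,
                        coupling_pairs = NULL, coupling_amplitude = 0,
                        coupling_lag_ms = 40,
                        effect_theta = 0, effect_alpha = 0,
                        effect_coupling = 0,
                        mmn_amplitude = 2, p3_amplitude = 1, effect_p3 = 0,
                        artifact_rate = 0, bad_channel_rate = 0,
                        seed = 1L) {
  stopifnot(p_deviant >= 0, p_deviant <= 1,
            artifact_rate >= 0, artifact_rate <= 1,
            bad_channel_rate >= 0, bad_channel_rate <= 1)
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  amp <- stats::setNames(numeric(5), bands)
  amp[names(band_amplitudes)] <- band_amplitudes
  layout <- make_layout(n_channels, geometry, neighbor_rule)
  if (is.null(coupling_pairs)) {
    # default: a triangle of channel 1 and two of its layout neighbors, so
    # planted coupling forms a connected set in the pair-adjacency graph
    nb <- which(layout$adjacency[1, ])
    if (length(nb) >= 2) {
      coupling_pairs <- rbind(c(1L, nb[1]), c(1L, nb[2]), sort(nb[1:2]))
    } else {
      coupling_pairs <- cbind(1L, 2L)
    }
  }
  structure(list(
    n_rplus = n_rplus, n_rminus = n_rminus, layout = layout, fs = fs,
    rest_duration = rest_duration, n_trials = n_trials, p_deviant = p_deviant,
    band_amplitudes = amp, noise_sd = noise_sd,
    pink_exponent = pink_exponent, sensor_noise_sd = sensor_noise_sd,
    coupling_pairs = coupling_pairs, coupling_amplitude = coupling_amplitude,
    coupling_lag_ms = coupling_lag_ms,
    effect_theta = effect_theta, effect_alpha = effect_alpha,
    effect_coupling = effect_coupling,
    mmn_amplitude = mmn_amplitude, p3_amplitude = p3_amplitude,
    effect_p3 = effect_p3,
    artifact_rate = artifact_rate, bad_channel_rate = bad_channel_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

band_centers <- c(delta = 2.5, theta = 6, alpha = 10, beta = 20, gamma = 37)

# deterministic per-subject/session/kind substream, kept below 2^31
substream_seed <- function(seed, subject, session, kind) {
  s_code <- match(session, c("pre", "post"))
  k_code <- match(kind, c("rest", "task", "aux"))
  (as.double(seed) * 97003 + subject * 1013 + s_code * 131 + k_code * 17) %% 2147483629
}

pink_noise <- function(n, exponent = 1) {
  # spectral shaping of white noise; unit-SD output. Work at a highly
  # composite FFT length and truncate, to keep the transform O(n log n).
  m <- stats::nextn(n)
  white <- stats::rnorm(m)
  f <- c(1, seq_len(floor(m / 2)), if (m > 2) rev(seq_len(ceiling(m / 2) - 1)))
  x <- Re(stats::fft(stats::fft(white) * f^(-exponent / 2), inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

bandlimited_noise <- function(n, fs, band) {
  # unit-SD Gaussian noise restricted to [band[1], band[2]] Hz via FFT masking
  m <- stats::nextn(n)
  x <- stats::rnorm(m)
  f <- c(0, seq_len(floor(m / 2)), if (m > 2) rev(seq_len(ceiling(m / 2) - 1))) * fs / m
  keep <- f >= band[1] & f <= band[2]
  y <- Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  y / stats::sd(y)
}

jittered_sinusoid <- function(n, fs, freq, amplitude, phase_jitter = 0.05) {
  if (amplitude == 0) return(numeric(n))
  t <- seq_len(n) / fs
  drift <- cumsum(stats::rnorm(n, 0, phase_jitter))
  amplitude * sin(2 * pi * freq * t + stats::runif(1, 0, 2 * pi) + drift)
}

new_recording <- function(data, fs, layout, events, meta) {
  structure(list(data = data, fs = fs, layout = layout,
                 events = events, meta = meta), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%s/%s, %s)\n",
              nrow(x$data), ncol(x$data), x$fs,
              x$meta$subject %||% "?", x$meta$session %||% "?",
              x$meta$kind %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

session_amplitudes <- function(spec, group, session) {
  amp <- spec$band_amplitudes
  coup <- spec$coupling_amplitude
  if (identical(group, "R+") && identical(session, "post")) {
    amp["theta"] <- amp["theta"] + spec$effect_theta
    amp["alpha"] <- amp["alpha"] + spec$effect_alpha
    coup <- coup + spec$effect_coupling
  }
  list(bands = amp, coupling = coup)
}

#' Simulate one resting-state recording
#'
#' Builds a continuous multichannel recording as pink 1/f background plus five
#' jittered-phase band-limited sinusoids, an optional lag-coupled latent
#' oscillator shared between designated channel pairs, white sensor noise and
#' injected rectangular artifacts. Responder (`R+`) post-stimulation sessions
#' receive the spec's planted theta/alpha power and coupling increments.
#'
#' @param spec A [cohort_spec()].
#' @param subject Subject index (used to derive the random substream).
#' @param session `"pre"` or `"post"`.
#' @param group `"R+"` or `"R-"`; decides whether planted effects apply.
#' @return An `eeg_recording`.
#' @export
simulate_resting <- function(spec, subject, session = c("pre", "post"),
                             group = "R-") {
  session <- match.arg(session)
  set.seed(substream_seed(spec$seed, subject, session, "rest"))
  n <- round(spec$rest_duration * spec$fs)
  nc <- length(spec$layout$channel_ids)
  amps <- session_amplitudes(spec, group, session)

  data <- matrix(0, nc, n)
  for (ch in seq_len(nc)) {
    x <- if (spec$noise_sd > 0) spec$noise_sd * pink_noise(n, spec$pink_exponent) else numeric(n)
    for (b in names(amps$bands)) {
      x <- x + jittered_sinusoid(n, spec$fs, band_centers[[b]], amps$bands[[b]])
    }
    if (spec$sensor_noise_sd > 0) x <- x + stats::rnorm(n, 0, spec$sensor_noise_sd)
    data[ch, ] <- x
  }

  if (amps$coupling > 0) {
    lag <- round(spec$coupling_lag_ms * spec$fs / 1000)
    for (r in seq_len(nrow(spec$coupling_pairs))) {
      z <- amps$coupling * bandlimited_noise(n + lag, spec$fs, c(4, 10))
      a <- spec$coupling_pairs[r, 1]; b <- spec$coupling_pairs[r, 2]
      data[a, ] <- data[a, ] + z[(lag + 1):(n + lag)]
      data[b, ] <- data[b, ] + z[1:n]
    }
  }

  data <- inject_artifacts(data, spec)
  new_recording(data, spec$fs, spec$layout,
                events = data.frame(sample = integer(), code = character()),
                meta = list(subject = subject, session = session,
                            kind = "rest", group = group))
}

inject_artifacts <- function(data, spec) {
  nc <- nrow(data); n <- ncol(data)
  if (spec$artifact_rate > 0) {
    n_seg <- max(1, floor(n / 200))
    for (seg in seq_len(n_seg)) {
      if (stats::runif(1) < spec$artifact_rate) {
        ch <- sample.int(nc, 1)
        i0 <- (seg - 1) * 200 + 1
        idx <- i0:min(n, i0 + 49)
        data[ch, idx] <- data[ch, idx] + 200 * sample(c(-1, 1), 1)
      }
    }
  }
  if (spec$bad_channel_rate > 0) {
    bad <- stats::runif(nc) < spec$bad_channel_rate
    if (any(bad)) data[bad, ] <- matrix(stats::rnorm(sum(bad) * n, 0, 120), sum(bad), n)
  }
  data
}

#' Simulate one auditory-oddball task recording
#'
#' Emulates the five-tone oddball design: trains of four identical tones
#' followed by a fifth tone that is identical (standard, 80% of trials) or
#' distinct (deviant, 20%). Events mark the onset of the fifth sound. Deviant
#' trials carry an early biphasic MMN-like deflection and a late sustained
#' P3-like component; `R+` post sessions receive the planted P3 increment.
#' Deviant allocation is exact (`round(n_trials * p_deviant)`) and the trial
#' order is a seeded shuffle.
#'
#' @inheritParams simulate_resting
#' @return An `eeg_recording` with an event per trial (`code` is `"standard"`
#'   or `"deviant"`).
#' @export
simulate_task <- function(spec, subject, session = c("pre", "post"),
                          group = "R-") {
  session <- match.arg(session)
  set.seed(substream_seed(spec$seed, subject, session, "task"))
  fs <- spec$fs
  pre_s <- ceiling(0.8 * fs); post_s <- ceiling(0.75 * fs)
  trial_len <- pre_s + post_s + round(0.2 * fs)
  n <- spec$n_trials * trial_len + pre_s + post_s
  nc <- length(spec$layout$channel_ids)

  p3_amp <- spec$p3_amplitude
  if (identical(group, "R+") && identical(session, "post")) {
    p3_amp <- p3_amp + spec$effect_p3
  }

  data <- matrix(0, nc, n)
  for (ch in seq_len(nc)) {
    x <- if (spec$noise_sd > 0) spec$noise_sd * pink_noise(n, spec$pink_exponent) else numeric(n)
    if (spec$sensor_noise_sd > 0) x <- x + stats::rnorm(n, 0, spec$sensor_noise_sd)
    data[ch, ] <- x
  }

  n_dev <- round(spec$n_trials * spec$p_deviant)
  labels <- sample(rep(c("deviant", "standard"),
                       c(n_dev, spec$n_trials - n_dev)))
  onsets <- pre_s + (seq_len(spec$n_trials) - 1) * trial_len + 1

  # spatial projections: anterior-weighted MMN, posterior-weighted P3.
  # Neither is spatially uniform, so both survive average referencing.
  w_mmn <- 0.5 + 0.5 * cos(seq(0, pi, length.out = nc))
  w_p3 <- 0.2 + 0.8 * sin(seq(0, pi / 2, length.out = nc))
  t_ms <- (seq_len(post_s) - 1) / fs * 1000
  mmn_shape <- -sin(pmax(0, pmin(1, (t_ms - 100) / 100)) * 2 * pi) # 100-200 ms biphasic
  p3_shape <- as.numeric(t_ms >= 300 & t_ms <= 600) *
    sin(pmin(1, pmax(0, (t_ms - 300) / 300)) * pi)

  for (i in seq_len(spec$n_trials)) {
    if (labels[i] == "deviant") {
      idx <- onsets[i]:(onsets[i] + post_s - 1)
      data[, idx] <- data[, idx] +
        (cbind(w_mmn * spec$mmn_amplitude) %*% rbind(mmn_shape)) +
        (cbind(w_p3 * p3_amp) %*% rbind(p3_shape))
    }
  }

  data <- inject_artifacts(data, spec)
  new_recording(data, fs, spec$layout,
                events = data.frame(sample = onsets - 1L, # 0-based
                                    code = labels),
                meta = list(subject = subject, session = session,
                            kind = "task", group = group))
}

#' Simulate a full responder/non-responder cohort
#'
#' Draws per-subject behavioral records (CRS-R totals pre/post consistent with
#' the response label: responders strictly increase, non-responders stay
#' constant) and generates resting and task recordings for both sessions.
#'
#' @param spec A [cohort_spec()].
#' @param recordings Which modalities to generate (`"rest"`, `"task"`).
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `diagnosis`, `crsr_pre`, `crsr_post` and list-columns of recordings.
#' @export
simulate_cohort <- function(spec, recordings = c("rest", "task")) {
  n <- spec$n_rplus + spec$n_rminus
  groups <- rep(c("R+", "R-"), c(spec$n_rplus, spec$n_rminus))
  set.seed(substream_seed(spec$seed, 0, "pre", "aux"))
  diagnosis <- sample(c("VS/UWS", "MCS", "exit-MCS"), n, replace = TRUE,
                      prob = c(0.4, 0.53, 0.07))
  crsr_pre <- pmin(20L, pmax(1L, 5L + as.integer(diagnosis == "MCS") * 4L +
    as.integer(diagnosis == "exit-MCS") * 10L + sample(0:3, n, replace = TRUE)))
  crsr_post <- crsr_pre + ifelse(groups == "R+", sample(1:3, n, replace = TRUE), 0L)
  crsr_post <- pmin(23L, crsr_post)

  out <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = groups, diagnosis = diagnosis,
    crsr_pre = crsr_pre, crsr_post = crsr_post
  )
  for (kind in recordings) {
    simfun <- if (kind == "rest") simulate_resting else simulate_task
    for (sess in c("pre", "post")) {
      col <- paste(kind, sess, sep = "_")
      out[[col]] <- lapply(seq_len(n), function(i) {
        simfun(spec, i, sess, groups[i])
      })
    }
  }
  out
}

#' Simulate a labeled reference database for classifier training
#'
#' Generates resting recordings for a VS/UWS-vs-MCS reference cohort in which
#' MCS-labeled subjects carry systematically larger theta-alpha power and
#' coupling, scaled by `separation` (0 = indistinguishable groups).
#'
#' @param n_vs,n_mcs Group sizes (each >= 5).
#' @param separation Effect scale multiplying the MCS theta/alpha amplitude
#'   and coupling increments (uV units at scale 1: +2 uV theta, +2 uV alpha,
#'   +3 uV coupling).
#' @param seed Integer seed.
#' @param spec Optional base [cohort_spec()] to take geometry/noise from.
#' @return A tibble with `subject_id`, `label` (`"VS"`/`"MCS"`) and a
#'   `recording` list-column.
#' @export
simulate_reference_database <- function(n_vs = 75, n_mcs = 68, separation = 1,
                                        seed = 1L, spec = NULL) {
  stopifnot(n_vs >= 5, n_mcs >= 5)
  if (is.null(spec)) spec <- cohort_spec(seed = seed)
  labels <- rep(c("VS", "MCS"), c(n_vs, n_mcs))
  recs <- lapply(seq_along(labels), function(i) {
    sp <- spec
    sp$seed <- (as.double(seed) * 131071 + i * 197) %% 2147483629
    if (labels[i] == "MCS") {
      sp$band_amplitudes["theta"] <- sp$band_amplitudes["theta"] + 2 * separation
      sp$band_amplitudes["alpha"] <- sp$band_amplitudes["alpha"] + 2 * separation
      sp$coupling_amplitude <- sp$coupling_amplitude + 3 * separation
    }
    simulate_resting(sp, i, "pre", "R-")
  })
  tibble::tibble(
    subject_id = sprintf("DB%03d", seq_along(labels)),
    label = labels, recording = recs
  )
}

#' Simulate smooth 3-D electric-field magnitude maps
#'
#' Produces per-subject non-negative field-magnitude volumes on a shared grid:
#' a smooth random background plus a designated ellipsoidal hotspot whose mean
#' magnitude exceeds the masking threshold and whose voxel values correlate
#' with a per-subject scalar outcome at `corr_strength`.
#'
#' @param n_subjects Number of subjects (>= 4 for correlation analyses).
#' @param grid_shape Integer length-3 vector, each >= 4.
#' @param hotspot_mean Mean field magnitude (V/m) inside the hotspot.
#' @param hotspot_radius Hotspot radius in voxels.
#' @param corr_strength Correlation (0-1) between hotspot voxels and outcome.
#' @param background_mean Background field magnitude (V/m).
#' @param seed Integer seed.
#' @return A list of class `field_map_set`: `maps` (list of 3-D arrays),
#'   `outcomes` (numeric), `hotspot` (logical array), `grid_shape`.
#' @export
simulate_field_maps <- function(n_subjects = 20, grid_shape = c(12, 12, 12),
                                hotspot_mean = 0.8, hotspot_radius = 3,
                                corr_strength = 0.7, background_mean = 0.2,
                                seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4))
  set.seed(as.integer(seed))
  ctr <- (grid_shape + 1) / 2
  ax <- lapply(1:3, function(d) seq_len(grid_shape[d]) - ctr[d])
  dist2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  hotspot <- dist2 <= hotspot_radius^2

  outcomes <- stats::rnorm(n_subjects)
  smooth3 <- function(a) {
    d <- dim(a); out <- array(0, d)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
      zs <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
      out <- out + a[xs, ys, zs]
    }
    out / 27
  }
  z_out <- as.numeric(scale(outcomes))
  maps <- lapply(seq_len(n_subjects), function(i) {
    bg <- array(stats::rnorm(prod(grid_shape), 0, 1), grid_shape)
    bg <- smooth3(bg)
    bg <- background_mean + 0.05 * bg / stats::sd(bg)
    hs_noise <- smooth3(array(stats::rnorm(prod(grid_shape)), grid_shape))
    hs_noise <- hs_noise / stats::sd(hs_noise)
    field <- bg
    field[hotspot] <- hotspot_mean +
      0.1 * (corr_strength * z_out[i] + sqrt(max(0, 1 - corr_strength^2)) * hs_noise[hotspot])
    pmax(field, 0)
  })
  structure(list(maps = maps, outcomes = outcomes, hotspot = hotspot,
                 grid_shape = grid_shape), class = "field_map_set")
}
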