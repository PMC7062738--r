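# epoch-set builder for fixtures constructed in code
make_epochs <- function(data, fs = 250, layout = NULL, labels = NULL,
                        time_ms = NULL) {
  d <- dim(data)
  if (is.null(layout)) layout <- make_layout(max(d[2], 3), "ring", "k-nearest", k = 2)
  ep <- structure(list(
    data = data, fs = fs, layout = layout,
    labels = labels %||% rep("rest", d[1]),
    rejected_channels = rep(FALSE, d[2]),
    rejected_epochs = rep(FALSE, d[1]),
    interpolated_channels = integer(), reference = "vertex",
    failed = FALSE
  ), class = "eeg_epochs")
  if (!is.null(time_ms)) ep$time_ms <- time_ms
  ep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a quiet cohort spec: no oscillations, no noise, no artifacts
silent_spec <- function(n_channels = 4, rest_duration = 5, ...) {
  cohort_spec(n_channels = n_channels, rest_duration = rest_duration,
              band_amplitudes = c(delta = 0, theta = 0, alpha = 0,
                                  beta = 0, gamma = 0),
              noise_sd = 0, sensor_noise_sd = 0, coupling_amplitude = 0,
              ...)
}

# band-limited unit-SD noise, used to build symbol-rich fixture signals
bl_noise <- function(n, fs = 250, band = c(4, 10)) {
  m <- stats::nextn(n)
  x <- stats::rnorm(m)
  f <- c(0, seq_len(floor(m / 2)), rev(seq_len(ceiling(m / 2) - 1))) * fs / m
  y <- Re(stats::fft(stats::fft(x) * (f >= band[1] & f <= band[2]),
                     inverse = TRUE)) / m
  y <- y[seq_len(n)]
  y / stats::sd(y)
}
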