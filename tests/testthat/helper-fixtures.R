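# Shared fixtures built in code.

# The worked five-boundary annotation used throughout the rhythm tests:
# two cycles, zones [0,0.5), [0.5,1.0), [1.0,1.75), [1.75,2.5).
ann5 <- function() cycle_annotation(c(0, 0.5, 1.0, 1.75, 2.5))

# Regular rhythm: M cycles of two zones of d seconds each.
regular_annotation <- function(M, d = 2) {
  cycle_annotation(seq(0, by = d, length.out = 2 * M + 1))
}

# Random valid annotation with positive, irregular zone durations.
random_annotation <- function(M = 5L) {
  cycle_annotation(c(0, cumsum(stats::runif(2 * M, 0.2, 3))))
}

# A deterministic cyclic recording on a regular rhythm: each cycle repeats
# the same waveform, an integer number of samples per cycle.
regular_recording <- function(M = 4L, d = 2, fs = 250, n_channels = 1L,
                              wave = function(t) sin(2 * pi * t)) {
  ann <- regular_annotation(M, d)
  L <- as.integer(2 * d * M * fs) + 1L
  t <- (0:(L - 1L)) / fs
  phase <- t %% (2 * d)
  x <- wave(phase)
  samples <- matrix(rep(x, n_channels), ncol = n_channels)
  list(rec = multichannel_recording(samples, fs), ann = ann)
}

sine_recording <- function(freq, fs = 250, seconds = 8, amplitude = 1) {
  t <- (0:(seconds * fs - 1)) / fs
  multichannel_recording(amplitude * sin(2 * pi * freq * t), fs)
}

# Peak amplitude over the middle half of a single-channel recording
# (discards filter edge transients).
mid_amplitude <- function(rec) {
  x <- rec$samples[, 1L]
  mid <- x[(length(x) %/% 4):(3 * length(x) %/% 4)]
  (max(mid) - min(mid)) / 2
}

mid_rms <- function(rec) {
  x <- rec$samples[, 1L]
  mid <- x[(length(x) %/% 4):(3 * length(x) %/% 4)]
  sqrt(mean(mid^2))
}

# Minimal moment_estimate wrapper for spectral tests.
fake_estimate <- function(values, dt = 1 / 250, kind = "mean", order = 1L,
                          zone = "zone1") {
  grid <- list(times = (seq_along(values) - 1L) * dt, zone = zone)
  cyclorhythm:::new_moment_estimate(kind, order, values, grid,
                                    channels = 1L, M = 1L)
}
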