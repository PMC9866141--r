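#' One-sided Fourier spectrum of a moment estimate
#'
#' Discrete Fourier transform of the estimate's values on its (uniform)
#' phase grid, reported as one-sided magnitudes on the Fourier-coefficient
#' scale `|X_j| / P`, DC first, ordered by increasing frequency. Energy is
#' accounted with one-sided weights (1 for DC and, for even `P`, the Nyquist
#' bin; 2 otherwise), so the total spectral energy equals the mean-square
#' energy of the grid signal (Parseval) to within numerical round-off, and
#' the per-bin cumulative energy fraction is nondecreasing to 1.
#'
#' @param est A `moment_estimate` on a uniform phase grid.
#' @return An object of class `spectrum_estimate`: list with `frequencies`
#'   (Hz), `magnitudes`, `energy` (per one-sided bin),
#'   `cumulative_energy_fraction` and the `source` descriptor.
#' @export
moment_spectrum <- function(est) {
  stopifnot(inherits(est, "moment_estimate"))
  v <- est$values
  P <- length(v)
  if (P < 2L) stop("spectrum requires at least 2 grid points", call. = FALSE)
  dt <- diff(est$phase)
  if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt)) {
    stop("phase grid is not uniform; resample the estimate first",
         call. = FALSE)
  }
  X <- stats::fft(v)
  nb <- P %/% 2L + 1L
  mags <- Mod(X[seq_len(nb)]) / P
  weights <- rep(2, nb)
  weights[1L] <- 1
  if (P %% 2L == 0L) weights[nb] <- 1
  energy <- weights * mags^2           # sums to mean(v^2)
  total <- sum(energy)
  cum <- if (total > 0) cumsum(energy) / total else rep(1, nb)
  fs_grid <- 1 / mean(dt)
  structure(
    list(frequencies = (seq_len(nb) - 1L) * fs_grid / P,
         magnitudes = mags, energy = energy,
         cumulative_energy_fraction = cum,
         source = list(kind = est$kind, order = est$order,
                       channels = est$channels, zone = est$zone)),
    class = "spectrum_estimate")
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf(
    "<spectrum_estimate> %d one-sided bins up to %.3g Hz (%s, order %d, %s)\n",
    length(x$magnitudes), max(x$frequencies), x$source$kind, x$source$order,
    x$source$zone))
  invisible(x)
}

#' Bessel-inequality feature reduction
#'
#' Retains the smallest prefix of low-frequency spectral coefficients whose
#' cumulative energy fraction reaches the threshold; by Bessel's inequality
#' the discarded tail carries at most `1 - threshold` of the estimate's
#' energy. The returned `K` is minimal (the `K - 1` prefix falls below the
#' threshold) and monotone nondecreasing in the threshold.
#'
#' @param spec A [moment_spectrum()] result.
#' @param threshold Required energy fraction in `(0, 1]` (default 0.95).
#' @return An object of class `feature_vector`: list with `K`,
#'   `coefficients` (the first `K` magnitudes), `energy_captured`,
#'   `threshold` and `source`.
#' @examples
#' est <- structure(list(kind = "mean", order = 1L, channels = 1L,
#'                       zone = "zone1", values = sin(2 * pi * (0:99) / 100),
#'                       phase = (0:99) / 100), class = "moment_estimate")
#' select_leading(moment_spectrum(est))
#' @export
select_leading <- function(spec, threshold = 0.95) {
  stopifnot(inherits(spec, "spectrum_estimate"))
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  cum <- spec$cumulative_energy_fraction
  if (length(cum) == 0L) stop("empty spectrum", call. = FALSE)
  # tolerance guards ties produced by floating-point prefix sums
  K <- which(cum >= threshold - 1e-9)[1L]
  if (is.na(K)) K <- length(cum)
  structure(
    list(K = K, coefficients = spec$magnitudes[seq_len(K)],
         energy_captured = cum[K], threshold = threshold,
         source = spec$source),
    class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf(
    "<feature_vector> K = %d leading coefficients, %.2f%% of energy (threshold %.0f%%)\n",
    x$K, 100 * x$energy_captured, 100 * x$threshold))
  invisible(x)
}

#' Write a feature vector as JSON
#'
#' @param fv A [select_leading()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(fv, path) {
  stopifnot(inherits(fv, "feature_vector"))
  jsonlite::write_json(
    list(K = fv$K, threshold = fv$threshold,
         coefficients = fv$coefficients,
         energy_captured = fv$energy_captured,
         source = fv$source),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Mean absolute distance between two same-kind estimates
#'
#' Sensitivity score between two estimates of the same characteristic (or
#' their spectra). Moment estimates are linearly interpolated onto a common
#' `L`-point normalized-phase grid (phase 0 at each estimate's first point,
#' 1 at its last) and the mean absolute difference is returned; spectra are
#' compared bin-by-bin on their first `L` bins. `L` defaults to the shorter
#' of the two inputs, which avoids extrapolation when activity and passivity
#' zones have different durations.
#'
#' @param a,b Two `moment_estimate`s of the same kind and order, or two
#'   `spectrum_estimate`s of same-kind sources.
#' @param L Comparison grid length (`>= 2`).
#' @return A non-negative scalar in the units of the inputs.
#' @examples
#' mean_absolute_distance_values(c(1, 2, 3), c(2, 2, 5)) # 1
#' @export
mean_absolute_distance <- function(a, b, L = NULL) {
  if (inherits(a, "spectrum_estimate") && inherits(b, "spectrum_estimate")) {
    if (a$source$kind != b$source$kind || a$source$order != b$source$order) {
      stop(sprintf("cannot compare %s(order %d) spectrum with %s(order %d)",
                   a$source$kind, a$source$order, b$source$kind,
                   b$source$order), call. = FALSE)
    }
    if (is.null(L)) L <- min(length(a$magnitudes), length(b$magnitudes))
    stopifnot(L >= 2L)
    return(mean(abs(a$magnitudes[seq_len(L)] - b$magnitudes[seq_len(L)])))
  }
  stopifnot(inherits(a, "moment_estimate"), inherits(b, "moment_estimate"))
  if (a$kind != b$kind || a$order != b$order) {
    stop(sprintf("cannot compare %s(order %d) with %s(order %d)",
                 a$kind, a$order, b$kind, b$order), call. = FALSE)
  }
  if (is.null(L)) L <- min(length(a$values), length(b$values))
  stopifnot(L >= 2L)
  mean_absolute_distance_values(
    resample_normalized(a$phase, a$values, L),
    resample_normalized(b$phase, b$values, L))
}

# Plain mean absolute difference of two equal-length numeric vectors.
#' @rdname mean_absolute_distance
#' @export
mean_absolute_distance_values <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1L)
  mean(abs(a - b))
}

resample_normalized <- function(t, v, L) {
  if (length(v) == L && L >= 2L) return(v)
  phase <- (t - t[1L]) / (t[length(t)] - t[1L])
  stats::approx(phase, v, xout = seq(0, 1, length.out = L))$y
}

#' Activity-versus-passivity sensitivity report
#'
#' For each channel and each characteristic, estimates the characteristic
#' separately on the passivity-zone and activity-zone phase grids, computes
#' their Fourier spectra, and scores the sensitivity of the characteristic
#' to the operator's mental-control action by the mean absolute distance
#' (MAD) between the two zone estimates -- once in the time (phase) domain
#' and once between the spectra. Rows are ordered from the 4th-order initial
#' moment down to the mathematical expectation, the ordering in which
#' higher-order characteristics show the strongest zone contrast.
#'
#' @param rec A [multichannel_recording()] (typically preprocessed).
#' @param rf A [rhythm_interpolant()].
#' @param ann The recording's [cycle_annotation()].
#' @param channels Channel indices to score (default: all).
#' @param characteristics Character vector naming the rows; any of
#'   `"initial4"`, `"central4"`, `"initial3"`, `"initial2"`, `"dispersion"`,
#'   `"mean"`.
#' @return An object of class `sensitivity_report`: list with matrices
#'   `time` and `spectral` (characteristics x channels, both blocks the same
#'   shape, all entries `>= 0`).
#' @export
sensitivity_report <- function(rec, rf, ann, channels = NULL,
                               characteristics = c("initial4", "central4",
                                                   "initial3", "initial2",
                                                   "dispersion", "mean")) {
  stopifnot(inherits(rec, "multichannel_recording"),
            inherits(rf, "rhythm_function"),
            inherits(ann, "cycle_annotation"))
  if (is.null(channels)) channels <- seq_len(ncol(rec$samples))
  characteristics <- match.arg(characteristics, several.ok = TRUE)
  g1 <- phase_grid(rec, ann, "zone1")
  g2 <- phase_grid(rec, ann, "zone2")
  one_estimate <- function(char, grid, ch) {
    switch(char,
      mean = estimate_mean(rec, rf, grid, ch),
      dispersion = estimate_dispersion(rec, rf, grid, ch),
      initial2 = estimate_initial_moment(rec, rf, grid, ch, 2L),
      initial3 = estimate_initial_moment(rec, rf, grid, ch, 3L),
      initial4 = estimate_initial_moment(rec, rf, grid, ch, 4L),
      central4 = estimate_central_moment(rec, rf, grid, ch, 4L))
  }
  tmat <- matrix(NA_real_, nrow = length(characteristics),
                 ncol = length(channels),
                 dimnames = list(characteristics, rec$labels[channels]))
  smat <- tmat
  for (ci in seq_along(channels)) {
    for (ri in seq_along(characteristics)) {
      e1 <- one_estimate(characteristics[ri], g1, channels[ci])
      e2 <- one_estimate(characteristics[ri], g2, channels[ci])
      tmat[ri, ci] <- mean_absolute_distance(e1, e2)
      smat[ri, ci] <- mean_absolute_distance(moment_spectrum(e1),
                                             moment_spectrum(e2))
    }
  }
  structure(list(time = tmat, spectral = smat, channels = channels),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, digits = 4, ...) {
  cat("<sensitivity_report> mean absolute distances, activity vs passivity\n")
  cat("\nTime domain:\n")
  print(round(x$time, digits))
  cat("\nSpectral domain:\n")
  print(round(x$spectral, digits))
  invisible(x)
}

#' Write a sensitivity report as CSV
#'
#' Layout mirrors the report: one row per characteristic, a block of
#' time-domain MAD columns followed by a block of spectral MAD columns.
#'
#' @param report A [sensitivity_report()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(report, path) {
  stopifnot(inherits(report, "sensitivity_report"))
  df <- data.frame(characteristic = rownames(report$time),
                   check.names = FALSE)
  for (nm in colnames(report$time)) df[[paste0("time_", nm)]] <- report$time[, nm]
  for (nm in colnames(report$spectral)) {
    df[[paste0("spectral_", nm)]] <- report$spectral[, nm]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
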