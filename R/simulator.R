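#' Simulation configuration
#'
#' Describes a synthetic vector of cyclic rhythmically connected random
#' processes: `n_channels` channels sharing one irregular rhythm, `n_cycles`
#' repeated trials, each cycle split into a passivity zone (zone 1) and an
#' activity zone (zone 2). Zone durations are drawn independently and
#' uniformly from `zone_durations[k] * [1 - jitter, 1 + jitter]`. Within
#' zone `k` of any cycle, channel `i` is
#' `x = mu[i,k](phi) + s[i,k](phi) * eps + shared_sd * eps0`, where `phi` is
#' the normalized position in the zone, `eps` is unit-variance noise of the
#' chosen family with optional AR(1) dependence (coefficient `rho`) across
#' cycles at fixed phase, and `eps0` is a Gaussian component shared by all
#' channels. Noise at distinct phases within a cycle is independent, which
#' keeps the analytic ground truth exact.
#'
#' @param n_channels Number of channels `N` (default 3, one per electrode).
#' @param n_cycles Number of cycles `M` (default 50, one series of trials).
#' @param fs Sampling rate in Hz (default 250).
#' @param zone_durations Nominal durations `c(d1, d2)` of the passivity and
#'   activity zones in seconds (default 2 s each).
#' @param jitter Zone-duration jitter fraction in `[0, 1)` (default 0.1,
#'   a realistic trial-to-trial variability for voice-paced trials).
#' @param mean_profiles Per-zone mean profiles: a list of two elements
#'   (zone 1, zone 2), each a single number (constant, microvolts), a
#'   [mean_profile()], or a function of normalized phase; recycled across
#'   channels, or a list of `n_channels` such pairs for per-channel control.
#'   Default: a 5 uV one-period sinusoid in the passivity zone and a 10 uV
#'   two-period sinusoid in the activity zone.
#' @param sd_profiles Per-zone noise standard deviations, same recycling
#'   rules (numbers or functions of phase). Default `c(2, 3)` uV.
#' @param noise Noise family: `"gaussian"` or `"exponential"` (centred
#'   exponential, skewness 2 at unit sd).
#' @param rho AR(1) coefficient of inter-cycle dependence at fixed phase,
#'   `|rho| < 1` (default 0.2; gaussian family only).
#' @param shared_sd Standard deviation of the Gaussian noise component
#'   shared across channels (default 0).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 3L, n_cycles = 50L, fs = 250,
                       zone_durations = c(2, 2), jitter = 0.1,
                       mean_profiles = NULL, sd_profiles = NULL,
                       noise = c("gaussian", "exponential"),
                       rho = 0.2, shared_sd = 0) {
  noise <- match.arg(noise)
  stopifnot(n_channels >= 1L, n_cycles >= 2L, fs > 0,
            length(zone_durations) == 2L, all(zone_durations > 0),
            jitter >= 0, jitter < 1, abs(rho) < 1, shared_sd >= 0)
  if (noise == "exponential" && rho != 0) {
    stop(paste("AR(1) inter-cycle dependence is only supported for the",
               "gaussian family (an AR recursion does not preserve an",
               "exponential marginal); set rho = 0"), call. = FALSE)
  }
  if (is.null(mean_profiles)) {
    mean_profiles <- list(
      mean_profile(offset = 0, amplitude = 5, periods = 1),
      mean_profile(offset = 0, amplitude = 10, periods = 2))
  }
  if (is.null(sd_profiles)) sd_profiles <- list(2, 3)
  structure(
    list(n_channels = as.integer(n_channels), n_cycles = as.integer(n_cycles),
         fs = fs, zone_durations = zone_durations, jitter = jitter,
         mean_profiles = normalize_profiles(mean_profiles, n_channels, "mean"),
         sd_profiles = normalize_profiles(sd_profiles, n_channels, "sd"),
         noise = noise, rho = rho, shared_sd = shared_sd),
    class = "sim_config")
}

#' Sinusoidal mean profile on normalized zone phase
#'
#' `mu(phi) = offset + sum_h amplitude[h] * sin(2*pi*periods[h]*phi +
#' phase[h])`, `phi` in `[0, 1)`.
#'
#' @param offset Constant offset, microvolts.
#' @param amplitude,periods,phase Parallel vectors describing the harmonics
#'   (amplitudes in microvolts, `periods` full oscillations per zone,
#'   phases in radians).
#' @return A function of normalized phase, tagged class `mean_profile`.
#' @export
mean_profile <- function(offset = 0, amplitude = numeric(0),
                         periods = numeric(0), phase = 0) {
  stopifnot(length(amplitude) == length(periods))
  phase <- rep_len(phase, length(amplitude))
  f <- function(phi) {
    out <- rep(offset, length(phi))
    for (h in seq_along(amplitude)) {
      out <- out + amplitude[h] * sin(2 * pi * periods[h] * phi + phase[h])
    }
    out
  }
  class(f) <- c("mean_profile", "function")
  f
}

# Coerce user-supplied profiles to an n_channels x 2 list of functions.
normalize_profiles <- function(profiles, n_channels, what) {
  as_fun <- function(p) {
    if (is.function(p)) return(p)
    if (is.numeric(p) && length(p) == 1L) {
      return(local({v <- p; function(phi) rep(v, length(phi))}))
    }
    stop(sprintf("%s profile must be a number or a function of phase", what),
         call. = FALSE)
  }
  is_pair <- function(p) is.list(p) && length(p) == 2L &&
    !is.function(p)
  if (is_pair(profiles)) profiles <- rep(list(profiles), n_channels)
  if (length(profiles) != n_channels) {
    stop(sprintf(
      "%s_profiles must be a list(zone1, zone2) or one such pair per channel",
      what), call. = FALSE)
  }
  lapply(profiles, function(pair) {
    if (!is_pair(pair)) stop(sprintf(
      "each per-channel %s profile must be a list(zone1, zone2)", what),
      call. = FALSE)
    lapply(pair, as_fun)
  })
}

# Deterministic sub-seed derivation so that adding channels does not
# reshuffle the draws of existing ones.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 16807) %% 2147483647
}

#' Sample a cycle/zone annotation from a simulation configuration
#'
#' Zone durations are independent uniform draws from
#' `zone_durations[k] * [1 - jitter, 1 + jitter]`; boundaries are their
#' cumulative sums starting at 0. All channels share these boundaries
#' (rhythmic connection). With `jitter = 0` the rhythm is regular.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the same annotation.
#' @return A [cycle_annotation()].
#' @export
sample_annotation <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(seed, 0L))
  d <- matrix(0, nrow = cfg$n_cycles, ncol = 2L)
  for (k in 1:2) {
    dk <- cfg$zone_durations[k]
    d[, k] <- stats::runif(cfg$n_cycles, dk * (1 - cfg$jitter),
                           dk * (1 + cfg$jitter))
  }
  cycle_annotation(c(0, cumsum(as.numeric(t(d)))))
}

# Unit-variance innovations of the configured family.
draw_innovations <- function(n, family) {
  if (family == "gaussian") stats::rnorm(n) else stats::rexp(n) - 1
}

#' Simulate a vector of cyclic rhythmically connected random processes
#'
#' Generates a multichannel recording with the configured cyclic structure:
#' the single-cycle law (zone mean and noise profiles on normalized phase)
#' repeats in every cycle under the sampled irregular rhythm, which makes
#' the joint distributions invariant under the rhythm shift by
#' construction. Noise is realized on a per-zone canonical phase lattice of
#' `round(d_k * fs)` points (so that, for a regular rhythm with an integer
#' number of samples per zone, every sample has its own independent draw)
#' with AR(1) recursion across the cycle index at each lattice point;
#' samples of jittered cycles read the lattice point nearest below their
#' phase, preserving the marginal law exactly.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `cyclic_simulation`: list with `recording`
#'   (a [multichannel_recording()]), `annotation` (a [cycle_annotation()])
#'   and `truth` (a `ground_truth` for [true_moment()]).
#' @examples
#' sim <- simulate_recording(sim_config(n_channels = 1, n_cycles = 10), seed = 7)
#' sim$recording
#' @export
simulate_recording <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  ann <- sample_annotation(cfg, seed)
  b <- ann$boundaries
  M <- cfg$n_cycles
  fs <- cfg$fs
  n_lattice <- pmax(1L, as.integer(round(cfg$zone_durations * fs)))
  n_tot <- sum(n_lattice)

  L <- floor(b[length(b)] * fs + 1e-9) + 1L
  t_s <- (0:(L - 1L)) / fs
  # the 1e-9 s guard keeps boundary samples in their own zone despite
  # floating-point drift in the cumulated boundary times
  idx <- findInterval(t_s + 1e-9, b, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), 2L * M)
  m_of <- (idx + 1L) %/% 2L
  k_of <- 2L - idx %% 2L
  phi <- pmin(pmax((t_s - b[idx]) / (b[idx + 1L] - b[idx]), 0), 1)
  lat <- ifelse(k_of == 1L, 0L, n_lattice[1L]) +
    pmin(floor(phi * n_lattice[k_of] + 1e-6) + 1L, n_lattice[k_of])

  ar_field <- function(seed_stream, family) {
    set.seed(seed_stream)
    eta <- matrix(draw_innovations(M * n_tot, family), nrow = M)
    if (cfg$rho == 0) return(eta)
    z <- rbind(eta[1L, , drop = FALSE],
               sqrt(1 - cfg$rho^2) * eta[-1L, , drop = FALSE])
    matrix(stats::filter(z, cfg$rho, method = "recursive"), nrow = M)
  }

  eps0 <- if (cfg$shared_sd > 0) ar_field(derive_seed(seed, 1L), "gaussian")
  samples <- matrix(0, nrow = L, ncol = cfg$n_channels)
  flat <- cbind(m_of, lat)
  for (i in seq_len(cfg$n_channels)) {
    eps <- ar_field(derive_seed(seed, 1L + i), cfg$noise)
    mu <- numeric(L)
    s <- numeric(L)
    for (k in 1:2) {
      sel <- k_of == k
      mu[sel] <- cfg$mean_profiles[[i]][[k]](phi[sel])
      s[sel] <- cfg$sd_profiles[[i]][[k]](phi[sel])
    }
    x <- mu + s * eps[flat]
    if (cfg$shared_sd > 0) x <- x + cfg$shared_sd * eps0[flat]
    samples[, i] <- x
  }
  truth <- structure(list(config = cfg, annotation = ann), class = "ground_truth")
  structure(
    list(recording = multichannel_recording(samples, fs = fs),
         annotation = ann, truth = truth),
    class = "cyclic_simulation")
}

#' @export
print.cyclic_simulation <- function(x, ...) {
  cat(sprintf("<cyclic_simulation> %d channels, %d cycles, %s noise\n",
              x$truth$config$n_channels, x$truth$config$n_cycles,
              x$truth$config$noise))
  invisible(x)
}

#' Analytic moment profile implied by a simulation configuration
#'
#' Closed-form value of a probabilistic characteristic of one simulated
#' channel in one zone, as a function of normalized phase. With
#' `v(phi) = s^2(phi) + shared_sd^2` the total noise variance, the central
#' moments follow from the cumulants of the configured family (gaussian:
#' skewness 0, excess kurtosis 0; centred exponential at unit sd: 3rd
#' cumulant `2 s^3`, 4th cumulant `6 s^4`), and initial moments from the
#' central ones plus the mean profile. The lag-one inter-cycle covariance at
#' fixed phase is `rho * v(phi)`.
#'
#' @param gt The `truth` element of a [simulate_recording()] result.
#' @param kind One of `"mean"`, `"dispersion"`, `"initial"`, `"central"`,
#'   `"lag1_cov"`.
#' @param order Moment order (ignored for `"mean"`, `"dispersion"`,
#'   `"lag1_cov"`).
#' @param channel,zone Channel and zone index.
#' @param phi Normalized phases in `[0, 1)` at which to evaluate.
#' @return Numeric vector of the same length as `phi`.
#' @export
true_moment <- function(gt, kind = c("mean", "dispersion", "initial",
                                     "central", "lag1_cov"),
                        order = 2L, channel = 1L, zone = 1L,
                        phi = seq(0, 1, length.out = 101L)) {
  stopifnot(inherits(gt, "ground_truth"))
  kind <- match.arg(kind)
  cfg <- gt$config
  mu <- cfg$mean_profiles[[channel]][[zone]](phi)
  s <- cfg$sd_profiles[[channel]][[zone]](phi)
  v <- s^2 + cfg$shared_sd^2
  k3 <- if (cfg$noise == "gaussian") rep(0, length(phi)) else 2 * s^3
  k4 <- if (cfg$noise == "gaussian") rep(0, length(phi)) else 6 * s^4
  central <- function(ord) {
    switch(as.character(ord),
      "1" = rep(0, length(phi)),
      "2" = v,
      "3" = k3,
      "4" = k4 + 3 * v^2,
      stop("closed forms available up to order 4", call. = FALSE))
  }
  switch(kind,
    mean = mu,
    dispersion = v,
    lag1_cov = cfg$rho * v,
    central = central(order),
    initial = switch(as.character(order),
      "1" = mu,
      "2" = v + mu^2,
      "3" = k3 + 3 * mu * v + mu^3,
      "4" = central(4) + 4 * mu * k3 + 6 * mu^2 * v + mu^4,
      stop("closed forms available up to order 4", call. = FALSE)))
}
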