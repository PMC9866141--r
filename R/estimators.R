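#' Zone indicator and zone components of a recording
#'
#' Each cycle of the recording splits into a passivity zone (zone 1) and an
#' activity zone (zone 2). `zone_indicator()` evaluates the indicator
#' function of zone `(m, k)` at arbitrary times; `zone_component()` masks
#' one channel with it, returning the signal on `W[m,k]` and zero elsewhere.
#' Summing the components over all cycles and zones reconstructs the
#' recording exactly on the annotated support.
#'
#' Intervals are half-open `[start, end)`; the final boundary closes the
#' last cycle so that its end sample belongs to zone `(M, 2)`.
#'
#' @param ann A [cycle_annotation()].
#' @param cycle,zone Cycle index `m` and zone index `k` (1 or 2).
#' @param times Numeric vector of times in seconds.
#' @return `zone_indicator()`: 0/1 vector. `zone_component()`: numeric
#'   vector of length `nrow(rec$samples)`.
#' @export
zone_indicator <- function(ann, cycle, zone, times) {
  w <- zone_window(ann, cycle, zone)
  b_end <- ann$boundaries[length(ann$boundaries)]
  inside <- times >= w[1L] & times < w[2L]
  if (cycle == ann$n_cycles && zone == 2L) {
    inside <- inside | times == b_end
  }
  as.numeric(inside)
}

#' @param rec A [multichannel_recording()].
#' @param channel Channel index or label.
#' @rdname zone_indicator
#' @export
zone_component <- function(rec, ann, channel = 1L, cycle = 1L, zone = 1L) {
  stopifnot(inherits(rec, "multichannel_recording"),
            inherits(ann, "cycle_annotation"))
  if (is.character(channel)) channel <- match(channel, rec$labels)
  rec$samples[, channel] * zone_indicator(ann, cycle, zone, sample_times(rec))
}

new_moment_estimate <- function(kind, order, values, grid, channels,
                                exponents = NULL, lag_cycles = NULL,
                                M, M1 = NA_integer_) {
  structure(
    list(kind = kind, order = as.integer(order), values = as.numeric(values),
         phase = grid$times, zone = grid$zone, channels = as.integer(channels),
         exponents = exponents, lag_cycles = lag_cycles,
         M = as.integer(M), M1 = as.integer(M1),
         units = sprintf("uV^%d", as.integer(order))),
    class = "moment_estimate")
}

#' @export
print.moment_estimate <- function(x, ...) {
  cat(sprintf(
    "<moment_estimate> %s (order %d), channel(s) %s, %s zone grid, %d phases, M=%d%s\n",
    x$kind, x$order, toString(x$channels), x$zone, length(x$values), x$M,
    if (!is.na(x$M1)) sprintf(", M1=%d", x$M1) else ""))
  invisible(x)
}

#' Cycle-aligned moment-function estimators
#'
#' Cycle-aligned statistical estimates of the probabilistic characteristics
#' of one channel of a rhythmically connected multichannel recording, as
#' functions of phase `t` within the first cycle. With `x(n, t)` the aligned
#' value of the channel at `t + That(t, n)` and `M` cycles:
#'
#' * mean: `mhat(t) = (1/M) * sum_n x(n, t)`
#' * dispersion: `dhat(t) = (1/M) * sum_n (x(n, t) - mhat(t))^2`
#' * initial moment of order `k`: `(1/M) * sum_n x(n, t)^k`
#' * central moment of order `k`: `(1/(M-1)) * sum_n (x(n, t) - mhat(t))^k`
#'
#' The mean estimate at a shifted argument is taken as its cyclic extension,
#' `mhat(t + That(t, n)) := mhat(t)`: the estimate's own invariance under the
#' fitted rhythm. The printed `1/M` versus `1/(M-1)` normalizations are kept
#' as stated, so `dhat = ((M-1)/M) * dhat2` where `dhat2` is the 2nd central
#' moment -- an identity that holds to machine precision on any input.
#'
#' @param rec A [multichannel_recording()].
#' @param rf A [rhythm_interpolant()] for the recording's annotation.
#' @param grid A [phase_grid()].
#' @param channel Channel index or label.
#' @param order Moment order `k >= 1`.
#' @return A `moment_estimate` (values in microvolts^order on the grid).
#' @examples
#' sim <- simulate_recording(sim_config(n_channels = 1, n_cycles = 20), seed = 1)
#' rf <- rhythm_interpolant(sim$annotation)
#' g <- phase_grid(sim$recording, sim$annotation, "zone1")
#' estimate_mean(sim$recording, rf, g, 1)
#' @name estimators
NULL

#' @rdname estimators
#' @export
estimate_mean <- function(rec, rf, grid, channel = 1L) {
  X <- align_cycles(rec, rf, grid, channel)
  new_moment_estimate("mean", 1L, colMeans(X), grid, attr(X, "channel"),
                      M = nrow(X))
}

#' @rdname estimators
#' @export
estimate_dispersion <- function(rec, rf, grid, channel = 1L) {
  X <- align_cycles(rec, rf, grid, channel)
  m <- colMeans(X)
  vals <- colMeans(sweep(X, 2L, m)^2)
  new_moment_estimate("dispersion", 2L, vals, grid, attr(X, "channel"),
                      M = nrow(X))
}

#' @rdname estimators
#' @export
estimate_initial_moment <- function(rec, rf, grid, channel = 1L, order = 2L) {
  stopifnot(order >= 1L)
  X <- align_cycles(rec, rf, grid, channel)
  new_moment_estimate("initial", order, colMeans(X^order), grid,
                      attr(X, "channel"), M = nrow(X))
}

#' @rdname estimators
#' @export
estimate_central_moment <- function(rec, rf, grid, channel = 1L, order = 2L) {
  stopifnot(order >= 1L)
  X <- align_cycles(rec, rf, grid, channel)
  M <- nrow(X)
  if (M < 2L) stop("central moments require at least 2 cycles", call. = FALSE)
  m <- colMeans(X)
  vals <- colSums(sweep(X, 2L, m)^order) / (M - 1)
  new_moment_estimate("central", order, vals, grid, attr(X, "channel"), M = M)
}

#' Mixed moment-function estimators across channels and cycles
#'
#' Joint (compatible) moment estimates of several channels at several
#' phase-linked times. The `j`-th factor is channel `channels[j]` evaluated
#' at `t + That(t, n + lag_cycles[j])` and raised to `exponents[j]`; the lag
#' times are parameterized as phase-preserving cycle shifts (`lag_cycles[1]`
#' must be 0, the reference), which keeps the configuration independent of
#' the particular irregular rhythm. `M1 = max(lag_cycles) + 1` is the number
#' of leading cycles over which the lagged arguments range, and the sums run
#' over `n = 0..M-M1` with the printed normalizations `1/(M-M1+1)` (initial)
#' and `1/(M-M1)` (central). With a single factor and `M1 = 1` the mixed
#' initial moment reduces exactly to the plain initial moment.
#'
#' @inheritParams estimators
#' @param channels Integer vector of channel indices, one per factor.
#' @param exponents Positive integer exponents `r_j`; the estimate's order is
#'   their sum.
#' @param lag_cycles Non-negative integer cycle shifts, one per factor;
#'   first entry 0. E.g. `c(0, 1)` pairs each phase with the same phase one
#'   cycle later.
#' @param M1 Number of leading cycles spanned by the lagged arguments;
#'   defaults to `max(lag_cycles) + 1`. Must be smaller than `M`.
#' @return A `moment_estimate` on the grid.
#' @export
estimate_mixed_initial <- function(rec, rf, grid, channels, exponents,
                                   lag_cycles = NULL, M1 = NULL) {
  mixed_moment(rec, rf, grid, channels, exponents, lag_cycles, M1,
               central = FALSE)
}

#' @rdname estimate_mixed_initial
#' @export
estimate_mixed_central <- function(rec, rf, grid, channels, exponents,
                                   lag_cycles = NULL, M1 = NULL) {
  mixed_moment(rec, rf, grid, channels, exponents, lag_cycles, M1,
               central = TRUE)
}

mixed_moment <- function(rec, rf, grid, channels, exponents, lag_cycles,
                         M1, central) {
  stopifnot(length(channels) == length(exponents))
  k <- length(channels)
  if (is.null(lag_cycles)) lag_cycles <- rep(0L, k)
  lag_cycles <- as.integer(lag_cycles)
  stopifnot(length(lag_cycles) == k)
  if (lag_cycles[1L] != 0L) {
    stop("the first factor is the reference: lag_cycles[1] must be 0",
         call. = FALSE)
  }
  if (any(lag_cycles < 0L)) stop("lag_cycles must be >= 0", call. = FALSE)
  M <- rf$annotation$n_cycles
  if (is.null(M1)) M1 <- max(lag_cycles) + 1L
  M1 <- as.integer(M1)
  if (M1 >= M) {
    stop(sprintf("M1 (%d) must be smaller than the number of cycles M (%d)",
                 M1, M), call. = FALSE)
  }
  if (max(lag_cycles) > M1 - 1L) {
    stop(sprintf(
      "lagged arguments reach cycle %d but M1 = %d allows only cycles 1..%d",
      max(lag_cycles) + 1L, M1, M1), call. = FALSE)
  }
  rows <- 0:(M - M1)             # summation index n
  P <- length(grid$times)
  # full aligned matrices once per distinct channel
  aligned <- lapply(unique(channels), function(ch)
    align_cycles(rec, rf, grid, ch))
  names(aligned) <- as.character(unique(channels))
  means <- if (central) {
    lapply(aligned, colMeans)
  }
  prod_mat <- matrix(1, nrow = length(rows), ncol = P)
  for (j in seq_len(k)) {
    Xj <- aligned[[as.character(channels[j])]]
    block <- Xj[rows + lag_cycles[j] + 1L, , drop = FALSE]
    if (central) {
      # cyclic extension: mhat at a phase-preserving shift is mhat at the
      # reference phase
      block <- sweep(block, 2L, means[[as.character(channels[j])]])
    }
    prod_mat <- prod_mat * block^exponents[j]
  }
  denom <- if (central) M - M1 else M - M1 + 1L
  vals <- colSums(prod_mat) / denom
  new_moment_estimate(
    kind = if (central) "mixed_central" else "mixed_initial",
    order = sum(exponents), values = vals, grid = grid,
    channels = channels, exponents = as.integer(exponents),
    lag_cycles = lag_cycles, M = M, M1 = M1)
}

#' Write a moment estimate as annotated CSV
#'
#' Metadata (kind, order, channels, zone, `M`, `M1`) is written as
#' `#`-prefixed header lines followed by `phase_s,value` rows at full
#' precision.
#'
#' @param est A `moment_estimate`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_estimate <- function(est, path) {
  stopifnot(inherits(est, "moment_estimate"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# kind: %s", est$kind),
    sprintf("# order: %d", est$order),
    sprintf("# channels: %s", paste(est$channels, collapse = " ")),
    sprintf("# zone: %s", est$zone),
    sprintf("# M: %d", est$M),
    sprintf("# M1: %s", ifelse(is.na(est$M1), "NA", est$M1)),
    "phase_s,value"
  ), con)
  writeLines(sprintf("%.17g,%.17g", est$phase, est$values), con)
  invisible(path)
}

#' Read a moment estimate written by [write_estimate()]
#'
#' @param path Path to an annotated estimate CSV.
#' @return A `moment_estimate` (without an attached annotation).
#' @export
read_estimate_csv <- function(path) {
  if (!file.exists(path)) {
    stop("estimate file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  meta <- list()
  for (ln in grep("^#", lines, value = TRUE)) {
    kv <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(kv) == 3L) meta[[kv[2L]]] <- kv[3L]
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  grid <- list(times = df$phase_s, zone = meta$zone %||% "full")
  est <- new_moment_estimate(
    kind = meta$kind %||% "mean",
    order = as.integer(meta$order %||% 1L),
    values = df$value, grid = grid,
    channels = as.integer(strsplit(meta$channels %||% "1", " ")[[1L]]),
    M = as.integer(meta$M %||% NA_integer_),
    M1 = suppressWarnings(as.integer(meta$M1 %||% NA_integer_)))
  est
}

`%||%` <- function(a, b) if (is.null(a)) b else a
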