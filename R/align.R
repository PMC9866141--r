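#' Phase grid within the first cycle
#'
#' Cycle-aligned estimates are evaluated on a grid of time points inside the
#' first cycle (the reference cycle). The default grid is the recording's own
#' sample times falling inside the chosen zone, so for a 2 s zone sampled at
#' 250 Hz the estimate has 500 values.
#'
#' @param rec A [multichannel_recording()].
#' @param ann A [cycle_annotation()].
#' @param zone `"full"` for the whole first cycle, `"zone1"`/`"passivity"`
#'   for zone 1, `"zone2"`/`"activity"` for zone 2.
#' @return An object of class `phase_grid`: list with `times` (seconds,
#'   strictly increasing, inside the stated window), `zone` and the source
#'   `annotation`.
#' @export
phase_grid <- function(rec, ann, zone = c("full", "zone1", "zone2",
                                          "passivity", "activity")) {
  stopifnot(inherits(rec, "multichannel_recording"),
            inherits(ann, "cycle_annotation"))
  zone <- match.arg(zone)
  zone <- switch(zone, passivity = "zone1", activity = "zone2", zone)
  w <- switch(zone,
    full = zone_window(ann, 1L),
    zone1 = zone_window(ann, 1L, 1L),
    zone2 = zone_window(ann, 1L, 2L))
  t <- sample_times(rec)
  t <- t[t >= w[1L] & t < w[2L]]
  if (length(t) == 0L) {
    stop("no sample times fall inside the requested zone of cycle 1",
         call. = FALSE)
  }
  structure(list(times = t, zone = zone, annotation = ann),
            class = "phase_grid")
}

#' @export
print.phase_grid <- function(x, ...) {
  cat(sprintf("<phase_grid> %d points in %s of cycle 1, [%g, %g] s\n",
              length(x$times), x$zone, min(x$times), max(x$times)))
  invisible(x)
}

# Linear interpolation of one channel at arbitrary times, with snapping to
# exact samples (tolerance 1e-6 of a sample period, so integer-sample
# alignments stay exact) and the last-cycle overflow rule: an overrun of
# less than one sample period reuses the final sample; larger overruns stop.
interp_channel <- function(rec, channel, times, context = "interpolation") {
  x <- rec$samples[, channel]
  L <- length(x)
  u <- (times - rec$t0) * rec$fs
  if (any(u < -1e-6)) {
    stop(sprintf("%s: time %g s precedes the recording start", context,
                 times[which(u < -1e-6)[1L]]), call. = FALSE)
  }
  over <- u > (L - 1L) + 1 + 1e-6
  if (any(over)) {
    stop(sprintf(
      "%s: time %.6f s overruns the recording end (%.6f s) by more than one sample",
      context, times[which(over)[1L]], rec$t0 + (L - 1L) / rec$fs),
      call. = FALSE)
  }
  i0 <- floor(u)
  frac <- u - i0
  snap_lo <- frac < 1e-6
  snap_hi <- frac > 1 - 1e-6
  i0[snap_hi] <- i0[snap_hi] + 1
  frac[snap_lo | snap_hi] <- 0
  i0 <- pmax(0, pmin(i0, L - 1L))
  i1 <- pmin(i0 + 1L, L - 1L)
  x[i0 + 1L] * (1 - frac) + x[i1 + 1L] * frac
}

#' Cycle-aligned sample matrix
#'
#' Aligns one channel across all cycles: entry `(n + 1, j)` is the signal at
#' `t[j] + That(t[j], n)`, `n = 0..M-1`, the single-phase image of grid point
#' `t[j]` in cycle `n + 1`. Because the piecewise-linear interpolant maps
#' each zone affinely onto the same zone of a later cycle, the aligned time
#' is computed exactly as the equal-normalized-phase point of the target
#' zone; alignment is therefore zone-preserving by construction. Values at
#' fractional sample times are linearly interpolated between adjacent
#' samples.
#'
#' @param rec A [multichannel_recording()].
#' @param rf A [rhythm_interpolant()] fitted to the recording's annotation.
#' @param grid A [phase_grid()] inside cycle 1.
#' @param channel Channel index (or label).
#' @return A numeric `M x P` matrix of class `aligned_matrix` with
#'   attributes `channel`, `grid` and `aligned_times` (`M x P`).
#' @export
align_cycles <- function(rec, rf, grid, channel = 1L) {
  stopifnot(inherits(rec, "multichannel_recording"),
            inherits(rf, "rhythm_function"),
            inherits(grid, "phase_grid"))
  if (is.character(channel)) channel <- match(channel, rec$labels)
  ann <- rf$annotation
  b <- ann$boundaries
  M <- ann$n_cycles
  t <- grid$times
  z <- findInterval(t + 1e-9, b)
  if (any(z < 1L | z > 2L)) {
    stop("phase grid must lie inside cycle 1 of the rhythm annotation",
         call. = FALSE)
  }
  phi <- pmin(pmax((t - b[z]) / (b[z + 1L] - b[z]), 0), 1)
  P <- length(t)
  out <- matrix(NA_real_, nrow = M, ncol = P)
  times <- matrix(NA_real_, nrow = M, ncol = P)
  for (n in 0:(M - 1L)) {
    jz <- z + 2L * n
    aligned <- b[jz] + phi * (b[jz + 1L] - b[jz])
    times[n + 1L, ] <- aligned
    out[n + 1L, ] <- interp_channel(
      rec, channel, aligned,
      context = sprintf("alignment row n=%d", n))
  }
  structure(out, class = c("aligned_matrix", "matrix"),
            channel = channel, grid = grid, aligned_times = times)
}
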