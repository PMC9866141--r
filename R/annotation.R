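#' Cycle/zone boundary annotation
#'
#' A `cycle_annotation` stores the ordered boundary times delimiting `M`
#' experiment cycles, each split into two zones: zone 1 (operator passivity)
#' and zone 2 (operator activity, the mental-control action). With two zones
#' per cycle there are `2 * M + 1` boundaries; the last boundary closes the
#' final cycle. Zone `(m, k)` spans the half-open interval
#' `[boundaries[2 * (m - 1) + k], boundaries[2 * (m - 1) + k + 1])`, so the
#' end of zone 2 of cycle `m` is the start of cycle `m + 1`.
#'
#' @param boundaries Numeric vector of strictly increasing boundary times in
#'   seconds, of odd length `2 * M + 1` with `M >= 1`.
#'
#' @return An object of class `cycle_annotation` with elements `boundaries`,
#'   `n_cycles` (`M`) and `zones_per_cycle` (always 2).
#' @examples
#' ann <- cycle_annotation(c(0, 0.5, 1.0, 1.75, 2.5))
#' ann$n_cycles
#' zone_window(ann, cycle = 2, zone = 1)
#' @export
cycle_annotation <- function(boundaries) {
  boundaries <- as.numeric(boundaries)
  problems <- check_boundaries(boundaries)
  if (length(problems) > 0L) {
    stop("invalid cycle annotation: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  structure(
    list(
      boundaries = boundaries,
      n_cycles = (length(boundaries) - 1L) %/% 2L,
      zones_per_cycle = 2L
    ),
    class = "cycle_annotation"
  )
}

# Returns a character vector of violations (empty when valid).
check_boundaries <- function(boundaries) {
  problems <- character(0)
  if (length(boundaries) < 3L) {
    problems <- c(problems, "need at least 3 boundaries (one full cycle)")
  }
  if (length(boundaries) %% 2L != 1L) {
    problems <- c(problems, sprintf(
      "number of boundaries must be odd (2*M + 1), got %d", length(boundaries)))
  }
  if (anyNA(boundaries) || any(!is.finite(boundaries))) {
    problems <- c(problems, "boundaries must be finite numbers")
    return(problems)
  }
  bad <- which(diff(boundaries) <= 0)
  if (length(bad) > 0L) {
    problems <- c(problems, sprintf(
      "boundaries must be strictly increasing (violated at index %d: %g >= %g)",
      bad[1L], boundaries[bad[1L]], boundaries[bad[1L] + 1L]))
  }
  problems
}

#' @export
print.cycle_annotation <- function(x, ...) {
  cat(sprintf(
    "<cycle_annotation> %d cycles x 2 zones on [%g, %g] s\n",
    x$n_cycles, x$boundaries[1L], x$boundaries[length(x$boundaries)]))
  invisible(x)
}

#' Support window of one zone
#'
#' @param ann A [cycle_annotation()].
#' @param cycle Cycle index `m` in `1..M`.
#' @param zone Zone index `k` (1 = passivity, 2 = activity), or `NULL` for
#'   the full cycle window.
#' @return Numeric `c(start, end)` in seconds; the interval is half-open
#'   `[start, end)` except that the final boundary closes the last cycle.
#' @export
zone_window <- function(ann, cycle, zone = NULL) {
  stopifnot(inherits(ann, "cycle_annotation"))
  if (cycle < 1L || cycle > ann$n_cycles) {
    stop(sprintf("cycle %d outside 1..%d", cycle, ann$n_cycles), call. = FALSE)
  }
  if (is.null(zone)) {
    j <- 2L * (cycle - 1L) + 1L
    return(c(ann$boundaries[j], ann$boundaries[j + 2L]))
  }
  if (!zone %in% c(1L, 2L)) {
    stop("zone must be 1 or 2", call. = FALSE)
  }
  j <- 2L * (cycle - 1L) + zone
  c(ann$boundaries[j], ann$boundaries[j + 1L])
}

#' Read / write a cycle annotation as JSON
#'
#' The on-disk form is a JSON object
#' `{"boundaries": [...], "zones_per_cycle": 2, "units": "s"}`.
#'
#' @param path Path to a JSON annotation file.
#' @return [read_annotation()] returns a [cycle_annotation()];
#'   [write_annotation()] returns `path` invisibly.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$boundaries)) {
    stop(sprintf("%s: missing 'boundaries' field", path), call. = FALSE)
  }
  if (!is.null(obj$zones_per_cycle) && obj$zones_per_cycle != 2) {
    stop(sprintf("%s: zones_per_cycle must be 2, got %s",
                 path, obj$zones_per_cycle), call. = FALSE)
  }
  problems <- check_boundaries(as.numeric(obj$boundaries))
  if (length(problems) > 0L) {
    stop(sprintf("%s: %s", path, paste(problems, collapse = "; ")),
         call. = FALSE)
  }
  cycle_annotation(obj$boundaries)
}

#' @param ann A [cycle_annotation()] to serialize.
#' @rdname read_annotation
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "cycle_annotation"))
  # boundaries are formatted with 17 significant digits so the JSON round
  # trip reproduces the doubles bit-exactly
  writeLines(sprintf(
    '{"boundaries": [%s], "zones_per_cycle": 2, "units": "s"}',
    paste(sprintf("%.17g", ann$boundaries), collapse = ", ")), path)
  invisible(path)
}
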