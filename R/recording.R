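#' Multichannel recording container
#'
#' Holds a uniformly sampled `N`-channel signal (microvolts) with its
#' sampling rate. Samples are stored time-in-rows (an `L x N` matrix), one
#' column per channel, the layout native to R's matrix operations.
#'
#' @param samples Numeric `L x N` matrix (or vector for one channel),
#'   microvolts; rows are time points.
#' @param fs Sampling rate in Hz.
#' @param labels Optional character vector of `N` channel labels; defaults to
#'   `ch1..chN`.
#' @param t0 Start time of the first sample in seconds (default 0).
#' @return An object of class `multichannel_recording`.
#' @examples
#' rec <- multichannel_recording(cbind(sin(1:100), cos(1:100)), fs = 250)
#' rec
#' @export
multichannel_recording <- function(samples, fs, labels = NULL, t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number (Hz)", call. = FALSE)
  }
  if (nrow(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
  n_ch <- ncol(samples)
  if (is.null(labels)) labels <- paste0("ch", seq_len(n_ch))
  if (length(labels) != n_ch) {
    stop(sprintf("got %d labels for %d channels", length(labels), n_ch),
         call. = FALSE)
  }
  colnames(samples) <- labels
  structure(
    list(samples = samples, fs = as.numeric(fs),
         labels = as.character(labels), t0 = as.numeric(t0)),
    class = "multichannel_recording"
  )
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf(
    "<multichannel_recording> %d channels x %d samples @ %g Hz (%.3f s)\n",
    ncol(x$samples), nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  cat("  channels:", toString(x$labels), "\n")
  invisible(x)
}

#' Sample times of a recording
#'
#' @param rec A [multichannel_recording()].
#' @return Numeric vector of sample times in seconds.
#' @export
sample_times <- function(rec) {
  stopifnot(inherits(rec, "multichannel_recording"))
  rec$t0 + (seq_len(nrow(rec$samples)) - 1L) / rec$fs
}

#' Read / write a multichannel recording as delimited text
#'
#' The canonical on-disk dialect mirrors OpenBCI-style delimited logs:
#' `#`-prefixed metadata lines (`# fs: <Hz>`, `# t0: <s>`, `# units: uV`)
#' followed by a CSV header of channel labels and one row per sample. Values
#' are written with full precision so a write/read round trip is
#' bit-identical.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz; required if the file has no `# fs:` line.
#' @return [read_recording()] returns a [multichannel_recording()];
#'   [write_recording()] returns `path` invisibly.
#' @export
read_recording <- function(path, fs = NULL) {
  if (!file.exists(path)) {
    stop("recording file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta_idx <- meta_idx[meta_idx == seq_along(meta_idx)]  # leading block only
  t0 <- 0
  for (ln in lines[meta_idx]) {
    kv <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(kv) == 3L) {
      key <- kv[2L]
      if (key == "fs" && is.null(fs)) fs <- as.numeric(kv[3L])
      if (key == "t0") t0 <- as.numeric(kv[3L])
    }
  }
  if (is.null(fs) || is.na(fs)) {
    stop(sprintf("%s: sampling rate not found in header; pass fs=", path),
         call. = FALSE)
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(body)]
  if (length(body) < 2L) {
    stop(sprintf("%s: no data rows", path), call. = FALSE)
  }
  labels <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  rows <- strsplit(body[-1L], ",", fixed = TRUE)
  n_ch <- length(labels)
  len <- lengths(rows)
  if (any(len != n_ch)) {
    bad <- which(len != n_ch)[1L]
    stop(sprintf(
      "%s: row %d has %d fields, expected %d",
      path, bad + length(meta_idx) + 1L, len[bad], n_ch), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(rows, use.names = FALSE)))
  if (anyNA(vals)) {
    bad <- (which(is.na(vals))[1L] - 1L) %/% n_ch + 1L
    stop(sprintf("%s: non-numeric value in data row %d", path, bad),
         call. = FALSE)
  }
  samples <- matrix(vals, ncol = n_ch, byrow = TRUE)
  multichannel_recording(samples, fs = fs, labels = trimws(labels), t0 = t0)
}

#' @param rec A [multichannel_recording()] to serialize.
#' @rdname read_recording
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "multichannel_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs: %s", format(rec$fs, digits = 17)),
    sprintf("# t0: %s", format(rec$t0, digits = 17)),
    "# units: uV",
    paste(rec$labels, collapse = ",")
  ), con)
  body <- apply(rec$samples, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(body, con)
  invisible(path)
}
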