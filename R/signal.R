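#' Split a raw trace into its five modulation-level segments
#'
#' The raw response matrix (5 sensors x T samples) is cut into the five
#' active-level segments by cumulative stage timing at the sampling rate.
#' The pre-heat period and all 0 V rests are excluded. Segment boundaries
#' are half-open in sample indices, so the segments partition the active
#' samples without duplication.
#'
#' @param trace a `response_trace` (see [simulate_trace()]) or a plain
#'   numeric matrix with 5 rows.
#' @param pattern a [daq_pattern()] object.
#' @return a named list of class `modulation_segments`, one 5 x M matrix per
#'   active level, named `"7"`, `"5.5"`, `"5"`, `"6"`, `"6.5"` in pattern
#'   order.
#' @examples
#' pat <- daq_pattern("DAQ10")
#' tr <- matrix(rnorm(5 * 6000), nrow = 5)
#' segs <- split_modulation_levels(tr, pat)
#' vapply(segs, ncol, integer(1))  # 300 points each
#' @export
split_modulation_levels <- function(trace, pattern) {
  values <- trace_values(trace)
  spans <- active_spans(pattern)
  need <- pattern$nominal_points
  if (is.na(need)) need <- max(vapply(spans, function(s) s$to, numeric(1)))
  if (ncol(values) < need) {
    stop(sprintf("trace has %d samples but the pattern needs %d (short by %d)",
                 ncol(values), need, need - ncol(values)))
  }
  segs <- lapply(spans, function(s) values[, s$from:s$to, drop = FALSE])
  names(segs) <- vapply(spans, function(s) format(s$level), character(1))
  structure(segs, class = "modulation_segments")
}

#' Baseline subtraction
#'
#' Subtracts, per sensor, the mean of the first five samples of the segment
#' from every sample, anchoring each response curve at its initial level.
#'
#' @param segment numeric matrix, sensors x time, with at least 5 columns.
#' @return matrix of the same shape; the mean of the first five columns of
#'   each row is 0.
#' @examples
#' subtract_baseline(matrix(c(1, 1, 1, 1, 1, 3), nrow = 1))
#' @export
subtract_baseline <- function(segment) {
  segment <- as.matrix(segment)
  if (ncol(segment) < 5) stop("segment must have at least 5 samples for baseline estimation")
  baseline <- rowMeans(segment[, 1:5, drop = FALSE])
  sweep(segment, 1, baseline, "-")
}

#' Per-sensor min-max scaling of a segment
#'
#' Maps each sensor's samples to `[0, 1]` via `(x - min) / (max - min)`.
#' A constant (zero-range) row maps to all zeros rather than NaN, keeping
#' degenerate sensors usable.
#'
#' @param segment numeric matrix, sensors x time.
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
scale_segment <- function(segment) {
  segment <- as.matrix(segment)
  lo <- apply(segment, 1, min)
  hi <- apply(segment, 1, max)
  rng <- hi - lo
  out <- sweep(segment, 1, lo, "-")
  nz <- rng > 0
  out[nz, ] <- out[nz, , drop = FALSE] / rng[nz]
  out[!nz, ] <- 0
  out
}

#' Downsample a segment to a fixed length
#'
#' Linear interpolation of each sensor's samples onto `target_len` equally
#' spaced points spanning the segment; the first and last samples are
#' preserved exactly. Used to bring modulation-level segments to the fixed
#' lengths (100 for DAQ10, 300 for DAQ48) expected by sequence models.
#'
#' @param segment numeric matrix, sensors x time (at least 2 columns).
#' @param target_len number of output samples (at least 2). Upsampling
#'   (`target_len > ncol(segment)`) is allowed but flagged with a message.
#' @return matrix sensors x `target_len`.
#' @export
downsample_segment <- function(segment, target_len) {
  segment <- as.matrix(segment)
  m <- ncol(segment)
  stopifnot(m >= 2, target_len >= 2)
  if (target_len > m) message("downsample_segment: target length exceeds input (upsampling)")
  xi <- seq(1, m, length.out = target_len)
  t(apply(segment, 1, function(row) stats::approx(seq_len(m), row, xout = xi)$y))
}

#' Cut a continuous acquisition into fixed-duration windows
#'
#' For constant-heating (DAQcont) traces there is no stage structure;
#' instead the trace is split into consecutive non-overlapping windows of
#' `window_s` seconds. A trailing partial window is dropped.
#'
#' @param trace a `response_trace` or 5-row numeric matrix.
#' @param window_s window duration in seconds (default 600 s = 10 min).
#' @param sampling_rate samples per second (taken from the trace when it
#'   carries one).
#' @return list of sensors x W matrices; empty (with a warning) when the
#'   trace is shorter than one window.
#' @export
window_continuous <- function(trace, window_s = 600, sampling_rate = NULL) {
  values <- trace_values(trace)
  if (is.null(sampling_rate)) {
    sampling_rate <- if (is.list(trace) && !is.null(trace$sampling_rate)) trace$sampling_rate else 10
  }
  stopifnot(window_s > 0)
  w <- floor(window_s * sampling_rate)
  n <- floor(ncol(values) / w)
  if (n == 0) {
    warning("trace shorter than one window; returning empty list")
    return(list())
  }
  lapply(seq_len(n), function(i) values[, ((i - 1) * w + 1):(i * w), drop = FALSE])
}

# Accept either a response_trace or a bare matrix.
trace_values <- function(trace) {
  v <- if (is.list(trace) && !is.null(trace$values)) trace$values else trace
  v <- as.matrix(v)
  if (nrow(v) != 5) stop("expected 5 sensor rows, got ", nrow(v))
  if (!all(is.finite(v))) stop("trace contains non-finite values")
  v
}
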