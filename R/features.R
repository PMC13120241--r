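#' Maximum response at a modulation level
#'
#' Per-sensor maximum of the segment over time; with the 7 V segment this is
#' the `m7V` feature.
#'
#' @param segment numeric matrix, sensors x time.
#' @return named numeric vector, one value per sensor.
#' @export
max_response <- function(segment) {
  segment <- as.matrix(segment)
  stopifnot(ncol(segment) >= 1)
  out <- apply(segment, 1, max)
  names(out) <- paste0("s", seq_len(nrow(segment)))
  out
}

#' Response difference (range) at a modulation level
#'
#' Per-sensor max minus min over time; with the 7 V segment this is the
#' `d7V` feature. Always non-negative.
#'
#' @inheritParams max_response
#' @return named numeric vector, one value per sensor.
#' @export
diff_response <- function(segment) {
  segment <- as.matrix(segment)
  stopifnot(ncol(segment) >= 1)
  out <- apply(segment, 1, function(r) max(r) - min(r))
  names(out) <- paste0("s", seq_len(nrow(segment)))
  out
}

# Normalised EWMA smoothing of one signal:
#   xhat[m] = sum_{i<=m} (1-a)^(m-i) x[i] / sum_{i<=m} (1-a)^(m-i)
# computed with the O(M) recursion num[m] = x[m] + (1-a) num[m-1],
# den[m] = 1 + (1-a) den[m-1].
ewma_smooth <- function(x, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  m <- length(x)
  num <- numeric(m)
  den <- numeric(m)
  nprev <- 0
  dprev <- 0
  q <- 1 - alpha
  for (i in seq_len(m)) {
    nprev <- x[i] + q * nprev
    dprev <- 1 + q * dprev
    num[i] <- nprev
    den[i] <- dprev
  }
  num / den
}

#' Maximum of the EWMA-smoothed segment
#'
#' Each sensor's signal is smoothed with a normalised exponentially weighted
#' moving average (weights `(1 - alpha)^(m - i)` over samples `i <= m`) and
#' the maximum of the smoothed signal is returned. Small `alpha` values
#' smooth more aggressively; the feature set uses alpha in
#' `{0.1, 0.01, 0.001}`. Smoothing never leaves the range of the input, so
#' the result lies within `[min, max]` of the segment.
#'
#' @inheritParams max_response
#' @param alpha smoothing weight in `(0, 1]`; `alpha = 1` reduces to
#'   [max_response()].
#' @return named numeric vector, one value per sensor.
#' @export
ewma_max <- function(segment, alpha) {
  segment <- as.matrix(segment)
  stopifnot(ncol(segment) >= 1)
  out <- apply(segment, 1, function(r) max(ewma_smooth(r, alpha)))
  names(out) <- paste0("s", seq_len(nrow(segment)))
  out
}

#' Assemble the feature vector for one modulated sample
#'
#' The large set (85 features for 5 sensors x 5 levels) is: the per-sensor
#' maximum (`m7v`) and range (`d7v`) at the 7 V level, followed by the EWMA
#' maximum at alpha in `{0.1, 0.01, 0.001}` for every sensor at every level,
#' ordered level-major, then sensor, then alpha. The small set keeps only
#' the 10 amplitude features `m7v` and `d7v`.
#'
#' @param segments a `modulation_segments` list from
#'   [split_modulation_levels()].
#' @param feature_set `"large"` (85 features) or `"small"` (10 features).
#' @param alphas EWMA smoothing weights for the large set.
#' @return named numeric vector.
#' @examples
#' pat <- daq_pattern("DAQ10")
#' segs <- split_modulation_levels(matrix(rnorm(5 * 6000), 5), pat)
#' length(build_feature_vector(segs, "large"))  # 85
#' length(build_feature_vector(segs, "small"))  # 10
#' @export
build_feature_vector <- function(segments, feature_set = c("large", "small"),
                                 alphas = c(0.1, 0.01, 0.001)) {
  feature_set <- match.arg(feature_set)
  levels_expected <- c("7", "5.5", "5", "6", "6.5")
  missing_lv <- setdiff(levels_expected, names(segments))
  if (length(missing_lv) > 0) {
    stop("missing modulation level segment(s): ", paste(missing_lv, "V", collapse = ", "))
  }
  seg7 <- segments[["7"]]
  m7 <- max_response(seg7)
  d7 <- diff_response(seg7)
  out <- c(stats::setNames(m7, paste0("m7v_s", seq_along(m7))),
           stats::setNames(d7, paste0("d7v_s", seq_along(d7))))
  if (feature_set == "large") {
    for (lv in levels_expected) {
      seg <- segments[[lv]]
      for (s in seq_len(nrow(seg))) {
        for (a in alphas) {
          out[sprintf("ewma_%sv_s%d_a%g", lv, s, a)] <- max(ewma_smooth(seg[s, ], a))
        }
      }
    }
  }
  out
}

#' Windowed time-domain statistics for continuous acquisition
#'
#' For constant-heating data the response-curve features do not apply;
#' instead each window yields, per sensor, the mean, standard deviation
#' (population), maximum, minimum and root mean square: 25 features for 5
#' sensors.
#'
#' @param window numeric matrix, sensors x time, from [window_continuous()].
#' @return named numeric vector of length `5 * nrow(window)`.
#' @export
cont_features <- function(window) {
  window <- as.matrix(window)
  stopifnot(ncol(window) >= 1)
  stat_names <- c("mean", "sd", "max", "min", "rms")
  out <- numeric(0)
  for (s in seq_len(nrow(window))) {
    x <- window[s, ]
    m <- mean(x)
    vals <- c(m, sqrt(mean((x - m)^2)), max(x), min(x), sqrt(mean(x^2)))
    names(vals) <- sprintf("%s_s%d", stat_names, s)
    out <- c(out, vals)
  }
  out
}

#' Min-max feature scaling with train-only fitting
#'
#' `fit_scaler()` learns per-feature minima and maxima from a training set
#' only; `apply_scaler()` maps features via `(x - min) / (max - min)`.
#' Training data lands in `[0, 1]`; test values outside the training range
#' extrapolate beyond `[0, 1]` and are deliberately not clipped, since
#' distribution shift between acquisition batches is part of what the
#' downstream analysis measures. Zero-range features map to 0 with a
#' warning. The scaler is never refitted on test folds.
#'
#' @param train matrix or data.frame of training feature rows, or a list of
#'   named feature vectors.
#' @return `fit_scaler()`: an object of class `feature_scaler` with fields
#'   `min`, `max`; `apply_scaler()`: scaled matrix (or vector, matching the
#'   input shape).
#' @examples
#' sc <- fit_scaler(matrix(c(2, 4, 6), ncol = 1))
#' apply_scaler(sc, matrix(c(4, 8), ncol = 1))  # 0.5, 1.5
#' @export
fit_scaler <- function(train) {
  train <- as_feature_matrix(train)
  stopifnot(nrow(train) >= 1)
  structure(
    list(min = apply(train, 2, min), max = apply(train, 2, max),
         names = colnames(train)),
    class = "feature_scaler"
  )
}

#' @rdname fit_scaler
#' @param scaler a fitted `feature_scaler`.
#' @param x feature matrix or single named feature vector to transform.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"))
  vec <- is.null(dim(x))
  x <- as_feature_matrix(x)
  if (!is.null(scaler$names) && !is.null(colnames(x))) {
    if (!identical(colnames(x), scaler$names)) {
      stop("feature names do not match the fitted scaler")
    }
  }
  rng <- scaler$max - scaler$min
  out <- sweep(x, 2, scaler$min, "-")
  zero <- rng == 0
  if (any(zero)) {
    warning("zero-range feature(s) mapped to 0: ",
            paste(utils::head(scaler$names[zero], 5), collapse = ", "))
    out[, zero] <- 0
  }
  out[, !zero] <- sweep(out[, !zero, drop = FALSE], 2, rng[!zero], "/")
  if (vec) out[1, ] else out
}

as_feature_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  as.matrix(x)
}

#' Feature table for a simulated dataset
#'
#' Convenience wrapper running split -> feature extraction over every trace
#' of a [simulate_dataset()] result (optionally after response correction).
#'
#' @param dataset a `simulated_dataset`.
#' @param feature_set `"large"` or `"small"`; see [build_feature_vector()].
#' @param correction `"off"`, `"features"` (append mean temperature and
#'   humidity as two extra features) or `"response"` (correct the raw
#'   traces with `surfaces` before extraction).
#' @param surfaces per-sensor correction surfaces for
#'   `correction = "response"`; defaults to the dataset's generating
#'   surfaces when present.
#' @return numeric matrix, samples x features, rownames = sample ids.
#' @export
feature_table <- function(dataset, feature_set = c("large", "small"),
                          correction = c("off", "features", "response"),
                          surfaces = NULL) {
  feature_set <- match.arg(feature_set)
  correction <- match.arg(correction)
  pattern <- dataset$pattern
  rows <- lapply(dataset$traces, function(tr) {
    if (correction == "response") {
      sf <- if (is.null(surfaces)) dataset$surfaces else surfaces
      tr <- correct_trace(tr, sf)
    }
    f <- build_feature_vector(split_modulation_levels(tr, pattern), feature_set)
    if (correction == "features") {
      f <- augment_features(f, mean(tr$env$temp_c), mean(tr$env$rh_pct))
    }
    f
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(dataset$traces, function(tr) tr$metadata$sample_id, character(1))
  out
}
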