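#' Fit a humidity/temperature correction surface
#'
#' MOX sensor resistance depends on ambient temperature and humidity. The
#' sensor datasheets tabulate RS/R0 — the ratio of the resistance at a
#' given (temperature, humidity) to the resistance at the reference
#' condition 20 degC / 65 RH% — at a handful of conditions. This function
#' interpolates those reference points with an exact thin-plate-spline
#' radial basis function, yielding a correction factor `alpha(temp, rh)`
#' defined at any operating condition. The interpolant reproduces every
#' reference point exactly (no smoothing); queries outside the convex hull
#' of the reference grid are extrapolated with a warning.
#'
#' @param reference_points data.frame with columns `temp_c`, `rh_pct`,
#'   `rs_over_r0` (at least 3 non-collinear points).
#' @return object of class `correction_surface`; evaluate with
#'   [predict_alpha()].
#' @examples
#' grid <- expand.grid(temp_c = c(10, 20, 30), rh_pct = c(40, 65, 90))
#' grid$rs_over_r0 <- 1.5 - 0.005 * grid$rh_pct - 0.01 * (grid$temp_c - 20)
#' sf <- fit_surface(grid)
#' predict_alpha(sf, 20, 65)
#' @export
fit_surface <- function(reference_points) {
  pts <- as.data.frame(reference_points)
  stopifnot(all(c("temp_c", "rh_pct", "rs_over_r0") %in% names(pts)))
  pts <- unique(pts[, c("temp_c", "rh_pct", "rs_over_r0")])
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 reference points")
  # scale coordinates to comparable ranges for conditioning
  sc <- c(temp = max(diff(range(pts$temp_c)), 1), rh = max(diff(range(pts$rh_pct)), 1))
  x <- pts$temp_c / sc["temp"]
  y <- pts$rh_pct / sc["rh"]
  if (abs(stats::cor(x, y)) > 1 - 1e-10 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    if (qr(cbind(1, x, y))$rank < 3) stop("degenerate (collinear) reference point set")
  }
  K <- tps_kernel_matrix(x, y, x, y)
  P <- cbind(1, x, y)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(pts$rs_over_r0, rep(0, 3))
  coefs <- solve(A, rhs)
  structure(
    list(x = x, y = y, scale = sc, w = coefs[seq_len(n)], c = coefs[n + 1:3],
         hull = list(temp = range(pts$temp_c), rh = range(pts$rh_pct)),
         reference_points = pts),
    class = "correction_surface"
  )
}

tps_kernel_matrix <- function(x1, y1, x2, y2) {
  d2 <- outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
  k <- matrix(0, nrow = length(x1), ncol = length(x2))
  pos <- d2 > 0
  k[pos] <- 0.5 * d2[pos] * log(d2[pos])  # r^2 log r
  k
}

#' Evaluate a correction surface
#'
#' @param surface a [fit_surface()] object.
#' @param temp_c,rh_pct operating condition(s); vectors are recycled to a
#'   common length.
#' @param warn_extrapolation warn when a query falls outside the bounding
#'   box of the reference grid.
#' @return numeric vector of correction factors alpha.
#' @export
predict_alpha <- function(surface, temp_c, rh_pct, warn_extrapolation = TRUE) {
  stopifnot(inherits(surface, "correction_surface"))
  n <- max(length(temp_c), length(rh_pct))
  temp_c <- rep_len(temp_c, n)
  rh_pct <- rep_len(rh_pct, n)
  if (warn_extrapolation) {
    out <- temp_c < surface$hull$temp[1] | temp_c > surface$hull$temp[2] |
      rh_pct < surface$hull$rh[1] | rh_pct > surface$hull$rh[2]
    if (any(out)) warning(sum(out), " query point(s) outside the reference grid; extrapolating")
  }
  qx <- temp_c / surface$scale["temp"]
  qy <- rh_pct / surface$scale["rh"]
  K <- tps_kernel_matrix(qx, qy, surface$x, surface$y)
  as.numeric(K %*% surface$w + cbind(1, qx, qy) %*% surface$c)
}

#' Correct a sensor output voltage for temperature/humidity
#'
#' The sensor sits in a voltage divider with supply `vc` (5 V), so its
#' resistance is proportional to `vc / vout - 1`. Dividing the resistance
#' by the correction factor `alpha = RS/R0` at the sample's conditions and
#' converting back through the divider gives the response the sensor would
#' have produced at the reference condition:
#' `vout_corr = vc / ((vc / vout - 1) / alpha + 1)`.
#' `alpha = 1` is the identity. Strictly increasing in `vout` for fixed
#' `alpha`. `distort_response()` is the exact algebraic inverse, used by the
#' synthetic-data generator to imprint a known environmental distortion.
#'
#' @param vout measured output voltage(s), strictly between 0 and `vc`.
#' @param vc circuit supply voltage (5 V).
#' @param alpha correction factor(s) > 0.
#' @return corrected (or distorted) voltage(s), still in `(0, vc)`.
#' @examples
#' correct_response(2.5, 5, 2)              # 3.3333
#' distort_response(correct_response(2.5, 5, 2), 5, 2)  # 2.5
#' @export
correct_response <- function(vout, vc = 5, alpha = 1) {
  if (any(vout <= 0 | vout >= vc)) stop("vout must lie strictly between 0 and vc")
  if (any(alpha <= 0)) stop("alpha must be positive")
  vc / ((vc / vout - 1) / alpha + 1)
}

#' @rdname correct_response
#' @export
distort_response <- function(vout, vc = 5, alpha = 1) {
  if (any(vout <= 0 | vout >= vc)) stop("vout must lie strictly between 0 and vc")
  if (any(alpha <= 0)) stop("alpha must be positive")
  vc / ((vc / vout - 1) * alpha + 1)
}

#' Apply response correction to a whole trace
#'
#' Corrects sensors 2-5 of a trace sample-by-sample, using the trace's
#' recorded temperature/humidity channels and one correction surface per
#' sensor. Sensor 1 passes through unchanged: its datasheet does not
#' tabulate RS/R0, so no surface exists for it. `distort_trace()` applies
#' the inverse mapping and is what the simulator uses.
#'
#' @param trace a `response_trace` with an `env` data.frame
#'   (`temp_c`, `rh_pct`).
#' @param surfaces list of 5 elements; elements 2-5 are
#'   `correction_surface` objects (element 1 is ignored and may be NULL).
#' @param vc circuit supply voltage.
#' @return the trace with corrected (or distorted) `values`.
#' @export
correct_trace <- function(trace, surfaces, vc = 5) {
  transform_trace(trace, surfaces, vc, correct_response)
}

#' @rdname correct_trace
#' @export
distort_trace <- function(trace, surfaces, vc = 5) {
  transform_trace(trace, surfaces, vc, distort_response)
}

transform_trace <- function(trace, surfaces, vc, f) {
  stopifnot(is.list(trace), !is.null(trace$values), !is.null(trace$env))
  values <- trace$values
  for (s in 2:5) {
    sf <- surfaces[[s]]
    if (is.null(sf)) next
    a <- predict_alpha(sf, trace$env$temp_c, trace$env$rh_pct, warn_extrapolation = FALSE)
    values[s, ] <- f(values[s, ], vc = vc, alpha = a)
  }
  trace$values <- values
  trace
}

#' Append environmental readings as features
#'
#' The alternative to response correction: the sample's temperature and
#' humidity are concatenated to the feature vector prior to scaling, giving
#' 87 (large) or 12 (small) features.
#'
#' @param x named feature vector.
#' @param temp_c,rh_pct scalar environmental readings for the sample.
#' @return the vector with `env_temp_c` and `env_rh_pct` appended.
#' @export
augment_features <- function(x, temp_c, rh_pct) {
  if (is.na(temp_c) || is.na(rh_pct)) {
    stop("missing environmental reading; exclude the sample")
  }
  c(x, env_temp_c = as.numeric(temp_c), env_rh_pct = as.numeric(rh_pct))
}

#' Bundled synthetic RS/R0 reference grids
#'
#' The sensors' datasheet RS/R0 tables are not redistributable, so the
#' package ships a synthetic but physically plausible grid per sensor
#' (ratio decreasing with humidity and temperature, passing through 1 at
#' the 20 degC / 65 RH% reference condition, with per-sensor slopes).
#' Users can substitute their own grid CSV with columns
#' `sensor, temp_c, rh_pct, rs_over_r0`.
#'
#' @param path optional CSV path overriding the bundled grid.
#' @return list of 5 elements: NULL for sensor 1, `correction_surface`
#'   objects for sensors 2-5.
#' @export
reference_surfaces <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_rs_r0_grid.csv", package = "odourfusion")
  }
  grid <- utils::read.csv(path)
  out <- vector("list", 5)
  for (s in 2:5) {
    g <- grid[grid$sensor == s, c("temp_c", "rh_pct", "rs_over_r0")]
    if (nrow(g) >= 3) out[[s]] <- fit_surface(g)
  }
  out
}

#' Flat (identity) correction surfaces
#'
#' Surfaces with RS/R0 = 1 everywhere; distortion/correction with them is
#' the identity. Useful for null simulations.
#'
#' @return list in the format of [reference_surfaces()].
#' @export
flat_surfaces <- function() {
  grid <- expand.grid(temp_c = c(0, 20, 40), rh_pct = c(20, 65, 95))
  grid$rs_over_r0 <- 1
  sf <- fit_surface(grid)
  out <- vector("list", 5)
  for (s in 2:5) out[[s]] <- sf
  out
}
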