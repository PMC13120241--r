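#' Heater-voltage modulation patterns
#'
#' A modulation pattern describes the schedule of voltages applied to the
#' heater element (VH) of a MOX gas-sensor array during one acquisition:
#' a pre-heating period followed by alternating active voltage levels and
#' 0 V rests. The five active levels (7, 5.5, 5, 6 and 6.5 V) are the ones
#' analysed downstream; rests and pre-heat are recorded in the trace but
#' excluded from analysis segments.
#'
#' The two modulated protocols are `DAQ10` (5 min pre-heat at 5 V, then
#' nine alternating 30 s stages) and `DAQ48` (20 min pre-heat, then 30 s
#' rests alternating with 300 s active stages). Their scheduled stages sum
#' to 9.5 and 47.5 min while the saved traces are 10 min (6000 points) and
#' 48 min (28,800 points) at 10 Hz; the remainder is recorded as a trailing
#' 0 V rest so the nominal point count is met without changing any active
#' stage's duration. `DAQcont` is continuous 5 V heating with no stage
#' structure.
#'
#' @param id one of `"DAQ10"`, `"DAQ48"`, `"DAQcont"`.
#' @param sampling_rate samples per second; the saved data rate is 10 Hz.
#' @return an object of class `modulation_pattern` with elements
#'   `id`, `preheat` (voltage, duration), `stages` (data.frame with columns
#'   `voltage`, `duration`, `active`), `active_levels`, `nominal_points`
#'   and `sampling_rate`. For `DAQcont`, `stages` is empty and
#'   `nominal_points` is `NA` (open-ended acquisition).
#' @examples
#' p <- daq_pattern("DAQ10")
#' p$nominal_points  # 6000
#' sum(p$stages$duration[p$stages$active]) * p$sampling_rate  # 1500 active samples
#' @export
daq_pattern <- function(id = c("DAQ10", "DAQ48", "DAQcont"), sampling_rate = 10) {
  id <- match.arg(id)
  stopifnot(sampling_rate > 0)
  active_levels <- c(7, 5.5, 5, 6, 6.5)
  if (id == "DAQ10") {
    preheat <- c(voltage = 5, duration = 5 * 60)
    v <- c(7, 0, 5.5, 0, 5, 0, 6, 0, 6.5)
    d <- rep(30, 9)
    nominal <- 6000
  } else if (id == "DAQ48") {
    preheat <- c(voltage = 5, duration = 20 * 60)
    v <- c(0, 7, 0, 5.5, 0, 5, 0, 6, 0, 6.5)
    d <- rep(c(30, 300), 5)
    nominal <- 28800
  } else {
    preheat <- c(voltage = 5, duration = 0)
    v <- numeric(0)
    d <- numeric(0)
    nominal <- NA_integer_
  }
  stages <- data.frame(voltage = v, duration = d)
  stages$active <- stages$voltage > 0
  # pad with a trailing rest so the saved trace reaches the nominal length
  if (!is.na(nominal)) {
    scheduled <- (preheat[["duration"]] + sum(stages$duration)) * sampling_rate
    pad <- (nominal - scheduled) / sampling_rate
    stopifnot(pad >= 0)
    if (pad > 0) {
      stages <- rbind(stages, data.frame(voltage = 0, duration = pad, active = FALSE))
    }
  }
  structure(
    list(id = id, preheat = preheat, stages = stages,
         active_levels = active_levels, nominal_points = nominal,
         sampling_rate = sampling_rate),
    class = "modulation_pattern"
  )
}

#' @export
print.modulation_pattern <- function(x, ...) {
  cat(sprintf("<modulation_pattern %s: preheat %gs @ %gV, %d stages, %s points @ %g Hz>\n",
              x$id, x$preheat[["duration"]], x$preheat[["voltage"]],
              nrow(x$stages),
              ifelse(is.na(x$nominal_points), "open-ended", x$nominal_points),
              x$sampling_rate))
  invisible(x)
}

# Half-open [start, end) sample-index spans of the five active stages, in
# pattern order. Indices are 1-based for R subsetting.
active_spans <- function(pattern) {
  stopifnot(inherits(pattern, "modulation_pattern"))
  rate <- pattern$sampling_rate
  offs <- pattern$preheat[["duration"]]
  spans <- list()
  for (i in seq_len(nrow(pattern$stages))) {
    dur <- pattern$stages$duration[i]
    if (pattern$stages$active[i]) {
      start <- round(offs * rate)
      end <- round((offs + dur) * rate)
      spans[[length(spans) + 1L]] <- list(
        level = pattern$stages$voltage[i],
        from = start + 1L, to = end
      )
    }
    offs <- offs + dur
  }
  spans
}
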