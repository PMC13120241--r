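#' Configuration of the synthetic acquisition generator
#'
#' The generator emulates the statistical structure of open-air
#' temperature-modulated gas-sensor acquisitions paired with camera
#' detections: class-dependent response amplitudes with first-order
#' rise/decay kinetics on top of per-sensor baselines, Gaussian measurement
#' noise, shared per-day amplitude effects (short-term environmental
#' variability that correlates temporally close samples), multiplicative
#' baseline drift between acquisition batches, daily temperature/humidity
#' cycles that distort the responses through a known RS/R0 surface, and a
#' lighting model governing whether and how well the image side detects
#' fruits (night samples have no usable image at all).
#'
#' @param n_samples_per_class samples to generate per class.
#' @param classes the two class labels; the first is the "positive"
#'   (ripe) class whose plants carry ripe fruits.
#' @param pattern_id acquisition protocol, see [daq_pattern()].
#' @param sampling_rate saved-data rate in Hz.
#' @param baseline per-sensor clean-air output voltage (length 5, volts).
#' @param class_amplitudes matrix (classes x 5 sensors) of response
#'   amplitudes in volts at the 7 V heater level; other levels are scaled
#'   by `(VH / 7)^2`. Equal rows give a null (non-separable) simulation.
#' @param rise_tau,decay_tau first-order response time constants, seconds.
#' @param noise_sd Gaussian measurement noise, volts.
#' @param day_noise_sd relative s.d. of the per-day, per-sensor amplitude
#'   effect shared by all samples of a day (day-correlated noise).
#' @param drift_rate fractional multiplicative signal shift per day past
#'   `drift_onset_day` (`drift_mode = "linear"`), or the one-off fractional
#'   step at the batch boundary (`drift_mode = "step"`).
#' @param drift_onset_day day index separating batch 1 from batch 2;
#'   defaults to `n_days` (single batch, no drift window).
#' @param drift_mode `"linear"` or `"step"`.
#' @param env_model daily sinusoidal temperature/humidity cycle parameters:
#'   `temp_mean`, `temp_amp` (degC), `rh_mean`, `rh_amp` (RH%),
#'   `peak_hour` (hour of maximum temperature; humidity is in anti-phase).
#' @param surfaces true RS/R0 correction surfaces used to distort sensors
#'   2-5 (see [reference_surfaces()]); `NULL` disables distortion.
#' @param n_days span of the acquisition campaign in days.
#' @param swap_every_days plants are alternated between classes every this
#'   many days, making the label temporally blocked as in a real campaign.
#' @param night_fraction fraction of samples acquired at night (no image).
#' @param lighting_probs relative probabilities of the daylight lighting
#'   conditions `well_lit`, `backlit`, `artificial` (normalised internally;
#'   combined with `night_fraction` they form the full lighting law).
#' @param detect_quality per-lighting detection model: element `p` gives
#'   per-class detection probabilities, `conf` per-class Beta(shape1,
#'   shape2) confidence parameters, `flip` the probability that a detected
#'   unripe fruit is mislabelled as ripe (backlight artefact). Validation
#'   enforces that backlit ripe fruits have lower detection probability and
#'   lower mean confidence than well-lit ones.
#' @param fruit_counts ranges of true fruit counts per plant class.
#' @param image_size image width/height in pixels for the synthetic boxes.
#' @param cont_duration_s trace duration for `DAQcont` acquisitions.
#' @param seed base seed; every derived random draw is a pure function of
#'   it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_class = 50,
                       classes = c("ripe", "unripe"),
                       pattern_id = "DAQ10",
                       sampling_rate = 10,
                       baseline = c(0.90, 0.80, 1.00, 0.85, 0.95),
                       class_amplitudes = rbind(
                         ripe = c(1.20, 1.00, 1.50, 1.30, 1.10),
                         other = c(0.78, 0.65, 0.98, 0.85, 0.72)
                       ),
                       rise_tau = 8,
                       decay_tau = 15,
                       noise_sd = 0.02,
                       day_noise_sd = 0.15,
                       drift_rate = 0,
                       drift_onset_day = n_days,
                       drift_mode = c("linear", "step"),
                       env_model = list(temp_mean = 20, temp_amp = 5,
                                        rh_mean = 65, rh_amp = 12,
                                        peak_hour = 15),
                       surfaces = reference_surfaces(),
                       n_days = 25,
                       swap_every_days = 3,
                       night_fraction = 0.5,
                       lighting_probs = c(well_lit = 0.4, backlit = 0.4,
                                          artificial = 0.2),
                       detect_quality = default_detect_quality(),
                       fruit_counts = list(ripe = c(1, 3), unripe = c(1, 4)),
                       image_size = c(1024, 768),
                       cont_duration_s = 3600,
                       seed = 1) {
  drift_mode <- match.arg(drift_mode)
  stopifnot(length(classes) == 2, n_samples_per_class >= 1,
            sampling_rate > 0, rise_tau > 0, decay_tau > 0, noise_sd >= 0,
            day_noise_sd >= 0, length(baseline) == 5,
            nrow(class_amplitudes) == 2, ncol(class_amplitudes) == 5,
            night_fraction >= 0, night_fraction <= 1,
            all(lighting_probs >= 0), sum(lighting_probs) > 0,
            n_days >= 1, swap_every_days >= 1)
  rownames(class_amplitudes) <- classes
  lighting_probs <- lighting_probs / sum(lighting_probs)
  validate_detect_quality(detect_quality)
  # full categorical lighting law, including night
  full_probs <- c(lighting_probs * (1 - night_fraction), night = night_fraction)
  stopifnot(abs(sum(full_probs) - 1) < 1e-9)
  structure(
    list(n_samples_per_class = n_samples_per_class, classes = classes,
         pattern_id = pattern_id, sampling_rate = sampling_rate,
         baseline = baseline, class_amplitudes = class_amplitudes,
         rise_tau = rise_tau, decay_tau = decay_tau, noise_sd = noise_sd,
         day_noise_sd = day_noise_sd, drift_rate = drift_rate,
         drift_onset_day = drift_onset_day, drift_mode = drift_mode,
         env_model = env_model, surfaces = surfaces, n_days = n_days,
         swap_every_days = swap_every_days, night_fraction = night_fraction,
         lighting_probs = full_probs, detect_quality = detect_quality,
         fruit_counts = fruit_counts, image_size = image_size,
         cont_duration_s = cont_duration_s, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_detect_quality <- function() {
  list(
    well_lit = list(p = c(ripe = 0.90, unripe = 0.85),
                    conf = list(ripe = c(8, 2), unripe = c(8, 2)),
                    flip = 0.01),
    backlit = list(p = c(ripe = 0.35, unripe = 0.55),
                   conf = list(ripe = c(4, 4), unripe = c(5, 3)),
                   flip = 0.05),
    artificial = list(p = c(ripe = 0.75, unripe = 0.70),
                      conf = list(ripe = c(6, 3), unripe = c(6, 3)),
                      flip = 0.02)
  )
}

validate_detect_quality <- function(dq) {
  stopifnot(all(c("well_lit", "backlit", "artificial") %in% names(dq)))
  for (l in names(dq)) {
    stopifnot(all(dq[[l]]$p >= 0 & dq[[l]]$p <= 1),
              dq[[l]]$flip >= 0, dq[[l]]$flip <= 1)
  }
  beta_mean <- function(ab) ab[1] / (ab[1] + ab[2])
  if (dq$backlit$p["ripe"] > dq$well_lit$p["ripe"]) {
    stop("backlit ripe detection probability must not exceed well-lit")
  }
  if (beta_mean(dq$backlit$conf$ripe) > beta_mean(dq$well_lit$conf$ripe)) {
    stop("backlit ripe mean confidence must not exceed well-lit")
  }
  invisible(dq)
}

# Daily sinusoidal environment at fractional-day timestamps (in days).
env_at <- function(env_model, timestamp_days) {
  h <- (timestamp_days * 24) %% 24
  phase <- 2 * pi * (h - env_model$peak_hour) / 24
  data.frame(
    temp_c = env_model$temp_mean + env_model$temp_amp * cos(phase),
    rh_pct = env_model$rh_mean - env_model$rh_amp * cos(phase)
  )
}

# Multiplicative drift factor for a given (possibly fractional) day.
drift_factor <- function(config, day) {
  past <- pmax(0, day - config$drift_onset_day)
  if (config$drift_mode == "linear") {
    1 + config$drift_rate * past
  } else {
    1 + config$drift_rate * (past > 0)
  }
}

# Per-sensor relative amplitude effect shared by all samples of one day.
day_effect <- function(config, day) {
  if (config$day_noise_sd == 0) return(rep(0, 5))
  with_seed(derive_seed(config$seed, 1e6 + floor(day)),
            stats::rnorm(5, 0, config$day_noise_sd))
}

#' Simulate one acquisition trace
#'
#' Generates a 5-sensor response trace under the configured modulation
#' pattern: each sensor follows first-order kinetics toward a plateau
#' proportional to `amplitude(label, sensor) * (VH / 7)^2` during active
#' heater stages and relaxes toward its baseline during rests and the
#' pre-heat period. The clean signal is scaled by the drift factor of the
#' sample's day and by the shared day effect, Gaussian noise is added, and
#' finally sensors 2-5 are distorted through the true RS/R0 surface at the
#' trace's evolving temperature/humidity. The trace has exactly the
#' pattern's nominal point count (6000 for DAQ10, 28,800 for DAQ48) and
#' carries the environment channels.
#'
#' @param config a [sim_config()].
#' @param label class label of the sample.
#' @param day fractional day of acquisition start (its integer part is the
#'   day index).
#' @param seed seed for the trace's noise draws.
#' @return an object of class `response_trace`: `values` (5 x T volts),
#'   `time` (seconds), `env` (per-time `temp_c`, `rh_pct`),
#'   `sampling_rate`, and `metadata`.
#' @export
simulate_trace <- function(config, label, day = 0, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), label %in% config$classes)
  pattern <- daq_pattern(config$pattern_id, config$sampling_rate)
  rate <- config$sampling_rate
  if (config$pattern_id == "DAQcont") {
    n <- floor(config$cont_duration_s * rate)
    schedule <- data.frame(voltage = 5, duration = config$cont_duration_s)
  } else {
    n <- pattern$nominal_points
    schedule <- rbind(
      data.frame(voltage = pattern$preheat[["voltage"]],
                 duration = pattern$preheat[["duration"]]),
      pattern$stages[, c("voltage", "duration")]
    )
  }
  time_s <- (seq_len(n) - 1) / rate
  env <- env_at(config$env_model, day + time_s / 86400)

  amp <- config$class_amplitudes[label, ] * (1 + day_effect(config, day))
  dr <- drift_factor(config, floor(day))
  # piecewise-exponential kinetics of the activation in [0, 1] scale
  act <- matrix(0, nrow = 5, ncol = n)
  state <- rep(0, 5)
  idx <- 1L
  for (i in seq_len(nrow(schedule))) {
    v <- schedule$voltage[i]
    m <- round(schedule$duration[i] * rate)
    if (m == 0) next
    m <- min(m, n - idx + 1L)
    if (m <= 0) break
    target <- if (v > 0) (v / 7)^2 else 0
    tt <- seq_len(m) / rate
    for (s in 1:5) {
      tau_s <- if (target >= state[s]) config$rise_tau else config$decay_tau
      act[s, idx:(idx + m - 1L)] <- target + (state[s] - target) * exp(-tt / tau_s)
    }
    state <- act[, idx + m - 1L]
    idx <- idx + m
  }

  clean <- dr * (matrix(config$baseline, 5, n) + amp * act)
  values <- with_seed(seed, clean + if (config$noise_sd > 0) {
    matrix(stats::rnorm(5 * n, 0, config$noise_sd), 5, n)
  } else 0)
  trace <- structure(
    list(values = values, time = time_s, env = env, sampling_rate = rate,
         metadata = list(sample_id = NA_character_, timestamp = day,
                         day = floor(day), batch = NA_integer_, label = label)),
    class = "response_trace"
  )
  if (!is.null(config$surfaces)) {
    trace <- distort_trace(trace, config$surfaces)
  }
  trace
}

#' Simulate the detection output of the image model for one sample
#'
#' Emulates an object detector run on one image: each true fruit on the
#' plant is detected independently with a lighting- and class-dependent
#' probability, detected boxes receive a confidence drawn from the
#' lighting/class Beta distribution, and under poor lighting a detected
#' unripe fruit may be mislabelled as ripe. Night samples have no usable
#' image and return `NULL`.
#'
#' @param config a [sim_config()].
#' @param label class of the plant (`ripe` plants carry at least one ripe
#'   fruit; `unripe` plants only unripe fruits).
#' @param lighting one of `"well_lit"`, `"backlit"`, `"artificial"`,
#'   `"night"`.
#' @param seed seed for the draws.
#' @return `NULL` for night, otherwise a (possibly empty) data.frame of
#'   detections with columns `x1, y1, x2, y2, cls, conf`.
#' @export
simulate_detections <- function(config, label, lighting, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  lighting <- match.arg(lighting, c("well_lit", "backlit", "artificial", "night"))
  if (lighting == "night") return(NULL)
  dq <- config$detect_quality[[lighting]]
  positive <- config$classes[1]
  pick <- function(v) v[sample.int(length(v), 1)]  # safe for length-1 ranges
  with_seed(seed, {
    if (label == positive) {
      n_ripe <- pick(config$fruit_counts$ripe[1]:config$fruit_counts$ripe[2])
      n_unripe <- pick(0:config$fruit_counts$unripe[2])
    } else {
      n_ripe <- 0
      n_unripe <- pick(config$fruit_counts$unripe[1]:config$fruit_counts$unripe[2])
    }
    fruit_cls <- c(rep("ripe", n_ripe), rep("unripe", n_unripe))
    rows <- list()
    for (cls in fruit_cls) {
      if (stats::runif(1) > dq$p[[cls]]) next
      seen_cls <- cls
      if (cls == "unripe" && stats::runif(1) < dq$flip) seen_cls <- "ripe"
      conf <- stats::rbeta(1, dq$conf[[cls]][1], dq$conf[[cls]][2])
      w <- stats::runif(1, 40, 120)
      h <- stats::runif(1, 40, 120)
      x1 <- stats::runif(1, 0, config$image_size[1] - w)
      y1 <- stats::runif(1, 0, config$image_size[2] - h)
      rows[[length(rows) + 1L]] <- data.frame(
        x1 = x1, y1 = y1, x2 = x1 + w, y2 = y1 + h,
        cls = seen_cls, conf = conf, stringsAsFactors = FALSE
      )
    }
    if (length(rows) == 0) {
      data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                 y2 = numeric(0), cls = character(0), conf = numeric(0),
                 stringsAsFactors = FALSE)
    } else {
      do.call(rbind, rows)
    }
  })
}

#' Simulate a full acquisition campaign
#'
#' Lays out `2 * n_samples_per_class` samples over `n_days` days with the
#' plant class alternating every `swap_every_days` days (so the label is
#' temporally blocked, as when single plants are swapped in and out of the
#' measurement tent), draws each sample's lighting condition and time of
#' day, and generates the odour trace and image detections for every
#' sample. Batches are separated at `drift_onset_day`. The result is fully
#' determined by the config (including its seed).
#'
#' @param config a [sim_config()].
#' @return an object of class `simulated_dataset` with elements `traces`
#'   (list of `response_trace`), `detections` (list, `NULL` for night
#'   samples), `metadata` (data.frame: `sample_id, timestamp, day, batch,
#'   label, lighting, image_available`), `labels` (factor), `day_index`,
#'   `batch_id`, `image_available`, `pattern`, `surfaces` and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- 2 * config$n_samples_per_class
  # class of each calendar day: alternating blocks of swap_every_days
  day_class <- config$classes[(floor((0:(config$n_days - 1)) / config$swap_every_days) %% 2) + 1]
  # allocate each class's quota evenly (round-robin) over its days
  day_of_sample <- integer(0)
  label_of_sample <- character(0)
  for (cl in config$classes) {
    days_cl <- which(day_class == cl) - 1L
    if (length(days_cl) == 0) stop("no days allocated to class ", cl)
    d <- rep_len(days_cl, config$n_samples_per_class)
    day_of_sample <- c(day_of_sample, sort(d))
    label_of_sample <- c(label_of_sample, rep(cl, config$n_samples_per_class))
  }
  ord0 <- order(day_of_sample)
  day_of_sample <- day_of_sample[ord0]
  label_of_sample <- label_of_sample[ord0]

  lighting_levels <- names(config$lighting_probs)
  lighting <- with_seed(derive_seed(config$seed, 2), {
    sample(lighting_levels, n_total, replace = TRUE, prob = config$lighting_probs)
  })
  hours <- with_seed(derive_seed(config$seed, 3), {
    ifelse(lighting == "night",
           (20 + stats::runif(n_total) * 10) %% 24,  # 20:00-06:00
           8 + stats::runif(n_total) * 10)           # 08:00-18:00
  })
  timestamp <- day_of_sample + hours / 24
  # keep acquisition chronological within the campaign
  ord <- order(timestamp)
  day_of_sample <- day_of_sample[ord]
  label_of_sample <- label_of_sample[ord]
  lighting <- lighting[ord]
  timestamp <- timestamp[ord]

  batch <- ifelse(day_of_sample < config$drift_onset_day, 1L, 2L)
  sample_id <- sprintf("s%04d", seq_len(n_total))

  traces <- vector("list", n_total)
  detections <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    tr <- simulate_trace(config, label_of_sample[i], day = timestamp[i],
                         seed = derive_seed(config$seed, 10 + i))
    tr$metadata$sample_id <- sample_id[i]
    tr$metadata$batch <- batch[i]
    traces[[i]] <- tr
    # note [i] <- list(...): night samples are NULL and must keep their slot
    detections[i] <- list(simulate_detections(config, label_of_sample[i], lighting[i],
                                              seed = derive_seed(config$seed, 5e5 + i)))
  }
  metadata <- data.frame(
    sample_id = sample_id, timestamp = timestamp, day = day_of_sample,
    batch = batch, label = label_of_sample, lighting = lighting,
    image_available = lighting != "night", stringsAsFactors = FALSE
  )
  structure(
    list(traces = traces, detections = detections, metadata = metadata,
         labels = factor(label_of_sample, levels = config$classes),
         day_index = day_of_sample, batch_id = batch,
         image_available = metadata$image_available,
         pattern = daq_pattern(config$pattern_id, config$sampling_rate),
         surfaces = config$surfaces, config = config),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset: %d samples (%s), %s, days 0-%d, %d%% night>\n",
              nrow(x$metadata),
              paste(sprintf("%d %s", table(x$labels), levels(x$labels)), collapse = ", "),
              x$config$pattern_id, max(x$day_index),
              round(100 * mean(!x$image_available))))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' One CSV per trace (`t_s, s1_v..s5_v, temp_c, rh_pct`), a metadata CSV,
#' and detections as JSON-lines (`{"sample_id": ..., "boxes": [...]}`,
#' pixel coordinates with origin top-left; night samples are omitted).
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in dataset$traces) {
    df <- data.frame(t_s = tr$time, t(tr$values), tr$env)
    names(df) <- c("t_s", paste0("s", 1:5, "_v"), "temp_c", "rh_pct")
    utils::write.csv(df, file.path(dir, paste0(tr$metadata$sample_id, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(dataset$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  con <- file(file.path(dir, "detections.jsonl"), "w")
  on.exit(close(con))
  for (i in seq_along(dataset$detections)) {
    det <- dataset$detections[[i]]
    if (is.null(det)) next
    writeLines(jsonlite::toJSON(
      list(sample_id = dataset$metadata$sample_id[i], boxes = det),
      auto_unbox = TRUE, digits = NA
    ), con)
  }
  invisible(dir)
}

#' Read a JSON-lines detection file
#'
#' @param path path to a `detections.jsonl` written by [write_dataset()].
#' @return named list of detection data.frames keyed by sample id.
#' @export
read_detections_jsonl <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines) {
    rec <- jsonlite::fromJSON(ln)
    boxes <- as.data.frame(rec$boxes)
    out[[rec$sample_id]] <- boxes
  }
  out
}
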