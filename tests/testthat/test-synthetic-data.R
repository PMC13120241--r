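test_that("simulated traces have protocol shape, env channels and seeded determinism", {
  cfg <- quick_config()
  tr <- simulate_trace(cfg, "ripe", day = 1.5, seed = 42)
  expect_s3_class(tr, "response_trace")
  expect_equal(dim(tr$values), c(5, 6000))
  expect_equal(nrow(tr$env), 6000)
  expect_true(all(is.finite(tr$values)))
  expect_identical(tr$values, simulate_trace(cfg, "ripe", 1.5, seed = 42)$values)
  expect_false(identical(tr$values,
                         simulate_trace(cfg, "ripe", 1.5, seed = 43)$values))
  cfg48 <- quick_config(pattern_id = "DAQ48")
  expect_equal(ncol(simulate_trace(cfg48, "ripe", 0, seed = 1)$values), 28800)
})

test_that("the degenerate null produces identical traces for both classes", {
  amp <- rbind(ripe = rep(1, 5), other = rep(1, 5))
  cfg <- clean_config(class_amplitudes = amp)
  a <- simulate_trace(cfg, "ripe", 0.4, seed = 9)
  b <- simulate_trace(cfg, "unripe", 0.4, seed = 9)
  expect_identical(a$values, b$values)
})

test_that("without drift the baseline on day 30 equals day 0", {
  cfg <- clean_config()
  t0 <- simulate_trace(cfg, "ripe", 0.25, seed = 3)
  t30 <- simulate_trace(cfg, "ripe", 30.25, seed = 3)
  # pre-heat onset: both start from the clean baseline
  expect_equal(t30$values[, 1], t0$values[, 1], tolerance = 1e-9)
  cfg_drift <- clean_config(drift_rate = 0.02, drift_onset_day = 0)
  t30d <- simulate_trace(cfg_drift, "ripe", 30.25, seed = 3)
  expect_equal(t30d$values[, 1] / t0$values[, 1], rep(1.6, 5), tolerance = 1e-9)
})

test_that("night samples have no detections; a degenerate detector is exact", {
  cfg <- quick_config()
  expect_null(simulate_detections(cfg, "ripe", "night", seed = 1))
  dq <- default_detect_quality()
  dq$well_lit$p <- c(ripe = 1, unripe = 1)
  dq$well_lit$conf <- list(ripe = c(1e6, 1e6 / 9), unripe = c(1e6, 1e6 / 9))
  dq$well_lit$flip <- 0
  cfg1 <- quick_config(detect_quality = dq,
                       fruit_counts = list(ripe = c(1, 1), unripe = c(0, 0)))
  det <- simulate_detections(cfg1, "ripe", "well_lit", seed = 2)
  expect_equal(nrow(det), 1)
  expect_equal(det$cls, "ripe")
  expect_equal(det$conf, 0.9, tolerance = 1e-3)
  expect_true(det$x1 < det$x2 && det$y1 < det$y2)
})

test_that("empirical detection rate matches the configured probability", {
  dq <- default_detect_quality()
  dq$well_lit$p <- c(ripe = 0.4, unripe = 0.4)
  dq$well_lit$flip <- 0
  cfg <- quick_config(detect_quality = dq,
                      fruit_counts = list(ripe = c(4, 4), unripe = c(0, 0)))
  hits <- vapply(1:2500, function(i) {
    nrow(simulate_detections(cfg, "ripe", "well_lit", seed = i))
  }, numeric(1))
  n_fruit <- 2500 * 4
  rate <- sum(hits) / n_fruit
  se <- sqrt(0.4 * 0.6 / n_fruit)
  expect_lt(abs(rate - 0.4), 3 * se)
})

test_that("detection-quality validation enforces the backlight ordering", {
  dq <- default_detect_quality()
  dq$backlit$p["ripe"] <- 0.99
  expect_error(quick_config(detect_quality = dq), "backlit")
  dq <- default_detect_quality()
  dq$backlit$conf$ripe <- c(20, 1)  # mean 0.95 > well-lit 0.8
  expect_error(quick_config(detect_quality = dq), "confidence")
})

test_that("datasets are balanced, chronological, batch-split and reproducible", {
  cfg <- sim_config(n_samples_per_class = 50, n_days = 10, seed = 3,
                    pattern_id = "DAQcont", cont_duration_s = 30,
                    drift_onset_day = 6)
  ds <- simulate_dataset(cfg)
  expect_length(ds$traces, 100)
  expect_length(ds$labels, 100)
  expect_equal(as.numeric(table(ds$labels)), c(50, 50))
  expect_true(all(diff(ds$metadata$timestamp) >= 0))
  expect_equal(ds$day_index, floor(ds$metadata$timestamp))
  expect_equal(ds$batch_id, ifelse(ds$day_index < 6, 1L, 2L))
  # one label per trace, night samples carry no detections
  for (i in seq_len(100)) {
    expect_equal(ds$traces[[i]]$metadata$label, as.character(ds$labels[i]))
    if (!ds$image_available[i]) expect_null(ds$detections[[i]])
  }
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds$metadata, ds2$metadata)
  expect_identical(ds$traces[[17]]$values, ds2$traces[[17]]$values)
})

test_that("the night fraction is respected at the configured rate", {
  cfg <- sim_config(n_samples_per_class = 500, n_days = 20, seed = 8,
                    pattern_id = "DAQcont", cont_duration_s = 3,
                    night_fraction = 0.5)
  ds <- simulate_dataset(cfg)
  frac <- mean(!ds$image_available)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("wider class amplitude gaps never reduce linear-classifier CV accuracy", {
  gaps <- c(1.0, 0.85, 0.6)  # second-class amplitude as a fraction of the first
  accs <- vapply(gaps, function(g) {
    amp <- rbind(ripe = c(1.20, 1.00, 1.50, 1.30, 1.10),
                 other = g * c(1.20, 1.00, 1.50, 1.30, 1.10))
    cfg <- sim_config(n_samples_per_class = 12, n_days = 8, seed = 21,
                      class_amplitudes = amp, day_noise_sd = 0.05,
                      surfaces = NULL)
    ds <- simulate_dataset(cfg)
    X <- feature_table(ds, "small")
    plan <- make_cv_plan(ds$metadata, "stratified_kfold", k = 4, seed = 2)
    run_suite(X, ds$labels, plan, models = "lr", base_seed = 5)$metrics$accuracy_mean
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("datasets round-trip through the CSV/JSON-lines disk format", {
  cfg <- sim_config(n_samples_per_class = 3, n_days = 4, seed = 13,
                    pattern_id = "DAQcont", cont_duration_s = 10)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  md <- read.csv(file.path(dir, "metadata.csv"))
  expect_equal(nrow(md), 6)
  tr <- read.csv(file.path(dir, paste0(md$sample_id[1], ".csv")))
  expect_equal(names(tr), c("t_s", paste0("s", 1:5, "_v"), "temp_c", "rh_pct"))
  expect_equal(unname(as.matrix(tr[, 2:6])), unname(t(ds$traces[[1]]$values)),
               tolerance = 1e-6)
  dets <- read_detections_jsonl(file.path(dir, "detections.jsonl"))
  avail <- md$sample_id[md$image_available]
  expect_setequal(names(dets), avail)
})
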