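# Small simulation configurations reused across test files. Trace length
# is the dominant cost, so most tests run on DAQ10 (6000 points) with few
# samples, or on short DAQcont traces when only metadata-level structure
# matters.

quick_config <- function(...) {
  config_with(list(n_samples_per_class = 5, n_days = 6, seed = 11), ...)
}

# Noise-free, distortion-free, drift-free configuration for exactness
# checks.
clean_config <- function(...) {
  config_with(list(n_samples_per_class = 2, n_days = 4, noise_sd = 0,
                   day_noise_sd = 0, drift_rate = 0, surfaces = NULL,
                   seed = 7), ...)
}

config_with <- function(defaults, ...) {
  args <- utils::modifyList(defaults, list(...), keep.null = TRUE)
  do.call(sim_config, args)
}

# Gaussian two-class blobs for classifier-level tests that do not need
# the trace machinery.
make_blobs <- function(n_per_class, d = 10, gap = 2, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = gap), ncol = d))
  rownames(x) <- sprintf("b%04d", seq_len(2 * n_per_class))
  list(x = x, y = factor(rep(c("ripe", "unripe"), each = n_per_class)))
}
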