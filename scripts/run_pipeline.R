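#!/usr/bin/env Rscript
# Thin command-line wrapper over odourfusion::run_pipeline(): simulates a
# campaign under the default study conditions and writes every artifact
# (feature table, prediction CSVs, metrics JSON, fusion report, manifest).
#
# Usage: Rscript scripts/run_pipeline.R [--seed <int>] [--out <dir>]
#          [--pattern DAQ10|DAQ48] [--n <samples per class>]
#          [--feature-set large|small] [--correction off|features|response]
#          [--cv stratified_kfold|leave_k_day_out|group_24h]
#          [--models lr,rf,xgb,svm,mlp,elm]

suppressPackageStartupMessages(library(odourfusion))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, out = "pipeline_out", pattern = "DAQ10", n = 30L,
            feature_set = "large", correction = "off",
            cv = "stratified_kfold", models = "lr,rf,elm")
i <- 1
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  key <- gsub("-", "_", key)
  if (!key %in% names(opt)) stop("unknown argument: ", args[i])
  opt[[key]] <- args[i + 1]
  i <- i + 2
}

cfg <- pipeline_config(
  sim = sim_config(n_samples_per_class = as.integer(opt$n),
                   pattern_id = opt$pattern, seed = as.integer(opt$seed)),
  feature_set = opt$feature_set, correction = opt$correction,
  cv_scheme = opt$cv,
  models = strsplit(opt$models, ",")[[1]],
  seed = as.integer(opt$seed), out_dir = opt$out
)
bundle <- run_pipeline(cfg)
print(bundle)
cat("artifacts written to", opt$out, "\n")
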