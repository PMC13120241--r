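test_that("maximum-confidence fusion picks the more confident modality", {
  od <- prediction("s1", "ripe", 0.6, "odour")
  im <- prediction("s1", "unripe", 0.9, "image")
  expect_equal(fuse_max_confidence(od, im), "unripe")
  im_na <- prediction("s1", NA, NA, "image", available = FALSE)
  expect_equal(fuse_max_confidence(od, im_na), "ripe")
  tie <- prediction("s1", "unripe", 0.6, "image")
  expect_equal(fuse_max_confidence(od, tie), "ripe")  # ties go to odour
  od_na <- prediction("s1", NA, NA, "odour", available = FALSE)
  expect_error(fuse_max_confidence(od_na, im), "available")
  # fused label is always one of the inputs' labels
  set.seed(5)
  for (i in 1:20) {
    o <- prediction("x", sample(c("ripe", "unripe"), 1), runif(1), "odour")
    m <- prediction("x", sample(c("ripe", "unripe"), 1), runif(1), "image")
    expect_true(fuse_max_confidence(o, m) %in% c(o$label, m$label))
  }
})

test_that("majority voting follows the plurality with documented tie-breaks", {
  votes <- rbind(prediction("s", "ripe", 0.7, "odour"),
                 prediction("s", "ripe", 0.6, "odour"),
                 prediction("s", "unripe", 0.99, "image"))
  expect_equal(fuse_majority(votes), "ripe")
  unanimous <- rbind(prediction("s", "unripe", 0.5, "odour"),
                     prediction("s", "unripe", 0.6, "odour"),
                     prediction("s", "unripe", 0.7, "image"))
  expect_equal(fuse_majority(unanimous), "unripe")
  # unavailable voter dropped; < 3 remain -> max-confidence fallback
  fallback <- rbind(prediction("s", "ripe", 0.8, "odour"),
                    prediction("s", "unripe", 0.6, "odour"),
                    prediction("s", NA, NA, "image", available = FALSE))
  expect_equal(fuse_majority(fallback), "ripe")
  # even split among 4 voters: highest confidence decides
  split4 <- rbind(prediction("s", "ripe", 0.55, "odour"),
                  prediction("s", "ripe", 0.60, "odour"),
                  prediction("s", "unripe", 0.95, "odour"),
                  prediction("s", "unripe", 0.40, "image"))
  expect_equal(fuse_majority(split4), "unripe")
  expect_error(fuse_majority(fallback[3, ]), "no available voters")
})

test_that("agreement analysis enumerates the stated rule", {
  odour <- do.call(rbind, Map(prediction, paste0("s", 1:4),
                              c("ripe", "ripe", "unripe", "unripe"),
                              0.7, "odour"))
  image <- rbind(prediction("s1", "ripe", 0.9, "image"),
                 prediction("s2", "unripe", 0.9, "image"),
                 prediction("s3", NA, NA, "image", available = FALSE),
                 prediction("s4", "unripe", 0.9, "image"))
  truth <- c("ripe", "ripe", "unripe", "unripe")
  ag <- agreement_analysis(odour, image, truth)
  expect_equal(ag$n_agreed, 2)          # samples 1 and 4
  expect_equal(ag$fraction_agreed, 0.5)
  expect_equal(ag$accuracy_on_agreed, 1)
  # identical always-available predictions: fraction 1, agreed = overall
  same <- do.call(rbind, Map(prediction, paste0("s", 1:4),
                             c("ripe", "unripe", "unripe", "unripe"),
                             0.8, "image"))
  odour2 <- same
  odour2$modality <- "odour"
  ag2 <- agreement_analysis(odour2, same, truth)
  expect_equal(ag2$fraction_agreed, 1)
  expect_equal(ag2$accuracy_on_agreed, mean(same$label == truth))
  # image never available
  dark <- do.call(rbind, lapply(paste0("s", 1:4), function(id)
    prediction(id, NA, NA, "image", available = FALSE)))
  expect_equal(agreement_analysis(odour, dark, truth)$fraction_agreed, 0)
})

test_that("fusion recovers the completeness lost to missing images", {
  # image perfect when available (50% of samples), odour 70% overall
  set.seed(42)
  n <- 1000
  truth <- sample(c("ripe", "unripe"), n, replace = TRUE)
  avail <- rep(c(TRUE, FALSE), length.out = n)
  odour_ok <- runif(n) < 0.7
  odour <- do.call(rbind, lapply(1:n, function(i) {
    lab <- if (odour_ok[i]) truth[i] else setdiff(c("ripe", "unripe"), truth[i])
    prediction(i, lab, 0.6, "odour")
  }))
  image <- do.call(rbind, lapply(1:n, function(i) {
    if (avail[i]) prediction(i, truth[i], 1.0, "image")
    else prediction(i, NA, NA, "image", available = FALSE)
  }))
  rep <- fusion_report(odour, image, truth, strategies = "max_confidence")
  tab <- rep$table
  fused_acc <- tab$accuracy[tab$source == "fused_max_confidence"]
  image_all <- tab$accuracy[tab$source == "image_all"]
  expect_gt(fused_acc, image_all)
  # when image is available everywhere with confidence 1, fusion = image
  image_full <- do.call(rbind, lapply(1:n, function(i) {
    prediction(i, truth[i], 1.0, "image")
  }))
  rep2 <- fusion_report(odour, image_full, truth, strategies = "max_confidence")
  expect_equal(rep2$fused$max_confidence, image_full$label)
  # one strategy -> exactly one fused row plus three baselines
  expect_equal(nrow(rep$table), 4)
  # deterministic on rerun
  rep3 <- fusion_report(odour, image, truth, strategies = "max_confidence")
  expect_identical(rep$table, rep3$table)
})
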