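test_that("balanced class weights counteract imbalance", {
  w <- class_weights(rep(c("ripe", "unripe"), c(25, 75)))
  expect_equal(unname(w["ripe"]), 2.0)
  expect_equal(unname(w["unripe"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(class_weights(rep(c("a", "b"), 10))), c(1, 1))
  labels <- rep(c("ripe", "unripe"), c(30, 70))
  w <- class_weights(labels)
  expect_equal(mean(w[labels]), 1)  # weighted mean identity
  expect_error(class_weights(factor(rep("a", 3), levels = c("a", "b"))), "empty")
})

test_that("stratified folds balance labels and never overlap", {
  md <- data.frame(label = rep(c("ripe", "unripe"), each = 50),
                   day = rep(0:24, 4))
  plan <- make_cv_plan(md, "stratified_kfold", k = 10, seed = 1)
  expect_length(plan$folds, 10)
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_equal(as.numeric(table(md$label[f$test])), c(5, 5))
  }
  expect_equal(sort(unlist(lapply(plan$folds, `[[`, "test"))), 1:100)
})

test_that("leave-k-day-out blocks contiguous days with disjoint day sets", {
  md <- data.frame(label = rep(c("ripe", "unripe"), 50),
                   day = sort(rep(0:24, 4)))
  plan <- make_cv_plan(md, "leave_k_day_out", block_days = 5)
  expect_length(plan$folds, 5)
  for (f in plan$folds) {
    test_days <- unique(md$day[f$test])
    expect_length(test_days, 5)
    expect_equal(sort(test_days), min(test_days):max(test_days))  # contiguous
    expect_length(intersect(test_days, md$day[f$train]), 0)
  }
  expect_error(make_cv_plan(data.frame(label = "a", day = 1),
                            "leave_k_day_out", block_days = 5), "fewer")
})

test_that("24-hour group folds never split a day across train and test", {
  set.seed(3)
  md <- data.frame(label = sample(c("ripe", "unripe"), 120, replace = TRUE),
                   day = sort(runif(120, 0, 12)))
  plan <- make_cv_plan(md, "group_24h", k = 5, seed = 2)
  for (f in plan$folds) {
    expect_length(intersect(floor(md$day[f$test]), floor(md$day[f$train])), 0)
  }
})

test_that("the ELM separates blobs, is seed-deterministic and shrinks under ridge", {
  blobs <- make_blobs(40, d = 5, gap = 3, seed = 2)
  m <- train_elm(blobs$x, blobs$y, hidden_units = 200, seed = 7)
  pr <- predict_elm(m, blobs$x)
  expect_gte(mean(pr$label == as.character(blobs$y)), 0.99)
  m2 <- train_elm(blobs$x, blobs$y, hidden_units = 200, seed = 7)
  expect_identical(predict_elm(m2, blobs$x), pr)
  big <- train_elm(blobs$x, blobs$y, hidden_units = 50, ridge = 1e12, seed = 7)
  pb <- predict_elm(big, blobs$x)
  expect_true(all(abs(pb$confidence - 0.5) < 1e-6))
  expect_error(train_elm(blobs$x, blobs$y, hidden_units = 0))
})

test_that("the ELM solve matches the augmented least-squares oracle", {
  for (seed in 1:5) {
    blobs <- make_blobs(20, d = 6, gap = 1, seed = seed)
    w <- as.numeric(class_weights(blobs$y)[as.character(blobs$y)])
    m <- train_elm(blobs$x, blobs$y, hidden_units = 30, ridge = 1e-2,
                   seed = seed, weights = w)
    beta_o <- elm_beta_oracle(m, blobs$x, blobs$y, w)
    expect_lt(max(abs(m$beta - beta_o)), 1e-8)
  }
})

test_that("metrics match direct arithmetic including zero-division handling", {
  m <- compute_metrics(c(rep("a", 9), "b"), rep("a", 10), classes = c("a", "b"))
  expect_equal(m$accuracy, 0.9)
  pred <- rep("ripe", 20)
  truth <- rep(c("ripe", "unripe"), 10)
  m <- compute_metrics(pred, truth, c("ripe", "unripe"))
  expect_equal(unname(m$recall), c(1, 0))
  expect_true(m$zero_division)
  # confusion [[40, 8], [2, 50]]
  truth <- rep(c("c1", "c2"), c(48, 52))
  pred <- c(rep("c1", 40), rep("c2", 8), rep("c1", 2), rep("c2", 50))
  m <- compute_metrics(pred, truth, c("c1", "c2"))
  expect_equal(m$accuracy, 0.90)
  expect_equal(unname(m$precision["c1"]), 40 / 42, tolerance = 1e-12)
  expect_equal(rowSums(m$confusion), c(c1 = 48, c2 = 52))
  expect_error(compute_metrics("a", c("a", "b")), "mismatch")
})

test_that("every suite model learns separable blobs under cross-validation", {
  blobs <- make_blobs(30, d = 8, gap = 3, seed = 4)
  md <- data.frame(label = blobs$y)
  plan <- make_cv_plan(md, "stratified_kfold", k = 5, seed = 1)
  suite <- run_suite(blobs$x, blobs$y, plan,
                     models = c("lr", "rf", "xgb", "svm", "mlp", "elm"),
                     base_seed = 9)
  expect_true(all(suite$metrics$accuracy_mean >= 0.95))
  expect_equal(nrow(suite$predictions), 6 * 60)
  # one prediction per sample per model
  expect_true(all(table(suite$predictions$model) == 60))
})

test_that("a suite rerun with identical seeds reproduces the report exactly", {
  blobs <- make_blobs(15, d = 4, gap = 2, seed = 6)
  plan <- make_cv_plan(data.frame(label = blobs$y), "stratified_kfold",
                       k = 3, seed = 2)
  s1 <- run_suite(blobs$x, blobs$y, plan, models = c("lr", "elm"), base_seed = 4)
  s2 <- run_suite(blobs$x, blobs$y, plan, models = c("lr", "elm"), base_seed = 4)
  expect_identical(s1$metrics, s2$metrics)
  expect_identical(s1$predictions, s2$predictions)
  expect_error(run_suite(blobs$x, blobs$y, plan, models = "nonsense"), "unknown")
})

test_that("suite_predictions yields one odour prediction record per sample", {
  blobs <- make_blobs(15, d = 4, gap = 2, seed = 6)
  plan <- make_cv_plan(data.frame(label = blobs$y), "stratified_kfold",
                       k = 3, seed = 2)
  suite <- run_suite(blobs$x, blobs$y, plan, models = "elm", base_seed = 4)
  op <- suite_predictions(suite, "elm")
  expect_equal(sort(op$sample_id), sort(rownames(blobs$x)))
  expect_true(all(op$modality == "odour"))
  expect_true(all(op$confidence >= 0 & op$confidence <= 1))
})
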