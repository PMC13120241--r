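#' Balanced class weights
#'
#' Weight `n_total / (n_classes * n_c)` for a sample of class `c`, so that
#' every class contributes equally to the loss regardless of imbalance.
#' The weighted mean of the per-sample weights is always 1.
#'
#' @param labels factor or character vector of class labels.
#' @return named numeric vector of per-class weights.
#' @examples
#' class_weights(rep(c("ripe", "unripe"), c(25, 75)))  # 2.0, 0.6667
#' @export
class_weights <- function(labels) {
  tab <- table(labels)
  if (any(tab == 0)) stop("empty class: ", paste(names(tab)[tab == 0], collapse = ", "))
  w <- length(labels) / (length(tab) * as.numeric(tab))
  stats::setNames(w, names(tab))
}

#' Build a cross-validation plan
#'
#' Three schemes matching how temporally correlated acquisition campaigns
#' should (and should not) be evaluated:
#' * `stratified_kfold` — label-stratified k folds with seeded shuffling.
#'   Temporally close samples land on both sides of a split, so this is
#'   optimistic when day-level effects exist.
#' * `leave_k_day_out` — unique days sorted chronologically and partitioned
#'   into contiguous blocks of `block_days` days; each block is the test
#'   set once. No day appears on both sides of any fold.
#' * `group_24h` — samples grouped into 24-hour windows; whole groups are
#'   assigned to folds with greedy label balancing, so no 24-h group is
#'   split across train and test.
#'
#' @param metadata data.frame with columns `label` and (for the block
#'   schemes) `day`.
#' @param scheme one of the three schemes.
#' @param k number of folds for the stratified/group schemes.
#' @param block_days days per held-out block for `leave_k_day_out`.
#' @param seed seed for the stratified shuffles.
#' @return object of class `cv_plan`: list of folds, each with integer
#'   `train` and `test` indices, plus the scheme and parameters.
#' @export
make_cv_plan <- function(metadata,
                         scheme = c("stratified_kfold", "leave_k_day_out", "group_24h"),
                         k = 10, block_days = 5, seed = 1) {
  scheme <- match.arg(scheme)
  labels <- as.character(metadata$label)
  n <- length(labels)
  folds <- switch(scheme,
    stratified_kfold = {
      assign <- integer(n)
      for (cl in unique(labels)) {
        idx <- with_seed(derive_seed(seed, match(cl, unique(labels))),
                         sample(which(labels == cl)))
        assign[idx] <- rep_len(seq_len(k), length(idx))
      }
      lapply(seq_len(k), function(f) {
        list(train = which(assign != f), test = which(assign == f))
      })
    },
    leave_k_day_out = {
      if (is.null(metadata$day)) stop("day indices required for leave_k_day_out")
      days <- sort(unique(metadata$day))
      if (length(days) < block_days) stop("fewer distinct days than one block")
      blocks <- split(days, ceiling(seq_along(days) / block_days))
      lapply(blocks, function(b) {
        test <- which(metadata$day %in% b)
        list(train = setdiff(seq_len(n), test), test = test)
      })
    },
    group_24h = {
      if (is.null(metadata$day)) stop("day indices required for group_24h")
      groups <- floor(metadata$day)
      ug <- with_seed(derive_seed(seed, 7), sample(unique(groups)))
      # greedy: place each 24-h group in the fold where it least worsens
      # the per-class balance
      classes <- sort(unique(labels))
      counts <- matrix(0, nrow = k, ncol = length(classes),
                       dimnames = list(NULL, classes))
      gsizes <- vapply(ug, function(g) sum(groups == g), numeric(1))
      ug <- ug[order(-gsizes)]
      fold_of_group <- stats::setNames(integer(length(ug)), ug)
      for (g in ug) {
        gc <- table(factor(labels[groups == g], levels = classes))
        cost <- vapply(seq_len(k), function(f) {
          trial <- counts
          trial[f, ] <- trial[f, ] + as.numeric(gc)
          sum(apply(trial, 2, function(col) max(col) - min(col)))
        }, numeric(1))
        f <- which.min(cost)
        counts[f, ] <- counts[f, ] + as.numeric(gc)
        fold_of_group[as.character(g)] <- f
      }
      assign <- fold_of_group[as.character(groups)]
      keep <- sort(unique(assign))
      lapply(keep, function(f) {
        list(train = which(assign != f), test = which(assign == f))
      })
    }
  )
  folds <- unname(folds)
  for (f in folds) stopifnot(length(intersect(f$train, f$test)) == 0)
  structure(list(folds = folds, scheme = scheme, k = k,
                 block_days = block_days, seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan %s: %d folds, test sizes %s>\n", x$scheme,
              length(x$folds),
              paste(vapply(x$folds, function(f) length(f$test), numeric(1)),
                    collapse = "/")))
  invisible(x)
}

#' Extreme learning machine
#'
#' A single-hidden-layer network whose input weights and biases are drawn
#' at random (uniform on `[-1, 1]`, seeded) and never trained; only the
#' output weights are fitted, by (class-weighted) ridge-regularised least
#' squares on +/-1 targets against the sigmoid hidden activations. Training
#' is a single linear solve, and predictions are deterministic given the
#' seed. The prediction confidence is the logistic of the absolute margin,
#' so infinite ridge shrinks all confidences to 0.5.
#'
#' @param x numeric feature matrix (rows = samples), already scaled.
#' @param y factor with two levels; the second level maps to target +1.
#' @param hidden_units number of hidden neurons.
#' @param ridge ridge penalty on the output weights.
#' @param seed seed for the random input layer.
#' @param weights optional per-sample weights (e.g. from
#'   [class_weights()]).
#' @return object of class `elm_model`.
#' @export
train_elm <- function(x, y, hidden_units = 200, ridge = 1e-3, seed = 1,
                      weights = NULL) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  stopifnot(hidden_units >= 1, nlevels(y) == 2, nrow(x) == length(y))
  if (is.null(weights)) weights <- rep(1, nrow(x))
  d <- ncol(x)
  wb <- with_seed(seed, list(
    W = matrix(stats::runif(d * hidden_units, -1, 1), d, hidden_units),
    b = stats::runif(hidden_units, -1, 1)
  ))
  H <- elm_hidden(x, wb$W, wb$b)
  t_target <- ifelse(y == levels(y)[2], 1, -1)
  # weighted ridge normal equations: (H' Λ H + λI) β = H' Λ t
  A <- crossprod(H, H * weights) + diag(ridge, hidden_units)
  beta <- solve(A, crossprod(H, weights * t_target))
  structure(list(W = wb$W, b = wb$b, beta = beta, levels = levels(y),
                 hidden_units = hidden_units, ridge = ridge, seed = seed),
            class = "elm_model")
}

elm_hidden <- function(x, W, b) {
  stats::plogis(sweep(as.matrix(x) %*% W, 2, b, "+"))
}

#' @rdname train_elm
#' @param model a fitted `elm_model`.
#' @param sample_ids optional ids attached to the returned predictions.
#' @return `predict_elm()`: data.frame of prediction records (one row per
#'   sample: `sample_id, label, confidence, modality, available`).
#' @export
predict_elm <- function(model, x, sample_ids = NULL) {
  stopifnot(inherits(model, "elm_model"))
  x <- as.matrix(x)
  margin <- as.numeric(elm_hidden(x, model$W, model$b) %*% model$beta)
  label <- model$levels[(margin > 0) + 1]
  conf <- stats::plogis(abs(margin))
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(x)))
  do.call(rbind, lapply(seq_along(label), function(i) {
    prediction(sample_ids[i], label[i], conf[i], "odour")
  }))
}

# ---- model dispatcher -------------------------------------------------------
# Standard classifiers delegate to established implementations; the ELM is
# native. Each fit returns an object usable by predict_suite_model(), and
# every model receives balanced class weights and a seed.

fit_suite_model <- function(name, x, y, seed, params = list()) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  cw <- class_weights(y)
  w <- as.numeric(cw[as.character(y)])
  y01 <- as.numeric(y == levels(y)[2])
  set.seed(seed)
  fit <- switch(name,
    lr = suppressWarnings(stats::glm.fit(cbind(1, x), y01, weights = w,
                                         family = stats::binomial())),
    rf = randomForest::randomForest(x, y, ntree = params$ntree %||% 300,
                                    classwt = cw),
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.3, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y01, weight = w),
      nrounds = params$nrounds %||% 50, verbose = 0
    ),
    svm = e1071::svm(x, y, kernel = "radial", class.weights = cw,
                     probability = TRUE),
    mlp = nnet::nnet(x, y01, size = params$size %||% 16,
                     decay = params$decay %||% 1e-3,
                     maxit = params$maxit %||% 300, entropy = TRUE,
                     weights = w, trace = FALSE, MaxNWts = 1e5),
    elm = train_elm(x, y, hidden_units = params$hidden_units %||% 200,
                    ridge = params$ridge %||% 1e-3, seed = seed, weights = w),
    stop("unknown model name: ", name)
  )
  list(name = name, fit = fit, levels = levels(y))
}

predict_suite_model <- function(model, x) {
  x <- as.matrix(x)
  lv <- model$levels
  p_pos <- switch(model$name,
    lr = {
      # rank-deficient fits (p > n) leave aliased coefficients as NA
      co <- model$fit$coefficients
      co[is.na(co)] <- 0
      as.numeric(stats::plogis(cbind(1, x) %*% co))
    },
    rf = stats::predict(model$fit, x, type = "prob")[, lv[2]],
    xgb = as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(x))),
    svm = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      probs <- attr(pr, "probabilities")
      if (!is.null(probs) && lv[2] %in% colnames(probs)) {
        as.numeric(probs[, lv[2]])
      } else {
        dv <- attr(stats::predict(model$fit, x, decision.values = TRUE),
                   "decision.values")
        sgn <- if (grepl(paste0("^", lv[2], "/"), colnames(dv)[1])) 1 else -1
        as.numeric(stats::plogis(sgn * dv[, 1]))
      }
    },
    mlp = as.numeric(stats::predict(model$fit, x)),
    elm = {
      margin <- as.numeric(elm_hidden(x, model$fit$W, model$fit$b) %*% model$fit$beta)
      stats::plogis(margin)
    }
  )
  p_pos <- pmin(pmax(p_pos, 0), 1)
  data.frame(label = lv[(p_pos > 0.5) + 1],
             confidence = pmax(p_pos, 1 - p_pos),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classification metrics
#'
#' Accuracy (correct / total), per-class precision (correct predictions
#' for the class / predictions of the class) and recall (correct
#' predictions for the class / instances of the class), macro-averaged F1,
#' and the confusion matrix (rows = truth, columns = prediction). Undefined
#' ratios (zero denominators) are reported as 0 and flagged.
#'
#' @param predicted predicted labels (character/factor), aligned with
#'   `truth`.
#' @param truth true labels.
#' @param classes class order for the report; defaults to the union of
#'   observed labels.
#' @return list of class `metrics_report`: `accuracy`, `precision`,
#'   `recall`, `f1`, `confusion`, `zero_division`.
#' @export
compute_metrics <- function(predicted, truth, classes = NULL) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, levels = classes), factor(predicted, levels = classes))
  acc <- sum(diag(cm)) / sum(cm)
  zero_flag <- FALSE
  prec <- rec <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    np <- sum(cm[, cl])
    ni <- sum(cm[cl, ])
    prec[cl] <- if (np > 0) cm[cl, cl] / np else {zero_flag <- TRUE; 0}
    rec[cl] <- if (ni > 0) cm[cl, cl] / ni else {zero_flag <- TRUE; 0}
  }
  f1c <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(accuracy = acc, precision = prec, recall = rec,
                 f1 = mean(f1c), f1_per_class = f1c, confusion = cm,
                 zero_division = zero_flag),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f, macro-F1 %.4f\n", x$accuracy, x$f1))
  print(round(rbind(precision = x$precision, recall = x$recall), 4))
  invisible(x)
}

#' Run the classifier suite under a cross-validation plan
#'
#' For every model, repeat and fold: fit on the training side with
#' balanced class weights (features min-max scaled with train-only
#' fitting), predict the test side, and aggregate accuracy and macro
#' metrics as mean and s.d. over repeats. Per-sample prediction records are
#' retained for decision fusion.
#'
#' @param x feature matrix (samples x features), unscaled; scaling is
#'   fitted within each training fold.
#' @param y factor of labels.
#' @param plan a [make_cv_plan()].
#' @param models character vector among
#'   `"lr", "rf", "xgb", "svm", "mlp", "elm"`.
#' @param n_repeats number of repeated runs with different seeds.
#' @param base_seed seed from which the repeat seeds are derived.
#' @param scale whether to min-max scale features per training fold.
#' @param params optional named list of per-model parameter lists.
#' @return object of class `suite_result`: `metrics` (one row per model:
#'   mean/sd accuracy, macro F1, precision and recall means),
#'   `predictions` (data.frame `sample_id, model, fold, rep, label_pred,
#'   confidence`), `per_repeat` accuracies, and the plan.
#' @export
run_suite <- function(x, y, plan, models = c("lr", "rf", "elm"),
                      n_repeats = 1, base_seed = 1, scale = TRUE,
                      params = list()) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  stopifnot(inherits(plan, "cv_plan"), nrow(x) == length(y))
  sample_ids <- rownames(x)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(x)))
  preds <- list()
  rep_acc <- list()
  for (model in models) {
    for (r in seq_len(n_repeats)) {
      seed_r <- derive_seed(base_seed, 1000 * match(model, models) + r)
      pl <- pt <- character(0)
      for (fi in seq_along(plan$folds)) {
        fold <- plan$folds[[fi]]
        xtr <- x[fold$train, , drop = FALSE]
        xte <- x[fold$test, , drop = FALSE]
        if (scale) {
          sc <- fit_scaler(xtr)
          xtr <- suppressWarnings(apply_scaler(sc, xtr))
          xte <- suppressWarnings(apply_scaler(sc, xte))
        }
        fit <- fit_suite_model(model, xtr, y[fold$train],
                               seed = derive_seed(seed_r, fi),
                               params = params[[model]] %||% list())
        pr <- predict_suite_model(fit, xte)
        preds[[length(preds) + 1L]] <- data.frame(
          sample_id = sample_ids[fold$test], model = model, fold = fi,
          rep = r, label_pred = pr$label, confidence = pr$confidence,
          stringsAsFactors = FALSE
        )
        pl <- c(pl, pr$label)
        pt <- c(pt, as.character(y[fold$test]))
      }
      rep_acc[[length(rep_acc) + 1L]] <- data.frame(
        model = model, rep = r, accuracy = mean(pl == pt),
        f1 = compute_metrics(pl, pt, levels(y))$f1,
        stringsAsFactors = FALSE
      )
    }
  }
  preds <- do.call(rbind, preds)
  rep_acc <- do.call(rbind, rep_acc)
  metrics <- do.call(rbind, lapply(models, function(m) {
    a <- rep_acc$accuracy[rep_acc$model == m]
    f <- rep_acc$f1[rep_acc$model == m]
    pm <- preds[preds$model == m, ]
    truth <- as.character(y)[match(pm$sample_id, sample_ids)]
    rep_metrics <- compute_metrics(pm$label_pred, truth, levels(y))
    data.frame(model = m, accuracy_mean = mean(a), accuracy_sd = stats::sd(a),
               f1_mean = mean(f),
               precision_1 = rep_metrics$precision[1],
               precision_2 = rep_metrics$precision[2],
               recall_1 = rep_metrics$recall[1],
               recall_2 = rep_metrics$recall[2],
               stringsAsFactors = FALSE)
  }))
  rownames(metrics) <- NULL
  structure(list(metrics = metrics, predictions = preds,
                 per_repeat = rep_acc, plan = plan, classes = levels(y)),
            class = "suite_result")
}

#' @export
print.suite_result <- function(x, ...) {
  cat(sprintf("<suite_result: %s CV, %d folds>\n", x$plan$scheme,
              length(x$plan$folds)))
  print(transform(x$metrics,
                  accuracy_mean = round(accuracy_mean, 4),
                  accuracy_sd = round(accuracy_sd, 4),
                  f1_mean = round(f1_mean, 4))[, c("model", "accuracy_mean",
                                                   "accuracy_sd", "f1_mean")],
        row.names = FALSE)
  invisible(x)
}

#' Per-sample odour predictions from a suite run
#'
#' Extracts one prediction record per sample for a given model (first
#' repeat by default): under cross-validation each sample is predicted
#' exactly once per repeat, when it falls in the test fold.
#'
#' @param suite a `suite_result`.
#' @param model model name.
#' @param rep which repeat to take.
#' @return data.frame of prediction records in metadata order.
#' @export
suite_predictions <- function(suite, model, rep = 1) {
  p <- suite$predictions
  p <- p[p$model == model & p$rep == rep, ]
  p <- p[!duplicated(p$sample_id), ]
  do.call(rbind, lapply(seq_len(nrow(p)), function(i) {
    prediction(p$sample_id[i], p$label_pred[i], p$confidence[i], "odour")
  }))
}
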