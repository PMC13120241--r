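#' Maximum-confidence fusion of two predictions
#'
#' The fused label is the label of the higher-confidence modality. When
#' the image modality is unavailable (night), the odour prediction is used
#' unchanged — the odour side is always available, which is where the
#' completeness gain of the multimodal system comes from. Exact confidence
#' ties go to the odour modality.
#'
#' @param odour one-row prediction data.frame, always available.
#' @param image one-row prediction data.frame, possibly unavailable.
#' @return the fused label (character scalar).
#' @export
fuse_max_confidence <- function(odour, image) {
  if (!isTRUE(odour$available)) stop("odour prediction must be available")
  if (!isTRUE(image$available)) return(odour$label)
  if (image$confidence > odour$confidence) image$label else odour$label
}

#' Majority-vote fusion
#'
#' The most frequent label among the available voters wins. Unavailable
#' voters are dropped first; if fewer than 3 remain the vote degenerates
#' and the decision falls back to maximum confidence over the remainder.
#' An even split among >= 3 voters is decided by the highest-confidence
#' voter.
#'
#' @param predictions data.frame of prediction records (>= 3 voters,
#'   e.g. two odour models and one image model).
#' @return the fused label (character scalar).
#' @export
fuse_majority <- function(predictions) {
  avail <- predictions[predictions$available, , drop = FALSE]
  if (nrow(avail) == 0) stop("no available voters")
  if (nrow(avail) < 3) {
    return(avail$label[which.max(avail$confidence)])
  }
  tab <- table(avail$label)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) return(top)
  cand <- avail[avail$label %in% top, , drop = FALSE]
  cand$label[which.max(cand$confidence)]
}

#' Agreement analysis between the two modalities
#'
#' A sample "agrees" when the image modality produced a prediction and
#' both modalities output the same label. The subset of agreeing samples
#' acts as a high-confidence selector: when the two independent error
#' processes coincide on a label it is very likely correct, which is the
#' basis for using agreement as an automatic pseudolabeling rule.
#'
#' @param odour,image prediction data.frames aligned with `labels`.
#' @param labels true labels.
#' @return list with `n_agreed`, `fraction_agreed` (of all samples) and
#'   `accuracy_on_agreed` (`NA` when nothing agrees).
#' @export
agreement_analysis <- function(odour, image, labels) {
  stopifnot(nrow(odour) == length(labels), nrow(image) == length(labels))
  agree <- image$available & odour$label == image$label
  agree[is.na(agree)] <- FALSE
  n <- sum(agree)
  acc <- if (n > 0) mean(odour$label[agree] == as.character(labels)[agree]) else NA_real_
  list(n_agreed = n, fraction_agreed = n / length(labels), accuracy_on_agreed = acc)
}

#' Fusion report
#'
#' Evaluates the requested fusion strategies for one odour model against
#' the image modality, alongside the unimodal baselines (odour accuracy,
#' and image accuracy both over available samples and projected over all
#' samples counting missing images as errors), and the agreement triple.
#'
#' @param odour prediction data.frame of the odour model, aligned with
#'   `labels`.
#' @param image prediction data.frame of the image modality.
#' @param labels true labels.
#' @param strategies subset of `"max_confidence"`, `"majority"`.
#' @param voters optional list of additional odour prediction data.frames
#'   used (with `odour` and `image`) in the majority vote; without them
#'   the majority falls back to max-confidence over two voters.
#' @return object of class `fusion_result` with elements `table` (one row
#'   per baseline and strategy: accuracy and macro F1), `agreement`,
#'   and `fused` (per-sample fused labels per strategy).
#' @export
fusion_report <- function(odour, image, labels,
                          strategies = c("max_confidence", "majority"),
                          voters = NULL) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  labels <- as.character(labels)
  n <- length(labels)
  stopifnot(nrow(odour) == n, nrow(image) == n)
  rows <- list()
  add_row <- function(name, pred_labels) {
    m <- compute_metrics(pred_labels, labels)
    rows[[length(rows) + 1L]] <<- data.frame(
      source = name, accuracy = m$accuracy, f1 = m$f1, stringsAsFactors = FALSE
    )
  }
  add_row("odour", odour$label)
  rows[[length(rows) + 1L]] <- data.frame(
    source = "image_available_only",
    accuracy = project_accuracy(image, labels, "available_only"),
    f1 = NA_real_, stringsAsFactors = FALSE
  )
  rows[[length(rows) + 1L]] <- data.frame(
    source = "image_all",
    accuracy = project_accuracy(image, labels, "all_counting_missing_wrong"),
    f1 = NA_real_, stringsAsFactors = FALSE
  )
  fused <- list()
  if ("max_confidence" %in% strategies) {
    lab <- vapply(seq_len(n), function(i) {
      fuse_max_confidence(odour[i, ], image[i, ])
    }, character(1))
    fused$max_confidence <- lab
    add_row("fused_max_confidence", lab)
  }
  if ("majority" %in% strategies) {
    lab <- vapply(seq_len(n), function(i) {
      votes <- rbind(odour[i, ], image[i, ],
                     do.call(rbind, lapply(voters, function(v) v[i, ])))
      fuse_majority(votes)
    }, character(1))
    fused$majority <- lab
    add_row("fused_majority", lab)
  }
  structure(list(table = do.call(rbind, rows),
                 agreement = agreement_analysis(odour, image, labels),
                 fused = fused),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  tab <- x$table
  tab$accuracy <- round(tab$accuracy, 4)
  tab$f1 <- round(tab$f1, 4)
  print(tab, row.names = FALSE)
  with(x$agreement, cat(sprintf(
    "agreement: %d samples (%.1f%%), accuracy on agreed %.4f\n",
    n_agreed, 100 * fraction_agreed, accuracy_on_agreed)))
  invisible(x)
}
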