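# Independent brute-force oracles used to cross-check the fast
# implementations.

# EWMA by the literal weighted sum: xhat[m] = sum w_i x_i / sum w_i with
# weights (1 - alpha)^(m - i), i = 1..m.
ewma_bruteforce <- function(x, alpha) {
  m <- length(x)
  vapply(seq_len(m), function(j) {
    w <- (1 - alpha)^(j - seq_len(j))
    sum(w * x[seq_len(j)]) / sum(w)
  }, numeric(1))
}

# Exhaustive suppression: repeatedly take the global confidence maximum
# among remaining boxes, keep it, and delete every same-class box whose
# IoU with it exceeds the threshold.
nms_bruteforce <- function(detections, iou_threshold) {
  remaining <- detections
  remaining$.ord <- seq_len(nrow(remaining))
  kept <- remaining[0, ]
  while (nrow(remaining) > 0) {
    i <- order(-remaining$conf, remaining$.ord)[1]
    top <- remaining[i, ]
    kept <- rbind(kept, top)
    box_t <- as.numeric(top[c("x1", "y1", "x2", "y2")])
    drop <- vapply(seq_len(nrow(remaining)), function(j) {
      if (j == i) return(TRUE)
      if (remaining$cls[j] != top$cls) return(FALSE)
      iou(as.numeric(remaining[j, c("x1", "y1", "x2", "y2")]), box_t) > iou_threshold
    }, logical(1))
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept$.ord <- NULL
  kept
}

# Ridge least squares on the ELM hidden layer via the augmented QR route,
# independent of the normal-equations solve used by train_elm().
elm_beta_oracle <- function(model, x, y, weights) {
  H <- stats::plogis(sweep(as.matrix(x) %*% model$W, 2, model$b, "+"))
  t_target <- ifelse(y == model$levels[2], 1, -1)
  sw <- sqrt(weights)
  A <- rbind(H * sw, diag(sqrt(model$ridge), ncol(H)))
  rhs <- c(sw * t_target, rep(0, ncol(H)))
  qr.coef(qr(A), rhs)
}

# Small box generator for NMS property tests.
random_detections <- function(n, seed) {
  set.seed(seed)
  x1 <- runif(n, 0, 80)
  y1 <- runif(n, 0, 80)
  data.frame(x1 = x1, y1 = y1,
             x2 = x1 + runif(n, 10, 40), y2 = y1 + runif(n, 10, 40),
             cls = sample(c("ripe", "unripe"), n, replace = TRUE),
             conf = round(runif(n), 3), stringsAsFactors = FALSE)
}
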