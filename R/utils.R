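# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic stream of derived seeds, kept below 2^31 (doubles are exact
# well past this range, so the arithmetic is reproducible everywhere).
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + as.double(k)) %% 2147483647)
}

#' Construct a prediction record
#'
#' Predictions are plain one-row data.frames shared by the odour and image
#' modalities: a label, the winning-class confidence, the modality, and an
#' availability flag (night samples have no image prediction).
#'
#' @param sample_id sample identifier.
#' @param label predicted class (NA when unavailable).
#' @param confidence winning-class probability/score in `[0, 1]`.
#' @param modality `"odour"` or `"image"`.
#' @param available whether the modality produced a prediction.
#' @return one-row data.frame with columns
#'   `sample_id, label, confidence, modality, available`.
#' @export
prediction <- function(sample_id, label, confidence, modality = c("odour", "image"),
                       available = TRUE) {
  modality <- match.arg(modality)
  if (available) {
    stopifnot(!is.na(confidence), confidence >= 0, confidence <= 1)
  }
  data.frame(sample_id = as.character(sample_id),
             label = as.character(label),
             confidence = as.numeric(confidence),
             modality = modality,
             available = available,
             stringsAsFactors = FALSE)
}
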