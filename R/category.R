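#' Ordinal category correction for ICDAS score vectors
#'
#' Adjacent ICDAS codes are visually similar, so a detector's seven
#' class scores typically peak at the true code and fall off on both
#' sides. The plain argmax decode ignores the shape of that profile:
#' when the profile is skewed, the classes above the peak may jointly
#' carry far more mass than those below, and the code one step up is
#' closer to the truth. The correction replaces argmax with the rounded
#' score-weighted mean of the ordinal codes,
#' `round(sum(c * s_c) / sum(s_c))`, except at the edge codes: a
#' weighted mean is always pulled off 0 and 6 toward the middle, so
#' when the argmax is C0 or C6 the argmax is kept unchanged.
#'
#' Rounding is half-away-from-zero (3.5 -> 4), fixed explicitly so the
#' result does not depend on the platform's banker's rounding.
#'
#' @name category_correction
NULL

#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Corrected ordinal class for one or more score vectors
#'
#' @param scores Either a numeric vector of 7 nonnegative class scores
#'   (`s0`..`s6`) with positive sum, or a 7-column matrix of such rows.
#' @return Integer class label(s) in `0..6`.
#' @examples
#' correct_category(c(0, 0.02, 0.08, 0.35, 0.30, 0.20, 0.05))  # 4, argmax was 3
#' correct_category(c(0.5, 0.3, 0.1, 0.05, 0.03, 0.02, 0))     # 0, edge reversion
#' @export
correct_category <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (ncol(scores) != 7) {
    rlang::abort("Score vectors must have exactly 7 entries (ICDAS C0-C6).",
                 class = "dentpost_schema_error")
  }
  if (any(scores < 0)) {
    rlang::abort("Scores must be nonnegative.", class = "dentpost_schema_error")
  }
  total <- rowSums(scores)
  if (any(total <= 0)) {
    rlang::abort("All-zero score vector: weighted class is undefined.",
                 class = "dentpost_undefined_weights_error")
  }
  amax <- max.col(scores, ties.method = "first") - 1L
  wmean <- as.vector(scores %*% (0:6)) / total
  corrected <- as.integer(round_half_up(wmean))
  corrected <- pmin(pmax(corrected, 0L), 6L)
  out <- ifelse(amax %in% c(0L, 6L), amax, corrected)
  as.integer(out)
}

#' Apply category correction to a detection table
#'
#' Replaces each detection's `cls` by [correct_category()] of its
#' retained score vector. Boxes, confidences and row order are left
#' untouched; only the reported class changes. Typically applied after
#' NMS, to surviving detections.
#'
#' @param dets Tibble of detections with score columns `s0`..`s6`.
#' @return The same tibble with corrected `cls`.
#' @export
apply_category_correction <- function(dets) {
  dets <- tibble::as_tibble(dets)
  if (nrow(dets) == 0) {
    if (!"cls" %in% names(dets)) dets$cls <- integer(0)
    return(dets)
  }
  s <- score_matrix(dets)
  dets$cls <- correct_category(s)
  dets
}
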