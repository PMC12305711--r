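#' Non-maximum suppression over decoded detections
#'
#' A detector emits one box plus a 7-class ICDAS score vector per anchor
#' point; many anchors cover the same tooth, so redundant boxes must be
#' removed. Raw predictions are rows with box columns `cx`, `cy`, `w`,
#' `h` and score columns `s0`..`s6`; [decode_predictions()] turns them
#' into detections by taking the per-row maximum score and its class,
#' and the NMS functions then keep one box per physical tooth.
#'
#' @name nms
NULL

score_cols <- paste0("s", 0:6)

#' @noRd
score_matrix <- function(dets) {
  missing <- setdiff(score_cols, names(dets))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("Detections are missing score column(s): %s (7 ICDAS classes required).",
              paste(missing, collapse = ", ")),
      class = "dentpost_schema_error"
    )
  }
  m <- as.matrix(dets[score_cols])
  storage.mode(m) <- "double"
  m
}

#' @noRd
split_images <- function(dets) {
  if (!"image_id" %in% names(dets)) dets$image_id <- "img"
  dets
}

#' Decode raw per-anchor predictions into detections
#'
#' For each row, the predicted class is the argmax over the seven ICDAS
#' score columns (ties broken toward the lower class index) and the
#' confidence score is that maximum. The full score vector is retained
#' for later ordinal category correction.
#'
#' @param preds Data frame of raw predictions with columns `cx`, `cy`,
#'   `w`, `h`, `s0`..`s6` (each score in `[0, 1]`), and optionally
#'   `image_id`.
#' @return A tibble of detections: the input plus integer `cls` (0-6)
#'   and numeric `score` columns.
#' @examples
#' raw <- tibble::tibble(cx = 10, cy = 10, w = 4, h = 4,
#'                       s0 = 0, s1 = 0, s2 = 0, s3 = 1,
#'                       s4 = 0, s5 = 0, s6 = 0)
#' decode_predictions(raw)  # cls 3, score 1
#' @export
decode_predictions <- function(preds) {
  validate_boxes(preds, "preds")
  s <- score_matrix(preds)
  out <- tibble::as_tibble(preds)
  if (nrow(out) == 0) {
    out$cls <- integer(0)
    out$score <- numeric(0)
    return(out)
  }
  out$cls <- max.col(s, ties.method = "first") - 1L
  out$score <- s[cbind(seq_len(nrow(s)), out$cls + 1L)]
  dplyr::relocate(out, "cls", "score", .after = "h")
}

#' Greedy non-maximum suppression
#'
#' Per image: detections scoring below `conf_thresh` are dropped
#' (at-threshold boxes are kept), then the highest-scoring box is kept
#' and every remaining box whose IoU with it exceeds `iou_thresh` is
#' removed, repeating until no boxes remain. Suppression is
#' class-agnostic: a tooth is a single physical object, so boxes of
#' different ICDAS codes still suppress each other. Score ties are
#' broken by lower input row index, making the output deterministic.
#'
#' @param dets Tibble of decoded detections (see [decode_predictions()]).
#' @param conf_thresh Confidence threshold in `[0, 1]`; default 0.1.
#' @param iou_thresh IoU above which a lower-scoring box is suppressed;
#'   default 0.5.
#' @return Kept detections, sorted by descending score within image.
#' @export
nms_greedy <- function(dets, conf_thresh = 0.1, iou_thresh = 0.5) {
  stopifnot(conf_thresh >= 0, conf_thresh <= 1, iou_thresh >= 0, iou_thresh <= 1)
  validate_boxes(dets, "dets")
  dets <- split_images(tibble::as_tibble(dets))
  if (nrow(dets) == 0) return(dets)
  dets |>
    dplyr::group_by(.data$image_id) |>
    dplyr::group_modify(~ nms_greedy_one(.x, conf_thresh, iou_thresh)) |>
    dplyr::ungroup()
}

#' @noRd
nms_greedy_one <- function(dets, conf_thresh, iou_thresh) {
  keep_mask <- dets$score >= conf_thresh
  dets <- dets[keep_mask, , drop = FALSE]
  n <- nrow(dets)
  if (n == 0) return(dets)
  ord <- order(-dets$score, seq_len(n))
  x1 <- dets$cx - dets$w / 2; x2 <- dets$cx + dets$w / 2
  y1 <- dets$cy - dets$h / 2; y2 <- dets$cy + dets$h / 2
  alive <- rep(TRUE, n)
  kept <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    cand <- alive
    cand[i] <- FALSE
    if (any(cand)) {
      iou <- iou_xyxy(x1[i], y1[i], x2[i], y2[i],
                      x1[cand], y1[cand], x2[cand], y2[cand])
      alive[which(cand)[iou > iou_thresh]] <- FALSE
    }
  }
  dets[kept, , drop = FALSE]
}

#' Soft non-maximum suppression (linear decay)
#'
#' Instead of deleting overlapping boxes, the confidence of each box
#' overlapping the current top box (IoU above `iou_thresh`) is weighted
#' by `1 - IoU`, so heavily overlapping boxes decay toward zero while
#' mild overlaps survive with reduced score. After the sweep, boxes
#' scoring below `conf_thresh` are dropped. With IoU = 1 the decay
#' factor is 0 and the behavior coincides with [nms_greedy()].
#'
#' @inheritParams nms_greedy
#' @return Kept detections with decayed scores, sorted by descending
#'   (decayed) score within image. Score vectors `s0`..`s6` are rescaled
#'   proportionally so `max` stays consistent with `score`.
#' @export
nms_soft <- function(dets, conf_thresh = 0.1, iou_thresh = 0.5) {
  stopifnot(conf_thresh >= 0, conf_thresh <= 1, iou_thresh >= 0, iou_thresh <= 1)
  validate_boxes(dets, "dets")
  dets <- split_images(tibble::as_tibble(dets))
  if (nrow(dets) == 0) return(dets)
  dets |>
    dplyr::group_by(.data$image_id) |>
    dplyr::group_modify(~ nms_soft_one(.x, conf_thresh, iou_thresh)) |>
    dplyr::ungroup()
}

#' @noRd
nms_soft_one <- function(dets, conf_thresh, iou_thresh) {
  n <- nrow(dets)
  if (n == 0) return(dets)
  x1 <- dets$cx - dets$w / 2; x2 <- dets$cx + dets$w / 2
  y1 <- dets$cy - dets$h / 2; y2 <- dets$cy + dets$h / 2
  score <- dets$score
  pending <- rep(TRUE, n)
  picked <- integer(0)
  while (any(pending)) {
    idx <- which(pending)
    top <- idx[order(-score[idx], idx)][1]
    pending[top] <- FALSE
    picked <- c(picked, top)
    rest <- which(pending)
    if (length(rest) > 0) {
      iou <- iou_xyxy(x1[top], y1[top], x2[top], y2[top],
                      x1[rest], y1[rest], x2[rest], y2[rest])
      decay <- rest[iou > iou_thresh]
      score[decay] <- score[decay] * (1 - iou[iou > iou_thresh])
    }
  }
  out <- dets[picked, , drop = FALSE]
  new_score <- score[picked]
  out <- rescale_score_vectors(out, new_score)
  out <- out[out$score >= conf_thresh, , drop = FALSE]
  out[order(-out$score, seq_len(nrow(out))), , drop = FALSE]
}

#' Rescale the 7-class score vector so its max equals a new score
#' @noRd
rescale_score_vectors <- function(dets, new_score) {
  if (all(score_cols %in% names(dets)) && nrow(dets) > 0) {
    old <- dets$score
    fac <- ifelse(old > 0, new_score / old, 0)
    for (col in score_cols) dets[[col]] <- dets[[col]] * fac
  }
  dets$score <- new_score
  dets
}
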