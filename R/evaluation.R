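#' Detection evaluation: matching, PR curves, AP and mAP@50
#'
#' Evaluation follows the standard object-detection protocol: per image
#' and per class, detections are matched greedily (descending score) to
#' unmatched ground-truth boxes at IoU >= 0.5; each ground truth can be
#' matched at most once, and unmatched ground truths are false
#' negatives. Matching is class-aware: a C3 detection cannot match a C4
#' ground truth, so a right box with the wrong code counts as both a
#' false positive and a missed tooth. Average precision is the
#' all-point interpolated area under the precision-recall curve, and
#' mAP@50 is its unweighted mean over classes with at least one ground
#' truth instance.
#'
#' @name evaluation
NULL

#' Match detections to ground truth at an IoU threshold
#'
#' @param dets Tibble of detections (`image_id`, `cx`, `cy`, `w`, `h`,
#'   `cls`, `score`).
#' @param gts Tibble of ground-truth boxes (`image_id`, `cls`, `cx`,
#'   `cy`, `w`, `h`).
#' @param iou_thresh Match criterion; a detection is a true positive iff
#'   its IoU with an unmatched same-class ground truth is at least this.
#' @return `dets` with logical column `tp` and integer column
#'   `gt_match` (row index into `gts`, `NA` for false positives),
#'   ordered by descending score within image and class. The total
#'   false-negative count is attached as attribute `"fn"`.
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  dets <- split_images(tibble::as_tibble(dets))
  gts <- split_images(tibble::as_tibble(gts))
  dets$tp <- logical(nrow(dets))
  dets$gt_match <- rep(NA_integer_, nrow(dets))
  gt_used <- logical(nrow(gts))
  if (nrow(dets) > 0) {
    ord <- order(dets$image_id, dets$cls, -dets$score, seq_len(nrow(dets)))
    dets <- dets[ord, , drop = FALSE]
    for (i in seq_len(nrow(dets))) {
      cand <- which(gts$image_id == dets$image_id[i] &
                    gts$cls == dets$cls[i] & !gt_used)
      if (length(cand) == 0) next
      iou <- box_iou(dets[i, ], gts[cand, ])
      best <- which.max(iou)
      if (iou[best] >= iou_thresh) {
        dets$tp[i] <- TRUE
        dets$gt_match[i] <- cand[best]
        gt_used[cand[best]] <- TRUE
      }
    }
  }
  attr(dets, "fn") <- sum(!gt_used)
  dets
}

#' Precision-recall curve for one class
#'
#' Sweeps the confidence threshold over the labeled detections of one
#' class (all images pooled), accumulating true and false positives in
#' descending-score order.
#'
#' @param labeled Tibble with `score` and logical `tp` columns, as
#'   produced by [match_detections()] (filtered to one class).
#' @param n_gt Number of ground-truth instances of the class (> 0).
#' @return Tibble with columns `score`, `recall`, `precision`; recall is
#'   nondecreasing along the sweep.
#' @export
pr_curve <- function(labeled, n_gt) {
  if (n_gt <= 0) {
    rlang::abort("`n_gt` must be positive; classes absent from the ground truth are skipped.")
  }
  if (nrow(labeled) == 0) {
    return(tibble::tibble(score = numeric(0), recall = numeric(0),
                          precision = numeric(0)))
  }
  ord <- order(-labeled$score, seq_len(nrow(labeled)))
  tp <- cumsum(labeled$tp[ord])
  fp <- cumsum(!labeled$tp[ord])
  tibble::tibble(
    score = labeled$score[ord],
    recall = tp / n_gt,
    precision = tp / (tp + fp)
  )
}

#' All-point interpolated average precision
#'
#' The precision envelope is made monotone nonincreasing in recall
#' (each point takes the maximum precision at any equal-or-higher
#' recall), then integrated over recall. An empty curve has AP 0.
#'
#' @param curve Tibble from [pr_curve()].
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(curve) {
  if (nrow(curve) == 0) return(0)
  recall <- c(0, curve$recall)
  precision <- c(0, curve$precision)
  precision <- rev(cummax(rev(precision)))
  sum(diff(recall) * precision[-1])
}

#' Evaluate detections against ground truth
#'
#' Computes per-class AP (at the IoU 0.5 match criterion), mAP@50, and
#' precision/recall counts at a fixed operating confidence threshold.
#'
#' @inheritParams match_detections
#' @param operating_conf Confidence threshold at which the single
#'   precision/recall operating point is computed; default 0.25.
#' @param iou_thresh Match criterion for both AP and the operating
#'   point; default 0.5 (mAP@50).
#' @return An object of class `"dentpost_eval"`: a list with `per_class`
#'   (tibble of `cls`, `n_gt`, `ap`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`), `map50`, `operating_conf`, and the pooled PR curves.
#' @export
evaluate_detections <- function(dets, gts, operating_conf = 0.25,
                                iou_thresh = 0.5) {
  gts <- split_images(tibble::as_tibble(gts))
  if (nrow(gts) == 0) {
    rlang::abort("No ground-truth boxes: evaluation is undefined.",
                 class = "dentpost_schema_error")
  }
  labeled <- match_detections(dets, gts, iou_thresh = iou_thresh)
  curves <- list()
  per_class <- purrr::map_dfr(0:6, function(k) {
    n_gt <- sum(gts$cls == k)
    dk <- labeled[labeled$cls == k, , drop = FALSE]
    if (n_gt == 0) {
      if (nrow(dk) > 0) {
        rlang::inform(sprintf("Class C%d has detections but no ground truth; skipped in mAP.", k))
      }
      return(tibble::tibble(cls = k, n_gt = 0L, ap = NA_real_,
                            tp = 0L, fp = as.integer(sum(dk$score >= operating_conf)),
                            fn = 0L, precision = NA_real_, recall = NA_real_))
    }
    curve <- pr_curve(dk, n_gt)
    curves[[as.character(k)]] <<- curve
    op <- dk[dk$score >= operating_conf, , drop = FALSE]
    tp <- sum(op$tp); fp <- sum(!op$tp); fn <- n_gt - tp
    tibble::tibble(
      cls = k, n_gt = as.integer(n_gt), ap = average_precision(curve),
      tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = tp / n_gt
    )
  })
  structure(
    list(
      per_class = per_class,
      map50 = mean(per_class$ap[per_class$n_gt > 0]),
      operating_conf = operating_conf,
      iou_thresh = iou_thresh,
      curves = curves
    ),
    class = "dentpost_eval"
  )
}

#' @export
print.dentpost_eval <- function(x, ...) {
  cat(sprintf("Detection evaluation (IoU %.2f): mAP@%d = %.4f\n",
              x$iou_thresh, round(100 * x$iou_thresh), x$map50))
  cat(sprintf("Operating point at confidence %.2f:\n", x$operating_conf))
  print(x$per_class)
  invisible(x)
}

#' Tidy a detection evaluation into its per-class table
#'
#' @param x A `"dentpost_eval"` object.
#' @param ... Unused.
#' @return The per-class tibble (`cls`, `n_gt`, `ap`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`).
#' @export
tidy.dentpost_eval <- function(x, ...) x$per_class

#' One-row summary of a detection evaluation
#'
#' @param x A `"dentpost_eval"` object.
#' @param ... Unused.
#' @return One-row tibble: `map50`, macro-averaged `precision` and
#'   `recall` over classes present in the ground truth, and pooled
#'   `tp`, `fp`, `fn` counts.
#' @export
glance.dentpost_eval <- function(x, ...) {
  pc <- x$per_class[x$per_class$n_gt > 0, , drop = FALSE]
  tibble::tibble(
    map50 = x$map50,
    precision = mean(pc$precision, na.rm = TRUE),
    recall = mean(pc$recall, na.rm = TRUE),
    tp = sum(x$per_class$tp), fp = sum(x$per_class$fp),
    fn = sum(pc$fn)
  )
}

#' Generic tidiers
#'
#' `tidy()` and `glance()` generics, following the broom convention, for
#' the package's result objects.
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Rank-test comparison of two seed sets of mAP scores
#'
#' Unpaired two-sample Wilcoxon rank-sum (Mann-Whitney U) test on two
#' sets of per-seed mAP scores, e.g. a corrected pipeline versus its
#' baseline across 20 random seeds.
#'
#' @param maps_a,maps_b Numeric vectors of per-seed scores (each length
#'   >= 1; lengths may differ).
#' @param alternative `"two.sided"` (default), `"greater"` (a tends
#'   larger than b) or `"less"`.
#' @return One-row tibble: `statistic` (U), `p_value`, `n_a`, `n_b`,
#'   `median_a`, `median_b`.
#' @export
compare_runs <- function(maps_a, maps_b, alternative = "two.sided") {
  if (length(maps_a) == 0 || length(maps_b) == 0) {
    rlang::abort("Both score sets must be non-empty.",
                 class = "dentpost_schema_error")
  }
  ht <- suppressWarnings(
    stats::wilcox.test(maps_a, maps_b, alternative = alternative,
                       paired = FALSE)
  )
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # all observations tied: no evidence against the null
  tibble::tibble(
    statistic = unname(ht$statistic), p_value = p,
    n_a = length(maps_a), n_b = length(maps_b),
    median_a = stats::median(maps_a), median_b = stats::median(maps_b)
  )
}
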