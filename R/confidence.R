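#' Spatial confidence correction
#'
#' In a well-aligned dentition, adjacent teeth form a nearly equidistant,
#' nearly linear arrangement: seen from any high-confidence tooth box,
#' the two nearest high-confidence neighbors lie on either side at
#' similar distances (`d2/d1 < 1.5`, angle `theta > 90` degrees).
#' Departures from that regime carry diagnostic information:
#'
#' * `d2/d1 > 2` (rule R1): there is likely a missed tooth (false
#'   negative) between the current box and its second neighbor — e.g. a
#'   crowded canine or a corner wisdom tooth that was not scored highly.
#'   The expected tooth position is simulated inside the gap toward the
#'   second neighbor (see `gap_placement`), and every low-confidence
#'   box overlapping that simulated box (IoU > 0.6) has its score
#'   boosted by `score + w * (1 - score)`.
#' * `theta < 33` degrees with `d2/d1 <= 2.7` (rule R2): both neighbors
#'   lie in the same direction, so the current box sits in the
#'   background, far from the arch — typically a mouth opener or a lens
#'   bubble scored like a tooth. Its score is suppressed by a small
#'   multiplicative factor.
#' * `theta < 33` degrees with `d2/d1 > 2.7` (rule R3): the current box
#'   is an edge tooth (last molar), whose neighbors necessarily lie to
#'   one side; its score is boosted with the same formula as R1.
#'
#' The full pass is: a first round of NMS at a high confidence threshold
#' (0.5) selects anchor teeth; the three rules adjust scores; NMS runs
#' again at the original threshold (0.1) to produce the final output.
#'
#' @name confidence_correction
NULL

#' Parameters of the spatial confidence correction
#'
#' Defaults follow the tuned operating point of the method: the gap
#' ratio trigger 2 and angle trigger 33 degrees were selected by a grid
#' sweep (ratio 1 to 4 in steps of 0.5, angle 10 to 40 degrees in steps
#' of 5), and the boost weight 0.5 keeps boosted scores below 1.
#'
#' @param high_conf Confidence threshold of the first (anchor) NMS pass.
#' @param fn_ratio `d2/d1` above which a gap (missed tooth) is flagged.
#' @param edge_ratio `d2/d1` above which a small-angle box is treated as
#'   an edge tooth (boosted) rather than background (suppressed).
#' @param fp_angle_deg Angle (degrees) below which a box is flagged as
#'   off-arch.
#' @param fn_iou IoU with the simulated missing-tooth box above which a
#'   low-confidence detection is boosted.
#' @param boost_weight Weight `w` in `score + w * (1 - score)`.
#' @param suppress_factor Multiplier applied to flagged false-positive
#'   scores. The default 0.1 is an order-of-magnitude cut: with the
#'   final pass at `base_conf = 0.1` and anchors at `high_conf = 0.5`,
#'   any factor at or above `base_conf / high_conf = 0.2` could only
#'   re-rank a flagged false positive, never remove it.
#' @param far_d1 The angle rules (R2/R3) diagnose boxes sitting in the
#'   background or past the arch edge, i.e. far from the other teeth;
#'   they fire only when the anchor's `d1` exceeds `far_d1` times the
#'   median nearest-anchor distance in the image. Without this gate the
#'   terminal tooth of any convex arch — whose two nearest anchors
#'   necessarily lie on the same side, subtending a small angle — would
#'   be flagged in every image. Set to 0 to disable the gate.
#' @param base_conf Confidence threshold of the final NMS pass.
#' @param nms_iou IoU threshold used by both NMS passes.
#' @param gap_placement Where to center the simulated missing-tooth box:
#'   `"midpoint"` (default) uses the midpoint of the segment from the
#'   current box center to the second neighbor's center — correct
#'   whenever the missing tooth sits centrally in the gap; `"distance"`
#'   places it one `d1` step from the current box instead. The two
#'   coincide when `d2 = 2 * d1`, but the gap rule fires from anchors
#'   near a crowded arch end, where `d1` is the tightened terminal gap
#'   and the one-step placement systematically undershoots the gap
#'   center.
#' @return A list of class `"correction_params"`.
#' @export
correction_params <- function(high_conf = 0.5,
                              fn_ratio = 2.0,
                              edge_ratio = 2.7,
                              fp_angle_deg = 33.0,
                              fn_iou = 0.6,
                              boost_weight = 0.5,
                              suppress_factor = 0.1,
                              far_d1 = 1.5,
                              base_conf = 0.1,
                              nms_iou = 0.5,
                              gap_placement = c("midpoint", "distance")) {
  gap_placement <- match.arg(gap_placement)
  # fn_ratio = 1 is a legitimate sweep point (d2/d1 >= 1 by definition),
  # and sweeps may push fn_ratio past edge_ratio; no ordering is imposed.
  stopifnot(
    fn_ratio >= 1, edge_ratio >= 1,
    fp_angle_deg > 0, fp_angle_deg < 90,
    high_conf >= 0, high_conf <= 1, base_conf >= 0, base_conf <= 1,
    fn_iou >= 0, fn_iou <= 1, nms_iou >= 0, nms_iou <= 1,
    boost_weight >= 0, boost_weight <= 1,
    suppress_factor >= 0, suppress_factor <= 1, far_d1 >= 0
  )
  structure(
    list(high_conf = high_conf, fn_ratio = fn_ratio, edge_ratio = edge_ratio,
         fp_angle_deg = fp_angle_deg, fn_iou = fn_iou,
         boost_weight = boost_weight, suppress_factor = suppress_factor,
         far_d1 = far_d1, base_conf = base_conf, nms_iou = nms_iou,
         gap_placement = gap_placement),
    class = "correction_params"
  )
}

#' @export
print.correction_params <- function(x, ...) {
  cat("Spatial confidence-correction parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-15s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' First-pass anchor selection
#'
#' Runs greedy NMS at the high confidence threshold; the survivors are
#' the anchor teeth whose neighbor geometry drives the correction rules.
#'
#' @param dets Tibble of decoded detections.
#' @param params A [correction_params()] list.
#' @return The anchor subset of `dets`.
#' @export
high_confidence_pass <- function(dets, params = correction_params()) {
  nms_greedy(dets, conf_thresh = params$high_conf, iou_thresh = params$nms_iou)
}

#' Boost a confidence score toward 1
#'
#' `score + weight * (1 - score)`: the `(1 - score)` term normalizes the
#' increment so the boosted score never exceeds 1, and the map is a
#' strict increase for any score below 1.
#'
#' @param score Scores in `[0, 1]`.
#' @param weight Boost weight in `[0, 1]`; default 0.5.
#' @return Boosted scores.
#' @examples
#' boost_score(0)    # 0.5
#' boost_score(0.2)  # 0.6
#' boost_score(1)    # 1
#' @export
boost_score <- function(score, weight = 0.5) {
  if (any(score < 0 | score > 1)) {
    rlang::abort("Scores must lie in [0, 1].", class = "dentpost_range_error")
  }
  score + weight * (1 - score)
}

#' Simulate the box of a suspected missing tooth
#'
#' When the gap rule fires for an anchor, the missing tooth is assumed
#' to sit at the equidistant position: one `d1` step from the anchor's
#' center toward the second neighbor's center. Its width and height are
#' the means of the two boxes' dimensions.
#'
#' @param current One-row data frame: the anchor box.
#' @param second_neighbor One-row data frame: the second-nearest anchor.
#' @param d1 Distance from the anchor to its nearest neighbor (> 0).
#' @param placement `"distance"` (one `d1` step) or `"midpoint"`.
#' @return A one-row tibble with columns `cx`, `cy`, `w`, `h`.
#' @export
simulate_missing_box <- function(current, second_neighbor, d1,
                                 placement = "distance") {
  validate_boxes(current, "current")
  validate_boxes(second_neighbor, "second_neighbor")
  dx <- second_neighbor$cx - current$cx
  dy <- second_neighbor$cy - current$cy
  len <- sqrt(dx^2 + dy^2)
  if (len == 0 || d1 <= 0) {
    rlang::abort("Coincident centers: cannot place a simulated box.",
                 class = "dentpost_degenerate_geometry_error")
  }
  if (placement == "midpoint") {
    cx <- current$cx + dx / 2
    cy <- current$cy + dy / 2
  } else {
    cx <- current$cx + d1 * dx / len
    cy <- current$cy + d1 * dy / len
  }
  tibble::tibble(
    cx = cx, cy = cy,
    w = (current$w + second_neighbor$w) / 2,
    h = (current$h + second_neighbor$h) / 2
  )
}

#' Adjust detection scores from anchor neighbor geometry
#'
#' Applies rules R1 (gap boost), R2 (background suppression) and R3
#' (edge boost) described in [confidence_correction]. Anchors are
#' iterated; non-anchor detections are only ever touched by R1. Each
#' detection's score is adjusted at most once per rule, and its full
#' score vector `s0`..`s6` is rescaled proportionally so the vector
#' maximum equals the new score (keeping later category correction
#' consistent). Images with fewer than 3 anchors are passed through
#' unchanged, since `d1`, `d2` and `theta` are undefined there.
#'
#' Simulated gap boxes flagged by several anchors are deduplicated
#' (IoU > 0.5) before boosting, and R3 takes precedence over R2 when a
#' small-angle anchor also exceeds the edge ratio.
#'
#' @param dets Tibble of decoded detections.
#' @param anchors Output of [high_confidence_pass()] on the same table.
#' @param params A [correction_params()] list.
#' @return `dets` with adjusted scores, original row order; the counts
#'   of rule firings are attached as attribute `"rule_counts"`.
#' @export
adjust_scores <- function(dets, anchors, params = correction_params()) {
  dets <- split_images(tibble::as_tibble(dets))
  anchors <- split_images(tibble::as_tibble(anchors))
  added_id <- !".det_id" %in% names(dets)
  if (added_id) dets$.det_id <- seq_len(nrow(dets))
  if (!".det_id" %in% names(anchors)) {
    key <- function(d) paste(d$image_id, d$cx, d$cy, d$w, d$h, sep = "\r")
    anchors$.det_id <- dets$.det_id[match(key(anchors), key(dets))]
    if (anyNA(anchors$.det_id)) {
      rlang::abort("`anchors` must be a subset of `dets`.",
                   class = "dentpost_schema_error")
    }
  }
  counts <- c(R1 = 0L, R2 = 0L, R3 = 0L)
  new_score <- dets$score
  for (img in unique(anchors$image_id)) {
    a <- anchors[anchors$image_id == img, , drop = FALSE]
    if (nrow(a) < 3) next
    di <- which(dets$image_id == img)
    is_anchor_row <- dets$.det_id[di] %in% a$.det_id
    sim_boxes <- NULL
    profs <- vector("list", nrow(a))
    for (i in seq_len(nrow(a))) {
      profs[[i]] <- neighbor_profile(a[i, ], a[-i, , drop = FALSE])
    }
    # Far-field gate for the angle rules: an anchor counts as off-arch
    # only if even its nearest anchor is well beyond typical spacing.
    med_nn <- stats::median(purrr::map_dbl(profs, "d1"))
    for (i in seq_len(nrow(a))) {
      others <- a[-i, , drop = FALSE]
      prof <- profs[[i]]
      if (prof$ratio > params$fn_ratio) {
        sim <- simulate_missing_box(a[i, ], others[prof$n2, ],
                                    prof$d1, params$gap_placement)
        sim_boxes <- dplyr::bind_rows(sim_boxes, sim)
      }
      far_field <- params$far_d1 == 0 || prof$d1 > params$far_d1 * med_nn
      if (prof$theta < params$fp_angle_deg && far_field) {
        j <- di[dets$.det_id[di] == a$.det_id[i]]
        if (prof$ratio > params$edge_ratio) {
          new_score[j] <- boost_score(dets$score[j], params$boost_weight)
          counts["R3"] <- counts["R3"] + 1L
        } else {
          new_score[j] <- dets$score[j] * params$suppress_factor
          counts["R2"] <- counts["R2"] + 1L
        }
      }
    }
    if (!is.null(sim_boxes) && nrow(sim_boxes) > 0) {
      sim_boxes <- dedup_boxes(sim_boxes, iou_thresh = 0.5)
      low <- di[!is_anchor_row]
      if (length(low) > 0) {
        hit <- rep(FALSE, length(low))
        for (k in seq_len(nrow(sim_boxes))) {
          iou <- box_iou(sim_boxes[k, ], dets[low, ])
          hit <- hit | (iou > params$fn_iou)
        }
        if (any(hit)) {
          tgt <- low[hit]
          new_score[tgt] <- boost_score(dets$score[tgt], params$boost_weight)
          counts["R1"] <- counts["R1"] + sum(hit)
        }
      }
    }
  }
  out <- rescale_score_vectors(dets, new_score)
  if (added_id) out$.det_id <- NULL
  attr(out, "rule_counts") <- counts
  out
}

#' Drop boxes that duplicate an earlier box (IoU above threshold)
#' @noRd
dedup_boxes <- function(boxes, iou_thresh = 0.5) {
  keep <- logical(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- boxes[which(keep), , drop = FALSE]
    keep[i] <- all(box_iou(boxes[i, ], prev) <= iou_thresh)
  }
  boxes[keep, , drop = FALSE]
}

#' Two-pass spatial confidence correction
#'
#' Runs the full correction: anchor selection at the high threshold,
#' score adjustment from neighbor geometry, then a final NMS round at
#' the original confidence threshold. When no rule fires the output
#' equals plain [nms_greedy()] at `base_conf`.
#'
#' @param dets Tibble of decoded detections.
#' @param params A [correction_params()] list.
#' @return Final kept detections; rule-firing counts are attached as
#'   attribute `"rule_counts"`.
#' @export
correct_confidence <- function(dets, params = correction_params()) {
  dets <- split_images(tibble::as_tibble(dets))
  dets$.det_id <- seq_len(nrow(dets))
  anchors <- high_confidence_pass(dets, params)
  adjusted <- adjust_scores(dets, anchors, params)
  counts <- attr(adjusted, "rule_counts")
  out <- nms_greedy(adjusted, conf_thresh = params$base_conf,
                    iou_thresh = params$nms_iou)
  out$.det_id <- NULL
  attr(out, "rule_counts") <- counts
  out
}
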