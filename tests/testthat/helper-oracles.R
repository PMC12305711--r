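# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive results from first principles (corner
# coordinates, explicit loops) so they share no code with the package
# implementation they check.

box_tbl <- function(cx, cy, w = 1, h = 1) {
  tibble::tibble(cx = cx, cy = cy, w = w, h = h)
}

# detections with given boxes and scores, one-hot score vectors
det_tbl <- function(cx, cy, w = 1, h = 1, score = 0.9, cls = 0,
                    image_id = "img") {
  n <- length(cx)
  out <- tibble::tibble(image_id = image_id, cx = cx, cy = cy,
                        w = rep_len(w, n), h = rep_len(h, n),
                        cls = as.integer(rep_len(cls, n)),
                        score = rep_len(score, n))
  s <- matrix(0, n, 7)
  s[cbind(seq_len(n), out$cls + 1L)] <- out$score
  out[paste0("s", 0:6)] <- as.data.frame(s)
  out
}

oracle_iou <- function(a, b) {
  ax1 <- a$cx - a$w / 2; ax2 <- a$cx + a$w / 2
  ay1 <- a$cy - a$h / 2; ay2 <- a$cy + a$h / 2
  bx1 <- b$cx - b$w / 2; bx2 <- b$cx + b$w / 2
  by1 <- b$cy - b$h / 2; by2 <- b$cy + b$h / 2
  ix <- max(0, min(ax2, bx2) - max(ax1, bx1))
  iy <- max(0, min(ay2, by2) - max(ay1, by1))
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

# exhaustive greedy NMS: sort, sweep, suppress -- single image
oracle_nms <- function(dets, conf_thresh, iou_thresh) {
  dets <- dets[dets$score >= conf_thresh, , drop = FALSE]
  remaining <- seq_len(nrow(dets))
  kept <- integer(0)
  while (length(remaining) > 0) {
    scores <- dets$score[remaining]
    top <- remaining[which(scores == max(scores))[1]]
    kept <- c(kept, top)
    remaining <- setdiff(remaining, top)
    drop <- vapply(remaining, function(j) {
      oracle_iou(dets[top, ], dets[j, ]) > iou_thresh
    }, logical(1))
    remaining <- remaining[!drop]
  }
  dets[kept, , drop = FALSE]
}

# brute-force mAP@50 evaluator, sharing no code with the package
oracle_map50 <- function(dets, gts, iou_thresh = 0.5) {
  aps <- c()
  for (k in sort(unique(gts$cls))) {
    gk <- gts[gts$cls == k, , drop = FALSE]
    dk <- dets[dets$cls == k, , drop = FALSE]
    dk <- dk[order(-dk$score, seq_len(nrow(dk))), , drop = FALSE]
    used <- logical(nrow(gk))
    tp <- logical(nrow(dk))
    for (i in seq_len(nrow(dk))) {
      best <- 0; best_j <- 0
      for (j in seq_len(nrow(gk))) {
        if (used[j] || gk$image_id[j] != dk$image_id[i]) next
        v <- oracle_iou(dk[i, ], gk[j, ])
        if (v > best) { best <- v; best_j <- j }
      }
      if (best_j > 0 && best >= iou_thresh) {
        tp[i] <- TRUE
        used[best_j] <- TRUE
      }
    }
    if (nrow(dk) == 0) { aps <- c(aps, 0); next }
    cum_tp <- cumsum(tp); cum_fp <- cumsum(!tp)
    rec <- cum_tp / nrow(gk)
    prec <- cum_tp / (cum_tp + cum_fp)
    # all-point interpolation by explicit scan from the right
    env <- prec
    for (i in rev(seq_len(length(env) - 1))) env[i] <- max(env[i], env[i + 1])
    r_prev <- 0; ap <- 0
    for (i in seq_along(rec)) {
      ap <- ap + (rec[i] - r_prev) * env[i]
      r_prev <- rec[i]
    }
    aps <- c(aps, ap)
  }
  mean(aps)
}

random_detections <- function(n, span = 10, image_id = "img") {
  det_tbl(cx = runif(n, 0, span), cy = runif(n, 0, span),
          w = runif(n, 0.5, 3), h = runif(n, 0.5, 3),
          score = round(runif(n), 3),
          cls = sample(0:6, n, replace = TRUE),
          image_id = image_id)
}

# strip bookkeeping attributes before identity comparisons
plain <- function(x) {
  attr(x, "rule_counts") <- NULL
  attr(x, "fn") <- NULL
  x
}
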