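#' Box geometry for tooth-instance post-processing
#'
#' Boxes are rows of a data frame with center-form columns `cx`, `cy`
#' (center coordinates, pixels; x right, y down), `w`, `h` (width and
#' height, strictly positive). Corner form is derived as
#' `x1 = cx - w/2`, `x2 = cx + w/2` and likewise for y. All geometric
#' rules downstream (NMS, spatial confidence correction) consume these
#' primitives.
#'
#' @name geometry
NULL

box_cols <- c("cx", "cy", "w", "h")

#' @noRd
validate_boxes <- function(boxes, arg = "boxes") {
  if (!is.data.frame(boxes)) {
    rlang::abort(sprintf("`%s` must be a data frame of boxes.", arg),
                 class = "dentpost_schema_error")
  }
  missing <- setdiff(box_cols, names(boxes))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("`%s` is missing box column(s): %s.", arg,
              paste(missing, collapse = ", ")),
      class = "dentpost_schema_error"
    )
  }
  if (nrow(boxes) > 0 && (any(boxes$w <= 0) || any(boxes$h <= 0))) {
    rlang::abort(
      sprintf("`%s` contains boxes with nonpositive width or height.", arg),
      class = "dentpost_invalid_box_error"
    )
  }
  invisible(boxes)
}

#' Intersection-over-union of box pairs
#'
#' Computes IoU between corresponding rows of `a` and `b` (recycling a
#' single row). IoU is symmetric, equals 1 for identical boxes and 0 for
#' boxes with disjoint interiors.
#'
#' @param a,b Data frames of boxes with columns `cx`, `cy`, `w`, `h`.
#'   One of the two may have a single row, which is then compared against
#'   every row of the other.
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @examples
#' u <- tibble::tibble(cx = 0, cy = 0, w = 1, h = 1)
#' box_iou(u, u)                                  # 1
#' box_iou(u, dplyr::mutate(u, cx = 0.5))         # 1/3
#' @export
box_iou <- function(a, b) {
  validate_boxes(a, "a")
  validate_boxes(b, "b")
  if (nrow(a) != nrow(b)) {
    if (nrow(a) == 1) a <- a[rep(1, nrow(b)), ] else
    if (nrow(b) == 1) b <- b[rep(1, nrow(a)), ] else
      rlang::abort("`a` and `b` must have the same number of rows (or one row).")
  }
  iou_xyxy(
    a$cx - a$w / 2, a$cy - a$h / 2, a$cx + a$w / 2, a$cy + a$h / 2,
    b$cx - b$w / 2, b$cy - b$h / 2, b$cx + b$w / 2, b$cy + b$h / 2
  )
}

#' @noRd
iou_xyxy <- function(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2) {
  iw <- pmin(ax2, bx2) - pmax(ax1, bx1)
  ih <- pmin(ay2, by2) - pmax(ay1, by1)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- (ax2 - ax1) * (ay2 - ay1) + (bx2 - bx1) * (by2 - by1) - inter
  ifelse(union > 0, inter / union, 0)
}

#' Pairwise IoU matrix of one box set
#' @noRd
iou_matrix <- function(boxes) {
  n <- nrow(boxes)
  x1 <- boxes$cx - boxes$w / 2; x2 <- boxes$cx + boxes$w / 2
  y1 <- boxes$cy - boxes$h / 2; y2 <- boxes$cy + boxes$h / 2
  m <- matrix(0, n, n)
  if (n == 0) return(m)
  for (i in seq_len(n)) {
    m[i, ] <- iou_xyxy(x1[i], y1[i], x2[i], y2[i], x1, y1, x2, y2)
  }
  m
}

#' Euclidean distance between box centers
#'
#' @inheritParams box_iou
#' @return Numeric vector of nonnegative center distances.
#' @examples
#' a <- tibble::tibble(cx = 0, cy = 0, w = 1, h = 1)
#' b <- tibble::tibble(cx = 3, cy = 4, w = 1, h = 1)
#' center_distance(a, b)  # 5
#' @export
center_distance <- function(a, b) {
  validate_boxes(a, "a")
  validate_boxes(b, "b")
  sqrt((a$cx - b$cx)^2 + (a$cy - b$cy)^2)
}

#' Angle subtended at a point by two neighbors
#'
#' Returns the angle, in degrees within `[0, 180]`, between the vectors
#' from `current` to `n1` and from `current` to `n2`. Invariant to
#' uniform scaling, translation and rotation of all three points.
#'
#' @param current,n1,n2 Numeric length-2 vectors `c(x, y)`.
#' @return Angle in degrees.
#' @examples
#' neighbor_angle(c(0, 0), c(-1, 0), c(1, 0))  # 180
#' neighbor_angle(c(0, 0), c(1, 0), c(0, 1))   # 90
#' @export
neighbor_angle <- function(current, n1, n2) {
  v1 <- c(n1[1] - current[1], n1[2] - current[2])
  v2 <- c(n2[1] - current[1], n2[2] - current[2])
  l1 <- sqrt(sum(v1^2)); l2 <- sqrt(sum(v2^2))
  if (l1 == 0 || l2 == 0) {
    rlang::abort("A neighbor coincides with the current point; angle undefined.",
                 class = "dentpost_degenerate_geometry_error")
  }
  cosang <- sum(v1 * v2) / (l1 * l2)
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Nearest-neighbor profile of a box among its peers
#'
#' For a box in a dentition, the two nearest (by center distance)
#' neighboring boxes define the geometric features driving the spatial
#' confidence correction: `d1` and `d2` (the two smallest distances,
#' `d1 <= d2`), their ratio `d2/d1`, and `theta`, the angle the two
#' neighbor centers subtend at the current box center. In a well-aligned
#' dentition neighbors sit on either side at similar distances, so
#' `d2/d1 < 1.5` and `theta > 90` degrees; departures from that regime
#' flag likely missed teeth (gaps) or background false positives.
#'
#' Distance ties are broken by lower row index of `others`.
#'
#' @param current One-row data frame (a box).
#' @param others Data frame of at least two boxes with centers distinct
#'   from `current`'s.
#' @return A one-row tibble with columns `d1`, `d2`, `ratio`, `theta`.
#' @export
neighbor_profile <- function(current, others) {
  validate_boxes(current, "current")
  validate_boxes(others, "others")
  if (nrow(current) != 1) rlang::abort("`current` must be a single box.")
  d <- sqrt((others$cx - current$cx)^2 + (others$cy - current$cy)^2)
  if (nrow(others) < 2 || sum(d > 0) < 2) {
    rlang::abort("Need at least 2 neighbor boxes with distinct centers.",
                 class = "dentpost_insufficient_neighbors")
  }
  ord <- order(d, seq_along(d))
  i1 <- ord[1]; i2 <- ord[2]
  if (d[i1] == 0) {
    rlang::abort("A neighbor coincides with the current box center.",
                 class = "dentpost_degenerate_geometry_error")
  }
  theta <- neighbor_angle(c(current$cx, current$cy),
                          c(others$cx[i1], others$cy[i1]),
                          c(others$cx[i2], others$cy[i2]))
  tibble::tibble(
    d1 = d[i1], d2 = d[i2], ratio = d[i2] / d[i1], theta = theta,
    n1 = i1, n2 = i2
  )
}
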