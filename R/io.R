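#' File formats and pipeline drivers
#'
#' Ground truth travels in the YOLO txt dialect (one file per image,
#' lines `class cx cy w h`, coordinates normalized to `[0, 1]`);
#' detections and raw predictions travel as JSONL (one JSON record per
#' box). All internal computation is in absolute pixels; normalized
#' inputs are denormalized at load using the image size.
#'
#' @name io
NULL

#' Read ground truth in YOLO txt format
#'
#' @param path Path to a txt file with lines `class cx cy w h`
#'   (normalized coordinates).
#' @param image_size Square image side used to denormalize.
#' @param image_id Identifier attached to the boxes; defaults to the
#'   file name without extension.
#' @return Tibble with `image_id`, `cls`, `cx`, `cy`, `w`, `h` (pixels).
#' @export
read_ground_truth <- function(path, image_size, image_id = NULL) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Ground-truth file not found: %s", path),
                 class = "dentpost_io_error")
  }
  if (is.null(image_id)) image_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(image_id = character(0), cls = integer(0),
                          cx = numeric(0), cy = numeric(0),
                          w = numeric(0), h = numeric(0)))
  }
  parsed <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(trimws(line), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(fields) != 5 || anyNA(vals)) {
      rlang::abort(sprintf("Malformed line %d in %s: '%s'", i, path, line),
                   class = "dentpost_parse_error")
    }
    if (vals[1] != round(vals[1]) || vals[1] < 0 || vals[1] > 6) {
      rlang::abort(sprintf("Class outside 0-6 at line %d in %s", i, path),
                   class = "dentpost_validation_error")
    }
    if (any(vals[2:5] < 0) || any(vals[2:3] > 1) || any(vals[4:5] > 1)) {
      rlang::abort(sprintf("Coordinates outside [0, 1] at line %d in %s", i, path),
                   class = "dentpost_validation_error")
    }
    tibble::tibble(cls = as.integer(vals[1]),
                   cx = vals[2] * image_size, cy = vals[3] * image_size,
                   w = vals[4] * image_size, h = vals[5] * image_size)
  })
  dplyr::bind_rows(parsed) |>
    dplyr::mutate(image_id = image_id, .before = 1)
}

#' Write ground truth in YOLO txt format
#'
#' @param gts Tibble with `cls`, `cx`, `cy`, `w`, `h` (pixels).
#' @param path Output file.
#' @param image_size Square image side used to normalize.
#' @export
write_ground_truth <- function(gts, path, image_size) {
  lines <- sprintf("%d %.9f %.9f %.9f %.9f", gts$cls,
                   gts$cx / image_size, gts$cy / image_size,
                   gts$w / image_size, gts$h / image_size)
  writeLines(lines, path)
  invisible(path)
}

#' Read detections or raw predictions from JSONL
#'
#' Each line is a JSON object with `image_id`, `cx`, `cy`, `w`, `h`, a
#' `scores` array of exactly 7 values, and optionally `cls` and
#' `score`. Round-trips with [write_detections()] to 9 decimal places.
#'
#' @param path JSONL file path.
#' @return Tibble with box columns, `s0`..`s6`, and `cls`/`score` when
#'   present.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Detections file not found: %s", path),
                 class = "dentpost_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- tibble::tibble(image_id = character(0), cx = numeric(0),
                          cy = numeric(0), w = numeric(0), h = numeric(0))
    out[score_cols] <- rep(list(numeric(0)), 7)
    return(out)
  }
  recs <- purrr::imap(lines, function(line, i) {
    rec <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    if (is.null(rec[["scores"]]) || length(rec[["scores"]]) != 7) {
      rlang::abort(sprintf("Record %d in %s: `scores` must have exactly 7 entries.",
                           i, path),
                   class = "dentpost_schema_error")
    }
    out <- tibble::tibble(image_id = rec[["image_id"]] %||% "img",
                          cx = rec[["cx"]], cy = rec[["cy"]],
                          w = rec[["w"]], h = rec[["h"]])
    out[score_cols] <- as.list(as.numeric(rec[["scores"]]))
    if (!is.null(rec[["cls"]])) out$cls <- as.integer(rec[["cls"]])
    if (!is.null(rec[["score"]])) out$score <- as.numeric(rec[["score"]])
    out
  })
  dplyr::bind_rows(recs)
}

#' Write detections or raw predictions as JSONL
#'
#' @param dets Tibble with `image_id`, box columns and `s0`..`s6`;
#'   `cls` and `score` are written when present.
#' @param path Output file.
#' @export
write_detections <- function(dets, path) {
  s <- if (nrow(dets) > 0) score_matrix(dets) else NULL
  lines <- purrr::map_chr(seq_len(nrow(dets)), function(i) {
    rec <- list(image_id = dets$image_id[i],
                cx = dets$cx[i], cy = dets$cy[i],
                w = dets$w[i], h = dets$h[i],
                scores = round(as.numeric(s[i, ]), 9))
    if ("cls" %in% names(dets)) rec$cls <- dets$cls[i]
    if ("score" %in% names(dets)) rec$score <- dets$score[i]
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 9)
  })
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a YAML configuration
#'
#' Recognized keys are the fields of [correction_params()], the fields
#' of [scene_params()], and `operating_conf`; unknown keys are rejected
#' with a message naming them.
#'
#' @param path YAML file.
#' @return A list: `correction` ([correction_params()]), `scene`
#'   ([scene_params()]), `operating_conf`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  corr_keys <- names(formals(correction_params))
  scene_keys <- names(formals(scene_params))
  known <- c(corr_keys, scene_keys, "operating_conf")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
                 class = "dentpost_validation_error")
  }
  corr <- do.call(correction_params, cfg[intersect(names(cfg), corr_keys)])
  scene <- do.call(scene_params, cfg[intersect(names(cfg), scene_keys)])
  list(correction = corr, scene = scene,
       operating_conf = cfg$operating_conf %||% 0.25)
}

#' Run the four-way correction ablation on one dataset
#'
#' Evaluates the same raw predictions under all four on/off
#' combinations of the category (Cls) and confidence (Conf)
#' corrections: plain NMS baseline, each correction alone, and both.
#'
#' @param raw Tibble of raw predictions (multi-image).
#' @param gts Tibble of ground-truth boxes.
#' @param params A [correction_params()] list.
#' @param operating_conf Confidence threshold for the precision/recall
#'   operating point.
#' @return Tibble with one row per combination: `cls_correction`,
#'   `conf_correction`, `map50`, `precision`, `recall`.
#' @export
run_pipeline <- function(raw, gts, params = correction_params(),
                         operating_conf = 0.25) {
  dets <- decode_predictions(raw)
  combos <- tidyr::expand_grid(cls_correction = c(FALSE, TRUE),
                               conf_correction = c(FALSE, TRUE))
  purrr::pmap_dfr(combos, function(cls_correction, conf_correction) {
    out <- if (conf_correction) {
      correct_confidence(dets, params)
    } else {
      nms_greedy(dets, conf_thresh = params$base_conf,
                 iou_thresh = params$nms_iou)
    }
    if (cls_correction) out <- apply_category_correction(out)
    ev <- evaluate_detections(out, gts, operating_conf = operating_conf)
    dplyr::bind_cols(
      tibble::tibble(cls_correction = cls_correction,
                     conf_correction = conf_correction),
      glance(ev)[c("map50", "precision", "recall")]
    )
  })
}

#' Grid sweep of the confidence-correction triggers
#'
#' Evaluates mAP@50 of the fully corrected pipeline over a grid of gap
#' ratio (`fn_ratio`) and angle (`fp_angle_deg`) triggers on a fixed
#' dataset — the tuning protocol behind the default operating point
#' (ratio swept 1 to 4 in steps of 0.5, angle 10 to 40 degrees in
#' steps of 5).
#'
#' @param raw,gts As in [run_pipeline()].
#' @param fn_ratios,fp_angles Numeric grids.
#' @param params Base [correction_params()]; each grid cell overrides
#'   `fn_ratio` and `fp_angle_deg`.
#' @param operating_conf Operating threshold passed through.
#' @return Tibble with `fn_ratio`, `fp_angle_deg`, `map50`; the argmax
#'   cell is attached as attribute `"best"`.
#' @export
sweep_correction <- function(raw, gts,
                             fn_ratios = seq(1, 4, by = 0.5),
                             fp_angles = seq(10, 40, by = 5),
                             params = correction_params(),
                             operating_conf = 0.25) {
  if (length(fn_ratios) == 0 || length(fp_angles) == 0) {
    rlang::abort("Empty sweep grid.", class = "dentpost_validation_error")
  }
  dets <- decode_predictions(raw)
  grid <- tidyr::expand_grid(fn_ratio = fn_ratios, fp_angle_deg = fp_angles)
  res <- purrr::pmap_dfr(grid, function(fn_ratio, fp_angle_deg) {
    p <- params
    p$fn_ratio <- fn_ratio
    p$fp_angle_deg <- fp_angle_deg
    out <- apply_category_correction(correct_confidence(dets, p))
    ev <- evaluate_detections(out, gts, operating_conf = operating_conf)
    tibble::tibble(fn_ratio = fn_ratio, fp_angle_deg = fp_angle_deg,
                   map50 = ev$map50)
  })
  attr(res, "best") <- res[which.max(res$map50), ]
  res
}
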