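#' Synthetic dentition scenes and emulated detector output
#'
#' The simulator generates the inputs the post-processing stack
#' consumes, without images or a trained network: ground-truth tooth
#' boxes arranged along a semi-elliptical dental arch, and raw
#' per-anchor predictions with the statistical structure the
#' corrections assume — several redundant jittered boxes per tooth,
#' class-score profiles peaked at the true ICDAS code (normal or
#' right-skewed), long-tail class frequencies, occasional near-end
#' teeth scored too low (planted false negatives behind a spacing gap),
#' and occasional tooth-like background boxes past the arch end
#' (planted false positives).
#'
#' @name synthetic
NULL

#' Default long-tail ICDAS class priors
#'
#' Relative frequencies of ICDAS codes C0-C6 in a large annotated
#' intraoral-photograph corpus: mild lesions dominate and severe ones
#' are rare (instance counts 9443, 21102, 14502, 8531, 6706, 725, 271),
#' normalized to probabilities.
#'
#' @return Named numeric vector of 7 probabilities summing to 1.
#' @export
icdas_priors <- function() {
  counts <- c(C0 = 9443, C1 = 21102, C2 = 14502, C3 = 8531,
              C4 = 6706, C5 = 725, C6 = 271)
  counts / sum(counts)
}

#' Parameters of the dentition-scene simulator
#'
#' The defaults define the package's standard study conditions; see the
#' methods vignette for the rationale behind each value.
#'
#' @param teeth_per_arch Number of teeth (>= 3); default 14 (one arch).
#' @param image_size Square image side in pixels; default 640.
#' @param arch_a,arch_b Horizontal and vertical semi-axes of the
#'   semi-elliptical arch (pixels). The default `b > a` puts the
#'   tightest curvature at the front of the arch (incisors), keeping
#'   the posterior segments straighter, as in real dentitions.
#' @param arch_center `c(x, y)` of the ellipse center.
#' @param class_priors 7 probabilities for ICDAS codes C0-C6; default
#'   [icdas_priors()] (long tail); use `rep(1/7, 7)` for balanced tests.
#' @param width_gradient Relative mesiodistal width spread along the
#'   arch: tooth width scales from `1 + width_gradient` at the ends
#'   (molars) down to `1 - width_gradient` at the center (incisors),
#'   around the base size set by the arch length. Default 0.225; 0
#'   gives uniform widths.
#' @param end_crowding Multiplier on the two terminal gaps (posterior
#'   crowding: the last molar sits tighter against its neighbor than
#'   regular spacing). Default 0.75; 1 gives an equidistant arch. The
#'   crowding is what makes a missing near-end tooth detectable: seen
#'   from the second tooth, the across-gap distance then exceeds twice
#'   the crowded terminal gap (`d2/d1 > 2`), while for an interior gap
#'   the second-nearest tooth is always the two-step same-side one at
#'   `d2/d1` just below 2.
#' @param score_sigma Spread (in class units) of the Gaussian score
#'   profile around the true code; default 0.8. 0 gives one-hot scores.
#' @param skew Probability that a detection's score profile is
#'   right-skewed (mode one code below the truth, heavy upper tail with
#'   weighted mean near the truth); default 0.25.
#' @param redundancy Raw anchor boxes emitted per tooth; default 3.
#' @param fn_rate Probability, per near-end candidate tooth (positions
#'   3 and `n - 2`, the crowded canine / corner region), that all its
#'   raw peak scores are rescaled into `[0.1, 0.45]` — a planted false
#'   negative sitting behind a spacing gap with `d2/d1 > 2`.
#' @param fp_rate Expected number (Poisson) of background false boxes
#'   per image, placed 2-3 gap units past a random arch end with
#'   tooth-like peak scores in `[0.5, 0.8]`.
#' @param jitter Positional/size noise (pixels, 1 sd) applied to ground
#'   truth and raw boxes; default 2. 0 disables all geometric noise.
#' @param fn_teeth Optional integer vector of tooth positions to force
#'   as planted false negatives (overrides `fn_rate`).
#' @param fp_count Optional fixed number of planted false positives
#'   (overrides the Poisson draw).
#' @return A list of class `"scene_params"`.
#' @export
scene_params <- function(teeth_per_arch = 14,
                         image_size = 640,
                         arch_a = 200,
                         arch_b = 230,
                         arch_center = c(320, 420),
                         class_priors = icdas_priors(),
                         width_gradient = 0.225,
                         end_crowding = 0.75,
                         score_sigma = 0.8,
                         skew = 0.25,
                         redundancy = 3,
                         fn_rate = 0.2,
                         fp_rate = 0.5,
                         jitter = 2,
                         fn_teeth = NULL,
                         fp_count = NULL) {
  stopifnot(
    teeth_per_arch >= 3,
    length(class_priors) == 7, all(class_priors >= 0),
    abs(sum(class_priors) - 1) < 1e-8,
    score_sigma >= 0, skew >= 0, skew <= 1, redundancy >= 1,
    fn_rate >= 0, fn_rate <= 1, fp_rate >= 0, jitter >= 0,
    width_gradient >= 0, width_gradient < 1,
    end_crowding > 0, end_crowding <= 1
  )
  structure(
    list(teeth_per_arch = teeth_per_arch, image_size = image_size,
         arch_a = arch_a, arch_b = arch_b, arch_center = arch_center,
         class_priors = class_priors, width_gradient = width_gradient,
         end_crowding = end_crowding, score_sigma = score_sigma, skew = skew, redundancy = redundancy,
         fn_rate = fn_rate, fp_rate = fp_rate, jitter = jitter,
         fn_teeth = fn_teeth, fp_count = fp_count),
    class = "scene_params"
  )
}

#' Sample ICDAS class labels
#'
#' @param n Number of labels.
#' @param priors 7 probabilities for C0-C6; default the long-tail
#'   [icdas_priors()].
#' @param seed Optional integer seed.
#' @return Integer vector of labels in `0..6`.
#' @export
sample_icdas_classes <- function(n, priors = icdas_priors(), seed = NULL) {
  if (length(priors) != 7 || any(priors < 0) || sum(priors) <= 0) {
    rlang::abort("`priors` must be 7 nonnegative values with positive sum.",
                 class = "dentpost_schema_error")
  }
  if (!is.null(seed)) set.seed(seed)
  sample(0:6, n, replace = TRUE, prob = priors)
}

#' Arc-length parameterization of the semi-elliptical arch
#' @noRd
arch_curve <- function(params, n_grid = 4001) {
  phi <- seq(0, pi, length.out = n_grid)
  x <- params$arch_center[1] + params$arch_a * cos(phi)
  y <- params$arch_center[2] - params$arch_b * sin(phi)
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  list(phi = phi, x = x, y = y, cumlen = c(0, cumsum(seg)),
       total = sum(seg))
}

#' Relative tooth widths along the arch (ends wide, center narrow)
#' @noRd
tooth_width_profile <- function(n, gradient) {
  p <- abs(seq_len(n) - (n + 1) / 2) / ((n - 1) / 2)
  1 + gradient * (2 * p - 1)
}

#' Generate the ground-truth dentition of one arch
#'
#' Tooth centers are spaced along the semi-elliptical arc with
#' arc-length gaps proportional to the mean width of the adjacent
#' teeth, so the arrangement is near-equidistant (consecutive gap
#' ratios well inside `[1/1.5, 1.5]`) and interior teeth see their two
#' nearest neighbors on either side (`theta > 90` degrees). Box sizes
#' follow the width profile with jitter.
#'
#' @param params A [scene_params()] list.
#' @param seed Optional integer seed.
#' @param image_id Image identifier stored in the output.
#' @return Tibble of ground-truth boxes: `image_id`, `tooth` (position
#'   1..n along the arch), `cls`, `cx`, `cy`, `w`, `h`.
#' @export
generate_arch <- function(params = scene_params(), seed = NULL,
                          image_id = "img_001") {
  if (!is.null(seed)) set.seed(seed)
  n <- params$teeth_per_arch
  curve <- arch_curve(params)
  rel_w <- tooth_width_profile(n, params$width_gradient)
  rel_gaps <- (rel_w[-n] + rel_w[-1]) / 2
  rel_gaps[c(1, n - 1)] <- rel_gaps[c(1, n - 1)] * params$end_crowding
  unit <- curve$total / sum(rel_gaps)
  if (unit * min(rel_w) < 4) {
    rlang::abort("Arch too small for this many teeth.",
                 class = "dentpost_geometry_error")
  }
  s_pos <- c(0, cumsum(rel_gaps * unit))
  cx <- stats::approx(curve$cumlen, curve$x, xout = s_pos)$y
  cy <- stats::approx(curve$cumlen, curve$y, xout = s_pos)$y
  w <- 0.95 * rel_w * unit
  h <- 1.15 * w
  j <- params$jitter
  if (j > 0) {
    cx <- cx + stats::rnorm(n, 0, j)
    cy <- cy + stats::rnorm(n, 0, j)
    w <- pmax(w + stats::rnorm(n, 0, j), 4)
    h <- pmax(h + stats::rnorm(n, 0, j), 4)
  }
  tibble::tibble(
    image_id = image_id, tooth = seq_len(n),
    cls = sample_icdas_classes(n, params$class_priors),
    cx = cx, cy = cy, w = w, h = h
  )
}

#' Score profile over the 7 ICDAS codes for one detection
#'
#' Symmetric: discretized Gaussian centered at the true code. Skewed:
#' mode one code below the truth with a heavy upper tail whose weighted
#' mean sits near the truth — the profile shape for which the argmax
#' decode is wrong by one code and the weighted-average correction
#' recovers the true code.
#' @noRd
score_profile <- function(true_cls, sigma, skewed = FALSE) {
  cls <- 0:6
  if (skewed && true_cls >= 1) {
    rel <- cls - true_cls
    s <- numeric(7)
    s[match(-1, rel)] <- 1
    s[match(0, rel)] <- 0.9
    if (true_cls + 1 <= 6) s[match(1, rel)] <- 0.55
    if (true_cls + 2 <= 6) s[match(2, rel)] <- 0.25
    if (true_cls - 2 >= 0) s[match(-2, rel)] <- 0.05
    return(s)
  }
  if (sigma == 0) return(as.numeric(cls == true_cls))
  exp(-(cls - true_cls)^2 / (2 * sigma^2))
}

#' Emulate raw detector output over a ground-truth dentition
#'
#' For each tooth, `redundancy` jittered anchor boxes are emitted, each
#' with a 7-class score profile peaked at the true code and rescaled so
#' the peak lands in `[0.6, 0.95]`. Planted false negatives (near-end
#' candidate teeth, probability `fn_rate` each, or the forced
#' `fn_teeth`) have peaks rescaled into `[0.1, 0.45]` instead — teeth
#' whose features did not earn a high score. Planted false positives
#' (`fp_rate` expected per image) are single stray boxes past a random
#' arch end with tooth-like peaks in `[0.5, 0.8]` — mouth openers,
#' bubbles on the lens.
#'
#' @param gts Ground-truth tibble from [generate_arch()].
#' @param params A [scene_params()] list.
#' @param seed Optional integer seed.
#' @return A list: `raw` (tibble of raw predictions with provenance
#'   columns `tooth` and `source`), `injected_fn` (tooth positions
#'   planted as false negatives), `injected_fp` (row indices in `raw`
#'   of planted background boxes).
#' @export
emulate_detector <- function(gts, params = scene_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(gts)
  if (is.null(params$fn_teeth)) {
    cand <- if (n >= 6) c(3L, n - 2L) else integer(0)
    fn_teeth <- cand[stats::runif(length(cand)) < params$fn_rate]
  } else {
    fn_teeth <- as.integer(params$fn_teeth)
  }
  j <- params$jitter
  rows <- purrr::map(seq_len(n), function(i) {
    r <- params$redundancy
    skewed <- stats::runif(r) < params$skew
    peak_lo <- if (gts$tooth[i] %in% fn_teeth) 0.1 else 0.6
    peak_hi <- if (gts$tooth[i] %in% fn_teeth) 0.45 else 0.95
    peaks <- stats::runif(r, peak_lo, peak_hi)
    noise_sd <- if (params$score_sigma > 0) 0.01 else 0
    s <- t(vapply(seq_len(r), function(k) {
      prof <- score_profile(gts$cls[i], params$score_sigma, skewed[k])
      prof <- prof * peaks[k] / max(prof)
      pmin(pmax(prof + stats::rnorm(7, 0, noise_sd), 0), 1)
    }, numeric(7)))
    # renormalize so the peak is exactly the drawn value after noise
    s <- s * peaks / apply(s, 1, max)
    out <- tibble::tibble(
      image_id = gts$image_id[i], tooth = gts$tooth[i], source = "tooth",
      cx = gts$cx[i] + stats::rnorm(r, 0, j),
      cy = gts$cy[i] + stats::rnorm(r, 0, j),
      w = pmax(gts$w[i] + stats::rnorm(r, 0, j), 4),
      h = pmax(gts$h[i] + stats::rnorm(r, 0, j), 4)
    )
    out[score_cols] <- as.data.frame(s)
    out
  })
  raw <- dplyr::bind_rows(rows)
  n_fp <- if (!is.null(params$fp_count)) params$fp_count else
    stats::rpois(1, params$fp_rate)
  injected_fp <- integer(0)
  if (n_fp > 0) {
    fp_rows <- purrr::map(seq_len(n_fp), function(k) {
      end <- sample(c(1L, n), 1)
      nb <- if (end == 1L) 2L else n - 1L
      gap <- sqrt((gts$cx[end] - gts$cx[nb])^2 + (gts$cy[end] - gts$cy[nb])^2)
      # outward continuation of the arch past its end
      dx <- gts$cx[end] - gts$cx[nb]; dy <- gts$cy[end] - gts$cy[nb]
      len <- sqrt(dx^2 + dy^2)
      d <- stats::runif(1, 2, 3) * gap
      cxf <- gts$cx[end] + d * dx / len + stats::rnorm(1, 0, j)
      cyf <- gts$cy[end] + d * dy / len + stats::rnorm(1, 0, j)
      prof <- score_profile(sample(0:6, 1), params$score_sigma, FALSE)
      prof <- prof * stats::runif(1, 0.5, 0.8) / max(prof)
      out <- tibble::tibble(
        image_id = gts$image_id[1], tooth = NA_integer_,
        source = "background",
        cx = cxf, cy = cyf,
        w = gts$w[end] * stats::runif(1, 0.8, 1.1),
        h = gts$h[end] * stats::runif(1, 0.8, 1.1)
      )
      out[score_cols] <- as.list(prof)
      out
    })
    raw <- dplyr::bind_rows(raw, dplyr::bind_rows(fp_rows))
    injected_fp <- which(raw$source == "background")
  }
  list(raw = raw, injected_fn = sort(fn_teeth), injected_fp = injected_fp)
}

#' Simulate one dentition scene
#'
#' Generates the ground-truth arch and its emulated raw detector
#' output, with bookkeeping of the planted errors.
#'
#' @param params A [scene_params()] list.
#' @param seed Optional integer seed controlling the whole scene.
#' @param image_id Image identifier.
#' @return An object of class `"dentition_scene"`: a list with `gts`,
#'   `raw`, `injected_fn` (tooth positions whose scores were
#'   suppressed), `injected_fp` (row indices of planted background
#'   boxes in `raw`), and `params`.
#' @export
simulate_scene <- function(params = scene_params(), seed = NULL,
                           image_id = "img_001") {
  if (!is.null(seed)) set.seed(seed)
  gts <- generate_arch(params, image_id = image_id)
  det <- emulate_detector(gts, params)
  structure(
    list(gts = gts, raw = det$raw, injected_fn = det$injected_fn,
         injected_fp = det$injected_fp, params = params),
    class = "dentition_scene"
  )
}

#' @export
print.dentition_scene <- function(x, ...) {
  cat(sprintf(
    "Dentition scene '%s': %d teeth, %d raw predictions, %d planted FN, %d planted FP\n",
    x$gts$image_id[1], nrow(x$gts), nrow(x$raw),
    length(x$injected_fn), length(x$injected_fp)))
  invisible(x)
}

#' Degrade raw predictions (score noise + positional jitter)
#'
#' Emulates image-level distortion (noise, blur, compression) at the
#' prediction level: zero-mean Gaussian noise with sd `0.05 * level` is
#' added to every class score (clipped to `[0, 1]`) and positional
#' jitter with sd `2 * level` pixels to every box center. `level = 0`
#' is the identity.
#'
#' @param raw Tibble of raw predictions.
#' @param level Nonnegative degradation level.
#' @param seed Optional integer seed.
#' @return Degraded copy of `raw`.
#' @export
degrade_predictions <- function(raw, level, seed = NULL) {
  stopifnot(level >= 0)
  if (level == 0) return(raw)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(raw)
  raw$cx <- raw$cx + stats::rnorm(n, 0, 2 * level)
  raw$cy <- raw$cy + stats::rnorm(n, 0, 2 * level)
  for (col in score_cols) {
    raw[[col]] <- pmin(pmax(raw[[col]] + stats::rnorm(n, 0, 0.05 * level), 0), 1)
  }
  raw
}

#' Generate a multi-image synthetic dataset on disk
#'
#' Writes `n_images` scenes: per-image ground truth in the YOLO txt
#' dialect under `labels/`, all raw predictions as one JSONL file, and
#' a JSON manifest recording the parameters and per-image seeds so the
#' dataset is fully reproducible.
#'
#' @param n_images Number of scenes.
#' @param params A [scene_params()] list.
#' @param dir Output directory (created if needed).
#' @param seed Master integer seed; per-image seeds are derived from it.
#' @return Invisibly, the manifest list.
#' @export
generate_dataset <- function(n_images, params = scene_params(),
                             dir, seed = 1) {
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  image_ids <- sprintf("img_%04d", seq_len(n_images))
  seeds <- derive_seeds(seed, n_images)
  all_raw <- list()
  injected <- list()
  for (i in seq_len(n_images)) {
    sc <- simulate_scene(params, seed = seeds[i], image_id = image_ids[i])
    write_ground_truth(sc$gts, file.path(dir, "labels", paste0(image_ids[i], ".txt")),
                       image_size = params$image_size)
    all_raw[[i]] <- sc$raw
    injected[[i]] <- list(image_id = image_ids[i],
                          fn_teeth = sc$injected_fn,
                          fp_rows = sc$injected_fp)
  }
  raw <- dplyr::bind_rows(all_raw)
  write_detections(raw, file.path(dir, "predictions.jsonl"))
  manifest <- list(
    n_images = n_images, image_ids = image_ids, seeds = seeds,
    image_size = params$image_size,
    params = unclass(params), injected = injected
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Per-image seeds derived from a master seed (kept below 2^31)
#' @noRd
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 1000003 + 9973 * seq_len(n)) %% 2147483647
}

#' Read back a dataset written by [generate_dataset()]
#'
#' @param dir Dataset directory.
#' @return A list with `gts` (all images), `raw`, and `manifest`.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  gts <- purrr::map_dfr(manifest$image_ids, function(id) {
    read_ground_truth(file.path(dir, "labels", paste0(id, ".txt")),
                      image_size = manifest$image_size, image_id = id)
  })
  raw <- read_detections(file.path(dir, "predictions.jsonl"))
  list(gts = gts, raw = raw, manifest = manifest)
}
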