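---
title: "Post-processing corrections for ordinal tooth-instance detection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-processing corrections for ordinal tooth-instance detection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(dentpost)
library(dplyr)
```

## The problem

A tooth-instance detector scans an intraoral photograph and, at every
anchor point of its feature grid, emits a candidate bounding box plus a
score for each of the seven ICDAS caries codes (C0 sound … C6 extensive
cavity). Two structural facts about this task are ignored by the
standard decode-and-suppress pipeline:

1. **The labels are ordinal.** Adjacent ICDAS codes look alike, so the
   seven scores typically form a peaked profile around the true code.
   Taking only the argmax discards the profile's shape; when the mass
   above the peak outweighs the mass below it, the code one step up is
   usually the better answer.
2. **Teeth are arranged on an arch.** Adjacent teeth form a nearly
   equidistant, locally linear chain. A detection pattern that violates
   this — a gap twice the local spacing, or a high-confidence box whose
   nearest neighbors all lie in one direction — signals a missed tooth
   or a background false positive (a mouth opener, a bubble on the
   lens).

`dentpost` implements the two post-processing corrections built on
these facts, plus the NMS variants they wrap, an mAP@50 evaluator, and
a synthetic dentition/detector simulator so every stage can be
exercised and measured without images or trained weights. All data
structures are plain tibbles: one row per box, with center-form
coordinates `cx, cy, w, h` (pixels; x right, y down) and score columns
`s0`–`s6`.

## Decode and non-maximum suppression

`decode_predictions()` takes the per-row maximum score as the
confidence and its class as the prediction (ties to the lower code).
`nms_greedy()` then drops boxes below the confidence threshold
(default 0.1; boxes exactly at the threshold are kept) and greedily
keeps the highest-scoring box while removing every remaining box whose
IoU with it strictly exceeds the IoU threshold (default 0.5).
Suppression is deliberately class-agnostic: a tooth is a single
physical object, so two boxes on the same tooth are redundant even if
they disagree about the caries code. Score ties break by input row
order, making results reproducible.

`nms_soft()` is the linear Soft-NMS variant: overlapping candidates
are not removed but have their confidence multiplied by `1 − IoU`,
with sub-threshold boxes dropped after the sweep. At IoU 1 the decay
factor is 0 and the two algorithms coincide. Only the linear decay is
provided; a Gaussian decay would introduce a second bandwidth
parameter without changing anything the corrections depend on.

## Category correction

For a score vector $s_0,\dots,s_6$ the corrected code is

$$\widehat{c} \;=\; \mathrm{round}\!\left[\frac{\sum_{c=0}^{6} c\, s_c}{\sum_{c=0}^{6} s_c}\right],$$

except when the argmax is C0 or C6, where the argmax is kept: a
weighted mean is always strictly inside $(0, 6)$, so without the
reversion every sound tooth and every extensive cavity would drift
toward the middle codes. The scores are used unnormalized with an
explicit division, so the rule accepts both softmax and
independent-sigmoid detector heads. Rounding is fixed to
half-away-from-zero (3.5 → 4) rather than the platform's banker's
rounding, so behavior is identical everywhere. The correction is
applied after NMS, to surviving detections only; each detection's box,
confidence and rank are untouched. The reported confidence remains
`max(scores)` — the corrected code's own score would down-weight
exactly the detections the correction just improved.

## Confidence correction

The spatial pass runs in three stages
(`correct_confidence()`):

1. **Anchor selection.** Greedy NMS at a high threshold (0.5) yields
   the anchor teeth — boxes reliable enough to trust their geometry.
2. **Score adjustment** (`adjust_scores()`). For each anchor, let
   $d_1 \le d_2$ be the center distances to its two nearest fellow
   anchors and $\theta$ the angle those two centers subtend at it. In
   the normal regime ($d_2/d_1 < 1.5$, $\theta > 90^\circ$) nothing
   happens. Otherwise:
   - **Gap rule (R1), $d_2/d_1 > 2$:** a tooth is probably missing
     between the anchor and its second neighbor. A box is simulated in
     the gap (dimensions: mean of the two anchors'), and every
     non-anchor detection overlapping it with IoU > 0.6 is boosted by
     $s \leftarrow s + 0.5\,(1-s)$ — the $(1-s)$ term caps the result
     at 1.
   - **Background rule (R2), $\theta < 33^\circ$ and
     $d_2/d_1 \le 2.7$:** both neighbors lie in one direction; the
     anchor sits off-arch and its score is multiplied by a small
     factor (default 0.1, below).
   - **Edge rule (R3), $\theta < 33^\circ$ and $d_2/d_1 > 2.7$:** the
     anchor is an edge tooth rather than background; it is boosted
     with the same formula as R1.

   After any adjustment the full score vector is rescaled
   proportionally so its maximum equals the new confidence, keeping a
   later category correction consistent. Each rule touches a box at
   most once per image, and images with fewer than three anchors pass
   through untouched ($d_1, d_2, \theta$ are undefined there).
3. **Final NMS** at the original threshold (0.1) produces the output.

### Design choices worth explaining

**The far-field gate.** The angle rules carry an extra condition: they
fire only when the anchor's $d_1$ exceeds `far_d1` (default 1.5) times
the median nearest-anchor distance in the image. The reason is
geometric: the terminal tooth of *any* convex arch sees both of its
nearest neighbors on the same side, and the angle they subtend is
about half the per-tooth tangent turn — a few degrees, far below
33° — so without the gate the background rule would fire on every last
molar in every image. What distinguishes a genuine background box is
not the small angle alone but being *far from the other teeth*; the
gate encodes exactly that, with the median spacing as the scale so the
rule stays invariant to image resolution. Setting `far_d1 = 0`
disables the gate.

**The suppression factor.** With the final pass at confidence 0.1 and
anchors selected at 0.5, any factor at or above $0.1/0.5 = 0.2$ can
only re-rank a flagged false positive, never remove it from the
output. The default 0.1 is an order-of-magnitude cut that guarantees a
flagged anchor-level false positive falls below the final threshold;
it is config-exposed for users who prefer pure re-ranking (e.g. 0.5).

**Gap-box placement.** The simulated tooth is centered at the midpoint
of the segment from the flagging anchor to its second neighbor
(`gap_placement = "midpoint"`). The alternative — one $d_1$ step from
the anchor — is equivalent when $d_2 = 2 d_1$, but the gap rule fires
predominantly from anchors beside a crowded arch end, where $d_1$ is
the tightened terminal gap; stepping by $d_1$ then lands measurably
short of the gap center and the simulated box can miss the 0.6-IoU
criterion against the true tooth's raw boxes. The midpoint is exact
whenever the missing tooth sits centrally in its gap. `"distance"`
remains available as a switch.

**Rule precedence.** When an anchor satisfies both the small-angle and
the edge-ratio condition, the edge rule (boost) wins over the
background rule (suppression): that is the only ordering under which
both rules can be stated together without contradiction.

**Strict inequalities.** All triggers use strict comparison
(`d2/d1 > 2`, `θ < 33°`, IoU `> 0.6`), so a perfectly equidistant
collinear arrangement — where the terminal ratio is exactly 2 — fires
nothing.

**Duplicate gaps.** Two anchors flanking the same gap can both
simulate a box; simulated boxes with IoU > 0.5 are merged before
boosting so no detection is boosted twice.

## Evaluation

`match_detections()` implements the standard protocol: per image and
per class, detections in descending score order claim the unmatched
ground-truth box of highest IoU, provided IoU ≥ 0.5; each ground truth
is claimed at most once; leftovers are false negatives. Matching is
class-aware, so a correctly placed box with the wrong code is both a
false positive and a miss — this is what lets the category correction
move mAP. `average_precision()` uses all-point interpolation (the
precision envelope made monotone, integrated over recall), i.e. the
literal area under the precision–recall curve; mAP@50 averages AP over
the classes with at least one ground-truth instance, avoiding 0/0 for
codes absent from a test set. Operating-point precision/recall are
reported at a configurable threshold (default 0.25). `compare_runs()`
wraps the unpaired two-sample Wilcoxon rank-sum test for comparing two
sets of per-seed mAP scores.

## The simulator and its study conditions

`simulate_scene()` builds one upper arch per scene (the rules act on
local neighborhoods, so one arch exercises all of them):

- **Arch:** 14 teeth on a semi-ellipse, horizontal semi-axis 200 px
  and vertical 230 px in a 640 px image. With the vertical axis the
  longer one, curvature is tightest at the front (incisors) and the
  posterior segments are straighter, as in real dentitions.
- **Widths and spacing:** tooth widths taper from molars to incisors
  (`width_gradient = 0.225`, a 1.30:0.85 relative span) and
  center-to-center gaps are proportional to the mean width of the
  adjacent teeth, so consecutive gap ratios stay within about 15% of
  1 — comfortably inside the near-equidistant band. The two terminal
  gaps are tightened by `end_crowding = 0.75` (posterior crowding).
  This crowding is load-bearing: for an interior missing tooth the
  flagging anchor's second-nearest neighbor is the two-step same-side
  tooth at $d_2/d_1 = 2\cos(\alpha/2) < 2$, so interior gaps are
  geometrically undetectable by the ratio rule; only near an arch end,
  where the crowded terminal gap shrinks $d_1$, does a missing tooth
  push the ratio above 2. This matches the clinical picture the gap
  rule was designed for — crowded canines and corner wisdom teeth.
- **Classes:** i.i.d. draws from the long-tail ICDAS frequencies
  (`icdas_priors()`; C1 most common at ~34%, C6 rarest at ~0.4%).
- **Scores:** per tooth, 3 redundant boxes with 2 px positional
  jitter. Profiles are discretized Gaussians over the codes
  (σ = 0.8 class units) peaked at the true code and rescaled so the
  peak lands in [0.6, 0.95]. With probability `skew = 0.25` a profile
  is instead right-skewed — mode one code below the truth, heavy upper
  tail, weighted mean near the truth — the exact failure mode the
  category correction targets. At σ = 0 profiles are exactly one-hot.
- **Planted errors:** with probability `fn_rate = 0.2` each, the
  near-end candidate teeth (positions 3 and 12) have their peaks
  rescaled into [0.1, 0.45] — present but below the anchor threshold,
  a false negative in the making. An expected `fp_rate = 0.5`
  background boxes per image are placed 2–3 gap-units past a random
  arch end with tooth-like peaks in [0.5, 0.8]; they are single stray
  boxes, not redundant triples, because the redundancy structure
  models dense detector responses on real objects while a weak
  background artifact typically triggers an isolated anchor.
- **Degradation:** `degrade_predictions()` emulates image noise, blur
  and compression at the prediction level — score noise with
  sd 0.05·level and positional jitter 2·level px.

All of these values were fixed once, by the closed-form geometry above
and by what a practitioner would call a plausible detector, and define
the package's standard study conditions.

**What the simulator does not emulate** — and hence what passing tests
do not show about real data: pixel appearance (lighting, occlusion,
specularity), correlated detector errors across neighboring teeth,
two-arch scenes with occlusal contact (a two-arch layout is a
parameter choice away but not the default), class confusions that are
not ordinal-neighbor shaped, and detector miscalibration drift. Gains
measured on simulated scenes demonstrate that the corrections do what
their derivation claims under their stated assumptions; they are not
estimates of gains on photographs.

## Problem sizes and numerical conventions

The test suite checks the NMS and evaluator implementations against
independent brute-force oracles (1,000 random NMS instances of up to
12 boxes; 50 random evaluation fixtures, agreement to 1e-9), verifies
the no-op regime exactly, and measures planted-error recovery and
suppression on a fixed list of 20 seeds. The directional experiment
uses 20 seeds × 50 images with the default error rates and a one-sided
rank test; `scripts/acceptance.R` recomputes the same quantities from
scratch plus the four-way ablation (each correction alone and
together). These sizes were chosen so the whole suite runs in a few
minutes on one core while leaving the stochastic checks comfortable
margins.

Conventions: coordinates are absolute pixels internally (normalized
YOLO-txt input is denormalized at load); nearest-neighbor ties break
by lower row index; all random generation is controlled by explicit
integer seeds, with per-image seeds derived from a master seed kept
below 2³¹.

## Known limitations

- The gap rule can only recover a missing tooth flagged by a near-end
  anchor (see above); a missing tooth in a perfectly regular interior
  span is invisible to the `d2/d1` statistic by construction.
- The background rule suppresses only the flagged anchor box itself;
  if a background artifact produced several overlapping raw boxes, the
  survivors of the first NMS pass could re-emerge at the final pass.
- The evaluator implements mAP@50 only; mAP@[.5:.95] would need a
  straightforward loop over IoU thresholds but is not provided.
- Confidence intervals for mAP are not computed.

## A worked call

```{r example, eval = FALSE}
sc <- simulate_scene(scene_params(fn_teeth = 3, fp_count = 1), seed = 42)
dets <- decode_predictions(sc$raw)
baseline <- nms_greedy(dets, conf_thresh = 0.1, iou_thresh = 0.5)
corrected <- dets |>
  correct_confidence() |>
  apply_category_correction()
run_pipeline(sc$raw, sc$gts)  # the four-way ablation table
```
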