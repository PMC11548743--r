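---
title: "From pose tracks and call tables to light/dark statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pose tracks and call tables to light/dark statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratduet)
```

`ratduet` analyzes 20-minute recordings of rat pairs spanning a light/dark
transition: 10 minutes of one lighting condition, then 10 minutes of the
other.  Its inputs are the tabular outputs of upstream deep-learning tools —
per-frame keypoint coordinates for two animals (12 body parts each, 12 fps)
and per-call acoustic detections (onset, offset, principal frequency,
bandwidth) — and its output is a set of rank-based repeated-measures ANOVAs
asking whether the light switch changes each of 11 social behaviors and 4
ultrasonic call types.  This vignette explains the model choices, the
tunable parameters, what the synthetic-data generator does and does not
emulate, and the numerical conventions.

## Pose preprocessing

Keypoint detections carry a likelihood; coordinates below the cutoff
(`p_cutoff`, default 0.6 — the customary pose-estimation operating point)
are treated as missing and replaced by the *temporally nearest* trusted
value of the same series.  Nearest-neighbour interpolation (rather than
linear) is the right conservative choice for occlusion gaps: it never
invents intermediate positions during a hidden grapple, and it is
idempotent.  Ties between an equally distant earlier and later frame go to
the earlier frame, which also fixes the leading-fill direction.  A keypoint
never trusted in a whole session is set to 0 for every frame, because the
downstream forests need a complete matrix; the preprocessing step records
which parts it zero-filled so centroid computation can exclude them (for
tracks re-read from disk, a part frozen at the origin for the entire
session is recognized as filled).  No outlier correction is applied: the
interpolation plus the centroid-based features already absorb isolated
misdetections.

## The 111-feature vector

Classifier features are deliberately restricted — large generic feature
sets overfit and are expensive — to two families:

* **Polygon features.**  Each animal's body polygon is the convex hull of
  its 12 keypoints.  `polygon_pct_overlap` = 100·(intersection area) /
  min(area~A~, area~B~); the *smaller* hull in the denominator makes the
  measure saturate at 100 when one animal is on top of the other (mounting,
  crawling), which is exactly when it is most informative.  A union
  (Jaccard) denominator is available via an argument.
  `difference_area` is the absolute hull-area difference; the sign carries
  no information because animal identity assignment is arbitrary.
  Degenerate hulls (fewer than three distinct points) get area 0 and
  overlap 0.  Hulls and their intersection (Sutherland–Hodgman clipping of
  convex polygons) run in compiled code.
* **109 custom features** spanning the families that separate the
  ethogram's categories: the 24 raw likelihoods (occlusion itself is
  informative — during mounting the bottom animal's parts vanish); three
  centroids per animal (whole body; head = nose, both eyes, head; anogenital
  = pelvis, anogenital, tail middle) as coordinates and 1-s rolling means;
  body and head hull areas, rolling means, and each body hull's ratio to
  its own rolling mean (rearing shrinks it sharply); per-frame and 1-s
  rolling centroid movements plus a both-animal total (following and
  fighting are movement signatures); all nine between-animal centroid
  distances with rolling means and their minimum (proximity structure:
  nose–anogenital distance flags anogenital sniffing, head–head distance
  flags nosing); raw nose–nose and nose–anogenital keypoint distances;
  within-animal distances (nose–back, head-centroid–anogenital-centroid,
  nose–tail-end, nose–pelvis elongation — self-grooming folds the head to
  the pelvis); the nose–head–back and head–back–pelvis angles; and mean and
  minimum likelihood per animal.  The inventory is fixed — 109 columns,
  enumerated by `feature_manifest()` — so that trained models and new data
  can be checked against each other by name.

Rolling windows are *trailing* and one second long (`fps` frames),
truncated at the session start: frame *i* aggregates frames
max(1, *i*−`fps`+1)…*i*.  All rolling quantities therefore exist from frame
1 without NA padding.

Feature tables from the polygon and custom stages are merged by truncating
to the shorter row count (recordings can disagree by trailing frames), for
exactly 111 columns.

## Behavior classification

One independent binary random forest per behavior (probability forest, 100
trees by default, single-threaded for reproducibility); several behaviors
may be present on one frame, so this is multi-label, not multi-class.  The
data are split 80/20 with stratification per behavior — rare behaviors
would otherwise risk an empty test class — and no under- or over-sampling
is applied.  The split impurity is the Gini index, the standard impurity in
the R forest implementations; with hundreds of informative features the
choice between the common impurity measures does not alter which splits are
found.

The detection threshold comes from the precision-recall curve evaluated at
every distinct predicted probability on the held-out fraction, with
predicted-positive meaning probability ≥ threshold and F1 defined as 0 when
precision + recall = 0.  The selected point is the F1 argmax, ties broken
toward the higher (stricter) threshold.  Because prediction uses the strict
rule "present iff probability > threshold" (a probability exactly at the
threshold is absent), the stored threshold is the midpoint between the
argmax probability and the next lower distinct probability — the strict
rule then reproduces the selected operating point exactly.  Thresholds and
minimum bout lengths can be overridden per behavior through a YAML config,
which is where a user would record manual threshold adjustments after video
inspection.  The default minimum bout length is 0: a behavior may exist for
a single 1/12-s frame, which favours accurate *duration* estimates over
bout counts.

## Ultrasonic call typing

Call records are band-filtered first (50-kHz detector path: principal
frequency within [35, 95] kHz; 22-kHz path: [10, 35] kHz; bounds
inclusive), then typed:

| type  | rule |
|-------|------|
| ALARM | every call from the 22-kHz detector path (unknown detector: principal frequency < 32 kHz) |
| SHORT | duration ≤ 12 ms |
| FLAT  | duration > 12 ms and bandwidth ≤ 6 kHz |
| FM    | duration > 12 ms and bandwidth > 6 kHz |

Both boundary cases are inclusive on the first matching rule: a 12-ms call
is SHORT whatever its bandwidth; a 6-kHz-bandwidth call is FLAT.  FM calls
are not sub-typed into trills or steps, and no attempt is made to attribute
a call to one animal of the pair — microphones cannot separate them.  The
unit contract is seconds and kHz throughout.  Spectrogram/detector settings
are provenance of the upstream detection stage and are not re-applied here.

## Audio–video alignment

Audio and video come from different devices with different clocks and
different durations.  The audio stream is rasterized onto the video frame
clock: `floor(audio_duration × fps)` rows — drop a partial trailing frame,
never invent one.  Each call then sets its type's 0/1 column over the
inclusive span of frames it touches, so a 12-ms call (a seventh of a frame)
still marks one frame, and overlapping calls of different types can mark
the same frame.

Start lags are recovered from the session index timestamps, which recorders
log at whole-second resolution.  The later-starting stream defines time
zero; the earlier stream loses `round(lag × fps)` head frames; both tails
are cut to equal length.  Trimming only drops rows — it never rewrites an
annotation.  Because the sub-second part of the true lag is unrecoverable
from whole-second logs, the residual misalignment is bounded by one second
= 12 frames at 12 fps; with exact lags it is bounded by half a frame of
rounding.  The trim report records the head/tail cuts and the sub-frame
rounding residue.

## Epochs, design collapse and co-occurrence

Annotations are aggregated over consecutive 1-minute epochs (up to 720
frames at 12 fps); a category's duration in an epoch is its positive frames
divided by `fps`, so a behavior shown continuously for a whole epoch scores
60 s.  A trailing partial epoch is kept in the raw output with its true
length but excluded from the ANOVA cells, where only whole minutes are
comparable.  The 2×2 within-subject design collapses epochs 1–10
(before the light change) vs 11–20 (after), then days 1–3 (early) vs 4–6
(late), averaging whatever days exist; a box missing an entire cell is
flagged and dropped from that category's ANOVA.

Co-occurrence uses two unit conventions, chosen to match how the quantities
are read: for two *call types*, the per-epoch sum of their call counts
(1 SHORT + 4 FM = 5); for a *behavior × call type*, the number of calls of
that type whose marked frames intersect the behavior's positive frames — a
call-count unit, with a seconds-of-overlap variant behind an argument.

## Statistics

Durations of behavioral and call categories are heavily non-normal
(zero-inflated, right-skewed), so the pipeline screens each analysis cell
with four normality tests — Anderson–Darling, D'Agostino & Pearson
(implemented from the K² omnibus formulas and verified against an
independent implementation), Shapiro–Wilk, and Kolmogorov–Smirnov in its
Lilliefors form, the composite-null variant statistics packages actually
report — and applies a rank transform whenever any cell fails.  Ranks are
computed over the 4·n values entering *one* ANOVA (one category × one
session type), with average ranks for ties; ranking is not global across
categories, because each analysis is its own hypothesis.

Each 2×2 within-subject ANOVA is computed by the classical sums-of-squares
decomposition: every effect (lighting, phase, interaction) is tested
against its own subject-by-effect interaction, df = (1, n−1), with partial
η² = SS~effect~/(SS~effect~+SS~error~).  In a 2×2 design every effect has a
single df, so sphericity corrections are moot.  A zero error SS with a
positive effect SS is reported as F = ∞, p = 0 rather than NaN.  The full
battery is 15 categories × 2 transition directions = 30 ANOVAs; no
multiplicity correction is applied by default, matching the per-test α =
0.05 convention of exploratory designs of this kind, with Holm adjustment
available behind a flag.

## The synthetic study generator

The generator exists so the entire pipeline can be exercised against known
ground truth.  Its defaults are the study conditions: 6 boxes × 6 days × 2
transition directions, 1200-s sessions at 12 fps with the light change at
600 s, a 500 × 500 px arena (a 50 × 50 cm box at a nominal 10 px/cm — the
true pixel scale of the recordings is not knowable from the tables, so this
is a stand-in), audio start offsets uniform within ±2 s, audio durations
within ~2 s of video, index timestamps truncated to whole seconds, Gaussian
keypoint jitter of 1.5 px and 5% low-likelihood keypoints.

Rats are 2-segment body-axis skeletons with fixed part offsets.  Behavior
episodes are keyframed: each behavior imposes the geometric configuration
its classifier must detect (adjacent lying: parallel side-by-side contact
with near-zero movement; mounting: one animal atop the other with ~100%
hull overlap; rearing: one animal's hull contracted to a fraction of
baseline; following: a leader path with the follower one body length
behind; fighting: tight high-agitation tumbling; self-grooming: head folded
to pelvis far from the partner; and so on).  Episode demand is kept near
25% of each half-session and episodes are placed non-overlapping in random
order, so each frame's geometry belongs to one behavior and scheduling
pressure from one category cannot distort another's scripted rate — user
scripts may still overlap behaviors, except pairs whose postures contradict
(e.g. adjacent lying with following), which are rejected.  Call events are
Poisson (or fixed-count) per window per type, with acoustics sampled
strictly inside each type's defining region so rule-based typing recovers
the script exactly on clean data.

The programmed biology is a lights-off effect in light-to-dark sessions:
after minute 10 the fighting episode rate is multiplied by 5 and the
ALARM/FLAT/SHORT call rates by 8/3/3, while every other category keeps
symmetric rates — a known-positive and known-null set for end-to-end
recovery tests.  What the generator does *not* emulate: identity swaps
between the two similar-looking animals, camera distortion, detector false
positives/negatives and boundary-truncated calls, correlated (non-Gaussian)
keypoint noise, and within-episode behavioral variability beyond jitter.
Passing the recovery tests therefore shows the pipeline is correct and
sensitive under clean geometry, not that any particular classifier
accuracy will be reached on real videos.

## Problem sizes and numerical conventions

The test suite trains forests on three pooled sessions and analyzes a full
6 × 6 × 2 synthetic study at native scale (14,400 frames per session);
classifier tests use 40–60 trees, and the type-I-error simulation uses 200
replicates — sizes chosen so the whole suite completes in minutes while
leaving the study design itself untouched.  Numerical conventions
collected in one place: duration→rows uses floor; call→frame spans are
inclusive; interpolation ties break earlier; threshold ties break higher;
prediction is strict-greater; epoch bins and event bins are half-open with
boundary events in the later bin; hull degeneracies yield zeros rather than
NA; angles are degrees in [0, 180] at the middle vertex.

## Known limitations

* The classifier stage presumes the 111-column feature contract; models
  and features are matched by column name, and a mismatch is an error, not
  a silent reorder.
* Identity swaps are neither simulated nor repaired; on real tracks,
  frequent swaps would degrade the asymmetric features (who sniffs whom).
* The lighting factor is inferred from epoch position (1–10 vs 11–20), not
  from a photodetector signal; sessions that do not follow the
  10-minutes-each layout need the `change_epoch` argument.
* With 6 subjects the rank ANOVA has limited power for small effects;
  the battery reports raw p values, and 30 tests at α = 0.05 are expected
  to yield one or two false positives — interpretation should weigh effect
  sizes (partial η²), not stars alone.
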