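---
title: "Crowding and distancing violations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowding and distancing violations: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During the COVID-19 pandemic many countries asked pedestrians to keep a
minimum interpersonal distance (1.5 m in the Netherlands).  Whether people
comply is partly a question of circumstance: the more people share a street,
the harder it is to stay apart.  But a raw correlation between crowding and
close contacts is ambiguous — some close pairs are forced by geometry
(limited space), while others reflect behaviour (walking companions,
gravitating towards the middle of the street).  `crowdprox` implements the
full analysis chain needed to separate these components on ground-plane
pedestrian detections: proximity scoring, person- and frame-level
regressions, and a random-placement null model.

Because large-scale surveillance detection data are rarely shareable, the
package ships a synthetic scene generator that reproduces the statistical
structure such data exhibit, so that every downstream stage is exercised
end to end by code anyone can run.

## Outcome definitions

For every person in a still frame we count the *other* persons at
ground-plane Euclidean distance at most the threshold (default 1.5 m).
"Within a radius" is read as a closed ball (distance ≤ threshold): ties are
a measure-zero event with no statistical effect, but fixing the convention
makes tests bit-exact.  Two binary outcomes derive from the count:

* `violation` — at least one other person within the threshold;
* `violation2` — at least two others.  Detections cannot tell household
  members (exempt from distancing rules) from strangers; requiring two or
  more close contacts discounts the single walking companion and is the
  stricter proxy for stranger encounters.  Group identity known to the
  generator is deliberately *not* used in scoring.

Frames with fewer than two persons are excluded before scoring — a person
alone cannot be in violation, so such frames are uninformative.  At the
frame level we record both the number of violating persons and the number
of violating (unordered) pairs.  Which of the two a published aggregate
curve shows is not always knowable; the package computes both, uses
violators as the default frame-level outcome and pairs for the null-model
comparison (the null model is defined on pairs).

## The statistical battery

**Person level.**  A linear probability model regresses `violation` on the
number of persons present, so the slope is the change in violation
probability per additional person.  Persons in one frame share the same
scene, so standard errors are cluster-robust with frames as clusters:
the sandwich estimator over per-cluster score sums, with CR1 scaling
`G/(G-1) * (N-1)/(N-k)` — the convention of the major commercial
implementation of clustered OLS, adopted so results are comparable with the
bulk of the applied literature; CR0 is a switch away.  Camera fixed effects
are absorbed by within-camera demeaning of outcome and predictor (exact for
the slope); `k` then counts the absorbed means.  Confidence intervals use
normal quantiles (z = 3.4808 at the 99.95% level used for the very
conservative α = .0005 testing convention; z = 2.8070 at 99.5%): with
thousands of clusters the difference from t quantiles is far below the
reported precision.

**Robustness variants.**  The crowding predictor is winsorized at the Tukey
outer fence Q3 + 3×IQR, with quartiles by linear interpolation (type-7,
R's default; the fence value depends on the quantile algorithm, so the
choice is fixed and documented).  Values above the fence are capped at the
fence, all others untouched; the operation is idempotent.

**Frame level.**  OLS of the violator count on the persons present, with
conventional standard errors and R².  Aggregation to frames is also the
pragmatic answer to within-frame dependence: each frame contributes one
observation.

**Visualisation.**  Binned scatterplots assign observations to equal-count
quantile bins of the predictor (default 20; bin sizes differ by at most
one, ties broken by input order) and plot within-bin means of outcome
against predictor — a nonparametric view of the functional form.

**Reliability.**  Krippendorff's α (interval level, squared-difference
distance, exact coincidence-matrix computation) measures chance-corrected
agreement between two raters of per-frame violation counts.  Counts are
compared on an interval scale, the convention for this coefficient applied
to numeric ratings; a ratio-level distance is available.  The package's
`scorer_agreement()` mirrors a human-vs-machine validation: it scores the
same scenes twice, once complete and once with a fraction of detections
randomly dropped (an imperfect rater), and computes α on the per-frame
counts.  When expected disagreement is zero (all ratings identical) α = 1
is returned by convention and flagged.

## The random-placement null model

To quantify how many close pairs arise from geometry alone, fixed numbers
of individuals are placed uniformly and independently in a rectangle of
area A (default 650 m², a typical camera viewshed; 300 and 150 m² model
streets that are only partly walkable) and pairs within d = 1.5 m are
counted.  Attraction and repulsion are both absent by construction.  Three
design choices matter:

* *Boundary.*  The default is a plain rectangle — a literal street segment,
  where points near the edge have fewer potential neighbours.  A torus
  (wrap-around) mode removes edge effects; in that geometry the expected
  pair count is exactly `C(n,2)·πd²/A`, which makes the torus mode the
  analytic validation device: simulated torus means must sit within Monte-
  Carlo noise of the formula, and plain-rectangle means must sit below the
  torus means.  `expected_pairs_analytic()` exposes the formula and is
  documented as an upper bound for plain rectangles.
* *Aspect ratio.*  Only the area is typically known; the rectangle defaults
  to 2:1 (36.06 m × 18.03 m at 650 m²).  The effect of the aspect ratio on
  pair counts is second-order (it enters only through edge terms).
* *Coincident points.*  Placement is continuous with no hard-core
  exclusion radius: the null deliberately models *no* interaction at all.

Replicates default to 10,000 per crowd size with deterministic per-size
child seeds.  `compare_observed_to_null()` lines observed per-crowd-size
mean pair counts up against each null curve; crowd sizes absent from the
simulated grid are linearly interpolated and flagged.  An observed curve
above the null indicates attraction beyond geometric necessity.

Two arithmetic conveniences round the picture out.
`distancing_capacity(650, 1.5)` returns 433 under the simple area-ratio
convention `floor(A/d)` — the figure in circulation for how many people a
650 m² street could hold without violations.  That convention divides an
area by a length; the geometrically meaningful bound is hexagonal packing,
`floor(2A/(√3 d²))` = 333 at the same inputs, exposed as
`method = "hex_packing"` and clearly labelled.  `personal_space(650, 7)`
is the average space per person at median crowding, 92.86 m², displayed
as 93.

## The synthetic scene generator

The generator emulates the structure of hourly still frames from street
surveillance, not images: only ground-plane coordinates are produced.

* **Crowd sizes.**  Published summaries of such footage report a median of
  7 persons per frame (SD 7.7) over a 2–67 range: strongly overdispersed
  with a long right tail.  A negative binomial (size 1.2, mean 8) truncated
  to [2, 67] by exact renormalisation reproduces the median exactly and the
  SD to 7.69; parameters were fixed by matching those two statistics and
  are not revisited.
* **Companion groups.**  Street pedestrians walk alone or in small groups
  (households, dyads).  Default group-size probabilities are P(1) = 0.55,
  P(2) = 0.30, P(3) = 0.10, P(4) = 0.05 — singletons and dyads dominate.
  Group members sit on a circle around the group anchor whose
  adjacent-member spacing is drawn uniformly from 0.9–2.6 m, an interval
  straddling the 1.5 m threshold so that a walking companion is a close
  contact often but not always.
* **Attraction.**  Group anchors are placed by a sequential
  parent–offspring process: each anchor after the first is, with
  probability c/(1+c), Gaussian-scattered (sd 2 m) around a uniformly
  chosen earlier anchor, and otherwise placed uniformly.  The single knob
  c (`clustering_strength`) nests uniform placement at c = 0 and makes the
  violation rate monotonically increasing in c.  Anchors are confined to an
  inset rectangle so every member stays in the viewshed.
* **Calibration.**  The spacing interval, c = 0.6 and the 2 m scatter were
  calibrated once, at design time, so that the default 49-camera study
  reproduces the marginal person-level violation rate of ~0.44 reported
  for real footage; with those values the synthetic study also lands near
  the reported frame-level slope (~0.57 vs 0.61) and R² (~0.78 vs 0.80)
  without either being targeted.  They are defaults of the configuration
  object, not constants.
* **Determinism.**  One root seed; crowd sizes and every frame use child
  streams derived deterministically from (seed, frame index), so results
  never depend on generation order and datasets are byte-for-byte
  reproducible.

What the generator does *not* emulate: detector noise and occlusion
(except via the deliberate thinning used in reliability studies),
non-rectangular walkable areas, per-camera heterogeneity in area or
crowding (all viewsheds share the 650 m² default unless configured
otherwise), temporal dependence between frames, and any pedestrian
dynamics — frames are independent static snapshots.  Tests passing on
synthetic data therefore validate the *pipeline* — definitions, estimators,
null comparison — not the empirical claims about any particular city's
pedestrians.

## Numerical and degenerate-input conventions

* Distance comparisons are `<=`; scaling all coordinates and the threshold
  by the same constant leaves every outcome unchanged.
* A constant predictor, fewer than 2 clusters, fewer than 3 frames, or an
  empty input is an error, never a silent NA; cameras failing a
  precondition in the stratified fits are reported in an attribute.
* A degenerate design with a true zero slope variance can land a hair
  below zero in floating point; the variance is clamped at zero.
* `binscatter` requires at least as many distinct predictor values as
  bins; the pipeline shrinks the bin count to that limit per camera.

## Problem sizes

The shipped tests and the acceptance script run the default study at 49
cameras × 100 frames (~48,000 persons), the null model at 10,000
replicates per crowd size, the parameter-recovery study at 500 replicates
of 150 frames, and reliability at 600 frames — sizes chosen so the whole
battery completes in a few minutes on a single core while keeping
Monte-Carlo noise well below the tolerances tested.

## Known limitations

* The linear probability model is used deliberately (its slope is directly
  interpretable as percentage points per person); no logistic/probit
  alternative is provided.
* No spatial-autocorrelation correction beyond frame clustering and frame
  aggregation.
* Persons are not tracked across frames; exposure duration is out of
  scope.
* The area-ratio capacity convention is dimensionally loose (see above);
  both conventions are printed so readers can judge.
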