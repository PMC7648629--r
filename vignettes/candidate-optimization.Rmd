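---
title: "Candidate optimization for tooth detection: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate optimization for tooth detection: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothopt)
```

## The problem

A CNN tooth detector run on a dental panoramic radiograph emits, per
image, a set of candidate bounding boxes, each labeled with a tooth
position (Universal Tooth Numbering, 1–32) and a confidence score in
[0, 1]. Detectors of this kind are accurate but leak characteristic
errors: *double detections* (two boxes on one physical tooth),
occasional spurious boxes, and boxes carrying a neighbor's label. All
three inflate false positives while leaving recall nearly intact, so
the repair stage should prune aggressively without discarding true
teeth.

`toothopt` treats the repair as a discrete optimization. For each tooth
position $x$ with $N(x)$ detected candidates, the optimizer picks one
element of $\{C_{x,0}, C_{x,1}, \dots, C_{x,N(x)}\}$, where $C_{x,0}$
is the explicit *missing tooth* option and candidates are ranked by
decreasing confidence. A complete assignment $P$ (a *pattern*) is
scored

$$f(P) = \frac{1}{32}\sum_{x=1}^{32}
  \omega_c\,\mu_c(p_x) + \omega_p\,\mu_p(p_x),$$

with $\mu_c$ the detector confidence of the selected candidate and
$\mu_p$ the positional relationship score below. The weights satisfy
$\omega_c + \omega_p = 1$, so $f \in [0, 1]$.

## The positional relationship score

Adult dentition has strong geometric regularity along the arch: the
horizontal distance between the box centers of neighboring teeth falls
in a narrow, predictable band. The score of tooth $x$ averages a
trapezoidal membership function $\delta$ over its up-to-four in-range
neighbors $x+i$, $i \in \{-2,-1,1,2\}$ (two neighbors at arch ends,
three next to the ends):

$$\mu_p(p_x) = \frac{1}{|\Omega|}\sum_{p_y \in \Omega}\delta(p_x, p_y).$$

$\delta$ depends only on the absolute difference of horizontal box
centers: it is 0 below $a$ (two teeth cannot almost coincide), ramps
linearly from $k$ to 1 on $(a,b)$, is 1 on the plausible plateau
$[b,c]$, ramps back to $k$ on $(c,d)$, is 0 beyond $d$, and equals the
neutral constant $k$ whenever either tooth is missing — missing
neighbors neither reward nor punish a placement.

Parameters, all in pixels of the source radiograph (panoramic images
are typically 1400–3100 px wide; a global `scale` factor adapts resized
images):

| parameter | adjacent (order 1) | second-order (order 2) | meaning |
|---|---|---|---|
| a | 30 | 80 | below: implausibly close, score 0 |
| b | 47 | 97 | start of full-score plateau |
| c | 114 | 164 | end of plateau |
| d | 130 | 180 | above: implausibly far, score 0 |

and $k = 0.35$, the neutral/missing score. These defaults were fitted
to real panoramic data at native resolution and are exposed through
`delta_params()`.

### Numerical closure at the corner points

The piecewise definition uses strict inequalities, leaving the measure-
zero boundary points $a, b, c, d$ unassigned. We close each ramp and
the plateau at their endpoints ($a \mapsto k$, $b \mapsto 1$,
$c \mapsto 1$, $d \mapsto k$), which maximizes continuity: the only
discontinuities are the unavoidable jumps $0 \leftrightarrow k$ at $a$
and $d$.

### The missing-candidate confidence

$\mu_c$ of the rank-0 missing candidate is a genuinely open choice: it
is the price of declaring a tooth absent. We default it to $k = 0.35$,
consistent with $\delta$'s missing-tooth value, so that the all-missing
pattern scores exactly $k$ under any weights; it is exposed as
`missing_conf`. Raising it makes the optimizer more eager to discard
dubious candidates (precision up, recall down).

### The neighborhood at the jaw boundary

The index rule $1 \le x+i \le 32$ lets the neighborhood of tooth 16
(upper left) include teeth 17 and 18 (lower left), which sit nearly
below it, at small horizontal distance — so the literal rule penalizes
a perfectly placed tooth 16. We follow the literal rule by default
(it is what the published parameters were tuned with) and provide
`restrict_omega_to_jaw = TRUE` to truncate neighborhoods at the 16/17
boundary, which is the anatomically cleaner variant. The package's
tests exercise both.

## The search

`optimize_greedy()` is coordinate ascent: initialize with the
highest-confidence candidate per tooth ($C_{x,0}$ where none exist),
then sweep positions 1→32; at each position substitute every candidate
(including missing) into the working pattern, recompute the full score,
and accept strict improvements; stop after a sweep with no acceptance.
Strictness (no tolerance) plus the finiteness of the pattern space
guarantees termination and makes the result deterministic; the final
score can never fall below the initialization score.

Two sweep disciplines are provided because "try all candidates, keep
the best combination" can be read either way: `"immediate"` (default;
each improvement updates the working pattern before the next position —
standard coordinate ascent) and `"batch"` (evaluate all substitutions
against the sweep's starting pattern, apply the single best per sweep).
Both terminate; they can reach different local optima.

Internally the sweep rescores only the five positions a substitution
can affect (the tooth itself and the neighbors whose $\Omega$ contains
it) and re-anchors the full score after each acceptance, so incremental
round-off cannot accumulate; the tests verify the engine against a
naive term-by-term recomputation to 1e−12.

`optimize_exhaustive()` enumerates all $\prod_x (N(x)+1)$ patterns (the
whole search space) and is the oracle the greedy search is tested
against; it refuses spaces above `max_combinations` (default $10^6$)
rather than silently subsample. Ties on the maximum are broken toward
the lexicographically smallest rank vector — teeth 1→32 most
significant, rank 0 first — which the enumeration order delivers for
free and which makes the oracle invariant to candidate input order.
A whole-mouth sweep (not per-jaw) is used throughout, matching the
32-position objective.

## Evaluation

Matching is class-aware and greedy at IOU ≥ 0.5: within a tooth class,
detections in decreasing confidence order claim the unmatched
ground-truth box of highest overlap. A second detection on an
already-claimed box counts as a false positive — deliberately, since
duplicates are exactly the error the optimizer must be penalized for
keeping. Precision, recall and F1 are micro-averaged (pooled counts)
across teeth and images; AP is computed per tooth class by all-point
interpolation (exact area under the precision envelope; the 11-point
variant is selectable), and mAP macro-averages the APs of classes with
at least one ground-truth box. 0/0 ratios are reported as 0 with a
warning so aggregate tables stay total. Fold-wise aggregation
(`folds =` in `evaluate_dataset()`) reproduces K-fold cross-validation
reporting: one row per fold plus an average row.

## The synthetic detector simulator

No public radiograph dataset with per-tooth boxes is bundled, so
`sim_config()` + `generate_dataset()` stand in for the detector. The
generator emulates exactly the statistical structure the optimizer
relies on:

* two straight 16-tooth rows in a 2000 × 1000 px frame; adjacent
  horizontal center spacing drawn from Normal(80, 8) px and clipped to
  the adjacent-score plateau (47, 114), so a noise-free arch has
  $\mu_p \approx 1$ and the relationship between geometry and score is
  analyzable by construction;
* per-tooth absence with probability 0.08 (roughly 29.5 teeth per
  mouth, matching typical adult panoramic series);
* detector noise: missed detections (0.02), displaced duplicates
  (0.2, displaced 0.4–0.8 box widths so their IOU is below 0.5),
  neighbor label swaps (0.03), and Poisson(2) spurious boxes;
* confidences Uniform(0.7, 1) for correct and Uniform(0.3, 0.8) for
  erroneous candidates — overlapping on purpose, so confidence alone
  cannot separate them and the positional term has work to do;
* correct candidates are jittered by at most 12% of each box dimension,
  which keeps their IOU against the ground truth above 0.72: recall
  loss can only come from modeled misses, never from jitter.

Everything is seeded (case $i$ uses `seed + i`) and the manifest
regenerates a dataset bit-identically.

What the simulator does *not* model: arch curvature (rows are straight,
since $\delta$ only sees x-coordinates), box-size correlation with
tooth type, implants/residual roots/severely broken teeth, and the
spatially correlated failure modes of a real CNN. Passing tests
therefore demonstrate the correctness and the qualitative behavior of
the optimization and evaluation machinery — duplicates pruned,
precision up, objective never degraded — not clinical-grade performance
figures on real radiographs.

## Problem sizes in the test suite

The suite verifies the greedy search against the exhaustive oracle on
200 seeded instances of 6 teeth with up to 3 candidates each (the
largest size the oracle enumerates comfortably), checks the scoring
engine against a naive reimplementation on random instances, and runs
the end-to-end refinement comparison on 20 seeded datasets of 100
images — the dataset size the evaluation protocol is designed around.
The acceptance script repeats the end-to-end run at 100 images for both
published weight sets, (0.8, 0.2) and (0.5, 0.5).

## Known limitations

* The greedy search is a local optimizer; on a small fraction of
  instances it stops below the global optimum (the oracle-equivalence
  test reports the measured fraction). Chain-structured dynamic
  programming could solve the problem exactly but is not the published
  method.
* $\delta$ uses only horizontal distances, so it cannot penalize
  vertically displaced boxes or wrong-side placements at equal |Δx|;
  no left/right ordering constraint is imposed.
* Thresholds are pixel-absolute: images at substantially different
  resolutions need the `scale` parameter (or refitted thresholds).
* With `missing_conf = k`, a true tooth whose confidence falls well
  below $k$ can be dropped in favor of "missing"; this is the intended
  trade-off, biased toward precision.
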