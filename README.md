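# toothopt

Prior-knowledge candidate optimization for tooth detection on dental
panoramic radiographs.

CNN object detectors (e.g. faster R-CNN) applied to panoramic
radiographs output, for each tooth position, zero or more candidate
bounding boxes with confidence scores — and their characteristic failure
mode is the *double detection*: two boxes for one physical tooth, plus
occasional spurious boxes and neighbor label mix-ups. `toothopt`
implements the post-processing stage that repairs this: for each of the
32 permanent tooth positions (Universal Tooth Numbering; FDI conversion
included) it selects either one candidate or "missing" so as to maximize
a combined confidence + anatomical-plausibility objective. The package
is aimed at researchers building tooth-recognition pipelines who need
the refinement stage, its evaluation metrics, and a simulator to test
both without radiographs or a trained detector.

## The objective

A *pattern* P assigns one candidate **p**ₓ (or the missing-tooth option)
to each tooth position x = 1..32 and is scored

    f(P) = (1/32) Σₓ [ ω_c μ_c(pₓ) + ω_p μ_p(pₓ) ]

where μ_c is the detector confidence (a configurable surrogate for the
missing option) and μ_p is the positional relationship score: the mean,
over the up-to-four neighbors pₓ₊ᵢ, i ∈ {−2, −1, 1, 2}, of a
trapezoidal score δ of the horizontal center distance |pₓˣ − pᵧˣ|:
0 below a, ramp k→1 on (a, b), 1 on [b, c], ramp 1→k on (c, d), 0 above
d, and the neutral value k when either tooth is missing. Defaults:
(a, b, c, d) = (30, 47, 114, 130) px for adjacent neighbors,
(80, 97, 164, 180) px for second-order neighbors, k = 0.35,
(ω_c, ω_p) = (0.8, 0.2).

The search is greedy coordinate ascent: start from the
highest-confidence candidate per tooth, sweep positions 1→32 trying
every candidate (including "missing") at each, accept strict
improvements, stop when a full sweep accepts nothing. An exhaustive
enumerator over all ∏(N(x)+1) combinations serves as the test oracle.

Evaluation follows the standard detection protocol: class-aware greedy
matching at IOU ≥ 0.5 (duplicates on a matched ground truth count as
false positives), micro-averaged precision/recall/F1, per-tooth average
precision and mAP.

## Worked example

Tooth T1 got a double detection; the displaced box (x 1615–1675) has the
*higher* confidence, so confidence alone keeps the wrong one.
Optimization swaps in the box that fits the arch geometry:

```r
library(toothopt)
det <- data.frame(
  tooth      = c(1,    1,    2,    3,    4,    5),
  x_min      = c(1570, 1615, 1490, 1410, 1330, 1250),
  y_min      = 330, y_max = 430,
  x_max      = c(1630, 1675, 1550, 1470, 1390, 1310),
  confidence = c(0.90, 0.95, 0.88, 0.91, 0.85, 0.92))
cs  <- candidate_set(det, image_id = "example")
res <- optimize_greedy(cs, weights = score_weights(0.8, 0.2))
res
#> <tooth_optim> score 0.435016 (initial 0.429251 )
#>   teeth present: 5 of 32; sweeps: 2 ; evaluations: 12
pattern_detections(cs, res$ranks)[, c("tooth", "x_min", "x_max", "confidence", "rank")]
#>   tooth x_min x_max confidence rank
#> 1     1  1570  1630       0.90    2
#> 2     2  1490  1550       0.88    1
#> 3     3  1410  1470       0.91    1
#> 4     4  1330  1390       0.85    1
#> 5     5  1250  1310       0.92    1
```

The score rose from 0.429 to 0.435 and T1's rank-2 candidate (the
anatomically consistent one) replaced the rank-1 pick; the other 27
positions stay "missing", which is why the absolute score is modest.

On full synthetic datasets (100 images, duplicates + label swaps +
spurious boxes enabled) refinement typically lifts pooled precision
from ≈ 0.76 to ≈ 0.97 at nearly unchanged recall — run
`Rscript inst/cli/toothopt.R run-all --out out --seed 7` to see the
before/after report.

## Command line

`inst/cli/toothopt.R` is a thin Rscript over the exported functions:

```sh
Rscript inst/cli/toothopt.R simulate --out data --seed 1 --n-images 100
Rscript inst/cli/toothopt.R optimize --detections data/detections.csv --out run --weights 0.5,0.5
Rscript inst/cli/toothopt.R evaluate --detections run/optimized.csv \
        --ground-truth data/ground_truth.csv --pre data/detections.csv --out run --folds 10
Rscript inst/cli/toothopt.R run-all --out run --seed 7
```

Detections travel as CSV (corner coordinates) or COCO-style results
JSON (`bbox = [x, y, w, h]`, `category_id` = UTN tooth number), so real
detector output drops in unchanged. Every run directory receives its
effective `config.yaml`.

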