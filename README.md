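# fmsdetect

Rule-based detection and counting of fundamental movement skills (FMS) —
jumps and sidesteps — in 20-joint skeleton motion streams recorded by
consumer depth sensors, together with the reliability statistics used to
validate automated movement counts against human raters.

The package is aimed at movement scientists and active-video-game
researchers who want to count how often children (or adults) perform basic
motor patterns during free play, without frame-by-frame manual video coding.
It provides:

* a data model and file formats (binary `.kss`, JSONL) for skeleton streams:
  20 joints × XYZ position in metres, a per-joint tracking state
  (`tracked` / `inferred` / `not_tracked`), bone orientations and a
  timestamp per frame at a nominal 30 fps, with exclusion intervals for time
  spent outside the capture space;
* dual-sensor support: T-pose calibration of a second camera (yaw about the
  vertical axis + translation, accepted only if the two cameras agree on the
  wrist-to-wrist distance to within 10 cm) and per-joint fusion of the two
  views;
* a Boolean rule language over joint-motion conditions, with a plain-English
  renderer, a compact `.krt` file format, and a sliding-window matcher that
  counts rule matches in a stream;
* a synthetic session generator with ground truth, so the whole pipeline is
  testable end to end without any recording;
* reliability statistics for comparing two count vectors: intraclass
  correlation ICC(2,1) with a 95% CI and Fleiss interpretation bands,
  percentage agreement, and Bland–Altman limits of agreement.

## The classifier

A *condition* constrains the motion of one joint inside a time window: the
displacement along one axis relative to the window's anchor frame must reach
a threshold in strictly less than *W* seconds, either in magnitude
(|Δ| ≥ θ, a "changes at least" clause) or signed (Δ ≤ θ, a "changes less
than" clause). Conditions combine with `AND`, `OR` and `IF-THEN` into a
rule. The matcher slides an anchor over the stream; at each anchor the
window grows frame by frame, each condition is marked at the first frame
that satisfies it, and a match is declared at the first frame where the
whole Boolean expression holds. A continuous supra-threshold movement is
counted once (the run of immediately re-firing anchors is consumed), and no
window may cross an exclusion boundary.

The built-in rules are the final game-play classifiers:

* **JUMP** — vertical movement of the head, both ankles and the hip centre
  each changes at least 5 cm in under 1 second (all four ANDed);
* **SIDESTEP** — either hip centre, right foot and shoulder centre move
  horizontally (≥ 10 cm / 0.5 s, ≥ 30 cm / 0.3 s, ≥ 10 cm / 0.5 s), or the
  mirrored left-foot branch plus a signed clause requiring the right foot to
  move at least 25 cm towards the player's left in under 0.5 s.

`render_english(builtin_jump())` prints the exact clause set.

For reliability, counts from two sources over *n* participants are compared
with the single-measures, absolute-agreement intraclass correlation from
the two-way random-effects model,

    ICC(2,1) = (MSR − MSE) / (MSR + (k−1)·MSE + k·(MSC − MSE)/n),

interpreted by the Fleiss bands (≥ 0.75 excellent, < 0.40 poor, moderate
between), plus percentage agreement (mean of 100·min/max per participant)
and Bland–Altman limits of agreement (mean difference ± 1.96 SD).

## Worked example

Simulate the isolated-skills assessment protocol (three jumps, then twelve
sidesteps alternating sides), run the built-in rules, and score the
detections against the generator's ground truth:

```r
library(fmsdetect)

sim     <- simulate_session(fms_condition_config(seed = 42))
matches <- match_all(sim$stream)
matches
#> <fms_matches: JUMP = 3, SIDESTEP = 12>
#> # A tibble: 15 × 6
#>   rule     start_s end_s start_frame end_frame anchor_frame
#> 1 JUMP        2.07  2.1           63        64           35
#> 2 JUMP        5.07  5.07         153       153          125
#> ...

score_detection(sim$truth, matches)
#> # A tibble: 2 × 9
#>   rule     n_truth n_detected precision recall
#> 1 JUMP           3          3         1      1
#> 2 SIDESTEP      12         12        1      1
```

All fifteen scheduled movements are recovered, each within half a second of
its true onset, with no false positives. Reliability of two raters' counts
over eight participants:

```r
counts <- tibble::tibble(participant = 1:8,
                         r1 = c(21, 18, 25, 16, 22, 19, 24, 17),
                         r2 = c(20, 18, 26, 15, 22, 20, 23, 17))
icc21(counts, r1, r2)
#> ICC(2,1) = 0.973 (95% CI 0.875-0.994), n = 8, k = 2: excellent reliability
percentage_agreement(counts, r1, r2)
#> [1] 97
glance(bland_altman(counts, r1, r2))
#> # A tibble: 1 × 5
#>   mean_diff sd_diff loa_low loa_high     n
#> 1     0.125   0.835   -1.51     1.76     8
```

The ICC of 0.973 says 97% of the variance in the counts is between
participants rather than between raters; the Bland–Altman limits say the two
raters' counts differ by at most about ±1.8 movements per participant.
`autoplot()` draws the Bland–Altman plot; `ggplot2::autoplot(sim$stream)`
plots joint trajectories with matches overlaid.

A command-line front end is installed as `exec/fmsdetect` with subcommands
`simulate`, `calibrate`, `fuse`, `match`, `score` and `report`; every
subcommand is deterministic given its inputs and `--seed`.

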