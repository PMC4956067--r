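---
title: "Counting movement skills in skeleton streams: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting movement skills in skeleton streams: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmsdetect)
```

# The problem

Consumer depth sensors track a 20-joint skeleton at a nominal 30 frames per
second, reporting each joint as XYZ coordinates in metres with a per-joint
confidence flag (`tracked`: directly measured; `inferred`: reconstructed
from other joints; `not_tracked`: no data). During active video game play,
children perform fundamental movement skills — mainly jumps and sidesteps —
and researchers want to count them objectively instead of hand-coding
video. `fmsdetect` implements the whole chain: the stream data model and
file formats, two-camera calibration and fusion, a Boolean kinematic rule
language with a sliding-window matcher, a labelled synthetic-data
generator, and the reliability statistics used to compare automated counts
with human raters.

Coordinate conventions, fixed once and used everywhere: X is the player's
right (+), Y is up (+), Z is away from the camera (+), all in metres in
camera 1's frame; timestamps are seconds relative to the first frame.
"Vertical" in rule language means Y and "horizontal" means X.

# The rule model

A **condition** constrains one joint's motion inside a time window
anchored at a reference frame: writing $p_0$ for the joint's coordinate
along the condition's axis at the anchor and $p_t$ at a later frame, the
condition is satisfied at the first frame with elapsed time strictly less
than the window $W$ for which the displacement $d = p_t - p_0$ meets the
comparator: $|d| \ge \theta$ (`abs_ge`, a "changes at least" clause),
$d \ge \theta$, or $d \le \theta$ (`signed_le`, a "changes less than"
clause with $\theta < 0$). The strict bound reads "in under $W$ seconds"
literally. A joint that is `not_tracked` at the anchor or at a candidate
frame cannot satisfy a condition — game-play data contains dropouts, and a
dropout should silence a clause, not crash an analysis.

Angle conditions (the change in the angle at a joint, between the segments
to its parent and first child in the skeleton hierarchy) are accepted by
the grammar for completeness; the built-in rules use displacement only, and
terminal joints (head, hands, feet) have no defined angle.

Conditions combine into an expression tree with `AND`, `OR` (two or more
children) and `IF-THEN` (exactly two). Within a window an `IF-THEN` node is
true while its antecedent is unsatisfied, and, once the antecedent is first
satisfied, from the consequent's first satisfaction at or after that frame.
Because a vacuously true antecedent alone should never count as a movement,
a match additionally requires at least one satisfied condition. `IF-THEN`
is an extension point: the shipped classifiers never use it, so we chose
the least surprising sequential reading.

The built-in **JUMP** rule requires vertical movement of at least 5 cm in
under 1 s simultaneously (ANDed) for the head, both ankles and the hip
centre — a two-footed take-off that lifts the whole body. **SIDESTEP** is an
OR of a right-lead branch (hip centre ≥ 10 cm/0.5 s, right foot ≥ 30
cm/0.3 s, shoulder centre ≥ 10 cm/0.5 s, all horizontal magnitudes) and a
left-lead branch (the mirrored left-foot clause plus a signed clause:
the right foot moves at least 25 cm towards the player's left in under
0.5 s). The two branches are deliberately asymmetric — the published
classifier has the extra trailing-foot clause only on the left branch, and
we preserve that asymmetry verbatim rather than "fixing" it. The magnitude
comparator for the positive clauses and the signed comparator for the
negative one is the only reading under which both mirrored branches can
fire under a single axis convention.

## Matching semantics

The matcher scans anchors left to right, skipping frames inside exclusion
intervals. At an anchor the window grows frame by frame up to the largest
condition window $W_{\max}$; a valid match is declared at the first frame
where the Boolean expression over the marked conditions becomes true, and
an anchor whose window is exhausted advances by one frame (a sliding
window cannot miss an event this way). Windows never cross an exclusion
boundary: a movement interrupted by the player leaving the capture space is
not evidence of a completed skill.

One semantic point deserves care: a physical jump both rises **and** falls.
Under magnitude comparators, any anchor taken near the first
threshold-crossing of the ascent is re-satisfied by the descent (the body
returns to baseline, so the displacement from that anchor reaches the
threshold again), and anchors up to $W_{\max}$ *before* the take-off also
fire, because the take-off happens inside their window. Naively counting
every firing anchor would therefore double-count every jump and time-stamp
it almost a second early. `fmsdetect` resolves both issues structurally:

* after a valid match, the scan resumes at the match's end frame and
  **consumes** the run of consecutively re-firing anchors without recording
  them — one continuous movement, one match; a new match requires an anchor
  whose predecessor did not fire;
* the reported interval spans the frames that exhibited the displacement:
  from the earliest satisfying frame among the satisfied conditions to the
  frame at which the expression became true (the idle anchor itself is
  reported separately as `anchor_frame`).

With these rules, isolated supra-threshold events separated by at least
twice the window are recovered exactly once each, with start times within
half a second of the true onset — properties the test suite checks over
seeded replicates, and which also match the magnitudes reported for the
original validation study (system jump counts close to, not double, the
raters'). A brute-force oracle that evaluates every (anchor, end) pair with
explicit loops reproduces the production matcher exactly on hundreds of
random streams and rules.

A consequence worth knowing: count monotonicity in a threshold (raising an
`abs_ge` threshold never increases the count) holds for isolated events,
and is verified there, but is not a theorem on arbitrary signals — on a
long meandering trajectory a higher threshold can split one firing run in
two. This is inherent to counting "movements" rather than frames.

## The rule file format

Rules serialize to a line-oriented UTF-8 `.krt` format: a `RULE <name>`
header, leaves
`DISP <joint> <X|Y|Z> <ABS>=|>=|<=> <metres> WITHIN <seconds>` and
`ANGLE <joint> <cmp> <degrees> WITHIN <seconds>`, operators `AND`, `OR`,
`THEN` with precedence `AND` > `OR` > `THEN`, parentheses, and `#`
comments. A leaf may carry an optional `AS "<clause>"` label holding its
plain-English rendering; `render_english()` uses the label verbatim when
present and a canonical template otherwise. The labels exist because the
published clause set is typographically inconsistent ("5cm" vs "5 cm",
"Movement" vs "movement", "cm" vs "centimetres"), and faithful reproduction
of a published classifier should be byte-faithful, not normalised. The
shipped `inst/extdata/rules/jump.krt` and `sidestep.krt` parse to exactly
the built-in rules.

# Streams, files and exclusions

A stream is a tibble, one row per frame × joint in a fixed joint order,
with stream-level attributes (rate, metadata, exclusions), so the usual
data-frame tools apply. The binary `.kss` format is little-endian with a
16-byte header (magic `KSS1`, u16 version, u16 reserved, u32 frame count,
u32 rate in mHz) and fixed-size 508-byte frame records: an f64 timestamp,
20 × (3 × f32 position + 1 validity byte), and 20 × 3 × f32 Euler angles.
The validity byte packs the tracking state in its low two bits and, for
fused streams, a provenance code in bits 2–4. Fixed-size records make
truncation detectable (the reader names the offending frame) and seeking
trivial; 508 bytes is already 4-byte aligned, so no padding is needed.
Positions are stored in single precision — sub-0.1 mm at room scale, far
below sensor noise — while timestamps keep full double precision.
Recording metadata and exclusion intervals live in a JSON sidecar so the
binary frames stay fixed-size; a JSONL interchange format exists for
debugging and plain-text fixtures.

Exclusion intervals `[start, end)` mark time the participant spent outside
the capture space. Frames are flagged, never deleted: the matcher refuses
to anchor on them and windows cannot cross them, but timestamps and frame
indices stay stable. Flagging is idempotent and order-independent for
disjoint interval sets.

# Two-camera calibration and fusion

Two sensors flank the player to reduce self-occlusion. Calibration uses a
T-pose (arms straight, shoulders abducted to horizontal): the wrist-to-wrist
distance must agree between cameras to within 10 cm or the calibration is
rejected outright; the heading difference of the wrist-to-wrist vector in
the horizontal plane gives camera 2's yaw (both cameras are assumed level,
so a single rotation about Y suffices); and since a rotation alone cannot
co-locate two skeletons, aligning the hip centres after rotation supplies
the translation. Noise-free, the planted yaw is recovered to machine
precision across ±80°; with 1 cm Gaussian joint noise the error stays
around a degree, which a 1.4 m wrist baseline makes plausible
(atan(0.014/1.4) ≈ 0.6°).

Fusion pairs camera 2's frames to camera 1's by nearest timestamp within
half a frame period (bounded skew without resampling), transforms them, and
merges per joint: both usable (`tracked` or `inferred`) in the **same**
state → coordinate-wise mean (`averaged`); states differ → the directly
tracked sample wins (`cam1_only`/`cam2_only`) — averaging a measured and a
guessed position would corrupt the better one; one usable → that camera;
neither → camera 1's stored value, flagged `fallback_cam1`. Output
timestamps are camera 1's. Averaging two independently noisy views reduces
RMS error by the expected factor of √2, which the tests verify.

# The synthetic generator

`simulate_session()` renders a neutral standing skeleton (camera 2.5 m
away) with i.i.d. Gaussian postural sway per coordinate (default SD
0.5 cm — large enough to be honest about noise, an order of magnitude below
the 5 cm jump threshold), plus scheduled events:

* **jumps**: a half-sine vertical excursion of the whole skeleton over the
  event duration (default 0.10 m, 0.4 s) — the smooth rise-and-fall is what
  makes the double-count hazard above real, so the generator exercises it
  honestly rather than using a convenient monotone profile;
* **sidesteps**: a smoothstep lateral translation of the body by the
  amplitude (default 0.20 m over 0.6 s) that persists after the event
  (alternating sides keeps the player in the capture space), the lead foot
  travelling twice the amplitude in under 0.3 s and the trailing foot
  following within 0.5 s — proportions chosen so each clause of the
  published sidestep rule is exercised with roughly 2× margin over its
  threshold.

Occlusion spans arrive as a Poisson process (rate per minute, exponential
span lengths) and overwrite tracking states of randomly chosen joints;
positions are left as recorded, as real dropouts return stale or inferred
coordinates. The dual-camera mode renders camera 2 in its own rotated and
translated frame and puts independent measurement noise on both views.
`fms_condition_config()` encodes the isolated-skills assessment protocol —
three jumps then twelve sidesteps, six per side, alternating, ~3 s apart in
a 50 s session — used throughout validation.

What the generator does **not** emulate: biomechanical coupling between
joints (beyond rigid translation), countermovement depth, cadence
variability between children, systematic sensor biases, or
skeleton-tracking failure modes correlated with pose. Passing tests on
synthetic data therefore demonstrate the correctness of the *pipeline* —
rules, windows, exclusions, calibration, fusion, statistics — not the
field accuracy of the thresholds on new populations, which can only come
from human-rated recordings.

# Reliability statistics

Counts from two sources over $n$ participants are compared with the
single-measures, absolute-agreement intraclass correlation from the
two-way random-effects model (participants and raters both random),
computed from the ANOVA mean squares:

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + k(MS_C - MS_E)/n},$$

with the standard F-based 95% confidence interval and the Fleiss
interpretation bands (≥ 0.75 excellent, < 0.40 poor, moderate between). The
implementation is checked to 1e-10 against an independently coded oracle
that takes its mean squares from `stats::aov()`, against an external
reference implementation on a fixed example, and against the theoretical
ICC $\sigma_p^2/(\sigma_p^2+\sigma_r^2+\sigma_e^2)$ of data simulated from
the generating model at $n = 1000$.

Percentage agreement has no universal formula, and published figures often
omit theirs. We adopt the per-participant ratio $100\min(a,b)/\max(a,b)$,
averaged over participants, with a $(0,0)$ pair counting as full
agreement: it is scale-free, handles unequal counts, and is 100 exactly
iff the vectors are identical. Anyone comparing this package's percentage
agreement against previously published values should be aware the
definitions may differ; the ICC and the totals are the robust points of
comparison.

Bland–Altman limits use the literal 1.96 multiplier on the sample SD of the
differences (not a t-quantile), the convention of the original method and
of the validation study's figures. `reliability_report()` assembles the
per-source means ± SD, exact integer totals, ICC, percentage agreement and
limits of agreement for one skill × condition × comparison; its printed
table and JSON output come from the same numbers. The raters' consensus
("100% agreement") column is an input, not something the package computes:
the consensus process is a human discussion.

Count tables are read from CSV (`participant, condition, skill, rater1,
rater2, consensus, system`), with a column mapping for files using other
column names; spreadsheet sources should be exported to CSV first.

# Numerical and testing choices

* Strict window bounds (`<` not `≤`) everywhere, in both the matcher and
  the oracle, so borderline frames are treated identically.
* Rule thresholds serialize via R's default 15-significant-digit decimal
  formatting, which round-trips the decimal-valued thresholds rules are
  written with.
* ICC degenerate cases: fewer than 3 participants is an error (the ANOVA
  needs df), all-identical counts is an error (zero variance), identical
  non-constant vectors give ICC exactly 1 with a collapsed interval.
* Test problem sizes: matcher–oracle equivalence runs 500 random streams
  (20–90 frames, plus a handful at 300) × random rules; event-recovery
  checks use 20 seeded replicates of the 50 s skills protocol; the ICC
  simulation uses 1000 participants. These sizes give stable results while
  keeping the default suite fast.
* All stochastic tests fix their seeds; identical configs and seeds
  reproduce sessions — and `.kss` files — bit for bit.

# Known limitations

* The classifiers count movements; they say nothing about movement
  *quality*, and thresholds tuned for 10–15-year-olds will need re-tuning
  for younger children whose body dimensions differ.
* Fusion supports exactly two cameras at equal height; general multi-camera
  rigs and full 6-DoF extrinsics are out of scope.
* The consensus process between raters is not modelled.
* Percentage agreement is definition-dependent, as discussed above.
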