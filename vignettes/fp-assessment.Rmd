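---
title: "Facial-paralysis assessment from animation units: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facial-paralysis assessment from animation units: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpgrade)
```

## The clinical problem

Unilateral facial paralysis (FP) leaves one side of the face unable to move
normally while the other side serves as a within-subject reference. Clinical
grading scales (House–Brackmann, Nottingham, eFace) are subjective,
time-consuming and poorly repeatable. `fpgrade` implements a quantitative
alternative built on *facial animation units* (FAUs): 17 scalar activations,
tracked per video frame by consumer depth-camera SDKs, each describing one
facial muscle-group motion (Jaw Open, Lip Pucker, Left Eye Closed, ...).
Twelve of the units form six left/right mirror pairs — eyes, eyebrow
lowerers, lip corner pullers, lip stretchers, lip corner depressors and
cheek puffs — which is what makes bilateral symmetry computable directly
from the signal.

A patient is recorded at rest and while performing five voluntary
movements: smiling, eye closure, raising eyebrows, blowing cheeks and
whistling. From those six recordings the package produces three
complementary assessments:

1. **Symmetry analysis** — 18 animation symmetry indices (ASIs): 3 facial
   areas × 6 movements.
2. **Ability of movement** — five Yes / No / May-be decisions from a
   probabilistic movement classifier.
3. **Movement grading** — ten integer grades (5 movements × 2 sides) on a
   0–10 scale.

## Data model and units

Activations are dimensionless. Most units live in $[0, 1]$; the jaw-slide
and the two eyebrow-lowerer units are signed and live in $[-1, 1]$ (the
lowerer goes negative when the brow is *raised*). Frames failing these
bounds are rejected at the I/O boundary with the offending column and row
named. A session is an ordered frame sequence with patient, movement,
sample and affected-side metadata; CSV (frame per row) and JSON (session
structured) schemas round-trip losslessly.

The resting baseline is the per-unit **median** over the rest session
(restricted to well-tracked frames when a tracking flag is present). A
median rather than a single "resting frame" is a deliberate robustness
choice: consumer depth sensors glitch, and the median of even a short rest
recording is insensitive to isolated tracking failures.

## Symmetry: the animation symmetry index

For a mirror pair with activations $L$ and $R$,

$$\mathrm{ASI} = \bigl(1 - |L - R|\bigr) \times 100\% ,$$

clamped to $[0, 100]$. Clamping matters only for the signed eyebrow units,
where $|L-R|$ can exceed 1; without it the index would go negative and stop
being interpretable as a percent symmetry. The eyes and eyebrows areas each
use their single pair; the mouth ASI is the exact arithmetic mean of four
pair ASIs (corner puller, stretcher, corner depressor, cheek puff), and the
per-movement total is the exact mean of the three area ASIs. These two
identities are enforced to $10^{-12}$ in the test suite.

Static symmetry is evaluated on the rest baseline. Dynamic symmetry is
evaluated at the **peak frame** of each voluntary movement rather than
averaged over the session: asymmetry is clinically most meaningful at
maximal effort, and averaging over the neutral run-in frames would dilute
it toward the static value. The peak frame is the one maximising the mean
direction-folded movement-minus-rest delta over the units the movement
engages, ties broken toward the earliest frame (deterministic on plateaus).

## Grading: one point per completed tenth

Each movement engages specific units with a known direction of change:

| movement          | left unit               | right unit               | shared     | direction |
|-------------------|--------------------------|---------------------------|------------|-----------|
| smiling           | lip corner puller left   | lip corner puller right   | —          | increase  |
| eye closure       | left eye closed          | right eye closed          | —          | increase  |
| raising eyebrows  | left eyebrow lowerer     | right eyebrow lowerer     | —          | decrease  |
| blowing cheeks    | left cheek puff          | right cheek puff          | —          | increase  |
| whistling         | left cheek puff          | right cheek puff          | lip pucker | cheeks decrease, pucker increases |

The *effective delta* of a unit is `direction × (peak value − rest value)`,
so "the brow lowerer fell by 0.5" and "the puller rose by 0.5" score
identically. The grade is

$$\mathrm{grade} = \min\!\bigl(\lfloor (\max(\delta, 0) + 10^{-9}) \times 10 \rfloor,\; 10\bigr),$$

one point per **completed** 0.1 of effective delta, 10 exactly when the
delta reaches its maximum of 1. The $10^{-9}$ epsilon absorbs binary
floating-point representations of tenths ($0.3 \times 10 = 2.999\ldots$);
it is far below any physiologically meaningful difference. Negative
(paradoxical or synkinetic) deltas grade 0 rather than raising an error —
paradoxical motion is expected in FP and must not abort a report.

Whistling needs a combination rule: the pucker is a midline unit while the
cheek deflations are per side. The per-side whistling delta is the
unweighted mean of the shared pucker rise and that side's cheek decrease.
Unweighted because nothing in the phenomenology privileges either term, and
the mean keeps the delta on the same $[0,1]$ scale as the other movements.

## Ability of movement: the confidence-margin rule

A six-class radial-kernel SVM (via `e1071`/libsvm, with Platt-style
pairwise probability calibration) classifies each voluntary session from
its movement-minus-rest difference vector, restricted to the nine units
engaged by at least one movement (the default feature set; overridable at
training time). The decision rule compares the top two class confidences
$p_1 \ge p_2$:

* if $p_1 - p_2 < 0.07$ and the intended movement is one of the top two,
  the evidence cannot separate them: **"maybe"**;
* otherwise **"yes"** if the top class is the intended movement, **"no"**
  if not.

The 7-percentage-point margin is an absolute difference of calibrated
probabilities (so 0.46 vs 0.40 is inconclusive while 0.40 vs 0.33 is
decisive), applied strictly: a gap of exactly 0.07 is decisive. Exact
probability ties are broken by the canonical movement order, which makes
the rule total — every confidence vector maps to exactly one of the three
values. An intended movement outside the top two is always "no", even
under a small top-two gap.

The classifier shipped by the training pipeline is a stand-in trained on
synthetic healthy subjects (see below); it is **not** a clinically
validated model. Training is deterministic given a seed, and a saved model
reloads to bit-identical confidence vectors.

## ReliefF feature ranking

The mapping from movements to engaged units is itself derived, not assumed:
binary ReliefF (movement vs rest) on the 17 difference features. For each
instance, the `k = 10` nearest hits and misses by Manhattan distance on
range-normalised features contribute

$$W_f \mathrel{+}= \sum_{\text{miss}} \frac{\mathrm{diff}_f}{mk} - \sum_{\text{hit}} \frac{\mathrm{diff}_f}{mk},$$

with every instance used once ($m$ = all samples — the datasets are small
and subsampling would add a needless randomness source). A zero-range
feature is defined to contribute 0, hence weight 0. The implementation is
checked against an exhaustive brute-force oracle to $10^{-12}$.

Pooling the five per-movement rankings into one consensus list was a
genuinely open design point. Mean rank fails structurally: among the
near-zero-weight irrelevant features rank order is arbitrary, so a unit
that dominates a *single* movement (the eye units only matter for eye
closure) averages worse than a unit that is unremarkable everywhere.
Best-rank pooling fails more subtly: range normalisation makes whistling's
pucker and cheek features commensurate, so the pucker can rank third in its
only movement and tie with a lucky noise feature. The rule adopted is
**maximum weight across movements** (mean weight, then canonical order, as
tie-breaks): ReliefF weights are commensurable across movements precisely
because features are range-normalised, engaged-unit weights are an order of
magnitude above noise weights, and a single-movement specialist is never
displaced.

## The synthetic generator

Real FAU recordings of FP patients are not publicly available, so the
package ships a generator that emulates the acquisition protocol: per
session, frames follow

$$x_t = \text{rest level} + \text{offset} + \text{profile} \times \text{rise}(t) + \varepsilon_t,$$

clamped to the legal activation range, where `rise` is a smoothstep ramp
reaching its plateau at the final third of the session (so peak selection
has a well-defined, tie-broken target) and $\varepsilon_t$ is i.i.d.
Gaussian frame noise. Defaults, chosen once as plausible for consumer
depth-sensor data: 30 frames at 30 Hz (a one-second hold), noise SD 0.02
activation units, engaged-unit peak $|\delta| = 0.8$ (vigorous but
submaximal effort), resting levels 0.05 (cheek puffs 0.35, so that
whistling's cheek *deflation* is observable; signed units 0).

Unilateral palsy is modelled by two severity-coupled mechanisms, severity
$s \in [0,1]$:

* **dynamic attenuation** — movement deltas of affected-side units are
  scaled by $1 - s$; midline units (the whistling pucker) are attenuated
  too, reflecting that puckering requires both sides and FP patients
  typically cannot whistle. A consequence worth stating: the healthy-side
  whistling grade shares the pucker term and therefore also declines with
  severity, while the four lateralised movements keep a constant
  healthy-side grade.
* **static asymmetry** — a per-patient resting offset on affected-side
  paired units, drawn once per patient with scale
  $0.05 \times s$, reproducing resting droop.

The optional `mirrored_blow` mode encodes the clinical observation that
some patients can puff the affected cheek but not the healthy one; it is
off by default because the observation is surprising enough that it should
be an explicit modelling choice.

Everything is reproducible: sub-seeds are derived deterministically from
the master seed plus patient/movement/sample identity, so a given
configuration always produces bit-identical sessions, and the full
simulate → assess → render path produces byte-identical JSON.

What the generator does **not** emulate: synkinesis and involuntary
co-movement, tracking dropouts and non-Gaussian sensor artefacts,
inter-patient anatomical variability in resting levels, fatigue across
samples, and any correlation structure between units beyond the engaged
set. Tests passing on generator output therefore demonstrate the
correctness and internal consistency of the pipeline, not clinical
validity on real recordings.

## Numerical choices and degenerate inputs

* ASI clamped to $[0,100]$; mouth and total means exact by construction.
* Grade epsilon $10^{-9}$; negative deltas floor at grade 0.
* Peak-frame ties → earliest frame; ReliefF neighbour ties → lowest row
  index; ranking ties → canonical descriptor order; probability ties in the
  margin rule → canonical movement order. Every tie-break is deterministic.
* Constant (zero-range) ReliefF features get weight exactly 0.
* A rest-only patient yields a partial report with explicit missing
  markers; a missing rest session is an error, because both the symmetry
  baseline and all grades are defined relative to rest.
* Report metadata excludes wall-clock timestamps so that identical inputs
  render byte-identical JSON.

## Problem sizes

The test suite trains classifiers at 12–60 subjects per class, cross-checks
ReliefF against brute force at $n \le 20$ instances, recovers the
engaged-unit ranking at 60–200 subjects per class, and sweeps severity over
$0, 0.1, \ldots, 1$ noise-free plus 20 noise seeds at three severities.
These sizes give stable statistics for every property tested while keeping
the whole suite fast enough to run routinely.

## Known limitations

* The ability classifier is trained on synthetic healthy subjects; its
  accuracy on generator data says nothing about accuracy on real patients.
* The 7% margin and the 1-per-0.1 score rule are fixed clinical
  conventions here, not fitted quantities.
* Grading evaluates a single peak frame; movements with tremor or unstable
  plateaus may deserve window-averaged variants.
* No synkinesis scoring, no severity-level classification, no geometric
  (landmark-distance) symmetry measures — FAU-based indices only.
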