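---
title: "Evaluating continuous cough monitors against a multi-annotator gold standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating continuous cough monitors against a multi-annotator gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coughval)
```

## The problem

Smartphone apps that passively listen for coughs promise continuous,
unobtrusive symptom monitoring, but validating them is awkward: the
reference ("gold") standard is itself a judgment call. A common design
has participants produce scripted, solicited sounds — coughs, sneezes,
throat clears, explosive words — in quiet ten-minute sessions while a
continuous recorder and one or more phones running the detector listen.
Trained listeners then annotate the continuous recording, and the
detector's event log is compared against their consensus.

`coughval` implements that whole evaluation as a reusable, tested
pipeline over four kinds of input: annotation label tracks (tab-separated
text exported from an audio editor), detector event logs (timestamp plus
a prediction score in [0, 1] per detected explosive sound), a session
manifest, and — because no recordings of this kind are publicly
deposited — a simulator that generates all of the above with known ground
truth.

## From label tracks to analysis seconds

Each of the **three** annotators grades every sound on a 4-tier scale:
0 definitely not a cough, 1 disputable, 2 definite but distant or
muffled, 3 definite cough. The session timeline is divided into
half-open one-second bins `[s, s+1)`. Within an annotator's track,
labels closer than 1 s chain into a single cluster (a cough with several
explosive phases is one event), and a cluster belongs to the second of
its first label. Interval labels, which a duration-aware annotation
protocol produces, count toward every second they overlap.

The analysis universe is the set of seconds containing at least one
label. Each second in the universe receives exactly one gold class:

* `TRUE_COUGH` — all three annotators assigned tier 3;
* `NON_COUGH` — every label in the second is tier 0;
* `COUGH_LIKE_NONCONSENSUS` — all three agree on the same sub-definite
  cough-like tier (for example 2, 2, 2);
* `DISPUTED` — any other combination; an annotator with no label in a
  cough-like second counts as tier 0, i.e. as disagreement.

Only the first two classes enter the contingency table; the last two are
excluded from accuracy counting, mirroring studies that drop seconds
without listener consensus. Detector events in unlabeled silence are
tallied separately as out-of-universe detections: they cannot be false
positives because no listener assessed those seconds, but they do count
in the minute-level rates below. Whether a second where one annotator
stayed silent while the others heard a definite cough should count as
disagreement is genuinely open; we treat it as disagreement because the
consensus definition demands three affirmative judgments.

A session survives quality control only if all its device streams could
be synchronized and at least 10 of its sounds were unanimous definite
coughs (the bound is inclusive). Sessions of subjects whose voluntary
coughs simply do not sound like coughs fall at this bar.

## Clock synchronization

Phone clocks and the recorder are not aligned; the pipeline estimates,
per session and device, the offset such that detector time + offset =
annotation time. Candidate offsets are searched on a −60 to +60 s grid
at 0.1 s (generous against any plausible start skew, still instant to
compute). At each candidate, cough-like labels (tier ≥ 1, with
co-labels of the same sound merged across annotators) are matched
greedily one-to-one to detections within a tolerance of 2 s — the
tolerance manual alignment achieves when solicited sounds sit in ≥ 5 s
of silence. The reported match error is
`1 − matched / max(n_labels, n_detections)`.

Two numerical choices matter here:

* **The search objective is a truncated absolute loss**, not the raw
  match fraction: each matched pair costs its |time residual| and each
  unmatched event the full tolerance. The match fraction alone is flat
  across a plateau as wide as the tolerance, and a single spurious
  detection that coincidentally lands near an unmatched label can tip
  the flat optimum a second or more away from truth. The truncated loss
  agrees with the match fraction up to such coincidences and is sharp at
  the true offset.
* **A sub-grid polish step** then shifts the winning grid point by the
  *median* signed residual of its matched pairs (median, so the odd
  coincidental match cannot drag it). Without this, the ±0.05 s grid
  quantization systematically pushes corrected detections across second
  boundaries — about 2.5 % of cough-seconds change bins, a bias that is
  invisible at minute resolution but material for per-second
  sensitivity.

If the best candidate still leaves more than half the events unmatched
(error > 0.5), the stream is flagged unsynchronizable and the session is
excluded; sessions whose detectors recorded almost nothing fail exactly
this way. Automatic offsets can be overridden
(`manual_offset()`), and the override is recorded as
`method = "manual_override"` in the offsets report. The pipeline
estimates offsets on at-threshold detections only: sub-threshold log
entries have no annotated counterpart and only dilute the match
fraction.

## Detection accuracy

Detections are pooled into seconds with the same 1 s merge rule; a
second's score is the maximum over its members, and the second counts as
detected when that score is at or above the threshold (0.85 by default —
the comparison is inclusive because the threshold is a *minimal*
qualifying score). Sensitivity is TP/(TP+FN) over `TRUE_COUGH` seconds,
specificity 1 − FP/(FP+TN) over `NON_COUGH` seconds, pooled across all
included sessions per device and also per session.

Confidence intervals are exact Clopper–Pearson, computed by the beta
quantile closed form for inverting binomial tail probabilities. The
choice of the exact interval over a Wald or Wilson interval is ours: with
specificities near 1 and a thousand-odd non-cough seconds, Wald
intervals misbehave, and the exact interval reproduces published
interval bounds in this literature. Per-session metrics are summarized
by five-number summaries using linearly interpolated quantiles
(`stats::quantile` type 7, the default of the analysis environment this
methodology grew in). A session with no gold cough-seconds has undefined
sensitivity; the pipeline skips it for that metric with a warning rather
than failing — such sessions occur in practice, for example when a
participant's out-of-script coughing makes timestamping impossible.

## Rate agreement

Because a monitor's practical value is in tracking rates rather than
flagging individual events, the pipeline also cuts every included
session into fixed segments (60 s default; a final partial segment is
kept only if it covers at least half the segment length) and counts
per-segment gold cough-seconds and device detection-seconds, zero-count
segments included. Agreement is assessed three ways:

* Pearson correlation between the paired counts;
* an OLS fit `device = intercept + slope × gold` (a perfect monitor has
  r = 1, slope 1, intercept 0);
* Bland–Altman on percentage error,
  `100 × (device − gold) / gold`, with mean bias and ±1.96 SD limits of
  agreement. The denominator is the gold count, not the pair mean,
  because the reference axis in this design is the human count;
  zero-gold segments cannot contribute a percentage and are excluded
  (their number is reported), though they do inform the correlation.

Per-device and pooled (all device-session segments concatenated) results
are both produced, since published summaries alternate between the two.

## Study-design utilities

`generate_script()` produces a session script: a seeded random
permutation of 46 isolated sounds — 18 coughs, 10 sneezes, 5 throat
clears, 13 explosive words — plus one read-aloud text passage containing
2 embedded coughs (20 solicited coughs in all), each isolated sound
preceded by at least 5 s of silence. Coughs are thus 39 % of isolated
sounds. The published description of this composition is internally
inconsistent (its item counts sum to 48, not the stated 46); we fixed
the word count at 13 so that both the 46-sound total and the 39 % cough
fraction hold, and the composition is fully configurable. Where exactly
the two embedded coughs sit inside the passage is unstated anywhere; the
simulator places them 15 s and 40 s in.

`buderer_sample_size()` computes the diagnostic-accuracy sample size:
per branch, `z² p (1−p) / d²` cases, divided by the prevalence of the
branch's condition among sounds and by (1 − dropout), ceiling of the
larger branch. With 90 % target sensitivity, 85 % specificity, 5 %
precision, 40 % cough prevalence, 10 % dropout and z = 1.96 this yields
385 sounds. Dropout as division by (1 − dropout) before the ceiling is
the standard adjustment and is what reproduces that figure exactly. A
branch whose condition has zero prevalence is vacuous and is dropped
rather than made infinite.

## The simulator: what it emulates, and what not

`simulate_cohort()` generates complete sessions: script-driven true
event times (with up to 1 s of human response jitter), three annotators,
one or more detectors, and an unknown clock offset per device drawn
uniformly from ±30 s. Defaults describe a 49-session, two-phone,
600-second study.

The **detector is parameterized at its operating point**:
`p_detect_cough` (default 0.92) is the probability that a cough yields a
detection at or above the score threshold, so it is directly the
quantity the pipeline estimates. Scores of counting detections are drawn
from Beta(8, 1) truncated to [threshold, 1]; sounds the detector heard
but scored low (probability `p_subthreshold`, default 0.3, for misses
and non-cough sounds) enter the log with scores truncated below
threshold, so the 0.85 threshold is genuinely exercised from both sides.
Non-cough solicited sounds trigger false at-threshold detections with
probability 0.007 (matching false-positive burdens of roughly 7 per
thousand non-cough seconds), and a Poisson stream of spurious detections
(0.1/min default) fires in silence with Beta(1, 6)-shaped scores above
threshold. Detection timestamps carry Gaussian noise (sd 0.1 s).

**Annotators** draw a tier for every sound from a per-kind confusion
row. Typical subjects' coughs are rated 3 with probability 0.96 per
annotator; with probability 10/49 a subject is "atypical" — their
voluntary coughs do not sound like coughs — and the cough row flattens
to (0.15, 0.20, 0.30, 0.35), which reliably drops the session below the
10-unanimous-cough bar. Annotation times jitter by ±0.05 s. A small
fraction of sessions (2/49) have degenerate detector streams that fail
synchronization. `degrade_annotators()` instead injects a controlled
unanimity-failure rate for calibration tests.

Two visible consequences of this measurement model are worth knowing:

* **Second-binning attrition.** With 0.1 s timestamp noise, a detection
  near a bin boundary can land in the neighboring second; the per-second
  sensitivity the pipeline measures on default simulations is therefore
  a few percent *below* the injected `p_detect_cough`, even though
  every event was heard. The same mechanism operates on real data and is
  one reason per-second accuracy is a stricter metric than event-level
  accuracy. Parameter-recovery tests therefore set timestamp noise (and
  the spurious stream, which can merge into a cough's cluster and steal
  its second) to zero, isolating the detection probability.
* **Boundary straddling by annotators.** With nonzero annotation-time
  jitter, co-labels of one cough can fall in adjacent seconds, creating
  two disputed seconds from a single sound. The cough-conservation
  property (true coughs = unanimous + non-consensus + missed) is
  therefore exact only at zero timing jitter, and tests verify it there.

The simulator does not model audio at all — no waveforms, no room
acoustics, no sound levels — and it does not model out-of-script
behavior (spontaneous coughing, speech between prompts) or
annotator-specific bias structure (its three annotators are
exchangeable). Passing tests demonstrate that the *pipeline arithmetic*
is right and that known parameters are recovered under the stated
measurement model; they cannot certify any real detector's performance.

## Problem sizes and determinism

All randomness flows from one integer seed through R's generator, with
the caller's RNG state preserved; the same seed reproduces output files
byte for byte. The test suite runs cohorts of 1–4 sessions for unit
checks, 20 single-session seeds for offset recovery, and 20 cohorts of
37 sessions for end-to-end sensitivity recovery (the published cohort's
included-session count); the exact-interval implementation is checked
against an independent binomial-CDF bisection oracle exhaustively for
all n ≤ 50. The bundled `inst/extdata/synthetic_sessions/` fixture (3
sessions, seed 42) exists so file-format and pipeline tests run from
disk; it is simulator output, never a recording.

## Known limitations

* The offset-error functional form is a design choice anchored by
  parameter-recovery tests; published descriptions of such procedures
  rarely specify the objective, and other reasonable forms (e.g.
  cross-correlation of binned event trains) exist.
* The consensus rule is strict unanimity on tier 3. Softer rules
  (majority, or tier ≥ 2) would change the gold standard's size and the
  measured accuracy; the data model carries full tier information so
  such variants are easy to add, but they are not implemented.
* Pearson correlation on per-minute counts is dominated by high-count
  segments in solicited-cough designs; the Bland–Altman output exists
  precisely to expose disagreement that the correlation hides.
* The exact interval treats seconds as independent Bernoulli trials;
  within-session correlation (a participant whose coughs are uniformly
  hard to detect) makes the nominal intervals slightly anticonservative
  for pooled estimates. The per-session summaries are the honest
  companion view.
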