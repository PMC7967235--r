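---
title: "Rest-period detection and cluster-based rest quality from patch accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rest-period detection and cluster-based rest quality from patch accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Digital medicine systems (DMS) pair an ingestible sensor embedded in a pill
with a torso-worn patch.  The patch logs each medication ingestion with a
timestamp and, as a by-product of its activity monitoring, emits per-minute
accelerometer summaries: a step count, the mean acceleration along three
axes $a_x, a_y, a_z$ (in g, with $x$ calibrated to the longitudinal body
axis), and a mean posture angle $\theta$ (degrees from horizontal, 0 =
lying).  A single-lead ECG adds a mean heart rate every 5 minutes.  This
cadence is far too coarse for heart-rate-variability sleep staging, but it
is enough for actigraphy: detecting when a patient is at rest and how
settled that rest is.  `actirest` implements such a pipeline end to end and
relates the resulting daily rest metrics to the objective ingestion record.

## Interval classification

Each patient-day is cut into non-overlapping 15-minute intervals.  An
interval is *analyzable* only if (1) the patch was never pairing with the
phone during it, (2) it holds at least 10 accelerometer records, and (3) at
least 2 ECG records; otherwise it is MISSING.  Within an analyzable
interval, a minute is a *rest minute* when $\theta < 30^\circ$ (strict),
and the interval is REST when strictly more than 70% of its *collected*
records are rest minutes, else ACTIVE.  Two readings deserve comment:

* Both thresholds are strict inequalities, matching their verbal
  definitions ("less than", "greater than").
* The 70% denominator is the number of collected records (10-15), not the
  nominal 15.  This follows the wording ("of the records in that interval")
  and behaves sensibly when records are missing: an interval with 10 of 15
  records and 8 rest minutes is REST (80%), which a nominal-15 denominator
  would misclassify.

Days run from noon to noon by default (`day_boundary_clock_time`), so a
night's sleep is never split at midnight.  The source analysis assigns one
rest period per day without defining the boundary; noon is our choice and
is configurable.

## Longest rest period

The *longest continuous rest period* (LCRP) is the longest run of REST
intervals with no ACTIVE or MISSING interval inside (earliest run on ties).
Missing data and brief awakenings artificially truncate it, so the LCRP is
extended into the *longest rest period* (LRP): from each end, a nearby run
of consecutive REST intervals is annexed when the gap to it spans at most 5
intervals and

* the gap is entirely MISSING, or
* the gap contains exactly one ACTIVE interval and the candidate run has at
  least 4 consecutive REST intervals.

A gap containing two or more ACTIVE intervals closes that end.  The
published branch table covers "all missing", "exactly one active" and "more
than two active"; the two-active case is unstated, and we block it (the
conservative reading consistent with the "exactly one" branch).  Setting
`two_active_blocks = FALSE` shifts the boundary so that only three or more
active intervals block.  Annexation restarts the scan from the new end and
iterates to a fixed point; `single_pass_extension = TRUE` gives the
single-pass variant for sensitivity analysis.  "Within 5 intervals" is
implemented as a bound on the gap length.  Bridged MISSING/ACTIVE intervals
inside the final span count toward the LRP duration but are never scored
for quality.

The implementation is verified against an independently coded run-table
oracle by exhaustive enumeration of every {REST, ACTIVE, MISSING} sequence
up to length 12 (797,160 sequences) and by randomized fuzzing.

## Rest features

Within each 15-minute interval of an LRP, 3-minute rolling windows (stride
1 minute) of the per-minute records are formed; a fully sampled interval
yields 13 windows.  Windows never span an interval boundary, and a window
overlapping an unsampled minute slot is dropped rather than imputed.  Four
features are computed per window:

| feature | definition | units |
|---|---|---|
| y-z circular deviation (mean) | mean of $\lvert\sqrt{a_y^2+a_z^2} - 1\rvert$ | g |
| posture angle (mean) | mean of $\theta$ | deg |
| acceleration norm (mean) | mean of $\sqrt{a_x^2+a_y^2+a_z^2}$ | g |
| x acceleration (SD) | $\sigma(a_x)$ | g |

The circular deviation is the distinctive one: lying still and horizontal
puts gravity in the y-z plane, so $(a_y, a_z)$ sits on the unit (1 g)
circle and the deviation is near 0; movement or uprightness pulls it away.
Two formalization choices are worth recording.  First, "circular deviation"
is deviation of the vector magnitude from the unit circle, not a
circular-statistics dispersion of the angle $\mathrm{atan2}(a_z, a_y)$ —
the latter is available in the candidate registry as a separate feature,
but the unit-circle reading is the one forced by the feature's own
rationale (points cluster *around a circle of radius 1*; stillness gives a
deviation *near zero*).  Second, because the feature is anchored to the
absolute 1-g circle, it is deliberately *not* invariant to a global
rescaling of the accelerations: a miscalibrated gain genuinely changes what
the feature measures.  The other three features are homogeneous (or
independent) in the accelerations and their min-max-normalized values are
exactly scale-free, which the test suite asserts.

The SD uses the population (n) denominator over the 3 minutes
(`feature_sd_ddof = 0`); with $n = 3$ the choice is material and the source
is silent, so it is exposed as configuration.

A registry of 35 documented rolling-window statistics (axis means and SDs,
ranges, successive differences, step statistics, circular statistics)
supports the optional agglomeration-based selection: per patient, features
are hierarchically merged using $1 - \lvert r\rvert$ dissimilarity (average
linkage) and cut into $k$ clusters; a cross-patient consensus then picks
one representative per group.  The 31 non-canonical candidates are
stand-ins — the original 35-feature list is not published in the main text
— and the default pipeline uses the four canonical features without any
selection step.

## The cluster-based quality metric

Per patient, the four features of all scored windows are min-max normalized
to the patient's own ranges and clustered with k-means, $k = 2$
(`stats::kmeans`, 25 seeded restarts, so fits are deterministic given
`rng_seed`).  The cluster whose centroid posture angle is nearer horizontal
is the *rest-reference* (RR) cluster; the other is *deviation-from-rest*
(DFR).  Every window assigned to RR scores exactly 0; every DFR window
scores its Euclidean distance to the RR centroid across the full 4-D
normalized space.  Assignment ties break toward RR (conservative toward
rest).  Distances are summed within each 15-minute interval — an interval
observed with $n < 13$ windows is rescaled by $13/n$ so sums stay
comparable — and the LRP quality is the mean over its scored intervals.
Lower values mean better rest; the metric is relative to the patient's own
data, so it is not comparable in absolute terms across patients.

Two scope decisions are config-exposed because the source does not settle
them: the model is fitted on the windows inside the patient's LRPs
(`fit_scope = "lrp"`, the default, matching the per-patient night-time
framing of the metric) or on all analyzable windows, day and night
(`fit_scope = "all"`).  A patient whose windows are all identical cannot be
split into two clusters; this is surfaced as an error, mirroring the
published check that no patient was well represented by a single rest
cluster.  A constant feature column is normalized to 0 with a warning.

## Daily scores and ingestion metrics

Per patient, three per-day series — LRP quality, LRP start time (minutes
from the day-window start) and LRP duration — are standardized into
z-scores using the patient's own mean and SD across days (sample SD,
`score_sd_ddof = 1`; a constant series yields zeros with a warning).  The
*composite rest score* for a day is $\lvert z_q\rvert + \lvert z_s\rvert +
\lvert z_d\rvert$: the combined magnitude of deviation from the patient's
typical rest.  Ingestion behaviour is summarized by the *ingestion rate* —
distinct calendar days with a recorded dose divided by the regimen span
(first patch-data day through last ingestion day, once-daily regimen) — and
by a z-score of daily ingestion clock time.  Duplicate ingestion events on
one calendar day collapse to the earliest; the rate counts days.

Finally, single-day outliers in the composite rest series are matched to
single-day outliers in the ingestion-time series at most one day apart.
Outlier *detection* standardizes both series robustly — the
Iglewicz-Hoaglin modified z-score, $(x - \mathrm{median})/(1.4826\,
\mathrm{MAD})$ — before applying the threshold `outlier_z` (2.0 default;
one-sided for the non-negative composite, two-sided for ingestion time).
The robust step matters: the composite is a sum of three absolute z-scores,
so its null level already sits near 2, and a mean/SD threshold self-masks
because the very excursions being searched for inflate the SD.  With the
classical rule (available via `robust_outliers = FALSE`) most ordinary days
of a contaminated series are flagged and the "single-day" requirement —
that neighbouring days not be outliers themselves — then suppresses the
genuine events; detection sensitivity roughly halves on simulated streams.
The reported `quality_z`/`start_z`/`duration_z`/`ingestion_z` columns
remain classical mean/SD z-scores throughout; robustness applies only to
the outlier flags.  The threshold, lag, single-day strictness and
robustness are all configuration.

## What the simulator emulates — and what it does not

`simulate_patient()` generates the four channels at their native cadences
with known ground truth.  Defaults are chosen once as a realistic adherent
patient and define the conditions under which the package validates itself:

* nightly rest onset 23:00 (SD 30 min), duration 480 min (SD 45 min);
* awakenings Poisson(1.5) per night, lasting 1 min plus an exponential tail
  of mean 2 min (capped at 20 min) — at per-minute actigraphy resolution,
  nocturnal arousals are few and mostly a few minutes long;
* during rest, gravity in the y-z plane at a nightly orientation angle with
  per-axis Gaussian noise (SD 0.05 g), $\theta \sim \lvert N(5^\circ,
  3^\circ)\rvert$, zero steps; while active, gravity mostly on the x axis,
  $\theta \sim N(80^\circ, 9^\circ)$, Poisson steps;
* missing spans Poisson(0.5 per day) of 20-60 min; one 10-minute pairing
  span per evening at 20:00;
* a 09:00 dose (SD 45 min) taken with probability 0.9;
* optional planted joint outlier days (dose shifted +4 dose-SD; rest
  delayed 4 onset-SD, shortened 4 duration-SD, and made restless) and
  matched "restless" nights (noise and posture jitter multiplied, schedule
  untouched) for paired quality comparisons.

Every draw is governed by one seed, so a seeded run is byte-identical;
cohort seeds follow the counter scheme `master * 1000 + i` so any patient
regenerates in isolation.  The simulator does **not** model sleep
architecture, ECG waveforms, postural transitions within a minute, sensor
drift, or daytime naps — passing tests demonstrate that the pipeline
recovers what the generator planted under these idealized conditions, not
that it measures sleep as a polysomnograph would.

## Numerical and testing choices

Interval membership is half-open `[start, end)`; a record exactly on a
boundary belongs to the interval it starts.  Pairing overlap is any
non-zero intersection.  Timestamps are ISO 8601 in a single patient-local
timezone with no DST arithmetic (streams are at most a couple of months).
Posture angles are canonicalized to $[0, 180]$ and derived from
$\lvert\arcsin(a_x/\lVert a\rVert)\rvert$ when the angle channel is absent.
Score tables round-trip through CSV at 12 significant digits (relative
error below $10^{-9}$), and all dump files are formatted stably so reruns
are byte-identical.

The validation suite sizes its simulations to be informative while staying
quick: 100 nights for LRP recovery (detected-versus-planted Jaccard
overlap), 100 seeded replicates of the paired restless/quiet quality
comparison, 20 independent 60-day streams (100 planted days) for the
outlier-coincidence sensitivity estimate — a Bernoulli proportion whose
standard error at 5 planted days per stream would otherwise dominate the
measurement — and exhaustive oracle comparison for all state sequences up
to length 12.

## Known limitations

* The day boundary, the two-active gap rule, the rolling-window
  completeness rescaling, the SD denominators and the outlier calibration
  are all artifact decisions on points the source leaves open; each is
  config-exposed and defaulted as documented above.
* Rest quality is relative within a patient; absolute values are not
  comparable across patients, devices or gain calibrations (the circular
  deviation is anchored to 1 g by design).
* Naps (multiple rest periods per day), heart-rate analytics and daytime
  activity markers are out of scope.
* With per-minute summaries, awakenings shorter than the interval scale can
  still flip an interval to ACTIVE and truncate an LRP when they fall near
  its ends; this is faithful to the published rules, and the simulator
  quantifies how often it happens rather than hiding it.
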