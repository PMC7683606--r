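---
title: "Anticipating the LH surge from ultradian wavelet power: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anticipating the LH surge from ultradian wavelet power: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgewave)
```

## The problem

Across the menstrual cycle, the power of ultradian rhythms (URs; here the
2–5 h band) in peripheral physiological signals changes in a stereotyped
way around ovulation. In wearable recordings of distal body temperature
(DBT, measured continuously at the finger) and sleeping heart rate
variability (HRV, as RMSSD), the smoothed 2–5 h wavelet power shows a
characteristic sequence relative to the onset of the preovulatory
luteinizing hormone (LH) surge: a *first inflection* (the end of a slow
early-cycle decline) roughly six days before onset, a *subsequent peak*
roughly two and a half days before onset, and a *trough* about two days
after it. Because the inflection and peak precede the surge by days,
they are candidates for prospective, non-invasive fertility awareness —
in contrast to LH strips, which are retrospective.

surgewave implements the full analysis chain for this phenomenon and a
synthetic cohort generator whose latent event days are known, so every
stage can be validated by recovery rather than by eyeball.

## The analysis chain

Per cycle and channel:

1. **Cleaning.** Points outside ±4 SD of the whole series, and points
   with an absolute first difference above 1e5 (a deliberately extreme
   cutoff for near-instantaneous glitches), are replaced by the median of
   the prior hour of already-cleaned samples. Statistics are computed
   once over the whole series, not on a rolling basis; both thresholds
   are configuration (`cleaning_config()`).
2. **Excerption and concatenation.** DBT shows high nocturnal plateaus,
   so only waking samples are kept; HR/RMSSD exist only during sleep.
   The kept segments of all days (nights) are concatenated into one
   continuous signal. Gaps shorter than 60 min inside a kept segment are
   linearly interpolated; an empty day/night is recorded as missing.
   The concatenated "hours" are therefore pseudo-hours of stitched time.
3. **Wavelet band power.** A generalized Morse wavelet
   (Psi(w) ∝ w^β e^(−w^γ), default β = 5, γ = 3 — a low-oscillation
   wavelet that favours transitions) is applied by FFT per scale on a
   geometric grid (16 voices/octave), peak-amplitude-normalized to 2 so
   a unit sinusoid yields |W| ≈ 1. Power is the squared coefficient
   modulus averaged over the scales whose period lies in the band
   (2–5 h ultradian; 23–25 h circadian available for the full-day DBT
   series). No padding is used; instead the first and last day of each
   cycle are discarded (`trim_edge_days()`).
4. **Feature detection.** The trimmed band power is z-scored over the
   cycle and smoothed with a centered moving mean spanning one nominal
   day of samples (960 for 1-min waking DBT, 96 for 5-min sleeping
   channels). The first inflection is the earliest zero-crossing of the
   first difference whose day label exceeds 5 (the surge is very
   unlikely in the first five cycle days); the subsequent peak is the
   earliest strict local maximum after it; the post-surge trough is the
   earliest local minimum after onset. Sample indices are mapped to
   fractional days relative to LH onset (taken at midday of the onset
   day); absent features stay `NA`.
5. **Cohort level.** Cycles are aligned from onset −7 to +7 days
   (perimenopausal cycles, which have tonically supra-threshold LH and
   hence no onset, align to `floor(cycle_length/2)`); daily means, the
   cumulative fraction of cycles showing each feature by each day, and
   the intra- vs inter-individual range ratio are computed. Statistics:
   Kruskal–Wallis on per-cycle pre- vs post-onset slopes of aligned
   daily power (windows −7..0 and 0..+7; rank tests avoid normality
   assumptions), Kruskal–Wallis on per-cycle mean raw power in 25-min
   windows centered on the detected peak vs trough (one value per cycle
   per group), and one-way repeated-measures ANOVA with Holm-corrected
   paired per-day contrasts for the urinary hormone panels.

## Inclusion rules

A cycle is analyzed as premenopausal when (a) its LH strips show a
single localized run of positives (≤ 5 days), and (d) its nightly
temperature deviation is positive from two days after onset to the end
of the cycle; when a daily hormone panel exists, (b) E2 must rise before
or coincident with the surge (max over onset−4..onset above 1.5× the
follicular median) and (c) both pregnanediol metabolites must rise
afterwards (means over onset+3..onset+8 above 2× their follicular
medians). Any night with no channel data within 16 days of onset
excludes the cycle, since a missing night distorts the rhythmic power
estimate. Tonic LH (positives on ≥ 80% of sampled days) with age > 45
defines the perimenopausal group. "Localized" and "tonic" are
operationalized here (run length ≤ 5; ≥ 80% positive) because only the
qualitative wording is given; both are arguments of `detect_lh_onset()`.

The temperature deviation for night *n* is the mean DBT between 22:00
and 08:00 minus the mean of the previous 20 *nightly* values. The
night-vs-night reference matters: distal temperature peaks nocturnally,
so referencing nights against whole days would add a constant ~0.5 °C
offset and make the criterion vacuous.

## The synthetic cohort

`generate_cohort()` draws individuals with 2–3 cycles each. Cycle
length, LH onset day, surge length, the envelope event days and the E2
peak offset follow truncated normal distributions whose parameters are
the cohort statistics reported for the study population (see
`?cohort_config` for the full list); the surge-length pmf
(.40/.18/.16/.16/.10 over 1–5 days) matches the reported persistence
fractions (42% still positive two days after onset, 26% at three days).
Each variable combines an individual-level and a cycle-level normal
score before the quantile transform, with the within-individual SD set
to 25% of the between-individual SD; the marginal distribution of every
event day is therefore *exactly* the configured truncated normal, while
cycles of one individual cluster. The DBT and RMSSD event days share the
same latent scores (they are comonotone): both channels express one
underlying hormonal event, which is what makes the "co-detected by both
channels" anticipation fractions track the single-channel ones.

The channels are built as base level + circadian cosine (DBT only) +
envelope-modulated ultradian sinusoids + AR(1) noise + a luteal shift
(+0.3 °C DBT, −8 ms RMSSD, +2 bpm HR) ramped linearly over one day from
onset. The amplitude envelope is piecewise linear through five anchors:
1.3 at cycle start, 1.0 at the inflection, 2.0 at the peak, 0.5 at the
trough, and back to 1.0 three days later. The early decline from 1.3 to
1.0 is what makes the inflection the *first* derivative zero-crossing
after the early-cycle exclusion. HR carries an ultradian component that
is *not* envelope-modulated: it is the designed null channel.
Perimenopausal cycles have a flat envelope, no luteal shift, tonic LH,
flat E2 and only a modest metabolite rise after midcycle.

Hormones: E2 is a Gaussian bump (×3 baseline, width 1.5 d) centered an
integer 0–4 days before onset; the pregnanediol metabolites rise
five-fold over the six days after onset; lognormal noise uses the assay
CVs (8/12/13%), and values under the detection limits (0.2/0.2/10
ng/mL) are reported at the limit and flagged censored.

### Calibration for detection well-posedness

The first-crossing rule has no robustness margin: *any* up-tick of the
smoothed derivative during the shallow pre-inflection decline fires
detection early. Three generator choices follow from making that rule
well-posed, and they are the main places where the simulation departs
from realistic wearable noise:

* **Day-commensurate ultradian periods** (DBT 3.0 h and 2.4 h, RMSSD
  24/7 h, HR 24/9 h). Excising the sleep window from a signal whose
  components do not complete an integer number of cycles per day
  creates a drifting daily interference pattern between the circadian
  arc's harmonics (16-h pseudo-period harmonics at 16/k h fall inside
  the 2–5 h band) and the ultradian component; its band-power wiggles
  cross zero in the derivative even with zero noise. With integer
  cycles per day the stitched pattern repeats daily and the one-day
  moving average cancels it exactly.
* **Fixed sleep windows** (23:30–07:30, no nightly jitter by default).
  Jitter modulates the night-boundary stitch transient night-to-night,
  which breaks that daily periodicity the same way.
* **Low AR(1) noise** (marginal SD 0.001 °C DBT, 0.02 ms RMSSD at
  ultradian amplitudes of 0.30 °C and 8 ms). The derivative of the
  day-smoothed band power is a difference of band-power values one day
  apart; its noise does not average down with window length, so the
  in-band noise amplitude must stay roughly two orders of magnitude
  below the ultradian component for the ~7%/day pre-inflection power
  slope to keep a stable sign over the ~5-day decline.

These are statements about the *detection rule*, not about physiology:
on real data, where broadband noise is large, the rule's published
success implies the real pre-surge decline is steeper or the real
band-power trajectory smoother than a conservative linear envelope.
Passing the recovery tests here demonstrates that the pipeline computes
the method correctly and recovers latent events whose geometry matches
the reported cohort statistics — not that the method is robust to
realistic wearable noise, which this generator deliberately does not
emulate (nor does it emulate missing data in the default configuration,
activity masking, or device drift).

Two further generator details keep the latent events observable: the LH
onset day is drawn with its lower bound raised to
`max(10, 7.5 − inflection, cycle_length − 22)`, so the inflection falls
after the excluded first five days and the 20-night deviation reference
always reaches back before the luteal rise (the marginal onset mean
rises from 15.75 to about 16.2 as a consequence); and the luteal shift
is a one-day ramp rather than a step, whose broadband transient would
otherwise fake an early post-onset trough.

## Numerical choices and conventions

* Power = |W|²; z-scoring downstream makes the |W| vs |W|² choice a
  units question only (config-exposed).
* The moving mean shrinks its window at the series edges; detection
  indices map to days via the left sample of the derivative
  sign-change pair; fractional days are kept (rounding is left to
  report time).
* Detection resolution: on the continuously sampled DBT channel,
  noise-free recovery is bounded by the smoothing window (measured
  ~0.2–0.4 d, systematically early because the pre-inflection decline
  is ~10× shallower than the post-inflection rise, which shifts the
  smoothed minimum toward the shallow side). On nightly-sampled
  channels the crossing can only be localized to the night with minimal
  smoothed power, adding up to one night of quantization; RMSSD feature
  days are therefore validated at ±1 night per cycle, and at ±0.5 day
  on cohort means.
* Ties/plateaus in extrema detection resolve to the leftmost sample.
* A degenerate all-equal repeated-measures matrix returns F = 0, p = 1
  (the 0/0 limit), and all-tied Kruskal–Wallis input returns H = 0,
  p = 1.

## Problem sizes used in validation

The recovery checks simulate 500 premenopausal cycles (seed 42) and
analyze both channels with the default configuration; statistical power
and type-I-error checks use 100 replicates of 45-cycle cohorts (DBT for
power on the premenopausal pattern, RMSSD flat-envelope perimenopausal
cohorts for the null), 10,000 Kruskal–Wallis null simulations with two
groups of 45, and two independent 100-cycle perimenopausal runs for the
negative control. These sizes were chosen to estimate each quantity to
well within its acceptance band.

## Known limitations

* The slope-trend comparison uses the display windows (−7..0, 0..+7).
  For RMSSD, whose aligned curve rises and falls steeply within the
  pre-window, the linear pre-slope partially cancels and the test is
  much less powered than for DBT — the statistical power criterion is
  therefore evaluated on DBT.
* Truncating the event-day distributions to their reported ranges
  shifts their realized means (e.g. the realized inflection mean is
  −5.50 when the parent mean is −5.82); detected cohort means still
  match the reported values because the truncation shift and the
  smoothing-induced detection bias act in opposite directions, but
  tail fractions (such as the percentage of peaks at least one day
  before onset) land a few points below the reported ones.
* Perimenopausal "feature days" are whatever the first noise wiggle
  after day 5 produces; they are reported (as in the negative-control
  comparisons) but have no latent meaning.
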