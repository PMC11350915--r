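---
title: "Acoustic niche partitioning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic niche partitioning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anuraniche)
```

## The scientific question

Male anurans advertise acoustically, and co-occurring species compete for
acoustic space. `anuraniche` quantifies how a community partitions that
space along three dimensions: the *structure* of the advertisement call
(dominant frequency, number of notes, number of pulses), the *diel*
timing of calling, and its *seasonal* timing. The inputs are per-minute
call-annotation tables from passive acoustic monitoring: each row is one
species' calling in one recorded minute, with per-call features, band
sound-pressure context (1–5 kHz, dB relative to digital full scale) and
a categorical rain index. Silent minutes are first-class rows — they
carry the denominators for presence percentages and activity profiles.

## Resource classes and niche profiles

Each dimension is discretized into an ordered resource-class scheme:

* **Call structure, r = 25.** Nine dominant-frequency classes of 500 Hz
  width spanning 500–5000 Hz, five call-composition classes (1–5
  notes), and eleven pulse classes (class 1 for tonal calls with zero
  pulses, nine classes of width 3 covering 1–27 pulses, and an
  open-ended class for more than 27). Every annotated call contributes
  one count to each block; the blocks are normalized to mass 1/3 each
  and concatenated, so the 11-class pulse block cannot dominate the
  profile merely by having more classes. Out-of-range features are
  clamped to the nearest edge class *with a warning* — the annotation
  protocol already filters 400–6000 Hz, and silently dropping such
  calls would bias profiles invisibly.
* **Diel, r = 24.** For each clock hour, the mean call rate over all
  recorded minutes at the site in that hour (silent minutes included),
  normalized to proportions.
* **Seasonal, r = number of study months at the site.** As the diel
  profile, with months as classes. Because r is taken from the site's
  survey design, sites with unequal coverage standardize against
  different r (e.g. 7 vs 6 months).

A species with no recorded activity in a dimension has an *undefined*
profile. Undefined profiles propagate as flagged errors, never as
zero-filled vectors: the breadth statistic below is simply not defined
at zero total use.

## Breadth, overlap, and the randomization null

Niche breadth is the inverse Simpson concentration
$NB = 1/\sum_i p_i^2$, standardized to $NB^* = (NB - 1)/(r - 1) \in
[0, 1]$; a specialist using one class scores 0, a perfectly even
generalist 1. Under equal exclusive partitioning among $n$ species each
would hold $NB^* = 1/n$ (`equal_partition_breadth()`), the natural
reference for a community average.

The combined ("total") niche uses an additive model: the three
dimension profiles are concatenated after scaling by weights (default
1/3 each), giving $r_{total} = 25 + 24 + r_{seasonal}$ classes. Setting
a degenerate weight vector recovers a single dimension's NB exactly,
restandardized by $r_{total}$. Published per-dimension and total
breadth values for the two field communities shipped with the package
are *not* mutually derivable under this (or any simple concatenation)
model; the package therefore reports totals but treats published totals
as data, not as a cross-check.

Pairwise overlap defaults to Schoener's proportional similarity
$O(p, q) = 1 - \tfrac12 \sum_i |p_i - q_i|$ — bounded, symmetric, equal
to 1 only for identical profiles — with Pianka's symmetric index
available by flag. The community matrix is summarized by the mean and
*sample* (n−1) standard deviation of its 15 (for six species) upper-
triangle values, matching how field summaries are usually printed.

The no-partitioning null draws each overlap value as the mean of 10
independent uniform(0,1) numbers: analytically mean 0.5 and sd
$\sqrt{1/120} \approx 0.0913$. Whether the 10-draw average is applied
per pair or per community is a convention choice; the implementation
exposes `n_pairs`, `n_draws` and `reps` so either reading is available,
and the comparison against empirical overlap uses the pooled-variance
two-sample t statistic (Welch by flag; pooled is the classical default
and the choice is reported) plus the variance-ratio F oriented
larger-over-smaller with the orientation recorded.

## Cross-site comparison and rarefaction

To compare niches across sites, profiles must live on one scheme; the
seasonal classes are therefore restricted to the *shared* study months
(`cross_site_profiles()`), and leaves are labelled `species@site`.
Complete-linkage agglomerative clustering is run on `1 - overlap` — a
bounded dissimilarity that need not satisfy the triangle inequality,
which complete linkage does not require. Merge heights are
non-decreasing by construction; ties are broken by the
lexicographically smallest pair of leaf-label sets so identical inputs
always produce identical trees. The implementation is small and
self-contained because the tie-break rule is part of its contract; the
test suite checks it against `stats::hclust` on random instances, where
ties almost surely do not occur.

Species accumulation uses sample-based rarefaction on binary incidence
matrices (days or single minutes as units, day and night separately).
The curve is the mean richness in the first k units over randomized
sample orders (default 100, seeded), with 95% bounds taken as mean ±
1.96 sd of the randomization spread — the stated resampling procedure
itself, rather than an analytic variance formula, so the curve at k = n
ends exactly at the observed richness with zero spread.

## The synthetic community generator

Field recordings cannot ship with the package, so every downstream
stage is exercised against a generator that emulates the survey's
statistical structure:

* the recording schedule (the first `minutes_per_hour = 5` minutes of
  every hour, per site and study month);
* per-minute call counts that are Poisson with mean
  `diel_rate[hour] × seasonal_mult[month] × site_mult[site]`;
* truncated-normal dominant frequencies (inverse-CDF sampling, so the
  analytic bin masses are exact), categorical note and pulse counts;
* i.i.d. hourly rain with two severities; only heavy rain (index 2)
  multiplies rates by `rain_suppression`;
* daylight bird-band noise: an hourly activity level B ~ U(−1, 1)
  raises the 4–5 kHz bands and multiplies daytime rates by
  `1 + day_bird_response × B`, reproducing both positive and negative
  species responses. The multiplier is *mean-neutral* by construction.

These are the simplest laws with the right support; nothing finer is
claimed about the field system. Because rain is i.i.d. across hours and
the bird multiplier has mean 1, expected activity profiles have closed
forms (`expected_profiles()`): the diel expectation is the normalized
`diel_rate`, and the seasonal expectation is the normalized per-month
multipliers — month lengths cancel because the seasonal estimator is a
per-month *mean* rate, not a total. The frequency-bin expectation is
the truncated-normal CDF increment with the edge-class clamping
applied.

Call features are annotated for at most `max_annotated_calls` calls per
minute (default 1, the first recognizable call, as in manual annotation
protocols); the call *rate* is always the full count, and because call
features are i.i.d. within a species the first-call subsample leaves
call-structure profiles unbiased.

`example_community_config()` packages a two-site, six-species
configuration with the qualitative structure of an equatorial highland
assemblage: a dominant nocturnal high-frequency pulsed caller favoured
at the high site, a diurnal tonal caller favoured at the low site, two
low-frequency species with long- and short-pulsed calls, a broadband
day-and-night generalist, and a rare nocturnal species. Rates are
calibrated on the presence scale (unconditional hourly-mean calls per
minute) so that community daylight presence lands around 80–90% and
night presence near 100%; a homogeneous Poisson minute process cannot
simultaneously reproduce chorus-bout rates of hundreds of calls per
minute and realistic fractions of silent hours, and presence is the
quantity the analyses consume. That burstiness — along with call
masking between species, spatially variable detectability, and
autocorrelated weather — is deliberately outside the generator, so
passing recovery tests demonstrate estimator correctness under the
stated laws, not robustness to clumped field data.

## Problem sizes and numerical choices

Parameter-recovery tests run the full pipeline on a dense-chorus
variant of the example configuration (site multipliers 1, diel rates
scaled to a mean of 4 calls/min, two sites × 7 months × all calendar
days × 24 h × 5 min ≈ 51,000 recorded minutes) and require every
per-dimension NB\* and every pairwise total overlap to sit within
±0.02 of the generator's analytic expectation, and every species' two
site-leaves to pair first under complete linkage. The dense variant is
used because the band probes estimator convergence: locally rare
species (which the example config retains for realism) carry sampling
error larger than 0.02 in their seasonal profiles at this survey size.

Band SPL values are decibels relative to digital full scale (0 dBFS =
full-scale sine), since recorder gain calibration is unknowable from
the files; each band is the single FFT bin nearest the requested center
(1024-point frames, Blackman–Harris window, 50% overlap) averaged over
frames, floored at −120 dB. The square-root-y activity regression is
ordinary least squares of √CA on SPL, reported as CA = (a + b·SPL)²
with R² on the transformed scale, the convention of the common
statistics packages that print such models.

Proportion vectors are validated to sum to 1 within 1e−9; profile
comparisons require identical schemes; degenerate inputs (zero-variance
predictors, empty rain strata, fewer than two species or samples) raise
immediate errors rather than returning silent NA. All stochastic
functions take explicit seeds, restore the caller's RNG state, and the
pipeline splits one root seed per stage by stage name, so reruns are
byte-identical.
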