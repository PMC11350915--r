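# anuraniche

Acoustic niche partitioning analysis for anuran communities surveyed by
passive acoustic monitoring (PAM).

Co-occurring frog species compete for acoustic space: advertisement
calls that overlap in frequency, timing or structure interfere with
each other. Given per-minute call-annotation tables (species, calls per
minute, per-call dominant frequency / notes / pulses, band
sound-pressure levels at 1–5 kHz, a rain index), `anuraniche`
discretizes each species' resource use into three niche dimensions —
**call structure** (25 classes: 9 × 500 Hz frequency bands, 5 note
counts, 11 pulse classes), **diel** (24 hourly classes) and
**seasonal** (one class per study month) — and computes:

* standardized niche breadth — the inverse Simpson index
  `NB = 1/Σ pᵢ²` scaled to `NB* = (NB − 1)/(r − 1) ∈ [0, 1]`, with the
  equal-partition reference `NB* = 1/n` for an n-species community;
* pairwise niche overlap — Schoener's proportional similarity
  `1 − ½ Σ|pᵢ − qᵢ|` (Pianka optional) over the additively combined
  total niche, summarized as the community mean ± sd;
* a randomization null for overlap (each null value the mean of 10
  uniform(0,1) draws; analytically 0.5 ± √(1/120) ≈ 0.0913), compared
  with empirical overlap by two-sample t and variance-ratio F;
* complete-linkage clustering of `species@site` niches on 1 − overlap,
  for cross-site (altitudinal) comparison, plus conspecific cross-site
  overlap;
* sample-based rarefaction of acoustic species richness (days or
  minutes as units, day/night separately, seeded sample-order
  randomization);
* band-SPL noise proxies (dB re full scale, from audio if desired) and
  noise–activity regressions (square-root-y and linear models), with
  heavy-rain calling contrasts;
* a synthetic community generator with closed-form expected profiles,
  so the whole pipeline is testable end-to-end without field
  recordings.

## Worked example

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `04_assembly.R`); each stage reads the previous
stage's output and writes its tables under `results/`. Stage 1
simulates the packaged two-site, six-species highland community
(15,600 recorded minutes at seed 1). Stage 3 then prints, for the
high-altitude site:

```
Mean call-structure NB*: highland 0.20, lowland 0.20 (equal 6-species partition would give 0.17).

highland: NO_empiric = 0.52 +/- 0.13 over 15 pairs; NO_random = 0.50 +/- 0.09
  t = 0.91 (p = 0.37), variance ratio F = 2.13 (p = 0.016, larger: empiric)

Mean call-structure-only overlap: highland 0.35, lowland 0.35.
```

Read: each species occupies about a fifth of the standardized
call-structure niche space, close to the 1/6 = 0.17 expected under
equal exclusive partitioning; the call-structure dimension alone is
strongly partitioned (mean pairwise overlap 0.35, well below the 0.5
null mean), while shared nocturnal and seasonal timing keeps the
combined total-niche overlap near the null. Stage 4 clusters the
`species@site` niches — every species' two site-leaves pair together
before joining any other species (conspecific altitudinal overlap
0.96 ± 0.02) — and confirms that night rarefaction curves plateau at
six species versus five during daylight.

The same computations run on any annotation CSV via the exported
functions (`read_annotations()`, `breadth_table()`,
`community_overlap_matrix()`, `rarefy_incidence()`, …) or in one call
with `run_pipeline()`. Published pairwise-overlap and breadth tables
for two field communities (Sandi and Malalo wetlands, Volcanoes
National Park, Rwanda) ship under `inst/extdata/` and load with
`vnp_overlap()` / `vnp_breadth()`:

```r
library(anuraniche)
sandi <- vnp_overlap("sandi")
round(c(mean = sandi$mean, sd = sandi$sd), 2)
#> mean   sd
#> 0.35 0.16
```

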