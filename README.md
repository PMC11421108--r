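# deepclick

Passive acoustic monitoring turns a single deep-sea hydrophone into a
year-round census instrument for foraging sperm whales, whose echolocation
"usual clicks" arrive in trains with a near-constant inter-click interval
(ICI) of about 0.5–2 s. `deepclick` is an R package for the full analysis
chain built on that signal:

* **Detection** — a two-stage workflow: band-limited energy detection
  (1.4–4 kHz, +5 dB over a running background) flags candidate impulses,
  then a filtration step keeps only runs of ≥ *r* consecutive
  inter-detection intervals that round (to the nearest ¼ s) to the same
  value inside [0.5, 2.0] s. A day with at least one surviving sequence is
  scored "present". `tune_r()` picks *r* by balanced accuracy against a
  labeled corpus.
* **Seasonal statistics** — monthly percent of recording days with
  presence, a cyclic-spline GAM (month smooth + year random intercept),
  and ICI demographics (ICI < 0.6 s: females/juveniles; > 0.8 s: adult
  males) with a month×year ANOVA on log ICI.
* **Movement simulation** — 100 agents over 10 years under four candidate
  strategies (seasonal resource tracking, nomadism, to-and-fro migration,
  sex-specific partial migration), observed through two circular listening
  ranges; strategies are ranked by the root-mean-square deviation (RMSD)
  of their emergent monthly detection (12 months × 2 stations) from a
  reference seasonal series.
* **Oceanography** — the North Pacific Transition Zone latitude as the
  mean 18 °C SST isotherm between 160–180 °W, related to presence via
  ranged major axis (model II) regression with a permutation test.
* **Synthetic data** — generators for labeled hydrophone audio (click
  trains + impulsive confounders in Gaussian noise), reference presence
  series, and SST grids, so every stage is testable without any external
  data.

## Worked example

Synthesize a minute of audio holding one 8-click train (ICI 1.0 s, 20 dB
above the in-band background), detect it, and call the day:

```r
library(deepclick)

tr  <- click_train_spec(start_time = 5, n_clicks = 8, ici_mean = 1.0,
                        snr_db = 20)
day <- gen_audio_day(list(tr), day_length = 60, rng_seed = 2)
daily_call(day, detector_config(), r = 6)
#> daily call 2016-01-01: present=TRUE (8 candidate(s), 1 sequence(s))
```

The eight candidates form one sequence of 7 consecutive intervals, all
rounding to 1.0 s — at least `r = 6` are required, so the day is present.
A day of bursty impulses at irregular spacing yields many candidates but
no sequence, and stays absent.

Tuning *r* on the default 50-day labeled corpus (25 positive days, mixed
10–25 dB SNR; negatives carry Poisson-burst confounders):

```r
corpus <- gen_labeled_corpus(n_days = 50, prevalence = 0.5, rng_seed = 42)
tune_r(corpus)$reports
#>    r tp fp tn fn precision recall balanced_accuracy  fpr
#> 1  3 25  3 22  0     0.893   1.00              0.94 0.12
#> 2  4 24  0 25  1     1.000   0.96              0.98 0.00
#> ...
#> 8 10 21  0 25  4     1.000   0.84              0.92 0.00
```

Small *r* admits chance runs from the confounders (12% false positives at
r = 3); large *r* costs recall. Balanced accuracy peaks at 0.98.

Compare the four movement strategies against the built-in reference
seasonality (southern station: 59.3% of days in January, 31.1% in July;
northern station opposite phase):

```r
cmp <- compare_strategies(n_reps = 10, seed = 1)
cmp
#> strategy comparison (RMSD vs reference, percentage points):
#>   1. resource_tracking  median 13.6 (mean 14.3 +/- 1.9)
#>   2. nomadic            median 17.8 (mean 18.0 +/- 0.7)
#>   3. to_and_fro         median 36.8 (mean 36.8 +/- 0.1)
#>   4. partial            median 47.4 (mean 47.4 +/- 0.0)
```

Only seasonal resource tracking reproduces both defining features of the
reference pattern — year-round presence *and* opposite-phase seasonality
at the two stations — so it deviates least. Nomadism gives year-round but
aseasonal detection; the distinct-habitat migrations produce months of
structural absence that the reference does not show.

The whole pipeline (synthesis → detection → monthly statistics →
simulation → NPTZ/RMA) runs end to end with
`run_pipeline(default_pipeline_config(seed = 1), "out/")`, writing CSV/JSON
artifacts plus a manifest; a thin command-line wrapper lives at
`inst/scripts/deepclick.R`.

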