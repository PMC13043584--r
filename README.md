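# keyclock

Passive assessment of diurnal regularity, sleep, and cognitive performance
from smartphone keystroke metadata.

People type on their phones in sporadic bursts, so an hour without
keystrokes is ambiguous: asleep, or just not typing?  `keyclock` resolves
this by treating a participant's days × 24-hour typing-activity grid as a
flow on a torus — hours wrap 23:00 → 00:00 into the next day, and the same
hour is coupled across nearby days — and smoothing it with a
graph-regularized singular value decomposition:

```
min_{H,W}  ||X − HW||²_F + α·Tr(W B Wᵀ)    s.t.  HᵀH = I_r
```

where `X` stacks the normalized hourly keystroke counts and hourly typing
speed (median alphanumeric-to-alphanumeric interkey delay), `B` is the
graph Laplacian of a weighted adjacency over neighbouring hours and days
(hour edges weighted by the mean of the two cell counts, day edges by
seven-day-window medians), and by default `r = 1`, `α = 100`.  The solver
is exact via the Cholesky factor `D` of `I + αB`: the SVD of `X·D⁻ᵀ` gives
`H* = Ẽ` and the smoothed trajectory `W* = Σ̃ F̃ᵀ D⁻¹`.

From `W*` the package derives, per participant:

* **estimated sleep** — binarize, flood-fill the dominant inactive block,
  extend sleep backwards across midnight, clean small gaps with an 8 h /
  2 h sliding window, and keep one contiguous sleep block per relative
  24 h period (a behavioural proxy, not measured sleep);
* **typing-regularity features** — circular-variance spread, estimated
  sleep quantity statistics, and cosine similarity of activity patterns 1
  and 4 days apart;

and combines them with typing and phone-orientation features in ±3 h
windows around each digital Trail-Making-Test part B (dTMT-B)
administration to predict practice-adjusted completion times
(z-scored within task-number groups) using mutual-information feature
selection and Lasso / SVR / KNN / random-forest models under
participant-grouped cross-validation, with exact Shapley attributions and a
paired sign-flip permutation test for model comparison.

The study data this pipeline targets is private, so the package ships a
synthetic-cohort generator (`generate_cohort()`) with planted ground truth
— circadian keystroke intensity with a nightly inactivity window, weekend
modulation, lognormal interkey delays, orientation clusters, practice
decay, and two latent states linking typing speed, sleep regularity, task
performance, and PHQ — used throughout the tests as a recovery oracle.

## Worked example

```r
library(keyclock)

co  <- generate_cohort(cohort_config(n_participants = 6, n_days = 16, seed = 42))
ev  <- co$keystrokes[co$keystrokes$participant_id == "P001", ]
m   <- build_activity_matrices(ev)          # days x 24 counts and speed
wf  <- week_filter(m$counts, m$speed)       # 7-day activity filter
fit <- torus_svd(wf$counts, wf$speed, alpha = 100)
fit
#> Toroidal graph-regularized SVD (rank 1, alpha 100)
#>   participant: P001, 14 days x 24 hours
#>   singular value(s): 3.903
#>   objective 2.5288, roughness Tr(WBW') 4.9781e-05

sleep <- estimate_sleep(fit)
sleep
#> <sleep_labels P001: 14 days, anchor 00:00, median 6 h sleep/period>
```

The printed fit says the participant's 14 retained days were compressed
into one rank-1 trajectory (singular value 3.903) whose roughness penalty
is tiny — activity varies smoothly over the torus.  The sleep labels place
this participant's nightly block around midnight with a median of 6 h of
estimated sleep per relative 24 h period; against the generator's planted
truth this labelling is 90.8% correct at hour level.  The detected block is
shorter than the planted 8 h window because nightly onset jitter makes the
boundary hours inconsistent — the method recovers the *consistent* core of
the inactive block.

Building the per-task table and selecting predictors:

```r
ft  <- build_feature_table(co$keystrokes, co$accel, co$tasks, seed = 1)
ft
#> <feature_table: 30 task row(s), 6 participant(s), 6 smoothed participant(s)>

tab  <- ft$table[complete.cases(ft$table[c(candidate_features(), "adjusted_time")]), ]
plan <- split_cohort(tab, seed = 1)
sel  <- select_features_mi(tab[tab$participant_id %in% plan$train, ],
                           candidate_features(), k = 10)
head(sel, 3)
#>             feature        mi
#> 1      nSessions_gm 0.5935457
#> 2 avgNkeypresses_gm 0.4939697
#> 3      nClusters_gm 0.2618774
```

`select_features_mi()` keeps the 10 of 36 candidates with the highest
estimated mutual information with the adjusted task time; `tune_model()`
then fits any of the four model families on those columns, and
`shapley_attribution()` explains the predictions.  `run_pipeline()` wires
all stages together from a single seeded config and writes a manifest of
hashes, and `inst/cli/keyclock` exposes the same stages as shell
subcommands.

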