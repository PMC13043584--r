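---
title: "Methods: toroidal smoothing of typing activity, passive sleep estimation, and prediction of adjusted task performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: toroidal smoothing of typing activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keyclock)
```

## The problem

Smartphone keystroke metadata — timestamps and key categories, never text —
is a passive, zero-burden window onto two things clinicians care about in
mood disorders: diurnal/sleep regularity and processing speed.  The catch is
missingness: nobody types continuously, so an hour without keystrokes is
ambiguous between "asleep" and "just not typing".  `keyclock` implements a
pipeline that resolves this ambiguity by smoothing hourly typing activity
*as a flow on a torus* — hours wrap 23:00 → 00:00 into the next day, and the
same hour is coupled across nearby days — and then uses the smoothed
trajectory both to label one contiguous block of behavioural "sleep" per
relative 24 h period and to build typing-regularity features that feed a
subject-wise predictive model of practice-adjusted digital Trail-Making-Test
part B (dTMT-B) completion times.

"Sleep" throughout means a prolonged contiguous absence of typing, a
behavioural proxy; nothing here is validated against actigraphy or
polysomnography.

## Activity matrices and filters

Per participant, keystrokes are tabulated into a days × 24 count matrix
$k_{i,j}$ (hour $i$, day $j$) and a matching typing-speed matrix holding the
hourly median interkey delay (IKD) over consecutive
alphanumeric→alphanumeric keystrokes within a session, in seconds; empty
cells are zero.  The first and last calendar days are dropped as potentially
truncated.  Participants are kept only if the mean fraction of active hours
per day is ≥ 20% and the median daily keystroke total is ≥ 50 (inclusive
bounds).  The same thresholds are applied to every 7-consecutive-day window
(stride 1); a day survives if it lies in at least one passing window, and a
participant with fewer than 7 surviving days is dropped.  We read "windows
with one-day gaps" as stride 1 — the most permissive reading; a stride-8
tiling is the alternative and would only remove more days.  Surviving rows
may be non-contiguous dates; all later "day adjacency" means adjacency of
surviving rows in chronological rank.

## The graph-regularized SVD

The two hourly features (counts normalized by the participant's grand
total, and raw speed in seconds) are flattened day-major into a 2 × n data
matrix $X$, where $n = 24 \times \text{days}$.  The smoother solves

$$\min_{H,W} \; \lVert X - HW \rVert_F^2 + \alpha\,\mathrm{Tr}(W B W^{\mathsf T})
\quad \text{s.t. } H^{\mathsf T} H = I_r$$

with defaults $r = 1$, $\alpha = 100$.  Edge weights come from the raw
count matrix: neighbouring hours within a day (plus the 23:00→00:00 wrap
into the next retained day) get the mean of the two counts; the same hour
on days up to three rows apart gets the seven-day-window median of counts
at that hour, symmetrized as the mean of the two endpoint-centred medians
(an undirected edge needs a symmetric weight; the printed one-sided median
is not).  $B$ is the combinatorial graph Laplacian of this weighted
adjacency.  Two reasons: the solution route requires the Cholesky factor of
$I + \alpha B$, which a Laplacian guarantees to exist for every
$\alpha \ge 0$ (a raw nonnegative adjacency does not), and
$\mathrm{Tr}(WLW^{\mathsf T})$ is the standard graph-smoothness penalty
matching the "borrow strength from neighbouring hours and days" intuition.
The raw-adjacency variant is retained behind `build_regularizer(type =
"adjacency")` for comparison.

The solver is exact, not iterative: with $D$ the lower Cholesky factor of
$I + \alpha B$, the SVD of $X D^{-\mathsf T}$ gives
$H^* = \tilde E$ and $W^* = \tilde\Sigma \tilde F^{\mathsf T} D^{-1}$ from
the first $r$ singular triples; substituting the closed-form optimal
$W(H) = H^{\mathsf T} X (I+\alpha B)^{-1}$ shows this attains the global
minimum.  The tests verify this against an independent brute-force oracle
that walks $H = (\cos\theta, \sin\theta)^{\mathsf T}$ over a $10^5$-point
grid.

Numerical choices worth stating:

* **Sign fix.**  The SVD's sign is arbitrary; the trajectory is reported
  nonnegative.  Cells graph-disconnected from all activity survive
  smoothing as exact zeros, so "every entry negative" can never hold
  literally; we negate when no entry is positive beyond a $10^{-12}$
  relative tolerance and some are negative.
* **Clamping and zero tolerance.**  Entries that remain negative after the
  sign fix are clamped to 0, and entries with magnitude at or below
  `zero_tol` ($10^{-9} \times \max |W^*|$ by default) are treated as exact
  zeros, because floating-point smoothing otherwise never reproduces the
  structural zeros the sleep step depends on.
* **Observation set.**  All days × 24 cells of the retained rows are graph
  nodes, not only active cells; the sleep stage needs the inactive cells
  present in $W^*$.

## Sleep estimation

$W^*$ is binarized (activity > `zero_tol` → 1).  The dominant inactive
block is found by flood fill: the seed is the zero cell in the hour column
with minimal mean binarized activity (earliest such day), and the mask is
the 4-connected component of zero cells, treating the matrix as a 2-D image
with no wraparound.  Because the image rows cut time at midnight, sleep
beginning before midnight is recovered by walking backwards from each
masked 00:00 cell through the previous day's trailing zero hours.  Labels
are then flattened chronologically and cleaned by a sliding window of 8 h
advancing 2 h at a time: inside a window, a maximal run of ≤ 2 h flanked on
both sides by the opposite label is flipped, repeatedly until the window is
stable.  Finally, within each relative 24 h period — anchored at the
participant's modal sleep-onset hour so a block spanning midnight counts
once — only the longest sleep run (earliest on ties) is kept.

The seed rule, the flip rule inside the 8 h window, and the period anchor
are all under-determined design points; the choices above are documented
alternatives chosen for idempotence (a second cleanup pass is a no-op) and
for making the one-block invariant hold by construction, which the tests
check on randomized inputs.

## Features

Each retained task gets a window of keystrokes and accelerometer samples
within ±3 h of the task timestamp ("a six hour range around" is read as
total width 6 h), kept only if it holds ≥ 20 keystrokes.  Thirteen typing
and orientation features are computed per window (session counts, mean
keypresses per session, backspace and autocorrect rates, median
alphanumeric–alphanumeric IKD restricted to two-handed sessions, IKD
variance, median press duration, median |x|-acceleration, fractions of
upright and of nighttime non-upright sessions, orientation-cluster count
and transition rates).  Upright means a session representative (per-axis
median) with $-0.2 \le x \le 0.2$ and $z \le 0.1$; non-upright means
$(x > 0.5$ or $x < -0.5)$ and $z \ge 0.1$.  The nighttime window is
00:00–05:59 over the week before the task; a conflicting printed
12:00–17:59 window exists in the source material's feature table, but the
feature is named *nighttime* and the methods text says 00:00–05:59, so the
daytime variant is treated as a typo (both are configurable).

Phone orientations are discovered by a documented stand-in for the
published personalized-orientation method, which is not described in enough
detail to reproduce: session representatives are clustered by seeded
k-means over candidate counts 2–6, selected by mean silhouette width.

Five regularity features use the $W^*$ rows and sleep periods dated within
the week before the task (≥ 5 rows required): the variance of the rows'
activity-weighted circular variances ($1 - R$, $R$ the mean resultant
length of hour angles $2\pi h/24$ weighted by the row), the median and
variance of daily sleep hours, and the median cosine similarity of $W^*$
rows 1 and 4 days apart.

Every feature is expanded into a grand-mean column (`_gm`, the
participant's average — a between-person predictor) and a subject-centred
column (`_sc`, deviation from that average — a within-person predictor),
giving 36 candidates (26 without the regularity block).  `gm + sc`
reconstructs the raw value exactly, and `sc` is zero-mean within
participant.

## Practice adjustment

dTMT-B completion times improve mechanically with repetition.  Tasks are
numbered chronologically per participant *before* any filtering, capped at
the first six, and tasks at or above the pool's 95th percentile in errors
or completion time are excluded (the published cutoffs are that cohort's
percentiles, so the package recomputes them from the data at hand by
default; a fixed mode accepts supplied cutoffs, and a strict-above switch
exists for degenerate constant pools).  Within each task-number group the
times are z-scored with the population SD, making every group mean 0 / SD 1
exactly and hence the pooled adjusted times mean 0 / SD 1.00.

## Modeling

Participants are split 80/20 such that the task-count split is also within
±3 points of 80/20 (randomized search; subject-disjointness is a hard
assertion).  Mutual information between each of the 36 candidates and the
adjusted time is estimated on training rows only with the
Kraskov–Stögbauer–Grassberger nearest-neighbour estimator ($k = 3$, seeded
tie-breaking jitter, estimates clamped at 0); the top 10 are kept.  Four
model families are tuned by grid search under participant-grouped 3-fold
CV minimizing RMSE: Lasso (on all candidates — it does its own selection),
polynomial/radial SVR, KNN, and random forest; features are standardized
with training statistics for all but the forest.  The default grids contain
the hyperparameter optima the package's documentation discusses (penalty
0.5; cost 0.5 polynomial kernel; 30 neighbours; forests of 15 trees /
depth 4 / leaf 5 and 30 trees / depth 5 / leaf 4).  One deliberate
substitution: R's forest implementations do not offer an absolute-error
split criterion, so the forest grid varies trees, depth, and minimum node
size under the variance criterion.

Evaluation reports RMSE, MAE, explained variance, and R² on the held-out
participants, against a baseline predicting the training-target mean.
Feature attributions are exact interventional Shapley values computed by
enumerating all $2^{10}$ coalitions against a seeded background sample of
training rows; additivity (attributions sum to prediction minus base value)
is asserted to $10^{-6}$ per prediction.  Model pairs are compared with a
paired sign-flip permutation test on absolute test residuals (two-sided,
add-one correction); the label-swap variant was considered and rejected as
equivalent for paired differences.  The mood experiment re-tunes the best
model after adding the participant-mean PHQ total (or the mean of the first
two items, anhedonia and depressed mood) and reports both models side by
side.

## The synthetic cohort

The study's raw data is private, so the package ships a generator whose
defaults *are* the study conditions the package is tested under: 60
participants × 30 days; a planted nightly sleep window of 8 h with onset
near 23:00, nightly onset jitter of SD 0.5 h rounded to whole hours and
bounded at ±1 h; a circadian intensity profile averaging ≈ 400 keystrokes
per waking day with a 1.15× weekend factor (7-day periodicity); lognormal
IKDs with participant-level median near 0.2 s; per-participant orientation
centroids (upright, flat, side, reclined) with 0.05 g within-cluster spread
and a sticky session-to-session Markov chain; up to six tasks with a 0.95
practice decay per administration; and PHQ totals of mean 6, SD 4.8.

Two independent standard-normal latent states plant recoverable signal:
a typing/mood state that raises the median IKD (coefficient 0.25 on the
log), the task log-time (0.2), and the PHQ; and a sleep-regularity state
that scales nightly onset jitter (0.3 on the log of the jitter SD) and
contributes its own 0.15 to task log-time.  The second state exists so that
regularity features carry information *not* mediated by typing speed —
without it they would be statistically redundant by construction, and the
package's claim that adding them does not hurt held-out error would be
untestable.  Its weaker coefficient encodes the expectation that regularity
is a moderate, not dominant, predictor.

What the generator deliberately does not emulate: naps or split sleep,
travel and timezone shifts, language content, within-day nonstationarity of
typing speed, missing-not-at-random gaps (phone off), or per-participant
learning-rate differences in the practice effect.  Passing recovery tests
therefore shows the pipeline recovers structure *of the kind it models*,
not that real cohorts behave this way.

## Problem sizes used in the package's checks

The test suite exercises the default 60 × 30 cohort once for sleep
recovery, ten seeded repetitions of the full cohort for each modeling arm
(planted effects and zero effects), 20 random instances for the solver
oracle, 500 simulated repeats for the permutation-test calibration, and
small 6–12-participant cohorts everywhere a property does not need scale.
These sizes were chosen to hold Monte-Carlo error comfortably below the
asserted margins on a single desktop core.

## Known limitations

* Hour-resolution sleep only; onset/offset inside an hour are invisible.
* The one-block constraint erases naps by design.
* The orientation stand-in is not the published clustering method; its
  cluster counts should not be compared numerically against published
  ones.
* The recomputed 95th-percentile task cut is degenerate on constant pools
  under at-or-above semantics (everything is "at the percentile"); use the
  strict-above switch or fixed cutoffs there.
* Timestamps are taken as local wall clock; travellers' matrices will
  smear.
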