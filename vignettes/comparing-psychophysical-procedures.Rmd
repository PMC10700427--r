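---
title: "Comparing psychophysical estimation procedures on simulated observers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing psychophysical estimation procedures on simulated observers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psycompare)
library(dplyr)
```

## The problem

A psychometric function maps a physical stimulus dimension — the diameter
of a disk, the tilt of a gabor, the asynchrony between two onsets — to the
probability of one of two perceptual responses. Laboratories estimate its
two summary quantities, the *point of subjective equality* (PSE, the 50%
point) and the *just-noticeable difference* (JND, half the distance
between the 25% and 75% points), with one of three families of
procedures:

* the **method of constant stimuli** (CS): a fixed, pre-specified stimulus
  set presented many times in random order — accurate but slow;
* the **simple up-down staircase**: a nonparametric adaptive track that
  moves the stimulus one step against each response, targeting the 50%
  point;
* **QUEST+**: a Bayesian adaptive procedure that maintains a posterior
  over the psychometric parameters on a grid and places every stimulus to
  minimise the expected entropy of that posterior.

Whether these procedures agree — and how quickly the adaptive ones reach
the accuracy of CS — is an empirical question. `psycompare` implements all
three procedures and the comparison analytics around them, and replaces
human participants with seeded simulated observers, so that procedure
agreement, parameter recovery and design bookkeeping can be studied as
reproducible computations.

## The model

All three procedures share one observer model, the lapse-corrected
cumulative Gaussian:

$$P_{yes}(x) = \lambda + (1 - 2\lambda)\,\Phi\!\left(\frac{x - m}{\sigma}\right)$$

with $m$ the mean (the PSE), $\sigma$ the standard deviation (inversely
related to slope) and $\lambda \in [0, 0.5)$ a stimulus-independent lapse
rate that compresses both asymptotes to $[\lambda, 1 - \lambda]$. The
function is symmetric about $m$ ($P(m) = 0.5$ for any $\lambda$), and the
JND is computed by *exact inversion* of this model — including the lapse —
rather than by the lapse-free shortcut $0.6745\,\sigma$, because the
definition lives on response probability, not on the latent Gaussian:

```{r}
pf_jnd(sd = 0.1, lapse = 0)     # = qnorm(0.75) * 0.1
pf_jnd(sd = 0.1, lapse = 0.05)  # lapse widens the JND
```

## The three experiments

Three configurations mirror a size, an orientation and a temporal-order
task:

| | units | stimuli | reference | CS trials | QUEST+ grid (m × sd × lapse) |
|-|-------|---------|-----------|-----------|------------------------------|
| 1 | dva | 1.2–2.0 by 0.01 | 1.6 | 184 | 1.2:0.01:2.0 × 0.02:0.01:0.3 × 0:0.01:0.06 |
| 2 | deg | −24–24 by 2 | 0 | 184 | −24:2:24 × 1:0.1:20 × 0:0.01:0.08 |
| 3 | frames | −60–60 by 1 | 0 | 180 | −40:1:40 × 1:1:50 × 0:0.01:0.08 |

QUEST+ always stops after 64 trials. The staircase interleaves three
tracks starting far below, at, and far above the supposed threshold, with
experiment-specific step schedules (e.g. 0.2 dva for the first two
reversals then 0.1 dva in Experiment 1), and stops each track after 15
reversals or 10 presentations at a domain bound, capped globally at 150
trials. Two conventions deserve note. First, the Experiment 3 schedule
specifies steps only *after* the first, second and third reversals (4, 3,
2 frames); before the first reversal we use 4 frames. Second, the
Experiment 2 track starts (−28, 0, 28) lie outside the stated ±24 bounds;
we present them as printed and clamp from the first step onwards, counting
boundary presentations pooled over the two bounds within each track.

The Experiment 3 CS schedule needs one completion: the stated values (six
SOA magnitudes × 12 per sign, plus 0, 24 and 30 frames twelve times each)
only reach 180 trials if the signed extremes are split evenly, so we use
0 × 12, ±24 × 6 each and ±30 × 6 each, which also preserves the half/half
sign balance of which stimulus leads.

## Simulated observers

A `simulated_observer()` answers by a Bernoulli draw from the model above.
Cohorts are sampled with $m$ uniform over the central 60% of its domain,
$\sigma$ log-uniform over the middle half (log scale) of its domain, and
lapse uniform over the lapse domain — deliberately away from the grid
boundaries that, in human cohorts, trigger exclusions. Procedure order is
counterbalanced by cycling all six permutations of (QUEST+, CS,
staircase) across observers, and "block" 1–3 is the position of a
procedure in the session, so block effects can be separated from
procedure effects.

Optional per-block drift factors multiply $\sigma$ (e.g. `c(1, 0.8, 0.6)`)
to emulate the fast sensitivity improvement seen in peripheral-vision
tasks. What the generator does *not* emulate: fatigue and attentional
fluctuations within a block, serial response dependencies, fixation
breaks, or the apparent-motion confound of temporal-order judgments.
Passing tests therefore show that the procedures and analytics behave
correctly for observers that follow the assumed model, not that any given
human cohort will.

Every source of randomness is seeded, and every component draws from its
own derived sub-stream (cohort sampling, per-observer responses, staircase
interleaving, CS shuffling), so a procedure's stimulus randomness never
perturbs the response stream.

```{r}
cfg <- experiment_config(1)
obs <- simulated_observer(m = 1.6, sd = 0.08, lapse = 0.02)
run <- run_questplus(obs, cfg, seed = 7)
tidy(run)
```

## Numerical choices

* **QUEST+ engine.** The posterior lives on the full Cartesian grid with a
  uniform prior (no explicit Bayesian prior). Likelihoods for every (grid
  cell, stimulus, outcome) triple are precomputed once per configuration
  and cached, which reduces each expected-entropy evaluation to a few
  matrix–vector products; the largest grid (Experiment 3: 36,450 cells ×
  121 stimuli) runs in seconds. Entropy uses natural logs with
  $0 \log 0 = 0$; argmin ties break towards the smallest stimulus value,
  a deterministic and test-friendly convention. Both posterior-mean and
  MAP summaries are computed, but the estimates used in the comparison
  analytics always come from the maximum-likelihood fit to the 64 trials,
  the same fit applied to the other procedures; posterior summaries feed
  the ceiling flag and diagnostics. The ceiling exclusion fires when the
  MAP sd equals the top grid value *or* the posterior-mean sd reaches 95%
  of it (which of the two the original exclusion rule used is not
  determinable, so both are exposed and the flag defaults to their union).
* **Maximum-likelihood fitting.** Derivative-free Nelder–Mead on a
  logistic transform of the parameter box (the QUEST+ parameter domain, so
  all procedures' fits are commensurate), five deterministic starts — one
  seeded by a probit GLM — best likelihood wins, ties to the smallest
  $|\sigma|$, tolerance $10^{-6}$. Predicted probabilities are clipped to
  $[10^{-9}, 1 - 10^{-9}]$ inside the likelihood so lapse-free fits stay
  finite. Single-response-category data return `converged = FALSE` with a
  degenerate flag instead of crashing. By default $\sigma > 0$; an
  `allow_negative_slope` mode fits the mirror-image function too, which is
  how negative JNDs can legitimately appear in fitted cohorts, and the JND
  transform below must then shift before taking logs.
* **Staircase bounds.** Experiment 1 uses the stated stimulus range
  [1.2, 2.0] dva as its bounds and Experiment 3 uses ±40 frames (the track
  start extremes); only Experiment 2's bounds are stated directly.
  Tracks that hit the 150-trial cap with fewer than five reversals
  contribute the mean of whatever reversals exist, with a warning.
* **Binning.** Staircase trials are binned for plotting by rank: sort by
  stimulus and split into nine near-equal-count bins, matching the nine CS
  stimulus values. Fits always consume per-trial records.
* **Sn scale.** The robust double-median scale uses the consistency
  constant 1.1926 and the standard finite-sample corrections (important at
  cohort sizes around 21). Outliers are screened per measure (PSE and JND
  separately, per procedure) and flags are unioned per observer.
* **JND transform.** JND distributions are right-skewed; a Box–Cox profile
  on simulated JNDs supports a log transform ($\hat\lambda$ near 0). Since
  mirror-image fits can produce negative JNDs, `transform_jnd()` shifts by
  $|\min| + \varepsilon$ before the log when needed and warns; the shift
  is recorded as an attribute.
* **Learning analysis.** The study-scale mixed-model analysis is replaced,
  at desk scale, by a one-way repeated-measures ANOVA whose partition is
  computed in closed form (between-block, between-observer and residual
  sums of squares), with $F$ defined as 0 when the between-block sum of
  squares vanishes exactly; pairwise block differences use unadjusted
  paired t-tests. Bayesian ANOVAs, Satterthwaite corrections and Tukey
  adjustment are out of scope.
* **Bland–Altman intervals.** Limits of agreement use exactly ±1.96 SD of
  the differences; confidence intervals use the classical large-sample
  t-approximations (bias: $\pm t_{n-1} SD/\sqrt{n}$; each limit:
  $\pm t_{n-1} SD \sqrt{3/n}$). The regression slope of differences on
  pair means is reported to detect proportional bias.

## A worked comparison

```{r}
repl <- run_replication(cfg, n_observers = 12, seed = 42)
an <- analyze_replication(repl, screen = FALSE)
an$correlations
```

On stationary cohorts the three procedures' PSEs correlate strongly and
Bland–Altman biases hover near zero; the staircase's conventional
threshold (mean of the last five reversals per track) and its fitted
threshold correlate near the top of the published .86–.99 range:

```{r}
repl$estimates |>
  filter(procedure == "staircase") |>
  summarise(r = cor(conventional, pse))
```

## Problem sizes

The package's test and acceptance computations use these sizes, chosen to
estimate each property with comfortable margins: 20–21 observers per
cohort (the study-scale sample size), 100 seeded observers for QUEST+
recovery (bias and RMSE of the posterior-mean threshold), 50 seeds per
sample size for the ML-consistency curve, 100 replications per condition
for the block-effect error rates (per-block JNDs estimated from full
184-trial CS sessions, the cheapest unbiased route to a per-block
estimate), and 100 random posteriors/datasets for each exact-oracle
equivalence.

## Known limitations

* The simulated-observer model is exactly the model being fitted; model
  misspecification (asymmetric functions, non-stationary lapses, serial
  dependencies) is not explored.
* The generator makes no attempt to reproduce the *rates* of human
  exclusions (ceiling flags, non-converging tracks, aberrant
  performance) — only the mechanisms that detect them.
* Published human headline values (cohort correlation tables, mean
  PSE/JND levels, learning effect sizes) depend on human data and are not
  reproduced here; the package reproduces the designs, the estimators and
  their internal consistency.
* Whether 0-frame SOA trials should count as "yes" or "no" at exact
  simultaneity is undefined; the simulator records the raw Bernoulli
  response at $P = P_{yes}(0)$.
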