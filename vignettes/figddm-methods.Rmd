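---
title: "Condition-dependent drift diffusion modeling of figure-ground object detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-dependent drift diffusion modeling of figure-ground object detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and the model

`figddm` models two-alternative figure-ground object-detection experiments:
a bipartite display sketches a familiar object on one ("critical") side of a
central border, and the participant reports whether the figure lies left or
right. Displays appear upright or inverted, and in labels-present study arms
a word label — valid (denoting the depicted object) or invalid — precedes
each display. A response is scored correct when it falls on the
familiar-configuration side.

Choices and response times are modeled jointly with a Wiener diffusion
process: evidence $y$ accumulates as

$$dy = v\,dt + dW, \qquad s = 1,$$

between absorbing boundaries at $0$ ("left") and $a$ ("right"), starting at
$z = w a$. Crossing time plus a non-decision time $T_{er}$ gives the
response time, $RT = DT + T_{er}$. With the noise scale fixed at 1, the
drift rate $v$ is a signal-to-noise ratio. The free parameters per
participant are the drift coefficients below, boundary separation $a$,
relative start $w$ (with $w - 0.5$ the rightward start bias), and
non-decision time.

Condition covariates are coded $S \in \{-1, +1\}$ (familiar side
left/right), $O \in \{0, 1\}$ (inverted/upright), $L \in \{0, 1\}$
(invalid/valid label). The drift on a trial is linear in these codes:

$$v = v_{base} + v_s S + v_{so} S O + v_{sl} S L + v_{sol} S O L,$$

and the non-decision time is $T_{er} = T_0 + T_l L$. Boundary separation
and starting point are constant within a participant: both are set before
the stimulus (and the label's validity) can be known, so they may differ
between study arms but not between trials. The *control* variant (no
labels) fixes $v_{sl} = v_{sol} = T_l = 0$, leaving 6 free parameters; the
*labels* variant has 9. Drift toward the *correct* side in a cell is the
model evaluated at $S = +1$: for example the upright-valid condition drift
is $v_s + v_{so} + v_{sl} + v_{sol}$, and the inverted-invalid condition
drift is $v_s$ alone.

## Likelihood

The per-trial likelihood is the Wiener first-passage-time density at the
boundary matching the choice (upper = "right"), evaluated at
$t = RT - T_{er}$. The density is computed from the standard
normalized-time decomposition
$f(t \mid v, a, w) = a^{-2} e^{-v a w - v^2 t / 2} f_0(t/a^2, w)$,
where $f_0$ is the zero-drift unit-boundary density, evaluated by whichever
of the small-time and large-time series needs fewer terms at the truncation
tolerance; the upper-boundary density follows from the reflection
$w \to 1 - w$, $v \to -v$. Numerical choices, all exposed through
`wfpt_config()`:

* **Series tolerance** `err = 1e-7` (absolute). The branch rule picks the
  cheaper series per evaluation; the two branches agree to within `2 * err`
  wherever both converge (this is tested).
* **Density floor** `density_floor = 1e-10`, applied before the log. A
  trial whose RT falls at or below the fitted $T_{er}$ has no support;
  flooring keeps the objective finite and leaves such trials locally flat
  for the optimizer.
* **Time floor** `t_floor = 1e-5` s: decision times at or below it are
  floored outright.

Non-responses (the deadline is 4 s) are excluded from the likelihood; they
are rare under the fitted parameter range and the recording rule censors
them without a usable RT.

## Fitting

`fit_participant()` minimizes the negative total log-likelihood with
bounded L-BFGS-B from multiple start points (default 10): one fixed neutral
start plus uniform draws inside the box from a participant-keyed seed
stream. Two properties follow by construction and are tested: fits are
bit-identical given the data and seed (regardless of trial or participant
ordering, thanks to a canonical trial sort), and the best log-likelihood is
non-decreasing in the number of starts (the start set is nested).

The gradient of the log-density is supplied analytically — both series are
differentiable term by term in $v$, $a$, $w$ and $t$ — which cuts the
optimizer's cost per iteration by roughly the parameter count and removes
finite-difference noise near the floors.

Box bounds: drift coefficients in $[-8, 8]$, $a \in [0.1, 5]$,
$w \in [0.05, 0.95]$, $T_l \in [-0.5, 0.5]$ with $T_0 + T_l \ge 0$ enforced
by penalty. The upper bound for $T_0$ is the participant's fastest
**invalid-label** (or control) RT, not the overall fastest RT: when
$T_l < 0$, the fastest responses are typically valid-label trials, whose
support constrains $T_0 + T_l$ rather than $T_0$, and bounding $T_0$ by the
overall minimum can exclude the true value.

## Synthetic data

`generate_design()` reproduces the study structure: 72 trials per
participant, 36 upright / 36 inverted, valid and invalid labels crossed 18
per orientation-by-label cell in labels-present arms, the familiar side
balanced left/right within every cell, trial order shuffled per
participant, and a 4 s response deadline. Default cohort sizes are 113
(control), 105 (study 1) and 103 (study 2), consistent with the
between-group degrees of freedom of the comparisons this design supports
(216, 214, 206). Exposure-duration subgroups (90/100 ms) are not
represented — no modeled parameter distinguishes them — and neither is
black/white counterbalancing, which no parameter depends on.

`simulate_trials()` integrates the diffusion with Euler–Maruyama steps of
`dt = 1e-4` s plus a Brownian-bridge crossing check inside every step (the
probability that the path crossed a boundary between step endpoints is
$e^{-2 d_0 d_1 / dt}$ for endpoint distances $d_0, d_1$). The bridge check
removes the $O(\sqrt{dt})$ crossing bias of the plain scheme, and the
simulated distribution is indistinguishable from the analytic
first-passage distribution by a Kolmogorov–Smirnov test at $10^5$ trials
(checked in the acceptance suite). `sample_rts()` draws instead from the
tabulated analytic distribution (inverse-CDF); it is used where large
model-predicted samples are needed cheaply, with the path simulator as the
process-level reference.

`population_spec()` supplies participant heterogeneity for simulation
studies. Its default means sit on group-level values typical of this task:
$a \approx 0.78$, a drift toward the familiar side of $\approx 0.8$
with an upright advantage of $\approx 0.17$, valid-label drift effects of
$\approx 0.45$ and $\approx 0.37$, a slight rightward start bias
($w = 0.52$), $T_0 = 0.38$ s and $T_l = -0.05$ s. The default SDs were set
once from the dispersion that group contrasts of this size imply — a
between-participant condition-drift SD of roughly 0.75, allocated mostly to
the side main effect (SD 0.6) with 0.35 on the modulatory coefficients —
plus SD 0.2 for $a$, 0.05 for $w$, 0.08 s for $T_0$ and 0.03 s for $T_l$.
Draws are truncated to the parameter box.

What the generator does **not** emulate: contaminant processes (attention
lapses, post-timeout responses), sequential trial-to-trial dependence,
within-participant drift variability across trials of the same cell, and
any difference between display exemplars. Passing recovery and contrast
tests on this generator therefore demonstrates correctness of the
estimation and inference machinery under the model's own assumptions, not
robustness of the model to real-data violations — the quantile diagnostics
below exist precisely to surface such violations.

## Parameter recovery and its limits

`run_recovery()` simulates a cohort, refits it, and reports per-parameter
true-versus-fitted correlation, bias and RMSE. Two regimes matter:

* $a$, $w$, $T_0$ and $T_l$ are strongly identified even at 72 trials per
  participant; their recovery correlations are high in every cohort we
  simulate.
* The drift coefficients are weakly identified at 72 trials. Each is
  resolved from contrasts of 18-trial cells, so its sampling SE is several
  tenths to above one drift unit — comparable to or larger than the
  plausible between-participant spread. Their recovery correlations are
  therefore moderate at the 72-trial design and rise steeply with trials
  per participant (the suite checks the 72 vs 576 ordering). Cohort-level
  contrasts remain usable because this noise averages out across
  participants. One caveat: contrasts **across model variants** (a labels
  arm against control) can carry a small finite-sample MLE bias of a
  couple of tenths of a drift unit at 72 trials, because the two
  variants' condition-drift estimators do not share identical
  small-sample bias. At the default cohort sizes this sits inside the
  contrast's 95% CI — the end-to-end acceptance analysis recovers an
  injected +0.5 upright-valid increment within its CI — but it is visible
  as a point estimate somewhat above the injected value.

```{r recovery-example}
library(figddm)
rec <- run_recovery(design_spec("study1", n_participants = 100, seed = 1),
                    population_spec(seed = 1),
                    fit_options(n_starts = 10, seed = 1))
rec$report
```

## Group-level analyses

`condition_drifts()` applies the exact coefficient algebra above.
`condition_increments()` compares a labels-present arm to control per
orientation with a pooled-variance two-sample $t$ test and $t$-based 95%
CI (the degrees of freedom, $n_1 + n_2 - 2$, match the reported
comparisons). `mixed_anova_2x2()` implements the
2 (study, between) × 2 (orientation or label, within) mixed ANOVA through
the exact sum/difference decomposition available for a two-level within
factor: the between effect is tested on participant means, the within main
effect as the unweighted (Type-III) grand mean of the within-participant
differences, and the interaction as the group contrast of those
differences; partial $\eta^2$ is $F / (F + df_2)$ for these single-df
effects. On balanced data this reproduces `aov()` stratum by stratum
(tested), and the unweighted within effect keeps Type-III behavior under
unequal group sizes.

`fastest_rt_contrast()` averages each participant's fastest 20% of RTs per
label condition; the leading edge of the RT distribution is dominated by
non-decision time, so the valid−invalid difference in fastest means tracks
$T_l$.

`quantile_check()` bins each participant's responded RTs per
orientation-by-label cell into quantile bins (rank-based, default 4),
draws a large model-predicted sample from the fitted parameters (truncated
at the deadline), and tests the per-bin observed−predicted mean-RT and
accuracy discrepancies across participants. For the contamination
acceptance analysis the flag level is set to $\alpha = 0.01$: with four
conditions and four bins, 16 tests run simultaneously, and a 0.05 level
would flag a clean bin in roughly one run in two by chance alone.

## Problem sizes and seeds

The acceptance analyses use: the full $5 \times 3 \times 3$ parameter grid
for the density invariants; $10^5$ paths for the simulator check; 100
participants × 72 trials for recovery; paper-sized cohorts (113 control +
105 study) for the increment and interaction recovery, with a $+0.5$
upright-valid shift injected through $v_{sol}$; and a 16-participant cohort
with 5% uniform-[2, 4] s contaminants for the quantile diagnostics. Every
stochastic stage takes its stream from a single base seed. `Rscript
scripts/acceptance.R --seed 1 --out results/acceptance.json` reruns all of
them.

## Known limitations

* No across-trial variability parameters ($s_v$, $s_t$, $s_z$): the model
  class deliberately matches the original analysis.
* Non-responses are dropped rather than censored into the likelihood.
* Individual drift coefficients should not be interpreted for single
  participants at 72 trials; use cohort-level contrasts.
* The CDF used in diagnostics is tabulated on a fixed grid (trapezoid,
  20001 points to 20 s); absolute error is far below the diagnostic
  noise floor but it is not adaptive quadrature.
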