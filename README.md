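# figddm

Condition-dependent drift diffusion modeling of figure-ground object
detection.

## What this package is for

In bipartite figure-ground experiments, a central border divides a display
into two regions, one of which sketches a familiar object, upright or
inverted; participants report which side holds the figure, sometimes after
a word label (valid or invalid for the upcoming object) has been flashed.
The scientific questions — does a valid label speed evidence accumulation?
does an invalid label raise the evidence threshold? does anything shift
response bias or motor/encoding time? — cannot be answered from accuracy
and mean RT separately. `figddm` answers them by fitting a drift diffusion
model jointly to every trial's choice and response time.

The model: evidence accumulates as `dy = v dt + dW` (noise fixed at
`s = 1`) between absorbing boundaries `0` ("left") and `a` ("right"),
starting at `z = w a`; `RT = DT + Ter`. The drift on each trial is linear
in the side code `S` (±1), orientation `O` (0/1) and label validity `L`
(0/1):

    v   = v_base + v_s S + v_so S O + v_sl S L + v_sol S O L
    Ter = T0 + Tl L

Boundary separation and starting point are constant within a participant.
Labels-present arms have 9 free parameters per participant; the control
(no-labels) variant fixes `v_sl = v_sol = Tl = 0`, leaving 6.

The package provides:

* the Wiener first-passage-time density (small-time / large-time series
  with the fewer-terms branch rule), its analytic gradient, closed-form
  choice probabilities and mean decision times (`wfpt_density()`,
  `choice_probability()`, `mean_decision_time()`);
* per-participant maximum likelihood with multi-start bounded
  optimization (`fit_participant()`, `fit_dataset()`);
* a design-faithful simulator — balanced 72-trial
  orientation-by-label-by-side designs, Euler–Maruyama paths with a
  Brownian-bridge crossing correction, heterogeneous participants
  (`generate_design()`, `simulate_dataset()`);
* parameter-recovery experiments (`run_recovery()`);
* the group-level analyses: condition drifts, increments over control
  with t-based CIs, 2×2 mixed ANOVAs, fastest-20% RT contrasts, and
  quantile-based fit diagnostics (`condition_increments()`,
  `mixed_anova_2x2()`, `fastest_rt_contrast()`, `quantile_check()`,
  `predicted_vs_observed_summary()`).

See `vignettes/figddm-methods.Rmd` for the modeling assumptions, numerical
choices and known limitations.

## Worked example

Simulate a small labels-present cohort with known parameters, refit it,
and look at condition-level drifts and model fit:

```r
library(figddm)

sim  <- simulate_dataset(design_spec("study1", n_participants = 3, seed = 42),
                         population_spec(seed = 42))
fits <- fit_dataset(sim$trials, fit_options(n_starts = 10, seed = 42))
round(fits[, c("v_s", "v_so", "v_sl", "v_sol", "a", "w", "T0", "Tl", "loglik")], 3)
#>      v_s  v_so  v_sl  v_sol     a     w    T0     Tl  loglik
#> 1  1.657 0.572 0.261  1.381 1.108 0.521 0.301 -0.088  37.894
#> 2  1.100 0.152 0.378 -0.296 1.245 0.483 0.572 -0.066 -10.985
#> 3 -0.177 0.960 0.836  1.103 0.558 0.719 0.519 -0.067  89.601

aggregate(drift ~ orientation + label, condition_drifts(fits), mean)
#>   orientation label     drift
#> 1           0     0 0.8603523
#> 2           1     0 1.4218973
#> 3           0     1 1.3523080
#> 4           1     1 2.6433640

round(predicted_vs_observed_summary(fits, sim$trials)[,
  c("orientation", "label", "acc_obs", "acc_pred", "rt_obs", "rt_pred")], 3)
#>   orientation label acc_obs acc_pred rt_obs rt_pred
#> 1           1     1   0.870    0.864  0.575   0.562
#> 2           0     1   0.796    0.771  0.580   0.591
#> 3           1     0   0.796    0.772  0.655   0.664
#> 4           0     0   0.685    0.704  0.698   0.678
```

Reading the tables: drift toward the correct side is highest for
upright displays after valid labels (`v_s + v_so + v_sl + v_sol`) and
lowest for inverted displays after invalid labels (`v_s` alone); fitted
and observed accuracy / mean RT agree cell by cell. With only 72 trials
per participant the individual drift coefficients are noisy (see the
vignette's identifiability discussion) — scientific conclusions should
rest on the cohort-level contrasts, e.g. `condition_increments()` against
a control cohort.

A thin command-line wrapper over the same functions lives at
`inst/cli/figddm.R`:

```sh
Rscript inst/cli/figddm.R simulate --seed 3 --study study1 --n_participants 10 --out_dir out/
Rscript inst/cli/figddm.R fit --trials_csv out/trials.csv --out_dir out/
Rscript inst/cli/figddm.R analyze --trials_csv out/trials.csv --fits_csv out/fits.csv --out_dir out/
```

## Using the deposited behavioral data

The trial-level data of the three studies are deposited at
`https://osf.io/g3mxb/` (displays at `https://osf.io/j9kz2/`) and are not
redistributed here. To run the refit comparison in
`tests/testthat/test-acceptance.R`, download the deposit, convert it to
the `read_trials()` CSV dialect (columns `participant_id, study, side,
orientation, label, choice, rt_s, responded`; sides −1/+1, orientation
0 = inverted / 1 = upright, label 0 = invalid / 1 = valid and empty for
control rows, RT in seconds) and place it at
`tests/testthat/data/osf-g3mxb-trials.csv`.
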