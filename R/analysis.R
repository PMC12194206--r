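#' Per-participant condition drifts toward the correct side
#'
#' Evaluates each participant's fitted drift model at `S = +1` (drift
#' toward the familiar-configuration side) for every orientation-by-label
#' cell: upright-valid `v_s + v_so + v_sl + v_sol`, inverted-valid
#' `v_s + v_sl`, upright-invalid `v_s + v_so`, inverted-invalid `v_s`;
#' control arms have upright `v_s + v_so` and inverted `v_s`.
#'
#' @param fits Fit table from [fit_dataset()].
#' @return Long data frame with columns `participant_id`, `study`,
#'   `orientation` (0/1), `label` (0/1, `NA` for control), `drift`.
#' @export
condition_drifts <- function(fits) {
  need <- c("participant_id", "study", "variant", "v_s", "v_so", "v_sl",
            "v_sol")
  if (!all(need %in% names(fits))) {
    stop("`fits` must be a fit table from fit_dataset()", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(fits)), function(i) {
    f <- fits[i, ]
    if (f$variant == "control") {
      data.frame(participant_id = f$participant_id, study = f$study,
                 orientation = c(1, 0), label = NA_real_,
                 drift = c(f$v_s + f$v_so, f$v_s),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(participant_id = f$participant_id, study = f$study,
                 orientation = c(1, 0, 1, 0), label = c(1, 1, 0, 0),
                 drift = c(f$v_s + f$v_so + f$v_sl + f$v_sol,
                           f$v_s + f$v_sl,
                           f$v_s + f$v_so,
                           f$v_s),
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Two-sample equal-variance t contrast with CI and Cohen's d.
.t_contrast <- function(x, y, conf = 0.95) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 participants per group", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = TRUE, conf.level = conf)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  data.frame(estimate = mean(x) - mean(y),
             se = unname(tt$stderr),
             ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value,
             cohen_d = (mean(x) - mean(y)) / sp,
             mean_1 = mean(x), mean_2 = mean(y),
             sd_1 = stats::sd(x), sd_2 = stats::sd(y),
             n_1 = n1, n_2 = n2)
}

#' Drift-rate increments of a labels-present study over control
#'
#' For one label condition (valid or invalid), compares condition drifts
#' of a labels-present study arm against the control arm, separately per
#' orientation: the increment is the study mean minus the control mean,
#' with a pooled-variance two-sample t-test and 95% confidence interval.
#'
#' @param fits_study Fit table for a labels-present arm.
#' @param fits_control Fit table for the control arm.
#' @param label_condition `"valid"` or `"invalid"`.
#' @param conf Confidence level.
#' @return Data frame with one row per orientation: increment estimate,
#'   SE, CI, t, df, p, Cohen's d, and the group means/SDs/sizes.
#' @export
condition_increments <- function(fits_study, fits_control,
                                 label_condition = c("valid", "invalid"),
                                 conf = 0.95) {
  label_condition <- match.arg(label_condition)
  if (any(fits_study$variant != "labels")) {
    stop("`fits_study` must be labels-variant fits", call. = FALSE)
  }
  if (any(fits_control$variant != "control")) {
    stop("`fits_control` must be control-variant fits", call. = FALSE)
  }
  lab <- if (label_condition == "valid") 1 else 0
  ds <- condition_drifts(fits_study)
  dc <- condition_drifts(fits_control)
  out <- lapply(c(1, 0), function(o) {
    x <- ds$drift[ds$orientation == o & ds$label == lab]
    y <- dc$drift[dc$orientation == o]
    cbind(orientation = o, label = lab, .t_contrast(x, y, conf))
  })
  res <- do.call(rbind, out)
  names(res)[names(res) == "estimate"] <- "increment"
  rownames(res) <- NULL
  res
}

#' Two-by-two mixed ANOVA (one between factor, one two-level within factor)
#'
#' Tests the between-group main effect, the within-participant main
#' effect, and their interaction on a long table with exactly two levels
#' of the within factor per participant.  With a two-level within factor
#' the mixed ANOVA reduces exactly to independent t-type contrasts on
#' per-participant sums and differences; the within-factor main effect is
#' the unweighted (Type-III) mean of the group difference means, so
#' unequal group sizes are handled.  Partial eta squared is reported as
#' `F / (F + df2)` for these single-df effects.
#'
#' @param data Long data frame.
#' @param dv Name of the response column.
#' @param between Name of the two-level between-participants factor.
#' @param within Name of the two-level within-participant factor.
#' @param id Name of the participant identifier column.
#' @return Data frame with rows `between`, `within`, `interaction`:
#'   columns `effect`, `estimate`, `F`, `df1`, `df2`, `p`, `eta_p2`.
#' @export
mixed_anova_2x2 <- function(data, dv = "drift", between = "study",
                            within = "orientation", id = "participant_id") {
  for (col in c(dv, between, within, id)) {
    if (!col %in% names(data)) stop("missing column: ", col, call. = FALSE)
  }
  g_levels <- sort(unique(as.character(data[[between]])))
  w_levels <- sort(unique(as.character(data[[within]])))
  if (length(g_levels) != 2L || length(w_levels) != 2L) {
    stop("both factors must have exactly 2 levels", call. = FALSE)
  }
  wide <- stats::reshape(
    data[, c(id, between, within, dv)], direction = "wide",
    idvar = c(id, between), timevar = within, v.names = dv)
  cn <- paste(dv, w_levels, sep = ".")
  if (!all(cn %in% names(wide)) || anyNA(wide[, cn])) {
    stop("every participant needs both levels of the within factor",
         call. = FALSE)
  }
  d <- wide[[cn[2]]] - wide[[cn[1]]]   # within contrast (level2 - level1)
  m <- (wide[[cn[2]]] + wide[[cn[1]]]) / 2
  grp <- as.character(wide[[between]])
  g1 <- grp == g_levels[1]
  n1 <- sum(g1)
  n2 <- sum(!g1)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 participants per group", call. = FALSE)
  df2 <- n1 + n2 - 2L

  pooled_var <- function(x) {
    ((n1 - 1) * stats::var(x[g1]) + (n2 - 1) * stats::var(x[!g1])) / df2
  }
  f_row <- function(effect, est, se) {
    Fv <- (est / se)^2
    data.frame(effect = effect, estimate = est, F = Fv, df1 = 1L, df2 = df2,
               p = stats::pf(Fv, 1, df2, lower.tail = FALSE),
               eta_p2 = Fv / (Fv + df2), stringsAsFactors = FALSE)
  }
  # between: group contrast on participant means
  sm <- sqrt(pooled_var(m))
  est_b <- mean(m[g1]) - mean(m[!g1])
  # within: unweighted grand mean of the within contrast
  sd_ <- sqrt(pooled_var(d))
  est_w <- (mean(d[g1]) + mean(d[!g1])) / 2
  # interaction: group difference of the within contrast
  est_i <- mean(d[g1]) - mean(d[!g1])
  hm <- sqrt(1 / n1 + 1 / n2)
  out <- rbind(
    f_row("between", est_b, sm * hm),
    f_row("within", est_w, sd_ * hm / 2),
    f_row("interaction", est_i, sd_ * hm))
  attr(out, "levels") <- list(between = g_levels, within = w_levels)
  out
}

#' Fastest-fraction response-time contrast between label conditions
#'
#' For each participant in a labels-present arm, takes the fastest
#' `ceiling(fraction * n)` responded trials separately for valid and
#' invalid labels and averages their response times; the valid-minus-
#' invalid difference in these fastest means isolates non-decision-time
#' effects, which dominate the leading edge of the RT distribution.
#' When two studies are present, a study-by-label mixed ANOVA on the
#' fastest means is included.
#'
#' @param trials Trial table from labels-present arms (all rows must carry
#'   label codes).
#' @param fraction Fraction of fastest trials to keep, in (0, 1].
#' @return A list with `participant` (per-participant fastest means and
#'   `diff = valid - invalid`), `summary` (per-study group means), and
#'   `anova` (study-by-label [mixed_anova_2x2()], or `NULL` with one
#'   study).
#' @export
fastest_rt_contrast <- function(trials, fraction = 0.20) {
  .validate_trials(trials)
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 ||
      fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (any(trials$study == "control")) {
    stop("fastest-RT label contrast needs labels-present data", call. = FALSE)
  }
  trials <- trials[trials$responded, , drop = FALSE]
  key <- unique(trials[, c("participant_id", "study")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sub <- trials[trials$participant_id == key$participant_id[i], ]
    fm <- vapply(c(1, 0), function(lab) {
      rt <- sort(sub$rt_s[sub$label == lab])
      if (!length(rt)) return(NA_real_)
      mean(rt[seq_len(ceiling(fraction * length(rt)))])
    }, numeric(1))
    data.frame(participant_id = key$participant_id[i], study = key$study[i],
               valid = fm[1], invalid = fm[2], diff = fm[1] - fm[2],
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per, per$study), function(s) {
    data.frame(study = s$study[1], n = nrow(s), valid = mean(s$valid),
               invalid = mean(s$invalid), diff = mean(s$diff),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  anova <- NULL
  if (length(unique(per$study)) == 2L) {
    long <- rbind(
      data.frame(participant_id = per$participant_id, study = per$study,
                 label = 1, fastest_rt = per$valid),
      data.frame(participant_id = per$participant_id, study = per$study,
                 label = 0, fastest_rt = per$invalid))
    anova <- mixed_anova_2x2(long, dv = "fastest_rt", between = "study",
                             within = "label")
  }
  list(participant = per, summary = summary, anova = anova)
}

# Accuracy of responded trials under the familiar-side scoring rule.
.trial_correct <- function(trials) {
  (trials$choice == "right") == (trials$side == 1)
}

# Effective diffusion parameters for one fit-table row.
.params_from_row <- function(f) {
  if (f$variant == "control") {
    ddm_params(v_base = f$v_base, v_s = f$v_s, v_so = f$v_so, a = f$a,
               w = f$w, T0 = f$T0, variant = "control")
  } else {
    ddm_params(v_base = f$v_base, v_s = f$v_s, v_so = f$v_so, v_sl = f$v_sl,
               v_sol = f$v_sol, a = f$a, w = f$w, T0 = f$T0, Tl = f$Tl,
               variant = "labels")
  }
}

#' Quantile-based goodness-of-fit diagnostics
#'
#' Splits each participant's responded trials in every orientation-by-
#' label cell into `n_quantiles` RT bins (by that sample's own quantiles)
#' and compares per-bin mean RT and accuracy with bins of a large sample
#' drawn from the participant's fitted model (inverse-CDF draws from the
#' analytic first-passage distribution, truncated at the deadline).
#' Across participants, per-condition-and-bin paired discrepancies are
#' tested with one-sample t-tests; bins where the model misses (for
#' example a contaminated slow tail) are flagged.
#'
#' @param trials Observed trial table (one study arm).
#' @param fits Fit table from [fit_dataset()] covering the participants.
#' @param n_quantiles Number of RT bins (>= 2).
#' @param n_sim Model draws per participant and condition.
#' @param deadline Response deadline (s); model draws beyond it are
#'   discarded, mirroring the recording rule.
#' @param seed Integer seed for the model draws.
#' @param alpha Flagging level for the per-bin t-tests.
#' @return A list with `bins` (per participant, condition, bin: observed
#'   and predicted mean RT and accuracy) and `tests` (per condition and
#'   bin: mean RT and accuracy discrepancies, t statistics, p values, and
#'   logical `flag_rt` / `flag_acc`).
#' @export
quantile_check <- function(trials, fits, n_quantiles = 4L, n_sim = 10000L,
                           deadline = 4, seed = 1L, alpha = 0.05) {
  .validate_trials(trials)
  n_quantiles <- as.integer(n_quantiles)
  if (n_quantiles < 2L) stop("`n_quantiles` must be >= 2", call. = FALSE)
  trials <- trials[trials$responded, , drop = FALSE]
  is_control <- all(trials$study == "control")
  cells <- if (is_control) {
    data.frame(orientation = c(1, 0), label = NA_real_)
  } else {
    expand.grid(orientation = c(1, 0), label = c(1, 0))
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  # rank-based quantile split (robust to tied response times)
  bin_stats <- function(rt, correct) {
    bin <- ceiling(rank(rt, ties.method = "first") * n_quantiles / length(rt))
    vapply(seq_len(n_quantiles), function(b) {
      sel <- bin == b
      c(rt = mean(rt[sel]), acc = mean(correct[sel]))
    }, numeric(2))
  }

  out <- list()
  skipped <- 0L
  for (pid in unique(trials$participant_id)) {
    ptr <- trials[trials$participant_id == pid, ]
    frow <- fits[fits$participant_id == pid, ]
    if (nrow(frow) != 1L) next
    params <- .params_from_row(frow)
    for (ci in seq_len(nrow(cells))) {
      o <- cells$orientation[ci]
      lab <- cells$label[ci]
      sel <- ptr$orientation == o &
        (if (is_control) TRUE else ptr$label == lab)
      obs <- ptr[sel, ]
      if (nrow(obs) < n_quantiles) {
        skipped <- skipped + 1L
        next
      }
      ob <- bin_stats(obs$rt_s, .trial_correct(obs))
      # model draws: half per familiar side, pooled on correctness
      sim_list <- lapply(c(1, -1), function(S) {
        ep <- effective_params(params, S, o, if (is_control) NULL else lab)
        draws <- sample_rts(ceiling(n_sim / 2),
                            diffusion_spec(ep$v, ep$a, ep$w), Ter = ep$Ter)
        draws$correct <- (draws$choice == "right") == (S == 1)
        draws
      })
      simd <- do.call(rbind, sim_list)
      simd <- simd[simd$rt_s <= deadline, ]
      sb <- bin_stats(simd$rt_s, simd$correct)
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid, orientation = o, label = lab,
        bin = seq_len(n_quantiles),
        rt_obs = ob["rt", ], acc_obs = ob["acc", ],
        rt_pred = sb["rt", ], acc_pred = sb["acc", ],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no condition cell had enough trials", call. = FALSE)
  if (skipped > 0L) {
    message(sprintf("quantile_check: skipped %d under-filled condition cells",
                    skipped))
  }
  bins <- do.call(rbind, out)
  bins$rt_diff <- bins$rt_obs - bins$rt_pred
  bins$acc_diff <- bins$acc_obs - bins$acc_pred

  test_one <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3L || stats::sd(x) == 0) {
      return(c(mean = mean(x), t = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(x)
    c(mean = mean(x), t = unname(tt$statistic), p = tt$p.value)
  }
  keys <- unique(bins[, c("orientation", "label", "bin")])
  tests <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- bins$orientation == k$orientation & bins$bin == k$bin &
      (is.na(k$label) | bins$label %in% k$label)
    rt <- test_one(bins$rt_diff[sel])
    ac <- test_one(bins$acc_diff[sel])
    data.frame(orientation = k$orientation, label = k$label, bin = k$bin,
               rt_diff = rt["mean"], rt_t = rt["t"], rt_p = rt["p"],
               acc_diff = ac["mean"], acc_t = ac["t"], acc_p = ac["p"],
               stringsAsFactors = FALSE)
  }))
  tests$flag_rt <- !is.na(tests$rt_p) & tests$rt_p < alpha
  tests$flag_acc <- !is.na(tests$acc_p) & tests$acc_p < alpha
  rownames(tests) <- NULL
  list(bins = bins, tests = tests)
}

#' Observed versus model-predicted condition summaries
#'
#' Per study-by-orientation-by-label cell, compares observed accuracy and
#' mean response time (pooled over correct and error responses) with the
#' closed-form model predictions of [predicted_condition_summary()]
#' averaged over participants and familiar-configuration sides.
#'
#' @param fits Fit table from [fit_dataset()].
#' @param trials The trial table the fits came from.
#' @return Data frame per cell: `study`, `orientation`, `label`,
#'   `acc_obs`, `acc_pred`, `rt_obs`, `rt_pred`, `acc_gap`, `rt_gap`,
#'   `n_participants`.
#' @export
predicted_vs_observed_summary <- function(fits, trials) {
  .validate_trials(trials)
  trials <- trials[trials$responded, , drop = FALSE]
  out <- list()
  for (st in unique(fits$study)) {
    f_st <- fits[fits$study == st, ]
    t_st <- trials[trials$study == st, ]
    is_control <- st == "control"
    cells <- if (is_control) {
      data.frame(orientation = c(1, 0), label = NA_real_)
    } else {
      expand.grid(orientation = c(1, 0), label = c(1, 0))
    }
    for (ci in seq_len(nrow(cells))) {
      o <- cells$orientation[ci]
      lab <- cells$label[ci]
      sel <- t_st$orientation == o &
        (if (is_control) TRUE else t_st$label == lab)
      obs <- t_st[sel, ]
      pred <- vapply(seq_len(nrow(f_st)), function(i) {
        params <- .params_from_row(f_st[i, ])
        ps <- predicted_condition_summary(params, S = c(1, -1), O = o,
                                          L = if (is_control) NULL else lab)
        c(mean(ps$p_correct), mean(ps$mean_rt))
      }, numeric(2))
      out[[length(out) + 1L]] <- data.frame(
        study = st, orientation = o, label = lab,
        acc_obs = mean(.trial_correct(obs)), acc_pred = mean(pred[1, ]),
        rt_obs = mean(obs$rt_s), rt_pred = mean(pred[2, ]),
        n_participants = nrow(f_st), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$acc_gap <- res$acc_obs - res$acc_pred
  res$rt_gap <- res$rt_obs - res$rt_pred
  rownames(res) <- NULL
  res
}
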