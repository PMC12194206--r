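test_that("condition drifts follow the coefficient algebra exactly", {
  set.seed(3)
  fits <- draw_fits_table(5, population_spec(seed = 3))
  cd <- condition_drifts(fits)
  for (i in seq_len(nrow(fits))) {
    f <- fits[i, ]
    g <- cd[cd$participant_id == f$participant_id, ]
    expect_equal(g$drift[g$orientation == 1 & g$label == 1],
                 f$v_s + f$v_so + f$v_sl + f$v_sol)
    expect_equal(g$drift[g$orientation == 0 & g$label == 1], f$v_s + f$v_sl)
    expect_equal(g$drift[g$orientation == 1 & g$label == 0], f$v_s + f$v_so)
    expect_equal(g$drift[g$orientation == 0 & g$label == 0], f$v_s)
  }
  ctl <- draw_fits_table(4, population_spec(variant = "control", seed = 3),
                         study = "control")
  cdc <- condition_drifts(ctl)
  expect_equal(cdc$drift[cdc$orientation == 1], ctl$v_s + ctl$v_so)
  expect_equal(cdc$drift[cdc$orientation == 0], ctl$v_s)
})

test_that("null increments are near zero and a known shift is recovered", {
  pop_c <- population_spec(variant = "control", seed = 8)
  fits_c <- draw_fits_table(60, pop_c, study = "control")
  # same drift structure, no label effect: expected increment 0
  pop_null <- population_spec(mean = list(v_sl = 0, v_sol = 0), seed = 9)
  inc0 <- condition_increments(draw_fits_table(60, pop_null), fits_c, "valid")
  expect_true(all(abs(inc0$increment) < 0.4))
  expect_true(all(inc0$ci_lo < 0 & inc0$ci_hi > 0))
  # +0.5 upright-valid shift through the three-way coefficient
  pop_shift <- population_spec(mean = list(v_sl = 0, v_sol = 0.5), seed = 10)
  inc <- condition_increments(draw_fits_table(60, pop_shift), fits_c, "valid")
  up <- inc[inc$orientation == 1, ]
  expect_true(up$ci_lo < 0.5 && up$ci_hi > 0.5)
  expect_lt(inc$p[inc$orientation == 1], 0.01)
  expect_equal(up$df, 118)
  expect_error(condition_increments(fits_c, fits_c), "labels-variant")
})

test_that("t-based confidence intervals agree with a bootstrap oracle", {
  set.seed(12)
  x <- rnorm(40, 0.5, 0.7)
  y <- rnorm(45, 0, 0.7)
  ct <- figddm:::.t_contrast(x, y)
  boot <- replicate(4000, mean(sample(x, replace = TRUE)) -
                      mean(sample(y, replace = TRUE)))
  bw <- diff(unname(quantile(boot, c(0.025, 0.975)))) / 2
  tw <- (ct$ci_hi - ct$ci_lo) / 2
  expect_lt(abs(tw - bw) / bw, 0.10)
})

test_that("mixed ANOVA matches hand-computed sums of squares on a toy table", {
  # 2 participants per group, hand-checkable numbers
  toy <- data.frame(
    participant_id = rep(c("a", "b", "c", "d"), each = 2),
    study = rep(c("g1", "g1", "g2", "g2"), each = 2),
    orientation = rep(c(0, 1), 4),
    drift = c(1, 2, 2, 4, 3, 3, 4, 6))
  an <- mixed_anova_2x2(toy)
  # by hand: participant means m = (1.5, 3, 3, 5); d = up - inv = (1, 2, 0, 2)
  m <- c(1.5, 3, 3, 5)
  d <- c(1, 2, 0, 2)
  g <- c(1, 1, 2, 2)
  sp2_m <- (var(m[1:2]) + var(m[3:4])) / 2
  t_b <- (mean(m[1:2]) - mean(m[3:4])) / sqrt(sp2_m * (1 / 2 + 1 / 2))
  sp2_d <- (var(d[1:2]) + var(d[3:4])) / 2
  t_w <- ((mean(d[1:2]) + mean(d[3:4])) / 2) / (sqrt(sp2_d) / 2 * sqrt(1))
  t_i <- (mean(d[1:2]) - mean(d[3:4])) / sqrt(sp2_d * 1)
  expect_equal(an$F[an$effect == "between"], t_b^2, tolerance = 1e-12)
  expect_equal(an$F[an$effect == "within"], t_w^2, tolerance = 1e-12)
  expect_equal(an$F[an$effect == "interaction"], t_i^2, tolerance = 1e-12)
  expect_equal(an$df2, rep(2L, 3))
})

test_that("mixed ANOVA agrees with aov on balanced data", {
  set.seed(17)
  n <- 14
  long <- expand.grid(participant_id = sprintf("p%02d", 1:(2 * n)),
                      orientation = c(0, 1))
  long$study <- ifelse(as.integer(sub("p", "", long$participant_id)) <= n,
                       "s1", "ctrl")
  long$drift <- rnorm(nrow(long)) + 0.8 * long$orientation +
    0.5 * (long$study == "s1") + 0.4 * long$orientation * (long$study == "s1")
  an <- mixed_anova_2x2(long)
  fit <- summary(aov(drift ~ study * orientation + Error(participant_id),
                     data = transform(long, orientation = factor(orientation))))
  between <- fit[["Error: participant_id"]][[1]]
  within <- fit[["Error: Within"]][[1]]
  expect_equal(an$F[an$effect == "between"], between["study", "F value"],
               tolerance = 1e-8)
  expect_equal(an$F[an$effect == "within"], within["orientation", "F value"],
               tolerance = 1e-8)
  expect_equal(an$F[an$effect == "interaction"],
               within["study:orientation", "F value"], tolerance = 1e-8)
  expect_equal(an$p[an$effect == "within"],
               within["orientation", "Pr(>F)"], tolerance = 1e-8)
})

test_that("mixed ANOVA keeps its size under the null and sees a within effect", {
  set.seed(23)
  rates <- replicate(60, {
    long <- data.frame(
      participant_id = rep(sprintf("p%02d", 1:16), 2),
      study = rep(rep(c("g1", "g2"), each = 8), 2),
      orientation = rep(c(0, 1), each = 16),
      drift = rnorm(32))
    mixed_anova_2x2(long)$p < 0.05
  })
  expect_lt(mean(rates), 0.12)  # near-nominal rejection under the null
  hits <- replicate(30, {
    long <- data.frame(
      participant_id = rep(sprintf("p%02d", 1:20), 2),
      study = rep(rep(c("g1", "g2"), each = 10), 2),
      orientation = rep(c(0, 1), each = 20),
      drift = rnorm(40, sd = 0.5))
    long$drift <- long$drift + 1.0 * long$orientation
    p <- mixed_anova_2x2(long)$p
    c(orient = p[2] < 0.05, study = p[1] < 0.05, inter = p[3] < 0.05)
  })
  expect_gte(mean(hits["orient", ]), 0.9)
  expect_lte(mean(hits["study", ]), 0.2)
  expect_lte(mean(hits["inter", ]), 0.2)
})

test_that("contrast p-values agree with a permutation oracle", {
  set.seed(29)
  x <- rnorm(8, 0.8, 1)
  y <- rnorm(8, 0, 1)
  ct <- figddm:::.t_contrast(x, y)
  obs <- mean(x) - mean(y)
  pooled <- c(x, y)
  perm <- replicate(20000, {
    idx <- sample(16, 8)
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  p_perm <- mean(abs(perm) >= abs(obs))
  expect_lt(abs(ct$p - p_perm), 0.05 + 3 * sqrt(p_perm * (1 - p_perm) / 20000))
})

test_that("fastest-RT contrast reduces to condition means at fraction 1", {
  sim <- cached("sim_s1_small", {
    simulate_dataset(design_spec("study1", n_participants = 2, seed = 4),
                     population_spec(seed = 4))
  })
  tr <- sim$trials
  fr <- fastest_rt_contrast(tr, fraction = 1)
  resp <- tr[tr$responded, ]
  for (i in seq_len(nrow(fr$participant))) {
    pid <- fr$participant$participant_id[i]
    expect_equal(fr$participant$valid[i],
                 mean(resp$rt_s[resp$participant_id == pid & resp$label == 1]))
    expect_equal(fr$participant$invalid[i],
                 mean(resp$rt_s[resp$participant_id == pid & resp$label == 0]))
  }
  expect_error(fastest_rt_contrast(tr, fraction = 0), "fraction")
  expect_error(fastest_rt_contrast(tr, fraction = 1.5), "fraction")
})

test_that("fastest-RT contrast tracks the non-decision-time shift", {
  zero_sd <- as.list(setNames(rep(0, 9),
    c("v_base", "v_s", "v_so", "v_sl", "v_sol", "a", "w", "T0", "Tl")))
  zero_sd[c("v_s", "T0")] <- c(0.3, 0.04)
  pop <- population_spec(mean = list(v_sl = 0, v_sol = 0, Tl = -0.05),
                         sd = zero_sd, seed = 33)
  sim <- simulate_dataset(design_spec("study1", n_participants = 8,
                                      seed = 33), pop)
  fr <- fastest_rt_contrast(sim$trials)
  expect_lt(fr$summary$diff, 0)
  expect_lt(mean(fr$participant$diff < 0), 1.01)  # defined for all
  # permuting labels within participant washes the contrast out
  perm <- sim$trials
  set.seed(34)
  for (pid in unique(perm$participant_id)) {
    sel <- perm$participant_id == pid
    perm$label[sel] <- sample(perm$label[sel])
  }
  fr_perm <- fastest_rt_contrast(perm)
  tt <- t.test(fr_perm$participant$diff)
  expect_gt(tt$p.value, 0.05)
})

test_that("quantile diagnostics are self-consistent and degrade gracefully", {
  sim <- cached("qc_cohort", {
    simulate_dataset(design_spec("study1", n_participants = 10, seed = 44),
                     population_spec(seed = 44))
  })
  fits <- truth_as_fits(sim$truth)
  qc <- quantile_check(sim$trials, fits, n_sim = 4000, seed = 44)
  expect_equal(sort(unique(qc$tests$bin)), 1:4)
  # data generated from the very parameters being checked: discrepancies
  # are noise; allow the occasional nominal-level flag
  expect_lte(sum(qc$tests$flag_rt), 2)
  expect_lt(max(abs(qc$tests$rt_diff)), 0.25)
  qc2 <- quantile_check(sim$trials, fits, n_quantiles = 2, n_sim = 2000,
                        seed = 45)
  expect_equal(sort(unique(qc2$tests$bin)), 1:2)
  expect_error(quantile_check(sim$trials, fits, n_quantiles = 1), ">= 2")
})

test_that("raising the valid-label drift only improves predicted valid accuracy", {
  base <- ddm_params(v_s = 0.8, v_so = 0.2, v_sl = 0.2, v_sol = 0.1,
                     a = 0.8, w = 0.5, T0 = 0.35, Tl = -0.03)
  accs <- vapply(c(0.2, 0.5, 0.9, 1.4), function(vsl) {
    p <- ddm_params(v_s = 0.8, v_so = 0.2, v_sl = vsl, v_sol = 0.1,
                    a = 0.8, w = 0.5, T0 = 0.35, Tl = -0.03)
    mean(predicted_condition_summary(p, S = c(1, -1), O = 1, L = 1)$p_correct)
  }, numeric(1))
  expect_true(all(diff(accs) > 0))
  inv <- vapply(c(0.2, 0.9), function(vsl) {
    p <- ddm_params(v_s = 0.8, v_so = 0.2, v_sl = vsl, v_sol = 0.1,
                    a = 0.8, w = 0.5, T0 = 0.35, Tl = -0.03)
    mean(predicted_condition_summary(p, S = c(1, -1), O = 1, L = 0)$p_correct)
  }, numeric(1))
  expect_equal(inv[1], inv[2])  # invalid trials untouched
})

test_that("observed-predicted gaps shrink with more trials per participant", {
  pop <- population_spec(seed = 52)
  sim72 <- simulate_dataset(design_spec("study1", n_participants = 10,
                                        seed = 52), pop)
  sim1152 <- simulate_dataset(design_spec("study1", n_participants = 10,
                                          trials_per_participant = 1152,
                                          seed = 52), pop)
  f <- truth_as_fits(sim72$truth)
  g72 <- predicted_vs_observed_summary(f, sim72$trials)
  g1152 <- predicted_vs_observed_summary(truth_as_fits(sim1152$truth),
                                         sim1152$trials)
  expect_lt(mean(abs(g1152$acc_gap)), mean(abs(g72$acc_gap)))
  expect_lt(mean(abs(g1152$rt_gap)), mean(abs(g72$rt_gap)))
})
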