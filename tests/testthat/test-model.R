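test_that("drift and non-decision linear models evaluate exactly", {
  p <- ddm_params(v_base = 0.1, v_s = 0.9, v_so = 0.35, v_sl = 0.6,
                  v_sol = 0.25, a = 0.8, w = 0.52, T0 = 0.35, Tl = -0.03)
  expect_equal(effective_params(p, S = 1, O = 1, L = 1)$v, 2.2)
  expect_equal(effective_params(p, S = -1, O = 1, L = 1)$v, 0.1 - 2.1)
  expect_equal(effective_params(p, S = 1, O = 1, L = 1)$Ter, 0.32)
  expect_equal(effective_params(p, S = 1, O = 1, L = 0)$Ter, 0.35)
  zero <- ddm_params(T0 = 0.4, a = 1, w = 0.5)
  ep <- effective_params(zero, S = -1, O = 0, L = 0)
  expect_equal(ep$v, 0)
  expect_equal(ep$Ter, 0.4)
})

test_that("variant rules and covariate domains are enforced", {
  ctrl <- ddm_params(v_s = 1, a = 1, w = 0.5, T0 = 0.3, variant = "control")
  expect_error(effective_params(ctrl, S = 1, O = 1, L = 1), "control")
  lab <- ddm_params(v_s = 1, a = 1, w = 0.5, T0 = 0.3, variant = "labels")
  expect_error(effective_params(lab, S = 1, O = 1), "label code")
  expect_error(effective_params(lab, S = 2, O = 1, L = 1), "side code")
  expect_error(effective_params(lab, S = 1, O = 3, L = 1), "orientation")
  expect_error(ddm_params(v_sl = 1, variant = "control"), "control variant")
  expect_error(ddm_params(T0 = 0.1, Tl = -0.2), "T0 \\+ Tl")
})

test_that("out-of-support trials are floored at the density floor", {
  p <- ddm_params(v_s = 1, a = 1, w = 0.5, T0 = 0.5, variant = "control")
  tr <- data.frame(participant_id = "x", study = "control", side = 1,
                   orientation = 1, label = NA_real_, choice = "right",
                   rt_s = c(0.3, 0.5, 0.50001), responded = TRUE)
  ll <- trial_loglik(tr, p)
  expect_equal(ll[1], log(1e-10))
  expect_equal(ll[2], log(1e-10))
  expect_equal(ll[3], log(1e-10))  # below t_floor
  tr$rt_s <- 0.9
  expect_gt(trial_loglik(tr[1, ], p), log(1e-10))
})

test_that("trial likelihood equals the independent density oracle", {
  p <- ddm_params(v_base = -0.1, v_s = 0.8, v_so = 0.3, v_sl = 0.4,
                  v_sol = 0.2, a = 0.9, w = 0.45, T0 = 0.3, Tl = -0.04)
  tr <- data.frame(participant_id = "x", study = "study1",
                   side = c(1, -1, 1, -1), orientation = c(1, 0, 0, 1),
                   label = c(1, 1, 0, 0),
                   choice = c("right", "left", "left", "right"),
                   rt_s = c(0.8, 1.1, 0.6, 1.4), responded = TRUE)
  ll <- trial_loglik(tr, p)
  for (i in seq_len(nrow(tr))) {
    ep <- effective_params(p, tr$side[i], tr$orientation[i], tr$label[i])
    t <- tr$rt_s[i] - ep$Ter
    dens <- if (tr$choice[i] == "right") {
      oracle_wfpt_lower(t, -ep$v, ep$a, 1 - ep$w)
    } else {
      oracle_wfpt_lower(t, ep$v, ep$a, ep$w)
    }
    expect_equal(exp(ll[i]), dens, tolerance = 1e-6)
  }
})

test_that("likelihood is mirror symmetric under left/right relabeling", {
  p <- ddm_params(v_base = 0, v_s = 0.9, v_so = 0.4, v_sl = 0.3,
                  v_sol = 0.2, a = 0.8, w = 0.5, T0 = 0.3, Tl = -0.02)
  set.seed(5)
  n <- 40
  tr <- data.frame(participant_id = "x", study = "study1",
                   side = sample(c(-1, 1), n, TRUE),
                   orientation = sample(c(0, 1), n, TRUE),
                   label = sample(c(0, 1), n, TRUE),
                   choice = sample(c("left", "right"), n, TRUE),
                   rt_s = runif(n, 0.4, 2), responded = TRUE)
  mirrored <- tr
  mirrored$side <- -tr$side
  mirrored$choice <- ifelse(tr$choice == "left", "right", "left")
  expect_equal(trial_loglik(mirrored, p), trial_loglik(tr, p),
               tolerance = 1e-12)
})

test_that("labels variant with zeroed label effects reproduces the control likelihood", {
  p_lab <- ddm_params(v_base = 0.05, v_s = 0.8, v_so = 0.3, v_sl = 0,
                      v_sol = 0, a = 0.85, w = 0.48, T0 = 0.32, Tl = 0,
                      variant = "labels")
  p_ctl <- ddm_params(v_base = 0.05, v_s = 0.8, v_so = 0.3, a = 0.85,
                      w = 0.48, T0 = 0.32, variant = "control")
  set.seed(9)
  n <- 30
  tr <- data.frame(participant_id = "x", study = "study1",
                   side = sample(c(-1, 1), n, TRUE),
                   orientation = sample(c(0, 1), n, TRUE),
                   label = sample(c(0, 1), n, TRUE),
                   choice = sample(c("left", "right"), n, TRUE),
                   rt_s = runif(n, 0.4, 2), responded = TRUE)
  ll_lab <- trial_loglik(tr, p_lab)
  tr_ctl <- tr
  tr_ctl$study <- "control"
  tr_ctl$label <- NA_real_
  ll_ctl <- trial_loglik(tr_ctl, p_ctl)
  expect_identical(ll_lab, ll_ctl)
})

test_that("true parameters beat random perturbations in total log-likelihood", {
  pop0 <- population_spec(sd = as.list(setNames(rep(0, 9),
    c("v_base", "v_s", "v_so", "v_sl", "v_sol", "a", "w", "T0", "Tl"))),
    seed = 3)
  des <- design_spec("study1", n_participants = 1,
                     trials_per_participant = 10000, seed = 3)
  sim <- simulate_dataset(des, pop0)
  tr <- sim$trials[sim$trials$responded, ]
  tru <- sim$truth[1, ]
  p_true <- ddm_params(tru$v_base, tru$v_s, tru$v_so, tru$v_sl, tru$v_sol,
                       tru$a, tru$w, tru$T0, tru$Tl, variant = "labels")
  ll_true <- sum(trial_loglik(tr, p_true))
  th <- unlist(tru[free_param_names("labels")])
  set.seed(31)
  for (i in 1:20) {
    dir <- rnorm(9)
    thp <- th + 0.5 * dir / sqrt(sum(dir^2))
    thp["a"] <- max(thp["a"], 0.15)
    thp["w"] <- min(max(thp["w"], 0.06), 0.94)
    thp["T0"] <- max(thp["T0"], 0.01)
    thp["Tl"] <- max(thp["Tl"], -thp["T0"])
    p_pert <- ddm_params(thp["v_base"], thp["v_s"], thp["v_so"], thp["v_sl"],
                         thp["v_sol"], thp["a"], thp["w"], thp["T0"],
                         thp["Tl"], variant = "labels")
    expect_lt(sum(trial_loglik(tr, p_pert)), ll_true)
  }
})
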