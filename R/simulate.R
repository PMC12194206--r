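#' Study design specification
#'
#' Describes the trial structure of one study arm: 72 trials per
#' participant split 36 upright / 36 inverted, with valid/invalid labels
#' crossed 18 per orientation-by-label cell in the labels-present arms and
#' the familiar-configuration side on the right for exactly half the trials
#' of every cell.  Responses are accepted up to a 4 s deadline.  Default
#' group sizes (113 control, 105 study 1, 103 study 2) reproduce the
#' between-group degrees of freedom of the original cohorts.
#'
#' @param study `"control"`, `"study1"` or `"study2"`.
#' @param n_participants Number of participants; defaults to the study-arm
#'   cohort size above.
#' @param trials_per_participant Trials per participant; must be divisible
#'   by 4 (control) or 8 (labels arms) to keep the design balanced.
#' @param deadline Response deadline in seconds.
#' @param seed Integer seed for trial-order randomization.
#'
#' @return An object of class `"design_spec"`.
#' @export
design_spec <- function(study = c("control", "study1", "study2"),
                        n_participants = NULL, trials_per_participant = 72L,
                        deadline = 4, seed = 1L) {
  study <- match.arg(study)
  if (is.null(n_participants)) {
    n_participants <- switch(study, control = 113L, study1 = 105L,
                             study2 = 103L)
  }
  n_participants <- as.integer(n_participants)
  trials_per_participant <- as.integer(trials_per_participant)
  if (n_participants < 1L) stop("need at least one participant", call. = FALSE)
  cell <- if (study == "control") 4L else 8L
  if (trials_per_participant %% cell != 0L) {
    stop(sprintf("trials_per_participant must be divisible by %d for %s",
                 cell, study), call. = FALSE)
  }
  if (deadline <= 0) stop("deadline must be positive", call. = FALSE)
  structure(list(study = study, n_participants = n_participants,
                 trials_per_participant = trials_per_participant,
                 deadline = deadline, seed = as.integer(seed)),
            class = "design_spec")
}

#' Generate a balanced trial skeleton
#'
#' Expands a [design_spec()] into covariate rows (no choices or response
#' times yet): exact orientation / label / side cell counts, with the trial
#' order shuffled independently per participant under the design seed.
#'
#' @param spec A [design_spec()].
#' @return A data frame with columns `participant_id`, `study`, `trial`,
#'   `side`, `orientation`, `label` (`NA` for the control arm).
#' @export
generate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  n_tr <- spec$trials_per_participant
  if (spec$study == "control") {
    cells <- expand.grid(side = c(-1, 1), orientation = c(0, 1))
    cells$label <- NA_real_
    per_cell <- n_tr %/% 4L
  } else {
    cells <- expand.grid(side = c(-1, 1), orientation = c(0, 1),
                         label = c(0, 1))
    per_cell <- n_tr %/% 8L
  }
  base <- cells[rep(seq_len(nrow(cells)), each = per_cell), , drop = FALSE]
  out <- vector("list", spec$n_participants)
  digits <- max(3L, nchar(spec$n_participants))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(spec$seed)
  for (i in seq_len(spec$n_participants)) {
    ord <- sample.int(n_tr)
    d <- base[ord, , drop = FALSE]
    d$participant_id <- sprintf("%s_%0*d", spec$study, digits, i)
    d$study <- spec$study
    d$trial <- seq_len(n_tr)
    rownames(d) <- NULL
    out[[i]] <- d
  }
  res <- do.call(rbind, out)
  res[, c("participant_id", "study", "trial", "side", "orientation", "label")]
}

# Save / restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# First-passage simulation of dy = v dt + dW between absorbing boundaries
# 0 and a, started at z, by Euler-Maruyama steps of size dt with a
# Brownian-bridge crossing check inside each step (removes the O(sqrt(dt))
# boundary-crossing bias of the plain scheme).  Vectorized over trials.
# Returns decision time (NA if no absorption by t_max) and boundary.
.simulate_fpt <- function(v, a, z, t_max, dt = 1e-4) {
  n <- max(length(v), length(a), length(z))
  v <- rep_len(v, n)
  a <- rep_len(a, n)
  z <- rep_len(z, n)
  y <- z
  dtv <- rep(NA_real_, n)
  upper <- rep(NA, n)
  active <- seq_len(n)
  sqdt <- sqrt(dt)
  max_steps <- ceiling(t_max / dt)
  step <- 0L
  while (length(active) && step < max_steps) {
    step <- step + 1L
    m <- length(active)
    ya <- y[active]
    yn <- ya + v[active] * dt + sqdt * stats::rnorm(m)
    au <- a[active]
    lo <- yn <= 0
    hi <- !lo & yn >= au
    inside <- which(!lo & !hi)
    t_cross <- rep(step * dt, m)
    if (length(inside)) {
      # bridge crossing probabilities for paths that stayed inside
      p_lo <- exp(-2 * ya[inside] * yn[inside] / dt)
      p_hi <- exp(-2 * (au[inside] - ya[inside]) * (au[inside] - yn[inside]) / dt)
      u <- stats::runif(length(inside))
      b_lo <- u < p_lo
      b_hi <- !b_lo & u < p_lo + p_hi
      lo[inside[b_lo]] <- TRUE
      hi[inside[b_hi]] <- TRUE
      t_cross[inside[b_lo | b_hi]] <- (step - 0.5) * dt
    }
    done <- lo | hi
    if (any(done)) {
      gi <- active[done]
      dtv[gi] <- t_cross[done]
      upper[gi] <- hi[done]
      active <- active[!done]
      y[active] <- yn[!done]
    } else {
      y[active] <- yn
    }
  }
  list(dt = dtv, upper = upper)
}

#' Simulate diffusion trials
#'
#' Draws choices and response times from the diffusion process by
#' Euler-Maruyama simulation (step 1e-4 s) with a within-step
#' Brownian-bridge crossing correction.  `rt = DT + Ter`; trials whose
#' response time would exceed the deadline are returned as non-responses.
#'
#' @param n Number of trials (ignored if the parameter vectors are longer).
#' @param v,a,w,Ter Per-trial effective parameters (recycled to `n`).
#' @param deadline Response deadline (s).
#' @param dt Euler step size (s).
#' @return A data frame with columns `choice` ("left"/"right", `NA` for
#'   non-responses), `rt_s`, `responded`.
#' @export
simulate_trials <- function(n, v, a, w, Ter, deadline = 4, dt = 1e-4) {
  n <- max(n, length(v), length(a), length(w), length(Ter))
  v <- rep_len(v, n)
  a <- rep_len(a, n)
  w <- rep_len(w, n)
  Ter <- rep_len(Ter, n)
  fp <- .simulate_fpt(v, a, w * a, t_max = deadline, dt = dt)
  rt <- fp$dt + Ter
  responded <- !is.na(rt) & rt <= deadline
  choice <- ifelse(fp$upper, "right", "left")
  choice[!responded] <- NA_character_
  rt[!responded] <- NA_real_
  data.frame(choice = choice, rt_s = rt, responded = responded,
             stringsAsFactors = FALSE)
}

#' Population distribution of participant parameters
#'
#' Independent truncated normal distributions for each [ddm_params()]
#' field, used to draw heterogeneous participants for simulation and
#' parameter-recovery studies.  Defaults center on the fitted group-level
#' values reported for this task (boundary separation near 0.78, a drift
#' toward the familiar side near 0.8 with an upright advantage near 0.17,
#' valid-label drift effects near 0.45 and 0.37, a slight rightward start
#' bias, baseline non-decision time 0.38 s, and a -0.05 s valid-label
#' shift), with between-participant spreads chosen to match the
#' condition-drift dispersion implied by the reported group contrasts.
#'
#' @param mean Named list/vector overriding default parameter means.
#' @param sd Named list/vector overriding default parameter SDs (>= 0).
#' @param variant `"labels"` or `"control"`; the control variant pins
#'   `v_sl`, `v_sol`, `Tl` at 0.
#' @param seed Integer seed used when participants are drawn.
#'
#' @return An object of class `"population_spec"` with fields `mean`, `sd`,
#'   `variant`, `seed`.
#' @export
population_spec <- function(mean = list(), sd = list(),
                            variant = c("labels", "control"), seed = 1L) {
  variant <- match.arg(variant)
  mu <- c(v_base = 0, v_s = 0.80, v_so = 0.17, v_sl = 0.45, v_sol = 0.37,
          a = 0.78, w = 0.52, T0 = 0.38, Tl = -0.05)
  sg <- c(v_base = 0.15, v_s = 0.60, v_so = 0.35, v_sl = 0.35, v_sol = 0.35,
          a = 0.20, w = 0.05, T0 = 0.08, Tl = 0.03)
  mu[names(mean)] <- unlist(mean)
  sg[names(sd)] <- unlist(sd)
  if (variant == "control") {
    mu[c("v_sl", "v_sol", "Tl")] <- 0
    sg[c("v_sl", "v_sol", "Tl")] <- 0
  }
  if (any(sg < 0)) stop("population SDs must be >= 0", call. = FALSE)
  structure(list(mean = mu, sd = sg, variant = variant,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# Exact truncated-normal draws via the inverse-CDF method.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(stats::qnorm(p, mean, sd), lo), hi)
}

# Draw one participant-parameter table from a population_spec.  Truncation
# keeps every draw inside the ddm_params box (and T0 + Tl >= 0).
.draw_population <- function(n, population) {
  mu <- population$mean
  sg <- population$sd
  box <- list(v_base = c(-8, 8), v_s = c(-8, 8), v_so = c(-8, 8),
              v_sl = c(-8, 8), v_sol = c(-8, 8), a = c(0.1, 5),
              w = c(0.05, 0.95), T0 = c(0.01, 1), Tl = c(-0.5, 0.5))
  draws <- lapply(names(mu), function(nm) {
    .rtruncnorm(n, mu[[nm]], sg[[nm]], box[[nm]][1], box[[nm]][2])
  })
  names(draws) <- names(mu)
  d <- as.data.frame(draws)
  d$Tl <- pmax(d$Tl, -d$T0)  # keep valid-label non-decision time >= 0
  d
}

#' Simulate a full behavioral dataset with known parameters
#'
#' Draws per-participant true parameters from a [population_spec()],
#' expands the balanced design of a [design_spec()], and simulates every
#' trial from the diffusion process.  Returns both the trial table and the
#' ground-truth parameter table so that downstream fits can be scored.
#'
#' @param design A [design_spec()].
#' @param population A [population_spec()]; its variant must match the
#'   study arm (control arm with a control-variant population).
#' @param dt Euler step size (s) passed to [simulate_trials()].
#'
#' @return A list with elements `trials` (trial data frame in the
#'   [read_trials()] dialect) and `truth` (one row of true parameters per
#'   participant).
#' @export
simulate_dataset <- function(design, population, dt = 1e-4) {
  stopifnot(inherits(design, "design_spec"),
            inherits(population, "population_spec"))
  is_control <- design$study == "control"
  if (is_control != (population$variant == "control")) {
    stop("population variant must match the study arm", call. = FALSE)
  }
  skeleton <- generate_design(design)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(population$seed)
  truth <- .draw_population(design$n_participants, population)
  truth <- cbind(participant_id = unique(skeleton$participant_id),
                 study = design$study, truth, stringsAsFactors = FALSE)
  # per-trial effective parameters, then one vectorized simulation pass
  idx <- match(skeleton$participant_id, truth$participant_id)
  S <- skeleton$side
  O <- skeleton$orientation
  L <- if (is_control) 0 else skeleton$label
  v <- truth$v_base[idx] + truth$v_s[idx] * S + truth$v_so[idx] * S * O +
    truth$v_sl[idx] * S * L + truth$v_sol[idx] * S * O * L
  Ter <- truth$T0[idx] + truth$Tl[idx] * L
  sim <- simulate_trials(nrow(skeleton), v = v, a = truth$a[idx],
                         w = truth$w[idx], Ter = Ter,
                         deadline = design$deadline, dt = dt)
  trials <- cbind(skeleton, sim)
  if (mean(!trials$responded) > 0.5) {
    warning("more than half of the simulated trials hit the deadline",
            call. = FALSE)
  }
  list(trials = trials, truth = truth)
}

#' Sample response times from the analytic first-passage distribution
#'
#' Inverse-CDF sampling from the Wiener first-passage-time distribution:
#' the boundary is drawn from [choice_probability()] and the decision time
#' from the boundary-conditional CDF tabulated by [wfpt_cdf_fun()].  Used
#' by the quantile diagnostics, where large model-predicted samples are
#' needed cheaply; the Euler path simulator of [simulate_trials()] is the
#' process-level reference.
#'
#' @param n Number of draws.
#' @param spec A [diffusion_spec()] (scalar fields).
#' @param Ter Non-decision time added to each draw (s).
#' @param t_max Upper bound of the tabulated CDF (s).
#' @return A data frame with columns `choice`, `rt_s`, `responded`.
#' @export
sample_rts <- function(n, spec, Ter = 0, t_max = 20) {
  stopifnot(inherits(spec, "diffusion_spec"))
  p_up <- choice_probability(spec)
  upper <- stats::runif(n) < p_up
  rt <- numeric(n)
  grid <- seq(1e-5, t_max, length.out = 20001L)
  for (side in c("lower", "upper")) {
    sel <- if (side == "upper") upper else !upper
    if (!any(sel)) next
    cdf <- wfpt_cdf_fun(spec, boundary = side, t_max = t_max)
    vals <- cdf(grid)
    tot <- vals[length(vals)]
    u <- stats::runif(sum(sel), 0, tot)
    rt[sel] <- stats::approx(vals, grid, xout = u, ties = "ordered",
                             rule = 2)$y
  }
  data.frame(choice = ifelse(upper, "right", "left"), rt_s = rt + Ter,
             responded = TRUE, stringsAsFactors = FALSE)
}
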