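#' Options for maximum-likelihood fitting
#'
#' Controls the multi-start bounded optimization used by
#' [fit_participant()].  Box bounds follow standard practice for this
#' model class: drift coefficients in `[-8, 8]`, boundary separation in
#' `[0.1, 5]`, relative start in `[0.05, 0.95]`, baseline non-decision
#' time in `[0, min observed RT]` (the density has no support at
#' `rt <= Ter`), and the valid-label non-decision shift in `[-0.5, 0.5]`
#' with `T0 + Tl >= 0` enforced by penalty.
#'
#' @param n_starts Number of optimizer starts (>= 1).  The first start is a
#'   fixed neutral point; the rest are drawn uniformly inside the box from
#'   a nested, participant-keyed seed stream, so increasing `n_starts`
#'   extends rather than reshuffles the start set.
#' @param seed Base integer seed; each participant's start stream is
#'   derived from it and from a hash of the participant id, so batch fits
#'   and single fits agree and participant order is irrelevant.
#' @param tol Relative convergence tolerance passed to `optim`'s
#'   `"L-BFGS-B"` method (as `factr = tol / .Machine$double.eps`).
#' @param drift_bound Half-width of the symmetric drift-coefficient box.
#' @param a_bounds,w_bounds,Tl_bounds Two-element numeric bounds.
#' @param cfg A [wfpt_config()] used in the likelihood.
#'
#' @return An object of class `"fit_options"`.
#' @export
fit_options <- function(n_starts = 10L, seed = 1L, tol = 1e-8,
                        drift_bound = 8, a_bounds = c(0.1, 5),
                        w_bounds = c(0.05, 0.95), Tl_bounds = c(-0.5, 0.5),
                        cfg = wfpt_config()) {
  n_starts <- as.integer(n_starts)
  if (n_starts < 1L) stop("`n_starts` must be >= 1", call. = FALSE)
  for (b in list(a_bounds, w_bounds, Tl_bounds)) {
    if (length(b) != 2L || b[1] >= b[2]) {
      stop("bounds must be increasing pairs", call. = FALSE)
    }
  }
  structure(list(n_starts = n_starts, seed = as.integer(seed), tol = tol,
                 drift_bound = drift_bound, a_bounds = a_bounds,
                 w_bounds = w_bounds, Tl_bounds = Tl_bounds, cfg = cfg),
            class = "fit_options")
}

# Stable 31-bit seed derived from the base seed and a participant id, so
# per-participant RNG streams do not depend on fitting order.
.participant_seed <- function(seed, id) {
  h <- 0
  for (k in utf8ToInt(as.character(id))) h <- (h * 131 + k) %% 1982765321
  as.integer((abs(seed) * 7919 + h) %% 2147483629)
}

.param_bounds <- function(variant, opts, min_rt) {
  db <- opts$drift_bound
  if (variant == "labels") {
    list(lower = c(v_base = -db, v_s = -db, v_so = -db, v_sl = -db,
                   v_sol = -db, a = opts$a_bounds[1], w = opts$w_bounds[1],
                   T0 = 0, Tl = opts$Tl_bounds[1]),
         upper = c(v_base = db, v_s = db, v_so = db, v_sl = db, v_sol = db,
                   a = opts$a_bounds[2], w = opts$w_bounds[2],
                   T0 = min_rt, Tl = opts$Tl_bounds[2]))
  } else {
    list(lower = c(v_base = -db, v_s = -db, v_so = -db,
                   a = opts$a_bounds[1], w = opts$w_bounds[1], T0 = 0),
         upper = c(v_base = db, v_s = db, v_so = db, a = opts$a_bounds[2],
                   w = opts$w_bounds[2], T0 = min_rt))
  }
}

# Negative total log-likelihood and its analytic gradient for one
# participant.  Returns list(fn, gr) sharing the precomputed design.
.make_objective <- function(trials, variant, cfg) {
  rt <- trials$rt_s
  upper <- trials$choice == "right"
  sgn <- ifelse(upper, -1, 1)  # boundary reflection flips v and w
  S <- trials$side
  O <- trials$orientation
  if (variant == "labels") {
    L <- trials$label
    Xv <- cbind(1, S, S * O, S * L, S * O * L)
  } else {
    L <- rep(0, length(S))
    Xv <- cbind(1, S, S * O)
  }
  k <- ncol(Xv)
  n <- length(rt)
  log_floor <- log(cfg$density_floor)
  labels <- variant == "labels"

  fn <- function(th) {
    v <- drop(Xv %*% th[seq_len(k)])
    a <- th[k + 1L]
    w <- th[k + 2L]
    T0 <- th[k + 3L]
    Tl <- if (labels) th[k + 4L] else 0
    pen <- if (T0 + Tl < 0) 1e5 * (-(T0 + Tl)) else 0
    Ter <- T0 + Tl * L
    -sum(.loglik_core(rt, upper, v, a, w, Ter, cfg)) + pen
  }

  gr <- function(th) {
    v <- drop(Xv %*% th[seq_len(k)])
    a <- th[k + 1L]
    w <- th[k + 2L]
    T0 <- th[k + 3L]
    Tl <- if (labels) th[k + 4L] else 0
    Ter <- T0 + Tl * L
    t <- rt - Ter
    vv <- sgn * v
    ww <- ifelse(upper, 1 - w, w)
    act <- t > cfg$t_floor
    g_v <- g_a <- g_w <- g_t <- numeric(n)
    if (any(act)) {
      lg <- .wfpt_loggrad(t[act], vv[act], a, ww[act], err = cfg$err)
      live <- lg$logf > log_floor  # floored trials are locally flat
      sa <- sgn[act]
      g_v[act] <- ifelse(live, lg$dv * sa, 0)
      g_a[act] <- ifelse(live, lg$da, 0)
      g_w[act] <- ifelse(live, lg$dw * sa, 0)
      g_t[act] <- ifelse(live, lg$dt, 0)
    }
    g <- numeric(length(th))
    g[seq_len(k)] <- -drop(crossprod(Xv, g_v))
    g[k + 1L] <- -sum(g_a)
    g[k + 2L] <- -sum(g_w)
    g[k + 3L] <- sum(g_t)            # d t / d T0 = -1
    if (labels) g[k + 4L] <- sum(g_t * L)
    if (T0 + Tl < 0) {
      g[k + 3L] <- g[k + 3L] - 1e5
      if (labels) g[k + 4L] <- g[k + 4L] - 1e5
    }
    g
  }

  list(fn = fn, gr = gr)
}

.neutral_start <- function(variant, bounds, min_rt) {
  st <- c(v_base = 0, v_s = 1, v_so = 0, v_sl = 0, v_sol = 0, a = 1,
          w = 0.5, T0 = 0.5 * min_rt, Tl = 0)
  st <- st[names(bounds$lower)]
  pmin(pmax(st, bounds$lower), bounds$upper)
}

#' Fit the diffusion model to one participant by maximum likelihood
#'
#' Minimizes the negative total log-likelihood of all responded trials
#' (the sum of [trial_loglik()] over trials) with bounded `"L-BFGS-B"`
#' optimization from `opts$n_starts` start points, returning the best
#' local optimum.  Deterministic given the trials and `opts$seed`.
#'
#' @param trials Trial data frame for a single participant (one study).
#'   Non-responses are dropped before fitting; at least 20 responded
#'   trials are required.
#' @param variant `"labels"` or `"control"`; defaults to the variant
#'   implied by the `study` column.
#' @param opts A [fit_options()].
#'
#' @return An object of class `"fit_result"`: a list with `params`
#'   ([ddm_params()]), `loglik`, `n_trials`, `converged`, `n_starts_used`,
#'   `best_start` (index of the winning start).
#' @export
fit_participant <- function(trials, variant = NULL, opts = fit_options()) {
  .validate_trials(trials)
  if (length(unique(trials$participant_id)) != 1L) {
    stop("`trials` must contain exactly one participant", call. = FALSE)
  }
  if (length(unique(trials$study)) != 1L) {
    stop("`trials` must come from a single study arm", call. = FALSE)
  }
  if (is.null(variant)) {
    variant <- if (trials$study[1] == "control") "control" else "labels"
  }
  variant <- match.arg(variant, c("labels", "control"))
  if ((trials$study[1] == "control") != (variant == "control")) {
    stop("variant does not match the study arm of the trials", call. = FALSE)
  }
  trials <- trials[trials$responded, , drop = FALSE]
  if (nrow(trials) < 20L) {
    stop("need at least 20 responded trials to fit a participant",
         call. = FALSE)
  }
  # canonical trial order: floating-point likelihood sums, and hence the
  # optimizer path, become exactly invariant to input row permutations
  trials <- trials[order(trials$rt_s, trials$side, trials$orientation,
                         trials$choice), , drop = FALSE]
  # The density has support only at rt > Ter.  Ter on invalid-label (and
  # control) trials is T0 itself, so the fastest such trial bounds T0;
  # valid-label trials bound T0 + Tl instead and are handled by the
  # density floor.
  min_rt <- if (variant == "labels" && any(trials$label == 0)) {
    min(trials$rt_s[trials$label == 0])
  } else {
    min(trials$rt_s)
  }
  bounds <- .param_bounds(variant, opts, min_rt)
  obj <- .make_objective(trials, variant, opts$cfg)
  pseed <- .participant_seed(opts$seed, trials$participant_id[1])

  starts <- vector("list", opts$n_starts)
  starts[[1]] <- .neutral_start(variant, bounds, min_rt)
  if (opts$n_starts > 1L) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    npar <- length(bounds$lower)
    for (j in 2:opts$n_starts) {
      set.seed((pseed + 977L * j) %% 2147483629)
      u <- stats::runif(npar, 0.1, 0.9)
      starts[[j]] <- bounds$lower + u * (bounds$upper - bounds$lower)
    }
  }

  best <- NULL
  converged <- FALSE
  best_start <- NA_integer_
  factr <- max(10, opts$tol / .Machine$double.eps)
  for (j in seq_along(starts)) {
    fit <- tryCatch(
      stats::optim(starts[[j]], obj$fn, obj$gr, method = "L-BFGS-B",
                   lower = bounds$lower, upper = bounds$upper,
                   control = list(factr = factr, maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best_start <- j
    }
    if (fit$convergence == 0L) converged <- TRUE
  }
  if (is.null(best)) {
    stop("all optimizer starts failed for participant ",
         trials$participant_id[1], call. = FALSE)
  }
  th <- best$par
  params <- if (variant == "labels") {
    ddm_params(v_base = th[["v_base"]], v_s = th[["v_s"]], v_so = th[["v_so"]],
               v_sl = th[["v_sl"]], v_sol = th[["v_sol"]], a = th[["a"]],
               w = th[["w"]], T0 = th[["T0"]],
               Tl = max(th[["Tl"]], -th[["T0"]]), variant = "labels")
  } else {
    ddm_params(v_base = th[["v_base"]], v_s = th[["v_s"]], v_so = th[["v_so"]],
               a = th[["a"]], w = th[["w"]], T0 = th[["T0"]],
               variant = "control")
  }
  structure(list(params = params, loglik = -best$value,
                 n_trials = nrow(trials), converged = converged,
                 n_starts_used = opts$n_starts, best_start = best_start,
                 participant_id = trials$participant_id[1],
                 study = trials$study[1]),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> participant %s (%s, %s variant)\n",
              x$participant_id, x$study, x$params$variant))
  cat(sprintf("  log-likelihood %.3f over %d trials (converged: %s)\n",
              x$loglik, x$n_trials, x$converged))
  est <- unlist(x$params[free_param_names(x$params$variant)])
  cat("  ", paste(sprintf("%s=%.3f", names(est), est), collapse = " "), "\n")
  invisible(x)
}

#' Fit every participant in a dataset
#'
#' Applies [fit_participant()] to each participant, inferring the model
#' variant from the study arm.  Participants whose fit fails are reported
#' and dropped.  Rows are ordered by study then participant id, so the
#' result does not depend on the input row order.
#'
#' @param trials Trial data frame covering one or more participants.
#' @param opts A [fit_options()].
#'
#' @return A data frame with one row per participant: `participant_id`,
#'   `study`, `variant`, the nine parameter columns (structural zeros for
#'   the control variant), `loglik`, `n_trials`, `converged`.
#' @export
fit_dataset <- function(trials, opts = fit_options()) {
  .validate_trials(trials)
  if (nrow(trials) == 0L) stop("empty trial table", call. = FALSE)
  ids <- unique(trials[, c("participant_id", "study")])
  ids <- ids[order(ids$study, ids$participant_id), , drop = FALSE]
  rows <- vector("list", nrow(ids))
  failed <- character(0)
  for (i in seq_len(nrow(ids))) {
    sub <- trials[trials$participant_id == ids$participant_id[i] &
                    trials$study == ids$study[i], , drop = FALSE]
    fr <- tryCatch(fit_participant(sub, opts = opts), error = function(e) e)
    if (inherits(fr, "error")) {
      failed <- c(failed, sprintf("%s: %s", ids$participant_id[i],
                                  conditionMessage(fr)))
      next
    }
    p <- fr$params
    rows[[i]] <- data.frame(
      participant_id = fr$participant_id, study = fr$study,
      variant = p$variant, v_base = p$v_base, v_s = p$v_s, v_so = p$v_so,
      v_sl = p$v_sl, v_sol = p$v_sol, a = p$a, w = p$w, T0 = p$T0,
      Tl = p$Tl, loglik = fr$loglik, n_trials = fr$n_trials,
      converged = fr$converged, stringsAsFactors = FALSE)
  }
  if (length(failed)) {
    warning(sprintf("%d participant(s) failed to fit:\n  %s", length(failed),
                    paste(failed, collapse = "\n  ")), call. = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no participant could be fitted", call. = FALSE)
  rownames(out) <- NULL
  out
}
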