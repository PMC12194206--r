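#' Condition-dependent diffusion parameters
#'
#' Free parameters of the condition-dependent drift diffusion model.  The
#' drift on a trial is a linear function of the side code `S` (+1 familiar
#' configuration on the right, -1 left), the orientation code `O` (1 upright,
#' 0 inverted) and, in the labels variant, the label-validity code `L`
#' (1 valid, 0 invalid):
#'
#' \deqn{v = v_{base} + v_s S + v_{so} S O + v_{sl} S L + v_{sol} S O L}
#'
#' and the non-decision time is `Ter = T0 + Tl * L`.  Boundary separation
#' `a` and relative start `w = z / a` are constant within a participant:
#' both are set before the stimulus (and any label information) can act.
#' The control variant, for label-absent experiments, fixes
#' `v_sl = v_sol = Tl = 0`, leaving 6 free parameters; the labels variant
#' has 9.
#'
#' @param v_base Baseline drift bias (a left/right drift bias independent of
#'   the stimulus).
#' @param v_s Main effect of side on drift: drift toward the familiar
#'   configuration.
#' @param v_so Side-by-orientation effect: extra drift toward the familiar
#'   configuration when the display is upright.
#' @param v_sl Side-by-label effect: extra drift toward the familiar
#'   configuration following a valid label.
#' @param v_sol Side-by-orientation-by-label effect: extra drift when a
#'   valid label precedes an upright display.
#' @param a Boundary separation, > 0.
#' @param w Relative start point `z / a` in (0, 1); `w - 0.5` is the
#'   rightward start bias.
#' @param T0 Baseline non-decision time (s), >= 0.
#' @param Tl Change in non-decision time on valid-label trials (s);
#'   `T0 + Tl` must be >= 0.
#' @param variant `"labels"` or `"control"`.
#'
#' @return An object of class `"ddm_params"`.
#' @examples
#' ddm_params(v_s = 0.8, v_so = 0.2, a = 0.78, w = 0.52, T0 = 0.38,
#'            variant = "control")
#' @export
ddm_params <- function(v_base = 0, v_s = 0, v_so = 0, v_sl = 0, v_sol = 0,
                       a = 1, w = 0.5, T0 = 0.3, Tl = 0,
                       variant = c("labels", "control")) {
  variant <- match.arg(variant)
  if (variant == "control" && (v_sl != 0 || v_sol != 0 || Tl != 0)) {
    stop("control variant fixes v_sl, v_sol and Tl at 0", call. = FALSE)
  }
  for (nm in c("v_base", "v_s", "v_so", "v_sl", "v_sol", "a", "w", "T0", "Tl")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  if (a <= 0) stop("`a` must be > 0", call. = FALSE)
  if (w <= 0 || w >= 1) stop("`w` must lie strictly in (0, 1)", call. = FALSE)
  if (T0 < 0) stop("`T0` must be >= 0", call. = FALSE)
  if (T0 + Tl < 0) stop("`T0 + Tl` must be >= 0", call. = FALSE)
  structure(list(v_base = v_base, v_s = v_s, v_so = v_so, v_sl = v_sl,
                 v_sol = v_sol, a = a, w = w, T0 = T0, Tl = Tl,
                 variant = variant),
            class = "ddm_params")
}

#' Names of the free parameters of a model variant
#'
#' @param variant `"labels"` (9 free parameters) or `"control"` (6).
#' @return Character vector of parameter names.
#' @export
free_param_names <- function(variant = c("labels", "control")) {
  variant <- match.arg(variant)
  if (variant == "labels") {
    c("v_base", "v_s", "v_so", "v_sl", "v_sol", "a", "w", "T0", "Tl")
  } else {
    c("v_base", "v_s", "v_so", "a", "w", "T0")
  }
}

.check_codes <- function(S, O, L) {
  if (!all(S %in% c(-1, 1))) stop("side code `S` must be -1 or +1", call. = FALSE)
  if (!all(O %in% c(0, 1))) stop("orientation code `O` must be 0 or 1", call. = FALSE)
  if (!is.null(L) && !all(L %in% c(0, 1))) {
    stop("label code `L` must be 0 or 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Effective diffusion parameters for a trial
#'
#' Applies the drift and non-decision-time linear models of [ddm_params()]
#' to condition covariates, yielding the `(v, a, w, Ter)` that govern a
#' single trial.  `S`, `O` and `L` may be vectors (recycled).
#'
#' @param params A [ddm_params()].
#' @param S Side code, -1 (familiar configuration left) or +1 (right).
#' @param O Orientation code, 0 (inverted) or 1 (upright).
#' @param L Label-validity code, 0 (invalid) or 1 (valid); must be `NULL`
#'   for the control variant and supplied for the labels variant.
#'
#' @return A list with vector fields `v`, `a`, `w`, `Ter`.
#' @examples
#' p <- ddm_params(v_base = 0.1, v_s = 0.9, v_so = 0.35, v_sl = 0.6,
#'                 v_sol = 0.25, a = 0.8, w = 0.52, T0 = 0.35, Tl = -0.03)
#' effective_params(p, S = 1, O = 1, L = 1)$v  # 0.1 + 0.9 + 0.35 + 0.6 + 0.25
#' @export
effective_params <- function(params, S, O, L = NULL) {
  stopifnot(inherits(params, "ddm_params"))
  if (params$variant == "control" && !is.null(L)) {
    stop("label code supplied for a control-variant model", call. = FALSE)
  }
  if (params$variant == "labels" && is.null(L)) {
    stop("labels-variant model requires a label code", call. = FALSE)
  }
  .check_codes(S, O, L)
  n <- max(length(S), length(O), length(L), 1L)
  S <- rep_len(S, n)
  O <- rep_len(O, n)
  L <- if (is.null(L)) rep_len(0, n) else rep_len(L, n)
  v <- params$v_base + params$v_s * S + params$v_so * S * O +
    params$v_sl * S * L + params$v_sol * S * O * L
  Ter <- params$T0 + params$Tl * L
  list(v = v, a = rep_len(params$a, n), w = rep_len(params$w, n), Ter = Ter)
}

#' Per-trial log-likelihood
#'
#' Log first-passage-time density of each responded trial's choice and
#' response time under a [ddm_params()] model.  The decision time is
#' `rt_s - Ter`; the density is evaluated at the boundary matching the
#' choice (upper = "right", lower = "left") and floored at
#' `cfg$density_floor` before the log, so trials whose response time falls
#' at or below the non-decision time contribute `log(density_floor)` rather
#' than `-Inf`.
#'
#' @param trials Trial data frame (see [read_trials()] for the dialect);
#'   all rows must be responded trials.
#' @param params A [ddm_params()] of the variant matching the trials
#'   (control study rows carry no label; labels-study rows must).
#' @param cfg A [wfpt_config()].
#'
#' @return Numeric vector of per-trial log-likelihoods (nats).
#' @export
trial_loglik <- function(trials, params, cfg = wfpt_config()) {
  stopifnot(inherits(params, "ddm_params"))
  .validate_trials(trials)
  if (any(!trials$responded)) {
    stop("all trials must be responded; drop non-responses first",
         call. = FALSE)
  }
  L <- if (params$variant == "labels") trials$label else NULL
  ep <- effective_params(params, trials$side, trials$orientation, L)
  .loglik_core(trials$rt_s, trials$choice == "right", ep$v, params$a,
               params$w, ep$Ter, cfg)
}

# Shared likelihood kernel: log density at the chosen boundary, with the
# time floor and density floor applied.
.loglik_core <- function(rt, upper, v, a, w, Ter, cfg) {
  t <- rt - Ter
  vv <- ifelse(upper, -v, v)
  ww <- ifelse(upper, 1 - w, w)
  d <- rep(cfg$density_floor, length(rt))
  ok <- t > cfg$t_floor
  if (any(ok)) {
    d[ok] <- pmax(.wfpt_lower(t[ok], vv[ok], a, ww[ok], err = cfg$err),
                  cfg$density_floor)
  }
  log(d)
}

#' Model-predicted accuracy and mean response time for a condition
#'
#' Closed-form prediction for one design cell: the probability that the
#' diffusion absorbs at the boundary on the familiar-configuration side
#' (the "correct" response under the scoring rule), and the mean response
#' time `E[DT] + Ter` pooled over correct and error responses.
#'
#' @inheritParams effective_params
#' @return A list with fields `p_correct` and `mean_rt` (vectors, recycled
#'   over `S`, `O`, `L`).
#' @export
predicted_condition_summary <- function(params, S, O, L = NULL) {
  ep <- effective_params(params, S, O, L)
  n <- length(ep$v)
  S <- rep_len(S, n)
  p_up <- .p_upper(ep$v, ep$a, ep$w)
  p_correct <- ifelse(S > 0, p_up, 1 - p_up)
  spec <- diffusion_spec(ep$v, ep$a, ep$w)
  mean_rt <- mean_decision_time(spec) + ep$Ter
  list(p_correct = p_correct, mean_rt = mean_rt)
}
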