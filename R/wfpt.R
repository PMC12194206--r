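#' Diffusion process specification
#'
#' Bundles the parameters of a single Wiener diffusion process between two
#' absorbing boundaries: boundaries at 0 and `a`, start point `z = w * a`,
#' drift `v`, and within-trial noise fixed at `s = 1` so that the drift rate
#' is interpretable as a signal-to-noise ratio.
#'
#' @param v Drift rate (evidence/s, signed; positive drifts favor the upper
#'   boundary).
#' @param a Boundary separation (evidence units), strictly positive.
#' @param w Relative start point `z / a`, strictly inside (0, 1).
#'
#' @return An object of class `"diffusion_spec"`: a list with elements
#'   `v`, `a`, `w` and `s` (always 1).
#' @examples
#' spec <- diffusion_spec(v = 1, a = 1.5, w = 0.5)
#' choice_probability(spec)
#' @export
diffusion_spec <- function(v, a, w) {
  if (!is.numeric(v) || !all(is.finite(v))) {
    stop("drift rate `v` must be finite numeric", call. = FALSE)
  }
  if (!is.numeric(a) || !all(is.finite(a)) || any(a <= 0)) {
    stop("boundary separation `a` must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(w) || !all(is.finite(w)) || any(w <= 0 | w >= 1)) {
    stop("relative start `w` must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(v = v, a = a, w = w, s = 1), class = "diffusion_spec")
}

#' Precision controls for first-passage-time evaluation
#'
#' @param err Absolute truncation tolerance for the series expansions.
#' @param t_floor Smallest decision time evaluated (s); decision times at or
#'   below the floor are assigned `density_floor`.
#' @param density_floor Likelihood floor applied before taking logs, keeping
#'   the optimizer finite on trials whose response time is at or below the
#'   fitted non-decision time.
#'
#' @return An object of class `"wfpt_config"`.
#' @export
wfpt_config <- function(err = 1e-7, t_floor = 1e-5, density_floor = 1e-10) {
  if (!is.numeric(err) || length(err) != 1L || err <= 0 || err >= 1e-3) {
    stop("`err` must be a single value in (0, 1e-3)", call. = FALSE)
  }
  if (!is.numeric(t_floor) || length(t_floor) != 1L || t_floor <= 0) {
    stop("`t_floor` must be a single positive value", call. = FALSE)
  }
  if (!is.numeric(density_floor) || length(density_floor) != 1L ||
      density_floor <= 0) {
    stop("`density_floor` must be a single positive value", call. = FALSE)
  }
  structure(list(err = err, t_floor = t_floor, density_floor = density_floor),
            class = "wfpt_config")
}

# Zero-drift, unit-boundary first-passage density at the lower boundary,
# evaluated at normalized time tau = t / a^2 with relative start w.
# Per element, whichever of the small-time and large-time series needs
# fewer terms for absolute tolerance `err` is used; `branch` forces one
# series (used by the branch-agreement tests).
.wfpt_f0 <- function(tau, w, err, branch = c("auto", "small", "large")) {
  branch <- match.arg(branch)
  n <- max(length(tau), length(w))
  tau <- rep_len(tau, n)
  w <- rep_len(w, n)
  out <- numeric(n)

  # term counts needed by each series
  ks <- rep(2, n)
  idx <- 2 * sqrt(2 * pi * tau) * err < 1
  ks[idx] <- pmax(2 + sqrt(-2 * tau[idx] * log(2 * sqrt(2 * pi * tau[idx]) * err)),
                  sqrt(tau[idx]) + 1)
  kl <- 1 / (pi * sqrt(tau))
  idx <- pi * tau * err < 1
  kl[idx] <- pmax(sqrt(-2 * log(pi * tau[idx] * err) / (pi^2 * tau[idx])),
                  1 / (pi * sqrt(tau[idx])))

  use_small <- switch(branch,
                      auto  = ks < kl,
                      small = rep(TRUE, n),
                      large = rep(FALSE, n))

  if (any(use_small)) {
    ts <- tau[use_small]
    ws <- w[use_small]
    K <- ceiling(max(ks[use_small]))
    kk <- seq.int(-floor((K - 1) / 2), ceiling((K - 1) / 2))
    wk <- outer(ws, 2 * kk, "+")
    out[use_small] <- rowSums(wk * exp(-wk^2 / (2 * ts))) / sqrt(2 * pi * ts^3)
  }
  if (any(!use_small)) {
    tl <- tau[!use_small]
    wl <- w[!use_small]
    K <- ceiling(max(kl[!use_small]))
    kk <- seq_len(max(K, 1L))
    terms <- outer(tl, kk, function(t, k) k * exp(-k^2 * pi^2 * t / 2)) *
      sin(outer(wl, pi * kk))
    out[!use_small] <- pi * rowSums(terms)
  }
  pmax(out, 0)
}

# Derivatives of the zero-drift unit-boundary density with respect to
# normalized time tau and start w, using the same per-element branch rule
# as .wfpt_f0.  Returns list(f0, dtau, dw).
.wfpt_f0_grad <- function(tau, w, err) {
  n <- max(length(tau), length(w))
  tau <- rep_len(tau, n)
  w <- rep_len(w, n)
  f0 <- numeric(n)
  dtau <- numeric(n)
  dw <- numeric(n)

  ks <- rep(2, n)
  idx <- 2 * sqrt(2 * pi * tau) * err < 1
  ks[idx] <- pmax(2 + sqrt(-2 * tau[idx] * log(2 * sqrt(2 * pi * tau[idx]) * err)),
                  sqrt(tau[idx]) + 1)
  kl <- 1 / (pi * sqrt(tau))
  idx <- pi * tau * err < 1
  kl[idx] <- pmax(sqrt(-2 * log(pi * tau[idx] * err) / (pi^2 * tau[idx])),
                  1 / (pi * sqrt(tau[idx])))
  use_small <- ks < kl

  if (any(use_small)) {
    ts <- tau[use_small]
    ws <- w[use_small]
    K <- ceiling(max(ks[use_small])) + 2L
    kk <- seq.int(-floor((K - 1) / 2), ceiling((K - 1) / 2))
    b <- outer(ws, 2 * kk, "+")
    e <- exp(-b^2 / (2 * ts))
    pre <- 1 / sqrt(2 * pi * ts^3)
    s0 <- rowSums(b * e)
    f0[use_small] <- pre * s0
    dtau[use_small] <- pre * (rowSums(b^3 * e) / (2 * ts^2) - 1.5 * s0 / ts)
    dw[use_small] <- pre * rowSums(e * (1 - b^2 / ts))
  }
  if (any(!use_small)) {
    tl <- tau[!use_small]
    wl <- w[!use_small]
    K <- max(ceiling(max(kl[!use_small])), 1L) + 2L
    kk <- seq_len(K)
    E <- outer(tl, kk, function(t, k) exp(-k^2 * pi^2 * t / 2))
    sinm <- sin(outer(wl, pi * kk))
    cosm <- cos(outer(wl, pi * kk))
    kmat <- matrix(kk, nrow = length(tl), ncol = K, byrow = TRUE)
    f0[!use_small] <- pi * rowSums(kmat * E * sinm)
    dtau[!use_small] <- -pi^3 / 2 * rowSums(kmat^3 * E * sinm)
    dw[!use_small] <- pi^2 * rowSums(kmat^2 * E * cosm)
  }
  list(f0 = f0, dtau = dtau, dw = dw)
}

# Log lower-boundary density and its partial derivatives with respect to
# v, a, w and decision time t, elementwise.  Elements with t <= 0 or a
# non-positive series value return logf = -Inf and zero derivatives.
.wfpt_loggrad <- function(t, v, a, w, err = 1e-7) {
  n <- max(length(t), length(v), length(a), length(w))
  t <- rep_len(t, n)
  v <- rep_len(v, n)
  a <- rep_len(a, n)
  w <- rep_len(w, n)
  tau <- t / a^2
  g <- .wfpt_f0_grad(tau, w, err)
  ok <- g$f0 > 0
  logf <- rep(-Inf, n)
  dv <- da <- dw <- dt_ <- numeric(n)
  if (any(ok)) {
    f0 <- g$f0[ok]
    rt_tau <- g$dtau[ok] / f0
    rw <- g$dw[ok] / f0
    logf[ok] <- log(f0) - 2 * log(a[ok]) - v[ok] * a[ok] * w[ok] -
      v[ok]^2 * t[ok] / 2
    dv[ok] <- -a[ok] * w[ok] - v[ok] * t[ok]
    da[ok] <- rt_tau * (-2 * t[ok] / a[ok]^3) - 2 / a[ok] - v[ok] * w[ok]
    dw[ok] <- rw - v[ok] * a[ok]
    dt_[ok] <- rt_tau / a[ok]^2 - v[ok]^2 / 2
  }
  list(logf = logf, dv = dv, da = da, dw = dw, dt = dt_)
}

# Elementwise lower-boundary first-passage density for drift v, separation a,
# relative start w, at decision time t > 0.  All arguments recycle.
.wfpt_lower <- function(t, v, a, w, err = 1e-7, branch = "auto") {
  n <- max(length(t), length(v), length(a), length(w))
  t <- rep_len(t, n)
  v <- rep_len(v, n)
  a <- rep_len(a, n)
  w <- rep_len(w, n)
  tau <- t / a^2
  f0 <- .wfpt_f0(tau, w, err, branch = branch)
  pmax(f0 / a^2 * exp(-v * a * w - v^2 * t / 2), 0)
}

#' Wiener first-passage-time density
#'
#' Density of the time at which the diffusion of [diffusion_spec()] is
#' absorbed at the requested boundary, evaluated by the small-time /
#' large-time series pair with the branch chosen per call to need the fewer
#' terms at tolerance `cfg$err`.  The upper-boundary density is obtained
#' from the lower-boundary form by the reflection `w -> 1 - w`, `v -> -v`.
#'
#' The two boundary densities are sub-densities: each integrates to the
#' probability of absorbing at its boundary, and together they integrate
#' to 1.
#'
#' @param t Decision time(s) in seconds, strictly positive.
#' @param spec A [diffusion_spec()].
#' @param boundary `"lower"` or `"upper"`.
#' @param cfg A [wfpt_config()].
#'
#' @return Non-negative density values (1/s), recycled over `t` and the
#'   fields of `spec`.
#' @examples
#' spec <- diffusion_spec(v = 1, a = 1.5, w = 0.5)
#' wfpt_density(c(0.1, 0.5, 1), spec, boundary = "upper")
#' @export
wfpt_density <- function(t, spec, boundary = c("lower", "upper"),
                         cfg = wfpt_config()) {
  boundary <- match.arg(boundary)
  if (!inherits(spec, "diffusion_spec")) spec <- do.call(diffusion_spec, spec)
  if (!inherits(cfg, "wfpt_config")) stop("`cfg` must be a wfpt_config")
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0)) {
    stop("decision time `t` must be finite and > 0", call. = FALSE)
  }
  if (boundary == "upper") {
    .wfpt_lower(t, -spec$v, spec$a, 1 - spec$w, err = cfg$err)
  } else {
    .wfpt_lower(t, spec$v, spec$a, spec$w, err = cfg$err)
  }
}

# Stable probability of absorbing at the upper boundary, elementwise.
.p_upper <- function(v, a, w) {
  n <- max(length(v), length(a), length(w))
  v <- rep_len(v, n)
  a <- rep_len(a, n)
  w <- rep_len(w, n)
  z <- w * a
  p <- w  # zero-drift limit z / a
  idx <- abs(v) * a >= 1e-10
  p[idx] <- expm1(-2 * v[idx] * z[idx]) / expm1(-2 * v[idx] * a[idx])
  pmin(pmax(p, 0), 1)
}

#' Probability of absorbing at the upper boundary
#'
#' Closed form `P(upper) = (1 - exp(-2 v z)) / (1 - exp(-2 v a))` with
#' `z = w * a` and noise `s = 1`; the zero-drift limit `z / a` is used when
#' `|v| * a` is numerically zero.
#'
#' @inheritParams wfpt_density
#' @return Probability in `[0, 1]`, recycled over the fields of `spec`.
#' @export
choice_probability <- function(spec) {
  if (!inherits(spec, "diffusion_spec")) spec <- do.call(diffusion_spec, spec)
  .p_upper(spec$v, spec$a, spec$w)
}

#' Mean decision time, unconditional on boundary
#'
#' Wald-identity closed form `E[DT] = (a P(upper) - z) / v` for nonzero
#' drift and `E[DT] = z (a - z)` at zero drift (noise `s = 1`).
#'
#' @inheritParams wfpt_density
#' @return Expected first-passage time in seconds.
#' @export
mean_decision_time <- function(spec) {
  if (!inherits(spec, "diffusion_spec")) spec <- do.call(diffusion_spec, spec)
  n <- max(length(spec$v), length(spec$a), length(spec$w))
  v <- rep_len(spec$v, n)
  a <- rep_len(spec$a, n)
  w <- rep_len(spec$w, n)
  z <- w * a
  out <- z * (a - z)
  idx <- abs(v) >= 1e-6
  if (any(idx)) {
    p <- .p_upper(v[idx], a[idx], w[idx])
    out[idx] <- (a[idx] * p - z[idx]) / v[idx]
  }
  out
}

#' First-passage-time sub-distribution function (numeric)
#'
#' Builds the cumulative distribution of absorption times at one boundary by
#' trapezoidal integration of [wfpt_density()] on a fine grid, returning an
#' interpolating function.  `F(Inf)` equals the probability of absorbing at
#' that boundary; divide by [choice_probability()] (or its complement) for
#' the boundary-conditional CDF.
#'
#' @inheritParams wfpt_density
#' @param t_max Upper end of the integration grid (s).
#' @param n_grid Number of grid points.
#'
#' @return A vectorized function `F(t)` giving the sub-distribution value.
#' @export
wfpt_cdf_fun <- function(spec, boundary = c("lower", "upper"), t_max = 20,
                         n_grid = 20001L, cfg = wfpt_config()) {
  boundary <- match.arg(boundary)
  tt <- seq(cfg$t_floor, t_max, length.out = n_grid)
  ff <- wfpt_density(tt, spec, boundary = boundary, cfg = cfg)
  cum <- c(0, cumsum((ff[-1] + ff[-n_grid]) / 2 * diff(tt)))
  f_interp <- stats::approxfun(tt, cum, yleft = 0, yright = cum[n_grid])
  function(t) {
    out <- f_interp(t)
    out[t <= 0] <- 0
    out
  }
}
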