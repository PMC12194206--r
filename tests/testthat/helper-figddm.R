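# Independent high-truncation oracle for the lower-boundary first-passage
# density (plain small-time series, no branch switching; K = 50 terms is
# far beyond convergence for the times used in tests).
oracle_wfpt_lower <- function(t, v, a, w, K = 50) {
  vapply(t, function(ti) {
    tau <- ti / a^2
    k <- -K:K
    f0 <- sum((w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * tau))) /
      sqrt(2 * pi * tau^3)
    f0 / a^2 * exp(-v * a * w - v^2 * ti / 2)
  }, numeric(1))
}

# Convert a simulate_dataset() truth table into the fit-table layout, so
# analysis-level tests can run on known parameters without any fitting.
truth_as_fits <- function(truth, variant = "labels") {
  data.frame(participant_id = truth$participant_id, study = truth$study,
             variant = variant, v_base = truth$v_base, v_s = truth$v_s,
             v_so = truth$v_so, v_sl = truth$v_sl, v_sol = truth$v_sol,
             a = truth$a, w = truth$w, T0 = truth$T0, Tl = truth$Tl,
             loglik = NA_real_, n_trials = NA_integer_, converged = TRUE,
             stringsAsFactors = FALSE)
}

# Draw a fit-style parameter table straight from a population (no
# simulation, no fitting); used by group-analysis tests.
draw_fits_table <- function(n, population, study = "study1") {
  set.seed(population$seed)
  sim_truth <- figddm:::.draw_population(n, population)
  digits <- max(3L, nchar(n))
  data.frame(participant_id = sprintf("%s_%0*d", study, digits, seq_len(n)),
             study = study,
             variant = population$variant,
             sim_truth,
             loglik = NA_real_, n_trials = NA_integer_, converged = TRUE,
             stringsAsFactors = FALSE)
}

# Session-level cache for expensive shared fixtures.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
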