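#' Parameter-recovery experiment
#'
#' Simulates a cohort with known per-participant parameters from the
#' balanced study design, fits every simulated participant by maximum
#' likelihood, and scores identifiability: per-parameter correlation
#' between true and fitted values, mean bias (fitted minus true), and
#' RMSE.  Fit failures are counted and reported, not fatal.
#'
#' @param design A [design_spec()].
#' @param population A [population_spec()] matching the design's study arm.
#' @param opts A [fit_options()].
#' @param dt Euler step size for the simulator (s).
#'
#' @return An object of class `"recovery_report"`: a list with
#'   \describe{
#'     \item{report}{data frame, one row per free parameter: `parameter`,
#'       `correlation`, `bias`, `rmse`, `sd_true`, `sd_fitted`.}
#'     \item{scatter}{long data frame of (`participant_id`, `parameter`,
#'       `true`, `fitted`) pairs for plotting.}
#'     \item{n_participants, n_fitted, n_failed}{cohort bookkeeping.}
#'     \item{design, population}{the input specifications.}
#'   }
#' @export
run_recovery <- function(design, population, opts = fit_options(),
                         dt = 1e-4) {
  stopifnot(inherits(design, "design_spec"),
            inherits(population, "population_spec"))
  sim <- simulate_dataset(design, population, dt = dt)
  fits <- withCallingHandlers(
    fit_dataset(sim$trials, opts = opts),
    warning = function(w) {
      message(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  pars <- free_param_names(population$variant)
  merged <- merge(sim$truth, fits, by = "participant_id",
                  suffixes = c(".true", ".fit"))
  rows <- lapply(pars, function(p) {
    tru <- merged[[paste0(p, ".true")]]
    fit <- merged[[paste0(p, ".fit")]]
    data.frame(parameter = p,
               correlation = if (stats::sd(tru) > 0 && stats::sd(fit) > 0) {
                 stats::cor(tru, fit)
               } else NA_real_,
               bias = mean(fit - tru),
               rmse = sqrt(mean((fit - tru)^2)),
               sd_true = stats::sd(tru), sd_fitted = stats::sd(fit),
               stringsAsFactors = FALSE)
  })
  scatter <- do.call(rbind, lapply(pars, function(p) {
    data.frame(participant_id = merged$participant_id, parameter = p,
               true = merged[[paste0(p, ".true")]],
               fitted = merged[[paste0(p, ".fit")]],
               stringsAsFactors = FALSE)
  }))
  structure(list(report = do.call(rbind, rows), scatter = scatter,
                 n_participants = design$n_participants,
                 n_fitted = nrow(fits),
                 n_failed = design$n_participants - nrow(fits),
                 design = design, population = population,
                 seed = c(design = design$seed, population = population$seed,
                          fit = opts$seed)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %s arm, %d participants x %d trials (%d fitted, %d failed)\n",
              x$design$study, x$n_participants,
              x$design$trials_per_participant, x$n_fitted, x$n_failed))
  print(transform(x$report,
                  correlation = round(correlation, 3),
                  bias = round(bias, 3), rmse = round(rmse, 3),
                  sd_true = round(sd_true, 3),
                  sd_fitted = round(sd_fitted, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Write a recovery report to CSV
#'
#' @param x A `recovery_report` from [run_recovery()].
#' @param path Output path for the per-parameter summary.
#' @param scatter_path Optional path for the true-vs-fitted scatter table.
#' @return `path`, invisibly.
#' @export
write_recovery <- function(x, path, scatter_path = NULL) {
  stopifnot(inherits(x, "recovery_report"))
  utils::write.csv(x$report, path, row.names = FALSE)
  if (!is.null(scatter_path)) {
    utils::write.csv(x$scatter, scatter_path, row.names = FALSE)
  }
  invisible(path)
}
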