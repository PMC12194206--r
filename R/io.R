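#' @keywords internal
.trial_columns <- c("participant_id", "study", "side", "orientation",
                    "label", "choice", "rt_s", "responded")

.validate_trials <- function(trials) {
  if (!is.data.frame(trials)) stop("trials must be a data frame", call. = FALSE)
  missing <- setdiff(.trial_columns, names(trials))
  if (length(missing)) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(trials$study %in% c("control", "study1", "study2"))) {
    stop("`study` must be one of control, study1, study2", call. = FALSE)
  }
  if (!all(trials$side %in% c(-1, 1))) {
    stop("`side` must be -1 (left) or +1 (right)", call. = FALSE)
  }
  if (!all(trials$orientation %in% c(0, 1))) {
    stop("`orientation` must be 0 (inverted) or 1 (upright)", call. = FALSE)
  }
  is_control <- trials$study == "control"
  if (any(!is.na(trials$label[is_control]))) {
    stop("control-study trials must not carry a label code", call. = FALSE)
  }
  lab <- trials$label[!is_control]
  if (any(is.na(lab)) || !all(lab %in% c(0, 1))) {
    stop("labels-study trials must carry label codes 0 (invalid) or 1 (valid)",
         call. = FALSE)
  }
  resp <- trials$responded
  if (!is.logical(resp) || any(is.na(resp))) {
    stop("`responded` must be TRUE/FALSE without missing values", call. = FALSE)
  }
  if (any(resp & !(trials$choice %in% c("left", "right")))) {
    stop("`choice` must be \"left\" or \"right\" on responded trials",
         call. = FALSE)
  }
  if (any(resp & (!is.finite(trials$rt_s) | trials$rt_s <= 0))) {
    stop("`rt_s` must be a positive time in seconds on responded trials",
         call. = FALSE)
  }
  invisible(trials)
}

#' Read a trial table
#'
#' Reads the package's trial CSV dialect: header row with columns
#' `participant_id, study, side, orientation, label, choice, rt_s,
#' responded`.  `side` is -1/+1 (familiar-configuration side left/right),
#' `orientation` 0/1 (inverted/upright), `label` 0/1 (invalid/valid, empty
#' for control-study rows), `choice` "left"/"right", `rt_s` the response
#' time in seconds, `responded` TRUE/FALSE (responses later than the
#' deadline are recorded as non-responses).
#'
#' @param path Path to a CSV file.
#' @return A validated trial data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.trial_columns, names(trials))
  if (length(missing)) {
    stop(sprintf("%s is missing required columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  trials$participant_id <- as.character(trials$participant_id)
  trials$responded <- as.logical(trials$responded)
  trials$choice <- as.character(trials$choice)
  for (col in c("side", "orientation", "label", "rt_s")) {
    trials[[col]] <- as.numeric(trials[[col]])
  }
  .validate_trials(trials)
  trials
}

#' Write a trial table
#'
#' Writes the CSV dialect read by [read_trials()].  Response times are
#' written with six decimal digits (microsecond precision) to avoid
#' millisecond/second ambiguity on round trips.
#'
#' @param trials A trial data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  .validate_trials(trials)
  out <- trials[, .trial_columns]
  out$rt_s <- ifelse(is.na(out$rt_s), NA, sprintf("%.6f", out$rt_s))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a per-participant fit table
#'
#' @param fits Fit table from [fit_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a per-participant fit table written by [write_fits()]
#'
#' @param path Path to a CSV file.
#' @return A fit data frame.
#' @export
read_fits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character"))
}
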