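#' Behavioural quality control for one session
#'
#' Applies the three automatic exclusion rules used for the two-step
#' task before any model fitting:
#'
#' 1. *missed*: more than 20 trials with no response within the deadline
#'    (21 misses exclude, 20 do not);
#' 2. *stereotyped_choice1*: either stage-1 option chosen on >= 95% of
#'    non-missed trials (inclusive at exactly 95%);
#' 3. *low_reward_repeat*: previously rewarded stage-2 responses
#'    repeated at a rate strictly below 50%. Eligible pairs are
#'    (t, t' = next non-missed trial) where t was non-missed and
#'    rewarded and t' visits the same stage-2 state — the only pairs on
#'    which "repeating the rewarded second-step response" is defined. A
#'    session with no eligible pair leaves the rate `NA` and the rule
#'    unfired.
#'
#' @param trials a `trials` data frame for one subject.
#' @param subject_id identifier copied into the report.
#' @return A one-row `qc_report` data frame: `subject_id`, `n_missed`,
#'   `max_first_step_option_fraction`, `rewarded_stage2_repeat_rate`,
#'   `excluded`, `reasons` (semicolon-joined).
#' @export
qc_session <- function(trials, subject_id = "S1") {
  if (nrow(trials) == 0L) stop_config("empty session cannot be QC'd")
  missed <- trials$missed %in% TRUE
  n_missed <- sum(missed)
  ok <- trials[!missed, ]
  max_frac <- if (nrow(ok) == 0L) 1 else {
    max(mean(ok$choice1 == 0), mean(ok$choice1 == 1))
  }
  rate <- reward_repeat_rate(trials)
  reasons <- character()
  if (n_missed > 20L) reasons <- c(reasons, "missed")
  if (max_frac >= 0.95) reasons <- c(reasons, "stereotyped_choice1")
  if (!is.na(rate) && rate < 0.50) reasons <- c(reasons, "low_reward_repeat")
  out <- data.frame(subject_id = subject_id, n_missed = n_missed,
                    max_first_step_option_fraction = max_frac,
                    rewarded_stage2_repeat_rate = rate,
                    excluded = length(reasons) > 0L,
                    reasons = paste(reasons, collapse = ";"))
  class(out) <- c("qc_report", "data.frame")
  out
}

reward_repeat_rate <- function(trials) {
  idx <- which(!(trials$missed %in% TRUE))
  if (length(idx) < 2L) return(NA_real_)
  rep_n <- 0L
  opp_n <- 0L
  for (k in seq_len(length(idx) - 1L)) {
    t0 <- idx[k]
    t1 <- idx[k + 1L] # next non-missed trial (bridges missed trials)
    if (trials$reward[t0] == 1L &&
        identical(trials$state2[t1], trials$state2[t0])) {
      opp_n <- opp_n + 1L
      if (trials$choice2[t1] == trials$choice2[t0]) rep_n <- rep_n + 1L
    }
  }
  if (opp_n == 0L) NA_real_ else rep_n / opp_n
}

#' Quality control for a cohort of sessions
#'
#' @param sessions named list of `trials` data frames.
#' @return List with `included` (the passing sessions, input order
#'   preserved) and `report` (one `qc_report` row per input session).
#' @export
qc_cohort <- function(sessions) {
  stopifnot(length(sessions) >= 1L)
  ids <- names(sessions) %||% paste0("S", seq_along(sessions))
  report <- do.call(rbind, Map(qc_session, sessions, ids))
  class(report) <- c("qc_report", "data.frame")
  list(included = sessions[!report$excluded], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d session(s), %d excluded\n",
              nrow(x), sum(x$excluded)))
  print.data.frame(x, digits = 3)
  invisible(x)
}
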