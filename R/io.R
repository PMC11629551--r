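#' Write trial logs to tidy CSV
#'
#' One row per trial with columns `subject_id, trial, choice1,
#' transition, state2, choice2, reward, rt1, rt2, missed`; `trial` is
#' 1-based in the file (internally trials are 0-based).
#'
#' @param sessions named list of `trials` data frames.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sessions <- function(sessions, path) {
  stopifnot(length(sessions) >= 1L)
  ids <- names(sessions) %||% paste0("S", seq_along(sessions))
  rows <- Map(function(tr, id) {
    data.frame(subject_id = id, trial = tr$t + 1L,
               tr[, c("choice1", "transition", "state2", "choice2",
                      "reward", "rt1", "rt2", "missed")])
  }, sessions, ids)
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read trial logs from tidy CSV
#'
#' Validates the schema written by [write_sessions()]; malformed rows
#' are reported with their line numbers and offending columns.
#'
#' @param path CSV path.
#' @return Named list of `trials` data frames, one per subject, in file
#'   order.
#' @export
read_sessions <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  needed <- c("subject_id", "trial", "choice1", "transition", "state2",
              "choice2", "reward", "missed")
  miss <- setdiff(needed, names(raw))
  if (length(miss)) {
    stop_config("missing required columns: %s", paste(miss, collapse = ", "))
  }
  if (!"rt1" %in% names(raw)) raw$rt1 <- NA_real_
  if (!"rt2" %in% names(raw)) raw$rt2 <- NA_real_
  raw$missed <- raw$missed %in% c(TRUE, "TRUE", "true", 1)
  live <- !raw$missed
  bad_col <- function(ok, col) {
    rows <- which(live & !ok)
    if (length(rows)) {
      stop_config("invalid %s at file row(s) %s", col,
                  paste(rows + 1L, collapse = ", "))  # +1 for header line
    }
  }
  bad_col(raw$choice1 %in% 0:1, "choice1")
  bad_col(raw$choice2 %in% 0:1, "choice2")
  bad_col(raw$reward %in% 0:1, "reward")
  bad_col(raw$transition %in% c("common", "rare"), "transition")
  bad_col(raw$state2 %in% c("A", "B"), "state2")
  out <- lapply(split(raw, factor(raw$subject_id,
                                  levels = unique(raw$subject_id))),
                function(d) {
    d <- d[order(d$trial), ]
    tr <- new_trials(nrow(d))
    tr$t <- as.integer(d$trial) - 1L
    for (col in c("choice1", "choice2", "reward")) {
      tr[[col]] <- suppressWarnings(as.integer(d[[col]]))
    }
    tr$transition <- as.character(d$transition)
    tr$state2 <- as.character(d$state2)
    tr$rt1 <- suppressWarnings(as.numeric(d$rt1))
    tr$rt2 <- suppressWarnings(as.numeric(d$rt2))
    tr$missed <- d$missed
    tr
  })
  out
}

#' Write / read a reward-probability walk as CSV
#'
#' Columns `trial` (1-based), `pA1, pA2, pB1, pB2`.
#'
#' @param walk a `reward_walk` matrix.
#' @param path CSV path.
#' @return Invisibly `path` (write); a `reward_walk` (read).
#' @export
write_walk <- function(walk, path) {
  write.csv(data.frame(trial = seq_len(nrow(walk)), unclass(walk)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_walk
#' @export
read_walk <- function(path) {
  d <- read.csv(path)
  m <- as.matrix(d[order(d$trial), c("pA1", "pA2", "pB1", "pB2")])
  rownames(m) <- NULL
  structure(m, class = c("reward_walk", "matrix", "array"))
}

#' Run the full analysis pipeline on a cohort
#'
#' End-to-end: behavioural QC, per-subject model fitting, cortisol
#' preprocessing, merge, and the omega ~ group x cortisol-increase
#' regression. When `out_dir` is given, writes the per-subject
#' parameter CSV, QC report CSV, regression CSV and a JSON run manifest
#' (configuration, seeds, package version) so every output can be
#' regenerated from the manifest alone.
#'
#' @param sessions named list of `trials` data frames.
#' @param subjects data frame with `subject_id`, `group`, `arm`,
#'   `c1..c4` (and optional VAS columns).
#' @param method fitting method, `"map"` (default) or `"hierarchical"`.
#' @param cfg a [task_config()].
#' @param fit_cfg a [fit_config()].
#' @param out_dir optional output directory.
#' @return List with `qc` (report), `fit` (`hybrid_fit`), `merged`
#'   (subject-level analysis table) and `regression`
#'   (`omega_regression`).
#' @export
run_pipeline <- function(sessions, subjects, method = "map",
                         cfg = task_config(), fit_cfg = fit_config(),
                         out_dir = NULL) {
  qc <- qc_cohort(sessions)
  fit <- fit_hybrid(qc$included, method = method, cfg = cfg,
                    fit_cfg = fit_cfg)
  omega_tab <- posterior_omega_table(fit)
  stress <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    sv <- stress_variables(subjects[i, c("c1", "c2", "c3", "c4")])
    data.frame(subject_id = subjects$subject_id[i], pre = sv$pre,
               post = sv$post, d_cort = sv$d_cort, usable = sv$usable)
  }))
  merged <- merge(merge(omega_tab, subjects[, c("subject_id", "group", "arm")],
                        by = "subject_id"),
                  stress, by = "subject_id")
  merged <- merged[merged$usable, ]
  reg <- omega_interaction_regression(merged$omega_hat, merged$group,
                                      merged$d_cort, ids = merged$subject_id)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(fit$estimates, file.path(out_dir, "parameters.csv"),
              row.names = FALSE)
    write.csv(qc$report, file.path(out_dir, "qc_report.csv"),
              row.names = FALSE)
    write.csv(reg$coefficients, file.path(out_dir, "regression.csv"),
              row.names = FALSE)
    if (!is.null(fit$diagnostics)) {
      write.csv(fit$diagnostics, file.path(out_dir, "diagnostics.csv"),
                row.names = FALSE)
    }
    manifest <- list(
      method = method, task = unclass(cfg), fit = unclass(fit_cfg),
      n_sessions = length(sessions), n_included = length(qc$included),
      regression = list(F = reg$F, df1 = reg$df1, df2 = reg$df2,
                        r_squared = reg$r_squared, n_used = reg$n_used),
      package_version = as.character(utils::packageVersion("twostepRL")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(qc = qc$report, fit = fit, merged = merged, regression = reg)
}
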