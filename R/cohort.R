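#' Specification of a synthetic two-step-task study
#'
#' Describes the generative model for a full synthetic cohort with the
#' statistical structure the analysis pipeline assumes: two groups
#' (healthy controls and AUD), an imbalanced stress-arm assignment
#' (SECPT stressor vs warm-water control), a lognormal baseline
#' cortisol with an arm-dependent log-scale increase, VAS ratings, and
#' per-subject hybrid-agent parameters whose model-based weight omega is
#' linked to the true cortisol increase on the logit scale:
#' `logit(omega) = b0 + b_group AUD + b_dcort d + b_int AUD d + noise`.
#'
#' Defaults emulate the study scale: group sizes 62/55, arm split
#' 33/29 (HC) and 40/15 (AUD), 200 trials per session, and omega-model
#' coefficients calibrated once so that the standardized OLS
#' coefficients of the downstream regression land near (-0.5, -0.4,
#' +0.45) with R-squared near 0.15 at this n (see the package
#' vignette). Means/SDs of the remaining agent parameters are typical
#' two-step-task population values on the transformed scales.
#'
#' @param n_hc,n_aud group sizes.
#' @param p_secpt_hc,p_secpt_aud share of each group assigned to the
#'   stress arm (deterministic counts via rounding by default).
#' @param bernoulli_arms sample arms as Bernoulli draws instead of
#'   deterministic counts.
#' @param b0,b_group,b_dcort,b_int,omega_noise_sd logit-scale omega
#'   model.
#' @param param_means,param_sds transformed-scale population means/SDs
#'   for `a1, beta1, a2, beta2, lam, pi` (omega is generated by the
#'   omega model).
#' @param baseline_meanlog,baseline_sdlog lognormal baseline cortisol
#'   (nmol/l).
#' @param secpt_mu,secpt_sd SECPT log-increase, Normal truncated at 0.
#' @param wpt_sd WPT log-increase SD (mean 0).
#' @param sample_noise_sd multiplicative (log-scale) noise per cortisol
#'   sample.
#' @param vas_pain_secpt mean VAS pain increase under SECPT.
#' @param n_qc_violators number of planted QC-violating subjects.
#' @param task a [task_config()].
#' @param seed master seed.
#' @return A `cohort_spec` (named list).
#' @export
cohort_spec <- function(n_hc = 62L, n_aud = 55L,
                        p_secpt_hc = 33 / 62, p_secpt_aud = 40 / 55,
                        bernoulli_arms = FALSE,
                        b0 = 0.50, b_group = -1.27, b_dcort = -2.35,
                        b_int = 2.55, omega_noise_sd = 0.80,
                        param_means = c(a1 = 0, beta1 = log(4.5), a2 = -0.4,
                                        beta2 = log(3.5), lam = 0.4,
                                        pi = 0.2),
                        param_sds = c(a1 = 0.5, beta1 = 0.35, a2 = 0.5,
                                      beta2 = 0.35, lam = 0.7, pi = 0.3),
                        baseline_meanlog = log(6.5), baseline_sdlog = 0.5,
                        secpt_mu = 0.35, secpt_sd = 0.30, wpt_sd = 0.10,
                        sample_noise_sd = 0.12, vas_pain_secpt = 1.3,
                        n_qc_violators = 0L,
                        task = task_config(), seed = 1L) {
  stopifnot(n_hc >= 0, n_aud >= 0,
            p_secpt_hc >= 0, p_secpt_hc <= 1,
            p_secpt_aud >= 0, p_secpt_aud <= 1,
            omega_noise_sd >= 0, n_qc_violators >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a full synthetic cohort
#'
#' Realises a [cohort_spec()]: per subject, group and arm, a cortisol
#' panel, VAS ratings, true agent parameters with omega tied to the
#' true cortisol increase, and a simulated session of the two-step
#' task. Optionally plants QC-violating subjects (cycling through the
#' three exclusion rules) so the QC filters can be exercised.
#'
#' @param spec a [cohort_spec()].
#' @param sessions simulate the trial-level sessions (default). With
#'   `FALSE` only the subject-level latents are generated (useful for
#'   large calibration studies of the statistical layer, where the
#'   trial data would never be fitted).
#' @return List with `sessions` (named list of `trials`, or `NULL`),
#'   `subjects` (data frame: id, group, arm, `c1..c4`, VAS ratings),
#'   and `truth` (data frame of every latent used: true parameters,
#'   true log increase, QC-violation labels).
#' @examples
#' spec <- cohort_spec(n_hc = 3, n_aud = 3, task = task_config(n_trials = 30))
#' coh <- generate_cohort(spec)
#' names(coh)
#' @export
generate_cohort <- function(spec, sessions = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  n <- spec$n_hc + spec$n_aud
  group <- c(rep("HC", spec$n_hc), rep("AUD", spec$n_aud))
  ids <- sprintf("%s%03d", ifelse(group == "HC", "H", "A"),
                 c(seq_len(spec$n_hc), seq_len(spec$n_aud)))

  set.seed(derive_seed(spec$seed, "arms"))
  arm <- character(n)
  for (g in c("HC", "AUD")) {
    idx <- which(group == g)
    p <- if (g == "HC") spec$p_secpt_hc else spec$p_secpt_aud
    if (spec$bernoulli_arms) {
      arm[idx] <- ifelse(runif(length(idx)) < p, "SECPT", "WPT")
    } else {
      k <- round(length(idx) * p)
      arm[idx] <- c(rep("SECPT", k), rep("WPT", length(idx) - k))
    }
  }

  set.seed(derive_seed(spec$seed, "cortisol"))
  baseline <- exp(rnorm(n, spec$baseline_meanlog, spec$baseline_sdlog))
  inc <- ifelse(arm == "SECPT",
                pmax(0, rnorm(n, spec$secpt_mu, spec$secpt_sd)),
                rnorm(n, 0, spec$wpt_sd))
  noise <- matrix(rnorm(4 * n, 0, spec$sample_noise_sd), n, 4)
  c_pre <- baseline
  c_post <- baseline * exp(inc)
  panel <- cbind(c1 = c_pre * exp(noise[, 1]), c2 = c_pre * exp(noise[, 2]),
                 c3 = c_post * exp(noise[, 3]), c4 = c_post * exp(noise[, 4]))

  set.seed(derive_seed(spec$seed, "vas"))
  vas_pre <- matrix(pmin(10, pmax(0, rnorm(3 * n, 2.5, 1.5))), n, 3,
                    dimnames = list(NULL, c("stress", "pain", "craving")))
  bump <- cbind(stress = ifelse(arm == "SECPT", 0.3, 0),
                pain = ifelse(arm == "SECPT", spec$vas_pain_secpt, 0),
                craving = 0)
  vas_post <- pmin(pmax(vas_pre + bump + rnorm(3 * n, 0, 0.8), 0), 10)

  set.seed(derive_seed(spec$seed, "params"))
  theta6 <- sapply(seq_len(6), function(p) {
    rnorm(n, spec$param_means[p], spec$param_sds[p])
  })
  is_aud <- as.numeric(group == "AUD")
  logit_omega <- spec$b0 + spec$b_group * is_aud + spec$b_dcort * inc +
    spec$b_int * is_aud * inc + rnorm(n, 0, spec$omega_noise_sd)
  params <- data.frame(
    a1 = inv_logit(theta6[, 1]), beta1 = exp(theta6[, 2]),
    a2 = inv_logit(theta6[, 3]), beta2 = exp(theta6[, 4]),
    lam = inv_logit(theta6[, 5]), omega = inv_logit(logit_omega),
    pi = theta6[, 6])

  violator_type <- rep(NA_character_, n)
  if (spec$n_qc_violators > 0L) {
    set.seed(derive_seed(spec$seed, "violators"))
    picks <- sample(n, spec$n_qc_violators)
    violator_type[picks] <- rep(c("missed", "stereotyped_choice1",
                                  "low_reward_repeat"),
                                length.out = spec$n_qc_violators)
  }

  sess <- NULL
  if (sessions) sess <- simulate_cohort_sessions(spec, n, ids, params,
                                                 violator_type)
  subjects <- data.frame(subject_id = ids, group = group, arm = arm,
                         panel,
                         vas_stress_pre = vas_pre[, "stress"],
                         vas_stress_post = vas_post[, "stress"],
                         vas_pain_pre = vas_pre[, "pain"],
                         vas_pain_post = vas_post[, "pain"],
                         vas_craving_pre = vas_pre[, "craving"],
                         vas_craving_post = vas_post[, "craving"])
  truth <- data.frame(subject_id = ids, group = group, arm = arm,
                      baseline_cortisol = baseline, true_log_increase = inc,
                      logit_omega = logit_omega, params,
                      qc_violator = violator_type)
  list(sessions = sess, subjects = subjects, truth = truth)
}

simulate_cohort_sessions <- function(spec, n, ids, params, violator_type) {
  sess <- vector("list", n)
  names(sess) <- ids
  for (i in seq_len(n)) {
    sseed <- derive_seed(spec$seed, paste0("session-", ids[i]))
    walk <- init_walk(spec$task, derive_seed(sseed, "walk"))
    par_i <- do.call(agent_params, as.list(params[i, ]))
    if (identical(violator_type[i], "stereotyped_choice1")) {
      par_i <- do.call(agent_params,
                       as.list(utils::modifyList(as.list(unclass(par_i)),
                                                 list(beta1 = 0, pi = 50))))
    }
    tr <- simulate_subject(par_i, spec$task, walk, sseed)
    if (identical(violator_type[i], "missed")) {
      set.seed(derive_seed(sseed, "plant-missed"))
      hit <- sample(nrow(tr), 25)
      tr$missed[hit] <- TRUE
      tr$choice1[hit] <- NA_integer_
      tr$transition[hit] <- NA_character_
      tr$state2[hit] <- NA_character_
      tr$choice2[hit] <- NA_integer_
      tr$reward[hit] <- NA_integer_
    }
    if (identical(violator_type[i], "low_reward_repeat")) {
      tr <- break_reward_repeats(tr)
    }
    sess[[i]] <- tr
  }
  sess
}

# force repetition of a previously rewarded same-state stage-2 response
# to never happen (rate 0), while keeping stage-1/transition consistency
break_reward_repeats <- function(tr) {
  idx <- which(!(tr$missed %in% TRUE))
  for (k in seq_len(length(idx) - 1L)) {
    t0 <- idx[k]
    t1 <- idx[k + 1L]
    if (tr$reward[t0] == 1L && identical(tr$state2[t1], tr$state2[t0]) &&
        tr$choice2[t1] == tr$choice2[t0]) {
      tr$choice2[t1] <- 1L - tr$choice2[t1]
    }
  }
  tr
}

#' Write a canned synthetic fixture to disk
#'
#' Available fixtures: `tiny` (6 subjects x 50 trials, for unit tests),
#' `null` (40 subjects, all omega-model effects zero), `paper_like`
#' (117 subjects x 200 trials with the study's group sizes and arm
#' split), `qc_stress` (12 subjects x 100 trials with 3 planted QC
#' violators).
#'
#' @param name one of `"tiny"`, `"null"`, `"paper_like"`, `"qc_stress"`.
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @return Invisibly, the directory; writes `sessions.csv`,
#'   `subjects.csv`, `truth.csv` and `manifest.json`.
#' @export
make_fixture <- function(name, dir = tempfile("fixture-"), seed = 1L) {
  spec <- switch(name,
    tiny = cohort_spec(n_hc = 3L, n_aud = 3L,
                       task = task_config(n_trials = 50L), seed = seed),
    null = cohort_spec(n_hc = 20L, n_aud = 20L, b_group = 0, b_dcort = 0,
                       b_int = 0, task = task_config(n_trials = 100L),
                       seed = seed),
    paper_like = cohort_spec(seed = seed),
    qc_stress = cohort_spec(n_hc = 6L, n_aud = 6L, n_qc_violators = 3L,
                            task = task_config(n_trials = 100L), seed = seed),
    stop_config("unknown fixture name '%s'", name))
  coh <- generate_cohort(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sessions(coh$sessions, file.path(dir, "sessions.csv"))
  write.csv(coh$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  write.csv(coh$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  manifest <- list(fixture = name, seed = seed,
                   package_version = as.character(utils::packageVersion("twostepRL")),
                   spec = spec[!vapply(spec, is.function, TRUE)])
  manifest$spec$task <- unclass(spec$task)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
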