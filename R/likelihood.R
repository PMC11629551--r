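#' MCMC / MAP fitting configuration
#'
#' Defaults follow the study-scale analysis settings: 4 chains of 6000
#' iterations each with the first 3000 as warm-up. For test-scale runs
#' pass smaller values (the package's own tests use 2 chains x 1000
#' iterations, 500 warm-up).
#'
#' @param n_chains number of MCMC chains (>= 2 for split-R-hat).
#' @param n_iter total iterations per chain (warm-up included).
#' @param n_warmup warm-up (adaptation) iterations discarded per chain.
#' @param rhat_threshold convergence flag threshold for split-R-hat.
#' @param map_restarts number of Latin-hypercube restarts for MAP.
#' @param seed integer seed for fitting randomness.
#' @return A `fit_config` object (named list).
#' @export
fit_config <- function(n_chains = 4L, n_iter = 6000L, n_warmup = 3000L,
                       rhat_threshold = 1.1, map_restarts = 10L, seed = 1L) {
  if (n_warmup >= n_iter) stop_config("n_warmup must be < n_iter")
  if (n_chains < 2L) stop_config("need >= 2 chains for diagnostics")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_warmup = as.integer(n_warmup),
                 rhat_threshold = rhat_threshold,
                 map_restarts = as.integer(map_restarts),
                 seed = as.integer(seed)),
            class = "fit_config")
}

param_names <- c("a1", "beta1", "a2", "beta2", "lam", "omega", "pi")

# transforms: logit for rates/trace/MB weight, log for temperatures,
# identity for perseveration
to_transformed <- function(par) {
  th <- as.numeric(par)
  c(logit(th[1]), log(th[2]), logit(th[3]), log(th[4]),
    logit(th[5]), logit(th[6]), th[7])
}
to_natural <- function(theta) {
  p <- c(inv_logit(theta[1]), exp(theta[2]), inv_logit(theta[3]),
         exp(theta[4]), inv_logit(theta[5]), inv_logit(theta[6]), theta[7])
  names(p) <- param_names
  p
}

trials_arrays <- function(trials) {
  missed <- as.integer(trials$missed %in% TRUE)
  list(
    choice1 = ifelse(missed == 1L, 0L, as.integer(trials$choice1)),
    state2 = ifelse(missed == 1L, 0L, state_index(trials$state2) - 1L),
    choice2 = ifelse(missed == 1L, 0L, as.integer(trials$choice2)),
    reward = ifelse(missed == 1L, 0, as.numeric(trials$reward)),
    missed = missed
  )
}

#' Log-likelihood of a session under the hybrid model
#'
#' Sums, over non-missed trials, the log-probability of the observed
#' stage-1 and stage-2 choices while the agent's latent values evolve
#' exactly as in [update_after_trial()]. Missed trials contribute no
#' likelihood term, update no values, and clear the perseveration
#' memory.
#'
#' @param params an [agent_params()].
#' @param trials a `trials` data frame ordered by trial index.
#' @param cfg a [task_config()] (supplies `p_common` and `q_init`).
#' @return The log-likelihood (a scalar, always <= 0).
#' @examples
#' cfg <- task_config(n_trials = 50)
#' tr <- simulate_subject(agent_params(), cfg, init_walk(cfg, 1), 2)
#' session_loglik(agent_params(), tr, cfg)
#' @export
session_loglik <- function(params, trials, cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (nrow(trials) == 0L) return(0)
  if (is.unsorted(trials$t, strictly = TRUE)) {
    stop_config("trials must be ordered by strictly increasing index t")
  }
  a <- trials_arrays(trials)
  loglik_session_cpp(as.numeric(params), a$choice1, a$state2, a$choice2,
                     a$reward, a$missed, cfg$p_common, cfg$q_init)
}

# weakly-informative MAP prior SDs on the transformed scale
map_prior_sd <- c(1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 2)

map_objective <- function(theta, arrays, p_common, q_init) {
  ll <- loglik_session_cpp(to_natural(theta), arrays$choice1, arrays$state2,
                           arrays$choice2, arrays$reward, arrays$missed,
                           p_common, q_init)
  -(ll + sum(dnorm(theta, 0, map_prior_sd, log = TRUE)))
}

# Latin-hypercube starting points in the transformed space
lhc_starts <- function(n_restarts, scale = 1) {
  sapply(seq_len(7), function(p) {
    strata <- sample(seq_len(n_restarts))
    qnorm((strata - runif(n_restarts)) / n_restarts) * scale
  })
}

#' Maximum a posteriori fit of one session
#'
#' Maximises [session_loglik()] plus independent Normal log-priors on the
#' transformed parameters (logit scale for `a1`, `a2`, `lam`, `omega`;
#' log scale for `beta1`, `beta2`; identity for `pi`), taking the best of
#' `map_restarts` Latin-hypercube initialisations. Deterministic given
#' `fit_cfg$seed`.
#'
#' @param trials a `trials` data frame (one session that passed QC).
#' @param cfg a [task_config()].
#' @param fit_cfg a [fit_config()].
#' @return A list with `par` (the [agent_params()] estimate), `theta`
#'   (transformed scale), `loglik`, `logpost`, `converged`, and
#'   `restart_values` (objective value per restart).
#' @export
fit_map <- function(trials, cfg, fit_cfg = fit_config()) {
  arrays <- trials_arrays(trials)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(fit_cfg$seed, "map"))
  starts <- lhc_starts(fit_cfg$map_restarts)
  best <- NULL
  vals <- rep(NA_real_, fit_cfg$map_restarts)
  for (r in seq_len(fit_cfg$map_restarts)) {
    fit <- tryCatch(
      optim(starts[r, ], map_objective, arrays = arrays,
            p_common = cfg$p_common, q_init = cfg$q_init,
            method = "BFGS", control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    vals[r] <- fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop_config("all %d MAP restarts failed to converge", fit_cfg$map_restarts)
  }
  par <- do.call(agent_params, as.list(to_natural(best$par)))
  list(par = par, theta = best$par,
       loglik = session_loglik(par, trials, cfg),
       logpost = -best$value,
       converged = best$convergence == 0,
       restart_values = vals)
}
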