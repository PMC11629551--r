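#' Parameters of the 7-parameter hybrid MF/MB agent
#'
#' The hybrid reinforcement-learning model mixes a model-free SARSA(lambda)
#' learner with a model-based planner that exploits the known 70/30
#' transition structure. Its seven free parameters are:
#'
#' * `a1`, `a2` — stage-1 / stage-2 learning rates, in \[0, 1\];
#' * `beta1`, `beta2` — stage-1 / stage-2 inverse temperatures, >= 0;
#' * `lam` — eligibility trace propagating the stage-2 prediction error
#'   back to the stage-1 model-free value, in \[0, 1\];
#' * `omega` — model-based weight: relative contribution of model-based
#'   over model-free values at stage 1 (0 = pure MF, 1 = pure MB);
#' * `pi` — perseveration bonus for repeating the previous stage-1
#'   choice, unbounded real.
#'
#' @param a1,beta1,a2,beta2,lam,omega,pi numeric scalars as above.
#' @return An `agent_params` object (named numeric vector).
#' @examples
#' agent_params(omega = 1)   # pure model-based agent
#' @export
agent_params <- function(a1 = 0.5, beta1 = 4, a2 = 0.5, beta2 = 4,
                         lam = 0.6, omega = 0.5, pi = 0.2) {
  p <- c(a1 = a1, beta1 = beta1, a2 = a2, beta2 = beta2,
         lam = lam, omega = omega, pi = pi)
  if (any(!is.finite(p))) stop_config("agent parameters must be finite")
  for (nm in c("a1", "a2", "lam", "omega")) {
    if (p[nm] < 0 || p[nm] > 1) stop_config("%s must be in [0, 1]", nm)
  }
  if (p["beta1"] < 0 || p["beta2"] < 0) {
    stop_config("inverse temperatures must be >= 0")
  }
  structure(p, class = "agent_params")
}

#' Initial latent state of the hybrid agent
#'
#' @param q_init initial value for every Q entry (default 0; rewards are
#'   0/1 so all values then stay within \[0, 1\]).
#' @return An `agent_state`: list with `q_mf` (length-2 stage-1
#'   model-free values), `q2` (2x2 stage-2 values, state x option) and
#'   `prev_choice1` (previous stage-1 choice or `NA`).
#' @export
agent_state <- function(q_init = 0) {
  list(q_mf = rep(q_init, 2),
       q2 = matrix(q_init, 2, 2, dimnames = list(c("A", "B"), NULL)),
       prev_choice1 = NA_integer_)
}

#' Model-based stage-1 action values
#'
#' Bellman evaluation over the known transition structure:
#' `Q_MB(a) = p_common * max_b q2(freq(a), b) +
#'            (1 - p_common) * max_b q2(rare(a), b)`,
#' where `freq(a)` is option `a`'s frequent stage-2 destination
#' (option 0 -> state A, option 1 -> state B).
#'
#' @param q2 2x2 matrix of stage-2 values (rows = states A, B).
#' @param p_common common-transition probability.
#' @return Length-2 vector of model-based values.
#' @examples
#' mb_values(matrix(c(0.5, 0.25, 0, 0.75), 2), p_common = 0.7)
#' @export
mb_values <- function(q2, p_common) {
  stopifnot(is.matrix(q2), all(dim(q2) == 2L), all(is.finite(q2)))
  best <- c(max(q2[1, ]), max(q2[2, ]))
  c(p_common * best[1] + (1 - p_common) * best[2],
    p_common * best[2] + (1 - p_common) * best[1])
}

#' Advance the agent's latent values by one completed trial
#'
#' Applies, in order: the stage-1 SARSA backup towards the visited
#' stage-2 value (`delta1`), the stage-2 reward prediction error
#' (`delta2`), the eligibility-trace credit `a1 * lam * delta2` to the
#' stage-1 value, and the perseveration memory. A missed trial updates
#' no values and clears `prev_choice1` (no perseveration bonus on the
#' next trial).
#'
#' @param state an [agent_state()].
#' @param params an [agent_params()].
#' @param trial one-row `trials` data frame (or a list with fields
#'   `choice1`, `state2`, `choice2`, `reward`, `missed`).
#' @return The updated `agent_state`.
#' @export
update_after_trial <- function(state, params, trial) {
  if (isTRUE(trial$missed)) {
    state$prev_choice1 <- NA_integer_
    return(state)
  }
  s2 <- unname(state_index(trial$state2))
  c1 <- unname(trial$choice1) + 1L
  c2 <- unname(trial$choice2) + 1L
  delta1 <- state$q2[[s2, c2]] - state$q_mf[[c1]]
  state$q_mf[c1] <- state$q_mf[[c1]] + params[["a1"]] * delta1
  delta2 <- unname(trial$reward) - state$q2[[s2, c2]]
  state$q2[s2, c2] <- state$q2[[s2, c2]] + params[["a2"]] * delta2
  state$q_mf[c1] <- state$q_mf[[c1]] +
    params[["a1"]] * params[["lam"]] * delta2
  state$prev_choice1 <- as.integer(trial$choice1)
  state
}

state_index <- function(state2) {
  if (is.character(state2) || is.factor(state2)) {
    match(as.character(state2), c("A", "B"))
  } else {
    as.integer(state2) + 1L
  }
}

#' Stage-1 choice probabilities of the hybrid agent
#'
#' Mixes model-based and model-free values with weight `omega`, adds the
#' perseveration bonus, and applies a softmax:
#' `P(a) = softmax(beta1 * Q_net(a) + pi * 1[a == prev_choice1])` with
#' `Q_net = omega * Q_MB + (1 - omega) * q_mf`.
#'
#' @inheritParams update_after_trial
#' @param p_common common-transition probability of the task.
#' @return Length-2 probability vector (sums to 1).
#' @export
choice_probs_stage1 <- function(state, params, p_common) {
  q_net <- params[["omega"]] * mb_values(state$q2, p_common) +
    (1 - params[["omega"]]) * state$q_mf
  u <- params[["beta1"]] * q_net
  if (!is.na(state$prev_choice1)) {
    u[state$prev_choice1 + 1L] <- u[state$prev_choice1 + 1L] +
      params[["pi"]]
  }
  softmax2(u)
}

#' Stage-2 choice probabilities of the hybrid agent
#'
#' @inheritParams choice_probs_stage1
#' @param state2 visited stage-2 state (`"A"`/`"B"` or 0/1).
#' @return Length-2 probability vector: `softmax(beta2 * q2(state2, .))`.
#' @export
choice_probs_stage2 <- function(state, params, state2) {
  softmax2(params[["beta2"]] * state$q2[unname(state_index(state2)), ])
}

softmax2 <- function(u) {
  u <- u - max(u)
  e <- exp(u)
  unname(e / sum(e))
}

# stateful policy closure wiring the hybrid agent into simulate_episode
hybrid_policy <- function(params, cfg) {
  state <- agent_state(cfg$q_init)
  n_seen <- 0L
  function(stage, state2, history) {
    if (nrow(history) > n_seen) {
      for (i in (n_seen + 1L):nrow(history)) {
        state <<- update_after_trial(state, params, history[i, ])
      }
      n_seen <<- nrow(history)
    }
    if (stage == 1L) choice_probs_stage1(state, params, cfg$p_common)
    else choice_probs_stage2(state, params, state2)
  }
}

#' Simulate a full session from the hybrid agent
#'
#' Samples a synthetic session of the two-step task from the model at
#' the given parameters. Uses the same four per-component uniform
#' substreams as [simulate_episode()], so the result is bit-identical to
#' running [simulate_episode()] with the agent wrapped as a policy; the
#' inner loop runs in C++ for speed.
#'
#' @param params an [agent_params()].
#' @param cfg a [task_config()].
#' @param walk a `reward_walk` from [init_walk()].
#' @param rng_seed integer master seed.
#' @return A `trials` data frame (see [simulate_episode()]).
#' @examples
#' cfg <- task_config(n_trials = 20)
#' trials <- simulate_subject(agent_params(), cfg, init_walk(cfg, 1), 2)
#' head(trials)
#' @export
simulate_subject <- function(params, cfg, walk, rng_seed) {
  stopifnot(inherits(params, "agent_params"), inherits(cfg, "task_config"))
  n <- cfg$n_trials
  u <- episode_uniforms(n, rng_seed)
  sim <- simulate_hybrid_cpp(as.numeric(params), unclass(walk)[seq_len(n), , drop = FALSE],
                             cfg$p_common, cfg$q_init,
                             u$tr, u$rw, u$c1, u$c2)
  out <- new_trials(n)
  out$choice1 <- sim$choice1
  out$transition <- ifelse(sim$common == 1L, "common", "rare")
  out$state2 <- c("A", "B")[sim$state2 + 1L]
  out$choice2 <- sim$choice2
  out$reward <- sim$reward
  out
}
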