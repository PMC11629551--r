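#' Task configuration for the two-step Markov task
#'
#' Describes the environment of the two-stage sequential decision task:
#' number of trials, the fixed stage-1 -> stage-2 transition probability,
#' and the bounded Gaussian random walk followed by the four stage-2
#' reward probabilities. Defaults correspond to the standard layout of
#' the task: 200 trials, 70/30 transitions, reward probabilities drifting
#' within [0.25, 0.75] with step SD 0.025.
#'
#' Stage-1 option 0 transitions frequently to stage-2 state A, option 1
#' to state B; the mapping is fixed and recorded here as metadata.
#'
#' @param n_trials number of trials per session.
#' @param p_common probability of the common transition (must exceed 0.5).
#' @param walk_sd standard deviation of the Gaussian random-walk step.
#' @param walk_lo,walk_hi reflecting bounds of the reward-probability walk.
#' @param reward_value monetary value of a rewarded trial (currency units).
#' @param response_window response deadline in seconds.
#' @param q_init initial Q-value for all options (default 0).
#' @return An object of class `task_config` (a named list).
#' @examples
#' cfg <- task_config()
#' cfg$p_common
#' @export
task_config <- function(n_trials = 200L, p_common = 0.7, walk_sd = 0.025,
                        walk_lo = 0.25, walk_hi = 0.75,
                        reward_value = 0.20, response_window = 3.0,
                        q_init = 0) {
  if (!(p_common > 0.5 && p_common <= 1)) {
    stop_config("p_common must lie in (0.5, 1], got %g", p_common)
  }
  if (!(walk_lo >= 0 && walk_lo < walk_hi && walk_hi <= 1)) {
    stop_config("walk bounds must satisfy 0 <= walk_lo < walk_hi <= 1")
  }
  if (walk_sd < 0) stop_config("walk_sd must be >= 0")
  if (n_trials < 1) stop_config("n_trials must be >= 1")
  structure(list(
    n_trials = as.integer(n_trials), p_common = p_common,
    walk_sd = walk_sd, walk_lo = walk_lo, walk_hi = walk_hi,
    reward_value = reward_value, response_window = response_window,
    q_init = q_init,
    # frequent destination of stage-1 option 0 / option 1 (0 = A, 1 = B)
    mapping = c(option0 = 0L, option1 = 1L)
  ), class = "task_config")
}

reflect_bounds <- function(x, lo, hi) {
  # fold x back into [lo, hi]; repeated reflection handles large overshoots
  width <- hi - lo
  while (any(bad <- (x < lo | x > hi))) {
    x[bad] <- ifelse(x[bad] > hi, 2 * hi - x[bad], 2 * lo - x[bad])
  }
  x
}

#' Initialise the drifting reward-probability walk
#'
#' Draws the trial-by-trial reward probabilities of the four stage-2
#' options. Row 1 is uniform within the bounds; each later row adds an
#' independent Gaussian step per column and reflects at the bounds
#' (`x' = 2*bound - x` on overshoot), which preserves the nominal
#' marginal step SD better than clipping.
#'
#' @param cfg a [task_config()].
#' @param rng_seed integer seed; the walk is deterministic given it.
#' @return A `reward_walk`: numeric matrix `n_trials x 4` with columns
#'   `pA1, pA2, pB1, pB2` (stage-2 state x option).
#' @examples
#' w <- init_walk(task_config(), rng_seed = 1)
#' range(w)
#' @export
init_walk <- function(cfg, rng_seed) {
  stopifnot(inherits(cfg, "task_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  n <- cfg$n_trials
  probs <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, c("pA1", "pA2", "pB1", "pB2")))
  probs[1, ] <- runif(4, cfg$walk_lo, cfg$walk_hi)
  if (n > 1) {
    steps <- matrix(rnorm((n - 1) * 4, 0, cfg$walk_sd), n - 1, 4)
    for (t in 2:n) {
      probs[t, ] <- reflect_bounds(probs[t - 1, ] + steps[t - 1, ],
                                   cfg$walk_lo, cfg$walk_hi)
    }
  }
  structure(probs, class = c("reward_walk", "matrix", "array"))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Sample one stage-1 -> stage-2 transition
#'
#' @param choice1 stage-1 choice, 0 or 1.
#' @param cfg a [task_config()].
#' @param rng_seed optional integer seed (omit to use the current RNG
#'   stream, as [simulate_episode()] does).
#' @return List with `state2` (0 = A, 1 = B) and `transition`
#'   (`"common"` or `"rare"`). The label is `"rare"` exactly when the
#'   realised state differs from the frequent destination of `choice1`.
#' @export
transition_step <- function(choice1, cfg, rng_seed = NULL) {
  stopifnot(choice1 %in% c(0L, 1L))
  if (!is.null(rng_seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(rng_seed)
  }
  freq <- unname(cfg$mapping[choice1 + 1L])
  common <- runif(1) < cfg$p_common
  state2 <- if (common) freq else 1L - freq
  list(state2 = state2, transition = if (common) "common" else "rare")
}

#' Simulate one session of the two-step task under an arbitrary policy
#'
#' Runs `n_trials` of the task against a caller-supplied policy. The
#' policy is a function `policy(stage, state, history)` returning a
#' length-2 probability vector over options; `stage` is 1 or 2, `state`
#' is the stage-2 state (0/1) for stage 2 calls and `NA` for stage 1,
#' and `history` is the data frame of completed trials so far.
#'
#' Four independent seed substreams (transitions, rewards, stage-1
#' choices, stage-2 choices) are derived from `rng_seed` via
#' [derive_seed()], so the episode is bit-reproducible and each
#' stochastic component can be regenerated on its own.
#'
#' @param agent_policy policy function as described above.
#' @param cfg a [task_config()].
#' @param walk a `reward_walk` from [init_walk()].
#' @param rng_seed integer master seed for the episode.
#' @return A `trials` data frame with columns `t` (0-based index),
#'   `choice1`, `transition`, `state2` (`"A"`/`"B"`), `choice2`,
#'   `reward`, `rt1`, `rt2`, `missed`.
#' @examples
#' cfg <- task_config(n_trials = 10)
#' w <- init_walk(cfg, 1)
#' unif <- function(stage, state, history) c(0.5, 0.5)
#' simulate_episode(unif, cfg, w, rng_seed = 2)
#' @export
simulate_episode <- function(agent_policy, cfg, walk, rng_seed) {
  stopifnot(inherits(cfg, "task_config"), nrow(walk) >= cfg$n_trials)
  n <- cfg$n_trials
  u <- episode_uniforms(n, rng_seed)
  pick <- function(p, ui) {
    if (!is.numeric(p) || length(p) != 2L || any(!is.finite(p)) ||
        any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop_config("policy returned an invalid probability vector")
    }
    as.integer(ui >= p[1])
  }
  choice1 <- choice2 <- reward <- state2i <- integer(n)
  common <- logical(n)
  out <- new_trials(n)
  for (i in seq_len(n)) {
    hist <- out[seq_len(i - 1L), , drop = FALSE]
    c1 <- pick(agent_policy(1L, NA_integer_, hist), u$c1[i])
    freq <- unname(cfg$mapping[c1 + 1L])
    com <- u$tr[i] < cfg$p_common
    s2 <- if (com) freq else 1L - freq
    c2 <- pick(agent_policy(2L, s2, hist), u$c2[i])
    rew <- as.integer(u$rw[i] < walk[i, 2L * s2 + c2 + 1L])
    out$choice1[i] <- c1
    out$transition[i] <- if (com) "common" else "rare"
    out$state2[i] <- c("A", "B")[s2 + 1L]
    out$choice2[i] <- c2
    out$reward[i] <- rew
  }
  out
}

# four independent uniform substreams, one per stochastic component
episode_uniforms <- function(n, rng_seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  out <- lapply(c(tr = "transition", rw = "reward",
                  c1 = "choice1", c2 = "choice2"), function(s) {
    set.seed(derive_seed(rng_seed, s))
    runif(n)
  })
  out
}

new_trials <- function(n) {
  out <- data.frame(
    t = seq_len(n) - 1L, choice1 = NA_integer_,
    transition = NA_character_, state2 = NA_character_,
    choice2 = NA_integer_, reward = NA_integer_,
    rt1 = NA_real_, rt2 = NA_real_, missed = FALSE
  )
  class(out) <- c("trials", "data.frame")
  out
}
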