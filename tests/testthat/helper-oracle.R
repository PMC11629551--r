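# Independent, maximally naive oracles used to cross-check the package
# implementation. These deliberately re-derive everything line by line
# and share no code with the package internals.

# Naive replay of the hybrid model's session log-likelihood.
oracle_session_loglik <- function(params, trials, p_common, q_init = 0) {
  a1 <- params[["a1"]]; b1 <- params[["beta1"]]
  a2 <- params[["a2"]]; b2 <- params[["beta2"]]
  lam <- params[["lam"]]; w <- params[["omega"]]; pp <- params[["pi"]]
  qmf <- c(q_init, q_init)
  q2 <- matrix(q_init, 2, 2)  # rows: state A, B
  prev <- NA
  ll <- 0
  for (i in seq_len(nrow(trials))) {
    if (isTRUE(trials$missed[i])) { prev <- NA; next }
    c1 <- trials$choice1[i]
    s2 <- if (trials$state2[i] == "A") 1 else 2
    c2 <- trials$choice2[i]
    r <- trials$reward[i]
    qmb <- c(p_common * max(q2[1, ]) + (1 - p_common) * max(q2[2, ]),
             p_common * max(q2[2, ]) + (1 - p_common) * max(q2[1, ]))
    qn <- w * qmb + (1 - w) * qmf
    u <- b1 * qn
    if (!is.na(prev)) u[prev + 1] <- u[prev + 1] + pp
    p1 <- exp(u) / sum(exp(u))
    ll <- ll + log(p1[c1 + 1])
    u2 <- b2 * q2[s2, ]
    p2 <- exp(u2) / sum(exp(u2))
    ll <- ll + log(p2[c2 + 1])
    d1 <- q2[s2, c2 + 1] - qmf[c1 + 1]
    qmf[c1 + 1] <- qmf[c1 + 1] + a1 * d1
    d2 <- r - q2[s2, c2 + 1]
    q2[s2, c2 + 1] <- q2[s2, c2 + 1] + a2 * d2
    qmf[c1 + 1] <- qmf[c1 + 1] + a1 * lam * d2
    prev <- c1
  }
  ll
}

# Random but structurally valid trial log (transition label consistent
# with the option -> frequent-state mapping: option 0 -> A, 1 -> B).
random_trials <- function(n, p_missed = 0, seed = 1) {
  set.seed(seed)
  choice1 <- sample(0:1, n, replace = TRUE)
  common <- runif(n) < 0.7
  freq <- choice1                       # 0 -> state A(0), 1 -> B(1)
  state2i <- ifelse(common, freq, 1L - freq)
  out <- data.frame(
    t = seq_len(n) - 1L,
    choice1 = choice1,
    transition = ifelse(common, "common", "rare"),
    state2 = c("A", "B")[state2i + 1L],
    choice2 = sample(0:1, n, replace = TRUE),
    reward = rbinom(n, 1, 0.5),
    rt1 = runif(n, 0.2, 2.5), rt2 = runif(n, 0.2, 2.5),
    missed = runif(n) < p_missed
  )
  out$choice1[out$missed] <- NA_integer_
  out$transition[out$missed] <- NA_character_
  out$state2[out$missed] <- NA_character_
  out$choice2[out$missed] <- NA_integer_
  out$reward[out$missed] <- NA_integer_
  class(out) <- c("trials", "data.frame")
  out
}

random_agent_params <- function(seed = 1) {
  set.seed(seed)
  agent_params(a1 = runif(1), beta1 = runif(1, 0, 8), a2 = runif(1),
               beta2 = runif(1, 0, 8), lam = runif(1), omega = runif(1),
               pi = runif(1, -1, 2))
}

# Brute-force pairwise count for the Mann-Whitney U of the first sample.
oracle_u_count <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# Brute-force stay-table recount.
oracle_stay_counts <- function(trials) {
  counts <- list()
  for (i in seq_len(nrow(trials) - 1)) {
    if (isTRUE(trials$missed[i]) || isTRUE(trials$missed[i + 1])) next
    key <- paste(ifelse(trials$reward[i] == 1, "rewarded", "unrewarded"),
                 trials$transition[i], sep = ".")
    got <- counts[[key]] %||% c(stays = 0, opp = 0)
    got["opp"] <- got["opp"] + 1
    if (trials$choice1[i + 1] == trials$choice1[i]) {
      got["stays"] <- got["stays"] + 1
    }
    counts[[key]] <- got
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Population draws for a cohort of agents with omega forced, matching
# the synthetic-cohort population means/SDs for the other parameters.
stay_signature_cohort <- function(omega_fix, n_sub, seed,
                                  cfg = task_config()) {
  sp <- cohort_spec()
  set.seed(derive_seed(seed, "stay-cohort-params"))
  th <- sapply(1:6, function(p) rnorm(n_sub, sp$param_means[p],
                                      sp$param_sds[p]))
  inv_logit <- function(z) 1 / (1 + exp(-z))
  tabs <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    p <- agent_params(inv_logit(th[s, 1]), exp(th[s, 2]),
                      inv_logit(th[s, 3]), exp(th[s, 4]),
                      inv_logit(th[s, 5]), omega_fix, th[s, 6])
    sseed <- derive_seed(seed, paste0("stay-subject-", s))
    w <- init_walk(cfg, derive_seed(sseed, "walk"))
    tabs[[s]] <- stay_table(simulate_subject(p, cfg, w, sseed))
  }
  tabs
}
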