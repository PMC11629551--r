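test_that("model-based values evaluate the transition structure", {
  expect_equal(mb_values(matrix(0, 2, 2), 0.7), c(0, 0))

  # q2 rows: A = (0.5, 0.0), B = (0.25, 0.75)
  q2 <- matrix(c(0.5, 0.25, 0.0, 0.75), 2, 2)
  expect_equal(mb_values(q2, 0.7), c(0.575, 0.675))

  # at p_common = 0.5 + eps the two options approach equality
  both <- mb_values(q2, 0.5)
  expect_equal(both[1], both[2])
  expect_equal(both[1], 0.5 * (0.5 + 0.75))
})

test_that("value update follows the stated order", {
  p <- agent_params(a1 = 0.5, a2 = 0.5, lam = 1)
  st <- update_after_trial(agent_state(), p,
                           list(choice1 = 0L, state2 = "A", choice2 = 0L,
                                reward = 1, missed = FALSE))
  expect_equal(st$q2[[1, 1]], 0.5)
  expect_equal(st$q_mf[1], 0.5)   # 0 + 0.5*0 (backup) + 0.5*1*1 (trace)
  expect_identical(st$prev_choice1, 0L)

  # zero learning rates change nothing but the perseveration memory
  p0 <- agent_params(a1 = 0, a2 = 0)
  st0 <- update_after_trial(agent_state(), p0,
                            list(choice1 = 1L, state2 = "B", choice2 = 1L,
                                 reward = 1, missed = FALSE))
  expect_equal(st0$q_mf, c(0, 0))
  expect_equal(as.numeric(st0$q2), rep(0, 4))
  expect_identical(st0$prev_choice1, 1L)

  # lam = 0: stage-1 value untouched from zero (delta1 = 0, no trace)
  pl <- agent_params(a1 = 0.5, a2 = 0.5, lam = 0)
  stl <- update_after_trial(agent_state(), pl,
                            list(choice1 = 0L, state2 = "A", choice2 = 0L,
                                 reward = 1, missed = FALSE))
  expect_equal(stl$q_mf[1], 0)
  expect_equal(stl$q2[[1, 1]], 0.5)

  # missed trial: values untouched, perseveration memory cleared
  stm <- update_after_trial(st, p, list(missed = TRUE))
  expect_identical(stm$q_mf, st$q_mf)
  expect_identical(stm$q2, st$q2)
  expect_true(is.na(stm$prev_choice1))
})

test_that("choice rules are softmax with the omega mixture", {
  st <- agent_state()
  expect_equal(choice_probs_stage1(st, agent_params(beta1 = 0, pi = 0), 0.7),
               c(0.5, 0.5))

  # Q_net = (1, 0), beta1 = 1 -> logistic
  st$q_mf <- c(1, 0)
  p <- choice_probs_stage1(st, agent_params(beta1 = 1, omega = 0, pi = 0),
                           0.7)
  expect_equal(p, c(exp(1), 1) / (1 + exp(1)), tolerance = 1e-12)

  # omega mixture degenerate when q_mf equals the MB values
  st2 <- agent_state()
  st2$q2 <- matrix(c(0.6, 0.2, 0.1, 0.4), 2, 2)
  st2$q_mf <- mb_values(st2$q2, 0.7)
  pars <- function(w) agent_params(beta1 = 3, omega = w, pi = 0)
  expect_equal(choice_probs_stage1(st2, pars(0), 0.7),
               choice_probs_stage1(st2, pars(1), 0.7))

  # stage 2: beta2 = 2 on q2 = (0.75, 0.25) -> logistic at 1
  st3 <- agent_state()
  st3$q2[2, ] <- c(0.75, 0.25)
  p2 <- choice_probs_stage2(st3, agent_params(beta2 = 2), "B")
  expect_equal(p2, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(choice_probs_stage2(st3, agent_params(beta2 = 0), "A"),
               c(0.5, 0.5))

  # softmax shift invariance
  st4 <- st3
  st4$q2[2, ] <- st3$q2[2, ] + 5
  expect_equal(choice_probs_stage2(st4, agent_params(beta2 = 2), "B"), p2)
})

test_that("choice probabilities are proper and values stay bounded", {
  for (seed in 1:25) {
    p <- random_agent_params(seed)
    st <- agent_state()
    trials <- random_trials(40, p_missed = 0.1, seed = seed + 100)
    for (i in seq_len(nrow(trials))) {
      p1 <- choice_probs_stage1(st, p, 0.7)
      p2 <- choice_probs_stage2(st, p, "A")
      expect_equal(sum(p1), 1, tolerance = 1e-12)
      expect_equal(sum(p2), 1, tolerance = 1e-12)
      expect_true(all(p1 > 0 & p1 < 1))
      st <- update_after_trial(st, p, trials[i, ])
      expect_true(all(st$q_mf >= 0 & st$q_mf <= 1))
      expect_true(all(st$q2 >= 0 & st$q2 <= 1))
    }
  }
})

test_that("value update matches a naive line-by-line oracle", {
  # replay comparison over many random parameter/trial draws
  for (seed in 1:40) {
    p <- random_agent_params(seed)
    trials <- random_trials(25, p_missed = 0.08, seed = seed + 500)
    cfg <- task_config(n_trials = 25L)
    expect_equal(session_loglik(p, trials, cfg),
                 oracle_session_loglik(p, trials, cfg$p_common),
                 tolerance = 1e-12)
  }
})

test_that("simulated subjects behave as the parameters dictate", {
  cfg <- task_config()
  walk <- init_walk(cfg, 1)

  # beta = 0 everywhere: coin-flip choices
  p0 <- agent_params(beta1 = 0, beta2 = 0, pi = 0)
  tr <- simulate_subject(p0, cfg, walk, 7)
  expect_equal(mean(tr$choice1), 0.5, tolerance = 0.11)

  # huge perseveration, no value sensitivity: always stay after trial 1
  pstick <- agent_params(beta1 = 0, pi = 50)
  trs <- simulate_subject(pstick, cfg, walk, 8)
  expect_true(all(trs$choice1[-1] == trs$choice1[1]))

  # determinism and equivalence with the generic-policy path
  expect_identical(simulate_subject(p0, cfg, walk, 9),
                   simulate_subject(p0, cfg, walk, 9))
  phyb <- agent_params(omega = 0.8, beta1 = 5, beta2 = 5)
  expect_identical(simulate_subject(phyb, cfg, walk, 10),
                   simulate_episode(twostepRL:::hybrid_policy(phyb, cfg),
                                    cfg, walk, 10))
})
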