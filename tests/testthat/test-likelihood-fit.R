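test_that("session likelihood handles the analytic cases", {
  cfg <- task_config()
  trials <- random_trials(200, seed = 3)
  flat <- agent_params(beta1 = 0, beta2 = 0, pi = 0)
  expect_equal(session_loglik(flat, trials, cfg), 400 * log(0.5),
               tolerance = 1e-10)
  expect_equal(session_loglik(flat, trials[0, ], cfg), 0)
  expect_lte(session_loglik(random_agent_params(1), trials, cfg), 0)

  shuffled <- trials[c(2, 1, 3:200), ]
  expect_error(session_loglik(flat, shuffled, cfg), "ordered")
})

test_that("likelihood is highest near the generating parameters", {
  # expected log-likelihood comparison at theta vs a perturbed theta
  cfg <- task_config(n_trials = 150)
  p_true <- agent_params(a1 = 0.5, beta1 = 5, a2 = 0.45, beta2 = 5,
                         lam = 0.6, omega = 0.7, pi = 0.2)
  p_off <- agent_params(a1 = 0.5, beta1 = 5, a2 = 0.45, beta2 = 5,
                        lam = 0.6, omega = 0.15, pi = 0.2)
  diffs <- vapply(1:50, function(s) {
    w <- init_walk(cfg, 5000 + s)
    tr <- simulate_subject(p_true, cfg, w, 6000 + s)
    session_loglik(p_true, tr, cfg) - session_loglik(p_off, tr, cfg)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("MAP fitting is deterministic and recovers a strong MB agent", {
  cfg <- task_config()
  p_true <- agent_params(omega = 0.9, beta1 = 5, beta2 = 5)
  tr <- simulate_subject(p_true, cfg, init_walk(cfg, 21), 22)
  fc <- fit_config(map_restarts = 4, seed = 5)
  f1 <- fit_map(tr, cfg, fc)
  f2 <- fit_map(tr, cfg, fc)
  expect_identical(f1$par, f2$par)
  expect_gt(f1$par[["omega"]], 0.5)
  expect_true(all(is.finite(f1$restart_values)))
  expect_lte(f1$loglik, 0)
})

test_that("a flat likelihood reverts the MAP estimate toward the prior", {
  cfg <- task_config(n_trials = 100)
  flat <- agent_params(beta1 = 0, beta2 = 0, pi = 0)
  tr <- simulate_subject(flat, cfg, init_walk(cfg, 31), 32)
  f <- fit_map(tr, cfg, fit_config(map_restarts = 4, seed = 6))
  # prior centre is logit^-1(0) = 0.5 on the unit-range parameters
  expect_equal(f$par[["omega"]], 0.5, tolerance = 0.2)
  expect_lt(f$par[["beta1"]], 1.5)
})

test_that("hierarchical fit: bookkeeping, exchangeability and shrinkage", {
  cfg <- task_config(n_trials = 80)
  p <- agent_params(omega = 0.7, beta1 = 4, beta2 = 4)
  base <- simulate_subject(p, cfg, init_walk(cfg, 41), 42)
  sessions <- list(S1 = base, S2 = base, S3 = base, S4 = base)
  fc <- fit_config(n_chains = 2, n_iter = 400, n_warmup = 200, seed = 3)
  fit <- fit_hierarchical(sessions, cfg, fc)

  expect_s3_class(fit, "hybrid_fit")
  expect_identical(fit$n_save_per_chain, 200L)
  expect_equal(dim(fit$omega_draws), c(400L, 4L))
  expect_true(all(c("rhat", "ess") %in% names(fit$diagnostics)))
  # every monitored quantity carries a diagnostic row
  expect_equal(nrow(fit$diagnostics), 14L + 4L)

  # identical data -> exchangeable subject posteriors
  om <- fit$estimates$omega
  expect_lt(max(om) - min(om), 0.12)

  # posterior summaries respect parameter ranges
  po <- fit$posterior
  for (nm in c("a1", "a2", "lam", "omega")) {
    rows <- po[po$parameter == nm, ]
    expect_true(all(rows$mean >= 0 & rows$mean <= 1))
    expect_true(all(rows$q2.5 <= rows$median & rows$median <= rows$q97.5))
  }
})

test_that("posterior omega table is well-formed and round-trips CSV", {
  cfg <- task_config(n_trials = 60)
  sessions <- lapply(1:5, function(s) {
    simulate_subject(agent_params(omega = 0.6), cfg, init_walk(cfg, s),
                     100 + s)
  })
  names(sessions) <- paste0("P", 1:5)
  fit <- fit_hybrid(sessions, method = "map", cfg = cfg,
                    fit_cfg = fit_config(map_restarts = 2, seed = 2))
  tab <- posterior_omega_table(fit)
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab$omega_hat >= 0 & tab$omega_hat <= 1))

  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$omega_hat, tab$omega_hat, tolerance = 1e-12)
  expect_identical(back$subject_id, tab$subject_id)
})

test_that("hybrid_fit methods expose the model sensibly", {
  cfg <- task_config(n_trials = 60)
  tr <- simulate_subject(agent_params(omega = 0.8, beta1 = 5), cfg,
                         init_walk(cfg, 9), 10)
  fit <- fit_hybrid(tr, method = "map", cfg = cfg,
                    fit_cfg = fit_config(map_restarts = 2, seed = 4))
  expect_output(print(fit), "map")
  expect_output(print(summary(fit)), "omega|parameters|subjects")
  expect_equal(dim(coef(fit)), c(1L, 7L))
  expect_s3_class(logLik(fit), "logLik")
  expect_equal(attr(logLik(fit), "df"), 7)

  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2L)
  expect_equal(nrow(sims[[1]]), 60L)

  pr <- predict(fit, tr)
  expect_length(pr[[1]], 60L)
  expect_true(all(pr[[1]] > 0 & pr[[1]] < 1))
  # fitted model should beat chance on its own training choices
  expect_gt(mean(log(pr[[1]])), log(0.5))
})
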