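#' Hierarchical Bayesian fit of a cohort of sessions
#'
#' Subject-level transformed parameters are modelled as
#' `theta_s ~ Normal(mu, diag(sigma^2))` with weakly informative
#' hyperpriors `mu_p ~ Normal(0, 1)` and `sigma_p ~ half-Normal(0, 1)`
#' on the transformed scales (logit for `a1`, `a2`, `lam`, `omega`; log
#' for `beta1`, `beta2`; identity for `pi`). Sampling is adaptive
#' Metropolis-within-Gibbs: joint random-walk proposals per subject
#' (likelihoods for the whole cohort evaluated in one C++ pass),
#' conjugate Gibbs draws for `mu`, and log-scale random-walk updates for
#' `sigma`. Proposal scales adapt during warm-up only.
#'
#' Convergence is summarised by split-R-hat and effective sample size
#' for every group-level quantity and every subject's `omega`; a fit
#' with any split-R-hat above `fit_cfg$rhat_threshold` is returned with
#' `converged = FALSE`, never suppressed.
#'
#' @param sessions named list of `trials` data frames (>= 2 subjects).
#' @param cfg a [task_config()].
#' @param fit_cfg a [fit_config()].
#' @return An object of class `hybrid_fit` (see [fit_hybrid()]).
#' @export
fit_hierarchical <- function(sessions, cfg, fit_cfg = fit_config()) {
  stopifnot(length(sessions) >= 2L)
  ids <- names(sessions) %||% paste0("S", seq_along(sessions))
  arrays <- cohort_arrays(sessions)
  ns <- length(sessions)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  n_save <- fit_cfg$n_iter - fit_cfg$n_warmup
  chains <- vector("list", fit_cfg$n_chains)
  for (ch in seq_len(fit_cfg$n_chains)) {
    set.seed(derive_seed(fit_cfg$seed, paste0("mcmc-chain-", ch)))
    chains[[ch]] <- run_chain(arrays, ns, cfg, fit_cfg$n_iter,
                              fit_cfg$n_warmup)
  }

  summaries <- summarize_chains(chains, ids, n_save)
  diagnostics <- summaries$diagnostics
  converged <- all(diagnostics$rhat < fit_cfg$rhat_threshold, na.rm = TRUE)

  estimates <- summaries$subject
  estimates$loglik <- as.numeric(
    loglik_cohort_cpp(as.matrix(estimates[, param_names]), arrays$offset,
                      arrays$len, arrays$choice1, arrays$state2,
                      arrays$choice2, arrays$reward, arrays$missed,
                      cfg$p_common, cfg$q_init))

  structure(list(method = "hierarchical", estimates = estimates,
                 posterior = summaries$posterior, group = summaries$group,
                 diagnostics = diagnostics, converged = converged,
                 omega_draws = summaries$omega_draws,
                 n_save_per_chain = n_save, cfg = cfg, fit_cfg = fit_cfg,
                 subject_ids = ids),
            class = "hybrid_fit")
}

cohort_arrays <- function(sessions) {
  parts <- lapply(sessions, trials_arrays)
  len <- vapply(parts, function(p) length(p$choice1), integer(1))
  list(offset = c(0L, cumsum(len)[-length(len)]), len = len,
       choice1 = unlist(lapply(parts, `[[`, "choice1"), use.names = FALSE),
       state2 = unlist(lapply(parts, `[[`, "state2"), use.names = FALSE),
       choice2 = unlist(lapply(parts, `[[`, "choice2"), use.names = FALSE),
       reward = unlist(lapply(parts, `[[`, "reward"), use.names = FALSE),
       missed = unlist(lapply(parts, `[[`, "missed"), use.names = FALSE))
}

cohort_loglik <- function(theta_mat, arrays, cfg) {
  nat <- t(apply(theta_mat, 1, to_natural))
  as.numeric(loglik_cohort_cpp(nat, arrays$offset, arrays$len,
                               arrays$choice1, arrays$state2, arrays$choice2,
                               arrays$reward, arrays$missed,
                               cfg$p_common, cfg$q_init))
}

run_chain <- function(arrays, ns, cfg, n_iter, n_warmup) {
  mu <- rnorm(7, 0, 0.5)
  sigma <- abs(rnorm(7, 0, 0.3)) + 0.3
  theta <- matrix(rnorm(ns * 7), ns, 7) %*% diag(sigma) +
    matrix(mu, ns, 7, byrow = TRUE)
  ll <- cohort_loglik(theta, arrays, cfg)
  step_subj <- matrix(0.4, ns, 7)   # per-subject, per-parameter scales
  step_sigma <- rep(0.3, 7)
  n_save <- n_iter - n_warmup
  save_mu <- matrix(NA_real_, n_save, 7)
  save_sigma <- matrix(NA_real_, n_save, 7)
  save_theta <- array(NA_real_, c(n_save, ns, 7))
  acc_subj <- matrix(0, ns, 7)
  acc_sigma <- numeric(7)
  window <- 0L

  for (it in seq_len(n_iter)) {
    # componentwise RW sweep: one parameter at a time, all subjects in
    # a single vectorised likelihood pass, accepted per subject
    for (p in seq_len(7)) {
      prop <- theta
      prop[, p] <- theta[, p] + rnorm(ns) * step_subj[, p]
      ll_prop <- cohort_loglik(prop, arrays, cfg)
      lr <- ll_prop - ll +
        dnorm(prop[, p], mu[p], sigma[p], log = TRUE) -
        dnorm(theta[, p], mu[p], sigma[p], log = TRUE)
      acc <- log(runif(ns)) < lr
      theta[acc, p] <- prop[acc, p]
      ll[acc] <- ll_prop[acc]
      acc_subj[, p] <- acc_subj[, p] + acc
    }

    # conjugate Gibbs for mu_p (prior N(0,1))
    for (p in seq_len(7)) {
      v <- 1 / (ns / sigma[p]^2 + 1)
      mu[p] <- rnorm(1, v * sum(theta[, p]) / sigma[p]^2, sqrt(v))
    }

    # log-scale RW for sigma_p (prior half-Normal(0,1))
    for (p in seq_len(7)) {
      s_prop <- sigma[p] * exp(rnorm(1, 0, step_sigma[p]))
      lr <- sum(dnorm(theta[, p], mu[p], s_prop, log = TRUE)) -
        sum(dnorm(theta[, p], mu[p], sigma[p], log = TRUE)) -
        s_prop^2 / 2 + sigma[p]^2 / 2 + log(s_prop) - log(sigma[p])
      if (log(runif(1)) < lr) {
        sigma[p] <- s_prop
        acc_sigma[p] <- acc_sigma[p] + 1
      }
    }

    # ancillary rescaling move: jointly scale sigma_p and the subject
    # deviations (non-centered step; breaks the funnel when the
    # likelihood is weakly informative). Subject-prior terms and the
    # theta-Jacobian cancel exactly; remaining ratio is likelihood x
    # half-Normal prior x the log-scale Jacobian.
    for (p in seq_len(7)) {
      cc <- exp(rnorm(1, 0, 0.15))
      prop <- theta
      prop[, p] <- mu[p] + cc * (theta[, p] - mu[p])
      ll_prop <- cohort_loglik(prop, arrays, cfg)
      s_prop <- cc * sigma[p]
      lr <- sum(ll_prop - ll) - s_prop^2 / 2 + sigma[p]^2 / 2 + log(cc)
      if (log(runif(1)) < lr) {
        theta[, p] <- prop[, p]
        ll <- ll_prop
        sigma[p] <- s_prop
      }
    }

    window <- window + 1L
    if (it <= n_warmup && window == 50L) {
      step_subj <- step_subj * exp(acc_subj / 50 - 0.44)
      step_sigma <- step_sigma * exp(acc_sigma / 50 - 0.44)
      acc_subj[] <- 0; acc_sigma[] <- 0; window <- 0L
    }
    if (it > n_warmup) {
      k <- it - n_warmup
      save_mu[k, ] <- mu
      save_sigma[k, ] <- sigma
      save_theta[k, , ] <- theta
    }
  }
  list(mu = save_mu, sigma = save_sigma, theta = save_theta)
}

summarize_chains <- function(chains, ids, n_save) {
  ns <- dim(chains[[1]]$theta)[2]
  nch <- length(chains)
  # natural-scale subject draws pooled over chains: (n_save*nch) x ns x 7
  nat <- lapply(chains, function(ch) {
    out <- ch$theta
    for (p in c(1, 3, 5, 6)) out[, , p] <- inv_logit(out[, , p])
    for (p in c(2, 4)) out[, , p] <- exp(out[, , p])
    out
  })
  pooled <- do.call(abind3, nat)

  subject <- data.frame(subject_id = ids)
  posterior <- NULL
  for (p in seq_len(7)) {
    draws <- pooled[, , p, drop = FALSE]
    subject[[param_names[p]]] <- apply(draws, 2, mean)
    posterior <- rbind(posterior, data.frame(
      subject_id = ids, parameter = param_names[p],
      mean = apply(draws, 2, mean), median = apply(draws, 2, median),
      q2.5 = apply(draws, 2, quantile, 0.025),
      q97.5 = apply(draws, 2, quantile, 0.975), row.names = NULL))
  }

  group <- NULL
  diagnostics <- NULL
  for (p in seq_len(7)) {
    for (what in c("mu", "sigma")) {
      dmat <- sapply(chains, function(ch) ch[[what]][, p])
      group <- rbind(group, data.frame(
        quantity = sprintf("%s[%s]", what, param_names[p]),
        mean = mean(dmat), median = median(dmat),
        q2.5 = quantile(dmat, 0.025), q97.5 = quantile(dmat, 0.975),
        row.names = NULL))
      diagnostics <- rbind(diagnostics, data.frame(
        quantity = sprintf("%s[%s]", what, param_names[p]),
        rhat = split_rhat(dmat), ess = ess_basic(dmat), row.names = NULL))
    }
  }
  for (s in seq_len(ns)) {
    dmat <- sapply(nat, function(a) a[, s, 6])
    diagnostics <- rbind(diagnostics, data.frame(
      quantity = sprintf("omega[%s]", ids[s]),
      rhat = split_rhat(dmat), ess = ess_basic(dmat), row.names = NULL))
  }
  omega_draws <- pooled[, , 6]
  if (is.null(dim(omega_draws))) omega_draws <- matrix(omega_draws, ncol = ns)
  colnames(omega_draws) <- ids
  list(subject = subject, posterior = posterior, group = group,
       diagnostics = diagnostics, omega_draws = omega_draws)
}

abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, c(sum(vapply(parts, function(x) dim(x)[1], 0)),
                           d[2], d[3]))
  at <- 0L
  for (x in parts) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain
#' in half (detects within-chain trends as well as between-chain
#' disagreement).
#'
#' @param draws iterations x chains matrix of post-warm-up draws.
#' @return Scalar R-hat (1 at perfect mixing); `NA` for degenerate draws.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  sp <- cbind(draws[seq_len(half), , drop = FALSE],
              draws[n - half + seq_len(half), , drop = FALSE])
  m <- ncol(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, var)
  w <- mean(vars)
  b <- half * var(means)
  if (!is.finite(w) || w <= 0) return(NA_real_)
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' Effective sample size (initial positive sequence estimator)
#'
#' @param draws iterations x chains matrix of post-warm-up draws.
#' @return Estimated number of independent draws.
#' @export
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4) return(NA_real_)
  ac <- sapply(seq_len(m), function(j) {
    x <- draws[, j] - mean(draws[, j])
    a <- stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE,
                    demean = FALSE)$acf[, 1, 1]
    if (a[1] <= 0) rep(0, length(a) - 1) else a[-1] / a[1]
  })
  rho <- rowMeans(as.matrix(ac))
  s <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, (n * m) / (1 + 2 * s))
}

#' Fit the hybrid MF/MB model to one or more sessions
#'
#' Front end for model fitting. `method = "map"` runs an independent
#' maximum-a-posteriori fit per subject ([fit_map()]); `method =
#' "hierarchical"` runs the joint hierarchical Bayesian fit
#' ([fit_hierarchical()]). Returns a classed object with `print`,
#' `summary`, `coef`, `logLik`, `plot`, `predict` and `simulate`
#' methods.
#'
#' @param sessions a single `trials` data frame or a (named) list of
#'   them, one per subject.
#' @param method `"map"` or `"hierarchical"`.
#' @param cfg a [task_config()].
#' @param fit_cfg a [fit_config()].
#' @return An object of class `hybrid_fit` with at least: `method`,
#'   `estimates` (per-subject point estimates of the 7 parameters plus
#'   log-likelihood), `converged`, and for hierarchical fits `posterior`
#'   (per-subject summaries), `group` (hyperparameter summaries) and
#'   `diagnostics` (split-R-hat, ESS).
#' @examples
#' cfg <- task_config(n_trials = 60)
#' tr <- simulate_subject(agent_params(omega = 0.8), cfg, init_walk(cfg, 1), 2)
#' fit <- fit_hybrid(tr, method = "map", cfg = cfg,
#'                   fit_cfg = fit_config(map_restarts = 2))
#' coef(fit)
#' @export
fit_hybrid <- function(sessions, method = c("map", "hierarchical"),
                       cfg = task_config(), fit_cfg = fit_config()) {
  method <- match.arg(method)
  if (is.data.frame(sessions)) sessions <- list(S1 = sessions)
  if (is.null(names(sessions))) {
    names(sessions) <- paste0("S", seq_along(sessions))
  }
  if (method == "hierarchical") {
    return(fit_hierarchical(sessions, cfg, fit_cfg))
  }
  rows <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    sub_cfg <- fit_cfg
    sub_cfg$seed <- derive_seed(fit_cfg$seed, paste0("map-subject-", i))
    f <- fit_map(sessions[[i]], cfg, sub_cfg)
    rows[[i]] <- data.frame(subject_id = names(sessions)[i],
                            as.list(unclass(f$par)),
                            loglik = f$loglik, converged = f$converged)
  }
  estimates <- do.call(rbind, rows)
  structure(list(method = "map", estimates = estimates,
                 converged = all(estimates$converged),
                 cfg = cfg, fit_cfg = fit_cfg,
                 subject_ids = estimates$subject_id),
            class = "hybrid_fit")
}

#' Per-subject table of the model-based weight
#'
#' @param fit a `hybrid_fit`.
#' @return Data frame with `subject_id`, `omega_hat` (posterior mean, or
#'   MAP estimate for MAP fits) and, for hierarchical fits, the 95%
#'   posterior interval (`lo`, `hi`).
#' @export
posterior_omega_table <- function(fit) {
  stopifnot(inherits(fit, "hybrid_fit"))
  out <- data.frame(subject_id = fit$estimates$subject_id,
                    omega_hat = fit$estimates$omega)
  if (fit$method == "hierarchical") {
    po <- fit$posterior[fit$posterior$parameter == "omega", ]
    out$lo <- po$q2.5[match(out$subject_id, po$subject_id)]
    out$hi <- po$q97.5[match(out$subject_id, po$subject_id)]
  }
  out
}

#' @export
print.hybrid_fit <- function(x, ...) {
  cat(sprintf("Hybrid MF/MB model fit (%s), %d subject(s)\n",
              x$method, nrow(x$estimates)))
  cat(sprintf("  mean omega: %.3f   total log-likelihood: %.1f\n",
              mean(x$estimates$omega), sum(x$estimates$loglik)))
  if (!x$converged) cat("  WARNING: fit flagged non-converged\n")
  invisible(x)
}

#' @export
summary.hybrid_fit <- function(object, ...) {
  est <- object$estimates[, param_names]
  tab <- t(apply(est, 2, function(v) {
    c(mean = mean(v), sd = sd(v), median = median(v),
      min = min(v), max = max(v))
  }))
  out <- list(method = object$method, n_subjects = nrow(est),
              parameters = tab, converged = object$converged,
              diagnostics = object$diagnostics)
  class(out) <- "summary.hybrid_fit"
  out
}

#' @export
print.summary.hybrid_fit <- function(x, ...) {
  cat(sprintf("Hybrid model fit (%s), %d subjects\n", x$method, x$n_subjects))
  print(round(x$parameters, 3))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("max split-Rhat: %.3f   min ESS: %.0f\n",
                max(x$diagnostics$rhat, na.rm = TRUE),
                min(x$diagnostics$ess, na.rm = TRUE)))
  }
  if (!x$converged) cat("WARNING: fit flagged non-converged\n")
  invisible(x)
}

#' @export
coef.hybrid_fit <- function(object, ...) {
  m <- as.matrix(object$estimates[, param_names])
  rownames(m) <- object$estimates$subject_id
  m
}

#' @export
logLik.hybrid_fit <- function(object, ...) {
  structure(sum(object$estimates$loglik),
            df = 7 * nrow(object$estimates), class = "logLik")
}

#' @export
plot.hybrid_fit <- function(x, truth = NULL, ...) {
  est <- posterior_omega_table(x)
  if (!is.null(truth)) {
    plot(truth, est$omega_hat, xlab = "true omega",
         ylab = "estimated omega", xlim = 0:1, ylim = 0:1,
         main = "Parameter recovery", ...)
    abline(0, 1, lty = 2)
  } else {
    o <- order(est$omega_hat)
    plot(seq_along(o), est$omega_hat[o], ylim = 0:1, pch = 19,
         xlab = "subject (sorted)", ylab = "omega", ...)
    if (!is.null(est$lo)) {
      segments(seq_along(o), est$lo[o], seq_along(o), est$hi[o])
    }
  }
  invisible(x)
}

#' Simulate sessions from a fitted model
#'
#' Draws `nsim` synthetic sessions per fitted subject at the subject's
#' point estimates, each with a fresh reward walk.
#'
#' @param object a `hybrid_fit`.
#' @param nsim sessions per subject.
#' @param seed integer master seed.
#' @param ... unused.
#' @return Named list of `trials` data frames
#'   (`<subject_id>.<replicate>`).
#' @export
simulate.hybrid_fit <- function(object, nsim = 1, seed = 1, ...) {
  out <- list()
  for (i in seq_len(nrow(object$estimates))) {
    par <- do.call(agent_params,
                   as.list(object$estimates[i, param_names]))
    for (r in seq_len(nsim)) {
      s <- derive_seed(seed, sprintf("sim-%d-%d", i, r))
      walk <- init_walk(object$cfg, derive_seed(s, "walk"))
      out[[sprintf("%s.%d", object$estimates$subject_id[i], r)]] <-
        simulate_subject(par, object$cfg, walk, s)
    }
  }
  out
}

#' Predicted stage-1 choice probabilities for observed sessions
#'
#' Replays each session with the subject's fitted parameters and
#' returns the model's trial-by-trial probability of the choice the
#' subject actually made at stage 1.
#'
#' @param object a `hybrid_fit`.
#' @param newdata a `trials` data frame or named list of them; names
#'   must match fitted subject ids (a single data frame is paired with
#'   the first subject).
#' @param ... unused.
#' @return Named list of numeric vectors (NA for missed trials).
#' @export
predict.hybrid_fit <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- setNames(list(newdata), object$estimates$subject_id[1])
  }
  out <- list()
  for (id in names(newdata)) {
    i <- match(id, object$estimates$subject_id)
    if (is.na(i)) stop_config("no fitted subject '%s'", id)
    par <- do.call(agent_params, as.list(object$estimates[i, param_names]))
    trials <- newdata[[id]]
    st <- agent_state(object$cfg$q_init)
    pr <- rep(NA_real_, nrow(trials))
    for (k in seq_len(nrow(trials))) {
      if (!isTRUE(trials$missed[k])) {
        p1 <- choice_probs_stage1(st, par, object$cfg$p_common)
        pr[k] <- p1[trials$choice1[k] + 1L]
      }
      st <- update_after_trial(st, par, trials[k, ])
    }
    out[[id]] <- pr
  }
  out
}
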