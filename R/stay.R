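#' Stay-probability table for one session
#'
#' For every pair of consecutive non-missed trials, the second trial is
#' a "stay" if the stage-1 choice repeats. Stays are binned by the
#' previous trial's outcome (rewarded / unrewarded) and transition
#' (common / rare); the reward x transition interaction of the
#' resulting four cells is the classic model-based signature, while a
#' pure model-free learner shows only a reward main effect. Pairs that
#' span a missed trial are dropped, not bridged.
#'
#' @param trials a `trials` data frame with >= 2 non-missed trials.
#' @return A `stay_table` data frame with one row per cell: `reward`
#'   (`"rewarded"`/`"unrewarded"`), `transition`, `stays`,
#'   `opportunities`, `p_stay`.
#' @export
stay_table <- function(trials) {
  ok <- !(trials$missed %in% TRUE)
  if (sum(ok) < 2L) stop_config("need >= 2 non-missed trials")
  i <- which(ok[-nrow(trials)] & ok[-1])  # consecutive non-missed pairs
  if (length(i) == 0L) stop_config("no consecutive non-missed trial pairs")
  prev_rew <- factor(ifelse(trials$reward[i] == 1, "rewarded", "unrewarded"),
                     levels = c("rewarded", "unrewarded"))
  prev_tr <- factor(trials$transition[i], levels = c("common", "rare"))
  stay <- trials$choice1[i + 1L] == trials$choice1[i]
  cells <- expand.grid(reward = levels(prev_rew),
                       transition = levels(prev_tr),
                       stringsAsFactors = FALSE)
  cells$stays <- NA_integer_
  cells$opportunities <- NA_integer_
  for (r in seq_len(nrow(cells))) {
    in_cell <- prev_rew == cells$reward[r] & prev_tr == cells$transition[r]
    cells$opportunities[r] <- sum(in_cell)
    cells$stays[r] <- sum(stay[in_cell])
  }
  cells$p_stay <- ifelse(cells$opportunities > 0,
                         cells$stays / cells$opportunities, NA_real_)
  class(cells) <- c("stay_table", "data.frame")
  cells
}

#' Reward, transition and interaction contrasts across stay tables
#'
#' Pools the per-subject cell counts and fits a binomial logistic
#' regression of staying on previous reward, previous transition and
#' their interaction, with +-1/2 effects coding, so the coefficients are
#' the log-odds main effects and the crossover interaction. Complete
#' separation (e.g. an all-stay cohort) is detected and flagged rather
#' than trusted.
#'
#' @param tables a `stay_table` or list of them (one per subject).
#' @return A `stay_contrasts` data frame: one row per effect
#'   (`reward`, `transition`, `reward_x_transition`) with `estimate`,
#'   `se`, `ci_lo`, `ci_hi`, plus an attribute `separation` (logical).
#' @export
stay_contrasts <- function(tables) {
  if (inherits(tables, "stay_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  pooled <- do.call(rbind, lapply(tables, as.data.frame))
  agg <- stats::aggregate(cbind(stays, opportunities) ~ reward + transition,
                          data = pooled, FUN = sum)
  x_rew <- ifelse(agg$reward == "rewarded", 0.5, -0.5)
  x_tr <- ifelse(agg$transition == "common", 0.5, -0.5)
  fit <- suppressWarnings(glm(
    cbind(agg$stays, agg$opportunities - agg$stays) ~ x_rew * x_tr,
    family = binomial()))
  cf <- summary(fit)$coefficients
  mu_hat <- fit$fitted.values
  separation <- !fit$converged || any(abs(cf[, "Estimate"]) > 15) ||
    any(mu_hat > 1 - 1e-8) || any(mu_hat < 1e-8)
  rows <- c("x_rew", "x_tr", "x_rew:x_tr")
  out <- data.frame(
    effect = c("reward", "transition", "reward_x_transition"),
    estimate = cf[rows, "Estimate"], se = cf[rows, "Std. Error"],
    row.names = NULL)
  out$ci_lo <- out$estimate - 1.96 * out$se
  out$ci_hi <- out$estimate + 1.96 * out$se
  attr(out, "separation") <- separation
  class(out) <- c("stay_contrasts", "data.frame")
  out
}

#' @export
print.stay_contrasts <- function(x, ...) {
  cat("Stay-probability contrasts (log-odds, effects coded +-1/2)\n")
  print.data.frame(x, digits = 3)
  if (isTRUE(attr(x, "separation"))) {
    cat("NOTE: separation detected; estimates unreliable\n")
  }
  invisible(x)
}

#' @export
plot.stay_table <- function(x, ...) {
  p <- matrix(x$p_stay[order(x$transition, x$reward)], 2,
              dimnames = list(c("rewarded", "unrewarded"),
                              c("common", "rare")))
  graphics::barplot(t(p), beside = TRUE, ylim = c(0, 1),
                    ylab = "P(stay)", legend.text = colnames(p), ...)
  invisible(x)
}
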