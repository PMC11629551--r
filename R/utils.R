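logit <- function(p) log(p) - log1p(-p)
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Derive a per-stage random seed from a master seed
#'
#' Every stochastic stage of the pipeline (reward walk, transitions,
#' rewards, choices, cohort latents, fitting) receives its own seed
#' derived from one master seed by a stable string-hash rule, so any
#' single component can be regenerated independently of the others.
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"walk"`, `"transition"`.
#' @return An integer seed in `[0, 2^31 - 1)`, deterministic in
#'   `(master, stage)`.
#' @examples
#' derive_seed(42, "walk")
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (as.numeric(master) %% 2147483647) * 2654435) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
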