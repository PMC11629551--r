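#' Cortisol stress variables from the four-sample panel
#'
#' Salivary cortisol is sampled four times: on arrival (C1), after task
#' instructions (C2), 10 min after the stress/control procedure (C3)
#' and after the task (C4). The analysis variables are
#' `pre = ln(mean(C1, C2))`, `post = ln(mean(C3, C4))` and the cortisol
#' increase `d_cort = post - pre` (log units). Averaging precedes the
#' log transform; `d_cort` is therefore a log-ratio and invariant to
#' unit rescaling. A missing member of a pair is tolerated (the
#' available sample is used); a fully missing pair makes the subject
#' unusable for cortisol-dependent analyses.
#'
#' @param panel named list or vector with `c1`..`c4` in nmol/l
#'   (positive; `NA` allowed).
#' @return List with `pre`, `post`, `d_cort` (all `NA` with
#'   `usable = FALSE` if a pair is fully missing).
#' @examples
#' stress_variables(c(c1 = 6, c2 = 4, c3 = 8, c4 = 6))
#' @export
stress_variables <- function(panel) {
  p <- as.list(panel)
  v <- c(p$c1 %||% NA, p$c2 %||% NA, p$c3 %||% NA, p$c4 %||% NA)
  v <- as.numeric(v)
  if (any(!is.na(v) & v <= 0)) {
    stop_config("cortisol concentrations must be positive")
  }
  pre_s <- v[1:2][!is.na(v[1:2])]
  post_s <- v[3:4][!is.na(v[3:4])]
  if (length(pre_s) == 0L || length(post_s) == 0L) {
    return(list(pre = NA_real_, post = NA_real_, d_cort = NA_real_,
                usable = FALSE))
  }
  pre <- log(mean(pre_s))
  post <- log(mean(post_s))
  list(pre = pre, post = post, d_cort = post - pre, usable = TRUE)
}

#' Change in a visual-analogue-scale rating
#'
#' @param pre_rating,post_rating ratings on the 0-10 VAS.
#' @return `post_rating - pre_rating` (in \[-10, 10\]).
#' @export
vas_change <- function(pre_rating, post_rating) {
  if (any(c(pre_rating, post_rating) < 0 | c(pre_rating, post_rating) > 10,
          na.rm = TRUE)) {
    stop_config("VAS ratings must lie in [0, 10]")
  }
  post_rating - pre_rating
}
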