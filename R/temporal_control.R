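# Temporal control: per-step bottom-up onset probability from the loudness
# derivative, top-down lexical onset prediction from the word posterior,
# a hard refractory term, and their BU-only / AND / OR fusion.

#' Default model parameters
#'
#' All tunable parameters of the model with their defaults: decision
#' threshold 0.4, refractory period 50 steps, accumulator leak 0.005/step,
#' top-down kernel width 7.5 steps, bottom-up detector (window 5 steps,
#' 3 consecutive positive derivatives required, rise threshold 0.1,
#' logistic gain 60, floor probability 0.01), F-score half window 15 steps,
#' trailing silence pad 100 steps, and the lexical-matrix smoothing 0.02.
#'
#' @param ... Named overrides of individual defaults.
#' @return Named list of parameters.
#' @export
default_params <- function(...) {
  p <- list(threshold = 0.4, refractory = 50L, leak = 0.005, sigma_td = 7.5,
            bu_window = 5L, bu_run = 3L, theta_rise = 0.1, bu_gain = 60,
            p_floor = 0.01, half_window = 15L, pad = 100L, smoothing = 0.02)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  p
}

#' Bottom-up onset probability
#'
#' Tracks rapid loudness increases: an onset is probable when the loudness
#' derivative has been positive for at least `bu_run` consecutive steps and
#' the cumulative rise R (sum of positive derivatives over the last
#' `bu_window` steps) exceeds the rise threshold. Then
#' `p_bu = logistic(gain * (R - theta_rise))`, otherwise the floor.
#'
#' @param delta_history Recent loudness-derivative values, most recent last
#'   (zero-padded internally if shorter than the window).
#' @param params [default_params()] list.
#' @return Scalar probability in \[0, 1\].
#' @export
bottom_up_prob <- function(delta_history, params = default_params()) {
  w <- params$bu_window
  h <- c(rep(0, max(0, w - length(delta_history))), utils::tail(delta_history, w))
  recent <- utils::tail(h, params$bu_run)
  if (!all(recent > 0)) return(params$p_floor)
  R <- sum(pmax(h, 0))
  stats::plogis(params$bu_gain * (R - params$theta_rise))
}

# Whole-trace version used by run_trial (vectorized over all steps).
.bottom_up_trace <- function(dL, params) {
  w <- params$bu_window
  pos <- dL > 0
  run <- integer(length(dL))
  r <- 0L
  for (i in seq_along(pos)) {
    r <- if (pos[i]) r + 1L else 0L
    run[i] <- r
  }
  cp <- cumsum(pmax(dL, 0))
  R <- cp - c(rep(0, w), utils::head(cp, -w))
  ifelse(run >= params$bu_run,
         stats::plogis(params$bu_gain * (R - params$theta_rise)),
         params$p_floor)
}

#' Refractory probability
#'
#' Hard post-detection veto: 0 while fewer than `refractory` steps have
#' elapsed since the last detected onset, 1 otherwise (half-open window:
#' exactly `refractory` steps after an onset, detection is allowed again).
#'
#' @param t Current time step (origin 0).
#' @param last_onset Time of the last detected onset, or `NA`/`NULL`.
#' @param refractory Refractory length in steps (default 50).
#' @return 0 or 1.
#' @export
refractory_prob <- function(t, last_onset, refractory = 50L) {
  if (is.null(last_onset) || is.na(last_onset)) return(1)
  if (t - last_onset < refractory) 0 else 1
}

#' Top-down lexical onset probability
#'
#' Words predict syllabic onsets at their canonical instants, weighted by
#' their current posterior probability:
#' `p_td(t) = sum_w P(w) K(t; onsets(w))`, where K is a sum of Gaussian
#' bumps of height 1 and width `sigma_td` centered on each canonical onset
#' (clipped to at most 1 per word).
#'
#' @param word_posterior Probability vector over the 28 words (the previous
#'   step's word accumulator state).
#' @param t Time step (origin 0); may be a vector.
#' @param lexicon A [build_lexicon()] object.
#' @param sigma_td Kernel width in steps (default 7.5).
#' @return Probability value(s) in \[0, 1\].
#' @export
top_down_prob <- function(word_posterior, t, lexicon, sigma_td = 7.5) {
  K <- vapply(lexicon$onsets, function(on) {
    pmin(1, rowSums(exp(-outer(t, on, "-")^2 / (2 * sigma_td^2))))
  }, numeric(length(t)))
  if (length(t) == 1L) sum(K * word_posterior) else
    as.vector(matrix(K, nrow = length(t)) %*% word_posterior)
}

# Per-trial bump matrix: T x 28, column w = clipped bump kernel of word w.
.onset_bumps <- function(lexicon, T, sigma_td) {
  tt <- 0:(T - 1L)
  vapply(lexicon$onsets, function(on)
    pmin(1, rowSums(exp(-outer(tt, on, "-")^2 / (2 * sigma_td^2)))),
    numeric(T))
}

#' Fuse onset probabilities
#'
#' Combines the bottom-up, top-down and refractory terms: `bu_only` ignores
#' the top-down branch (`p_bu * p_ref`), `and` is conjunctive
#' (`p_td * p_bu * p_ref`: the top-down branch can veto spurious events),
#' `or` is a noisy-or (`(1 - (1 - p_td)(1 - p_bu)) * p_ref`: the top-down
#' branch can rescue missed events).
#'
#' @param p_bu,p_td,p_ref Probabilities in \[0, 1\] (vectorized).
#' @param mode One of `"bu_only"`, `"and"`, `"or"`.
#' @return Combined onset probability.
#' @export
fuse_onset <- function(p_bu, p_td, p_ref, mode = c("bu_only", "and", "or")) {
  mode <- match.arg(mode)
  switch(mode,
         bu_only = p_bu * p_ref,
         and = p_td * p_bu * p_ref,
         or = (1 - (1 - p_td) * (1 - p_bu)) * p_ref)
}

#' Count suprathreshold episodes of a probability trace
#'
#' Number of maximal runs of consecutive steps on which the trace is at or
#' above the threshold. Used e.g. to count distinct top-down onset
#' predictions in a trial.
#'
#' @param p Numeric trace.
#' @param threshold Episode threshold (default 0.4).
#' @return Integer count.
#' @export
count_episodes <- function(p, threshold = 0.4) {
  above <- p >= threshold
  sum(above & !c(FALSE, utils::head(above, -1)))
}
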