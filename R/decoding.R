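# Feed-forward decoding hierarchy: 12 phone accumulators (3 banks of 4
# slots), 3 syllable accumulators and 1 word accumulator, connected by
# gated ("controlled coherence") evidence propagation with a slow leak
# toward uniform. Gates are driven by the temporal-control module; a closed
# decoder only leaks.

#' Create a uniform accumulator
#'
#' An accumulator (decoder) is a probability vector over a discrete domain
#' plus a gate value in \[0, 1\]: the probability that the associated
#' control variable is open, used to temper incoming likelihoods.
#'
#' @param domain Character vector of category names.
#' @param gate Initial gate value (default 0, closed).
#' @return List with `prob` (named, uniform) and `gate`.
#' @export
new_accumulator <- function(domain, gate = 0) {
  list(prob = stats::setNames(rep(1 / length(domain), length(domain)), domain),
       gate = gate)
}

#' One accumulator update
#'
#' Leaky tempered-Bayes step: the posterior is mixed toward uniform at rate
#' `leak`, then multiplied by `likelihood^gate` and renormalized (gate 0
#' ignores the evidence, gate 1 applies it fully -- the "Bayesian
#' potentiometer"). Probabilities are floored at 1e-12 before
#' renormalization.
#'
#' @param acc Accumulator from [new_accumulator()].
#' @param likelihood Nonnegative vector over the same domain.
#' @param leak Leak rate in \[0, 1\] (default 0.005 per step).
#' @return Updated accumulator (gate unchanged).
#' @export
accumulator_step <- function(acc, likelihood, leak = 0.005) {
  n <- length(acc$prob)
  if (length(likelihood) != n)
    stop("likelihood length does not match accumulator domain")
  if (acc$gate > 0 && all(likelihood <= 0))
    stop("degenerate likelihood: all-zero evidence on an open decoder")
  p <- (1 - leak) * acc$prob + leak / n
  if (acc$gate > 0) p <- p * likelihood^acc$gate
  p <- pmax(p, 1e-12)
  acc$prob <- p / sum(p)
  acc
}

#' Syllable evidence from a phone bank
#'
#' Likelihood over syllable tokens given the phone accumulators of the
#' active bank: the product over the phone slots opened so far of the
#' expected mapping probability under each slot's posterior,
#' l(s) = prod_j sum_f P_j(f) M_pho\[j\](f, s).
#'
#' @param phone_probs 7 x 4 matrix of phone-slot posteriors (columns are
#'   slots).
#' @param n_open Number of slots opened so far (1--4).
#' @param lexicon A [build_lexicon()] object.
#' @return Named likelihood vector over the syllable inventory.
#' @export
syllable_evidence <- function(phone_probs, n_open, lexicon) {
  ell <- rep(1, length(lexicon$inventory))
  for (j in seq_len(n_open))
    ell <- ell * as.vector(crossprod(lexicon$M_pho[[j]], phone_probs[, j]))
  stats::setNames(ell, lexicon$inventory)
}

#' Word evidence from a syllable accumulator
#'
#' Likelihood over the 28 words given one syllable decoder's posterior,
#' l(w) = sum_s P(s) M_syl\[i\](s, w). During decoding the word accumulator
#' receives the product of this term over every syllable decoder opened so
#' far (closed decoders keep constraining word identity through their
#' frozen, slowly leaking posterior).
#'
#' @param syll_prob Posterior vector over the syllable inventory.
#' @param decoder_index Active syllable position (1--3).
#' @param lexicon A [build_lexicon()] object.
#' @return Named likelihood vector over words.
#' @export
word_evidence <- function(syll_prob, decoder_index, lexicon) {
  stats::setNames(as.vector(crossprod(lexicon$M_syl[[decoder_index]], syll_prob)),
                  lexicon$words$label)
}

#' Initial model state
#'
#' The full decoder bank: 3 x 4 phone accumulators over the 7 phones, 3
#' syllable accumulators over the syllable inventory, 1 word accumulator
#' over the 28 words (uniform prior), plus the gating bookkeeping (active
#' syllable index, decoder opening times, last detected onset).
#'
#' @param lexicon A [build_lexicon()] object.
#' @return Object of class `"model_state"`.
#' @export
new_model_state <- function(lexicon) {
  n_tok <- length(lexicon$inventory)
  structure(list(
    phone = lapply(1:3, function(i)
      matrix(1 / 7, 7L, 4L, dimnames = list(phone_symbols, NULL))),
    syll = matrix(1 / n_tok, n_tok, 3L, dimnames = list(lexicon$inventory, NULL)),
    word = stats::setNames(rep(1 / nrow(lexicon$words), nrow(lexicon$words)),
                           lexicon$words$label),
    active = 0L,            # 0 = no syllable decoder open yet (or all closed)
    open_time = rep(NA_integer_, 3L),
    activated = rep(FALSE, 3L),
    last_onset = NA_integer_,
    t = 0L), class = "model_state")
}

# Hot-path update shared by decoding_step() and run_trial(): applies the
# leak everywhere, then evidence to the active slot/decoders. `lik` is the
# 7-vector of phone likelihoods at the current input. Operates on and
# returns the plain state list. Time inside `state$t` is origin-0.
.decode_update <- function(state, lik, lexicon, leak = 0.005) {
  n_tok <- nrow(state$syll)
  n_w <- length(state$word)
  for (b in 1:3) state$phone[[b]] <- (1 - leak) * state$phone[[b]] + leak / 7
  state$syll <- (1 - leak) * state$syll + leak / n_tok
  state$word <- (1 - leak) * state$word + leak / n_w
  a <- state$active
  if (a >= 1L && a <= 3L) {
    slot <- min(4L, (state$t - state$open_time[a]) %/% 50L + 1L)
    p <- state$phone[[a]][, slot] * lik
    p <- pmax(p, 1e-12)
    state$phone[[a]][, slot] <- p / sum(p)
    ell_s <- rep(1, n_tok)
    for (j in seq_len(slot))
      ell_s <- ell_s * as.vector(crossprod(lexicon$M_pho[[j]],
                                           state$phone[[a]][, j]))
    ps <- state$syll[, a] * ell_s
    ps <- pmax(ps, 1e-12)
    state$syll[, a] <- ps / sum(ps)
  }
  if (any(state$activated)) {
    ell_w <- rep(1, n_w)
    for (i in which(state$activated))
      ell_w <- ell_w * as.vector(crossprod(lexicon$M_syl[[i]], state$syll[, i]))
    pw <- state$word * ell_w
    pw <- pmax(pw, 1e-12)
    state$word <- pw / sum(pw)
  }
  state$t <- state$t + 1L
  state
}

#' One feed-forward decoding step
#'
#' Updates the model state with one time step of input: the active phone
#' slot accumulates the phone likelihood of the input point (slots advance
#' every 50 steps, capped at slot 4), the active syllable accumulator
#' receives [syllable_evidence()] over the opened slots, the word
#' accumulator receives [word_evidence()] from the active syllable decoder,
#' and all closed decoders only leak. Gates are assumed to have been set by
#' the temporal-control decision of the previous step.
#'
#' @param state A [new_model_state()] object.
#' @param input_point Length-2 (F1, F2) input.
#' @param lexicon A [build_lexicon()] object.
#' @param leak Leak rate per step.
#' @return The updated state.
#' @export
decoding_step <- function(state, input_point, lexicon, leak = 0.005) {
  .decode_update(state, phone_likelihood(input_point)[, 1], lexicon, leak)
}

# Gate bookkeeping when an onset fires at time t (origin 0): the active
# syllable decoder (and its phone bank) closes; the next one, if any, opens
# with its first phone slot effective at t + 1. Onsets past the third
# decoder only close; further onsets are recorded but change no gates.
.apply_onset <- function(state, t) {
  a <- state$active
  nxt <- if (a < 3L) a + 1L else 0L
  state$active <- nxt
  if (nxt > 0L) {
    state$open_time[nxt] <- t + 1L
    state$activated[nxt] <- TRUE
  }
  state$last_onset <- as.integer(t)
  state
}
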