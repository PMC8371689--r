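test_that("accumulator updates implement leaky tempered Bayes", {
  acc <- new_accumulator(letters[1:5], gate = 0)
  lik <- c(5, 1, 1, 1, 1)
  # closed gate, no leak: posterior untouched
  expect_equal(accumulator_step(acc, lik, leak = 0)$prob, acc$prob)
  # open gate, uniform prior, no leak: normalized likelihood
  acc1 <- new_accumulator(letters[1:5], gate = 1)
  expect_equal(unname(accumulator_step(acc1, lik, leak = 0)$prob), lik / sum(lik))
  expect_error(accumulator_step(acc1, rep(0, 5)), "degenerate")
  expect_error(accumulator_step(acc1, rep(1, 4)), "length")
})

test_that("closed decoders converge to uniform geometrically at rate 1 - leak", {
  acc <- new_accumulator(letters[1:4], gate = 0)
  acc$prob <- c(a = 0.97, b = 0.01, c = 0.01, d = 0.01)
  leak <- 0.02
  tv <- numeric(30)
  for (i in 1:30) {
    acc <- accumulator_step(acc, rep(1, 4), leak = leak)
    tv[i] <- sum(abs(acc$prob - 0.25)) / 2
  }
  expect_equal(tv[-1] / tv[-30], rep(1 - leak, 29))
  expect_lt(tv[30], 0.4)
})

test_that("with no leak and open gate, accumulation equals the product of likelihoods", {
  # brute-force oracle on short random likelihood sequences
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(3:7, 1)
    liks <- replicate(sample(2:10, 1), stats::runif(n, 0.1, 2), simplify = FALSE)
    acc <- new_accumulator(paste0("c", 1:n), gate = 1)
    for (l in liks) acc <- accumulator_step(acc, l, leak = 0)
    oracle <- Reduce(`*`, liks)
    expect_equal(unname(acc$prob), oracle / sum(oracle), tolerance = 1e-9)
  }
})

test_that("raising the gate never lowers the winning category's posterior", {
  set.seed(7)
  for (rep in 1:20) {
    lik <- stats::runif(6, 0.05, 3)
    prior <- stats::runif(6); prior <- prior / sum(prior)
    gates <- sort(stats::runif(3))
    top <- which.max(lik)
    mass <- vapply(gates, function(g) {
      acc <- list(prob = stats::setNames(prior, letters[1:6]), gate = g)
      accumulator_step(acc, lik, leak = 0)$prob[[top]]
    }, numeric(1))
    expect_true(all(diff(mass) >= -1e-12))
  }
})

test_that("probability vectors stay normalized through a full trial", {
  st <- make_stimulus("apata", lex, "noisy", 3L, seed = 9)
  lik <- phone_likelihood(st$formants)
  state <- new_model_state(lex)
  state <- onsetfuse:::.apply_onset(state, 0L)
  state$t <- 1L
  for (i in seq(2, ncol(lik), by = 1)) {
    state <- onsetfuse:::.decode_update(state, lik[, i], lex, 0.005)
    if (i %% 150 == 0) {
      expect_equal(sum(state$word), 1, tolerance = 1e-9)
      expect_equal(unname(colSums(state$syll)), rep(1, 3), tolerance = 1e-9)
      for (b in 1:3)
        expect_equal(unname(colSums(state$phone[[b]])), rep(1, 4), tolerance = 1e-9)
    }
  }
})

test_that("syllable evidence mirrors the slots decoded so far", {
  pp <- matrix(1 / 7, 7, 4, dimnames = list(phone_symbols, NULL))
  # all phone posteriors uniform: every token equally likely
  ell <- syllable_evidence(pp, 1, lex)
  expect_equal(unname(ell), rep(ell[[1]], 16))
  # slot 1 resolved to p: perfect competition between p-initial syllables
  pp[, 1] <- onehot(phone_symbols, "p")
  ell <- syllable_evidence(pp, 1, lex)
  pstart <- c("pa", "pi", "pu", "pa#", "pi#", "pu#")
  expect_equal(unname(ell[pstart]), rep(ell[["pa"]], 6))
  expect_gt(ell[["pa"]], 10 * ell[["ta"]])
  # slots p, @, a: mass concentrates on pa and pa#
  pp[, 2] <- onehot(phone_symbols, "@")
  pp[, 3] <- onehot(phone_symbols, "a")
  ell <- syllable_evidence(pp, 3, lex)
  expect_equal(ell[["pa"]], ell[["pa#"]])
  expect_gt(ell[["pa"]], 10 * max(ell[setdiff(names(ell), c("pa", "pa#"))]))
})

test_that("word evidence follows the word-to-syllable composition", {
  inv <- lex$inventory
  # first decoder resolved to pa: all /pa/-initial words tie
  ell <- word_evidence(onehot(inv, "pa"), 1, lex)
  pa_words <- c("papa", "pata", "patu", "patata", "patati")
  expect_equal(unname(ell[pa_words]), rep(ell[["pata"]], 5))
  expect_gt(ell[["pata"]], 10 * ell[["tata"]])
  # second decoder: final ta# supports pata; non-final ta the embedders
  ell_f <- word_evidence(onehot(inv, "ta#"), 2, lex)
  ell_n <- word_evidence(onehot(inv, "ta"), 2, lex)
  expect_gt(ell_f[["pata"]], 10 * ell_f[["patata"]])
  expect_gt(ell_n[["patata"]], 10 * ell_n[["pata"]])
  expect_equal(ell_n[["patata"]], ell_n[["patati"]])
  # uniform syllable posterior: all words equal (columns normalized)
  ell_u <- word_evidence(rep(1 / 16, 16), 1, lex)
  expect_equal(unname(ell_u), rep(ell_u[[1]], 28))
})

test_that("decoding_step advances phone slots every 50 steps and leaks closed banks", {
  st <- make_stimulus("pata", lex, "nominal", seed = 4)
  state <- new_model_state(lex)
  state <- onsetfuse:::.apply_onset(state, 0L)  # open first decoder at t = 1
  state$t <- 1L
  # assert slot contents while their input is unambiguous: the last frames
  # of a C->V transition are acoustically the vowel (the trajectory lands
  # on its mean), so check slot 2 mid-transition
  for (i in 2:86)
    state <- decoding_step(state, st$formants[i, ], lex)
  expect_equal(names(which.max(state$phone[[1]][, 1])), "p")
  expect_equal(names(which.max(state$phone[[1]][, 2])), "@")
  # continue through the vowel (stop before /t/ starts at 150)
  for (i in 87:149)
    state <- decoding_step(state, st$formants[i, ], lex)
  expect_equal(names(which.max(state$phone[[1]][, 3])), "a")
  expect_equal(unname(state$phone[[3]]), matrix(1 / 7, 7, 4))
  expect_equal(unname(state$syll[, 3]), rep(1 / 16, 16))
  # first syllable decoder: pa and pa# lead, tied until slot 4 evidence
  s1 <- sort(state$syll[, 1], decreasing = TRUE)
  expect_setequal(names(s1)[1:2], c("pa", "pa#"))
  # word layer: /pa/-initial words lead
  expect_true(all(c("pata", "papa", "patu") %in%
                    names(sort(state$word, decreasing = TRUE))[1:6]))
})
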