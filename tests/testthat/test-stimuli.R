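test_that("phone acoustic models follow the vowel-triangle layout", {
  for (ph in phone_symbols) {
    m <- phone_model(ph)
    ev <- eigen(m$cov, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
  expect_equal(phone_model("#")$mean, c(0, 0))
  d <- function(a, b) sqrt(sum((phone_model(a)$mean - phone_model(b)$mean)^2))
  expect_lt(d("p", "u"), d("p", "i"))  # p is the back plosive
  expect_lt(d("t", "i"), d("t", "u"))  # t is the front plosive
  expect_error(phone_model("x"), "unknown phone")
})

test_that("phone likelihoods pick out the generating category", {
  la <- phone_likelihood(phone_model("a")$mean)
  seg <- c("p", "t", "a", "i", "u")
  expect_equal(names(which.max(la[seg, 1])), "a")
  l0 <- phone_likelihood(c(0, 0))
  expect_equal(names(which.max(l0[, 1])), "#")  # silence easily recognized
  mid <- (phone_model("p")$mean + phone_model("a")$mean) / 2
  lm <- phone_likelihood(mid)
  expect_gt(lm["@", 1], lm["p", 1])
  expect_gt(lm["@", 1], lm["a", 1])
  expect_error(phone_likelihood(c(NA, 1)), "non-finite")
})

test_that("formant tracks have word duration plus pad and are seed-reproducible", {
  expect_equal(nrow(sample_formant_track("pata", lex, seed = 7)), 350L + 100L)
  expect_equal(nrow(sample_formant_track("a", lex, seed = 7)), 150L + 100L)
  expect_identical(sample_formant_track("apata", lex, seed = 3),
                   sample_formant_track("apata", lex, seed = 3))
  expect_false(identical(sample_formant_track("apata", lex, seed = 3),
                         sample_formant_track("apata", lex, seed = 4)))
  # held samples: the p slot of pata is constant, the transition is not
  tr <- sample_formant_track("pata", lex, seed = 7)
  expect_equal(nrow(unique(tr[1:50, , drop = FALSE])), 1L)
  expect_gt(nrow(unique(tr[51:100, , drop = FALSE])), 40L)
})

test_that("nominal loudness has 0.8 plateaus and 0.6 boundary dips", {
  L <- nominal_loudness("pata", lex)
  expect_length(L, 450L)
  expect_true(all(L >= 0 & L <= 1))
  expect_equal(max(L), 0.8)
  expect_equal(min(L[131:150]), 0.6)        # internal boundary dip
  expect_equal(L[1], 0)
  expect_true(all(L[351:450] == 0))         # trailing pad silent
  # monosyllabic: single rise then fall, no internal dip
  Lm <- nominal_loudness("pa", lex)
  expect_equal(min(Lm[16:150]), 0.8)
  expect_equal(sum(diff(Lm) > 0 & c(diff(Lm)[-1], 0) <= 0), 1L)
})

test_that("noise events insert disjoint fall-then-rise excursions", {
  L <- nominal_loudness("pata", lex)
  expect_identical(add_noise_events(L, "pata", lex, k = 0), L)
  L2 <- add_noise_events(L, "pata", lex, k = 2, anchors = c(60, 200))
  # event window length = 10% of word duration
  changed <- which(L2 != L) - 1L
  expect_equal(length(changed), 2L * 35L - 2L)  # 35-step windows, ends at 0.8
  expect_true(all(changed %in% c(25:60, 165:200)))
  expect_equal(min(L2[26:61]), 0.55)
  # a sharp rise ends exactly at each anchor
  expect_equal(L2[61], 0.8)
  expect_equal(L2[201], 0.8)
  # random placement: seeds reproduce, events stay in sustained plateaus
  L3 <- add_noise_events(L, "pata", lex, k = 4, seed = 11)
  expect_identical(L3, add_noise_events(L, "pata", lex, k = 4, seed = 11))
  expect_true(all(L3 >= 0 & L3 <= 1))
  expect_error(add_noise_events(L, "pata", lex, k = 2, anchors = c(60, 70)),
               "disjoint")
  expect_error(add_noise_events(L, "pata", lex, k = 1, anchors = 140),
               "sustained-plateau")
})

test_that("hypo-articulation reshapes dips to the requested depth", {
  L <- nominal_loudness("pata", lex)
  for (depth in c(0.65, 0.7, 0.75)) {
    Lh <- hypo_dip(L, "pata", lex, depth, seed = 3)
    expect_equal(min(Lh[131:150]), depth)
    expect_equal(max(Lh), 0.8)
  }
  # depth 0.8 removes the dip altogether
  L8 <- hypo_dip(L, "pata", lex, 0.8, seed = 3)
  expect_true(all(L8[16:299] == 0.8))
  # depth 0.6 has nominal depth but a randomly drawn minimum position
  mins <- vapply(1:8, function(s)
    which.min(hypo_dip(L, "pata", lex, 0.6, seed = s)[131:151]), integer(1))
  expect_gt(length(unique(mins)), 1L)
  expect_error(hypo_dip(L, "pata", lex, 0.72, seed = 1), "depth")
  expect_error(hypo_dip(L, "pa", lex, 0.7, seed = 1), "2 syllables")
})

test_that("hypo depth 0.8 leaves no detectable rise at the boundary", {
  p <- default_params()
  L8 <- hypo_dip(nominal_loudness("pata", lex), "pata", lex, 0.8, seed = 1)
  dL <- loudness_derivative(L8)
  pb <- vapply(130:170, function(t) bottom_up_prob(dL[1:(t + 1)], p), numeric(1))
  expect_true(all(pb < p$threshold))
})

test_that("loudness derivative is the padded first difference", {
  expect_equal(loudness_derivative(rep(0.5, 10)), rep(0, 10))
  expect_equal(loudness_derivative(seq(0, 0.9, by = 0.1)),
               c(0, rep(0.1, 9)))
})

test_that("stimuli bundle aligned tracks with ground-truth annotations", {
  for (cond in c("nominal", "noisy", "hypo")) {
    sev <- switch(cond, nominal = NULL, noisy = 2L, hypo = 0.7)
    st <- make_stimulus("apata", lex, cond, sev, seed = 5)
    expect_equal(length(st$loudness), 450L + 100L)
    expect_equal(nrow(st$formants), length(st$loudness))
    expect_equal(length(st$silence), length(st$loudness))
    expect_equal(st$true_onsets, canonical_onsets("apata", lex))
    expect_true(all(st$loudness >= 0 & st$loudness <= 1))
  }
  # nominal profile is deterministic across seeds
  expect_equal(make_stimulus("pata", lex, "nominal", seed = 1)$loudness,
               make_stimulus("pata", lex, "nominal", seed = 99)$loudness)
  expect_error(make_stimulus("pata", lex, "noisy", severity = 7, seed = 1),
               "severity")
})

test_that("stimulus dumps are plain text and round-trippable", {
  st <- make_stimulus("pata", lex, "noisy", 1L, seed = 2)
  path <- file.path(tempdir(), "stim.tsv")
  write_stimulus(st, path)
  df <- read.delim(path)
  expect_equal(nrow(df), length(st$loudness))
  expect_equal(df$loudness, st$loudness)
  meta <- readLines(sub("tsv$", "meta", path))
  expect_true(any(grepl("true_onsets=0,150", meta)))
})
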