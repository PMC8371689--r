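---
title: "Syllabic parsing by fused top-down and bottom-up onset detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Syllabic parsing by fused top-down and bottom-up onset detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsetfuse)
```

## The model

Spoken word recognition is modelled here as two interacting processes. A
**decoding hierarchy** accumulates evidence about linguistic content: 12
phone decoders (3 banks of 4 slots) read the spectral input, 3 syllable
decoders read the phone decoders through a syllable-to-phone lexical layer,
and one word decoder reads the syllable decoders through a word-to-syllable
lexical layer, feed-forward only. A **temporal-control module** decides
*when* a new syllable begins: detected onset events close the currently
active phone/syllable decoders and open the next ones, so segmentation and
recognition unfold together.

Each decoder is a leaky evidence accumulator over a discrete domain. One
update mixes the posterior toward uniform at the leak rate and multiplies
in the current likelihood tempered by the decoder's gate,

$$p'(x) \propto \left[(1-\lambda)\,p(x) + \lambda/|X|\right]\,
\ell(x)^{g},$$

with $g = 1$ for an open decoder and $g = 0$ for a closed one ("Bayesian
potentiometer": intermediate gate values temper how much evidence
propagates; in the simulations gates are driven hard open or closed by the
onset decisions). The leak is slow ($\lambda = 0.005$ per step) so decoded
evidence persists across a word while still decaying to uniform in the
absence of input.

The onset decision fuses three per-step probabilities:

* **Bottom-up** $p_{BU}$: the loudness derivative must be positive for at
  least 3 consecutive steps; then
  $p_{BU} = \mathrm{logistic}(g_{BU}(R - \theta))$, where $R$ is the summed
  positive derivative over the last 5 steps, $\theta = 0.1$ and
  $g_{BU} = 60$. The nominal boundary rise (0.6 to 0.8 within 5 steps,
  $R = 0.2$) lands far above the decision threshold; a hypo-articulated
  rise from 0.75 ($R = 0.05$) lands far below it.
* **Top-down** $p_{TD}$: every word predicts onsets at its canonical
  syllable start times (from the 50-step phone-slot expansion), as Gaussian
  bumps of height 1 and width $\sigma = 7.5$ steps, weighted by the word's
  posterior probability from the previous step. A height-1 bump centred at
  150 crosses the 0.4 threshold near step 140, which is what makes the
  disjunctive model act a few steps *before* the canonical boundary.
* **Refractory** $p_{REF}$: a hard veto for 50 steps after each detection
  (half-open window).

The three fusion variants are `bu_only` ($p_{BU}p_{REF}$), `and`
($p_{TD}p_{BU}p_{REF}$: the lexicon can veto spurious bottom-up events) and
`or` ($(1-(1-p_{TD})(1-p_{BU}))p_{REF}$: the lexicon can supply events the
envelope no longer carries). An onset fires on the first step the fused
probability reaches the 0.4 threshold outside the refractory window.

## The toy linguistic material

The lexicon holds 28 words of 1–3 syllables over phones
{p, t, a, i, u}, the transition phone `@` and the silence phone `#`. Each
phone occupies a 50-step slot; a CV syllable is `C-@-V` (plus `#` if
word-final), a word-initial lone vowel occupies two slots of the same
vowel. This slot arithmetic reproduces every tabulated word duration
exactly and yields the canonical onset times used by the top-down branch:

```{r onsets}
lex <- build_lexicon()
canonical_onsets("pata", lex)
canonical_onsets("apata", lex)
```

Final and non-final variants of a syllable are distinct tokens (`ta` vs
`ta#`): the final token predicts silence in its trailing slots while the
non-final token predicts the onset consonant of a following syllable, and
this is the only cue that separates a word from words that embed it
("pata" vs "patata") once the input has gone silent. A silence
pseudo-syllable (expansion `#-#-#-#`) lets a third syllable decoder opened
on lexical expectation settle on "silence", which is consistent only with
the shorter word.

## The synthetic stimuli

Stimuli are generated, not recorded. The spectral track lives in (F1, F2)
Bark space: category means sit in the vowel-triangle layout (p near the
back rounded u, t near the front i, silence at the origin, far from all
speech sounds). Each produced phone is one Gaussian sample (articulation
scatter sd 0.15 Bark) held for its slot; transitions are linear
interpolations between the flanking category means. Recognition categories
are deliberately broader (sd 0.5) than the production scatter: the
degradation paradigms of interest act on the *envelope*, not the spectrum,
so spectral decoding is kept reliable by design. The transition phone is
modelled as a Gaussian tube (sd 1) around the legal C→V
barycenter-to-barycenter segments, covering the whole trajectory.

The loudness profile is piecewise linear in [0, 1]: a 15-step rise to the
0.8 within-syllable plateau, a gradual 15-step fall to 0.6 before each
internal boundary and a rapid 5-step rise ending exactly at it (rapid
rises mark onsets; falls are gradual), a decay to 0 over the final silence
phone, and a 100-step silent pad so every trial ends with a
disambiguating silence phase. Degradations:

* **noisy-event**: `k` = 0–4 disjoint excursions, each 10% of the word
  duration, placed in sustained plateaus — a gradual fall to 0.55 and a
  sharp 5-step rise back to 0.8, i.e. a spurious onset signature at the
  event anchor;
* **hypo-articulation**: every boundary dip minimum is raised to a depth
  in {0.6, 0.65, 0.7, 0.75, 0.8} with the minimum's position drawn
  uniformly 3–10 steps before the boundary (at 0.8 the dip disappears).
  Depth 0.6 keeps the nominal depth but randomizes the dip shape, so it is
  *not* identical to the nominal profile.

What the generator does **not** emulate: real envelope extraction
(auditory filterbanks), coarticulation beyond linear transitions, timing
variability of natural speech, or any spectral degradation. Passing tests
therefore show that the fusion logic behaves as designed under controlled
envelope perturbations — not that the model parses real speech.

## A worked trial

```{r trial}
r <- run_trial("pata", lex, variant = "and", condition = "nominal")
r
r$n_decoders_activated
count_episodes(r$p_td, 0.4)
```

The bottom-up branch fires near steps 0 and 150 (the two envelope rises);
the lexical branch additionally predicts an onset near 300 because "pata"
is a prefix of "patata" and "patati", which stay equiprobable with it until
silence — the conjunctive fusion filters that prediction out, only two
syllable decoders open, and the trailing silence resolves the embedding
competition in favour of the stimulus word.

## Numerical and design choices

Several choices were genuinely open and are fixed as follows:

* **Accumulator dynamics.** Leak-to-uniform then tempered multiplication
  is the simplest update satisfying slow decay, graded gating and
  persistence. Posteriors are floored at 1e-12 before renormalization; an
  all-zero likelihood on an open decoder is a hard error.
* **Word evidence from all opened decoders.** The word accumulator
  receives, each step, the product of the word-evidence terms of every
  decoder opened so far. Closed decoders keep constraining word identity
  through their frozen (slowly leaking) posteriors; using only the active
  decoder lets renormalization erase first-syllable distinctions long
  before the trial ends.
* **Smoothed lexical mappings.** Composition matrices are 0/1 mixed with a
  uniform component — 0.02 at the word-to-syllable layer, 0.1 at the
  syllable-to-phone layer. The broader phone-level floor matters when a
  decoder is opened a few steps early by the disjunctive model and briefly
  reads the tail of the previous phone: without it, exactly tied
  final/non-final hypotheses can be toppled by one or two misaligned
  steps, with no way back.
* **Onset bookkeeping.** Canonical onset times are anchored at trial
  start (isolated words), not re-anchored on detections. Onsets beyond
  the third close the last decoder but open nothing. A decision takes
  effect at the next step, breaking the within-step dependency cycle.
* **Word priors** are uniform over the 28 words at trial start.
* **Detection scoring.** Detections are matched one-to-one to true onsets
  greedily by distance within ±15 steps; F is the harmonic mean of the
  resulting precision and recall.

## The simulation campaign

The full campaign is 21 non-monosyllabic stimulus words × 3 fusion
variants × 82 cells (1 nominal; noisy severities 1–4 × 10 repetitions;
hypo depths 0.6–0.75 × 10 repetitions plus the deterministic depth 0.8) =
5,166 trials, enumerated by `grid_plan()`. Trial seeds are derived from
the campaign seed and the cell coordinates, and are shared across the
three variants of a cell so all variants see identical degraded stimuli —
the cleanest isolation of the fusion effect. Summaries are plain means
over words and repetitions.

The package's own test suite runs the deterministic worked examples, the
63 nominal trials, and the noisy (bottom-up vs conjunctive) and
hypo-articulation (all variants) sweeps at the full 10-repetition design —
about 4,300 trials, a few minutes of computation. The qualitative
regularities these sweeps check: conjunctive fusion matches or beats the
bottom-up-only model at every noise severity; disjunctive fusion is flat
across hypo-articulation depths while the other two variants degrade; and
the two performance measures are strongly rank-correlated.

## Known limitations

* With disjunctive fusion, words that are prefixes of longer lexicon
  words ("pata", "apa") receive a third, lexically generated onset even in
  the nominal condition, so their onset F-score is 0.8 by construction
  (recognition is still correct, via the silence syllable). This is a
  property of the model, not a defect of the implementation.
* The early firing of the disjunctive model (threshold crossed on the
  rising top-down bump) misaligns decoders with the stimulus by up to ~10
  steps; the smoothed mappings absorb this, but recognition margins shrink
  accordingly.
* The bottom-up detector is a fixed-window statistic with no intrinsic
  time scale adaptation; speech-rate variation, oscillatory tracking and
  real-audio envelopes are out of scope.
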