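# Synthetic stimulus generator: Gaussian phone clouds in (F1, F2) Bark
# space, piecewise-linear loudness profiles, and the two degradation
# paradigms (spurious noise events, hypo-articulated boundary dips).

# Phone category means in Bark. Chosen inside the vowel-triangle layout:
# the plosives sit between the high vowels, p near the back rounded u and
# t near the front i; silence is far outside, at the origin.
.phone_means <- rbind(
  p = c(3.5, 7.0),
  t = c(3.5, 12.5),
  a = c(7.0, 11.5),
  i = c(2.8, 13.5),
  u = c(2.8, 6.0),
  `#` = c(0.0, 0.0)
)
.phone_sd <- c(p = 0.5, t = 0.5, a = 0.5, i = 0.5, u = 0.5, `#` = 0.2)
.trans_sd <- 1.0
# Articulation scatter of produced tokens, deliberately smaller than the
# recognition categories' breadth: the toy stimuli are well-articulated and
# the degradation paradigms act on the loudness envelope, not the spectrum.
.phone_sample_sd <- 0.15

# Barycenter-to-barycenter segments for every legal C -> V pair; the
# transition phone @ is modelled as a Gaussian "tube" around the best of
# these segments, since a transition sweeps the whole line between the two
# category means, not just its midpoint.
.trans_segments <- local({
  pairs <- expand.grid(C = c("p", "t"), V = c("a", "i", "u"),
                       stringsAsFactors = FALSE)
  lapply(seq_len(nrow(pairs)), function(k)
    rbind(from = .phone_means[pairs$C[k], ], to = .phone_means[pairs$V[k], ]))
})
.trans_midpoints <- t(vapply(.trans_segments, colMeans, numeric(2)))

# squared distance from points (x1, x2) to a segment
.dist2_segment <- function(x1, x2, seg) {
  v <- seg["to", ] - seg["from", ]
  len2 <- sum(v^2)
  f <- ((x1 - seg["from", 1]) * v[1] + (x2 - seg["from", 2]) * v[2]) / len2
  f <- pmin(1, pmax(0, f))
  (x1 - seg["from", 1] - f * v[1])^2 + (x2 - seg["from", 2] - f * v[2])^2
}

#' Acoustic model of a phone
#'
#' Fixed bivariate Gaussian over (F1, F2) in Bark for each phone category.
#' Segmental phones occupy the vowel-triangle region, `#` is centered at the
#' origin (silence is far from all speech sounds, hence easily recognized),
#' and the transition phone `@` is a broad model around the legal
#' consonant-vowel barycenter-to-barycenter transition segments.
#'
#' @param phone One of [phone_symbols].
#' @return List with `phone`, `mean` (length-2, Bark), `cov` (2x2, Bark^2);
#'   for `"@"` additionally `midpoints` (segment midpoints) and `segments`
#'   (list of from/to endpoint matrices).
#' @export
phone_model <- function(phone) {
  if (!phone %in% phone_symbols) stop("unknown phone symbol: ", phone)
  if (phone == "@") {
    return(list(phone = "@", mean = colMeans(.trans_midpoints),
                cov = diag(.trans_sd^2, 2), midpoints = .trans_midpoints,
                segments = .trans_segments))
  }
  list(phone = phone, mean = unname(.phone_means[phone, ]),
       cov = diag(.phone_sd[[phone]]^2, 2))
}

.gauss2 <- function(x1, x2, m, sd) {
  exp(-((x1 - m[1])^2 + (x2 - m[2])^2) / (2 * sd^2)) / (2 * pi * sd^2)
}

#' Phone likelihoods of formant input
#'
#' Unnormalized likelihood of each of the 7 phones at one or more (F1, F2)
#' points: isotropic Gaussian densities for the five segmental phones and
#' `#`, and for `@` the maximum over the legal C->V transition segments of
#' a Gaussian in the distance to the segment (broad sd 1 Bark), so that the
#' whole linear transition trajectory is covered.
#'
#' @param input Numeric length-2 vector, or an n x 2 matrix of points.
#' @return A 7 x n matrix of likelihoods (rows named by phone).
#' @export
phone_likelihood <- function(input) {
  x <- if (is.matrix(input)) input else matrix(input, ncol = 2)
  if (!all(is.finite(x))) stop("non-finite formant coordinates")
  out <- matrix(0, 7L, nrow(x), dimnames = list(phone_symbols, NULL))
  for (ph in rownames(.phone_means))
    out[ph, ] <- .gauss2(x[, 1], x[, 2], .phone_means[ph, ], .phone_sd[[ph]])
  d2 <- rep(Inf, nrow(x))
  for (seg in .trans_segments)
    d2 <- pmin(d2, .dist2_segment(x[, 1], x[, 2], seg))
  out["@", ] <- exp(-d2 / (2 * .trans_sd^2)) / (2 * pi * .trans_sd^2)
  pmax(out, 1e-300)
}

#' Sample a formant track for a word
#'
#' One Gaussian sample per segmental phone, held for its 50-step slot(s)
#' (the doubled word-initial vowel holds a single sample for 100 steps);
#' `@` slots are linear interpolations between the barycenters of the
#' flanking phone categories; `#` slots and the trailing silence pad are
#' per-step samples around the origin.
#'
#' @param word Word label.
#' @param lexicon A [build_lexicon()] object.
#' @param seed Integer seed; identical seeds give identical tracks.
#' @param pad Trailing silence steps appended after the word (default 100).
#' @return A (duration + pad) x 2 matrix of (F1, F2) in Bark.
#' @export
sample_formant_track <- function(word, lexicon, seed, pad = 100L) {
  slots <- word_slots(lexicon_syllables(lexicon, word))
  set.seed(as.integer(seed))
  n <- length(slots)
  track <- matrix(NA_real_, 50L * n + pad, 2L)
  # group consecutive identical segmental slots: one held sample per group
  i <- 1L
  while (i <= n) {
    ph <- slots[i]
    j <- i
    while (j < n && slots[j + 1L] == ph) j <- j + 1L
    rows <- (50L * (i - 1L) + 1L):(50L * j)
    if (ph == "@") {
      from <- .phone_means[slots[i - 1L], ]
      to <- .phone_means[slots[j + 1L], ]
      f <- seq(0, 1, length.out = length(rows))
      track[rows, 1] <- from[1] + f * (to[1] - from[1])
      track[rows, 2] <- from[2] + f * (to[2] - from[2])
    } else if (ph == "#") {
      track[rows, ] <- matrix(stats::rnorm(2L * length(rows), 0, .phone_sample_sd),
                              ncol = 2)
    } else {
      track[rows, 1] <- .phone_means[ph, 1] + stats::rnorm(1, 0, .phone_sample_sd)
      track[rows, 2] <- .phone_means[ph, 2] + stats::rnorm(1, 0, .phone_sample_sd)
    }
    i <- j + 1L
  }
  if (pad > 0L) {
    rows <- (50L * n + 1L):(50L * n + pad)
    track[rows, ] <- matrix(stats::rnorm(2L * pad, 0, .phone_sample_sd), ncol = 2)
  }
  colnames(track) <- c("F1", "F2")
  track
}

# Piecewise-linear loudness profile. Geometry (all in steps, origin 0):
#  - word-initial rise 0 -> 0.8 over the first 15 steps;
#  - 0.8 plateau inside syllables;
#  - at each internal canonical boundary b: gradual fall from 0.8 starting
#    at b - 20 down to `depth` at the dip minimum (nominally b - 5), then a
#    rapid rise back to 0.8 ending exactly at b ("rapid increase at syllable
#    onsets, gradual decrease toward offsets");
#  - final decay 0.8 -> 0 across the last (#) phone slot, 0 during the pad.
.loudness_profile <- function(word, lexicon, depth = 0.6, argmins = NULL,
                              pad = 100L, plateau = 0.8, rise_len = 15L,
                              dip_lead = 20L) {
  r <- lexicon_word_row(lexicon, word)
  dur <- lexicon$words$duration[r]
  onsets <- lexicon$onsets[[word]]
  internal <- onsets[-1]
  if (is.null(argmins)) argmins <- internal - 5L
  tt <- 0:(dur + pad - 1L)
  L <- rep(plateau, length(tt))
  L[tt <= rise_len] <- plateau * tt[tt <= rise_len] / rise_len
  if (depth < plateau) {
    for (k in seq_along(internal)) {
      b <- internal[k]; a <- argmins[k]; s <- b - dip_lead
      fall <- tt >= s & tt <= a
      L[fall] <- plateau + (depth - plateau) * (tt[fall] - s) / (a - s)
      rise <- tt > a & tt <= b
      L[rise] <- depth + (plateau - depth) * (tt[rise] - a) / (b - a)
    }
  }
  decay <- tt >= dur - 50L & tt < dur
  L[decay] <- plateau * (dur - tt[decay]) / 50
  L[tt >= dur] <- 0
  L
}

#' Nominal loudness profile of a word
#'
#' Starts at 0, ramps to the 0.8 within-syllable plateau, dips to 0.6 at
#' each internal syllable boundary (gradual fall, rapid rise ending at the
#' canonical boundary), and decays to 0 over the final silence phone and the
#' trailing pad. Deterministic.
#'
#' @inheritParams sample_formant_track
#' @return Numeric vector of length duration + pad, values in \[0, 1\].
#' @export
nominal_loudness <- function(word, lexicon, pad = 100L) {
  .loudness_profile(word, lexicon, depth = 0.6, pad = pad)
}

# Sustained-plateau intervals [start, end] of the nominal profile, where
# noise-event windows may be placed.
.plateau_segments <- function(word, lexicon, rise_len = 15L, dip_lead = 20L) {
  r <- lexicon_word_row(lexicon, word)
  dur <- lexicon$words$duration[r]
  onsets <- lexicon$onsets[[word]]
  starts <- c(rise_len, onsets[-1])
  ends <- c(onsets[-1] - dip_lead, dur - 50L)
  cbind(start = starts, end = ends)
}

#' Insert spurious noise events into a loudness profile
#'
#' Each event replaces a window of length `round(0.1 * duration)` inside a
#' sustained plateau with a fall-then-sharp-rise excursion (gradual fall to
#' 0.55, rapid 5-step rise back to 0.8 ending at the event anchor), so a
#' spurious rapid loudness increase exists at the anchor. Events are
#' pairwise disjoint; `k = 0` returns the input unchanged.
#'
#' @param L Loudness vector (nominal profile of `word`).
#' @param word Word label.
#' @param lexicon A [build_lexicon()] object.
#' @param k Number of events, 0--4.
#' @param seed Integer seed for anchor placement (ignored if `anchors`
#'   given).
#' @param anchors Optional fixed anchor times (rise endpoints, origin-0),
#'   e.g. `c(60, 200)`.
#' @param depth Excursion minimum (default 0.55).
#' @return Modified loudness vector, same length as `L`.
#' @export
add_noise_events <- function(L, word, lexicon, k, seed = NULL, anchors = NULL,
                             depth = 0.55) {
  stopifnot(k >= 0L, k <= 4L)
  if (k == 0L && is.null(anchors)) return(L)
  r <- lexicon_word_row(lexicon, word)
  dur <- lexicon$words$duration[r]
  len <- round(0.1 * dur)
  seg <- .plateau_segments(word, lexicon)
  candidates <- unlist(apply(seg, 1, function(s) {
    lo <- s[["start"]] + len
    if (lo <= s[["end"]]) lo:s[["end"]] else integer(0)
  }, simplify = FALSE))
  if (is.null(anchors)) {
    set.seed(as.integer(seed))
    anchors <- integer(0)
    for (tries in seq_len(2000L)) {
      e <- sample(candidates, 1L)
      if (all(abs(e - anchors) > len)) anchors <- c(anchors, e)
      if (length(anchors) == k) break
    }
    if (length(anchors) < k)
      stop("cannot place ", k, " disjoint noise events for word '", word, "'")
  } else {
    anchors <- as.integer(anchors)
    if (any(!anchors %in% candidates))
      stop("noise-event anchor outside sustained-plateau region for '", word, "'")
    if (k > 0L && length(anchors) != k) k <- length(anchors)
    if (any(diff(sort(anchors)) <= len))
      stop("cannot place ", k, " disjoint noise events for word '", word, "'")
  }
  rise_len <- 5L
  for (e in anchors) {
    s <- e - len
    idx_fall <- (s:(e - rise_len)) + 1L          # 1-based indexing into L
    idx_rise <- ((e - rise_len):e) + 1L
    L[idx_fall] <- 0.8 + (depth - 0.8) * seq(0, 1, length.out = length(idx_fall))
    L[idx_rise] <- depth + (0.8 - depth) * seq(0, 1, length.out = length(idx_rise))
  }
  L
}

#' Hypo-articulated boundary dips
#'
#' Reshapes every internal syllable-boundary dip so that its minimum equals
#' `depth`, with the time of the minimum drawn uniformly inside the dip
#' window (between 10 and 3 steps before the canonical boundary). At depth
#' 0.8 the dip is removed entirely (loudness stays at the plateau). The
#' word-initial rise and final decay are untouched.
#'
#' @param L Loudness vector (accepted for interface symmetry; the profile
#'   is parametric and rebuilt with the requested dip geometry).
#' @param word Word label (must have at least 2 syllables).
#' @param lexicon A [build_lexicon()] object.
#' @param depth One of 0.6, 0.65, 0.7, 0.75, 0.8.
#' @param seed Integer seed for the dip-minimum draw.
#' @param pad Trailing silence steps (must match `L`).
#' @return Loudness vector of the same length as `L`.
#' @export
hypo_dip <- function(L, word, lexicon, depth, seed, pad = 100L) {
  if (!isTRUE(any(abs(depth - c(0.6, 0.65, 0.7, 0.75, 0.8)) < 1e-9)))
    stop("hypo-articulation depth must be one of 0.6, 0.65, 0.7, 0.75, 0.8")
  r <- lexicon_word_row(lexicon, word)
  if (lexicon$words$n_syllables[r] < 2L)
    stop("hypo-articulation requires a word with at least 2 syllables")
  internal <- lexicon$onsets[[word]][-1]
  set.seed(as.integer(seed))
  argmins <- internal - sample(3:10, length(internal), replace = TRUE)
  out <- .loudness_profile(word, lexicon, depth = depth, argmins = argmins,
                           pad = pad)
  if (length(out) != length(L))
    stop("loudness vector length does not match the word's profile")
  out
}

#' Loudness derivative
#'
#' First difference of a loudness sequence, same length (first element 0).
#' Positive values are what the bottom-up branch tracks to detect onsets.
#'
#' @param L Numeric loudness vector.
#' @return Numeric vector, `c(0, diff(L))`.
#' @export
loudness_derivative <- function(L) c(0, diff(L))

#' Generate a complete stimulus
#'
#' Bundles the formant track, loudness profile (nominal or degraded), its
#' derivative, silence flags and ground-truth onset annotations for one
#' trial. One trial seed controls formant sampling, noise-event placement
#' and dip-minimum draws through independent derived streams.
#'
#' @param word Word label.
#' @param lexicon A [build_lexicon()] object.
#' @param condition `"nominal"`, `"noisy"` or `"hypo"`.
#' @param severity Noisy: number of events 0--4; hypo: dip depth in
#'   \{0.6, 0.65, 0.7, 0.75, 0.8\}. Ignored for nominal.
#' @param seed Integer trial seed.
#' @param pad Trailing silence steps (default 100).
#' @param noise_anchors Optional fixed noise-event anchors (noisy condition).
#' @return Object of class `"stimulus"`.
#' @export
make_stimulus <- function(word, lexicon, condition = c("nominal", "noisy", "hypo"),
                          severity = NULL, seed = 1L, pad = 100L,
                          noise_anchors = NULL) {
  condition <- match.arg(condition)
  set.seed(as.integer(seed))
  sub <- sample.int(.Machine$integer.max - 1L, 3L)
  track <- sample_formant_track(word, lexicon, seed = sub[1], pad = pad)
  L <- nominal_loudness(word, lexicon, pad = pad)
  if (condition == "noisy") {
    if (is.null(severity)) severity <- 0L
    if (!severity %in% 0:4) stop("noisy severity must be an integer in 0..4")
    L <- add_noise_events(L, word, lexicon, k = severity, seed = sub[2],
                          anchors = noise_anchors)
  } else if (condition == "hypo") {
    if (is.null(severity)) severity <- 0.6
    L <- hypo_dip(L, word, lexicon, depth = severity, seed = sub[3], pad = pad)
  }
  r <- lexicon_word_row(lexicon, word)
  slots <- word_slots(lexicon$words$syllables[[r]])
  silence <- c(rep(slots == "#", each = 50L), rep(TRUE, pad))
  structure(list(word = word, formants = track, loudness = L,
                 delta_loudness = loudness_derivative(L),
                 silence = silence,
                 true_onsets = lexicon$onsets[[word]],
                 duration = lexicon$words$duration[r],
                 condition = condition, severity = severity,
                 seed = as.integer(seed), pad = as.integer(pad)),
            class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("Stimulus '%s' (%s%s), %d steps (+%d pad), onsets: %s\n",
              x$word, x$condition,
              if (x$condition == "nominal") "" else paste0(", severity ", x$severity),
              x$duration, x$pad, paste(x$true_onsets, collapse = ", ")))
  invisible(x)
}

#' Write a stimulus to plain-text files
#'
#' Dumps the per-step track as TSV (`t, F1, F2, loudness, delta_loudness,
#' silence`) plus a key-value sidecar with the annotations.
#'
#' @param stimulus A [make_stimulus()] object.
#' @param path Output TSV path; the sidecar gets extension `.meta`.
#' @export
write_stimulus <- function(stimulus, path) {
  df <- data.frame(t = seq_along(stimulus$loudness) - 1L,
                   F1 = stimulus$formants[, 1], F2 = stimulus$formants[, 2],
                   loudness = stimulus$loudness,
                   delta_loudness = stimulus$delta_loudness,
                   silence = as.integer(stimulus$silence))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(word = stimulus$word, condition = stimulus$condition,
            severity = as.character(stimulus$severity),
            seed = as.character(stimulus$seed),
            true_onsets = paste(stimulus$true_onsets, collapse = ","))
  writeLines(paste(names(meta), meta, sep = "="),
             paste0(tools::file_path_sans_ext(path), ".meta"))
  invisible(path)
}
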