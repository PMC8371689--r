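# Trial and grid runners, performance measures (event-detection F-score
# with tolerance window, word recognition probability), results output.

#' Run one word-recognition trial
#'
#' Generates the stimulus, then iterates the full loop over all time steps:
#' feed-forward decoding (phones -> syllables -> words) with the current
#' gates, bottom-up onset probability from the loudness derivative,
#' top-down onset prediction from the previous step's word posterior,
#' fusion, thresholded onset decision, and gate switching effective at the
#' next step. Fully reproducible from its arguments.
#'
#' @param word Stimulus word label (must be non-monosyllabic; monosyllables
#'   remain recognition candidates but are never presented).
#' @param lexicon A [build_lexicon()] object.
#' @param variant Fusion variant: `"bu_only"`, `"and"` or `"or"`.
#' @param condition `"nominal"`, `"noisy"` or `"hypo"`.
#' @param severity See [make_stimulus()].
#' @param seed Integer trial seed.
#' @param params [default_params()] list.
#' @param stimulus Optional pre-built [make_stimulus()] object (overrides
#'   `word`/`condition`/`severity`/`seed`).
#' @param noise_anchors Optional fixed noise-event anchors (noisy condition).
#' @return Object of class `"trial_result"`: detected and true onsets,
#'   F-score, recognition probability, final word posterior, number of
#'   syllable decoders activated, and the per-step `p_td`, `p_bu`, `p_ref`,
#'   `p_oc` traces.
#' @export
run_trial <- function(word, lexicon, variant = c("bu_only", "and", "or"),
                      condition = c("nominal", "noisy", "hypo"),
                      severity = NULL, seed = 1L, params = default_params(),
                      stimulus = NULL, noise_anchors = NULL) {
  variant <- match.arg(variant)
  condition <- match.arg(condition)
  if (is.null(stimulus)) {
    if (lexicon$words$n_syllables[lexicon_word_row(lexicon, word)] < 2L)
      stop("monosyllabic words are not used as stimuli: ", word)
    stimulus <- make_stimulus(word, lexicon, condition, severity, seed,
                              pad = params$pad, noise_anchors = noise_anchors)
  } else {
    word <- stimulus$word
    condition <- stimulus$condition
    severity <- stimulus$severity
  }
  T <- length(stimulus$loudness)
  lik <- phone_likelihood(stimulus$formants)          # 7 x T
  p_bu <- .bottom_up_trace(stimulus$delta_loudness, params)
  bumps <- .onset_bumps(lexicon, T, params$sigma_td)  # T x 28
  state <- new_model_state(lexicon)
  p_td <- p_ref <- p_oc <- numeric(T)
  detected <- integer(0)
  thr <- params$threshold
  for (i in seq_len(T)) {
    tt <- i - 1L
    prev_word <- state$word
    state <- .decode_update(state, lik[, i], lexicon, params$leak)
    p_td[i] <- min(1, sum(bumps[i, ] * prev_word))
    p_ref[i] <- refractory_prob(tt, state$last_onset, params$refractory)
    p_oc[i] <- fuse_onset(p_bu[i], p_td[i], p_ref[i], variant)
    if (p_ref[i] == 1 && p_oc[i] >= thr) {
      detected <- c(detected, tt)
      state <- .apply_onset(state, tt)
    }
  }
  structure(list(
    word = word, variant = variant, condition = condition,
    severity = severity, seed = stimulus$seed,
    detected_onsets = detected, true_onsets = stimulus$true_onsets,
    fscore = fscore(detected, stimulus$true_onsets, params$half_window),
    recognition_prob = unname(state$word[word]),
    final_posterior = state$word,
    n_decoders_activated = sum(state$activated),
    p_td = p_td, p_bu = p_bu, p_ref = p_ref, p_oc = p_oc),
    class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Trial '%s' [%s, %s%s]: onsets %s (truth %s), F = %.3f, P(word) = %.3f\n",
              x$word, x$variant, x$condition,
              if (x$condition == "nominal") "" else paste0(" ", x$severity),
              paste(x$detected_onsets, collapse = ","),
              paste(x$true_onsets, collapse = ","),
              x$fscore, x$recognition_prob))
  invisible(x)
}

#' Event-detection F-score with tolerance window
#'
#' One-to-one greedy nearest matching of detected to true onsets within
#' `half_window` steps on either side; precision is matched/|detected|,
#' recall matched/|truth|, and F their harmonic mean (0 when both are 0).
#'
#' @param detected,truth Numeric vectors of onset times.
#' @param half_window Matching half window in steps (default 15).
#' @return F-score in \[0, 1\].
#' @examples
#' fscore(c(0, 60, 150, 200), c(0, 150))  # 2/3
#' @export
fscore <- function(detected, truth, half_window = 15L) {
  nd <- length(detected); nt <- length(truth)
  if (nd == 0 && nt == 0) return(0)
  matched <- 0L
  if (nd > 0 && nt > 0) {
    d <- abs(outer(detected, truth, "-"))
    free_d <- rep(TRUE, nd); free_t <- rep(TRUE, nt)
    repeat {
      d2 <- d
      d2[!free_d, ] <- Inf
      d2[, !free_t] <- Inf
      if (all(!is.finite(d2)) || min(d2) > half_window) break
      ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
      free_d[ij[1]] <- FALSE
      free_t[ij[2]] <- FALSE
      matched <- matched + 1L
    }
  }
  P <- if (nd > 0) matched / nd else 0
  R <- if (nt > 0) matched / nt else 0
  if (P + R == 0) 0 else 2 * P * R / (P + R)
}

#' Recognition probability of a word
#'
#' Probability ascribed by the model to a word at the last simulated
#' iteration (default: the stimulus word).
#'
#' @param result A [run_trial()] result.
#' @param word Word label (default the trial's stimulus word).
#' @return Probability value.
#' @export
recognition_probability <- function(result, word = result$word) {
  if (!word %in% names(result$final_posterior))
    stop("unknown word label: ", word)
  unname(result$final_posterior[word])
}

# Stable per-trial seed from the grid seed and the cell coordinates.
# Variants are NOT part of the hash, so the three fusion variants of a cell
# see identical degraded stimuli (isolating the fusion effect).
.trial_seed <- function(grid_seed, word, condition, severity, rep) {
  m <- 2147483629
  h <- (as.numeric(grid_seed) * 48271) %% m
  for (ch in utf8ToInt(paste(word, condition, sep = "|")))
    h <- (h * 131 + ch) %% m
  h <- (h * 131 + round(100 * as.numeric(severity))) %% m
  h <- (h * 131 + as.numeric(rep)) %% m
  as.integer(h) + 1L
}

#' Simulation campaign plan
#'
#' Enumerates every trial of the full campaign: 21 stimulus words x 3
#' fusion variants x (1 nominal + 4 noisy severities x 10 repetitions +
#' 4 randomized hypo-articulation depths x 10 repetitions + 1 deterministic
#' depth-0.8 trial) = 5,166 rows. Noisy severity 0 duplicates the nominal
#' condition and is not re-enumerated. Trial seeds are derived from
#' `grid_seed` and shared across variants within a cell.
#'
#' @param lexicon A [build_lexicon()] object.
#' @param grid_seed Integer campaign seed.
#' @return Data frame with columns `word`, `variant`, `condition`,
#'   `severity`, `rep`, `seed`.
#' @export
grid_plan <- function(lexicon, grid_seed = 1L) {
  words <- stimulus_words(lexicon)
  cells <- rbind(
    data.frame(condition = "nominal", severity = NA_real_, rep = 1L),
    expand.grid(condition = "noisy", severity = 1:4, rep = 1:10,
                stringsAsFactors = FALSE),
    expand.grid(condition = "hypo", severity = c(0.6, 0.65, 0.7, 0.75),
                rep = 1:10, stringsAsFactors = FALSE),
    data.frame(condition = "hypo", severity = 0.8, rep = 1L))
  plan <- expand.grid(cell = seq_len(nrow(cells)), word = words,
                      variant = c("bu_only", "and", "or"),
                      stringsAsFactors = FALSE)
  plan <- cbind(plan[c("word", "variant")], cells[plan$cell, , drop = FALSE])
  plan <- plan[order(plan$word, plan$variant, plan$condition, plan$severity,
                     plan$rep), ]
  plan$seed <- mapply(.trial_seed, grid_seed, plan$word, plan$condition,
                      ifelse(is.na(plan$severity), 0, plan$severity), plan$rep)
  rownames(plan) <- NULL
  plan
}

#' Run a simulation campaign (or a subset of one)
#'
#' Runs every trial of a [grid_plan()] and returns one row per trial with
#' the configuration, the F-score and the recognition probability.
#'
#' @param lexicon A [build_lexicon()] object.
#' @param plan A [grid_plan()] data frame (or a subset of its rows).
#' @param params [default_params()] list.
#' @param progress Print a dot every 100 trials.
#' @return The plan with `fscore`, `recognition_prob` and
#'   `n_detected` columns appended.
#' @export
run_grid <- function(lexicon, plan = grid_plan(lexicon),
                     params = default_params(), progress = FALSE) {
  n <- nrow(plan)
  fs <- rp <- numeric(n)
  nd <- integer(n)
  for (i in seq_len(n)) {
    res <- run_trial(plan$word[i], lexicon, plan$variant[i],
                     plan$condition[i],
                     if (is.na(plan$severity[i])) NULL else plan$severity[i],
                     seed = plan$seed[i], params = params)
    fs[i] <- res$fscore
    rp[i] <- res$recognition_prob
    nd[i] <- length(res$detected_onsets)
    if (progress && i %% 100 == 0) cat(".")
  }
  if (progress) cat("\n")
  plan$fscore <- fs
  plan$recognition_prob <- rp
  plan$n_detected <- nd
  plan
}

#' Per-cell performance summary
#'
#' Mean F-score and recognition probability per (variant, condition,
#' severity) cell -- plain means over words and repetitions.
#'
#' @param results A [run_grid()] result table.
#' @return Data frame of cell means.
#' @export
summarize_grid <- function(results) {
  key <- interaction(results$variant, results$condition, results$severity,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(results, key), function(d)
    data.frame(variant = d$variant[1], condition = d$condition[1],
               severity = d$severity[1], n = nrow(d),
               mean_fscore = mean(d$fscore),
               mean_recognition = mean(d$recognition_prob))))
  rownames(out) <- NULL
  out[order(out$variant, out$condition, out$severity), ]
}

#' Write campaign results
#'
#' Writes the per-trial table as CSV (stable column order) plus a flat
#' key-value run manifest with the model parameters. Re-running with the
#' same plan and parameters reproduces the files byte for byte.
#'
#' @param results Nonempty [run_grid()] table.
#' @param dir Output directory (created if needed).
#' @param params [default_params()] list recorded in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, dir, params = default_params()) {
  if (is.null(results) || nrow(results) == 0) stop("empty results table")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "results.csv")
  cols <- c("word", "variant", "condition", "severity", "rep", "seed",
            "fscore", "recognition_prob", "n_detected")
  utils::write.csv(results[, intersect(cols, names(results))], csv,
                   row.names = FALSE)
  manifest <- file.path(dir, "manifest.txt")
  vals <- vapply(params, function(v) paste(format(v), collapse = ","),
                 character(1))
  writeLines(c(paste0("package_version=", as.character(utils::packageVersion("onsetfuse"))),
               paste0("n_trials=", nrow(results)),
               paste(names(vals), vals, sep = "=")), manifest)
  invisible(c(csv = csv, manifest = manifest))
}
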