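# Toy linguistic material: words, syllables, phones, and the lexical
# knowledge (word -> syllable, syllable -> phone, canonical onset times)
# shared by the decoding hierarchy and the top-down onset predictor.

#' Phone inventory
#'
#' The seven phones of the toy phonetics: two plosives (`p`, `t`), three
#' vowels (`a`, `i`, `u`), the consonant-vowel transition phone `@`, and the
#' silence / end-of-sequence phone `#`.
#'
#' @format Character vector of length 7.
#' @export
phone_symbols <- c("p", "t", "a", "i", "u", "@", "#")

.vowels <- c("a", "i", "u")
.consonants <- c("p", "t")

#' Silence pseudo-syllable token
#'
#' First-class syllable token representing pure silence after word offset
#' (phone expansion `#-#-#-#`). It lets a spuriously opened third syllable
#' decoder support words of fewer than three syllables.
#'
#' @format Character scalar.
#' @export
sil_token <- "sil"

#' Parse a phone sequence into syllable tokens
#'
#' Greedy deterministic parse of a word's phone sequence into V and CV
#' syllables. A CV syllable is spelled `C-@-V` in the phone sequence. The
#' last syllable of a word is marked word-final by a trailing `#` in its
#' token name (e.g. `"ta#"`), because it absorbs the end-of-sequence phone.
#'
#' @param phones Character vector of phone symbols ending with `"#"`.
#' @return Character vector of syllable tokens, e.g. `c("pa", "ta#")`.
#' @examples
#' syllabify(c("p", "@", "a", "t", "@", "a", "#"))
#' @export
syllabify <- function(phones) {
  if (length(phones) < 2L || phones[length(phones)] != "#")
    stop("phone sequence must end with the silence phone '#'")
  if (!all(phones %in% phone_symbols))
    stop("unknown phone symbol(s): ",
         paste(setdiff(phones, phone_symbols), collapse = ", "))
  core <- phones[-length(phones)]
  sylls <- character(0)
  i <- 1L
  n <- length(core)
  while (i <= n) {
    if (core[i] %in% .vowels) {
      sylls <- c(sylls, core[i])
      i <- i + 1L
    } else if (core[i] %in% .consonants && i + 2L <= n &&
               core[i + 1L] == "@" && core[i + 2L] %in% .vowels) {
      sylls <- c(sylls, paste0(core[i], core[i + 2L]))
      i <- i + 3L
    } else {
      stop("phone sequence not parseable as (V|C-@-V)+ followed by '#'")
    }
  }
  sylls[length(sylls)] <- paste0(sylls[length(sylls)], "#")
  sylls
}

#' @rdname syllable_slots
#' @export
token_final <- function(token) grepl("#$", token) | token == sil_token

token_base <- function(token) sub("#$", "", token)

#' Phone-slot expansion of a syllable token
#'
#' Each syllable token occupies up to four 50-step phone slots:
#' non-final V expands to `V-V` (a lone vowel syllable only occurs
#' word-initially, where it occupies two slots), final V to `V-#`, non-final
#' CV to `C-@-V`, final CV to `C-@-V-#`, and the silence token to `#-#-#-#`.
#'
#' @param token Syllable token such as `"pa"`, `"ta#"` or [sil_token].
#' @return Character vector of phone symbols (length 2--4).
#' @export
syllable_slots <- function(token) {
  if (token == sil_token) return(rep("#", 4L))
  base <- token_base(token)
  final <- token_final(token)
  ch <- strsplit(base, "")[[1]]
  if (length(ch) == 1L) {
    if (!ch %in% .vowels) stop("malformed syllable token: ", token)
    if (final) c(ch, "#") else c(ch, ch)
  } else if (length(ch) == 2L) {
    if (!(ch[1] %in% .consonants && ch[2] %in% .vowels))
      stop("malformed syllable token: ", token)
    if (final) c(ch[1], "@", ch[2], "#") else c(ch[1], "@", ch[2])
  } else stop("malformed syllable token: ", token)
}

# 50-step slot counts of each syllable within a word; the word-initial lone
# vowel occupies one extra slot (so the monosyllable "a" spans V-V-#).
.word_syllable_slot_counts <- function(sylls) {
  counts <- vapply(sylls, function(s) length(syllable_slots(s)), integer(1))
  if (nchar(token_base(sylls[1])) == 1L && token_final(sylls[1]))
    counts[1] <- counts[1] + 1L
  unname(counts)
}

#' Word-level phone slot sequence
#'
#' The sequence of 50-step phone slots a word occupies, including the
#' doubled word-initial vowel.
#'
#' @param sylls Character vector of syllable tokens (from [syllabify()]).
#' @return Character vector of phone symbols, one per 50-step slot.
#' @export
word_slots <- function(sylls) {
  slots <- unlist(lapply(sylls, syllable_slots), use.names = FALSE)
  if (nchar(token_base(sylls[1])) == 1L && token_final(sylls[1]))
    slots <- c(token_base(sylls[1]), slots)
  slots
}

#' Canonical syllabic onset times of a word
#'
#' Cumulative start time (in simulation steps, origin 0) of each syllable,
#' from the 50-step phone-slot expansion. The first onset is always 0.
#'
#' @param word A word label present in `lexicon`, or a character vector of
#'   syllable tokens when `lexicon` is `NULL`.
#' @param lexicon A [build_lexicon()] object (optional if `word` is already
#'   a syllable-token vector).
#' @return Integer vector of onset times.
#' @examples
#' lex <- build_lexicon()
#' canonical_onsets("pata", lex)   # 0 150
#' canonical_onsets("apata", lex)  # 0 100 250
#' @export
canonical_onsets <- function(word, lexicon = NULL) {
  sylls <- if (is.null(lexicon)) word else lexicon_syllables(lexicon, word)
  counts <- .word_syllable_slot_counts(sylls)
  as.integer(50 * c(0, cumsum(counts)[-length(counts)]))
}

#' Syllable inventory of a lexicon
#'
#' Union of all syllable tokens occurring in the lexicon's words, plus the
#' silence pseudo-syllable. Final and non-final variants of the same base
#' syllable are distinct tokens, so the fourth phone slot (`#`) can
#' disambiguate a word from words that embed it during trailing silence.
#'
#' @param lexicon A [build_lexicon()] object (or a list of syllable-token
#'   vectors).
#' @return Character vector of tokens, non-final first, then final, then
#'   [sil_token].
#' @export
build_syllable_inventory <- function(lexicon) {
  sylls <- if (inherits(lexicon, "lexicon")) lexicon$words$syllables else lexicon
  tokens <- unique(unlist(sylls, use.names = FALSE))
  nonfinal <- sort(tokens[!token_final(tokens)])
  final <- sort(tokens[token_final(tokens)])
  c(nonfinal, final, sil_token)
}

# Deterministic 0/1 lexical mappings, mixed with a small uniform component
# (label smoothing) so that a few steps of misaligned evidence cannot
# irrecoverably zero out the correct candidate.
#
# M_syl[[i]][s, w] = P(syllable at position i is s | word w); positions
# beyond a word's length map to the silence token.
# M_pho[[j]][f, s] = P(phone in slot j is f | syllable s); slots beyond a
# FINAL token's expansion map to '#' (post-word silence), slots beyond a
# NON-final token's expansion predict the onset of the (unknown) next
# syllable -- in this lexicon always a consonant, so uniform over {p, t}.
# This asymmetry is what makes trailing silence favour final over
# non-final readings, while a lingering vowel tail (when a decoder was
# opened a few steps early) penalizes both readings equally.

#' Lexical mapping matrices
#'
#' Word-to-syllable matrices (one per syllable position, 3) and
#' syllable-to-phone matrices (one per phone slot, 4). Every column is a
#' probability distribution: deterministic 0/1 composition mixed with a
#' uniform smoothing mass. Word-to-syllable composition is nearly
#' deterministic (`smoothing`); phone-slot predictions are broader
#' (`smoothing_pho`) because slot content is uncertain under timing jitter
#' and unknown continuations, which keeps brief misaligned evidence from
#' irrecoverably toppling tied syllable hypotheses.
#'
#' @param lexicon A [build_lexicon()] object.
#' @param smoothing Uniform mixing weight in \[0, 1) for the
#'   word-to-syllable columns (default 0.02).
#' @param smoothing_pho Uniform mixing weight for the syllable-to-phone
#'   columns (default 0.1).
#' @return List with elements `M_syl` (list of 3 matrices, tokens x words)
#'   and `M_pho` (list of 4 matrices, phones x tokens).
#' @export
lexical_matrices <- function(lexicon, smoothing = 0.02, smoothing_pho = 0.1) {
  inv <- lexicon$inventory
  labels <- lexicon$words$label
  n_tok <- length(inv)
  M_syl <- lapply(1:3, function(i) {
    M <- matrix(0, n_tok, length(labels), dimnames = list(inv, labels))
    for (w in seq_along(labels)) {
      sylls <- lexicon$words$syllables[[w]]
      tok <- if (i <= length(sylls)) sylls[i] else sil_token
      M[tok, w] <- 1
    }
    (1 - smoothing) * M + smoothing / n_tok
  })
  M_pho <- lapply(1:4, function(j) {
    M <- matrix(0, 7L, n_tok, dimnames = list(phone_symbols, inv))
    for (s in seq_len(n_tok)) {
      slots <- syllable_slots(inv[s])
      if (j <= length(slots)) {
        M[slots[j], s] <- 1
      } else if (token_final(inv[s])) {
        M["#", s] <- 1
      } else {
        M[.consonants, s] <- 1 / length(.consonants)
      }
    }
    (1 - smoothing_pho) * M + smoothing_pho / 7
  })
  list(M_syl = M_syl, M_pho = M_pho)
}

#' Build the 28-word toy lexicon
#'
#' Reads the word table (label, dash-separated phone sequence, duration in
#' steps), syllabifies every word, validates that the 50-step phone-slot
#' expansion reproduces the tabulated duration exactly, and precomputes the
#' syllable inventory, lexical mapping matrices and canonical onset times.
#'
#' @param path Path to a lexicon TSV; defaults to the table shipped with the
#'   package.
#' @param smoothing,smoothing_pho Passed to [lexical_matrices()].
#' @return An object of class `"lexicon"`: a list with `words` (data frame
#'   with list-columns `phones` and `syllables`), `inventory`, `M_syl`,
#'   `M_pho`, `onsets` (named list of canonical onset vectors) and
#'   `smoothing`.
#' @examples
#' lex <- build_lexicon()
#' nrow(lex$words)  # 28
#' @export
build_lexicon <- function(path = NULL, smoothing = 0.02,
                          smoothing_pho = 0.1) {
  if (is.null(path))
    path <- system.file("extdata", "lexicon.tsv", package = "onsetfuse",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!identical(names(tab), c("label", "phone_sequence", "duration")))
    stop("malformed lexicon TSV: expected columns label, phone_sequence, duration")
  phones <- vector("list", nrow(tab))
  sylls <- vector("list", nrow(tab))
  for (r in seq_len(nrow(tab))) {
    ph <- strsplit(tab$phone_sequence[r], "-", fixed = TRUE)[[1]]
    if (!all(ph %in% phone_symbols))
      stop("malformed lexicon row ", r, " ('", tab$label[r],
           "'): unknown phone symbol")
    sy <- tryCatch(syllabify(ph), error = function(e)
      stop("malformed lexicon row ", r, " ('", tab$label[r], "'): ",
           conditionMessage(e)))
    dur <- 50L * length(word_slots(sy))
    if (dur != tab$duration[r])
      stop("lexicon row ", r, " ('", tab$label[r], "'): slot expansion gives ",
           dur, " steps but table says ", tab$duration[r])
    phones[[r]] <- ph
    sylls[[r]] <- sy
  }
  words <- data.frame(label = tab$label, duration = as.integer(tab$duration),
                      n_syllables = vapply(sylls, length, integer(1)),
                      stringsAsFactors = FALSE)
  words$phones <- phones
  words$syllables <- sylls
  lex <- list(words = words,
              inventory = build_syllable_inventory(sylls),
              smoothing = smoothing)
  mats <- lexical_matrices(lex, smoothing, smoothing_pho)
  lex$M_syl <- mats$M_syl
  lex$M_pho <- mats$M_pho
  lex$onsets <- lapply(sylls, canonical_onsets)
  names(lex$onsets) <- words$label
  class(lex) <- "lexicon"
  lex
}

lexicon_word_row <- function(lexicon, word) {
  r <- match(word, lexicon$words$label)
  if (is.na(r)) stop("unknown word label: ", word)
  r
}

#' @rdname build_lexicon
#' @param word A word label.
#' @export
lexicon_syllables <- function(lexicon, word) {
  lexicon$words$syllables[[lexicon_word_row(lexicon, word)]]
}

#' @export
print.lexicon <- function(x, ...) {
  cat("Toy lexicon:", nrow(x$words), "words,",
      length(x$inventory), "syllable tokens (incl. silence)\n")
  cat("Syllable counts:",
      paste(names(table(x$words$n_syllables)),
            table(x$words$n_syllables), sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Stimulus word labels
#'
#' Labels of the words used as stimuli in the simulation campaign: all
#' non-monosyllabic words (21 of 28). Monosyllables only contain the initial
#' onset and are kept as recognition candidates, never presented.
#'
#' @param lexicon A [build_lexicon()] object.
#' @return Character vector of 21 labels.
#' @export
stimulus_words <- function(lexicon) {
  lexicon$words$label[lexicon$words$n_syllables >= 2L]
}
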