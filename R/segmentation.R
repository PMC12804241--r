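#' Segment a word into aligned grapheme-phoneme pairs
#'
#' Produces the attested segmentation of a written word into graphemes, each
#' paired with the phoneme token(s) it spells in this word.  Parsing is
#' phonology-constrained: the word's known pronunciation is consumed along
#' with its letters, so the result records the attested pairing rather than a
#' predicted one.  The parse always reconstructs both sides exactly:
#' concatenated graphemes equal the orthography and concatenated phonemes
#' equal the phonology.
#'
#' The search scans left to right.  At each position candidate steps are
#' ranked by rule precedence — longer graphemes before shorter,
#' context-sensitive before context-free at equal length, then rule-file
#' order — and a rule is preferred when its phoneme sequence matches the next
#' unconsumed phonemes (silent graphemes consume none).  In `"lenient"` mode
#' (the default), a grapheme whose rule phoneme does not match may still be
#' used with the single next phoneme assigned to it; these irregular pairings
#' rank below all rule-consistent steps, so regular words always get their
#' rule segmentation, while exception words (e.g. a vowel grapheme with an
#' unpredictable pronunciation) still receive the segmentation a human coder
#' would assign.  `"strict"` mode forbids such fallback pairings and
#' additionally errors when more than one fully rule-consistent parse exists.
#'
#' @param orthography written form: a string or a letter vector.
#' @param phonology pronunciation: a transcription string or phoneme-token
#'   vector.
#' @param rules a [gpc_rules()] table.
#' @param config a [language_config()].
#' @param mode `"lenient"` (default) or `"strict"`.
#' @return An object of class `grapheme_parse`: a list with parallel list
#'   elements `graphemes` (letter vectors) and `phonemes` (phoneme-token
#'   vectors, possibly empty for silent graphemes).
#' @examples
#' cfg <- language_config(letters = c("t", "h", "a", "c"),
#'                        phonemes = c("t", "θ", "æ", "k"),
#'                        vowel_letters = "a", vowel_phonemes = "æ")
#' rl <- gpc_rules(c("t", "th", "a", "c"), c("t", "θ", "æ", "k"), config = cfg)
#' parse_graphemes("that", "θæt", rl, cfg)
#' @export
parse_graphemes <- function(orthography, phonology, rules, config,
                            mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rules, "gpc_rules"), nrow(rules) > 0L,
            inherits(config, "language_config"))
  letters <- if (length(orthography) > 1L) norm_symbols(orthography)
             else split_letters(tolower(orthography), config)
  phon <- if (length(phonology) > 1L) norm_symbols(phonology)
          else tokenize_phonemes(phonology, config)

  prec <- rule_precedence(rules)
  n_l <- length(letters)
  n_p <- length(phon)

  # depth-first search; returns list of parses (1 in lenient / first-match,
  # up to 2 in strict to detect ambiguity)
  want <- if (mode == "strict") 2L else 1L
  found <- list()

  search <- function(li, pi, acc) {
    if (length(found) >= want) return()
    if (li > n_l) {
      if (pi > n_p) found[[length(found) + 1L]] <<- acc
      return()
    }
    steps <- list()
    fallback <- list()
    for (i in prec) {
      if (!rule_applies(rules, i, letters, li)) next
      g <- rules$grapheme_letters[[i]]
      rp <- rules$phoneme_tokens[[i]]
      k <- length(rp)
      if (k == 0L) {
        steps[[length(steps) + 1L]] <- list(g = g, p = character())
      } else if (pi + k - 1L <= n_p &&
                 identical(phon[pi:(pi + k - 1L)], rp)) {
        steps[[length(steps) + 1L]] <- list(g = g, p = phon[pi:(pi + k - 1L)])
      } else if (mode == "lenient" && pi <= n_p) {
        # irregular pairing: grapheme takes the single next phoneme
        fallback[[length(fallback) + 1L]] <- list(g = g, p = phon[pi])
      }
    }
    if (mode == "lenient") steps <- c(steps, dedup_steps(fallback))
    for (st in steps) {
      search(li + length(st$g), pi + length(st$p),
             c(acc, list(st)))
      if (length(found) >= want) return()
    }
  }
  search(1L, 1L, list())

  word <- paste(letters, collapse = "")
  if (length(found) == 0L)
    stop("no grapheme parse for ", sQuote(word), " /",
         paste(phon, collapse = " "), "/ under the given rules")
  if (mode == "strict" && length(found) > 1L)
    stop("ambiguous grapheme parse for ", sQuote(word),
         " beyond rule precedence (strict mode)")
  pairs <- found[[1L]]
  res <- structure(
    list(
      graphemes = lapply(pairs, `[[`, "g"),
      phonemes = lapply(pairs, `[[`, "p"),
      orthography = letters,
      phonology = phon
    ),
    class = "grapheme_parse"
  )
  # reconstruction invariants, asserted on every successful parse
  stopifnot(identical(unlist(res$graphemes), letters),
            identical(as.character(unlist(res$phonemes)), phon))
  res
}

# drop fallback steps duplicating the same (grapheme, phoneme) move
dedup_steps <- function(steps) {
  if (length(steps) < 2L) return(steps)
  key <- vapply(steps, function(s)
    paste(paste(s$g, collapse = ""), paste(s$p, collapse = " ")), "")
  steps[!duplicated(key)]
}

#' @export
print.grapheme_parse <- function(x, ...) {
  g <- vapply(x$graphemes, paste, "", collapse = "")
  p <- vapply(x$phonemes, function(t)
    if (length(t)) paste(t, collapse = " ") else "∅", "")
  cat("<grapheme_parse> ", paste(sprintf("(%s → /%s/)", g, p),
                                 collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Parse a monosyllabic word into onset, vowel and coda
#'
#' Splits the orthography at the first maximal run of vowel letters: letters
#' before it form the onset, the run itself is the vowel grapheme, and the
#' remainder is the coda; vowel grapheme plus coda make up the orthographic
#' body.  The phonology is split analogously at its maximal run of nucleus
#' tokens (vowel phonemes plus syllabic consonants), giving onset phonemes,
#' nucleus, and rime (nucleus plus coda phonemes).
#'
#' @param orthography written form: a string or letter vector.
#' @param phonology pronunciation: a string or phoneme-token vector.
#' @param config a [language_config()].
#' @return An object of class `syllable_parse` with elements
#'   `onset_letters`, `vowel_grapheme`, `coda_letters`, `body_letters`,
#'   `onset_phonemes`, `nucleus_phonemes`, `coda_phonemes`, `rime_phonemes`.
#' @export
parse_syllable <- function(orthography, phonology, config) {
  stopifnot(inherits(config, "language_config"))
  letters <- if (length(orthography) > 1L) norm_symbols(orthography)
             else split_letters(tolower(orthography), config)
  phon <- if (length(phonology) > 1L) norm_symbols(phonology)
          else tokenize_phonemes(phonology, config)

  isv <- letters %in% config$vowel_letters
  if (!any(isv))
    stop("no vowel letter in ", sQuote(paste(letters, collapse = "")))
  v1 <- which(isv)[1L]
  v_end <- v1
  while (v_end < length(letters) && isv[v_end + 1L]) v_end <- v_end + 1L

  nuc <- nucleus_tokens(config)
  isn <- phon %in% nuc
  if (!any(isn))
    stop("no nucleus phoneme in /", paste(phon, collapse = " "), "/")
  n1 <- which(isn)[1L]
  n_end <- n1
  while (n_end < length(phon) && isn[n_end + 1L]) n_end <- n_end + 1L

  structure(
    list(
      onset_letters = if (v1 > 1L) letters[1:(v1 - 1L)] else character(),
      vowel_grapheme = letters[v1:v_end],
      coda_letters = if (v_end < length(letters))
        letters[(v_end + 1L):length(letters)] else character(),
      body_letters = letters[v1:length(letters)],
      onset_phonemes = if (n1 > 1L) phon[1:(n1 - 1L)] else character(),
      nucleus_phonemes = phon[n1:n_end],
      coda_phonemes = if (n_end < length(phon))
        phon[(n_end + 1L):length(phon)] else character(),
      rime_phonemes = phon[n1:length(phon)]
    ),
    class = "syllable_parse"
  )
}

#' @export
print.syllable_parse <- function(x, ...) {
  cat("<syllable_parse> onset=", paste(x$onset_letters, collapse = ""),
      " vowel=", paste(x$vowel_grapheme, collapse = ""),
      " coda=", paste(x$coda_letters, collapse = ""),
      " | /", paste(x$onset_phonemes, collapse = " "),
      " . ", paste(x$nucleus_phonemes, collapse = " "),
      " . ", paste(x$coda_phonemes, collapse = " "), "/\n", sep = "")
  invisible(x)
}

#' Align letters (or bigrams) with phonemes (or biphones) by position
#'
#' One-to-one, left-to-right positional alignment: the i-th letter is paired
#' with the i-th phoneme token.  Trailing unmatched units on either side are
#' discarded, so the letter-level alignment always has
#' `min(n_letters, n_phonemes)` pairs.  At the bigram level, overlapping
#' adjacent pairs of the already-aligned letter sequence are paired with
#' overlapping adjacent pairs of the aligned phoneme sequence (single-letter
#' alignments yield no bigrams); set `overlap = FALSE` for disjoint windows.
#'
#' @param orthography written form: a string or letter vector.
#' @param phonology pronunciation: a string or phoneme-token vector.
#' @param level `"letters"` or `"bigrams"`.
#' @param config a [language_config()].
#' @param overlap logical; overlapping (default) or disjoint bigram windows.
#' @return A data frame with character columns `ortho` and `phono`, one row
#'   per aligned unit pair, in word order.
#' @examples
#' cfg <- language_config(letters = c("c", "h", "a", "t"),
#'                        phonemes = c("tʃ", "æ", "t"),
#'                        vowel_letters = "a", vowel_phonemes = "æ")
#' align_positional("chat", "tʃæt", "letters", cfg)  # a is paired with /t/
#' @export
align_positional <- function(orthography, phonology,
                             level = c("letters", "bigrams"),
                             config, overlap = TRUE) {
  level <- match.arg(level)
  letters <- if (length(orthography) > 1L) norm_symbols(orthography)
             else split_letters(tolower(orthography), config)
  phon <- if (length(phonology) > 1L) norm_symbols(phonology)
          else tokenize_phonemes(phonology, config)
  m <- min(length(letters), length(phon))
  l <- letters[seq_len(m)]
  p <- phon[seq_len(m)]
  if (level == "letters")
    return(data.frame(ortho = l, phono = p, stringsAsFactors = FALSE))
  if (m < 2L)
    return(data.frame(ortho = character(), phono = character(),
                      stringsAsFactors = FALSE))
  starts <- if (overlap) seq_len(m - 1L) else seq(1L, m - 1L, by = 2L)
  data.frame(
    ortho = paste0(l[starts], l[starts + 1L]),
    phono = paste(p[starts], p[starts + 1L]),
    stringsAsFactors = FALSE
  )
}

# parse every entry of a lexicon; returns list with parses (NULL on failure)
# and a logical vector of failures
parse_lexicon_graphemes <- function(lex, rules, mode = "lenient") {
  n <- length(lex)
  parses <- vector("list", n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    parses[[i]] <- tryCatch(
      parse_graphemes(lex$orthography[[i]], lex$phonology[[i]],
                      rules, lex$config, mode = mode),
      error = function(e) NULL
    )
    failed[i] <- is.null(parses[[i]])
  }
  list(parses = parses, failed = failed)
}

parse_lexicon_syllables <- function(lex) {
  lapply(seq_len(length(lex)), function(i)
    parse_syllable(lex$orthography[[i]], lex$phonology[[i]], lex$config))
}
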