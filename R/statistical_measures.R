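#' Discrete probability distributions and Shannon entropy
#'
#' `prob_dist()` builds a discrete distribution over outcomes, either from
#' probabilities directly or from non-negative counts/weights (normalized to
#' sum to one; zero-weight outcomes are dropped).  `entropy()` computes its
#' Shannon entropy in bits, the uncertainty of the outcome: zero for a
#' single outcome, `log2(n)` for a uniform distribution over `n` outcomes.
#'
#' @param p numeric vector of probabilities (summing to 1) or, with
#'   `counts = TRUE`, non-negative counts; may be named by outcome.
#' @param outcomes optional outcome labels.
#' @param counts interpret `p` as counts and normalize.
#' @return `prob_dist()`: an object of class `prob_dist` (a named numeric
#'   vector of positive probabilities summing to 1).  `entropy()`: entropy
#'   in bits.
#' @examples
#' entropy(prob_dist(c(0.25, 0.75)))        # 0.811...
#' entropy(prob_dist(rep(0.25, 4)))         # exactly 2 bits
#' @export
prob_dist <- function(p, outcomes = NULL, counts = FALSE) {
  if (!is.null(outcomes)) names(p) <- outcomes
  if (is.null(names(p))) names(p) <- paste0("x", seq_along(p))
  if (any(p < 0)) stop("negative probability or count")
  if (counts) {
    tot <- sum(p)
    if (tot <= 0) stop("counts sum to zero")
    p <- p / tot
  }
  p <- p[p > 0]
  if (!length(p)) stop("empty distribution")
  if (abs(sum(p) - 1) > 1e-9)
    stop("probabilities sum to ", format(sum(p)), ", not 1")
  structure(p, class = "prob_dist")
}

#' @rdname prob_dist
#' @param dist a `prob_dist` (or bare probability vector, validated first).
#' @export
entropy <- function(dist) {
  if (!inherits(dist, "prob_dist")) dist <- prob_dist(dist)
  p <- unclass(dist)
  -sum(p * log2(p))
}

# entropy of a count/weight vector (terms with zero weight contribute 0)
entropy_counts <- function(cnt) {
  cnt <- cnt[cnt > 0]
  if (length(cnt) <= 1L) return(0)
  p <- cnt / sum(cnt)
  -sum(p * log2(p))
}

#' @export
print.prob_dist <- function(x, ...) {
  cat("<prob_dist over", length(x), "outcomes, H =",
      format(entropy(x), digits = 4), "bits>\n")
  print(unclass(x))
  invisible(x)
}

#' Spelling-to-sound consistency of an orthographic unit
#'
#' For each monosyllabic word, the consistency of its orthographic unit
#' (vowel grapheme or body) is the proportion of words sharing that unit —
#' the word itself included — that also share the unit's pronunciation
#' (nucleus for the vowel, rime for the body): its friends among friends
#' plus enemies.  Values lie in `[0, 1]`; the lexicon mean is the
#' orthography-level measure, with low values marking a deep orthography.
#'
#' @param lex a monosyllabic `lexicon`.
#' @param unit `"vowel"` (vowel grapheme vs nucleus) or `"body"`
#'   (vowel-plus-coda letters vs rime).
#' @param freq_weighted weight words by token frequency, both inside the
#'   friend/enemy counts and in the mean.
#' @return A list of class `consistency_scores`: `per_word` (named numeric),
#'   `mean`, `unit`, and `n_singletons` (words whose unit occurs nowhere
#'   else; their consistency is 1 by the self-inclusive definition).
#' @export
unit_consistency <- function(lex, unit = c("vowel", "body"),
                             freq_weighted = FALSE) {
  unit <- match.arg(unit)
  stopifnot(inherits(lex, "lexicon"))
  if (length(lex) == 0L) stop("empty lexicon")
  syl <- parse_lexicon_syllables(lex)
  w <- entry_weights(lex, freq_weighted)
  o_unit <- vapply(syl, function(s) paste(
    if (unit == "vowel") s$vowel_grapheme else s$body_letters,
    collapse = ""), "")
  p_unit <- vapply(syl, function(s) paste(
    if (unit == "vowel") s$nucleus_phonemes else s$rime_phonemes,
    collapse = " "), "")
  per_word <- numeric(length(lex))
  for (i in seq_along(per_word)) {
    sharers <- o_unit == o_unit[i]
    friends <- sharers & p_unit == p_unit[i]
    per_word[i] <- sum(w[friends]) / sum(w[sharers])
  }
  names(per_word) <- orth_strings(lex)
  singletons <- vapply(seq_along(o_unit),
                       function(i) sum(o_unit == o_unit[i]) == 1L, logical(1))
  structure(
    list(per_word = per_word,
         mean = sum(w * per_word) / sum(w),
         unit = unit,
         n_singletons = sum(singletons)),
    class = "consistency_scores"
  )
}

#' @export
print.consistency_scores <- function(x, ...) {
  cat("<consistency_scores unit=", x$unit, ": mean ",
      format(x$mean, digits = 4), " over ", length(x$per_word),
      " words (", x$n_singletons, " singleton units)>\n", sep = "")
  invisible(x)
}

#' Onset entropy of an orthography
#'
#' For each word-initial letter, the entropy (in bits) of the distribution
#' of word-initial phonemes among words beginning with that letter; the
#' per-letter entropies are then summed, each weighted by the probability
#' that a word begins with that letter.  Sensitive both to unpredictable
#' initial correspondences (gift/gist) and to predictable complexity
#' (seat/sheet, where s opens the multiletter grapheme sh).
#'
#' @param lex a `lexicon`.
#' @param freq_weighted use token-frequency-weighted probabilities.
#' @return Onset entropy in bits.
#' @export
onset_entropy <- function(lex, freq_weighted = FALSE) {
  stopifnot(inherits(lex, "lexicon"))
  if (length(lex) == 0L) stop("empty lexicon")
  w <- entry_weights(lex, freq_weighted)
  l1 <- vapply(lex$orthography, `[`, "", 1L)
  p1 <- vapply(lex$phonology, `[`, "", 1L)
  tot <- sum(w)
  val <- 0
  for (ltr in unique(l1)) {
    sel <- l1 == ltr
    h <- entropy_counts(tapply(w[sel], p1[sel], sum))
    val <- val + (sum(w[sel]) / tot) * h
  }
  val
}

#' Vowel-grapheme entropy, context-independent or context-dependent
#'
#' For each vowel grapheme, the entropy of the distribution of its nucleus
#' pronunciations across monosyllabic words.  Context-independent entropy
#' pools all words containing the grapheme; onset- and coda-conditional
#' variants additionally condition on the full orthographic onset or coda
#' string (words with an empty onset form their own empty-string context).
#' Per-grapheme (and per-context) entropies are averaged weighted by
#' occurrence counts, so by the law of total entropy conditioning can only
#' lower the value.
#'
#' @param lex a monosyllabic `lexicon`.
#' @param mode `"context_independent"`, `"onset_conditional"` or
#'   `"coda_conditional"`.
#' @param freq_weighted use token-frequency weights.
#' @return Weighted mean vowel entropy in bits.
#' @export
vowel_entropy <- function(lex,
                          mode = c("context_independent", "onset_conditional",
                                   "coda_conditional"),
                          freq_weighted = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(lex, "lexicon"))
  if (length(lex) == 0L) stop("empty lexicon")
  syl <- parse_lexicon_syllables(lex)
  w <- entry_weights(lex, freq_weighted)
  vg <- vapply(syl, function(s) paste(s$vowel_grapheme, collapse = ""), "")
  nucleus <- vapply(syl, function(s) paste(s$nucleus_phonemes,
                                           collapse = " "), "")
  ctx <- switch(mode,
    context_independent = rep("", length(syl)),
    onset_conditional = vapply(syl, function(s)
      paste(s$onset_letters, collapse = ""), ""),
    coda_conditional = vapply(syl, function(s)
      paste(s$coda_letters, collapse = ""), "")
  )
  grp <- paste(vg, ctx, sep = "\r")
  tot <- sum(w)
  val <- 0
  for (g in unique(grp)) {
    sel <- grp == g
    h <- entropy_counts(tapply(w[sel], nucleus[sel], sum))
    val <- val + (sum(w[sel]) / tot) * h
  }
  val
}

#' All entropy measures of a lexicon
#'
#' Convenience wrapper returning onset entropy and the three vowel-entropy
#' variants together.
#'
#' @inheritParams vowel_entropy
#' @return A list with `onset_entropy`, `vowel_entropy_ci`,
#'   `vowel_entropy_onset_cond`, `vowel_entropy_coda_cond` (bits).
#' @export
entropy_summary <- function(lex, freq_weighted = FALSE) {
  list(
    onset_entropy = onset_entropy(lex, freq_weighted),
    vowel_entropy_ci = vowel_entropy(lex, "context_independent",
                                     freq_weighted),
    vowel_entropy_onset_cond = vowel_entropy(lex, "onset_conditional",
                                             freq_weighted),
    vowel_entropy_coda_cond = vowel_entropy(lex, "coda_conditional",
                                            freq_weighted)
  )
}
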