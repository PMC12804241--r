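#' Orthography-phonology co-occurrence counts
#'
#' Counts how often each orthographic unit is aligned with each phonological
#' unit across all words of the lexicon, pooling positions.  At the
#' `"letters"` level units are single letters vs single phonemes, aligned
#' one-to-one left-to-right with trailing unmatched units discarded;
#' repeated letters within a word are separate observations.  At the
#' `"bigrams"` level units are overlapping adjacent pairs of the aligned
#' sequences.  At the `"graphemes"` level units come from grapheme parses:
#' each grapheme is paired with its full phoneme sequence as one token, and
#' silent graphemes pair with an explicit null token `"∅"`.
#'
#' @param lex a `lexicon`.
#' @param level `"letters"`, `"bigrams"` or `"graphemes"`.
#' @param rules a [gpc_rules()] table; required at the grapheme level.
#' @param overlap overlapping (default) or disjoint bigram windows.
#' @param freq_weighted weight observations by word token frequency.
#' @return A contingency table (class `table`) of counts, orthographic units
#'   in rows, phonological units in columns, with an attribute
#'   `n_unparsed` at grapheme level.
#' @export
joint_counts <- function(lex, level = c("letters", "bigrams", "graphemes"),
                         rules = NULL, overlap = TRUE,
                         freq_weighted = FALSE) {
  level <- match.arg(level)
  stopifnot(inherits(lex, "lexicon"))
  w <- entry_weights(lex, freq_weighted)
  o_units <- character()
  p_units <- character()
  wt <- numeric()
  n_unparsed <- 0L
  if (level == "graphemes") {
    if (is.null(rules))
      stop("grapheme-level counts require a GPC rule table")
    pl <- parse_lexicon_graphemes(lex, rules)
    n_unparsed <- sum(pl$failed)
    for (i in seq_len(length(lex))) {
      pr <- pl$parses[[i]]
      if (is.null(pr)) next
      g <- vapply(pr$graphemes, paste, "", collapse = "")
      p <- vapply(pr$phonemes, function(t)
        if (length(t)) paste(t, collapse = " ") else "∅", "")
      o_units <- c(o_units, g)
      p_units <- c(p_units, p)
      wt <- c(wt, rep(w[i], length(g)))
    }
  } else {
    for (i in seq_len(length(lex))) {
      al <- align_positional(lex$orthography[[i]], lex$phonology[[i]],
                             level, lex$config, overlap = overlap)
      if (nrow(al) == 0L) next
      o_units <- c(o_units, al$ortho)
      p_units <- c(p_units, al$phono)
      wt <- c(wt, rep(w[i], nrow(al)))
    }
  }
  if (!length(o_units)) {
    tab <- table(factor(character()), factor(character()))
  } else {
    tab <- stats::xtabs(wt ~ o + p,
                        data = data.frame(o = o_units, p = p_units, wt = wt,
                                          stringsAsFactors = FALSE))
    class(tab) <- "table"
    names(dimnames(tab)) <- NULL
  }
  attr(tab, "n_unparsed") <- n_unparsed
  tab
}

#' Mutual information and efficiency of an orthography-phonology mapping
#'
#' From a co-occurrence table of aligned orthographic and phonological
#' units, computes the phonological entropy H(P) from the marginal
#' distribution of phonological units, the conditional entropy
#' H(P|O) = sum over o of P(o) H(P | O = o), the mutual information
#' I(O;P) = H(P) - H(P|O), and the efficiency I(O;P) / H(P) — the
#' proportion of phonological uncertainty removed by knowing the spelling.
#' Efficiency is 1 for a fully transparent mapping (H(P|O) = 0) and 0 when
#' orthography and phonology are statistically unrelated.  Probabilities are
#' maximum-likelihood relative frequencies; no smoothing is applied.
#'
#' @param counts a contingency table from [joint_counts()] (orthographic
#'   units in rows).
#' @param level optional level label carried into the result.
#' @return An object of class `efficiency_profile`: a list with `level`,
#'   `H_P`, `H_P_given_O`, `I_OP`, `efficiency`, `n_observations`.
#' @export
mutual_information <- function(counts, level = NA_character_) {
  m <- as.matrix(counts)
  if (length(m) == 0L || sum(m) <= 0) stop("empty co-occurrence table")
  tot <- sum(m)
  p_o <- rowSums(m) / tot
  H_P <- entropy_counts(colSums(m))
  H_cond <- sum(vapply(seq_len(nrow(m)), function(i)
    p_o[i] * entropy_counts(m[i, ]), numeric(1)))
  I <- H_P - H_cond
  if (H_P <= 0) {
    warning("H(P) = 0: single phonological unit; efficiency reported as 1")
    eff <- 1
  } else {
    eff <- I / H_P
  }
  structure(
    list(level = level, H_P = H_P, H_P_given_O = H_cond, I_OP = I,
         efficiency = eff, n_observations = tot),
    class = "efficiency_profile"
  )
}

#' @export
print.efficiency_profile <- function(x, ...) {
  cat(sprintf(
    "<efficiency_profile %s: H(P)=%.3f  H(P|O)=%.3f  I(O;P)=%.3f  efficiency=%.3f>\n",
    x$level, x$H_P, x$H_P_given_O, x$I_OP, x$efficiency))
  invisible(x)
}

#' Efficiency profiles at the three grain sizes
#'
#' Computes [mutual_information()] from [joint_counts()] at the
#' letter/phoneme, bigram/biphone, and grapheme/phoneme levels with
#' consistent preprocessing.
#'
#' @inheritParams joint_counts
#' @return A named list of three `efficiency_profile` objects (`letters`,
#'   `bigrams`, `graphemes`); the grapheme entry is `NULL` with a warning
#'   when no rules are supplied.
#' @export
efficiency_profile_all <- function(lex, rules = NULL, overlap = TRUE,
                                   freq_weighted = FALSE) {
  out <- list(
    letters = mutual_information(
      joint_counts(lex, "letters", freq_weighted = freq_weighted),
      level = "letters"),
    bigrams = mutual_information(
      joint_counts(lex, "bigrams", overlap = overlap,
                   freq_weighted = freq_weighted),
      level = "bigrams"),
    graphemes = NULL
  )
  if (!is.null(rules)) {
    out$graphemes <- mutual_information(
      joint_counts(lex, "graphemes", rules = rules,
                   freq_weighted = freq_weighted),
      level = "graphemes")
  } else {
    warning("no GPC rules supplied; grapheme-level profile skipped")
  }
  out
}
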