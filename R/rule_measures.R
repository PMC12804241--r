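#' Percentage of words with equal letter and phoneme counts
#'
#' The simplest proxy for complexity: the share of words whose written form
#' has exactly as many letters as the pronunciation has phonemes.  In a
#' perfectly shallow orthography with one-letter, one-phoneme
#' correspondences this is 100%; multiletter graphemes and silent letters
#' push it down.
#'
#' @param lex a `lexicon`.
#' @param freq_weighted weight words by token frequency instead of counting
#'   each word once.
#' @return Percentage in `[0, 100]`.
#' @export
pct_equal_length <- function(lex, freq_weighted = FALSE) {
  stopifnot(inherits(lex, "lexicon"))
  if (length(lex) == 0L) stop("empty lexicon")
  w <- entry_weights(lex, freq_weighted)
  eq <- lengths(lex$orthography) == lengths(lex$phonology)
  100 * sum(w[eq]) / sum(w)
}

#' Count distinct grapheme-phoneme pairings
#'
#' Across a collection of grapheme parses, counts the distinct
#' (grapheme, phoneme sequence) pairs that occur.  A grapheme pronounced one
#' way everywhere contributes one pairing; each additional pronunciation
#' contributes another, so the count grows with both complexity and
#' unpredictability.
#'
#' @param parses a list of `grapheme_parse` objects (see
#'   [parse_graphemes()]); `NULL` elements (failed parses) are skipped.
#' @return Integer count of unique pairings.
#' @export
count_unique_gp_mappings <- function(parses) {
  keys <- unlist(lapply(parses, function(pr) {
    if (is.null(pr)) return(character())
    mapply(function(g, p) paste0(paste(g, collapse = ""), "→",
                                 paste(p, collapse = " ")),
           pr$graphemes, pr$phonemes)
  }), use.names = FALSE)
  length(unique(keys))
}

# distinct graphemes observed across parses
count_unique_graphemes <- function(parses) {
  keys <- unlist(lapply(parses, function(pr) {
    if (is.null(pr)) return(character())
    vapply(pr$graphemes, paste, "", collapse = "")
  }), use.names = FALSE)
  length(unique(keys))
}

#' Summarize a rule system by rule class
#'
#' Counts single-letter, multiletter and context-sensitive rules and their
#' percentages of the total.  The number of complex (multiletter plus
#' context-sensitive) rules indexes the complexity of an orthography.
#'
#' @param rules a [gpc_rules()] table.
#' @return A list with `n_single`, `n_multi`, `n_context`, `n_total`, and
#'   `pct` (named percentage vector summing to 100).
#' @export
classify_rules <- function(rules) {
  stopifnot(inherits(rules, "gpc_rules"), nrow(rules) > 0L)
  n_single <- sum(rules$rule_class == "single-letter")
  n_multi <- sum(rules$rule_class == "multiletter")
  n_context <- sum(rules$rule_class == "context-sensitive")
  n <- nrow(rules)
  list(
    n_single = n_single,
    n_multi = n_multi,
    n_context = n_context,
    n_total = n,
    pct = c(single_letter = 100 * n_single / n,
            multiletter = 100 * n_multi / n,
            context_sensitive = 100 * n_context / n)
  )
}

#' Derive a word's pronunciation from GPC rules
#'
#' Deterministic left-to-right application of the rule table, the sublexical
#' reading route of rule-based models: at each position the
#' highest-precedence applicable rule fires (longer graphemes before
#' shorter, context-sensitive before context-free at equal length, then
#' rule-file order) and the scan advances past its grapheme.  No use is made
#' of the attested pronunciation, so comparing the output against it
#' determines regularity.
#'
#' @param orthography written form: a string or letter vector.
#' @param rules a [gpc_rules()] table.
#' @param config a [language_config()].
#' @return Character vector of predicted phoneme tokens.
#' @examples
#' cfg <- language_config(letters = c("g", "i", "f", "t", "s"),
#'                        phonemes = c("g", "dʒ", "ɪ", "f", "t", "s"),
#'                        vowel_letters = "i", vowel_phonemes = "ɪ")
#' rl <- gpc_rules(c("g", "i", "f", "t", "s"),
#'                 c("g", "ɪ", "f", "t", "s"), config = cfg)
#' apply_rules("gist", rl, cfg)  # hard-g prediction: g ɪ s t
#' @export
apply_rules <- function(orthography, rules, config) {
  stopifnot(inherits(rules, "gpc_rules"), nrow(rules) > 0L)
  letters <- if (length(orthography) > 1L) norm_symbols(orthography)
             else split_letters(tolower(orthography), config)
  prec <- rule_precedence(rules)
  out <- character()
  pos <- 1L
  n <- length(letters)
  while (pos <= n) {
    fired <- FALSE
    for (i in prec) {
      if (rule_applies(rules, i, letters, pos)) {
        out <- c(out, rules$phoneme_tokens[[i]])
        pos <- pos + length(rules$grapheme_letters[[i]])
        fired <- TRUE
        break
      }
    }
    if (!fired)
      stop("no rule applies at letter position ", pos, " of ",
           sQuote(paste(letters, collapse = "")))
  }
  out
}

#' Percentage of irregular words under a rule system
#'
#' A word is irregular when the pronunciation derived by [apply_rules()]
#' differs from its attested pronunciation; the percentage of irregular
#' words quantifies the unpredictability of the orthography under that rule
#' system.  Words the rules cannot cover at all are counted as irregular and
#' reported separately, so coverage gaps can be told apart from genuine
#' exceptions.
#'
#' @param lex a `lexicon`.
#' @param rules a [gpc_rules()] table.
#' @param freq_weighted weight words by token frequency.
#' @return Percentage in `[0, 100]`, with attributes `n_irregular` and
#'   `n_unparsed` (words with no rule coverage, included in the count).
#' @export
pct_irregular <- function(lex, rules, freq_weighted = FALSE) {
  stopifnot(inherits(lex, "lexicon"))
  if (length(lex) == 0L) stop("empty lexicon")
  w <- entry_weights(lex, freq_weighted)
  n <- length(lex)
  irregular <- logical(n)
  unparsed <- logical(n)
  for (i in seq_len(n)) {
    pred <- tryCatch(apply_rules(lex$orthography[[i]], rules, lex$config),
                     error = function(e) NULL)
    if (is.null(pred)) {
      unparsed[i] <- TRUE
      irregular[i] <- TRUE
    } else {
      irregular[i] <- !identical(pred, lex$phonology[[i]])
    }
  }
  res <- 100 * sum(w[irregular]) / sum(w)
  attr(res, "n_irregular") <- sum(irregular)
  attr(res, "n_unparsed") <- sum(unparsed)
  res
}

#' Induce modal GPC rules from attested parses
#'
#' For each grapheme observed in the parses (optionally split by its
#' following letter as a context), emits the most frequent phoneme mapping
#' by type count — the single mapping a rule-based system is assumed to
#' store, discarding minority pronunciations.  Exact ties are broken in
#' favor of the lexicographically smaller phoneme string and recorded in the
#' `ties` attribute.
#'
#' @param parses a list of `grapheme_parse` objects; `NULL` elements
#'   skipped.
#' @param config a [language_config()].
#' @param grain `"grapheme"` (default) or `"grapheme+context"`, which
#'   conditions each grapheme on the letter immediately following it
#'   (word-final occurrences condition on the empty context).
#' @return A [gpc_rules()] table with one rule per grapheme (or per
#'   grapheme-context), plus a `ties` attribute naming tied graphemes.
#' @export
induce_modal_rules <- function(parses, config,
                               grain = c("grapheme", "grapheme+context")) {
  grain <- match.arg(grain)
  recs <- list()
  for (pr in parses) {
    if (is.null(pr)) next
    k <- length(pr$graphemes)
    offs <- cumsum(c(1L, vapply(pr$graphemes, length, 1L)))
    for (j in seq_len(k)) {
      g <- paste(pr$graphemes[[j]], collapse = "")
      p <- paste(pr$phonemes[[j]], collapse = " ")
      ctx <- ""
      if (grain == "grapheme+context") {
        nxt <- offs[j + 1L]
        ctx <- if (nxt <= length(pr$orthography)) pr$orthography[nxt] else ""
      }
      recs[[length(recs) + 1L]] <- c(g = g, p = p, ctx = ctx)
    }
  }
  if (!length(recs))
    return(gpc_rules(character(), character(), config = config))
  df <- as.data.frame(do.call(rbind, recs), stringsAsFactors = FALSE)
  key <- paste(df$g, df$ctx, sep = "\r")
  ties <- character()
  rows <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    tab <- sort(table(df$p[idx]), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      ties <<- c(ties, df$g[idx[1L]])
      top <- sort(top)[1L]
    } else top <- top[1L]
    c(g = df$g[idx[1L]], p = top, ctx = df$ctx[idx[1L]])
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  res <- gpc_rules(grapheme = out$g, phoneme = out$p,
                   post = out$ctx, config = config)
  if (length(ties)) {
    message("modal-rule ties for grapheme(s): ",
            paste(unique(ties), collapse = ", "),
            " (lexicographically smaller phoneme kept)")
    attr(res, "ties") <- unique(ties)
  }
  res
}

#' Basic lexicon descriptives
#'
#' Inventory sizes and the two basic depth proxies: counts of letters,
#' phonemes and (when parses are supplied) graphemes in use, the percentage
#' of words with equal letter and phoneme counts, and the number of unique
#' grapheme-phoneme mappings.
#'
#' @param lex a `lexicon`.
#' @param parses optional list of `grapheme_parse` objects.
#' @param freq_weighted weight words by token frequency.
#' @return A list with `n_letters`, `n_phonemes`, `n_graphemes`,
#'   `pct_equal_length`, `n_unique_gp_mappings` (the latter two `NA` when
#'   not computable).
#' @export
basic_summary <- function(lex, parses = NULL, freq_weighted = FALSE) {
  stopifnot(inherits(lex, "lexicon"))
  list(
    n_letters = length(unique(unlist(lex$orthography))),
    n_phonemes = length(unique(unlist(lex$phonology))),
    n_graphemes = if (is.null(parses)) NA_integer_
                  else count_unique_graphemes(parses),
    pct_equal_length = if (length(lex)) pct_equal_length(lex, freq_weighted)
                       else NA_real_,
    n_unique_gp_mappings = if (is.null(parses)) NA_integer_
                           else count_unique_gp_mappings(parses)
  )
}
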