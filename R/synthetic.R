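#' Specify an artificial orthography
#'
#' Defines the generating conditions for a synthetic pronunciation lexicon
#' with known ground truth.  The generator builds a rule system around a
#' bijective letter-phoneme core, then adds the two ingredients of
#' orthographic depth as independent knobs: *complexity* via multiletter
#' graphemes, context-sensitive rules and silent final letters, and
#' *unpredictability* via exception words whose attested pronunciation
#' deviates from the rule-derived one.
#'
#' @param n_letters number of letters (including the silent-final marker
#'   letter when `silent_final_rate > 0`).
#' @param n_vowels number of vowel letters (each with a matching vowel
#'   phoneme).
#' @param n_multiletter number of two-consonant multiletter graphemes, each
#'   mapping to its own extra phoneme.
#' @param n_context number of context-sensitive rules (a consonant letter
#'   pronounced differently before a specific vowel letter).
#' @param silent_final_rate probability that a word spawns a homophonous
#'   twin with a silent final letter appended.
#' @param exception_rate probability that a word is an exception: its
#'   nucleus phoneme is replaced by a different vowel phoneme, off-rule.
#' @param word_length_range admissible word lengths in letters.
#' @param n_words number of distinct base word forms to sample.
#' @param seed integer seed; all generator randomness flows from it.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_letters = 24L, n_vowels = 6L,
                           n_multiletter = 0L, n_context = 0L,
                           silent_final_rate = 0, exception_rate = 0,
                           word_length_range = c(2L, 8L),
                           n_words = 1000L, seed = 1L) {
  stopifnot(n_letters >= 4L, n_vowels >= 2L, n_vowels < n_letters,
            n_multiletter >= 0L, n_context >= 0L,
            silent_final_rate >= 0, silent_final_rate <= 1,
            exception_rate >= 0, exception_rate <= 1,
            length(word_length_range) == 2L,
            word_length_range[1] >= 1L,
            word_length_range[2] >= word_length_range[1],
            n_words > 0L, length(seed) == 1L)
  structure(
    list(n_letters = as.integer(n_letters),
         n_vowels = as.integer(n_vowels),
         n_multiletter = as.integer(n_multiletter),
         n_context = as.integer(n_context),
         silent_final_rate = silent_final_rate,
         exception_rate = exception_rate,
         word_length_range = as.integer(word_length_range),
         n_words = as.integer(n_words),
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

# symbol pools; letters beyond 26 get diacritic forms, extra phonemes for
# multiletter graphemes come from a disjoint IPA-consonant pool
.vowel_pool <- c("a", "e", "i", "o", "u", "y", "á", "é", "í", "ó", "ú", "ý")
.cons_pool <- c("b", "c", "d", "f", "g", "h", "j", "k", "l", "m", "n", "p",
                "q", "r", "s", "t", "v", "w", "x", "z", "č", "ď", "ň", "ř",
                "š", "ť", "ž", "ĺ", "ŕ", "ś", "ź", "ć")
.extra_phoneme_pool <- c("θ", "ð", "ʃ", "ʒ", "ŋ", "χ", "ɸ", "β", "ʁ", "ʂ",
                         "ʐ", "ɣ", "ʝ", "ɬ", "ɮ", "ʋ", "ɰ", "ħ", "ʕ", "ʔ")

#' Generate an artificial rule system and its language configuration
#'
#' Builds a deterministic (seeded) GPC rule system from a
#' [generator_spec()]: a bijective letter core (every letter maps to its own
#' phoneme), the requested number of two-consonant multiletter graphemes
#' each mapping to an extra phoneme, the requested context-sensitive rules,
#' and — when `silent_final_rate > 0` — a dedicated word-final silent
#' letter.  The derived [language_config()] covers exactly these
#' inventories.
#'
#' @param spec a [generator_spec()].
#' @return A list with elements `rules` (a [gpc_rules()] table), `config`
#'   (a [language_config()]), and `spec`.
#' @export
generate_orthography <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  has_silent <- spec$silent_final_rate > 0
  n_cons <- spec$n_letters - spec$n_vowels - as.integer(has_silent)
  if (n_cons < 2L)
    stop("infeasible spec: need at least 2 pronounced consonant letters")
  if (spec$n_vowels > length(.vowel_pool) ||
      n_cons + as.integer(has_silent) > length(.cons_pool))
    stop("infeasible spec: letter inventory exceeds available symbol pool")
  if (spec$n_multiletter > length(.extra_phoneme_pool))
    stop("infeasible spec: too many multiletter graphemes for phoneme pool")
  if (spec$n_multiletter > n_cons * (n_cons - 1L))
    stop("infeasible spec: too many multiletter graphemes for consonant pairs")
  if (spec$n_context > n_cons * spec$n_vowels)
    stop("infeasible spec: too many context rules")

  vowels <- .vowel_pool[seq_len(spec$n_vowels)]
  consonants <- .cons_pool[seq_len(n_cons)]
  silent_letter <- if (has_silent) .cons_pool[n_cons + 1L] else NULL

  with_seed(spec$seed, {
    # bijective core: every pronounced letter maps to its own phoneme token
    core_g <- c(vowels, consonants)
    core_p <- core_g
    # multiletter graphemes: ordered pairs of distinct consonants
    pairs <- expand.grid(c1 = consonants, c2 = consonants,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$c1 != pairs$c2, , drop = FALSE]
    mi <- sample.int(nrow(pairs), spec$n_multiletter)
    multi_g <- paste0(pairs$c1[mi], pairs$c2[mi])
    multi_p <- .extra_phoneme_pool[seq_len(spec$n_multiletter)]
    # context rules: consonant pronounced as another consonant's phoneme
    # when followed by a specific vowel letter
    cv <- expand.grid(c = consonants, v = vowels, stringsAsFactors = FALSE)
    ci <- sample.int(nrow(cv), spec$n_context)
    ctx_g <- cv$c[ci]
    ctx_post <- cv$v[ci]
    ctx_p <- vapply(ctx_g, function(cc)
      sample(setdiff(consonants, cc), 1L), "")

    rules <- gpc_rules(
      grapheme = c(core_g, multi_g, ctx_g,
                   if (has_silent) silent_letter),
      phoneme = c(core_p, multi_p, ctx_p,
                  if (has_silent) ""),
      position = c(rep("any", length(core_g) + length(multi_g) +
                         length(ctx_g)),
                   if (has_silent) "final"),
      post = c(rep("", length(core_g) + length(multi_g)), ctx_post,
               if (has_silent) ""),
      config = language_config(
        letters = c(vowels, consonants, silent_letter),
        phonemes = c(core_p, multi_p),
        vowel_letters = vowels,
        vowel_phonemes = vowels
      )
    )
    list(rules = rules,
         config = language_config(
           letters = c(vowels, consonants, silent_letter),
           phonemes = c(core_p, multi_p),
           vowel_letters = vowels,
           vowel_phonemes = vowels
         ),
         spec = spec)
  })
}

#' Generate a synthetic lexicon with ground-truth labels
#'
#' Samples `n_words` distinct CVC-skeleton word forms (onset unit, vowel
#' letter, coda of one unit or two single consonants), derives each
#' pronunciation from the rule system, then applies the unpredictability
#' knob: with probability `exception_rate` a word's nucleus phoneme is
#' replaced by a different vowel phoneme, making it an exception.  With
#' probability `silent_final_rate` a word additionally spawns a
#' homophonous twin with the silent final letter appended, so the lexicon
#' is guaranteed to contain silent-letter homophone neighbor pairs.  Units
#' are chosen so that greedy longest-match rule application recovers the
#' generating segmentation exactly.
#'
#' @param orth output of [generate_orthography()] (rules + config + spec).
#' @return A list with `lexicon` (a `lexicon`), `ground_truth` (a data
#'   frame with `orthography`, `phonology`, `rule_phonology`,
#'   `is_exception`, `has_silent_final`, `segmentation`), and the `rules`,
#'   `config` and `spec` used.
#' @export
generate_lexicon <- function(orth) {
  stopifnot(is.list(orth), inherits(orth$rules, "gpc_rules"),
            inherits(orth$config, "language_config"),
            inherits(orth$spec, "generator_spec"))
  spec <- orth$spec
  rules <- orth$rules
  config <- orth$config
  has_silent <- spec$silent_final_rate > 0
  silent_letter <- if (has_silent)
    rules$grapheme[rules$position == "final" & rules$phoneme == ""][1]
  else NULL

  vowels <- config$vowel_letters
  is_multi <- rules$rule_class == "multiletter"
  multi_g <- rules$grapheme[is_multi]
  single_cons <- setdiff(config$letters, c(vowels, silent_letter))

  units <- c(single_cons, multi_g)
  # two-single-consonant codas, excluding accidental multiletter graphemes
  pair_codas <- as.vector(outer(single_cons, single_cons, paste0))
  pair_codas <- setdiff(pair_codas, multi_g)
  codas <- c(units, pair_codas)

  space <- expand.grid(onset = units, vowel = vowels, coda = codas,
                       stringsAsFactors = FALSE)
  words <- paste0(space$onset, space$vowel, space$coda)
  wlen <- nchar(words)
  keep <- wlen >= spec$word_length_range[1] & wlen <= spec$word_length_range[2]
  space <- space[keep, , drop = FALSE]
  words <- words[keep]
  if (spec$n_words > length(words))
    stop("cannot reach n_words = ", spec$n_words,
         ": only ", length(words), " distinct forms in the word space")

  with_seed(spec$seed + 1L, {
    pick <- sample.int(length(words), spec$n_words)
    base <- space[pick, , drop = FALSE]
    base_words <- words[pick]

    n <- length(base_words)
    seg <- character(n)
    phon <- vector("list", n)
    for (i in seq_len(n)) {
      u <- c(base$onset[i], base$vowel[i],
             coda_units(base$coda[i], multi_g))
      seg[i] <- paste(u, collapse = "|")
      phon[[i]] <- derive_unit_phonemes(u, rules)
    }

    is_exc <- stats::runif(n) < spec$exception_rate
    rule_phon <- phon
    for (i in which(is_exc)) {
      p <- phon[[i]]
      vi <- which(p %in% config$vowel_phonemes)[1L]
      p[vi] <- sample(setdiff(config$vowel_phonemes, p[vi]), 1L)
      phon[[i]] <- p
    }

    orth_forms <- base_words
    has_twin <- has_silent & stats::runif(n) < spec$silent_final_rate
    twin_idx <- which(has_twin)
    if (length(twin_idx)) {
      orth_forms <- c(orth_forms, paste0(base_words[twin_idx], silent_letter))
      phon <- c(phon, phon[twin_idx])
      rule_phon <- c(rule_phon, rule_phon[twin_idx])
      seg <- c(seg, paste0(seg[twin_idx], "|", silent_letter))
      is_exc <- c(is_exc, is_exc[twin_idx])
    }
    silent_flag <- c(rep(FALSE, n), rep(TRUE, length(twin_idx)))

    lex <- lexicon(orth_forms, phon, config, language_tag = "synthetic")
    gt <- data.frame(
      orthography = orth_forms,
      phonology = vapply(phon, paste, "", collapse = " "),
      rule_phonology = vapply(rule_phon, paste, "", collapse = " "),
      is_exception = is_exc,
      has_silent_final = silent_flag,
      segmentation = seg,
      stringsAsFactors = FALSE
    )
    list(lexicon = lex, ground_truth = gt, rules = rules, config = config,
         spec = spec)
  })
}

# split a coda string into its generating units (multiletter grapheme or
# single consonants)
coda_units <- function(coda, multi_g) {
  if (coda %in% multi_g) return(coda)
  strsplit(coda, "")[[1]]
}

# phonemes of a unit sequence under the rule system (local precedence:
# context-sensitive rule fires when its following-letter context matches)
derive_unit_phonemes <- function(units, rules) {
  out <- character()
  letters_flat <- strsplit(paste(units, collapse = ""), "")[[1]]
  pos <- 1L
  for (u in units) {
    k <- nchar(u)
    nxt <- if (pos + k <= length(letters_flat)) letters_flat[pos + k] else ""
    cand <- which(rules$grapheme == u &
                    (rules$post == "" | rules$post == nxt))
    if (!length(cand)) stop("no rule for generated unit ", sQuote(u))
    # context-sensitive first, then file order
    cand <- cand[order(rules$post[cand] == "", rules$file_order[cand])]
    out <- c(out, rules$phoneme_tokens[[cand[1L]]])
    pos <- pos + k
  }
  out
}

#' Generate a complete synthetic study lexicon
#'
#' One-call wrapper: [generate_orthography()] then [generate_lexicon()].
#'
#' @inheritParams generate_orthography
#' @return See [generate_lexicon()].
#' @export
synth_lexicon <- function(spec) {
  generate_lexicon(generate_orthography(spec))
}

#' Write a generated lexicon to disk as standard inputs
#'
#' Emits the lexicon TSV, the config YAML and the ground-truth JSON into a
#' directory, so generated fixtures are indistinguishable from real inputs
#' to the rest of the toolkit.
#'
#' @param sim output of [generate_lexicon()] / [synth_lexicon()].
#' @param dir output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_synth_lexicon <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    lexicon = file.path(dir, "lexicon.tsv"),
    config = file.path(dir, "config.yaml"),
    rules = file.path(dir, "rules.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_lexicon(sim$lexicon, paths[["lexicon"]])
  write_language_config(sim$config, paths[["config"]])
  write_gpc_rules(sim$rules, paths[["rules"]])
  jsonlite::write_json(sim$ground_truth, paths[["ground_truth"]],
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
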