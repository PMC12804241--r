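# Shared fixtures and independent oracles used across the suite.

# --- fixtures -------------------------------------------------------------

# small English-like inventory covering the worked examples
toy_config <- function() {
  language_config(
    letters = c("m", "i", "n", "t", "s", "p", "h", "a", "c", "e", "b",
                "g", "f", "l", "d", "r", "k", "o", "u"),
    phonemes = c("m", "n", "t", "s", "p", "h", "k", "b", "g", "f", "l",
                 "d", "r", "ɪ", "ɑɪ", "æ", "iː", "a", "ʃ", "tʃ", "dʒ",
                 "θ", "ʊ", "ɒ"),
    vowel_letters = c("i", "a", "e", "o", "u"),
    vowel_phonemes = c("ɪ", "ɑɪ", "æ", "iː", "a", "ʊ", "ɒ"),
    strip_symbols = c("ˈ", "ˌ")
  )
}

# the five-neighbor lexicon around 'mint'
mint_lexicon <- function(cfg = toy_config()) {
  lexicon(c("mint", "mints", "tint", "mist", "hint", "pint"),
          c("mɪnt", "mɪnts", "tɪnt", "mɪst", "hɪnt", "pɑɪnt"),
          cfg, language_tag = "toy")
}

# identity orthography: k letters, each its own phoneme
identity_lexicon <- function(words, cfg = NULL) {
  letters_used <- sort(unique(unlist(strsplit(words, ""))))
  if (is.null(cfg))
    cfg <- language_config(letters = letters_used, phonemes = letters_used,
                           vowel_letters = intersect(letters_used,
                                                     c("a", "e", "i", "o", "u")),
                           vowel_phonemes = intersect(letters_used,
                                                      c("a", "e", "i", "o", "u")))
  lexicon(words, words, cfg, language_tag = "identity")
}

identity_rules <- function(cfg) {
  gpc_rules(cfg$letters, cfg$letters, config = cfg)
}

# --- oracles --------------------------------------------------------------

# brute-force Levenshtein: enumerate edit scripts recursively, no DP table
brute_lev <- function(a, b) {
  if (length(a) == 0L) return(length(b))
  if (length(b) == 0L) return(length(a))
  same <- if (a[1] == b[1]) 0L else 1L
  min(brute_lev(a[-1], b[-1]) + same,   # substitute / match
      brute_lev(a[-1], b) + 1L,         # delete from a
      brute_lev(a, b[-1]) + 1L)         # insert into a
}

# mutual information via the joint double sum
# sum_{o,p} p(o,p) log2( p(o,p) / (p(o) p(p)) )
brute_mi <- function(counts) {
  m <- as.matrix(counts)
  tot <- sum(m)
  pj <- m / tot
  po <- rowSums(pj)
  pp <- colSums(pj)
  s <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (pj[i, j] > 0) s <- s + pj[i, j] * log2(pj[i, j] / (po[i] * pp[j]))
  }
  unname(s)
}

# all ways to segment string s into inventory tokens (exhaustive)
all_tokenizations <- function(s, inventory) {
  if (!nzchar(s)) return(list(character()))
  out <- list()
  for (tok in inventory) {
    k <- nchar(tok)
    if (k <= nchar(s) && substr(s, 1, k) == tok) {
      for (rest in all_tokenizations(substr(s, k + 1, nchar(s)), inventory))
        out[[length(out) + 1L]] <- c(tok, rest)
    }
  }
  out
}

# random lexicon over a tiny inventory, for property tests
random_small_lexicon <- function(n_words = 40L) {
  cfg <- language_config(
    letters = c("a", "e", "b", "d", "k"),
    phonemes = c("a", "e", "o", "b", "d", "k"),
    vowel_letters = c("a", "e"),
    vowel_phonemes = c("a", "e", "o")
  )
  cons <- c("b", "d", "k")
  vows <- c("a", "e")
  orth <- phon <- character(n_words)
  for (i in seq_len(n_words)) {
    on <- sample(cons, 1)
    v <- sample(vows, 1)
    cd <- sample(cons, 1)
    orth[i] <- paste0(on, v, cd)
    # pronunciation: vowel realized inconsistently
    phon[i] <- paste0(on, sample(c("a", "e", "o"), 1), cd)
  }
  keep <- !duplicated(paste(orth, phon))
  lexicon(orth[keep], phon[keep], cfg)
}
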