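#' Declare a language configuration
#'
#' A language configuration names the symbol inventories against which a
#' pronunciation lexicon is validated: the letter inventory (letters carrying
#' diacritics are distinct, atomic symbols), the phoneme inventory (tokens may
#' span several characters, e.g. diphthongs or affricates), the vowel subsets
#' on both sides, any consonants that can act as syllable nuclei, and
#' suprasegmental marks (stress, length, laryngealization) that are stripped
#' on load.
#'
#' @param letters character vector of letter symbols.
#' @param phonemes character vector of phoneme tokens; multi-character tokens
#'   allowed.
#' @param vowel_letters subset of `letters` treated as orthographic vowels.
#' @param vowel_phonemes subset of `phonemes` treated as vowels.
#' @param syllabic_consonants subset of `phonemes` that count as syllable
#'   nuclei in addition to the vowel phonemes (e.g. vocalic /r̩/).
#' @param strip_symbols suprasegmental symbols removed from transcriptions on
#'   load; must be disjoint from `phonemes`.
#'
#' @return An object of class `language_config`.
#' @examples
#' cfg <- language_config(
#'   letters = c("c", "a", "t", "h"),
#'   phonemes = c("k", "æ", "t", "θ"),
#'   vowel_letters = "a",
#'   vowel_phonemes = "æ"
#' )
#' @export
language_config <- function(letters, phonemes,
                            vowel_letters = character(),
                            vowel_phonemes = character(),
                            syllabic_consonants = character(),
                            strip_symbols = character()) {
  letters <- norm_symbols(letters)
  phonemes <- norm_symbols(phonemes)
  vowel_letters <- norm_symbols(vowel_letters)
  vowel_phonemes <- norm_symbols(vowel_phonemes)
  syllabic_consonants <- norm_symbols(syllabic_consonants)
  strip_symbols <- norm_symbols(strip_symbols)

  if (anyDuplicated(letters)) stop("duplicate letter symbols in inventory")
  if (anyDuplicated(phonemes)) stop("duplicate phoneme tokens in inventory")
  if (!all(vowel_letters %in% letters))
    stop("vowel_letters must be a subset of letters")
  if (!all(vowel_phonemes %in% phonemes))
    stop("vowel_phonemes must be a subset of phonemes")
  if (!all(syllabic_consonants %in% phonemes))
    stop("syllabic_consonants must be a subset of phonemes")
  if (length(intersect(strip_symbols, phonemes)))
    stop("strip_symbols must be disjoint from the phoneme inventory")

  structure(
    list(
      letters = letters,
      phonemes = phonemes,
      vowel_letters = vowel_letters,
      vowel_phonemes = vowel_phonemes,
      syllabic_consonants = syllabic_consonants,
      strip_symbols = strip_symbols
    ),
    class = "language_config"
  )
}

# UTF-8 + NFC normalization applied to every symbol before matching, so that
# composed and decomposed diacritic encodings compare equal.
norm_symbols <- function(x) {
  if (length(x) == 0) return(character())
  x <- enc2utf8(as.character(x))
  stringi::stri_trans_nfc(x)
}

# tokens counting as syllable nuclei
nucleus_tokens <- function(config) {
  union(config$vowel_phonemes, config$syllabic_consonants)
}

#' @export
print.language_config <- function(x, ...) {
  cat("<language_config>\n")
  cat("  letters:            ", length(x$letters),
      " (", length(x$vowel_letters), " vowels)\n", sep = "")
  cat("  phonemes:           ", length(x$phonemes),
      " (", length(x$vowel_phonemes), " vowels, ",
      length(x$syllabic_consonants), " syllabic consonants)\n", sep = "")
  if (length(x$strip_symbols))
    cat("  stripped on load:   ", paste(x$strip_symbols, collapse = " "), "\n")
  invisible(x)
}

#' Read or write a language configuration file
#'
#' Configurations are stored as YAML (or JSON, which YAML parses) documents
#' with fields `letters`, `phonemes`, `vowel_letters`, `vowel_phonemes`,
#' `syllabic_consonants`, and `strip_symbols`, each a list of symbol strings.
#'
#' @param path file path.
#' @return `read_language_config()` returns a `language_config`;
#'   `write_language_config()` returns `path` invisibly.
#' @export
read_language_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  field <- function(nm) as.character(unlist(doc[[nm]], use.names = FALSE))
  language_config(
    letters = field("letters"),
    phonemes = field("phonemes"),
    vowel_letters = field("vowel_letters"),
    vowel_phonemes = field("vowel_phonemes"),
    syllabic_consonants = field("syllabic_consonants"),
    strip_symbols = field("strip_symbols")
  )
}

#' @rdname read_language_config
#' @param config a `language_config`.
#' @export
write_language_config <- function(config, path) {
  stopifnot(inherits(config, "language_config"))
  yaml::write_yaml(lapply(unclass(config), as.list), path)
  invisible(path)
}

# stable hash of a config (provenance in reports)
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_language_config(config, tf)
  unname(tools::md5sum(tf))
}
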