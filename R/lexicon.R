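#' Tokenize a phonemic transcription into phoneme tokens
#'
#' Splits an IPA-like transcription string into the phoneme tokens declared in
#' the language configuration.  Suprasegmental symbols listed in
#' `config$strip_symbols` are removed first; the remainder is segmented by
#' greedy longest match, left to right, over the phoneme inventory, so that
#' multi-character tokens such as diphthongs (/ɑɪ/) or affricates (/tʃ/) are
#' kept whole.  Tokenization is lossless: concatenating the returned tokens
#' reproduces the stripped input.
#'
#' @param transcription a single transcription string.
#' @param config a [language_config()].
#' @return Character vector of phoneme tokens.
#' @examples
#' cfg <- language_config(letters = c("p", "i", "n", "t", "m"),
#'                        phonemes = c("p", "m", "n", "t", "ɪ", "ɑɪ"),
#'                        vowel_letters = "i",
#'                        vowel_phonemes = c("ɪ", "ɑɪ"))
#' tokenize_phonemes("pɑɪnt", cfg)  # "p" "ɑɪ" "n" "t"
#' @export
tokenize_phonemes <- function(transcription, config) {
  stopifnot(length(transcription) == 1L, inherits(config, "language_config"))
  s <- norm_symbols(transcription)
  if (length(config$strip_symbols)) {
    for (sym in config$strip_symbols) s <- gsub(sym, "", s, fixed = TRUE)
  }
  if (!nzchar(trimws(s)))
    stop("transcription empty after removing suprasegmental symbols: ",
         sQuote(transcription))
  # space-separated transcriptions (the format write_lexicon emits) are
  # segmented chunk by chunk; each chunk may still hold several tokens
  chunks <- strsplit(trimws(s), " +")[[1]]
  unlist(lapply(chunks, greedy_match, inventory = config$phonemes,
                what = "phoneme"), use.names = FALSE)
}

# Greedy longest-match segmentation of string `s` over `inventory`.
# Shared by phoneme tokenization and grapheme-string splitting.
greedy_match <- function(s, inventory, what = "symbol") {
  inv <- inventory[order(nchar(inventory), decreasing = TRUE)]
  n <- nchar(s)
  out <- character()
  pos <- 1L
  while (pos <= n) {
    hit <- NA_character_
    for (tok in inv) {
      k <- nchar(tok)
      if (pos + k - 1L <= n && substr(s, pos, pos + k - 1L) == tok) {
        hit <- tok
        break
      }
    }
    if (is.na(hit))
      stop("unknown ", what, " at position ", pos, " of ", sQuote(s),
           " (", sQuote(substr(s, pos, pos)), " matches no inventory token)")
    out <- c(out, hit)
    pos <- pos + nchar(hit)
  }
  out
}

# Split an orthographic form into its letter symbols (diacritic letters are
# atomic; multi-character letter symbols are honored via longest match).
split_letters <- function(word, config) {
  greedy_match(norm_symbols(word), config$letters, what = "letter")
}

new_lexicon <- function(orthography, phonology, frequency, config,
                        language_tag = "") {
  structure(
    list(
      orthography = orthography, # list of character vectors (letters)
      phonology = phonology,     # list of character vectors (phoneme tokens)
      frequency = frequency,     # numeric, NA when absent
      config = config,
      language_tag = language_tag
    ),
    class = "lexicon"
  )
}

#' Build a lexicon from orthographic and phonological forms
#'
#' @param orthography character vector of written word forms, or a list of
#'   letter vectors.
#' @param phonology character vector of transcriptions (tokenized against the
#'   config), or a list of phoneme-token vectors.
#' @param config a [language_config()].
#' @param frequency optional non-negative token counts.
#' @param language_tag label carried into reports.
#'
#' @details Word forms are case-folded, NFC-normalized and validated against
#' the configuration.  Exact duplicate (orthography, phonology) rows are
#' merged with frequencies summed; homographs and homophones remain distinct
#' entries.
#' @return An object of class `lexicon`.
#' @export
lexicon <- function(orthography, phonology, config, frequency = NULL,
                    language_tag = "") {
  stopifnot(inherits(config, "language_config"))
  n <- length(orthography)
  if (length(phonology) != n)
    stop("orthography and phonology must have the same length")
  if (is.null(frequency)) frequency <- rep(NA_real_, n)
  if (length(frequency) != n)
    stop("frequency must match the number of entries")
  if (any(!is.na(frequency) & frequency < 0))
    stop("frequencies must be non-negative")

  orth <- vector("list", n)
  phon <- vector("list", n)
  for (i in seq_len(n)) {
    o <- orthography[[i]]
    p <- phonology[[i]]
    if (length(o) == 1L) o <- split_letters(tolower(o), config)
    else {
      o <- norm_symbols(tolower(o))
      bad <- setdiff(o, config$letters)
      if (length(bad))
        stop("entry ", i, ": letter(s) outside inventory: ",
             paste(sQuote(bad), collapse = ", "))
    }
    if (length(p) == 1L) p <- tokenize_phonemes(p, config)
    else {
      p <- norm_symbols(p)
      bad <- setdiff(p, config$phonemes)
      if (length(bad))
        stop("entry ", i, ": phoneme(s) outside inventory: ",
             paste(sQuote(bad), collapse = ", "))
    }
    if (!length(o)) stop("entry ", i, ": empty orthography")
    if (!length(p)) stop("entry ", i, ": empty phonology")
    orth[[i]] <- o
    phon[[i]] <- p
  }

  # merge exact duplicates, summing frequencies (NA-preserving)
  key <- paste(vapply(orth, paste, "", collapse = ""),
               vapply(phon, paste, "", collapse = ""),
               sep = "")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    grp <- match(key, key[first])
    freq <- vapply(split(frequency, grp), function(f) {
      if (all(is.na(f))) NA_real_ else sum(f, na.rm = TRUE)
    }, numeric(1))
    orth <- orth[first]
    phon <- phon[first]
    frequency <- unname(freq[order(unique(grp))])
  }
  new_lexicon(orth, phon, frequency, config, language_tag)
}

#' Read a pronunciation lexicon from a delimited text file
#'
#' Reads a header-bearing TSV/CSV file with one row per word and validates it
#' against a language configuration.  Orthography is case-folded, the
#' transcription is stripped of suprasegmental symbols and tokenized with
#' [tokenize_phonemes()], and exact duplicate rows are merged with
#' frequencies summed.
#'
#' @param path file path.
#' @param config a [language_config()].
#' @param sep field delimiter; `"\t"` (default) or `","`.
#' @param orth_col,phon_col,freq_col column names for the written form, the
#'   transcription, and (optionally) the token frequency.  Set
#'   `freq_col = NULL` when the file has no frequency column.
#' @param language_tag label carried into reports; defaults to the file stem.
#' @return A `lexicon`.
#' @export
read_lexicon <- function(path, config, sep = "\t",
                         orth_col = "orthography", phon_col = "phonology",
                         freq_col = "frequency",
                         language_tag = NULL) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  if (is.null(language_tag))
    language_tag <- tools::file_path_sans_ext(basename(path))
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          colClasses = "character", fileEncoding = "UTF-8",
                          check.names = FALSE, quote = "",
                          blank.lines.skip = TRUE)
  if (nrow(df) == 0L)
    return(new_lexicon(list(), list(), numeric(), config, language_tag))
  for (col in c(orth_col, phon_col)) {
    if (!col %in% names(df))
      stop("column ", sQuote(col), " not found in ", path)
  }
  freq <- NULL
  if (!is.null(freq_col) && freq_col %in% names(df)) {
    freq <- suppressWarnings(as.numeric(df[[freq_col]]))
  }
  res <- tryCatch(
    lexicon(df[[orth_col]], df[[phon_col]], config,
            frequency = freq, language_tag = language_tag),
    error = function(e) {
      stop("while reading ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  res
}

#' Write a lexicon to a delimited text file
#'
#' Inverse of [read_lexicon()]: emits a UTF-8 TSV with columns
#' `orthography`, `phonology` and (when any frequency is present)
#' `frequency`.  Reading the file back with the same configuration
#' reproduces an equal lexicon.
#'
#' @param lex a `lexicon`.
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path, sep = "\t") {
  stopifnot(inherits(lex, "lexicon"))
  df <- data.frame(
    orthography = orth_strings(lex),
    phonology = phon_strings(lex),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(lex$frequency))) df$frequency <- lex$frequency
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "")
  invisible(path)
}

#' Keep only monosyllabic entries
#'
#' An entry is monosyllabic when its phonology contains exactly one maximal
#' run of nucleus tokens (vowel phonemes plus any declared syllabic
#' consonants).  All corpus-level depth measures here are defined over
#' monosyllabic words.
#'
#' @param lex a `lexicon`.
#' @return A `lexicon` containing the monosyllabic subset.
#' @export
filter_monosyllabic <- function(lex) {
  stopifnot(inherits(lex, "lexicon"))
  nuc <- nucleus_tokens(lex$config)
  keep <- vapply(lex$phonology, function(p) {
    count_nucleus_runs(p, nuc) == 1L
  }, logical(1))
  new_lexicon(lex$orthography[keep], lex$phonology[keep],
              lex$frequency[keep], lex$config, lex$language_tag)
}

count_nucleus_runs <- function(phon, nuc) {
  isn <- phon %in% nuc
  if (!any(isn)) return(0L)
  sum(isn & !c(FALSE, isn[-length(isn)]))
}

#' @export
length.lexicon <- function(x) length(x$orthography)

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon", if (nzchar(x$language_tag)) paste0(" ", sQuote(x$language_tag)),
      ": ", length(x), " entries>\n", sep = "")
  n <- min(length(x), 6L)
  if (n > 0) {
    for (i in seq_len(n)) {
      cat("  ", paste(x$orthography[[i]], collapse = ""), "  /",
          paste(x$phonology[[i]], collapse = " "), "/\n", sep = "")
    }
    if (length(x) > n) cat("  ...\n")
  }
  invisible(x)
}

#' @export
as.data.frame.lexicon <- function(x, ...) {
  data.frame(
    orthography = orth_strings(x),
    phonology = phon_strings(x),
    frequency = x$frequency,
    stringsAsFactors = FALSE
  )
}

orth_strings <- function(lex) {
  vapply(lex$orthography, paste, "", collapse = "")
}

phon_strings <- function(lex) {
  vapply(lex$phonology, paste, "", collapse = " ")
}

# analysis weights: 1 per type, or token frequencies behind the flag
entry_weights <- function(lex, freq_weighted = FALSE) {
  if (!freq_weighted) return(rep(1, length(lex)))
  w <- lex$frequency
  if (all(is.na(w)))
    stop("freq_weighted = TRUE but the lexicon has no frequencies")
  w[is.na(w)] <- 0
  w
}

lexicon_subset <- function(lex, idx) {
  new_lexicon(lex$orthography[idx], lex$phonology[idx], lex$frequency[idx],
              lex$config, lex$language_tag)
}
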