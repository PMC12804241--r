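#' Build a grapheme-phoneme correspondence rule table
#'
#' A GPC rule maps a grapheme (one or more letters) onto a phoneme sequence
#' (usually one phoneme; empty for silent graphemes; two or more for cases
#' like x -> /ks/), optionally restricted to a word position and/or a
#' letter context.  Rules are classed by their form:
#' `single-letter` (one letter, no context), `multiletter` (several letters,
#' no context), and `context-sensitive` (any rule with a letter context).
#'
#' @param grapheme character vector of grapheme strings (letters
#'   concatenated).
#' @param phoneme character vector of phoneme strings; tokens may be
#'   space-separated, otherwise they are segmented greedily against the
#'   configuration; `""` marks a silent grapheme.
#' @param position one of `"any"`, `"initial"`, `"medial"`, `"final"`,
#'   recycled.
#' @param pre,post optional preceding / following letter context strings
#'   (`""` = unconstrained), recycled.
#' @param config a [language_config()] used to validate symbols.
#' @return An object of class `gpc_rules`: a data frame with one row per
#'   rule, list columns `grapheme_letters` / `phoneme_tokens`, and a
#'   `rule_class` column.
#' @examples
#' cfg <- language_config(letters = c("c", "a", "t", "h", "i"),
#'                        phonemes = c("k", "s", "æ", "t", "θ", "ɪ"),
#'                        vowel_letters = c("a", "i"),
#'                        vowel_phonemes = c("æ", "ɪ"))
#' gpc_rules(grapheme = c("t", "th", "c", "c"),
#'           phoneme  = c("t", "θ", "k", "s"),
#'           post     = c("", "", "", "i"),
#'           config   = cfg)
#' @export
gpc_rules <- function(grapheme, phoneme, position = "any",
                      pre = "", post = "", config) {
  stopifnot(inherits(config, "language_config"))
  n <- length(grapheme)
  if (length(phoneme) != n) stop("grapheme and phoneme lengths differ")
  position <- rep_len(as.character(position), n)
  pre <- rep_len(as.character(pre), n)
  post <- rep_len(as.character(post), n)
  pre[is.na(pre)] <- ""
  post[is.na(post)] <- ""
  phoneme[is.na(phoneme)] <- ""
  bad_pos <- setdiff(position, c("any", "initial", "medial", "final"))
  if (length(bad_pos)) stop("unknown position value(s): ",
                            paste(bad_pos, collapse = ", "))

  g_letters <- lapply(grapheme, split_letters, config = config)
  if (any(vapply(g_letters, length, 1L) == 0L))
    stop("empty grapheme in rule table")
  p_tokens <- lapply(phoneme, function(p) {
    p <- trimws(p)
    if (!nzchar(p)) return(character())
    if (grepl(" ", p)) {
      toks <- norm_symbols(strsplit(p, " +")[[1]])
      bad <- setdiff(toks, config$phonemes)
      if (length(bad)) stop("rule phoneme(s) outside inventory: ",
                            paste(sQuote(bad), collapse = ", "))
      toks
    } else tokenize_phonemes(p, config)
  })
  pre_letters <- lapply(pre, function(s)
    if (nzchar(s)) split_letters(s, config) else character())
  post_letters <- lapply(post, function(s)
    if (nzchar(s)) split_letters(s, config) else character())

  has_context <- nzchar(pre) | nzchar(post)
  g_len <- vapply(g_letters, length, 1L)
  rule_class <- ifelse(has_context, "context-sensitive",
                       ifelse(g_len > 1L, "multiletter", "single-letter"))

  out <- data.frame(
    grapheme = vapply(g_letters, paste, "", collapse = ""),
    phoneme = vapply(p_tokens, paste, "", collapse = " "),
    position = position,
    pre = pre,
    post = post,
    rule_class = rule_class,
    file_order = seq_len(n),
    stringsAsFactors = FALSE
  )
  out$grapheme_letters <- g_letters
  out$phoneme_tokens <- p_tokens
  out$pre_letters <- pre_letters
  out$post_letters <- post_letters
  class(out) <- c("gpc_rules", "data.frame")
  out
}

#' Read or write a GPC rule file
#'
#' Rule files are delimited text with a header row and columns `grapheme`,
#' `phoneme`, and optionally `position`, `pre`, `post`.  The `rule_class`
#' column is always derived from the rule's form, never read.
#'
#' @param path file path.
#' @param config a [language_config()].
#' @param sep field delimiter.
#' @return `read_gpc_rules()` returns a `gpc_rules` table;
#'   `write_gpc_rules()` returns `path` invisibly.
#' @export
read_gpc_rules <- function(path, config, sep = "\t") {
  if (!file.exists(path)) stop("rule file not found: ", path)
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          colClasses = "character", fileEncoding = "UTF-8",
                          check.names = FALSE, quote = "")
  if (!all(c("grapheme", "phoneme") %in% names(df)))
    stop("rule file must have 'grapheme' and 'phoneme' columns: ", path)
  gpc_rules(
    grapheme = df$grapheme,
    phoneme = df$phoneme,
    position = if ("position" %in% names(df)) df$position else "any",
    pre = if ("pre" %in% names(df)) df$pre else "",
    post = if ("post" %in% names(df)) df$post else "",
    config = config
  )
}

#' @rdname read_gpc_rules
#' @param rules a `gpc_rules` table.
#' @export
write_gpc_rules <- function(rules, path, sep = "\t") {
  stopifnot(inherits(rules, "gpc_rules"))
  df <- rules[, c("grapheme", "phoneme", "position", "pre", "post")]
  class(df) <- "data.frame"
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.gpc_rules <- function(x, ...) {
  cat("<gpc_rules: ", nrow(x), " rules (",
      sum(x$rule_class == "single-letter"), " single-letter, ",
      sum(x$rule_class == "multiletter"), " multiletter, ",
      sum(x$rule_class == "context-sensitive"), " context-sensitive)>\n",
      sep = "")
  df <- x[, c("grapheme", "phoneme", "position", "pre", "post", "rule_class")]
  class(df) <- "data.frame"
  print(utils::head(df, 10L))
  if (nrow(x) > 10L) cat("  ... and", nrow(x) - 10L, "more\n")
  invisible(x)
}

rules_hash <- function(rules) {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  write_gpc_rules(rules, tf)
  unname(tools::md5sum(tf))
}

# Precedence order for parsing/application: longer grapheme first;
# context-sensitive before context-free at equal length; file order last.
rule_precedence <- function(rules) {
  g_len <- vapply(rules$grapheme_letters, length, 1L)
  order(-g_len, rules$rule_class != "context-sensitive", rules$file_order)
}

# does rule i apply orthographically at letter position `at` of `letters`?
rule_applies <- function(rules, i, letters, at) {
  g <- rules$grapheme_letters[[i]]
  k <- length(g)
  n <- length(letters)
  if (at + k - 1L > n) return(FALSE)
  if (!identical(letters[at:(at + k - 1L)], g)) return(FALSE)
  pos <- rules$position[i]
  if (pos == "initial" && at != 1L) return(FALSE)
  if (pos == "final" && at + k - 1L != n) return(FALSE)
  if (pos == "medial" && (at == 1L || at + k - 1L == n)) return(FALSE)
  pre <- rules$pre_letters[[i]]
  if (length(pre)) {
    if (at - length(pre) < 1L) return(FALSE)
    if (!identical(letters[(at - length(pre)):(at - 1L)], pre)) return(FALSE)
  }
  post <- rules$post_letters[[i]]
  if (length(post)) {
    if (at + k - 1L + length(post) > n) return(FALSE)
    if (!identical(letters[(at + k):(at + k - 1L + length(post))], post))
      return(FALSE)
  }
  TRUE
}
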