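#' Levenshtein distance between symbol sequences
#'
#' Minimal number of unit-cost insertions, deletions and substitutions
#' transforming one sequence into the other.  Operates on whole symbols —
#' letters or phoneme tokens — so a multi-character token such as the
#' diphthong /ɑɪ/ counts as a single unit.
#'
#' @param a,b character vectors of symbols (or single strings, split into
#'   characters).
#' @return Integer distance.
#' @examples
#' levenshtein(c("m", "ɪ", "n", "t"), c("p", "ɑɪ", "n", "t"))  # 2
#' @export
levenshtein <- function(a, b) {
  if (length(a) == 1L && nchar(a) > 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L && nchar(b) > 1L) b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[m + 1L]
}

# Map each entry's symbol sequence to a string of single unicode characters
# (one per distinct symbol), so that banks of sequences can be compared with
# utils::adist in one vectorized call.  Exactness is preserved because the
# remapping is a bijection on symbols.
remap_to_strings <- function(seqs) {
  alphabet <- unique(unlist(seqs, use.names = FALSE))
  # private-use plane keeps codes clear of anything meaningful
  codes <- 0xE000L + seq_along(alphabet) - 1L
  vapply(seqs, function(s) {
    if (!length(s)) return("")
    intToUtf8(codes[match(s, alphabet)])
  }, "")
}

#' Orthographic neighbors of a word
#'
#' All other lexicon entries at letter-level Levenshtein distance exactly 1
#' (one substitution, insertion or deletion).  Homographs of the target
#' (distance 0) are not neighbors; homographic pairs elsewhere in the
#' lexicon each count as separate neighbor tokens.
#'
#' @param i index of the target entry in the lexicon.
#' @param lex a `lexicon`.
#' @param orth_dist optional precomputed distance row (internal use).
#' @return Integer vector of neighbor indices (possibly empty).
#' @export
orthographic_neighbors <- function(i, lex, orth_dist = NULL) {
  stopifnot(inherits(lex, "lexicon"), i >= 1L, i <= length(lex))
  if (is.null(orth_dist)) {
    strs <- remap_to_strings(lex$orthography)
    orth_dist <- utils::adist(strs[i], strs)[1L, ]
  }
  out <- which(orth_dist == 1L)
  setdiff(out, i)
}

#' Orthography-phonology consistency of one word
#'
#' The mean phoneme-level Levenshtein distance between a word's
#' pronunciation and the pronunciations of its orthographic neighbors.  Low
#' values mean orthographically similar words sound similar — a shallow
#' mapping; silent-letter homophone neighbors contribute distance 0 and can
#' pull the value below 1.
#'
#' @inheritParams orthographic_neighbors
#' @return Mean distance (`NA` with a message if the word has no
#'   orthographic neighbors, in which case callers exclude it).
#' @export
opc_word <- function(i, lex, orth_dist = NULL) {
  nb <- orthographic_neighbors(i, lex, orth_dist)
  if (!length(nb)) return(NA_real_)
  d <- vapply(nb, function(j)
    levenshtein(lex$phonology[[i]], lex$phonology[[j]]), numeric(1))
  mean(d)
}

#' Mean OPC of a lexicon
#'
#' Samples words uniformly without replacement (seeded), computes each
#' sampled word's [opc_word()] value, and averages; sampled words with no
#' orthographic neighbors are excluded from the mean and reported.
#'
#' @param lex a `lexicon`.
#' @param sample_size number of words to sample (capped at the lexicon
#'   size).
#' @param seed integer seed for the sampling; required for reproducibility.
#' @return An object of class `opc_result`: a list with `per_word` (named,
#'   `NA` for neighbor-less words), `mean_opc`, `n_sampled`,
#'   `n_excluded`, `sample_size`, `seed`.
#' @export
mean_opc <- function(lex, sample_size = 1000L, seed = 1L) {
  stopifnot(inherits(lex, "lexicon"))
  n <- length(lex)
  if (n == 0L) stop("empty lexicon")
  k <- min(sample_size, n)
  idx <- with_seed(seed, sort(sample.int(n, k)))
  strs <- remap_to_strings(lex$orthography)
  # one vectorized distance matrix: sampled words x whole lexicon
  dmat <- utils::adist(strs[idx], strs)
  per_word <- vapply(seq_along(idx), function(r)
    opc_word(idx[r], lex, orth_dist = dmat[r, ]), numeric(1))
  names(per_word) <- orth_strings(lex)[idx]
  if (all(is.na(per_word)))
    stop("every sampled word is neighbor-less; OPC undefined")
  structure(
    list(per_word = per_word,
         mean_opc = mean(per_word, na.rm = TRUE),
         n_sampled = k,
         n_excluded = sum(is.na(per_word)),
         sample_size = sample_size,
         seed = seed),
    class = "opc_result"
  )
}

#' @export
print.opc_result <- function(x, ...) {
  cat(sprintf(
    "<opc_result: mean OPC %.3f over %d sampled words (%d neighbor-less excluded; seed %d)>\n",
    x$mean_opc, x$n_sampled, x$n_excluded, x$seed))
  invisible(x)
}

# run code under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
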