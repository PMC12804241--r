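#' Compute every depth measure for one lexicon
#'
#' Orchestrates the full battery over a pronunciation lexicon: basic
#' descriptives, rule-system classification and irregularity (when a rule
#' table is supplied), vowel and body consistency, onset and vowel
#' entropies, mutual-information efficiency at the three grain sizes, and
#' mean OPC.  The lexicon is first restricted to monosyllabic words.  A
#' failing measure is downgraded to an entry in `$skipped` with its error
#' message rather than aborting the report.
#'
#' @param lex a `lexicon`.
#' @param rules optional [gpc_rules()] table; without it the rule-based and
#'   grapheme-level measures are skipped.
#' @param freq_weighted weight statistical measures by token frequency.
#' @param sample_size,seed OPC sampling controls (see [mean_opc()]).
#' @param overlap bigram window scheme (see [joint_counts()]).
#' @return An object of class `depth_report`.
#' @export
compute_all <- function(lex, rules = NULL, freq_weighted = FALSE,
                        sample_size = 1000L, seed = 1L, overlap = TRUE) {
  stopifnot(inherits(lex, "lexicon"))
  mono <- filter_monosyllabic(lex)
  skipped <- list()
  grab <- function(name, expr) {
    tryCatch(suppressWarnings(expr), error = function(e) {
      skipped[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  parses <- NULL
  if (!is.null(rules)) {
    pl <- grab("grapheme_parses", parse_lexicon_graphemes(mono, rules))
    if (!is.null(pl)) parses <- pl$parses
  }

  basic <- grab("basic", basic_summary(mono, parses, freq_weighted))
  rule_sum <- NULL
  if (!is.null(rules)) {
    rule_sum <- grab("rules", {
      cls <- classify_rules(rules)
      irr <- pct_irregular(mono, rules, freq_weighted)
      c(cls, list(pct_irregular = as.numeric(irr),
                  n_unparsed = attr(irr, "n_unparsed")))
    })
  } else {
    skipped$rules <- "no GPC rule table supplied"
    skipped$grapheme_efficiency <- "no GPC rule table supplied"
  }

  consistency <- grab("consistency", list(
    vowel = unit_consistency(mono, "vowel", freq_weighted),
    body = unit_consistency(mono, "body", freq_weighted)
  ))
  entropies <- grab("entropy", entropy_summary(mono, freq_weighted))
  efficiency <- grab("efficiency",
                     efficiency_profile_all(mono, rules, overlap,
                                            freq_weighted))
  opc <- grab("opc", mean_opc(mono, sample_size = sample_size, seed = seed))

  structure(
    list(
      language_tag = lex$language_tag,
      n_words = length(mono),
      n_words_raw = length(lex),
      basic = basic,
      rules = rule_sum,
      consistency = consistency,
      entropy = entropies,
      efficiency = efficiency,
      opc = opc,
      skipped = skipped,
      provenance = list(
        config_hash = config_hash(lex$config),
        rules_hash = if (!is.null(rules)) rules_hash(rules) else NA_character_,
        seed = seed,
        freq_weighted = freq_weighted,
        toolkit_version = as.character(utils::packageVersion("orthodepth"))
      )
    ),
    class = "depth_report"
  )
}

#' @export
print.depth_report <- function(x, ...) {
  cat("<depth_report", if (nzchar(x$language_tag))
    paste0(" ", sQuote(x$language_tag)), ">\n", sep = "")
  cat("  monosyllabic words: ", x$n_words, " (of ", x$n_words_raw, ")\n",
      sep = "")
  m <- report_measures(x)
  for (nm in names(m)) {
    if (!is.na(m[[nm]]))
      cat(sprintf("  %-28s %s\n", nm, format(m[[nm]], digits = 4)))
  }
  if (length(x$skipped))
    cat("  skipped:", paste(names(x$skipped), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.depth_report <- function(object, ...) {
  df <- data.frame(measure = names(report_measures(object)),
                   value = unname(unlist(report_measures(object))),
                   stringsAsFactors = FALSE)
  df
}

#' Flat named measure vector of a report
#'
#' Extracts the standard cross-language measure set from a `depth_report`:
#' the fifteen variables entering the correlation/PCA comparison.  Missing
#' (skipped) measures are `NA`.
#'
#' @param report a `depth_report`.
#' @return Named numeric vector.
#' @export
report_measures <- function(report) {
  stopifnot(inherits(report, "depth_report"))
  g <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x)
  # consistency appears as nested scores in memory but flat values once a
  # report has been through JSON
  cons_mean <- function(which) {
    cn <- report$consistency
    if (is.null(cn)) return(NULL)
    v <- if (is.list(cn)) cn[[which]] else cn[which]
    if (is.list(v)) v$mean else v
  }
  c(
    n_unique_gp_mappings = g(report$basic$n_unique_gp_mappings),
    pct_equal_length = g(report$basic$pct_equal_length),
    n_single_letter_rules = g(report$rules$n_single),
    n_multiletter_rules = g(report$rules$n_multi),
    n_context_rules = g(report$rules$n_context),
    pct_irregular = g(report$rules$pct_irregular),
    vowel_consistency = g(cons_mean("vowel")),
    body_consistency = g(cons_mean("body")),
    vowel_entropy_ci = g(report$entropy$vowel_entropy_ci),
    vowel_entropy_onset_cond = g(report$entropy$vowel_entropy_onset_cond),
    vowel_entropy_coda_cond = g(report$entropy$vowel_entropy_coda_cond),
    efficiency_letters = g(report$efficiency$letters$efficiency),
    efficiency_graphemes = g(report$efficiency$graphemes$efficiency),
    mean_opc = g(report$opc$mean_opc),
    onset_entropy = g(report$entropy$onset_entropy)
  )
}

#' Serialize or read a depth report as JSON
#'
#' Reports serialize deterministically (given identical inputs and seeds the
#' file is byte-identical) and round-trip losslessly through
#' `read_report()` at the level of the measure values.
#'
#' @param report a `depth_report`.
#' @param path output / input file path.
#' @return `write_report()` returns `path` invisibly; `read_report()` a
#'   `depth_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "depth_report"))
  x <- unclass(report)
  x$consistency <- list(
    vowel = x$consistency$vowel$mean,
    body = x$consistency$body$mean,
    vowel_n_singletons = x$consistency$vowel$n_singletons,
    body_n_singletons = x$consistency$body$n_singletons
  )
  x$efficiency <- lapply(x$efficiency, function(pr)
    if (is.null(pr)) NULL else unclass(pr))
  if (!is.null(x$opc))
    x$opc <- x$opc[c("mean_opc", "n_sampled", "n_excluded",
                     "sample_size", "seed")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$skipped <- as.list(x$skipped)
  structure(x, class = "depth_report")
}

#' Compare languages: correlations and principal components
#'
#' Assembles the measure matrix (languages x measures) from a set of depth
#' reports, computes Pearson correlations between measures across
#' languages, and runs a PCA on the standardized measures (correlation
#' matrix), keeping the first two components.  Constant (or missing)
#' measure columns are dropped with a warning.  Component signs are fixed
#' by forcing the largest-magnitude loading of each component positive.
#' With few languages the results are descriptive only; a caveat is
#' attached (and printed) when fewer than 30 languages are compared.
#'
#' @param reports a list of at least three `depth_report` objects.
#' @param measures optional character vector selecting/ordering measures
#'   (default: all of [report_measures()]).
#' @return An object of class `cross_language_summary`: list with
#'   `matrix` (languages x measures), `correlations`, `pca` (the `prcomp`
#'   fit), `loadings` (measures x 2), `scores` (languages x 2),
#'   `variance_explained` (length 2), `dropped` (character).
#' @export
correlate_and_project <- function(reports, measures = NULL) {
  if (length(reports) < 3L)
    stop("need at least 3 reports to compare languages")
  rows <- lapply(reports, report_measures)
  tags <- vapply(reports, function(r) r$language_tag, "")
  tags[!nzchar(tags)] <- paste0("lang", seq_along(tags))[!nzchar(tags)]
  mat <- do.call(rbind, rows)
  rownames(mat) <- make.unique(tags)
  if (!is.null(measures)) mat <- mat[, measures, drop = FALSE]

  keep <- apply(mat, 2L, function(col)
    !anyNA(col) && stats::sd(col) > 0)
  dropped <- colnames(mat)[!keep]
  if (length(dropped))
    warning("dropping constant or incomplete measure(s): ",
            paste(dropped, collapse = ", "))
  m <- mat[, keep, drop = FALSE]
  if (ncol(m) < 2L) stop("fewer than 2 usable measures")

  correlations <- stats::cor(m)
  pca <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  k <- min(2L, ncol(pca$rotation))
  load2 <- pca$rotation[, seq_len(k), drop = FALSE]
  scores2 <- pca$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(load2[, j]))
    if (load2[top, j] < 0) {
      load2[, j] <- -load2[, j]
      scores2[, j] <- -scores2[, j]
    }
  }
  ve <- (pca$sdev^2 / sum(pca$sdev^2))[seq_len(k)]

  structure(
    list(matrix = mat, correlations = correlations, pca = pca,
         loadings = load2, scores = scores2, variance_explained = ve,
         dropped = dropped,
         descriptive_only = nrow(mat) < 30L),
    class = "cross_language_summary"
  )
}

#' @export
print.cross_language_summary <- function(x, ...) {
  cat("<cross_language_summary: ", nrow(x$matrix), " languages, ",
      ncol(x$correlations), " measures>\n", sep = "")
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$variance_explained[1],
              100 * x$variance_explained[2]))
  if (isTRUE(x$descriptive_only))
    cat("  note: fewer than 30 languages -- treat as descriptive only\n")
  print(round(x$scores, 3))
  invisible(x)
}

#' Biplot of the cross-language comparison
#'
#' Standard PCA biplot: language scores as points, measure loadings as
#' arrows, on the first two components.
#'
#' @param x a `cross_language_summary`.
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cross_language_summary <- function(x, y, ...) {
  sc <- x$scores
  ld <- x$loadings
  scale_f <- max(abs(sc)) / max(abs(ld))
  lds <- ld * scale_f * 0.8
  rng <- range(c(sc, lds))
  graphics::plot(sc, xlab = sprintf("PC1 (%.0f%%)",
                                    100 * x$variance_explained[1]),
                 ylab = sprintf("PC2 (%.0f%%)",
                                100 * x$variance_explained[2]),
                 xlim = rng, ylim = rng, pch = 19, ...)
  graphics::text(sc, labels = rownames(sc), pos = 3, cex = 0.8)
  graphics::arrows(0, 0, lds[, 1], lds[, 2], length = 0.08, col = "grey40")
  graphics::text(lds, labels = rownames(ld), col = "grey30", cex = 0.7,
                 pos = 4)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey70")
  invisible(x)
}
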