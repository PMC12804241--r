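test_that("compute_all aggregates every measure on a shallow lexicon", {
  sim <- synth_lexicon(generator_spec(n_words = 400, seed = 91))
  rep <- compute_all(sim$lexicon, sim$rules, sample_size = 200, seed = 2)
  m <- report_measures(rep)
  expect_equal(unname(m["pct_equal_length"]), 100)
  expect_equal(unname(m["pct_irregular"]), 0)
  expect_equal(unname(m["efficiency_letters"]), 1)
  expect_equal(unname(m["efficiency_graphemes"]), 1)
  expect_equal(unname(m["mean_opc"]), 1)
  expect_equal(unname(m["vowel_consistency"]), 1)
  expect_length(rep$skipped, 0L)
})

test_that("missing rules downgrade rule-based measures to skipped", {
  sim <- synth_lexicon(generator_spec(n_words = 200, seed = 93))
  rep <- compute_all(sim$lexicon, rules = NULL, sample_size = 100, seed = 2)
  expect_true("rules" %in% names(rep$skipped))
  m <- report_measures(rep)
  expect_true(is.na(m["pct_irregular"]))
  expect_false(is.na(m["vowel_consistency"]))   # statistical measures present
  expect_false(is.na(m["mean_opc"]))
  expect_true(is.na(m["efficiency_graphemes"]))
})

test_that("report JSON is deterministic and round-trips its measures", {
  sim <- synth_lexicon(generator_spec(n_words = 150, exception_rate = 0.1,
                                      seed = 95))
  rep <- compute_all(sim$lexicon, sim$rules, sample_size = 100, seed = 7)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_report(rep, f1)
  write_report(compute_all(sim$lexicon, sim$rules, sample_size = 100,
                           seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
  back <- read_report(f1)
  expect_equal(back$rules$pct_irregular, rep$rules$pct_irregular)
  expect_equal(back$opc$mean_opc, rep$opc$mean_opc)
  expect_equal(back$entropy$vowel_entropy_ci, rep$entropy$vowel_entropy_ci)
  expect_equal(report_measures(back), report_measures(rep))
})

.family_cache <- new.env(parent = emptyenv())

make_family_reports <- function() {
  if (!is.null(.family_cache$reports)) return(.family_cache$reports)
  reports <- list()
  k <- 1L
  for (eps in c(0, 0.15, 0.35)) {
    sim <- synth_lexicon(generator_spec(n_words = 500, exception_rate = eps,
                                        seed = 101))
    sim$lexicon$language_tag <- paste0("eps", eps)
    reports[[k]] <- compute_all(sim$lexicon, sim$rules, sample_size = 300,
                                seed = 3)
    k <- k + 1L
  }
  for (mult in c(2L, 5L, 8L)) {
    sim <- synth_lexicon(generator_spec(n_words = 500, n_multiletter = mult,
                                        silent_final_rate = 0.1 * mult,
                                        seed = 103))
    sim$lexicon$language_tag <- paste0("multi", mult)
    reports[[k]] <- compute_all(sim$lexicon, sim$rules, sample_size = 300,
                                seed = 3)
    k <- k + 1L
  }
  .family_cache$reports <- reports
  reports
}

test_that("cross-language comparison separates the two measure families", {
  reports <- make_family_reports()
  suppressWarnings(cl <- correlate_and_project(reports))
  expect_s3_class(cl, "cross_language_summary")
  # correlation matrix: symmetric, unit diagonal
  expect_equal(cl$correlations, t(cl$correlations))
  expect_equal(unname(diag(cl$correlations)), rep(1, ncol(cl$correlations)))
  # loadings columns orthonormal
  expect_equal(crossprod(cl$loadings), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  # unpredictability-family and complexity-family measures land on
  # different components
  ld <- cl$loadings
  main_pc <- apply(abs(ld), 1, which.max)
  expect_equal(main_pc[["pct_irregular"]], main_pc[["vowel_entropy_ci"]])
  expect_equal(main_pc[["pct_equal_length"]],
               main_pc[["n_multiletter_rules"]])
  expect_false(main_pc[["pct_irregular"]] == main_pc[["pct_equal_length"]])
})

test_that("PCA reconstruction error equals the dropped eigenvalue mass", {
  reports <- make_family_reports()
  suppressWarnings(cl <- correlate_and_project(reports))
  pca <- cl$pca
  k <- 2L
  Xs <- scale(cl$matrix[, rownames(pca$rotation), drop = FALSE])
  recon <- pca$x[, 1:k] %*% t(pca$rotation[, 1:k])
  err <- sum((Xs - recon)^2) / (nrow(Xs) - 1)
  dropped_mass <- sum(pca$sdev[-(1:k)]^2)
  expect_equal(err, dropped_mass, tolerance = 1e-8)
})

test_that("comparison contract cases: few reports, duplicates, self-correlation", {
  reports <- make_family_reports()
  expect_error(correlate_and_project(reports[1:2]), "at least 3")
  # duplicated report receives identical scores
  dup <- c(reports[1:3], reports[3])
  suppressWarnings(cld <- correlate_and_project(dup))
  expect_equal(unname(cld$scores[3, ]), unname(cld$scores[4, ]))
  # self-correlation is 1
  suppressWarnings(cl <- correlate_and_project(reports))
  expect_true(all(abs(diag(cl$correlations) - 1) < 1e-12))
})

test_that("the biplot renders without error", {
  reports <- make_family_reports()
  suppressWarnings(cl <- correlate_and_project(reports))
  tf <- tempfile(fileext = ".svg")
  grDevices::svg(tf)
  expect_no_error(plot(cl, main = "synthetic families"))
  grDevices::dev.off()
  expect_true(file.exists(tf))
})
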