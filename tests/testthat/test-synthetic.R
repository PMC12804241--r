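test_that("the generator is deterministic given the seed", {
  sp <- generator_spec(n_words = 200, n_multiletter = 3, n_context = 2,
                       silent_final_rate = 0.1, exception_rate = 0.1,
                       seed = 41)
  a <- synth_lexicon(sp)
  b <- synth_lexicon(sp)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$rules$grapheme, b$rules$grapheme)
  c <- synth_lexicon(generator_spec(n_words = 200, n_multiletter = 3,
                                    n_context = 2, silent_final_rate = 0.1,
                                    exception_rate = 0.1, seed = 42))
  expect_false(identical(a$ground_truth$orthography,
                         c$ground_truth$orthography))
})

test_that("a plain spec yields a bijective identity-style system", {
  orth <- generate_orthography(generator_spec(seed = 1))
  cls <- classify_rules(orth$rules)
  expect_equal(cls$n_multi, 0L)
  expect_equal(cls$n_context, 0L)
  expect_equal(cls$n_single, length(orth$config$letters))
  expect_equal(sort(orth$rules$grapheme), sort(orth$config$letters))
  # every rule maps to exactly one phoneme, all distinct
  expect_false(anyDuplicated(orth$rules$phoneme) > 0)
})

test_that("infeasible specs are rejected", {
  expect_error(generate_orthography(
    generator_spec(n_letters = 4, n_vowels = 3, seed = 1)), "infeasible")
  expect_error(generate_orthography(
    generator_spec(n_multiletter = 500, seed = 1)), "infeasible")
  expect_error(
    generate_lexicon(generate_orthography(
      generator_spec(n_letters = 6, n_vowels = 2, n_words = 100000,
                     seed = 1))),
    "cannot reach")
})

test_that("generated words are valid, monosyllabic and rule-derived", {
  sim <- synth_lexicon(generator_spec(n_words = 400, n_multiletter = 4,
                                      n_context = 2, exception_rate = 0.15,
                                      silent_final_rate = 0.1, seed = 53))
  lex <- sim$lexicon
  expect_length(filter_monosyllabic(lex), length(lex))
  # non-exceptions follow the rules exactly; exceptions never do
  for (i in seq_len(length(lex))) {
    pred <- apply_rules(lex$orthography[[i]], sim$rules, sim$config)
    if (sim$ground_truth$is_exception[i]) {
      expect_false(identical(pred, lex$phonology[[i]]))
    } else {
      expect_identical(pred, lex$phonology[[i]])
    }
    expect_identical(paste(pred, collapse = " "),
                     sim$ground_truth$rule_phonology[i])
  }
})

test_that("the exception-rate knob is recovered within binomial bounds", {
  eps <- 0.2
  n <- 2000
  sim <- synth_lexicon(generator_spec(n_words = n, exception_rate = eps,
                                      seed = 61))
  measured <- as.numeric(pct_irregular(sim$lexicon, sim$rules)) / 100
  # measured share equals the labeled share exactly ...
  expect_equal(measured, mean(sim$ground_truth$is_exception))
  # ... and the labeled share is binomially consistent with eps (99% CI)
  ci_half <- stats::qnorm(0.995) * sqrt(eps * (1 - eps) / length(sim$lexicon))
  expect_lt(abs(measured - eps), ci_half)
})

test_that("complexity and unpredictability knobs dissociate", {
  base <- function(eps, multi, silent, seed)
    synth_lexicon(generator_spec(n_words = 800, exception_rate = eps,
                                 n_multiletter = multi,
                                 silent_final_rate = silent, seed = seed))
  # raising epsilon leaves the length-based complexity proxy unchanged
  s0 <- base(0, 0, 0, 71)
  s1 <- base(0.3, 0, 0, 71)
  expect_equal(pct_equal_length(s0$lexicon), 100)
  expect_equal(pct_equal_length(s1$lexicon), 100)
  expect_gt(as.numeric(pct_irregular(s1$lexicon, s1$rules)),
            as.numeric(pct_irregular(s0$lexicon, s0$rules)))
  # adding complexity leaves irregularity at zero
  s2 <- base(0, 6, 0.2, 71)
  expect_lt(pct_equal_length(s2$lexicon), 100)
  expect_equal(as.numeric(pct_irregular(s2$lexicon, s2$rules)), 0)
})

test_that("unpredictability measures move monotonically in the epsilon knob", {
  eps_grid <- c(0, 0.1, 0.2, 0.3, 0.45)
  for (seed in c(3, 5)) {
    irr <- numeric(length(eps_grid))
    vent <- numeric(length(eps_grid))
    for (k in seq_along(eps_grid)) {
      sim <- synth_lexicon(generator_spec(n_words = 1500,
                                          exception_rate = eps_grid[k],
                                          seed = seed))
      irr[k] <- as.numeric(pct_irregular(sim$lexicon, sim$rules))
      vent[k] <- vowel_entropy(sim$lexicon, "context_independent")
    }
    expect_true(all(diff(irr) > 0))
    expect_true(all(diff(vent) > 0))
  }
})

test_that("generated fixtures round-trip through standard files", {
  sim <- synth_lexicon(generator_spec(n_words = 100, n_multiletter = 2,
                                      seed = 83))
  dir <- tempfile("synthfix")
  paths <- write_synth_lexicon(sim, dir)
  expect_true(all(file.exists(paths)))
  cfg <- read_language_config(paths[["config"]])
  lex <- read_lexicon(paths[["lexicon"]], cfg)
  rl <- read_gpc_rules(paths[["rules"]], cfg)
  expect_identical(lex$orthography, sim$lexicon$orthography)
  expect_identical(lex$phonology, sim$lexicon$phonology)
  expect_identical(rl$grapheme, sim$rules$grapheme)
  expect_equal(as.numeric(pct_irregular(lex, rl)),
               as.numeric(pct_irregular(sim$lexicon, sim$rules)))
})
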