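test_that("equal-length percentage counts letter/phoneme matches", {
  cfg <- toy_config()
  lex <- lexicon(c("cat", "that"), c("kæt", "θæt"), cfg)
  expect_equal(pct_equal_length(lex), 50)
  expect_equal(pct_equal_length(identity_lexicon(c("bad", "dab", "kad"))), 100)
  expect_equal(pct_equal_length(lexicon("that", "θæt", cfg)), 0)
  expect_error(pct_equal_length(lexicon(character(), character(), cfg)),
               "empty")
})

test_that("unique grapheme-phoneme mappings count distinct pairings", {
  cfg <- toy_config()
  rl <- gpc_rules(c("t", "c", "c", "a", "e", "i", "l", "n"),
                  c("t", "k", "s", "æ", "iː", "ɪ", "l", "n"),
                  post = c("", "", "i", "", "", "", "", ""),
                  config = cfg)
  lex <- lexicon(c("cat", "tin", "cin"), c("kæt", "tɪn", "sɪn"), cfg)
  pl <- orthodepth:::parse_lexicon_graphemes(lex, rl)
  # t -> /t/ once; c -> /k/ and /s/: two pairings for c
  expect_equal(count_unique_gp_mappings(pl$parses), 6L)
  # identity lexicon over k letters -> k mappings
  idl <- identity_lexicon(c("bad", "dib", "dab"))
  idr <- identity_rules(idl$config)
  pli <- orthodepth:::parse_lexicon_graphemes(idl, idr)
  expect_equal(count_unique_gp_mappings(pli$parses),
               length(unique(unlist(idl$orthography))))
  expect_equal(count_unique_gp_mappings(list()), 0L)
})

test_that("rule classification counts classes and percentages sum to 100", {
  cfg <- toy_config()
  rl <- gpc_rules(c("t", "th", "c"), c("t", "θ", "s"),
                  post = c("", "", "i"), config = cfg)
  cls <- classify_rules(rl)
  expect_equal(c(cls$n_single, cls$n_multi, cls$n_context), c(1L, 1L, 1L))
  expect_equal(sum(cls$pct), 100, tolerance = 1e-9)
  rl26 <- identity_rules(identity_lexicon(c("bad", "dab"))$config)
  cls26 <- classify_rules(rl26)
  expect_equal(cls26$n_multi + cls26$n_context, 0L)
  # generated rule system: exact recovery of the generator's composition
  orth <- generate_orthography(generator_spec(n_multiletter = 5, n_context = 2,
                                              seed = 3))
  cg <- classify_rules(orth$rules)
  expect_equal(cg$n_multi, 5L)
  expect_equal(cg$n_context, 2L)
})

test_that("rule application is deterministic and the gift/gist flip works", {
  cfg <- toy_config()
  base <- list(g = c("g", "i", "f", "s", "t"),
               p = c("g", "ɪ", "f", "s", "t"))
  rl <- gpc_rules(base$g, base$p, config = cfg)
  expect_identical(apply_rules("gift", rl, cfg), c("g", "ɪ", "f", "t"))
  # hard-g prediction makes gist irregular
  expect_false(identical(apply_rules("gist", rl, cfg),
                         c("dʒ", "ɪ", "s", "t")))
  lex <- lexicon(c("gift", "gist"), c("gɪft", "dʒɪst"), cfg)
  expect_equal(as.numeric(pct_irregular(lex, rl)), 50)
  # adding g[i] -> /dʒ/ flips which word is irregular
  rl2 <- gpc_rules(c(base$g, "g"), c(base$p, "dʒ"),
                   post = c(rep("", 5), "i"), config = cfg)
  expect_identical(apply_rules("gist", rl2, cfg), c("dʒ", "ɪ", "s", "t"))
  expect_false(identical(apply_rules("gift", rl2, cfg),
                         c("g", "ɪ", "f", "t")))
  expect_equal(as.numeric(pct_irregular(lex, rl2)), 50)
  # stuck position error
  expect_error(apply_rules("pig", rl, cfg), "position 1")
})

test_that("irregularity is zero for identity systems and counts no-parse words", {
  idl <- identity_lexicon(c("bad", "dab", "bid"))
  idr <- identity_rules(idl$config)
  expect_equal(as.numeric(pct_irregular(idl, idr)), 0)
  # a rule set not covering some letters counts those words irregular
  cfg <- idl$config
  partial <- gpc_rules("b", "b", config = cfg)
  irr <- pct_irregular(idl, partial)
  expect_equal(as.numeric(irr), 100)
  expect_equal(attr(irr, "n_unparsed"), 3L)
})

test_that("modal rule induction picks the majority mapping, ties lexicographic", {
  cfg <- toy_config()
  # c -> /k/ in 3 words, c -> /s/ in 1
  lex <- lexicon(c("cat", "can", "cap", "cin", "tin"),
                 c("kæt", "kæn", "kæp", "sɪn", "tɪn"), cfg)
  seed_rules <- gpc_rules(c("c", "c", "a", "t", "n", "p", "i"),
                          c("k", "s", "æ", "t", "n", "p", "ɪ"),
                          config = cfg)
  pl <- orthodepth:::parse_lexicon_graphemes(lex, seed_rules)
  modal <- induce_modal_rules(pl$parses, cfg)
  expect_identical(modal$phoneme[modal$grapheme == "c"], "k")
  # exact tie -> lexicographically smaller phoneme, tie reported
  lex2 <- lexicon(c("cat", "cin"), c("kæt", "sɪn"), cfg)
  pl2 <- orthodepth:::parse_lexicon_graphemes(lex2, seed_rules)
  expect_message(modal2 <- induce_modal_rules(pl2$parses, cfg), "ties")
  expect_identical(modal2$phoneme[modal2$grapheme == "c"], min(c("k", "s")))
  # identity lexicon induces identity rules
  idl <- identity_lexicon(c("bad", "dab"))
  pli <- orthodepth:::parse_lexicon_graphemes(idl, identity_rules(idl$config))
  mi <- induce_modal_rules(pli$parses, idl$config)
  expect_identical(sort(mi$grapheme), sort(mi$phoneme))
})

test_that("modal rules minimize irregularity among single-mapping rule sets", {
  # brute force: enumerate every assignment of one phoneme per grapheme
  cfg <- toy_config()
  lex <- lexicon(c("cat", "can", "cin", "tat", "tin"),
                 c("kæt", "kæn", "sɪn", "tæt", "tɪn"), cfg)
  seed_rules <- gpc_rules(c("c", "c", "a", "t", "n", "i"),
                          c("k", "s", "æ", "t", "n", "ɪ"), config = cfg)
  pl <- orthodepth:::parse_lexicon_graphemes(lex, seed_rules)
  modal <- induce_modal_rules(pl$parses, cfg)
  modal_irr <- as.numeric(pct_irregular(lex, modal))
  # enumerate alternatives: per grapheme, any observed phoneme
  obs <- list(c = c("k", "s"), a = "æ", t = "t", n = "n", i = "ɪ")
  combos <- expand.grid(obs, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(combos))) {
    alt <- gpc_rules(names(obs), unlist(combos[r, ]), config = cfg)
    expect_gte(as.numeric(pct_irregular(lex, alt)), modal_irr)
  }
})
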