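test_that("token-level Levenshtein matches hand examples", {
  expect_equal(levenshtein(c("m", "ɪ", "n", "t"), c("p", "ɑɪ", "n", "t")), 2)
  expect_equal(levenshtein(c("m", "ɪ", "n", "t"), c("m", "ɪ", "n", "t")), 0)
  expect_equal(levenshtein(character(), c("a", "b")), 2)
  expect_equal(levenshtein("kitten", "sitting"), 3)
  # tokens compare as wholes: /ɑɪ/ is one unit
  expect_equal(levenshtein(c("p", "ɑɪ"), c("p", "a", "ɪ")), 2)
})

test_that("Levenshtein equals exhaustive edit-script enumeration", {
  syms <- c("a", "b", "c")
  seqs <- list(character())
  for (len in 1:4) {
    grid <- do.call(expand.grid, rep(list(syms), len))
    seqs <- c(seqs, lapply(seq_len(nrow(grid)), function(r)
      as.character(unlist(grid[r, ]))))
  }
  set.seed(12)
  pick <- sample(length(seqs), 30)
  for (i in pick) for (j in pick) {
    expect_equal(levenshtein(seqs[[i]], seqs[[j]]),
                 brute_lev(seqs[[i]], seqs[[j]]))
  }
})

test_that("Levenshtein satisfies the metric axioms", {
  set.seed(13)
  syms <- c("x", "y", "z")
  rnd <- function() sample(syms, sample(0:5, 1), replace = TRUE)
  for (i in 1:40) {
    a <- rnd(); b <- rnd(); c <- rnd()
    dab <- levenshtein(a, b)
    expect_equal(dab, levenshtein(b, a))                 # symmetry
    expect_equal(levenshtein(a, a), 0)                   # identity
    expect_lte(dab, levenshtein(a, c) + levenshtein(c, b))  # triangle
    if (!identical(a, b)) expect_gt(dab, 0)
  }
})

test_that("token-level distance agrees with the vectorized string engine", {
  set.seed(14)
  seqs <- replicate(25, sample(c("a", "b", "ɑɪ", "tʃ"), sample(1:5, 1),
                               replace = TRUE), simplify = FALSE)
  strs <- orthodepth:::remap_to_strings(seqs)
  dmat <- utils::adist(strs, strs)
  for (i in seq_along(seqs)) for (j in seq_along(seqs))
    expect_equal(levenshtein(seqs[[i]], seqs[[j]]), unname(dmat[i, j]))
})

test_that("orthographic neighbors are at letter distance exactly 1", {
  lex <- mint_lexicon()
  nb <- orthographic_neighbors(1, lex)
  expect_setequal(vapply(lex$orthography[nb], paste, "", collapse = ""),
                  c("mints", "tint", "mist", "hint", "pint"))
  # symmetry of the neighbor relation
  for (i in seq_len(length(lex))) {
    for (j in orthographic_neighbors(i, lex)) {
      expect_true(i %in% orthographic_neighbors(j, lex))
    }
  }
  # no distance-1 entry -> empty
  cfg <- toy_config()
  lex2 <- lexicon(c("mint", "page"), c("mɪnt", "pɑɪdʒ"), cfg)
  expect_length(orthographic_neighbors(2, lex2), 0L)
})

test_that("word-level OPC averages phonological distances to neighbors", {
  lex <- mint_lexicon()
  expect_equal(opc_word(1, lex), 1.2)   # pint contributes distance 2
  expect_equal(levenshtein(lex$phonology[[1]], lex$phonology[[6]]), 2)
  # homophone neighbor contributes 0 and drags OPC below 1
  cfg <- toy_config()
  lex2 <- lexicon(c("chat", "chats", "chap"),
                  c("ʃa", "ʃa", "ʃap"), cfg)
  expect_equal(opc_word(1, lex2), 0.5)  # chats: 0, chap: 1
  # identity lexicon: every neighbor at phonological distance exactly 1
  idl <- identity_lexicon(c("bad", "dad", "bid", "bat"))
  expect_equal(opc_word(1, idl), 1)
  # neighbor-less word yields NA
  lex3 <- lexicon(c("mint", "page"), c("mɪnt", "pɑɪdʒ"), cfg)
  expect_true(is.na(opc_word(2, lex3)))
})

test_that("mean OPC is seeded, reproducible, and excludes neighbor-less words", {
  idl <- identity_lexicon(c("bad", "dad", "bid", "bat", "kad", "dak"))
  # sample >= lexicon: deterministic full mean
  r1 <- mean_opc(idl, sample_size = 100, seed = 5)
  expect_equal(r1$n_sampled, length(idl))
  r2 <- mean_opc(idl, sample_size = 100, seed = 5)
  expect_identical(r1, r2)
  # a shallow identity lexicon has mean OPC exactly 1
  sim <- synth_lexicon(generator_spec(n_words = 1500, seed = 23))
  opc <- mean_opc(sim$lexicon, sample_size = 500, seed = 9)
  expect_equal(opc$mean_opc, 1)          # neighbor-having words all score 1
  expect_lt(opc$n_excluded, opc$n_sampled)
  # all sampled words neighbor-less -> error
  cfg <- toy_config()
  lone <- lexicon(c("mint", "page"), c("mɪnt", "pɑɪdʒ"), cfg)
  far <- orthodepth:::lexicon_subset(lone, 2L)
  expect_error(mean_opc(far, seed = 1), "neighbor-less")
})

test_that("silent-final homophones strictly decrease mean OPC below 1", {
  s0 <- synth_lexicon(generator_spec(n_words = 600, seed = 19))
  s1 <- synth_lexicon(generator_spec(n_words = 600, silent_final_rate = 0.4,
                                     seed = 19))
  o0 <- mean_opc(s0$lexicon, sample_size = 600, seed = 3)$mean_opc
  o1 <- mean_opc(s1$lexicon, sample_size = 600, seed = 3)$mean_opc
  expect_equal(o0, 1)
  expect_lt(o1, o0)
  expect_lt(o1, 1)
})

test_that("mean OPC is invariant under phoneme relabeling", {
  sim <- synth_lexicon(generator_spec(n_words = 300, exception_rate = 0.2,
                                      seed = 29))
  lex <- sim$lexicon
  # relabel: append a marker to every phoneme token (bijective relabeling)
  cfg <- lex$config
  cfg2 <- language_config(letters = cfg$letters,
                          phonemes = paste0(cfg$phonemes, "ʹ"),
                          vowel_letters = cfg$vowel_letters,
                          vowel_phonemes = paste0(cfg$vowel_phonemes, "ʹ"))
  lex2 <- lexicon(lapply(lex$orthography, identity),
                  lapply(lex$phonology, function(p) paste0(p, "ʹ")),
                  cfg2)
  o1 <- mean_opc(lex, sample_size = 200, seed = 4)$mean_opc
  o2 <- mean_opc(lex2, sample_size = 200, seed = 4)$mean_opc
  expect_equal(o1, o2)
})
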