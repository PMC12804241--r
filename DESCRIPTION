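Package: orthodepth
Title: Quantifying Orthographic Depth from Pronunciation Lexicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A battery of measures of orthographic depth computed from
    machine-readable pronunciation lexicons of monosyllabic words.
    Implements basic proxies (equal letter/phoneme length, unique
    grapheme-phoneme mappings), rule-based complexity and unpredictability
    derived from grapheme-phoneme correspondence rule systems, statistical
    measures (vowel and body consistency, onset entropy, context-independent
    and context-dependent vowel entropy), information-theoretic efficiency
    via mutual information at the letter, bigram and grapheme grain sizes,
    and a distance-based orthography-phonology consistency measure built on
    Levenshtein neighborhoods.  Includes a seeded artificial-orthography
    generator with controllable grapheme complexity and mapping
    unpredictability, so every measure can be validated against a known
    ground truth without licensed corpora, and tools to compare languages
    via correlation and principal component analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    stringi,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
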