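# orthodepth

Quantifying **orthographic depth** — the closeness of the mapping between a
writing system's spellings and its pronunciations — from machine-readable
pronunciation lexicons of monosyllabic words.

Cross-linguistic reading research needs objective, reproducible depth
estimates, but the published operationalizations are scattered across
theoretical traditions: rule-based counts from dual-route models,
consistency ratios, entropy variants, and ad-hoc proxies. `orthodepth`
implements the full battery behind one set of containers, adds two
segmentation-free families (mutual-information efficiency and a
distance-based neighborhood measure), and ships a seeded
artificial-orthography generator so every measure can be validated against
ground truth without licensed corpora. The measures fall into two families,
reflecting the two dimensions of depth:

| dimension | idea | measures |
|---|---|---|
| complexity | how large must orthographic units be? | % words with equal letter/phoneme counts; rule-class composition; letter-grain efficiency |
| unpredictability | how inconsistent is the mapping at fixed unit size? | % irregular words; vowel/body consistency; onset & vowel entropy; grapheme-grain efficiency; mean OPC |

The core quantities, for a lexicon of monosyllabic (word, /pronunciation/)
pairs:

- **Consistency** of a word's unit (vowel grapheme or body): friends /
  (friends + enemies), self included — the proportion of words sharing the
  unit that also share its pronunciation.
- **Entropy** of a unit's pronunciation distribution:
  `H(X) = −Σᵢ p(xᵢ) log₂ p(xᵢ)` (bits), averaged over units weighted by
  occurrence; onset entropy weights initial letters by their probability.
- **Efficiency** from mutual information over positionally aligned units:
  `I(O;P) = H(P) − H(P|O)`, efficiency `= I(O;P) / H(P)` ∈ [0, 1].
- **OPC** (orthography–phonology consistency): the mean phoneme-level
  Levenshtein distance from a word to its orthographic neighbors (entries
  at letter-level Levenshtein distance 1), averaged over a seeded
  1,000-word sample.
- **Rule measures** over a grapheme–phoneme correspondence table: counts of
  single-letter / multiletter / context-sensitive rules, and the percentage
  of words whose attested pronunciation the rules fail to derive.

## Worked example

A miniature English-like lexicon (16 monosyllables), its configuration and
a small GPC rule table ship under `inst/extdata/`:

```r
library(orthodepth)

cfg   <- read_language_config(system.file("extdata", "demo_config.yaml",  package = "orthodepth"))
lex   <- read_lexicon(system.file("extdata", "demo_lexicon.tsv",  package = "orthodepth"), cfg,
                      language_tag = "demo")
rules <- read_gpc_rules(system.file("extdata", "demo_rules.tsv",  package = "orthodepth"), cfg)

compute_all(lex, rules, seed = 42)
#> <depth_report 'demo'>
#>   monosyllabic words: 16 (of 16)
#>   n_unique_gp_mappings         21
#>   pct_equal_length             50
#>   n_single_letter_rules        14
#>   n_multiletter_rules          6
#>   n_context_rules              0
#>   pct_irregular                18.75
#>   vowel_consistency            0.7955
#>   body_consistency             0.9167
#>   vowel_entropy_ci             0.4703
#>   vowel_entropy_onset_cond     0
#>   vowel_entropy_coda_cond      0.1722
#>   efficiency_letters           0.8387
#>   efficiency_graphemes         0.9541
#>   mean_opc                     1.278
#>   onset_entropy                0.5
```

Reading the numbers: only half the words have as many letters as phonemes
(`th`, `ch`, `ea`, `ll`, silent `e` — complexity), and 3 of 16 words
(*pint*, *gist*, *bite*) defy the rule table (unpredictability). Body
consistency (0.92) exceeds vowel consistency (0.80): the coda context
disambiguates vowels, which is also why coda-conditional vowel entropy
(0.17 bits) is below the context-independent value (0.47 bits). Grapheme
grain efficiency (0.95) exceeds letter-grain (0.84) because multiletter
graphemes misalign a one-to-one letter pairing. Mean OPC 1.28 > 1 reflects
neighbors like *mint*–*pint* whose pronunciations differ by two phonemes.

Single measures are available directly — e.g. the classic toy neighborhood:

```r
mint <- lexicon(c("mint","mints","tint","mist","hint","pint"),
                c("mɪnt","mɪnts","tɪnt","mɪst","hɪnt","pɑɪnt"), cfg)
opc_word(1, mint)
#> [1] 1.2
```

Synthetic orthographies with known ground truth come from the generator:

```r
sim <- synth_lexicon(generator_spec(n_words = 5000, exception_rate = 0.2, seed = 1))
pct_irregular(sim$lexicon, sim$rules)   # recovers ~20
```

## Command line

`exec/orthodepth` wraps the same functions:

```sh
Rscript exec/orthodepth compute  --lexicon lex.tsv --config cfg.yaml --rules rules.tsv --out report.json
Rscript exec/orthodepth simulate --n-words 1000 --exception-rate 0.2 --seed 1 --out-dir sim/
Rscript exec/orthodepth compare  --reports reports/ --out summary.json --plot biplot.svg
```

`compare` needs at least three reports and emits the measure matrix,
cross-measure correlations, and a two-component PCA with biplot.

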