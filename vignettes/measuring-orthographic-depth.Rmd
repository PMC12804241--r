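---
title: "Measuring orthographic depth: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring orthographic depth: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthodepth)
```

## The construct

Orthographic depth is the closeness of the mapping between spellings and
pronunciations. Czech or Finnish are shallow: a letter reliably names one
phoneme. English is deep: *mint* and *pint* share a body with different
vowels, *gift* and *gist* share an onset letter with different consonants,
and silent letters abound. Depth is not one dimension but (at least) two:

* **complexity** — how large the orthographic units must be before
  pronunciation becomes predictable (multiletter graphemes such as *th*,
  context-sensitive correspondences such as *c* before *i*, silent
  letters);
* **unpredictability** — how inconsistent the unit-to-sound mapping
  remains even after unit size is taken into account (true exceptions
  like *pint*).

`orthodepth` computes, from a pronunciation lexicon of monosyllabic
words, every widely used operationalization of both dimensions, plus two
measure families that need no sublexical segmentation at all (mutual
information and a distance-based neighborhood measure), and ships a
seeded artificial-orthography generator so that each measure can be
validated against a known ground truth.

All corpus-level measures here are restricted to monosyllabic words
(exactly one maximal run of nucleus phonemes — vowels plus any declared
syllabic consonants, as in Czech *krk* /kr̩k/). Several measures (body
consistency, the DRC-style rule measures) are only well defined there,
and restricting all measures to the same word set keeps them comparable.

## Inputs

A **language configuration** declares the letter inventory (diacritic
letters such as *ř* are atomic symbols, never decomposed), the phoneme
inventory (tokens may span characters: /ɑɪ/, /tʃ/), the vowel subsets on
both sides, syllabic consonants, and suprasegmental marks to strip on
load (stress marks, length marks, laryngealization symbols — whatever
the transcription convention carries that the measures should ignore).
Everything is UTF-8 and NFC-normalized before matching, so composed and
decomposed encodings of the same diacritic compare equal. In YAML
configuration files, quote the symbol lists: bare `n` or `y` are YAML
booleans.

Transcriptions are tokenized by greedy longest match against the phoneme
inventory. No tokenizer is implied by the measures themselves;
longest-match is deterministic, auditable, and lossless (the
concatenated tokens reproduce the stripped input — property-tested), at
the price that diphthongs and affricates must be listed as explicit
inventory tokens.

Lexicon files are header-bearing TSV/CSV with orthography,
transcription, and optional token frequency. Orthography is case-folded
on load. Exact duplicate rows merge with frequencies summed; homographs
and homophones stay distinct — homophones in particular carry real
signal (they are what pushes French OPC below 1). Per-language cleaning
(loanword or abbreviation exclusion) is deliberately *not* hard-coded:
filter the input file before loading.

## Rule-based measures

A GPC (grapheme–phoneme correspondence) rule table maps graphemes to
phoneme sequences, optionally position-restricted or letter-context
restricted, and is classed `single-letter` / `multiletter` /
`context-sensitive` from its form alone. `classify_rules()` summarizes
the class composition (a complexity index); `apply_rules()` derives a
pronunciation deterministically left-to-right; `pct_irregular()` counts
the words whose attested pronunciation the rules fail to derive (an
unpredictability index).

Three decisions matter here:

* **Precedence.** Longer graphemes beat shorter; context-sensitive beats
  context-free at equal length; remaining ties fall to rule-file order.
  This is the specific-before-general convention of rule-based reading
  models, and it makes `apply_rules()` a pure function of the table.
* **Rule tables are an input, not a truth.** Published rule sets are
  hand-curated, and whether *g*(i) → /dʒ/ is "a rule" flips which of
  *gift*/*gist* is irregular. The package accepts user tables as ground
  truth and offers `induce_modal_rules()` — the most frequent mapping
  per grapheme by type count, ties broken lexicographically and logged —
  as a reproducible default. Modal choice provably minimizes the
  exception count among single-mapping rule sets (brute-force verified
  in the tests).
* **Coverage gaps.** Words no rule sequence can cover are counted
  irregular but reported separately (`n_unparsed`), so users can
  distinguish an incomplete table from a deep orthography.

**Grapheme parsing** (`parse_graphemes()`) is phonology-constrained: the
attested pronunciation is consumed along with the letters, because the
statistical measures need the attested pairing, not a prediction. In the
default lenient mode, a grapheme whose rule phoneme does not match may
still take the single next phoneme — ranked below every rule-consistent
step — so exception words receive the segmentation a human coder would
assign (*gist* still parses as *g*-*i*-*s*-*t*, with *g* → /dʒ/
recorded as the attested pairing). Strict mode refuses such pairings and
errors on ambiguity beyond precedence. Silent letters are graphemes
mapping to the empty phoneme sequence; split graphemes (*a_e*) are not
modeled as discontinuous units — *bite* parses as vowel letter plus
silent *e*, which is one defensible convention among several.

## Statistical measures

**Consistency** (`unit_consistency()`): for each word, the proportion of
words sharing its orthographic unit (vowel grapheme, or body = vowel
plus coda letters) that also share the unit's pronunciation (nucleus,
or rime). The word counts among its own friends; the denominator
includes all sharers. Self-inclusion is required for the canonical
one-against-three scenario to score 0.25, and gives singleton units a
consistency of 1 (they are counted and reported). The lexicon mean is
the depth index; because bodies refine vowel graphemes, mean body
consistency is never below mean vowel consistency (a Cauchy–Schwarz
consequence, property-tested).

**Entropy** (`entropy()`, Shannon, bits): $H(X) = -\sum_i p(x_i)\log_2
p(x_i)$. Entropy refines consistency: a unit pronounced 1-vs-3 (H =
0.81) and a unit pronounced four different ways (H = 2) share a
consistency of 0.25 but differ in uncertainty.

* `onset_entropy()`: per word-initial letter, the entropy of the
  initial-phoneme distribution, summed weighted by the letter's
  probability. It reacts both to unpredictability (*gift*/*gist*) and to
  predictable complexity (*seat*/*sheet*), which is exactly why it is
  reported alongside the vowel measures rather than instead of them.
* `vowel_entropy()`: per vowel grapheme, the entropy of its nucleus
  pronunciations — context-independent, or conditioned on the full
  orthographic onset or coda string (not just the adjacent letter;
  empty onsets form their own conditioning context). Values average
  over graphemes (and contexts) weighted by occurrence count, so the
  law of total entropy guarantees conditioning never increases the
  measure — asserted on 100 random lexicons in the tests.

All probabilities are type-based by default (each word counts once): the
corpus-level readings of these measures average over words, not tokens.
Token-frequency weighting is available everywhere behind
`freq_weighted = TRUE` for item-level research; whether the original
onset-entropy and consistency formulations weighted by frequency is not
settled, so the type-based reading is the default and the flag makes the
alternative explicit.

## Mutual information and efficiency

For aligned orthographic and phonological units,
$I(O;P) = H(P) - H(P|O)$, and **efficiency** $= I(O;P)/H(P)$ is the
share of phonological uncertainty removed by knowing the spelling: 1
for a transparent mapping, 0 for unrelated distributions. The same
quantity is computed at three grains with consistent preprocessing:

* **letters/phonemes** — positional one-to-one, left-to-right
  alignment; trailing unmatched letters (silent *e* in *bite*) are
  discarded, and symmetrically trailing unmatched phonemes when the
  pronunciation is longer. Misalignment is intentional signal: in
  *chat*, position three pairs *a* with /t/, which is precisely how
  complexity depresses letter-level efficiency.
* **bigrams/biphones** — overlapping adjacent pairs of the aligned
  sequences. Overlap-vs-disjoint is not forced by anything in the
  measure; overlapping windows are the default and `overlap = FALSE`
  switches, so the choice is visible rather than buried.
* **graphemes/phonemes** — from grapheme parses; each grapheme pairs
  with its full phoneme sequence as one token, silent graphemes with an
  explicit null token.

Counts pool all word positions into a single table (one number per
language requires pooling), repeated letters are separate observations,
and probabilities are maximum-likelihood with no smoothing — smoothing
would destroy the exact identities (efficiency exactly 1 on transparent
systems) that anchor the scale. The entropy-difference form is checked
against the joint double-sum $\sum p(o,p)\log_2\frac{p(o,p)}{p(o)p(p)}$
to 1e-9 in every test run. The degenerate case H(P) = 0 (a single
phonological unit) leaves efficiency undefined; it is reported as 1
with a warning, since such a mapping is trivially transparent. The
P→O direction is not implemented: spelling consistency raises distinct
questions (French is shallow to read and deep to spell) and is out of
scope.

## The distance-based measure (OPC)

OPC needs no segmentation at all: a word's OPC is the mean
phoneme-token-level Levenshtein distance from its pronunciation to the
pronunciations of its orthographic neighbors — the other entries at
letter-level Levenshtein distance exactly 1 (substitution, insertion,
or deletion; *mints* is a neighbor of *mint*). Shallow mappings give
values near 1 (one letter changed, one phoneme changed); silent-letter
homophone pairs contribute distance 0 and can push the mean below 1.
Distances operate on symbol tokens, not characters, so /ɑɪ/ is one
unit; the *mint*–*pint* distance is 2 either way, but token-level is
the reading consistent with phonemes as units.

`mean_opc()` samples 1,000 words (the conventional estimation subset)
uniformly without replacement under a mandatory seed; neighbor-less
sampled words are excluded from the mean and counted in the result. The
token-level distance is implemented in the package and verified against
both exhaustive edit-script enumeration and the independent C
implementation in `utils::adist`; `adist` (on a bijective symbol
remapping into the private-use plane) also serves as the vectorized
engine for the neighbor search, where an R-level loop would be
needlessly slow.

## The synthetic generator

`generator_spec()` + `synth_lexicon()` build artificial orthographies
in which every measure has a known target. The design:

* a bijective letter core (each letter its own phoneme), so the ε = 0,
  no-complexity default is a perfectly transparent orthography — the
  analytic fixed point where equal-length = 100%, irregularity = 0,
  H(P|O) = 0, efficiency = 1 at all grains, and mean OPC = 1 exactly;
* **complexity knobs**: `n_multiletter` two-consonant graphemes with
  dedicated phonemes, `n_context` consonant-before-vowel context rules,
  and a dedicated word-final silent letter whose twins are constructed
  from words already in the lexicon, guaranteeing homophone neighbor
  pairs (the below-1 OPC regime);
* **the unpredictability knob**: with probability `exception_rate` a
  word's nucleus phoneme is replaced by a different vowel phoneme.
  Perturbing exactly one unit keeps the edit-distance effects local,
  keeps words monosyllabic, and leaves letter/phoneme counts untouched
  — which is what makes the two knob families dissociate cleanly
  (ε moves irregularity, consistency, entropy, efficiency and OPC while
  equal-length stays at 100%; unit-size knobs do the converse).

Words are CVC-skeleton forms (onset unit, vowel, coda of one unit or
two single consonants), with unit combinations restricted so that
greedy longest-match rule application provably recovers the generating
segmentation — no rejection sampling, no parse ambiguity. All
randomness flows from the single spec seed; the same spec is
byte-reproducible. Ground truth (rule classes, per-word exception and
silent-twin labels, generating segmentation) is always emitted, and
`write_synth_lexicon()` round-trips generated data through the same
TSV/YAML files as real corpora.

Defaults are 24 letters (6 vowels), 1,000 words, no complexity, no
exceptions — a clean baseline a user perturbs one knob at a time.
Validation in the tests uses 5,000-word lexicons for the transparency
and rate-recovery checks (large enough for binomial recovery of ε
within its 99% CI over ε ∈ {0, .05, .1, .2, .4} × 3 seeds), 1,200–1,500
words for monotonicity checks, and dozens of small random lexicons for
the entropy inequalities.

What the generator does **not** emulate — and therefore what passing
recovery tests do *not* show: real phonotactics (no sonority
constraints, uniform unit sampling), realistic frequency distributions
(no Zipf), morphology (no inflectional families of similar spellings),
polysyllables, and the messiness of real transcription conventions.
The generator establishes that the measures are *correct* (they recover
the quantities they claim to measure, and dissociate along the intended
dimensions); claims about particular natural languages still require
the corresponding corpora.

## Aggregation and comparison

`compute_all()` runs everything on the monosyllabic subset and returns
a `depth_report`; individual measure failures downgrade to
`skipped`-with-reason entries (a missing rule table skips the
rule-based and grapheme-grain measures, nothing else). Reports carry
provenance (config and rule-table hashes, seed, package version) and
serialize deterministically to JSON.

`correlate_and_project()` assembles the standard fifteen-measure matrix
across ≥3 reports, computes Pearson correlations between measures, and
runs a PCA on the correlation matrix (the measures live on incompatible
scales, so standardization is not optional). Constant or incomplete
columns are dropped with a warning. Biplot signs are arbitrary, so each
component is oriented to make its largest-magnitude loading positive.
On synthetic families varying one knob at a time, the unpredictability
measures and the complexity measures load on separate components — the
package-level restatement of the two-dimensional structure. With a
handful of languages such analyses are descriptive only; the objects
say so whenever fewer than 30 languages are compared, and no inferential
statistics are offered.

## Known limitations

* Monosyllables only; extending consistency/entropy to polysyllables
  requires aggregation decisions this package does not make.
* Alphabetic scripts only; the measures presume letter/phoneme units.
* Grapheme-level measures inherit whatever arbitrariness the supplied
  rule table carries; the modal-induction default is reproducible but
  not psychologically privileged.
* The bigram pairing scheme and the OPC sampling protocol are
  conventions (documented and switchable/seeded), not forced by the
  measures; exact numeric comparability with other implementations
  requires matching those conventions.
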