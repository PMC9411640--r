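---
title: "Encoding out-of-vocabulary medical terms by terminology decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding out-of-vocabulary medical terms by terminology decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medparts)
```

## The problem

Word-level embedding models (word2vec, GloVe and their biomedical
derivatives) assign a vector only to words seen during training. Clinical and
biomedical text is full of compound Greek/Latin terms — *mastodynia*,
*choledocholithiasis* — that are individually rare, so they fall out of the
vocabulary and receive either no vector or an arbitrary one. Yet their
meaning is largely compositional: medical terminology builds terms from a
closed inventory of prefixes, roots and suffixes, joined by combining vowels
(`pneum/o` → lung). A reader who knows the parts can read the whole; so can a
post-processor.

`medparts` exploits this. Given any pre-trained embedding table, an
out-of-vocabulary (OOV) token is pushed through a chain of increasingly
aggressive fallbacks, and the first stage that produces a vector wins:

1. **direct** — normalize the token (case folding, edge punctuation,
   possessives) and look it up;
2. **inflection** — convert between medical singular/plural forms
   (*vertebrae* → *vertebra*) and look the candidates up;
3. **parser** — decompose the term into prefix/root/suffix components,
   replace each component by its dictionary meaning words, and encode the
   term as the mean vector of those words
   (*dyspnea* → *painful, breathing*);
4. **segmenter** — split the term into frequent subword units
   (*seasickness* → *sea + sick + ness*) and encode their mean vector.

A token that survives all four stages is reported as `unresolved` with no
vector — deliberately *not* a random vector, so that downstream code can see
exactly what was approximated and what was not. Pipelines that require a
vector for every token can opt into zeros with
`encode_term(..., unresolved_zero = TRUE)`.

## The component lexicon

The parser's search space is a lexicon of `component_entry` objects: a
`form` (the matchable surface, e.g. `pnea`), its `combining_forms`
(`pneumo`), ordered `meaning_words`, and an optional `organ_system` label.
The on-disk format is plain TSV (columns `form`, `kind`, `combining_forms`,
`meanings`, `organ_system`; comma-joined lists inside cells), chosen because
dictionary data wants to be diffable and hand-editable. When the
`combining_forms` cell is empty the loader auto-generates `form` + each
combining vowel for prefixes and roots; suffixes are terminal, so a
combining form has no grammatical role there and none is generated.

The shipped fixture lexicon (`fixture_lexicon()`) holds a few dozen entries
— enough for the worked examples and the synthetic generator. It is a
fixture, not a reference dictionary: real deployments should load their own
TSV files with `load_lexicon()`, which accepts multiple files with
later-file override. A surface used both ways (e.g. `choledoch`) is stored
under both prefix and root, and the parser labels it by position:
term-initial occurrences are prefixes, later ones roots. The label never
changes the meaning words.

## Inflection as a finite-state transformation

Pluralization applies the first rule, in table order, whose singular suffix
ends the word; singularization is the reverse machine, matching plural
suffixes. The default table is the canonical medical set:

```{r}
default_inflection_rules()
```

Two design points deserve explanation.

*Longest-plural-first singularization.* Matching plural suffixes in raw
table order would singularize *therapies* via `is→es` into *therapis*; the
singularizer therefore prefers the longest matching plural suffix (then
table order). With that order every default rule is the inverse of its
partner, which the test suite verifies on hundreds of generated words per
rule, in both directions.

*Ambiguous rules are opt-in.* The traditional set also contains `ex→ices`
and `on→a`. Their plural suffixes collide with `ix→ices` and `um→a`, so no
deterministic singularizer can invert both members of a colliding pair:
*-ices* must map to either *-ix* or *-ex*. Rather than ship rules that
silently break the round-trip guarantee, the default table omits them;
`default_inflection_rules(extended = TRUE)` enables them, resolving
collisions by table precedence (`cortices` → `cortix`). In the encoder chain
this costs little: candidates are validated against the embedding
vocabulary, so a wrong reading is simply never found. For the same reason
`inflection_candidates()` happily returns both readings of an ambiguous form
(`vertebra` → `vertebrum`, `vertebrae`).

The generic English `+s` rule is also disabled by default (`append_s =
TRUE` enables it) because it collides with medical endings such as
*-sis/-osis*.

## The parser: exact search, not greedy matching

`decompose_term()` searches **all** segmentations of the term into an
optional prefix, any number of roots (each optionally followed by a
combining vowel), and an optional terminal suffix, where every non-vowel
segment must be a lexicon form or combining form. The search is a memoized
dynamic program over cut positions; greedy longest-match is not good enough
because medical forms overlap (*prostatism* must be `prostat + ism`, and a
greedy left-to-right matcher can strand itself).

Among complete segmentations, the parser prefers, in order:

1. fewest meaning-bearing components (combining vowels are free) — compound
   terms are usually built from the fewest parts that fit;
2. the longest terminal suffix — suffixes carry the condition/procedure
   meaning, so `sclerosis` must beat a hypothetical shorter tail match;
3. the lexicographically earliest component tuple — an arbitrary but
   deterministic tie-break.

Non-vowel components must be at least 2 characters (`min_len`), which
suppresses spurious single-letter matches. Meaning phrases are flattened to
word lists *including* their function words (`state, of, or, condition`),
because those are the dictionary's own glosses; `term_meanings(...,
drop_stopwords = TRUE)` can drop `of/or/a/the` before encoding. Words of a
meaning list that are missing from the embedding are skipped rather than
failing the stage — biomedical vocabularies often lack function words — and
the mean is taken over the words actually found.

The test suite verifies the search against an independent brute-force
enumeration of every grammar-valid segmentation on hundreds of generated
terms, plus the printed worked examples (`dyspnea`, `mastodynia`,
`dermatitis`, `arteriosclerosis`, `prostatism`, `urethrorrhea`,
`choledocholithiasis`).

## The segmenter: a unigram Viterbi model

The final fallback segments a term into subword units under a unigram
language model: `train_segmenter()` turns a (word, count) list into unit log
probabilities (relative frequencies plus a closed affix set
`ness, less, ful, ing, ed, er, s` with pseudo-count 1), and
`segment_term()` finds the maximum-likelihood segmentation by Viterbi over
cut positions. Unknown units are admitted at a penalty of
`unknown_penalty = 10` log units per character — large enough that any known
unit is preferred, small enough that arithmetic stays finite. Ties go to
fewer units, then to the leftmost-longest unit, which makes degenerate
all-unknown inputs come back whole (`qqqq` → `qqqq`).

This is a deliberately simple, fully deterministic stand-in for
semi-supervised morphological segmenters: the encoder chain only needs the
contract *term → meaningful subword units*. `segmenter_model()` accepts any
externally produced unit table with the same contract, so a model trained
elsewhere can be dropped in. The Viterbi result is verified against
exhaustive enumeration of all `2^(n-1)` segmentations for short terms.

## Evaluation kit

`evaluate_pairs()` reproduces the standard intrinsic evaluation: encode both
terms of each human-scored pair, cosine their vectors, and Spearman-correlate
model similarities with the human scores. A pair counts as covered only if
*both* terms resolve; unresolved pairs are excluded from the correlation
rather than zero-filled, because zero vectors corrupt cosine geometry.
Spearman uses average ranks for ties (the standard convention).
`token_coverage()` reports the token-level provenance histogram — how many
tokens each stage resolved — which is the right diagnostic for corpora.
Precision/recall/F1 helpers operate on confusion counts and propagate `NA`
when a denominator is zero.

## What the synthetic generator emulates — and what it does not

`generate_terms()` builds compound terms the way the terminology does:
optional prefix, roots, optional terminal suffix (2–3 meaning-bearing
components), inserting the combining vowel `o` after a root when the next
component starts with a consonant (prefixes attach bare, which is why
`dys + pnea` is *dyspnea*, not *dysopnea*). Each term is paired with the
concatenation of its components' meaning words as ground truth. Three
filters keep the ground truth well defined: generated terms must not collide
with any lexicon form or meaning word (so they are genuinely OOV for a
meaning-word embedding); duplicates are dropped; and terms whose canonical
decomposition disagrees with the generating components are rejected, because
concatenation can be morphologically ambiguous. All sampling is seeded and
the generators restore the global RNG state, so they are pure functions of
(config, lexicon).

`generate_pair_dataset()` scores term pairs by the cosine of their
ground-truth mean-meaning vectors plus Gaussian noise (`noise_sd`,
default 0, modelling annotator disagreement). At `noise_sd = 0` a correct
pipeline must reach 100% coverage and Spearman 1.0 — that is the end-to-end
recovery test.

What this does **not** emulate: real clinical term pairs are scored by
experts on relatedness, not only compositional similarity (*myocardial
infarction* relates to *aspirin* for reasons no morphology can see); real
OOV tokens include misspellings, abbreviations and eponyms the parser cannot
decompose; and real embedding geometry is not isotropic random directions.
Passing the synthetic suite therefore demonstrates that the machinery is
correct — normalization, inflection, exact parsing, mean-vector encoding,
coverage accounting — not that any particular correlation will be achieved
on expert-scored benchmarks, which require external embeddings and datasets.

## Numerical and scale choices

Default problem sizes keep the whole suite quick on a laptop: the coverage
check runs 500 generated terms against a 50-dimensional toy embedding; the
parser oracle enumerates segmentations for 200 terms; the Spearman oracle
runs 1,000 random instances of size ≤ 30; inflection round-trips use 200
words per rule and direction. Tolerances: rank correlations are compared to
1e-9 (they are exact arithmetic on ranks); cosine closed forms to 1e-4;
segmenter score ties within 1e-12 are treated as equal before tie-breaking.
Degenerate inputs are defined, not exceptional: empty meaning lists cannot
exist (the loader rejects them), all-unknown terms come back as one unit,
constant score vectors make Spearman `NA` with a clear error at the metric
level.

## Known limitations

- The fixture lexicon is small by construction; coverage of real text
  depends entirely on the dictionaries the user loads.
- Multi-suffix stacking (e.g. derivational chains) is out of grammar; the
  parser allows at most one terminal suffix.
- Hyphenated compounds are not split; only whitespace separates words of a
  multi-word term.
- The inflection table is a reconstruction of the standard medical rule set,
  not an exhaustive one; irregular English plurals are out of scope.
- Binary word2vec and contextual (transformer) embeddings are not read; the
  text format is the interchange point.
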