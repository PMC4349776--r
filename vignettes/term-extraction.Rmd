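---
title: "Headword-anchored term extraction with a modified-Huber classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Headword-anchored term extraction with a modified-Huber classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termenrich)
```

## The problem

Controlled vocabularies such as UMLS and MeSH define biomedical semantic
categories, but only a small fraction of their terms ever appears in
abstracts, and conversely many entity names used in articles are missing
from the vocabularies. termenrich implements a precision-oriented pipeline
for harvesting new category members from text: candidate noun phrases are
collected around *unique concept headwords* — words like "protein",
"disease" or "cell" whose presence as the head of a noun phrase fixes the
phrase's semantic category — and a linear classifier over character n-gram
features removes noisy candidates before the survivors are compared with
the existing vocabulary.

The pipeline has three stages:

1. **Chunking.** Sentences are tokenized and part-of-speech tagged; for a
   headword occurrence the noun phrase is the maximal run of adjectives,
   nouns and numbers ending at the headword, rejected outright when
   another noun follows immediately to the right (the headword is then not
   the head of its phrase, as in "protein kinase").
2. **Pattern extraction.** Three lexico-syntactic patterns produce
   candidates: removal of the headword when the reduced phrase recurs in
   the same abstract as a noun phrase in its own right (pattern 1);
   appositive definitions "X, a/an/the ... HEADWORD" (pattern 2); and
   copular/hyponymy templates "X is/are/was/were/as DT ... HEADWORD"
   (pattern 3), the generalization of the 40 alignment-learned "is a"
   templates shipped with the package (`load_pattern_table()`).
3. **Classification.** Each unique candidate is scored by an SVM-style
   linear model trained on a labeled vocabulary with the modified Huber
   loss; positives above the decision threshold are kept and partitioned
   into already-known versus new terms.

## The headword rule

`headword_of()` returns the last word of a term, or the last word before
the first preposition ("inhibitor of kinase" → "inhibitor"). The same rule
supplies the headword used to featurize vocabulary terms and candidates,
so training and prediction see features produced identically.

Headword matching during extraction is by lemma by default
(`match = "lemma"`), so "cells" is found when searching for "cell"; a
surface mode keeps singular and plural runs separate, which is how one
reproduces analyses that treat "cell" and "cells" as distinct headwords.

## Features

`featurize(phrase, headword)` emits binary features only — presence, not
counts:

* within-word letter trigrams ("mos", "osa", ...);
* word prefixes of two and three characters, marked "$" ("mo$", "mos$");
* the same two families from the headword with "!h" appended
  ("vir!h", "vi$!h"), keeping headword evidence separate;
* the last 3, 4 and 5 characters of the headword, marked "!s"
  ("ase!s"), emitted only when the headword has **more than five**
  characters. Suffixes such as *-ase* are strong category cues; the
  strict reading of the gate means a five-character headword like
  "virus" contributes none.

Trigrams never cross word boundaries (the worked example "mosaic virus"
contains no cross-boundary trigram, and within-word extraction keeps the
feature space small). Case is folded before featurization; digits and
internal hyphens are ordinary characters, so "21kDa" and "actin-binding"
contribute trigrams spanning them.

```{r}
featurize("mosaic virus", "virus")
```

## The classifier

For a training set of size $T$ with binary feature vectors $X_i$ and
labels $y_i \in \{-1,+1\}$ the objective is

$$C(w,\theta) = \tfrac{\lambda}{2}\lVert w\rVert^2 +
\tfrac1T \sum_{i=1}^{T} h\!\left(y_i(\theta + w\cdot X_i)\right),$$

with the modified Huber loss

$$h(z) = \begin{cases} -4z & z \le -1\\ (1-z)^2 & -1 < z < 1\\ 0 & z \ge 1.\end{cases}$$

$h$ is continuous with a continuous derivative (slope $-4$ at $z=-1$, $0$
at $z=+1$), so the convex objective is minimized by plain full-batch
gradient descent from $w=0,\theta=0$. The regularization strength is tied
to the data scale, $\lambda = \lambda' \langle\lVert x\rVert\rangle^2$,
where $\langle\lVert x\rVert\rangle$ is the mean Euclidean norm of the
training vectors; the default $\lambda' = 10^{-7}$. A hinge-loss variant
(`loss = "hinge"`) is provided for comparison; on the synthetic benchmark
the two agree closely, and neither is treated as preferable.

Numerical choices: the learning rate is fixed (default 0.5 over 200
epochs); a step that would increase the cost is rejected and the rate
halved, so the recorded cost sequence is non-increasing and training is
deterministic — the only randomness anywhere in the classifier stage is
the fold shuffle of `cross_validate()`, controlled by its `seed`.
Prediction uses $\theta + w\cdot x > 0$; ties go to the negative class,
the conservative choice for a precision-oriented filter. Class imbalance
is deliberately not reweighted (an imbalanced vocabulary depresses recall
while leaving precision high, which is the intended operating point);
`threshold` in `run_config()` exposes the precision/recall trade-off.

Cross-validation is stratified (positives and negatives split into folds
separately) and metrics are pooled over all held-out predictions rather
than averaged per fold; a fold with no positive predictions triggers a
warning and precision is reported as 0 with a flag.

## Bigram compatibility

`build_bigram_index()` collects every within-sentence contiguous word
bigram of a corpus (lemmatized and case-folded by default);
`bigram_compatible()` accepts a term iff all of its bigrams occur in the
index, single-word terms vacuously. Bigrams are kept sentence-local — the
conservative choice, since cross-sentence pairs are not evidence that a
word sequence is used in text. This screen is how one restricts a large
vocabulary to corpus-consistent entries before training.

## Tokenizer, tagger, lemmatizer

These are pluggable; the built-ins are deliberately simple rule systems.

* **Tokenizer**: whitespace split, leading/trailing punctuation detached
  as separate tokens, internal hyphens kept ("actin-binding" is one
  token).
* **Sentence splitter**: `[.?!]` + whitespace + uppercase/digit, with a
  short abbreviation guard list ("e.g.", "et al.", "Fig.").
* **Tagger contract**: any total function from a token vector to an
  equal-length tag vector over the closed set
  `NOUN, ADJ, NUM, DET, PREP, VERB, PUNCT, OTHER`. The built-in
  `rule_tagger()` combines a packaged closed-class lexicon with suffix
  rules (digit-initial tokens are `NUM`; hyphenated tokens ending
  *-ing/-ed* are `ADJ`, other hyphenated tokens `NOUN`; derivational
  adjective endings give `ADJ`) and defaults to `NOUN`. Participles and
  denominal forms will sometimes be mis-tagged; a corpus-trained tagger
  can be dropped in through the contract without touching the rest of the
  pipeline.
* **Lemmatizer**: regular plural stripping with a small
  irregular/invariant list; deterministic and idempotent. The backend
  name is recorded in serialized models.

## Pattern-matching decisions

Where the written description of the patterns leaves room, the package
resolves it as follows (all configurable):

* Pattern 2 determiners are `{a, an, the}` — "an" is included because the
  template table itself contains "X is an Y".
* Pattern 3 link tokens include "was"/"were" alongside "is/are/as",
  because the table contains "X was the only Y".
* The gap between the determiner and the headword is capped at 6 tokens
  (`gap`), which covers every packaged template while preventing runaway
  spans.
* The X slot is chunked with the same left-maximal ADJ/NOUN/NUM rule,
  anchored immediately left of the comma or link token; a pronoun or lone
  determiner there rejects the match ("It is a protein" yields nothing).
* Pattern-1 recurrence is compared on lemmatized, case-folded token
  sequences and must itself be a chunker-recognized noun phrase at a
  different span — substring hits inside larger phrases do not verify a
  candidate. A surface-exact mode is available.
* No candidate may equal or end with its headword.
* An optional, off-by-default `enumeration_guard` discards matches whose
  defining phrase is followed by a comma-separated list repeating the
  headword ("the 35S rRNA gene, the NTS1 spacer, the 5S rRNA gene, ...").
  It is a best-effort heuristic against the most common error mode of
  appositive matching, not a parser.
* The defining phrase is not required to end its clause; requiring a
  trailing comma after the headword would cost recall with no clear
  precision gain on the fixtures examined.
* An optional stopword hook in `run_config()` drops over-general terms
  ("fourth cell type"); the package ships no list, since a useful one is
  category-specific.

## Synthetic data: what it does and does not emulate

`generate_corpus()` assembles abstracts from sentence templates over a
closed word lexicon whose tags the built-in tagger gets exactly right;
this isolates pattern logic from tagger noise. Each record plants, with
configurable rates, a pattern-1 instance (the reduced phrase recurring in
the title, plus an unverified "foil" whose reduction never recurs), an
appositive, and a copular definition, and records exhaustive ground truth
with spans. `generate_vocabulary()` draws pronounceable stems and gives
positives and negatives disjoint suffix pools (defaults *-ase, -olin,
-idase, -erin* vs *-itis, -osis, -emia, -oid*), with an independent
label-flip noise rate; at noise 0.5 the labels carry no signal and pooled
cross-validation F1 collapses to chance.

Default sizes — 50-record corpora and 2000 terms per class — are small
enough to run in seconds yet large enough that cross-validation metrics
are stable to a few percent. What the generator does **not** emulate:
real PubMed token distributions, tagger errors, syntactic attachment
ambiguity, enumerations (except through the optional distractor for the
guard test), or the severe class imbalance of a real vocabulary. Passing
on synthetic corpora therefore demonstrates correctness of the pattern
and classifier machinery, not the field precision one would measure with
human review of real extractions.

## Limitations

The fallback tagger's default-NOUN policy merges unknown preceding words
into noun phrases more aggressively than a trained tagger would, which
mainly inflates pattern-1 source phrases whose reductions then simply
fail verification (a recall, not precision, cost). Pattern matching is
purely linear over tags — no attachment analysis — so enumerations and
parenthetical apposition remain the dominant error sources, as the guard
heuristic only partially mitigates. The classifier sees a candidate's
characters only; semantically mis-typed but well-formed names ("megsin
mRNA" as a gene) pass it, and routing rules between related categories
are left as a documented hook rather than implemented policy.
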