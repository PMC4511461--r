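---
title: "Recognizing and scoring bacteria habitat mentions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing and scoring bacteria habitat mentions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontohab)
```

`ontohab` detects mentions of bacteria habitats in text, normalizes them to
concepts of an OBO-format habitat ontology, extracts bacterium–habitat
*Localization* and habitat–habitat *PartOf* relations, and scores entity
predictions with the Slot Error Rate (SER). This vignette explains the
procedure, its assumptions, the tunable parameters, the numerical choices,
and what the packaged fixtures do and do not demonstrate.

## The recognition model and its assumptions

The central assumption is that habitat mentions are noun phrases, and that
shallow syntax — sentence boundaries, POS tags, lemmas and non-recursive NP
chunks — carries enough signal to find and delimit them. No full parse is
built.

The pipeline is: segment paragraphs (blank-line runs) and sentences;
tokenize, tag and chunk; extract maximal NP chunks; simplify each NP by
dropping non-informative tokens; match candidates against the ontology
label index; apply three boundary rules.

**Simplification.** Tokens tagged `DT`, `PDT`, `WDT`, `PRP$` or `POS` are
dropped wherever they occur. Determiners and possessive pronouns carry no
habitat information ("the mummy tissue" → "mummy tissue", "its small
intestine" → "small intestine"); the pre-determiner, wh-determiner and
possessive-clitic tags are conservative analogues of the same class.

**Matching.** Every ontology label — concept names plus EXACT and (by
default) RELATED synonyms — is normalized (lowercase, whitespace collapsed,
surrounding punctuation stripped) and compared against every contiguous
token subsequence of the candidate, on the surface stream and the lemma
stream simultaneously; a surface match wins over a lemma match for the same
(concept, range). Matching is whole-token: a label never matches inside a
token, and hyphenated words ("iron-rich") are single tokens. Only maximal
ranges per concept are kept. Lemma matching is what lets the plural
"animals" find the label "animal".

**Boundary rules.** An exact (full-cover) match makes the whole candidate
an entity normalized to the concept. A partial match that starts at the
first token bounds the entity at the matching sub-phrase only. A partial
match that starts later promotes the whole candidate to an entity
normalized to the matched concept. Mentions with identical spans merge,
keeping all concept ids; overlapping mentions from one candidate are all
emitted, with no containment suppression.

**Coordination.** A candidate containing exactly one "and" is split with
shared-head completion: with left conjunct L and right part R, the
sub-phrases are `L + R[-1]` and `R` (so "pharyngeal and gut mucosa" gives
"pharyngeal mucosa" / "gut mucosa"); a single-token R gives the plain split
("plants" / "animals"). This head rule is the simplest one that reproduces
all four canonical coordination phrases; an "and" in first or last position
is treated as non-coordinating. Each sub-phrase maps to its best match
(exact over prefix over internal, longer ranges first, ties by concept id —
the ordering that makes the most specific label win). If both concepts
share a direct is_a parent the phrase denotes one habitat covering the full
span — normalized to *both* concepts, which is lossless where a single
choice would be arbitrary — unless both sub-phrases are single nouns, in
which case they are separate entities; without a common parent they are
always separate, the first one discontinuous.

**Modifier attachment** (`NP prep NP` merging for *in*/*of*/*with*) is
implemented but **off by default**: prepositional-phrase attachment is
ambiguous under shallow syntax ("patient in Europe" vs "isolated … in
1993"), and merged candidates hurt more than they help on held-out data.
The merged candidate is emitted *in addition to* the plain NPs, so enabling
it never removes entities.

## Relation extraction

Two Localization strategies share one contract (gold entities in, typed
relations out):

* **Paragraph strategy**: the first bacterium of a paragraph is its topic
  and pairs with every habitat/geographical entity of the paragraph. The
  anchor's text, after deleting a standalone "strain" token, is re-anchored
  to its first document occurrence — documents introduce an organism early
  and later repeat it with strain designators.
* **Sentence strategy**: every *specific* bacterium of a sentence (generic
  "bacteria"/"bacterium" excluded, case-insensitively) pairs with every
  habitat/geographical entity of that sentence. All specific bacteria pair,
  not just the first: nothing in the co-occurrence assumption privileges
  one. Geographical entities participate exactly like habitats as
  Localization targets.

A sentence without a specific bacterium goes to the anaphora resolver,
in fixed order: **type 1** — the sentence contains one of 23 listed
anaphoric expressions (matched as lowercase token subsequences); the
antecedent is the first bacterium of the previous sentence, falling back to
the first in the document (documents are usually about one species,
mentioned first). **Type 2** — the sentence starts with "it"; previous
sentence only, no fallback, and no resolution in a document-initial
sentence. **Type 3** — the sentence starts with "this strain"; document
first. The official 23-expression list was never published; the packaged
list keeps the five documented expressions and fills the remainder with
systematic determiner/number/head variants, deliberately excluding bare
"this strain" so that type 3 governs it. The list is a plain-text file and
fully overridable.

**PartOf**: habitat A is the *part* and habitat B the *host* when A's span
contains B's and either (rule 1) B directly follows *of*, *in* or *from*
inside A — determiners between the preposition and B are skipped, because
annotated boundaries may keep an article outside the inner mention ("…from
a Lyme disease patient…") — or (rule 2) B is a proper prefix of A's token
sequence ("Aeschynomene stem nodule" / "Aeschynomene"). Only overlapping
mentions can be linked; long-distance PartOf is out of scope, as is
host/host-part pre-typing of habitats.

## The SER metric

For a prediction/reference pair, `J` is the Jaccard coefficient of the sets
of *character positions* covered by their (possibly discontinuous) spans,
and `W` the Jaccard coefficient of the two concepts' is_a ancestor sets.
Each ancestor set includes the concept itself, which is exactly what makes
`W = 1` iff the ids coincide. The pair's credit is `M = J·W`, its
substitution cost `S_pair = 1 − M`, and

    SER = (S + D + I) / N.

Candidate pairs are those with `J > 0`. The pairing is an optimal
one-to-one assignment maximizing ΣM (delegated to weighted bipartite
matching in `igraph`), not a greedy sweep: it is deterministic and
order-independent where greedy pairing depends on input order. A greedy
variant remains available behind `method = "greedy"` for comparison. When
an entity carries several concept ids, `W` takes the best id pair.

Numerical details: every edge weight gets an epsilon of 1e-9 so that among
matchings with equal ΣM the one with *more* pairs wins (a zero-credit
overlap then counts as one substitution, cost 1, rather than a deletion
plus an insertion, cost 2); weights are far enough apart in practice that
the epsilon cannot flip a non-tied optimum. `score_ser()` with no
references is an error, with no predictions gives SER 1 and a flagged,
zero-defaulted precision. Aggregate mode (`ser_from_totals()`) uses the
identity `S_pair + M = 1` per matched pair, so matched-pair count = S + M
and `N = S + M + D`; feeding it the published corpus-level totals of both
system configurations recovers N ≈ 507 and reproduces the printed SER
(0.68 / 0.68) and recall (0.60 / 0.63) — the package's internal-consistency
check on the metric, recomputed by `scripts/acceptance.R` and the test
suite. Reported precision uses the predicted-entity count as denominator;
published precision figures are not exactly recoverable from printed totals
under any simple denominator, so precision is documented but not treated as
a reference quantity.

## The analyzer contract and the fixture analyzer

Any analyzer can drive the pipeline if it supplies sentence spans and
per-token (surface, lemma, POS, chunk) with offsets that slice the original
text back to each surface — the offset contract is enforced, and offsets
are 0-based, end-exclusive, over the UTF-8 decoded text (the standoff
convention; whether real corpora count bytes or code points is
undocumented, so code points are used and checked).

The packaged analyzer is deliberately *not* a general tagger: it is a
deterministic lexicon (≈120 surface/lemma/POS entries covering every word
of the fixture corpus) plus suffix heuristics for unknowns (digits → `CD`,
capitalized → `NNP` — the slot bacteria names occupy —, `-ies`/`-s` →
plural noun with singular lemma, `-ed` → past participle, otherwise `NN`).
Chunking opens an NP at determiners/possessives/adjectives/nouns/cardinals,
continues through adjectives/nouns/cardinals, and absorbs "and" only when
the next token could continue the NP — which is what keeps "pharyngeal and
gut mucosa" in one chunk while leaving clause-level "and" outside. Sentence
segmentation splits after `.`/`!`/`?` before whitespace; abbreviation
periods (e.g. "B. subtilis") are not special-cased.

What this means for interpretation: the fixture corpus emulates the
*structures* the rules target (titles as one-line paragraphs, anaphoric
follow-up sentences, strain designators, coordinated and overlapping
mentions, discontinuous spans) under a perfect tagger. Passing tests show
the rules and metric are implemented exactly; they say nothing about
robustness to tagger errors, spelling variation, abbreviation-laden
sentence boundaries, or the lexical diversity of real web text — on real
corpora, error compounds from the analyzer down.

## Other design decisions

* Nested NPs are not candidates; only maximal chunks are. Label lookup can
  be restricted to names + EXACT synonyms (`match_related = FALSE`);
  RELATED synonyms match by default since names and synonyms are not
  distinguished by the matching rules.
* Ontology expansion appends a training surface form as an EXACT synonym
  unless it already equals one of the concept's labels, compared on
  normalized (case/whitespace-insensitive) strings — whether the original
  procedure lowercased first is unstated, so the insensitive comparison is
  used and the operation is idempotent by construction.
* Obsolete OBO terms stay in the concept map (ids remain resolvable) but
  never match. A synonym line without a scope keyword is RELATED, the OBO
  1.2 default.
* Serialization is canonical: entities by first-fragment start then id,
  normalizations/relations renumbered in entity order, discontinuous texts
  joined with single spaces — hence byte-identical reruns and stable
  round-trips.
* Fixture concept ids: four ids are fixed by the ontology release (mummy
  tissue, animal, body fluid, infant); every other fixture concept uses the
  reserved synthetic range `MBTO:0990xxxx`, listed with a `synthetic` flag
  in `fixture_concept_manifest()`. The "gastrointestinal tract" synonym on
  *digestive tract* is part of this synthetic closure.

## Problem sizes and runtime

The test suite runs entirely on generated data: the 24-concept fixture
ontology and 11 fixture documents; 200 random pairing instances of up to
6×6 entities checked against an exhaustive-permutation oracle; 250 random
standoff documents and 250 random ontologies for round-trip stability;
random DAGs of up to 50 nodes for the ancestor oracle and the symmetry of
`W`. These sizes keep the default run under a minute while covering every
branch of the matching, pairing and IO code; the components scale to
corpus-sized inputs (per-document work is quadratic only in tokens per
candidate and entities per document).

## Known limitations

Recognition covers habitat entities only (bacteria and geographical
entities are inputs, not outputs). PP-attachment ambiguity is accepted
behavior when modifier attachment is enabled. The anaphora list
approximates an unpublished keyword inventory. The sentence splitter has no
abbreviation model. PartOf requires overlapping mentions. None of these
affect the deterministic fixture corpus; all of them matter on real text.
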