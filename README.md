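# ontohab

Rule-based recognition and ontology normalization of bacteria habitat
mentions in text, with relation extraction and Slot Error Rate scoring.

## The problem

Most of what is known about bacteria biotopes — the hosts, host parts, food
matrices, soils and waters where bacterial species live — sits in
unstructured text such as sequencing-project web pages and encyclopedia
entries. Turning that text into structured facts takes three steps:

1. **Entity detection and categorization**: find habitat mentions
   ("human gastrointestinal tract", "iron-rich and wet environment") and
   normalize each to a concept of a habitat ontology (OBO format, ids of the
   form `MBTO:NNNNNNNN`).
2. **Relation extraction**: link bacteria to the habitats they live in
   (*Localization*) and host-part habitats to their hosts (*PartOf*),
   given gold entity annotations in BioNLP-ST standoff form
   (`.txt`/`.a1`/`.a2`).
3. **Evaluation**: score predicted entities against references with the
   Slot Error Rate, and relations with precision/recall/F.

`ontohab` implements all three as an R package with a command-line
interface, plus a deterministic lexicon-driven shallow analyzer and a
self-contained fixture bundle (mini-ontology + example corpus) so everything
runs and is testable offline.

## The method

**Recognition** works on shallow syntax only: sentences are segmented,
tokens get POS tags, lemmas and noun-phrase (NP) chunks. Each NP is
simplified by dropping non-informative tokens (determiners, possessive
pronouns), then matched — on surface and lemma streams — against the
ontology's names and synonyms:

* exact match → the whole candidate phrase is an entity, normalized to the
  concept;
* partial match starting at the first word → the matching sub-phrase alone
  is the entity;
* partial match starting later → the whole candidate phrase is the entity.

So "animal bodily fluid" yields two overlapping entities: "animal"
(prefix match on the name *animal*) and "animal bodily fluid" (internal
match on the exact synonym *bodily fluid* of *body fluid*).

Coordinated NPs ("pharyngeal and gut mucosa") are split at "and" with
shared-head completion into "pharyngeal mucosa" / "gut mucosa". If both
sub-phrases map to concepts sharing a direct is_a parent, the whole phrase
is one entity (normalized to both concepts), unless both sub-phrases are
single nouns; otherwise each sub-phrase is its own — possibly
discontinuous — entity.

**Relations**: the paragraph strategy treats the first bacterium of a
paragraph as its topic (re-anchored to the earliest strain-less mention of
the same name); the sentence strategy pairs every specific bacterium with
the habitats of its sentence and hands anaphoric sentences ("This
bacterium…", sentence-initial "It", "This strain…") to a three-rule
resolver. PartOf links overlapping habitat mentions when the inner mention
follows *of*/*in*/*from* inside the outer one, or is a prefix of it.

**Scoring**: with `S` the summed substitution scores, `D` deletions
(missed references), `I` insertions (spurious predictions) and `N`
reference entities,

    SER = (S + D + I) / N,   S_pair = 1 − M,   M = J · W

where `J` is the span Jaccard coefficient and `W` the Jaccard coefficient
of the two concepts' self-inclusive is_a ancestor sets. Predictions are
paired to references by maximum-weight one-to-one assignment over `M`.

## Worked example

```r
library(ontohab)
ont <- build_fixture_ontology()
doc <- analyze("The animal bodily fluid was collected for analysis.")
mentions <- detect_entities(doc, ont)
for (m in mentions) print(m)
#> <habitat_mention> "animal" [4-10] -> MBTO:00001660
#> <habitat_mention> "animal bodily fluid" [4-23] -> MBTO:00000921
```

The NP "the animal bodily fluid" is simplified to "animal bodily fluid";
the prefix match on *animal* bounds an entity at the matching sub-phrase
(characters 4–10), while the internal match on *bodily fluid* promotes the
whole phrase to an entity normalized to *body fluid* (`MBTO:00000921`).

Aggregate scoring from corpus-level totals uses the identity
`N = S + M + D` (each matched pair contributes `S_pair + M = 1`):

```r
print(ser_from_totals(S = 112.70, D = 89, I = 141, M = 305.30))
#> <ser_outcome> SER 0.6759 (S=112.70 D=89 I=141 M=305.30 N=507.00) R=0.6022 P=0.5462 F=0.5728
```

## Command line

```sh
ontohab fixtures --out fx                       # materialize ontology + corpus
ontohab detect --input fx/corpus --output pred --ontology fx/ontology.obo
ontohab relations --input fx/corpus --output rel --strategy sentence
ontohab evaluate --reference fx/corpus --prediction pred --ontology fx/ontology.obo
ontohab expand-ontology --ontology fx/ontology.obo --annotations train/ --out expanded.obo
```

The script is installed under the package's `exec/` directory
(`system.file("exec", "ontohab", package = "ontohab")`); run it with
`Rscript` if it is not on your `PATH`.

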