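---
title: "Mining gene–phenotype associations with ontology-propagated NPMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining gene–phenotype associations with ontology-propagated NPMI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomine)
library(dplyr)
```

## The problem

Most of what is known about which genes produce which phenotypes is reported
in free text rather than deposited in structured databases. phenomine
implements a pipeline that extracts candidate gene–phenotype associations
from a sentence-split corpus by dictionary-based named entity recognition
and co-occurrence statistics, and then uses the resulting per-gene phenotype
profiles to prioritize candidate disease genes by phenotype similarity. Both
steps lean on a phenotype ontology — its subclass structure is used as
background knowledge during counting, and its annotation frequencies define
the information content used for similarity.

## Ontology model

The ontology is read from an OBO flat file (`read_obo()`): `[Term]` stanzas
with `id`, `name`, `synonym`, `is_a`, `xref`/`equivalent_to` and
`is_obsolete`. Ids declared equivalent are merged symmetrically into one
node (union–find; the merged node keeps the lexicographically smallest
member id), because a cross-species phenotype pair such as a mouse "brain
inflammation" class and a human "encephalitis" class names one phenotype
and should pool its labels. The merge is symmetric rather than a directed
mapping; nothing downstream depends on which member id is canonical.
Relationship types other than `is_a` are ignored, and the merged `is_a`
graph must be a DAG (a cycle is a structural error naming the classes
involved).

The central modelling assumption is **mention propagation**: a mention of a
subclass is a mention of every superclass. Two consequences:

* `term_sets()` builds, for each class `C`, the set `Terms(C)` of
  normalized labels and synonyms of `C` and all its descendants, so the
  term set grows monotonically up the hierarchy.
* at counting time, a tagged phenotype class increments the counters of all
  of its ancestors, so associations can be detected at every level of the
  hierarchy even when no single specific class reaches significance.

## Dictionaries and tagging

Dictionaries (`build_gene_lexicon()`, `build_phenotype_lexicon()`) are
refined with two rules: terms shorter than 3 characters are dropped, and
terms colliding with common English words are dropped ("she" is a real gene
synonym). The packaged stoplist is a hand-curated list of several hundred
high-frequency English words (`inst/extdata/stoplist_en.txt`); it is
deliberately configurable because no fixed list suits every corpus.
Rejected terms are retained in the lexicon's `stoplist` field for audit.

Three policies are worth calling out:

* **Case.** Matching is case-insensitive, except gene terms that are
  all-uppercase and at most 5 characters ("GCL", "SHE"); these are matched
  case-sensitively. This removes a class of abbreviation false positives
  without introducing a disambiguation model.
* **Ambiguity is preserved.** A term mapping to several entities emits all
  of them. Sporadic mis-hits are diluted by the corpus-level statistics: a
  wrong pairing that occurs in few sentences relative to the marginals gets
  a low NPMI.
* **Most-specific mapping.** The phenotype dictionary maps each term only
  to the classes whose *own* labels or synonyms contain it; generalization
  happens at counting time through ancestor propagation, never in the
  dictionary.

Sentences are the co-occurrence unit. The splitter is rule-based (terminal
punctuation followed by whitespace and an uppercase/digit/quote start, with
an abbreviation exception list), so it is fully deterministic and
dependency-free; sentences are exact substrings whose concatenation
reconstructs the document. The tagger reduces each sentence to its
alphanumeric token stream and looks up token n-grams in the dictionaries,
so matches always start and end at token boundaries ("she" never fires
inside "shell"). Overlapping matches resolve longest-first, then leftmost,
then lexicographically — tagging is deterministic by construction. Negation
is not detected; a negated co-mention counts like any other, and only its
rarity relative to non-negated mentions keeps it out of the top ranks.

## Co-occurrence statistics

For gene `G` and phenotype class `D`, four sentence counts are kept
(`count_cooccurrences()`): the corpus size `n_tot`, the marginals `n_G` and
`n_D`, and the joint `n_GD`. All are *sentence-set* counts (a sentence
contributes at most 1 to any counter), and both `n_D` and `n_GD` are
propagated to ancestors so that `n_GD(G, C) >= n_GD(G, S)` whenever `S` is
a subclass of `C` — propagating the marginal as well keeps the invariant
`n_GD <= n_D` intact. Every pair with `n_GD >= 1` is scored with the
normalized pointwise mutual information

$$ npmi(G, D) \;=\; \frac{\log \dfrac{n_{GD}\, n_{tot}}{n_G\, n_D}}
                        {-\log \dfrac{n_{GD}}{n_{tot}}} \in [-1, 1], $$

which is 0 at exact independence and 1 at perfect co-occurrence. Numerical
edge cases are pinned explicitly: `n_GD = n_tot` makes the denominator 0
and returns the limit value 1, and `n_GD = n_G = n_D` returns exactly 1
rather than trusting two separately rounded logarithms to cancel. Pairs
that never co-occur are *absent*, not scored −1: with no shared sentence
there is no evidence to score. NPMI is scale-invariant — duplicating every
sentence changes no score — which is what makes it usable across corpora of
different sizes.

```{r npmi-examples}
npmi_value(10, 10, 10, 100)   # perfect co-occurrence
npmi_value(1, 10, 10, 100)    # exact independence
npmi_value(5, 50, 20, 1000)   # ln(5)/ln(200)
```

Within each gene, phenotypes are ranked by NPMI (ties: higher `n_GD`, then
class id — arbitrary but deterministic) and cut at rank `k`
(`rank_associations()`). The default `k = 25` keeps a compact profile with
less room for false positives while staying close to the similarity
optimum observed in rank-threshold sweeps; `sweep_rank_threshold()`
recomputes the whole curve for any data set, and the choice of `k` should
in general reflect how many true phenotypes per gene one expects (see the
benchmark section below).

## Semantic similarity and prioritization

Phenotype profiles (gene → classes, disease → classes) are compared with
Resnik similarity under best-match-average aggregation. Information content
(`information_content()`) is computed from an annotation corpus of
profiles: each entity's class set is closed under ancestors, `p(c)` is the
fraction of entities annotated to `c` post-closure, and
`IC(c) = -log p(c)` (natural log throughout; only ratios and maxima matter,
but fixing the base makes test vectors bit-exact). The closure makes `p`
monotone over the hierarchy, so IC never decreases toward the leaves and a
root that subsumes everything has IC 0. Which entity set defines `p` is a
genuine free choice; the package convention is the *target* side of a
ranking task (gene profiles when ranking genes), the standard Resnik
practice, and it is fully configurable by passing any profile table.

`resnik()` is the IC of the most informative common ancestor; two classes
sharing only a universal root score 0. `sim_bma()` aggregates a pair of
profiles of sizes $m$ and $n$ symmetrically:

$$ sim_{BMA}(g_1, g_2) = \frac{\sum_{i=1}^{m} \max_j sim(c_{1i}, c_{2j})
   + \sum_{j=1}^{n} \max_i sim(c_{1i}, c_{2j})}{m + n}. $$

An empty profile scores 0 with a warning rather than erroring, so partially
annotated sets do not abort a ranking. `rank_candidates()` sorts targets by
BMA score with a lexicographic tie-break, and `roc_auc()` evaluates
rankings with the rank-sum (Mann–Whitney) AUC, ties counting 0.5. Two
pooling protocols exist because neither is canonical: the default pools all
queries' (score, label) pairs into one micro AUC; `mode = "macro"`
averages per-query AUCs. Micro pooling assumes BMA scores are comparable
across queries, which holds when all queries share one IC table; macro is
insensitive to per-query score scale. Both are reported rather than one
being declared "the" protocol.

## What the synthetic generator emulates — and what it does not

`synth_generate()` produces a complete, self-contained study from a seeded
configuration: a random rooted `is_a` DAG with unique synthetic labels and
synonyms, a gene table, a sentence corpus, and reference annotation tables.
Each sentence independently emits a co-mention clause for every planted
(gene, class) pair with probability `strength`, so per-pair co-mention
counts are exactly binomial and multi-clause sentences occur naturally;
with probability `background_rate` a sentence additionally co-mentions one
uniformly random pair. Sentences without a co-mention may mention a lone
gene or phenotype (keeping the marginals realistic) or only filler text.
Reference tables copy the planted pairs but swap a class for a random
non-root ancestor or descendant with probability `hierarchy_noise`
(default 0.3), emulating the observation that curated annotations tend to
be related to, but more or less specific than, what the literature states.

The generator exercises the full pipeline honestly — real OBO parsing,
real sentence splitting, real dictionary matching with synonyms and
propagation — but its language is template-based. It does **not** model
ambiguous abbreviations, negated findings, nomenclature drift, cross-genre
writing, or the heavy-tailed gene mention distribution of real literature.
Passing the benchmarks therefore demonstrates that the statistical
machinery is correct and that the pipeline recovers planted signal under
realistic noise rates; it does not certify tagging precision on real
biomedical text.

## Benchmark problem sizes and their rationale

The packaged benchmarks (test suite and `scripts/acceptance.R`) use two
scenarios:

* **Planted recovery**: 20 planted pairs at per-sentence strength 0.3 over
  a 1% background in a 20 000-sentence corpus, 50 classes, 50 genes. Each
  planted pair expects ~6 000 co-mentions, far above background, and must
  land in its gene's top-25 list ≥90% of the time.
* **Candidate-gene prioritization**: 50 genes, each planted with 8 classes
  of a 120-class ontology at strength 0.005 over 40 000 sentences, one
  disease per gene annotated with hierarchy-noised copies of the causal
  gene's classes. Genes are ranked per disease by BMA similarity against
  their text-mined top-25 profiles.

The 8-classes-per-gene design is deliberate: a fixed rank threshold only
yields clean profiles when genes genuinely have several true phenotypes
(as genes in curated databases do — typically dozens of annotations). With
only 2–3 true classes per gene, a top-25 profile is mostly weak background
pairs and similarity-based recovery degrades — exactly the behaviour the
rank-threshold sweep makes visible, where sparse-profile data peak at
small `k`. Oracle-equivalence checks (brute-force recounting, ancestor-set
intersection, exhaustive AUC concordance) run on corpora of ≤500 sentences
and ontologies of ≤200 classes, where quadratic oracles are exact and
fast.

## Known limitations

* Dictionary NER misses entities absent from the lexicons and paraphrased
  phenotype descriptions; there is no machine-learned recognizer.
* No negation handling, no coreference, no document zoning; the sentence
  is the only context unit.
* Association direction (protective vs causative) is invisible to
  co-occurrence statistics.
* Gene mentions are not disambiguated between gene and protein or between
  species beyond explicit ortholog merging.
* Only Resnik/BMA similarity is implemented; other measures (Lin,
  Jiang–Conrath, simGIC) are out of scope.
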