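---
title: "Scoring and ranking text-mined target-disease associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and ranking text-mined target-disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biblioRank)
```

## The problem

Named-entity recognition pipelines tag gene/protein targets and disease
terms in millions of PubMed articles. For a researcher trying to decide
which *understudied* target deserves attention for a given disease, the
raw co-occurrence counts are nearly useless: heavily studied genes
co-occur with everything, and a mention in a review tagging fifty genes
is much weaker evidence than a dedicated paper. biblioRank turns a
tagged-mention table into ranked target-disease association tables using
two fractional-counting bibliometric scores, with special attention to
Tdark targets — proteins with approved-drug, chemical-tool or biology
knowledge still missing.

## The scores

Let $T_k$ and $D_k$ be the numbers of *distinct* targets and diseases
tagged in publication $k$. For target $i$ and disease $j$:

$$N_i = \frac{1}{\sum_k 1/T_k}, \qquad
  I_{ij} = \sum_k \frac{1}{T_k \, D_k},$$

where the novelty sum runs over all publications mentioning $i$ and the
importance sum over the publications supporting the pair $(i,j)$. High
novelty means little has been published about the target (a target with
one dedicated paper has $N_i = 1$); high importance means much has been
published tying the pair together, with each publication contributing at
most $1$ and dedicated single-target single-disease papers contributing
exactly $1$.

Two modelling choices deserve explicit statement:

* **The novelty sum has no disease condition.** A publication tagging a
  target but no disease still counts toward $N_i$ — the equation is
  about how much is written about the target, not about its
  associations. A consequence is the *conditional* conservation law
  used throughout the test suite: if every publication mentioning $i$
  tags at least one disease, then $\sum_j I_{ij} = 1/N_i$ over direct
  pairs (each publication distributes its $1/T_k$ mass across its $D_k$
  diseases). The law fails, by construction, for targets with
  disease-free publications, and the tests check both directions.
* **The unit $k$ is a publication**, however much of its text was mined
  (title, abstract or full text). Nothing in the scores changes with
  the extent of the mined text.

Disease novelty — needed to place diseases on a novelty axis when
browsing by target — is the symmetric analogue $N_j = 1/\sum_k 1/D_k$
over publications mentioning $j$. The source material defines novelty
only for targets, so the symmetric form is this package's choice, and it
is documented as such.

## Ontology propagation

Disease vocabularies are hierarchical: a paper about juvenile-onset
Parkinson disease is evidence for Parkinson disease as a whole.
biblioRank propagates support through the `is_a` DAG of the Disease
Ontology at the **publication-set level**: publication $p$ mentioning
disease $d$ supports $(t, a)$ for every target $t$ it mentions and every
$a \in \{d\} \cup \mathrm{ancestors}(d)$, and supports are *sets* of
publications. The alternative — summing child scores into parents — is
wrong whenever one abstract mentions two siblings: it would count the
same publication twice at the shared parent. With set-union propagation
the golden corpus below gives $I_{A,Z} = 1.25$, not $1.5$, because P2
mentions both children of $Z$ once.

$D_k$ is always the count of *directly* mentioned diseases; propagation
changes which pairs a publication supports, never its denominators.
For an ancestor term that is never mentioned directly, disease novelty
is computed over its propagated publication set (publications mentioning
the term or any descendant, each once); for directly mentioned and leaf
terms this reduces to the plain definition. Only `is_a` edges are
traversed; `alt_id` aliases resolve to their primary term; an obsolete
term with `replaced_by` is redirected once, and one without a valid
replacement stays resolvable as a hierarchy-less leaf. Disease ids
absent from the ontology altogether degrade gracefully to leaves with a
logged count, so a stale vocabulary never aborts a run.

## Non-dominated ranking

Associations are ordered by non-dominated-solution (NDS) rank over the
two maximized objectives (novelty, importance): rank 1 is the Pareto
front — points for which no point is superior in both coordinates —
rank 2 the front after removing rank 1, and so on. This deliberately
avoids collapsing the two scores into one number: the interesting
targets live at *both* ends of the front (well-studied important ones
and novel understudied ones).

* **Dominance convention.** The one-sentence verbal definition
  ("superior in all variables") reads as strict dominance, but strict
  dominance promotes a point that merely *ties* one coordinate of a
  better point onto the same front — a visible artifact at the exact
  score ties that small publication counts produce. The default is
  therefore weak dominance ($\ge$ in both, $>$ in at least one); the
  two conventions differ only at exact ties and `mode = "strict"`
  switches every ranking entry point.
* **Within-front order** is not defined by the front structure; the
  package uses importance descending, then novelty descending, then
  target id and disease id, making the output a total order and every
  export byte-reproducible.
* **Query domain.** Ranks are computed per browse query — over the
  targets of one disease, or the diseases of one target — matching how
  the tables are read. The batch `ranked.tsv` ranks targets within each
  disease group. The default display cut is $k = 300$ rows; with fewer
  than $k$ rows all are returned.
* **Algorithm.** Front assignment is the 2-D special case of
  non-dominated sorting: sort by novelty descending and binary-search
  each point against the per-front maxima of importance (a
  patience-sorting sweep), $O(n \log n)$; duplicates are collapsed
  first and share ranks, and strict mode processes equal-novelty
  batches together so ties never dominate each other. The test suite
  holds it against an independent $O(n^2)$ brute-force peeling oracle
  on a thousand point sets, including heavily tied grids.

## Numerical determinism

All scores are plain double-precision sums, but summation order is
pinned (publication id order within each group) so that rebuilding the
same corpus from shuffled input rows gives bit-identical scores, and two
runs of the batch pipeline give byte-identical files. Exported tables
print doubles with `%.17g` (full round-trip precision); JSON is written
with unrounded digits and a fixed key order. Checks against the naive
reference scorer use an absolute tolerance of 1e-12; the hand-derived
golden values are asserted at 1e-9.

Degenerate inputs are handled by contract rather than silently: a target
with no publications has *undefined* novelty (an error, never 0 or
infinity); an association with empty support does not exist (an error);
publications tagging entities of only one kind are kept (they matter for
novelty); fully empty publications are dropped with a logged count.

## The synthetic generator and the golden corpus

`makeGoldenFixture()` writes "corpus G", a four-publication corpus small
enough to score by hand (P1: {A} × {X}; P2: {A,B} × {X,Y}; P3: {B,C} ×
{Y}; P4: {C} × ∅; Z the ontology parent of X and Y; one deliberate
duplicate mention row). Every claimed score in this vignette and the
README is recomputed from it by the tests.

`simulateCorpus()` emulates a tagged literature at configurable scale:
per-publication target and disease counts are truncated Poisson draws
(zero disease counts arise naturally, as in real corpora — that is the
negative control for the conservation law), target selection is
Zipf-weighted (default exponent 1) so a few targets dominate the
literature while most are rarely mentioned — the skew that makes Tdark
targets invisible to raw counts — and the ontology is a random `is_a`
tree of bounded depth (default 3). Defaults (25 targets, 15 diseases,
200 publications, ~2 targets and ~1.5 diseases per publication) are
kept small because the corpus exists to exercise scoring paths, not to
mimic PubMed's scale; all randomness flows from one mandatory seed, and
identical configurations yield byte-identical files.

Each simulated corpus ships with ground truth computed by
`naiveAssociationScores()`, a loop-based scorer that shares no code with
the pipeline. What the generator does *not* model — citation networks,
MeSH structure, tagger errors, paper-mill contamination, realistic
ontology shapes — bounds what passing tests show: they validate the
arithmetic and the propagation semantics, not robustness to noisy NER
on real text.

## Validation sizes

The shipped test suite and `scripts/acceptance.R` validate on: the
golden corpus (exact hand values); batteries of 40-100 seeded corpora of
up to 500 publications against the naive scorer (max deviation observed
at machine precision, asserted at 1e-12) and for the conservation law
(1e-9); and 200-1000 random point sets of up to 2000 points against
brute-force front peeling, mixing continuous coordinates with small
discrete grids to stress ties and duplicates. These sizes keep a full
run in the low tens of seconds while covering every code path; the
algorithms themselves scale far beyond them.

## Known limitations

* Mentions are consumed as given: no confidence/z-score filtering of
  the upstream tagger output is applied or modelled. If the tagging
  pipeline scores its associations, filtering belongs upstream of this
  package.
* Disease novelty for ancestor terms is a package definition (see
  above), not a published formula.
* Only `is_a` edges propagate; `part_of` and other relationship types
  are ignored.
* The per-query ranking domain means a target's rank for one disease
  says nothing about its rank for another; there is no global rank.
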