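# biblioRank

Literature-based prioritization of protein targets and their disease
associations. Given a table of text-mined publication mentions (tagged
gene/protein targets and Disease Ontology terms, as produced by
named-entity-recognition pipelines over PubMed), biblioRank computes two
fractional-counting bibliometric scores, propagates evidence through the
Disease Ontology hierarchy, and ranks associations on the Pareto fronts
of the two scores. It is aimed at drug-discovery researchers hunting for
understudied (Tdark) targets: the interesting candidates are the ones
that are simultaneously *novel* (little published about the target) and
*important* (much published tying it to the disease).

## The scores

With `T_k` and `D_k` the numbers of distinct targets and diseases tagged
in publication `k`:

- **Novelty** of target *i*: `N_i = 1 / Σ_k 1/T_k`, summed over all
  publications mentioning *i*. A single dedicated paper gives `N_i = 1`;
  every additional paper lowers it.
- **Importance** of pair *(i, j)*: `I_ij = Σ_k 1/(T_k · D_k)`, summed
  over publications supporting the pair. Each publication contributes at
  most 1, and less the more entities it tags.

Evidence is propagated up the Disease Ontology `is_a` DAG at the
publication-set level (a paper mentioning two subtypes of a disease
counts once toward the parent), and each per-query table — targets of a
disease, or diseases of a target — is ordered by non-dominated-solution
(NDS) rank: rank 1 is the Pareto front over (novelty, importance), rank
2 the front after removing rank 1, and so on, with the top 300 rows
shown by default. See `vignettes/bibliorank-methods.Rmd` for the full
model description and design rationale.

## Worked example

The package ships a generator for a four-publication corpus ("corpus G")
small enough to score by hand: P1 tags target A with disease X; P2 tags
A, B with X, Y; P3 tags B, C with Y; P4 tags C with no disease; the
ontology makes Z the parent of X and Y.

```r
library(biblioRank)

paths  <- makeGoldenFixture(tempfile())
corpus <- buildCorpus(readMentions(paths[["mentions"]]))
onto   <- readOntology(paths[["obo"]])

targetNovelty(corpus)
#>         A         B         C
#> 0.6666667 1.0000000 0.6666667

assoc <- scoreAssociations(corpus, onto, readTargets(paths[["targets"]]))
associations(assoc)[, c("target_id", "tdl", "disease_id", "importance",
                        "target_novelty", "n_pubs")]
#>   target_id   tdl   disease_id importance target_novelty n_pubs
#> 1         A Tclin DOID:0000100       1.25      0.6666667      2
#> 2         A Tclin DOID:0000101       1.25      0.6666667      2
#> 3         A Tclin DOID:0000102       0.25      0.6666667      1
#> 4         B  Tbio DOID:0000100       0.75      1.0000000      2
#> 5         B  Tbio DOID:0000101       0.25      1.0000000      1
#> 6         B  Tbio DOID:0000102       0.75      1.0000000      2
#> 7         C Tdark DOID:0000100       0.50      0.6666667      1
#> 8         C Tdark DOID:0000102       0.50      0.6666667      1
```

Reading the numbers: A's novelty is `1/(1/1 + 1/2) = 2/3` (one dedicated
paper, one shared two-target paper); the A-X importance is
`1/(1·1) + 1/(2·2) = 1.25`. The parent term Z (DOID:0000100) picks up
propagated associations from its children — `I_AZ = 1.25`, with P2
counted once even though it mentions both children — which is why the
table has 8 rows instead of the 5 direct co-mention pairs. Target C is a
Tdark target whose only disease evidence arrives through P3.

Ranking the targets of disease X:

```r
queryAssociations(assoc, disease = "DOID:0000101")[,
  c("target_id", "importance", "target_novelty", "nds_rank", "within_rank_order")]
#>   target_id importance target_novelty nds_rank within_rank_order
#> 1         A       1.25      0.6666667        1                 0
#> 2         B       0.25      1.0000000        1                 1
```

A beats B on importance, B beats A on novelty, so both sit on the Pareto
front (rank 1); within the front, importance breaks the tie.

The batch pipeline (`runCompute()`, `runQuery()`, `exportJSON()`) writes
`associations.tsv`, `ranked.tsv`/`ranked.csv`, per-query tables with
log-scale plot coordinates and newest-first article listings, JSON
documents, and a checksummed run manifest. A thin command-line wrapper
is installed at `system.file("cli", "bibliorank.R", package = "biblioRank")`
with subcommands `compute`, `query`, `export-json`, `simulate` and
`fixture`.

Synthetic corpora of any size, with independently computed ground-truth
scores, come from `simulateCorpus(simulationConfig(seed = ...))`.

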