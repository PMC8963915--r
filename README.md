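# tissuehop

Explainable gene–disease link prediction for indication expansion
(target repositioning) on a dated, publication-weighted knowledge graph of
genes, diseases and tissues.

Drug-discovery teams asking *"which other diseases could this target
matter for?"* need predictions that come with evidence, not just scores.
`tissuehop` builds a typed, directed graph whose literature-derived edges
(gene–gene interactions, gene–disease associations) carry the year of
first/last report and the number of supporting publications, and whose
gene–tissue edges record RNA- and protein-level expression. On this graph
it provides:

* **Tissue-constrained hop inference** — a gene X is linked to disease D
  via one (X→Y, Y→D) or two (X→Y→Z, Z→D) intermediary genes, requiring
  all genes on the path to share at least one expression tissue. A path
  scores the sum of its edges' publication counts; a pair scores its best
  path (`max`, or optionally `sum`). Every prediction is explainable as a
  ranked list of concrete paths with their tissues and literature support.
* **Prospective time-split validation** — train on edges first reported
  up to a cutoff year, evaluate against associations reported after it
  (restricted to pairs within two hops of the training graph), with
  precision/recall/F1, precision@k, ROC/PR curves under the
  unpredicted-pairs-score-zero convention, and per-disease breakdowns.
* **A degree-preserving null model** — gene identities are permuted over
  gene node positions, keeping the topology fixed while scrambling the
  biology; observed metrics are tested against the replicate distribution
  with a one-sided z-test (log10 p reported alongside, since the raw
  value often underflows).
* **Knowledge-graph embeddings + classifier** — TransE / TransH / TransD
  (margin-ranking losses with typed negative sampling), DistMult, and an
  experimental random-walk skip-gram model; cosine/Euclidean gene–disease
  features feed a random-forest link classifier.
* **Graph characterization** — per-type degree tables, directed edge
  density E/(N·(N−1)), PageRank by damped power iteration, discrete
  power-law fits (plfit), largest weakly connected components and their
  temporal evolution.
* **A seeded synthetic benchmark** — a scale-free gene–gene graph with
  tissue assignments, dated disease annotations and *planted* post-cutoff
  gene–disease links reachable via tissue-consistent paths, so the whole
  pipeline can be exercised and scored as parameter recovery without any
  licensed inputs.

## Worked example

```r
library(tissuehop)

cfg  <- generator_config(seed = 7L)          # 200 genes, 20 diseases, 6+6 tissues
gen  <- generate_kg(cfg)
gen$kg
#> <knowledge_graph> 232 entities, 2327 edges
#>   entities: Gene=200 Disease=20 RNATissue=6 ProteinTissue=6
#>   edges:    Interaction=397 hasDisease=718 hasRNAExpression=592 hasProteinExpression=620

sp   <- time_split(gen$kg, 2010L)            # train graph + post-2010 associations
gold <- build_gold_standard(sp$train, sp$post_edges)
gold
#> <gold_standard> 470 gene-disease pairs (max 2 hops)

pred <- predict_links(sp$train, "onehop", "rna")
m    <- overall_metrics(pred, gold)
sprintf("precision %.3f recall %.3f F1 %.3f", m$precision, m$recall, m$f1)
#> "precision 0.504 recall 0.370 F1 0.427"

bl <- random_baseline(sp$train, gold, "onehop", "rna", n_reps = 20L, base_seed = 1L)
z  <- z_test_onesided(m$precision, bl$precision)
sprintf("null %.3f +/- %.3f  z = %.1f  p = %.2e", bl$precision$mean,
        bl$precision$sd, z$z, z$p)
#> "null 0.157 +/- 0.020  z = 17.4  p = 3.87e-68"
```

Half of the predicted links are planted future associations, against ~16%
under the shuffled-label null — the tissue-coherent path structure, not
the degree sequence, carries the signal. Any prediction can be unfolded
into its evidence:

```r
explain_pair(sp$train, "ENSG00000036", "D000003", "rna")$paths[1, ]
#>  nodes: ENSG00000036|ENSG00000019|D000003   path_score: 23
#>  shared_tissues: cerebral cortex [rna];lung [rna];skin [rna]
```

i.e. this candidate is backed by 23 publications along one interaction
step, with all genes co-expressed in three tissues.

A shell front-end over the same functions lives at `inst/cli/tissuehop.R`
(`simulate`, `build`, `characterize`, `split`, `predict`, `baseline`,
`embed`, `evaluate`, `explain`, `all`), driven by a flat key=value config
and a global seed; every run writes TSV artifacts plus a JSON manifest.

## Method vignette

`vignettes/tissuehop-methods.Rmd` documents the model conventions (edge
direction, time filtering, duplicate collapse, tie-breaking), the
embedding training choices, what the synthetic generator does and does not
emulate, and the known limitations of benchmark-scale embedding results.
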