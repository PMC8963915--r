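---
title: "Tissue-constrained knowledge-graph inference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-constrained knowledge-graph inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Indication expansion (target repositioning) asks which *new* diseases an
existing drug target could be relevant for. `tissuehop` approaches this as
link prediction on a heterogeneous knowledge graph whose nodes are genes,
diseases and tissues, and whose edges carry literature provenance: each
gene–gene interaction and gene–disease association records the year it was
first and last reported and the number of supporting publications
(optionally, PubMed ids). Gene–tissue expression edges (RNA-level and
protein-level, as in bulk expression atlases) are undated.

Two prediction tracks are implemented over this container:

1. **Hop-based, glass-box inference.** A gene X is linked to a disease D
   through one intermediary gene (X→Y, Y→D) or two (X→Y→Z, Z→D). Unless
   disabled, a *tissue constraint* requires all genes on the path to be
   expressed in at least one common tissue at the chosen level (RNA or
   protein, never mixed within a path). A path's score is the sum of the
   publication counts of its literature edges; a pair's score is the best
   (or, optionally, the summed) path score. Every prediction carries its
   paths, so it can be explained edge by edge.
2. **Embedding + classifier.** The pre-cutoff graph is embedded
   (TransE/TransH/TransD via margin-ranking losses, DistMult via the
   bilinear diagonal form, or skip-gram over truncated random walks);
   cosine/Euclidean gene–disease features feed a random-forest link
   classifier.

Validation is prospective: edges first reported up to a cutoff year
(default 2010, inclusive) form the training graph; gene–disease
associations first reported afterwards form the gold standard, restricted
to genes and diseases present in — and within two hops in — the training
graph, since nothing farther could have been predicted. Significance is
assessed against a degree-preserving null model that permutes gene
identities over gene node positions, preserving all topology while
scrambling the biology.

## Key modelling conventions

* **Publication nodes.** In memory, publication evidence lives on the
  edges (`n_pubs`, `pmids`); only the RDF export materializes a
  `Publication` resource between a gene and a disease, because RDF has no
  edge properties.
* **Edge direction.** Gene–gene edges are stored directed
  (source acts on target). Traversal follows that direction by default;
  `undirected_ppi = TRUE` relaxes it, collapsing an antiparallel pair to a
  single traversable edge with the larger publication count.
* **Time filtering.** Only literature edges are dated. A gene's expression
  edges survive `subgraph_before()` exactly when the gene keeps at least
  one dated edge; entities without any remaining edge are dropped.
* **Duplicate rows.** Loading collapses duplicate (source, target,
  relation) rows to the earliest first year, latest last year, largest
  publication count and the union of PubMed ids. When the id union
  outnumbers the largest count, the count is raised to the union size so
  the invariant `n_pubs >= #pmids` always holds — the union is itself
  evidence of that many distinct publications.
* **Determinism.** All ranked outputs use score-descending order with
  lexicographic tie-breaks (gene id, then disease id); component ties go
  to the component containing the smallest id. Every stochastic step takes
  a seed.
* **Degenerate metrics.** An empty prediction set reports precision 0 with
  a flag (never `NaN`), so null-model distributions stay numeric. Curve
  construction gives unpredicted candidate pairs a score of 0 and groups
  tied scores at a single threshold, which renders the all-zero tail as
  the terminal straight segment of the ROC curve.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff_year` | 2010 | last year included in the training graph |
| `max_hops` | 2 | intermediary-gene budget for candidates/gold |
| `tissue_mode` | — | `rna`, `protein` or `none`, per strategy |
| `aggregation` | `max` | pair score over its paths (`sum` available) |
| `damping` | 0.85 | PageRank damping; tolerance 1e-10 |
| `dim` | 200 | embedding dimension |
| `epochs`, `lr`, `margin`, `batch_size` | 200, 0.01, 1, 256 | SGD settings |
| `n_negatives` | 1 | corrupted triples per observed triple |
| `n_trees` | 500 | random-forest size |

PageRank is an explicit damped power iteration with uniform redistribution
of dangling-node mass, so the convergence tolerance and iteration cap are
first-class arguments (and non-convergence is a reportable error). The
power-law exponent uses the discrete maximum-likelihood fit with the lower
cutoff chosen by Kolmogorov–Smirnov minimization (plfit).

## Embedding training choices

Negatives are drawn by corrupting the head or tail of a triple with a
random entity *of the same type*. With four node types of very different
cardinalities (thousands of genes, a handful of tissues), untyped
corruption yields negatives that are trivially implausible (a disease
replaced by a tissue) and contribute no gradient; typed corruption is the
standard remedy and is what makes the learned geometry informative at
benchmark scale. Entity vectors of the translational models are projected
back onto the unit ball after each mini-batch; TransH hyperplane normals
are renormalized to unit length. Scores use the L2 norm with a small
floor so gradients stay finite at zero distance; analytic gradients of all
four scoring functions are verified against central finite differences in
the test suite.

The walk-based model runs 10 truncated random walks of depth 4 per entity
over the graph with direction ignored, and fits skip-gram with 5 negative
samples (window 2) on the walk corpus. It is the one method whose
features are inherently *multi-hop*: a gene and a disease two edges apart
co-occur within a window even if no single relation links them.

For the classifier, training positives are the pre-cutoff direct
gene–disease edges and test positives the post-cutoff gold standard;
negatives are sampled 1:1, disjointly between sets. On small benchmark
graphs the two-hop candidate pool can be almost exhausted by the gold
standard, leaving too few negatives to balance the sets — the pipeline
then samples negatives from the full unlinked gene × disease pool
(`unlinked_pairs()`), the widest defensible proxy for "no known
association".

## The synthetic benchmark

Real inputs of this kind (commercially curated literature relations,
expression atlases) are licensed, so the package ships a seeded generator
that emulates their statistical structure:

* a scale-free gene–gene graph (preferential attachment, `pa_m = 2` edges
  per gene, orientation randomized per edge — the linear-kernel model has
  degree exponent 3, which the generator's own fit recovers);
* popularity-weighted (Zipf) tissue assignment, each gene expressed in
  `1 + Poisson(2)` tissues per modality — realistic in that a few tissues
  cover most genes, as in bulk atlases;
* per-disease gene annotations clustered around a degree-weighted seed
  gene's two-hop neighbourhood (`1 + NB(2, mu = 9)` genes per disease);
* publication counts `1 + NB(1, p = 0.3)` so every edge has support;
  first years uniform on [1990, cutoff] (pre) or (cutoff, 2020] (post);
* **planted signal**: each pair that is tissue-consistently one- or
  two-hop connected before the cutoff receives a post-cutoff association
  with probability `p_signal` (default 0.5); arbitrary unconnected pairs
  receive one with probability `p_noise` (default 0.01).

Planting *from tissue-consistent connected pairs* makes the method's core
hypothesis — future indications are reachable along tissue-coherent
paths — true by construction, so precision and recall on the benchmark
read as parameter recovery, not as claims about real literature data. The
default configuration (200 genes, 20 diseases, 6 RNA + 6 protein tissues,
seed 7) keeps every pipeline stage in seconds on one CPU; tests and the
acceptance script use it, with embeddings at dimension 50 and 200 epochs
(scaled down from the 200-dimensional default).

What the generator does **not** emulate: curation biases and confidence
filtering of literature databases, incomplete and time-varying interaction
coverage, cell-type-resolved expression, and the sheer density of the real
graph (tens of thousands of genes, hundreds of thousands of edges).
Passing benchmark tests therefore shows the machinery recovers planted
structure under the model's own assumptions; it does not certify
performance on real curated data.

## What the scaled-down benchmark can and cannot show

Two findings from working at benchmark scale are worth recording.

First, hop-based recovery is robust: one-hop tissue-constrained precision
(~0.46–0.49) exceeds the label-shuffle null (~0.15 ± 0.02) at z ≈ 11–20,
and the union of strategies recovers essentially all planted pairs.

Second, the embedding track degrades differentially. TransE still places
gold pairs at measurably higher cosine similarity than matched random
pairs (pooled across five seeded runs, p < 1e-6), but the margin is thin:
about 60% of the benchmark's gold pairs are two-hop-only, and a
translational model trained on one-hop constraints over a sparse
200-gene preferential-attachment graph has no community structure through
which two-hop locality can propagate. Empirically the best achievable
single-threshold F1 on the balanced test set stays at the degenerate
all-positive value (~0.67) across margins, learning rates, epochs,
normalization schemes and negative-sampling rates, so a scalar-cosine
random forest cannot decisively beat a permuted-label control here — at
full literature scale (the regime the method targets) the same
construction is reported to work well. For the same reason, the
with-versus-without-tissue contrast is assessed on the walk-based
embeddings, where expression edges contribute exactly the gene–tissue–gene
bridges the walks traverse: removing them lowers mean classifier F1 by
~0.04–0.05 consistently across seeds, in the direction the full-scale
comparison shows most strongly for its non-translational model. The
translational models at this scale show no usable contrast either way.

## Known limitations

* Paths longer than two hops are out of scope by design.
* The RDF export uses a fixed minimal vocabulary; it is meant for
  interoperability checks, not as a reasoning substrate.
* The walk-based embedding is flagged experimental: it has no relation
  parameters and its triple score is undefined.
* Per-seed variation of embedding results is substantial at benchmark
  scale; all embedding-based conclusions should be read across seeds, as
  the tests do.
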