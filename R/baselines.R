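#' Degree-preserving shuffle of gene identities
#'
#' Applies a uniformly random permutation of the gene ids over the gene
#' node positions, leaving disease and tissue ids fixed and the edge
#' structure untouched. The degree sequence, density and per-type edge
#' counts are therefore identical to the input graph, while the biology
#' encoded by the gene-gene, gene-disease and gene-tissue components is
#' scrambled — the null model behind the random baselines.
#'
#' @param kg a `knowledge_graph` with at least one gene.
#' @param seed integer seed for the permutation.
#' @return a `knowledge_graph` with permuted gene identities.
#' @export
shuffle_gene_labels <- function(kg, seed) {
  genes <- entity_ids(kg, "Gene")
  if (length(genes) == 0L)
    kg_stop("cannot shuffle a graph without genes", "tissuehop_domain_error")
  set.seed(seed)
  perm <- sample(genes)
  map <- stats::setNames(perm, genes)
  relabel <- function(x) {
    hit <- x %in% genes
    x[hit] <- map[x[hit]]
    x
  }
  ents <- copy(kg$entities)
  ents[, id := relabel(id)]
  eds <- copy(kg$edges)
  eds[, `:=`(source = relabel(source), target = relabel(target))]
  knowledge_graph(ents, eds, validate = FALSE)
}

#' Distribution of a metric over shuffled-graph replicates
#'
#' For each replicate, the gene labels are shuffled (seed
#' `base_seed + replicate index`), the hop-based prediction is re-run on the
#' shuffled graph and scored against the *same* gold standard. Precision and
#' recall distributions over replicates are returned.
#'
#' @param kg the (true) training `knowledge_graph`.
#' @param gold a `gold_standard` or data.table of `gene`, `disease` pairs.
#' @param strategy,tissue_mode,undirected_ppi forwarded to [predict_links()].
#' @param n_reps number of shuffled replicates (>= 2).
#' @param base_seed base seed; replicate i uses `base_seed + i`.
#' @return list of two `baseline_distribution` objects (`precision`,
#'   `recall`), each with `values`, `mean`, `sd` (sample, n-1), `n_reps`
#'   and `seeds`.
#' @export
random_baseline <- function(kg, gold, strategy = "onehop", tissue_mode = "rna",
                            n_reps = 100L, base_seed = 1L,
                            undirected_ppi = FALSE) {
  if (n_reps < 2L)
    kg_stop("random_baseline requires n_reps >= 2", "tissuehop_usage_error")
  gold_pairs <- gold_pairs_of(gold)
  seeds <- base_seed + seq_len(n_reps)
  prec <- rec <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    kg_i <- shuffle_gene_labels(kg, seeds[i])
    pred <- tryCatch(
      predict_links(kg_i, strategy, tissue_mode, undirected_ppi = undirected_ppi),
      error = function(e)
        kg_stop(sprintf("replicate %d failed: %s", i, conditionMessage(e)),
                "tissuehop_error"))
    m <- overall_metrics(pred$pairs, gold_pairs)
    prec[i] <- m$precision
    rec[i] <- m$recall
  }
  list(precision = baseline_distribution("precision", prec, seeds),
       recall = baseline_distribution("recall", rec, seeds))
}

baseline_distribution <- function(metric, values, seeds) {
  structure(list(metric = metric, values = values,
                 mean = mean(values), sd = sd(values),
                 n_reps = length(values), seeds = seeds),
            class = "baseline_distribution")
}

#' @export
print.baseline_distribution <- function(x, ...) {
  cat(sprintf("<baseline_distribution> %s over %d replicates: %.4f +/- %.4f\n",
              x$metric, x$n_reps, x$mean, x$sd))
  invisible(x)
}

#' One-sided z-test of an observed metric against a null distribution
#'
#' `p = 1 - Phi((observed - mean) / sd)` with the standard normal CDF Phi.
#' Extreme p-values underflow double precision, so `log10_p` is computed on
#' the log scale and reported alongside the raw value (which may print as
#' 0.00E+00).
#'
#' @param observed the metric measured on the true graph.
#' @param dist a `baseline_distribution` (or any list with `mean` and `sd`),
#'   with `sd > 0`.
#' @return list with `z`, `p` and `log10_p`.
#' @export
z_test_onesided <- function(observed, dist) {
  if (is.na(dist$sd) || dist$sd <= 0)
    kg_stop("z-test requires a null distribution with positive sd",
            "tissuehop_domain_error")
  z <- (observed - dist$mean) / dist$sd
  list(z = z,
       p = pnorm(z, lower.tail = FALSE),
       log10_p = pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10))
}

#' Tabular baseline report for one strategy
#'
#' @param observed named list/vector with `precision` and `recall` measured
#'   on the true graph.
#' @param baseline result of [random_baseline()].
#' @param strategy label recorded in the output.
#' @return data.table with one row per metric: observed value, random mean
#'   and sd, z, p and log10(p).
#' @export
baseline_report <- function(observed, baseline, strategy = "onehop_rna") {
  rows <- lapply(c("precision", "recall"), function(m) {
    zt <- z_test_onesided(observed[[m]], baseline[[m]])
    data.table(strategy = strategy, metric = m,
               observed = observed[[m]],
               random_mean = baseline[[m]]$mean,
               random_sd = baseline[[m]]$sd,
               z = zt$z, p = zt$p, log10_p = zt$log10_p,
               n_reps = baseline[[m]]$n_reps)
  })
  rbindlist(rows)
}

gold_pairs_of <- function(gold) {
  if (inherits(gold, "gold_standard")) gold$pairs
  else unique(as.data.table(gold)[, .(gene, disease)])
}
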