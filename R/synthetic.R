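#' Configuration of the synthetic knowledge-graph generator
#'
#' Defines the statistical structure the benchmark graphs emulate: a
#' scale-free gene-gene interaction graph (preferential attachment with
#' `pa_m` edges per new gene, random edge orientation), popularity-weighted
#' gene-tissue expression assignments at the RNA and protein level,
#' pre-cutoff gene-disease annotations attached around disease seed-gene
#' neighbourhoods, shifted negative-binomial publication counts (every edge
#' has at least one supporting publication) and planted post-cutoff
#' gene-disease links: with probability `p_signal` a pair that is
#' tissue-consistently one/two-hop connected before the cutoff receives a
#' post-cutoff association (the recoverable signal), while with probability
#' `p_noise` an arbitrary unconnected pair does (background noise).
#'
#' @param n_genes,n_diseases,n_rna_tissues,n_protein_tissues entity counts.
#' @param pa_m preferential-attachment edges per new gene.
#' @param tissues_per_gene_lambda Poisson rate; each gene is expressed in
#'   `1 + Poisson(lambda)` tissues per modality (capped at the tissue count).
#' @param genes_per_disease_size,genes_per_disease_mu negative-binomial
#'   size/mean; each disease annotates `1 + NB` genes before the cutoff.
#' @param pub_size,pub_prob negative-binomial parameters of the
#'   publication-count distribution (`n_pubs = 1 + NB(size, prob)`).
#' @param y_min,y_max,cutoff_year year range and time-split cutoff
#'   (`y_min < cutoff_year < y_max`).
#' @param p_signal,p_noise planting probabilities in `[0, 1]`.
#' @param seed default RNG seed carried by the config.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 200L, n_diseases = 20L,
                             n_rna_tissues = 6L, n_protein_tissues = 6L,
                             pa_m = 2L, tissues_per_gene_lambda = 2,
                             genes_per_disease_size = 2,
                             genes_per_disease_mu = 9,
                             pub_size = 1, pub_prob = 0.3,
                             y_min = 1990L, y_max = 2020L,
                             cutoff_year = 2010L,
                             p_signal = 0.5, p_noise = 0.01,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_diseases = as.integer(n_diseases),
              n_rna_tissues = as.integer(n_rna_tissues),
              n_protein_tissues = as.integer(n_protein_tissues),
              pa_m = as.integer(pa_m),
              tissues_per_gene_lambda = tissues_per_gene_lambda,
              genes_per_disease_size = genes_per_disease_size,
              genes_per_disease_mu = genes_per_disease_mu,
              pub_size = pub_size, pub_prob = pub_prob,
              y_min = as.integer(y_min), y_max = as.integer(y_max),
              cutoff_year = as.integer(cutoff_year),
              p_signal = p_signal, p_noise = p_noise,
              seed = as.integer(seed))
  counts <- c(cfg$n_genes, cfg$n_diseases, cfg$n_rna_tissues,
              cfg$n_protein_tissues, cfg$pa_m)
  if (any(counts <= 0L))
    kg_stop("all entity counts and pa_m must be positive",
            "tissuehop_usage_error")
  if (cfg$p_signal < 0 || cfg$p_signal > 1 || cfg$p_noise < 0 || cfg$p_noise > 1)
    kg_stop("p_signal and p_noise must lie in [0, 1]", "tissuehop_usage_error")
  if (!(cfg$y_min < cfg$cutoff_year && cfg$cutoff_year < cfg$y_max))
    kg_stop("y_min < cutoff_year < y_max is required", "tissuehop_usage_error")
  structure(cfg, class = "generator_config")
}

TISSUE_VOCAB <- c("cerebral cortex", "liver", "lung", "kidney",
                  "heart muscle", "skin", "colon", "spleen", "testis",
                  "pancreas", "skeletal muscle", "thyroid gland")

#' Generate a synthetic knowledge graph with planted future links
#'
#' Draws a graph under the model described in [generator_config()]. Planted
#' signal pairs are chosen among pairs that are already tissue-consistently
#' connected before the cutoff, so that hop-based recovery of the planted
#' links is meaningful parameter recovery. Output is deterministic in
#' `seed`.
#'
#' @param config a `generator_config`.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `kg` (a `knowledge_graph`) and `truth` (class
#'   `synthetic_truth`: data.tables `signal_pairs`, `noise_pairs`, and
#'   `generating_paths` — the best pre-cutoff tissue-consistent path for
#'   each signal pair).
#' @export
generate_kg <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  genes <- sprintf("ENSG%08d", seq_len(config$n_genes))
  diseases <- sprintf("D%06d", seq_len(config$n_diseases))
  tissue_names <- function(n, suffix) {
    base <- if (n <= length(TISSUE_VOCAB)) TISSUE_VOCAB[seq_len(n)]
    else c(TISSUE_VOCAB, sprintf("tissue %02d", seq_len(n - length(TISSUE_VOCAB))))
    paste0(base, " [", suffix, "]")
  }
  rna_tissues <- tissue_names(config$n_rna_tissues, "rna")
  prot_tissues <- tissue_names(config$n_protein_tissues, "protein")

  rpubs <- function(n) 1L + rnbinom(n, size = config$pub_size,
                                    prob = config$pub_prob)
  ryear_pre <- function(n) sample(config$y_min:config$cutoff_year, n, replace = TRUE)
  ryear_post <- function(n) sample((config$cutoff_year + 1L):config$y_max, n,
                                   replace = TRUE)
  rlast <- function(first) pmin(first + rnbinom(length(first), size = 1,
                                                prob = 0.25), config$y_max)

  # 1. scale-free gene-gene graph, random per-edge orientation
  g <- igraph::sample_pa(config$n_genes, power = 1, m = config$pa_m,
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  flip <- runif(nrow(el)) < 0.5
  gg <- data.table(source = genes[ifelse(flip, el[, 2L], el[, 1L])],
                   target = genes[ifelse(flip, el[, 1L], el[, 2L])])
  gg <- unique(gg)                       # PA multi-edges collapse
  gg <- gg[source != target]
  gg[, `:=`(rtype = "Interaction", first_year = ryear_pre(.N))]
  gg[, `:=`(last_year = rlast(first_year), n_pubs = rpubs(.N))]

  # 2. popularity-weighted tissue assignment (Zipf weights over tissues)
  assign_tissues <- function(tissues, rt) {
    w <- 1 / seq_along(tissues)
    k <- pmin(1L + rpois(config$n_genes, config$tissues_per_gene_lambda),
              length(tissues))
    rows <- lapply(seq_len(config$n_genes), function(i)
      data.table(source = genes[i],
                 target = sample(tissues, k[i], prob = w)))
    out <- rbindlist(rows)
    out[, `:=`(rtype = rt, first_year = NA_integer_, last_year = NA_integer_,
               n_pubs = NA_integer_)]
    out
  }
  rna <- assign_tissues(rna_tissues, "hasRNAExpression")
  prot <- assign_tissues(prot_tissues, "hasProteinExpression")

  # 3. pre-cutoff disease annotations around a seed gene's neighbourhood
  deg <- table(factor(c(gg$source, gg$target), levels = genes))
  nbr <- rbind(gg[, .(g = source, n = target)], gg[, .(g = target, n = source)])
  gd_rows <- lapply(seq_len(config$n_diseases), function(j) {
    n_g <- 1L + rnbinom(1L, size = config$genes_per_disease_size,
                        mu = config$genes_per_disease_mu)
    seed_gene <- sample(genes, 1L, prob = as.numeric(deg) + 1)
    hood1 <- nbr$n[nbr$g == seed_gene]
    hood2 <- nbr$n[nbr$g %in% hood1]
    hood <- unique(c(seed_gene, hood1, hood2))
    picked <- if (length(hood) >= n_g) sample(hood, n_g)
    else unique(c(hood, sample(setdiff(genes, hood),
                               min(n_g - length(hood),
                                   config$n_genes - length(hood)))))
    data.table(source = picked, target = diseases[j])
  })
  gd <- rbindlist(gd_rows)
  gd[, `:=`(rtype = "hasDisease", first_year = ryear_pre(.N))]
  gd[, `:=`(last_year = rlast(first_year), n_pubs = rpubs(.N))]

  ents <- data.table(
    id = c(genes, diseases, rna_tissues, prot_tissues),
    etype = rep(c("Gene", "Disease", "RNATissue", "ProteinTissue"),
                c(config$n_genes, config$n_diseases,
                  config$n_rna_tissues, config$n_protein_tissues)))
  pre_edges <- rbind(gg, gd, rna, prot, fill = TRUE)
  pre_edges[, pmids := rep(list(character()), .N)]
  kg_pre <- knowledge_graph(ents, pre_edges, validate = FALSE)

  # 4. signal pool: tissue-consistent one/two-hop connected pairs pre-cutoff
  pool_pred <- predict_links(kg_pre, "union")$pairs
  pool <- pool_pred[, .(gene, disease)]
  if (nrow(pool) == 0L && config$p_signal > 0)
    kg_stop("infeasible config: no tissue-consistent connected pairs to plant",
            "tissuehop_domain_error")
  planted <- pool[runif(.N) < config$p_signal]

  direct <- gd[, .(gene = source, disease = target)]
  all_pairs <- CJ(gene = genes, disease = diseases)
  noise_pool <- all_pairs[!direct, on = c("gene", "disease")]
  noise_pool <- noise_pool[!pool, on = c("gene", "disease")]
  noise <- noise_pool[runif(.N) < config$p_noise]

  post <- rbind(planted, noise)
  post_edges <- data.table(source = post$gene, target = post$disease,
                           rtype = "hasDisease",
                           first_year = ryear_post(nrow(post)))
  post_edges[, `:=`(last_year = rlast(first_year), n_pubs = rpubs(.N),
                    pmids = rep(list(character()), .N))]

  kg <- knowledge_graph(ents, rbind(pre_edges, post_edges), validate = TRUE)

  paths <- if (nrow(planted)) {
    pool_pred[planted, on = c("gene", "disease"),
         .(gene, disease, nodes = best_path, path_score = score,
           shared_tissues)]
  } else data.table(gene = character(), disease = character(),
                    nodes = character(), path_score = integer(),
                    shared_tissues = character())
  truth <- structure(list(signal_pairs = planted[order(gene, disease)],
                          noise_pairs = noise[order(gene, disease)],
                          generating_paths = paths),
                     class = "synthetic_truth")
  list(kg = kg, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d planted signal pairs, %d noise pairs\n",
              nrow(x$signal_pairs), nrow(x$noise_pairs)))
  invisible(x)
}

#' Write a ready-to-run synthetic benchmark directory
#'
#' Generates a graph, writes its edge tables in the dialect
#' [load_edge_tables()] consumes, performs the time split at the config's
#' cutoff, writes the implied gold standard as TSV and the planted ground
#' truth as JSON.
#'
#' @param config a `generator_config`.
#' @param dir output directory.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return list with `kg`, `truth`, `split`, `gold` and `files` (named
#'   vector of written paths), invisibly.
#' @export
benchmark_bundle <- function(config, dir, seed = config$seed) {
  gen <- generate_kg(config, seed = seed)
  files <- write_edge_tables(gen$kg, dir, prefix = "synthetic")
  split <- time_split(gen$kg, config$cutoff_year)
  gold <- build_gold_standard(split$train, split$post_edges, max_hops = 2L)
  gold_path <- file.path(dir, "gold_standard.tsv")
  fwrite(gold$pairs, gold_path, sep = "\t")
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = seed, cutoff_year = config$cutoff_year,
         signal_pairs = gen$truth$signal_pairs,
         noise_pairs = gen$truth$noise_pairs,
         generating_paths = gen$truth$generating_paths[, .(gene, disease, nodes,
                                                           path_score)]),
    truth_path, dataframe = "rows", auto_unbox = TRUE)
  files <- c(files, gold = gold_path, truth = truth_path)
  invisible(list(kg = gen$kg, truth = gen$truth, split = split, gold = gold,
                 files = files))
}
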