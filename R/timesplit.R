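#' Prospective time split of a knowledge graph
#'
#' Splits the dated edges at a cutoff year: everything first published in or
#' before the cutoff forms the training graph (via [subgraph_before()]),
#' while gene-disease edges first published after the cutoff become the
#' candidate test associations.
#'
#' @param kg a `knowledge_graph`.
#' @param cutoff_year integer cutoff (inclusive on the training side).
#' @return list with `train` (a `knowledge_graph`), `post_edges` (data.table
#'   of post-cutoff gene-disease edges: `gene`, `disease`, `first_year`,
#'   `last_year`, `n_pubs`) and `cutoff_year`.
#' @export
time_split <- function(kg, cutoff_year) {
  train <- subgraph_before(kg, cutoff_year)
  post <- kg$edges[rtype == "hasDisease" & first_year > cutoff_year,
                   .(gene = source, disease = target, first_year, last_year, n_pubs)]
  setorder(post, gene, disease)
  list(train = train, post_edges = post, cutoff_year = as.integer(cutoff_year))
}

#' Build the post-cutoff gold standard
#'
#' Keeps the post-cutoff gene-disease pairs whose gene and disease both
#' exist in the training graph and whose structural (tissue-unconstrained)
#' hop distance in the training graph is at most `max_hops` — the only pairs
#' the hop-based methods can possibly predict.
#'
#' @param train_graph the pre-cutoff `knowledge_graph`.
#' @param post_edges data.table with columns `gene`, `disease` (e.g. from
#'   [time_split()]).
#' @param max_hops 1 or 2 intermediary genes.
#' @param undirected_ppi traverse gene-gene edges ignoring direction.
#' @return object of class `gold_standard`: list with `pairs` (data.table
#'   `gene`, `disease`), `max_hops` and the entity sets used.
#' @export
build_gold_standard <- function(train_graph, post_edges, max_hops = 2L,
                                undirected_ppi = FALSE) {
  stopifnot(max_hops %in% c(1L, 2L))
  post <- unique(as.data.table(post_edges)[, .(gene, disease)])
  genes <- entity_ids(train_graph, "Gene")
  diseases <- entity_ids(train_graph, "Disease")
  post <- post[gene %in% genes & disease %in% diseases]
  cand <- enumerate_candidates(train_graph, max_hops = max_hops,
                               undirected_ppi = undirected_ppi)
  pairs <- post[cand$pairs, on = c("gene", "disease"), nomatch = NULL,
                .(gene, disease)]
  setorder(pairs, gene, disease)
  structure(list(pairs = pairs, max_hops = as.integer(max_hops)),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("<gold_standard> %d gene-disease pairs (max %d hops)\n",
              nrow(x$pairs), x$max_hops))
  invisible(x)
}

#' Enumerate the candidate gene-disease pair universe
#'
#' All (gene, disease) pairs of the training graph reachable through one or
#' two intermediary genes (no tissue constraint), excluding pairs already
#' directly linked. The unrestricted cross product `|genes| x |diseases|` is
#' recorded alongside.
#'
#' @param train_graph the pre-cutoff `knowledge_graph`.
#' @param max_hops 1 or 2.
#' @param undirected_ppi traverse gene-gene edges ignoring direction.
#' @return object of class `candidate_universe`: list with `pairs`
#'   (data.table `gene`, `disease`, `hops` = minimal hop count),
#'   `n_genes`, `n_diseases`, `n_unrestricted` and `max_hops`.
#' @export
enumerate_candidates <- function(train_graph, max_hops = 2L,
                                 undirected_ppi = FALSE) {
  stopifnot(max_hops %in% c(1L, 2L))
  gg <- interaction_edges(train_graph, undirected_ppi)
  gd <- train_graph$edges[rtype == "hasDisease", .(gene = source, disease = target)]
  n_genes <- length(entity_ids(train_graph, "Gene"))
  n_diseases <- length(entity_ids(train_graph, "Disease"))

  gg1 <- gg[, .(X = from, Y = to)]
  gda <- gd[, .(Yg = gene, D = disease)]
  one <- unique(gg1[gda, on = c(Y = "Yg"), nomatch = NULL,
                    allow.cartesian = TRUE, .(gene = X, disease = D)])
  pairs <- one[, .(gene, disease, hops = 1L)]
  if (max_hops == 2L) {
    gg2 <- gg[, .(Y2 = from, Z = to)]
    g2 <- gg1[gg2, on = c(Y = "Y2"), nomatch = NULL, allow.cartesian = TRUE,
              .(X, Z)][X != Z]
    two <- unique(g2[gda, on = c(Z = "Yg"), nomatch = NULL,
                     allow.cartesian = TRUE, .(gene = X, disease = D)])
    two <- two[!one, on = c("gene", "disease")]
    pairs <- rbind(pairs, two[, .(gene, disease, hops = 2L)])
  }
  pairs <- pairs[!gd, on = c("gene", "disease")]
  setorder(pairs, gene, disease)
  structure(list(pairs = pairs, n_genes = n_genes, n_diseases = n_diseases,
                 n_unrestricted = as.numeric(n_genes) * n_diseases,
                 max_hops = as.integer(max_hops)),
            class = "candidate_universe")
}

#' @export
print.candidate_universe <- function(x, ...) {
  cat(sprintf(paste0("<candidate_universe> %d pairs within %d hop(s) ",
                     "(%d genes x %d diseases = %.0f unrestricted)\n"),
              nrow(x$pairs), x$max_hops, x$n_genes, x$n_diseases,
              x$n_unrestricted))
  invisible(x)
}

# gene-gene traversal table: from, to, pubs. Directed follows source ->
# target ("activates"); undirected adds the reverse direction, collapsing an
# antiparallel pair to max(n_pubs).
interaction_edges <- function(kg, undirected_ppi = FALSE) {
  gg <- kg$edges[rtype == "Interaction", .(from = source, to = target, pubs = n_pubs)]
  if (undirected_ppi && nrow(gg)) {
    gg <- rbind(gg, gg[, .(from = to, to = from, pubs)])
    gg <- gg[, .(pubs = max(pubs)), by = .(from, to)]
  }
  gg
}

#' Structural hop distance between a gene and a disease
#'
#' Returns 0 if the pair is directly linked, 1 if reachable through one
#' intermediary gene, 2 through two, and `NA` otherwise (within `max_hops`).
#' No tissue constraint is applied.
#'
#' @param kg a `knowledge_graph`.
#' @param gene,disease entity ids present in `kg`.
#' @param max_hops maximum number of intermediary genes considered (1 or 2).
#' @param undirected_ppi traverse gene-gene edges ignoring direction.
#' @return integer hop count, or `NA_integer_` if farther than `max_hops`.
#' @export
hop_distance <- function(kg, gene, disease, max_hops = 2L,
                         undirected_ppi = FALSE) {
  ids <- kg$entities$id
  if (!gene %in% ids || !disease %in% ids)
    kg_stop(sprintf("unknown entity id(s): %s",
                    paste(setdiff(c(gene, disease), ids), collapse = ", ")),
            "tissuehop_lookup_error")
  gd <- kg$edges[rtype == "hasDisease", .(gene = source, disease = target)]
  if (any(gd$gene == gene & gd$disease == disease)) return(0L)
  gg <- interaction_edges(kg, undirected_ppi)
  dg <- gd$gene[gd$disease == disease]         # genes annotated to the disease
  nb1 <- gg$to[gg$from == gene]                # one interaction step from gene
  if (length(intersect(nb1, dg))) return(1L)
  if (max_hops >= 2L) {
    nb2 <- gg$to[gg$from %in% nb1]
    nb2 <- setdiff(nb2, gene)
    if (length(intersect(nb2, dg))) return(2L)
  }
  NA_integer_
}
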