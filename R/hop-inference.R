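#' Tissue-constrained hop-based gene-disease link prediction
#'
#' Predicts new gene-disease links through one or two intermediary genes.
#' A one-hop path X -> Y -> D links gene X to disease D via an interacting
#' gene Y annotated to D; a two-hop path X -> Y -> Z -> D adds a second
#' intermediary. Unless `tissue_mode = "none"`, all genes on a path must be
#' expressed in at least one common tissue at the requested level (RNA or
#' protein) — modalities are never mixed within a path. Each path is scored
#' by the sum of the publication counts of its literature edges, and a
#' pair's score aggregates its path scores (max by default). Pairs already
#' directly linked in the input graph are never reported.
#'
#' @param kg a `knowledge_graph`.
#' @param strategy `"onehop"`, `"twohop"`, or `"union"` (the union of the
#'   four tissue-filtered strategies onehop/twohop x rna/protein, scored by
#'   the maximum across them).
#' @param tissue_mode `"rna"`, `"protein"`, or `"none"` (ignored for
#'   `"union"`).
#' @param aggregation `"max"` (default) or `"sum"` over a pair's path scores.
#' @param undirected_ppi traverse gene-gene edges ignoring direction.
#' @return object of class `link_predictions`: list with
#'   \describe{
#'     \item{pairs}{data.table `gene`, `disease`, `strategy`, `score`,
#'       `n_paths`, `best_path` (pipe-separated node ids),
#'       `shared_tissues` (semicolon-separated tissues of the best path),
#'       sorted by score desc, then gene, then disease}
#'     \item{paths}{data.table of all qualifying paths: `gene`, `disease`,
#'       `strategy`, `nodes`, `hops`, `edge_pubs` (list), `path_score`,
#'       `shared_tissues` (list)}
#'   }
#' @examples
#' kg <- knowledge_graph(
#'   data.frame(id = c("X", "Y", "D", "cortex"),
#'              etype = c("Gene", "Gene", "Disease", "RNATissue")),
#'   data.frame(source = c("X", "Y", "X", "Y"),
#'              target = c("Y", "D", "cortex", "cortex"),
#'              rtype = c("Interaction", "hasDisease",
#'                        "hasRNAExpression", "hasRNAExpression"),
#'              first_year = c(2000L, 2005L, NA, NA),
#'              last_year = c(2010L, 2008L, NA, NA),
#'              n_pubs = c(5L, 2L, NA, NA)))
#' predict_links(kg, "onehop", "rna")$pairs
#' @export
predict_links <- function(kg, strategy = c("onehop", "twohop", "union"),
                          tissue_mode = c("rna", "protein", "none"),
                          aggregation = c("max", "sum"),
                          undirected_ppi = FALSE) {
  strategy <- match.arg(strategy)
  tissue_mode <- match.arg(tissue_mode)
  aggregation <- match.arg(aggregation)
  if (strategy == "union") {
    parts <- list(
      enumerate_paths(kg, 1L, "rna", undirected_ppi),
      enumerate_paths(kg, 1L, "protein", undirected_ppi),
      enumerate_paths(kg, 2L, "rna", undirected_ppi),
      enumerate_paths(kg, 2L, "protein", undirected_ppi))
    paths <- rbindlist(parts)
    label <- "union"
  } else {
    hops <- if (strategy == "onehop") 1L else 2L
    paths <- enumerate_paths(kg, hops, tissue_mode, undirected_ppi)
    label <- paste(strategy, tissue_mode, sep = "_")
  }
  assemble_predictions(paths, label, aggregation, union_mode = strategy == "union")
}

# enumerate all qualifying paths for one hop level and tissue mode.
# Returns a data.table: gene, disease, strategy, nodes (chr "X|Y|D"),
# hops, edge_pubs (list int), path_score (int), shared_tissues (list chr).
enumerate_paths <- function(kg, hops, tissue_mode, undirected_ppi = FALSE,
                            from_gene = NULL, to_disease = NULL,
                            exclude_direct = TRUE) {
  gg <- interaction_edges(kg, undirected_ppi)
  gd <- kg$edges[rtype == "hasDisease",
                 .(gene = source, disease = target, dpubs = n_pubs)]
  direct <- gd[, .(gene, disease)]
  # restriction to a query pair applies to the first (X -> Y) and last
  # (gene -> disease) edge only; intermediary hops use the full edge set
  ggx <- if (is.null(from_gene)) gg else gg[from == from_gene]
  if (!is.null(to_disease)) gd <- gd[disease == to_disease]
  empty <- data.table(gene = character(), disease = character(),
                      strategy = character(), nodes = character(),
                      hops = integer(), edge_pubs = list(),
                      path_score = integer(), shared_tissues = list())
  if (nrow(ggx) == 0L || nrow(gd) == 0L) return(empty)

  gg1 <- ggx[, .(X = from, Y = to, p1 = pubs)]
  gda <- gd[, .(Zg = gene, D = disease, pd = dpubs)]
  if (hops == 1L) {
    p <- gg1[gda, on = c(Y = "Zg"), nomatch = NULL, allow.cartesian = TRUE,
             .(X, Y, D, p1, p2 = pd)]
    gene_cols <- c("X", "Y")
  } else {
    gg2 <- gg[, .(Y2 = from, Z = to, p2 = pubs)]
    g2 <- gg1[gg2, on = c(Y = "Y2"), nomatch = NULL, allow.cartesian = TRUE,
              .(X, Y, Z, p1, p2)]
    g2 <- g2[X != Z]
    p <- g2[gda, on = c(Z = "Zg"), nomatch = NULL, allow.cartesian = TRUE,
            .(X, Y, Z, D, p1, p2, p3 = pd)]
    gene_cols <- c("X", "Y", "Z")
  }
  if (exclude_direct && nrow(p))
    p <- p[!direct, on = c(X = "gene", D = "disease")]
  if (nrow(p) == 0L) return(empty)
  p[, pid := .I]

  if (tissue_mode == "none") {
    p[, shared_tissues := rep(list(character()), .N)]
  } else {
    rt <- if (tissue_mode == "rna") "hasRNAExpression" else "hasProteinExpression"
    expr <- kg$edges[rtype == rt, .(gene = source, tissue = target)]
    tj <- p[, .(pid, gene = get(gene_cols[1L]))][expr, on = "gene",
                                                 nomatch = NULL, allow.cartesian = TRUE,
                                                 .(pid, tissue)]
    for (gc in gene_cols[-1L]) {
      nxt <- p[, .(pid, gene = get(gc))][expr, on = "gene", nomatch = NULL,
                                         allow.cartesian = TRUE, .(pid, tissue)]
      tj <- tj[nxt, on = c("pid", "tissue"), nomatch = NULL]
      if (nrow(tj) == 0L) break
    }
    if (nrow(tj) == 0L) return(empty)
    shared <- tj[, .(shared_tissues = list(sort(unique(tissue)))), by = pid]
    p <- p[shared, on = "pid", nomatch = NULL]
  }

  strat <- paste0(if (hops == 1L) "onehop" else "twohop", "_", tissue_mode)
  if (hops == 1L) {
    p[, `:=`(nodes = paste(X, Y, D, sep = "|"),
             edge_pubs = mapply(c, p1, p2, SIMPLIFY = FALSE),
             path_score = p1 + p2)]
  } else {
    p[, `:=`(nodes = paste(X, Y, Z, D, sep = "|"),
             edge_pubs = mapply(c, p1, p2, p3, SIMPLIFY = FALSE),
             path_score = p1 + p2 + p3)]
  }
  p[, .(gene = X, disease = D, strategy = strat, nodes,
        hops = hops, edge_pubs, path_score = as.integer(path_score),
        shared_tissues)]
}

# aggregate paths into ranked pair records
assemble_predictions <- function(paths, label, aggregation, union_mode = FALSE) {
  if (nrow(paths) == 0L) {
    pairs <- data.table(gene = character(), disease = character(),
                        strategy = character(), score = integer(),
                        n_paths = integer(), best_path = character(),
                        shared_tissues = character())
    return(structure(list(pairs = pairs, paths = paths,
                          strategy = label, aggregation = aggregation),
                     class = "link_predictions"))
  }
  paths <- copy(paths)
  setorder(paths, -path_score, nodes)
  if (union_mode) {
    # the same pair may arise under several strategies; aggregate across all
    agg_paths <- paths
  } else agg_paths <- paths
  pairs <- agg_paths[, .(
    score = if (aggregation == "max") max(path_score) else
      as.integer(sum(path_score)),
    n_paths = .N,
    best_path = nodes[1L],
    shared_tissues = paste(shared_tissues[[1L]], collapse = ";")),
    by = .(gene, disease)]
  pairs[, strategy := label]
  setorder(pairs, -score, gene, disease)
  setcolorder(pairs, c("gene", "disease", "strategy", "score", "n_paths",
                       "best_path", "shared_tissues"))
  structure(list(pairs = pairs[], paths = paths[],
                 strategy = label, aggregation = aggregation),
            class = "link_predictions")
}

#' @export
print.link_predictions <- function(x, ...) {
  cat(sprintf("<link_predictions> strategy=%s: %d pairs, %d paths (%s aggregation)\n",
              x$strategy, nrow(x$pairs), nrow(x$paths), x$aggregation))
  if (nrow(x$pairs)) print(head(x$pairs, 10L))
  invisible(x)
}

#' Explain a gene-disease pair with its supporting paths
#'
#' Enumerates every qualifying one-hop and (optionally) two-hop path between
#' a gene and a disease, with per-edge publication counts and the tissues
#' shared along each path — the glass-box report behind a prediction.
#' Directly linked pairs may be explained too.
#'
#' @param kg a `knowledge_graph`.
#' @param gene,disease entity ids present in `kg`.
#' @param tissue_mode `"rna"`, `"protein"`, or `"none"`.
#' @param max_hops 1 or 2.
#' @param undirected_ppi traverse gene-gene edges ignoring direction.
#' @return list with `paths` (data.table sorted by score desc then node
#'   ids), `n_onehop` and `n_twohop` path counts.
#' @export
explain_pair <- function(kg, gene, disease,
                         tissue_mode = c("rna", "protein", "none"),
                         max_hops = 2L, undirected_ppi = FALSE) {
  tissue_mode <- match.arg(tissue_mode)
  ids <- kg$entities$id
  if (!gene %in% ids || !disease %in% ids)
    kg_stop(sprintf("unknown entity id(s): %s",
                    paste(setdiff(c(gene, disease), ids), collapse = ", ")),
            "tissuehop_lookup_error")
  p1 <- enumerate_paths(kg, 1L, tissue_mode, undirected_ppi,
                        from_gene = gene, to_disease = disease,
                        exclude_direct = FALSE)
  paths <- p1
  n2 <- 0L
  if (max_hops >= 2L) {
    p2 <- enumerate_paths(kg, 2L, tissue_mode, undirected_ppi,
                          from_gene = gene, to_disease = disease,
                          exclude_direct = FALSE)
    n2 <- nrow(p2)
    paths <- rbind(p1, p2)
  }
  setorder(paths, -path_score, nodes)
  list(paths = paths[], n_onehop = nrow(p1), n_twohop = n2)
}

#' Aggregate path scores into a pair score
#'
#' @param path_scores integer vector of path scores (sum of per-edge
#'   publication counts), non-empty.
#' @param aggregation `"max"` (best single path, default) or `"sum"`.
#' @return integer pair score.
#' @export
score_paths <- function(path_scores, aggregation = c("max", "sum")) {
  aggregation <- match.arg(aggregation)
  if (length(path_scores) == 0L)
    kg_stop("cannot score a pair with no supporting paths",
            "tissuehop_domain_error")
  if (aggregation == "max") as.integer(max(path_scores))
  else as.integer(sum(path_scores))
}
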