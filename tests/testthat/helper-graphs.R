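# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as plain nested loops / direct formulas, independent
# of the package's join-based implementations.

toy_onehop_kg <- function() {
  knowledge_graph(
    data.frame(id = c("X", "Y", "D1", "cortex", "liver"),
               etype = c("Gene", "Gene", "Disease", "RNATissue", "RNATissue")),
    data.frame(source = c("X", "Y", "X", "Y", "Y"),
               target = c("Y", "D1", "cortex", "cortex", "liver"),
               rtype = c("Interaction", "hasDisease", "hasRNAExpression",
                         "hasRNAExpression", "hasRNAExpression"),
               first_year = c(2000L, 2005L, NA, NA, NA),
               last_year = c(2010L, 2008L, NA, NA, NA),
               n_pubs = c(5L, 2L, NA, NA, NA)))
}

# random typed kg for oracle comparisons; densities chosen so one- and
# two-hop paths and tissue overlaps occur regularly at n ~ 10-20 genes
random_kg <- function(seed, n_genes = 12L, n_diseases = 3L, n_tissues = 3L,
                      p_gg = 0.15, p_gd = 0.2, p_expr = 0.5) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  diseases <- sprintf("d%d", seq_len(n_diseases))
  rna <- sprintf("rt%d", seq_len(n_tissues))
  prot <- sprintf("pt%d", seq_len(n_tissues))
  ents <- data.frame(
    id = c(genes, diseases, rna, prot),
    etype = rep(c("Gene", "Disease", "RNATissue", "ProteinTissue"),
                c(n_genes, n_diseases, n_tissues, n_tissues)))
  eg <- expand.grid(source = genes, target = genes, stringsAsFactors = FALSE)
  eg <- eg[eg$source != eg$target & runif(nrow(eg)) < p_gg, ]
  ed <- expand.grid(source = genes, target = diseases, stringsAsFactors = FALSE)
  ed <- ed[runif(nrow(ed)) < p_gd, ]
  er <- expand.grid(source = genes, target = rna, stringsAsFactors = FALSE)
  er <- er[runif(nrow(er)) < p_expr, ]
  ep <- expand.grid(source = genes, target = prot, stringsAsFactors = FALSE)
  ep <- ep[runif(nrow(ep)) < p_expr, ]
  addcol <- function(df, rt) { df$rtype <- rep(rt, nrow(df)); df }
  dated <- rbind(addcol(eg, "Interaction"), addcol(ed, "hasDisease"))
  dated$first_year <- sample(1995:2015, nrow(dated), replace = TRUE)
  dated$last_year <- dated$first_year + sample(0:5, nrow(dated), replace = TRUE)
  dated$n_pubs <- sample(1:50, nrow(dated), replace = TRUE)
  expr <- rbind(addcol(er, "hasRNAExpression"),
                addcol(ep, "hasProteinExpression"))
  if (nrow(expr)) expr[, c("first_year", "last_year", "n_pubs")] <- NA_integer_
  knowledge_graph(ents, rbind(dated, expr))
}

# --- oracles -------------------------------------------------------------

# exhaustive path enumeration with shared-tissue check, nested loops
oracle_paths <- function(kg, hops, tissue_mode, undirected_ppi = FALSE) {
  eds <- kg$edges
  gg <- eds[eds$rtype == "Interaction", ]
  gglist <- Map(c, gg$source, gg$target, gg$n_pubs)
  if (undirected_ppi) {
    pubs <- list()
    for (e in gglist) {
      k1 <- paste(e[1], e[2]); k2 <- paste(e[2], e[1])
      v <- as.integer(e[3])
      pubs[[k1]] <- max(pubs[[k1]] %||% 0L, v)
      pubs[[k2]] <- max(pubs[[k2]] %||% 0L, v)
    }
    gglist <- Map(function(k, v) c(strsplit(k, " ")[[1]], v),
                  names(pubs), unlist(pubs))
  }
  gd <- eds[eds$rtype == "hasDisease", ]
  direct <- paste(gd$source, gd$target)
  tiss <- function(g) {
    rt <- if (tissue_mode == "rna") "hasRNAExpression" else "hasProteinExpression"
    eds$target[eds$rtype == rt & eds$source == g]
  }
  out <- list()
  if (hops == 1L) {
    for (e1 in gglist) for (j in seq_len(nrow(gd))) {
      if (e1[2] != gd$source[j]) next
      X <- e1[1]; Y <- e1[2]; D <- gd$target[j]
      if (paste(X, D) %in% direct) next
      shared <- if (tissue_mode == "none") character() else
        intersect(tiss(X), tiss(Y))
      if (tissue_mode != "none" && length(shared) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        gene = X, disease = D, nodes = paste(X, Y, D, sep = "|"),
        path_score = as.integer(e1[3]) + gd$n_pubs[j])
    }
  } else {
    for (e1 in gglist) for (e2 in gglist) {
      if (e1[2] != e2[1]) next
      X <- e1[1]; Y <- e1[2]; Z <- e2[2]
      if (X == Z) next
      for (j in seq_len(nrow(gd))) {
        if (gd$source[j] != Z) next
        D <- gd$target[j]
        if (paste(X, D) %in% direct) next
        shared <- if (tissue_mode == "none") character() else
          Reduce(intersect, list(tiss(X), tiss(Y), tiss(Z)))
        if (tissue_mode != "none" && length(shared) == 0L) next
        out[[length(out) + 1L]] <- data.frame(
          gene = X, disease = D, nodes = paste(X, Y, Z, D, sep = "|"),
          path_score = as.integer(e1[3]) + as.integer(e2[3]) + gd$n_pubs[j])
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene = character(), disease = character(),
                      nodes = character(), path_score = integer()))
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-pair aggregation of oracle paths
oracle_pairs <- function(paths, aggregation = "max") {
  if (nrow(paths) == 0L)
    return(data.frame(gene = character(), disease = character(),
                      score = integer()))
  agg <- if (aggregation == "max") max else sum
  res <- aggregate(path_score ~ gene + disease, data = paths, FUN = agg)
  names(res)[3] <- "score"
  res[order(res$gene, res$disease), ]
}

# BFS hop distance oracle (0 = direct link, else # intermediary genes)
oracle_hop_distance <- function(kg, gene, disease, max_hops = 2L,
                                undirected_ppi = FALSE) {
  eds <- kg$edges
  gd <- eds[eds$rtype == "hasDisease", ]
  if (any(gd$source == gene & gd$target == disease)) return(0L)
  gg <- eds[eds$rtype == "Interaction", ]
  succ <- function(v) {
    s <- gg$target[gg$source == v]
    if (undirected_ppi) s <- c(s, gg$source[gg$target == v])
    unique(s)
  }
  annotated <- gd$source[gd$target == disease]
  frontier <- succ(gene)
  if (length(intersect(frontier, annotated))) return(1L)
  if (max_hops >= 2L) {
    f2 <- setdiff(unique(unlist(lapply(frontier, succ))), gene)
    if (length(intersect(f2, annotated))) return(2L)
  }
  NA_integer_
}

# union-find connected components oracle (undirected)
oracle_components <- function(ids, edges_from, edges_to) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(edges_from)) {
    ra <- find(edges_from[i]); rb <- find(edges_to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  vapply(ids, find, character(1))
}

# dense power-iteration pagerank oracle
oracle_pagerank <- function(kg, damping = 0.85, iters = 500L) {
  ids <- kg$entities$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(kg$edges)))
    A[kg$edges$target[i], kg$edges$source[i]] <- 1
  outdeg <- colSums(A)
  x <- rep(1 / n, n)
  for (it in seq_len(iters)) {
    contrib <- rep(0, n)
    for (j in seq_len(n)) {
      if (outdeg[j] > 0) contrib <- contrib + x[j] * A[, j] / outdeg[j]
      else contrib <- contrib + x[j] / n
    }
    x <- damping * contrib + (1 - damping) / n
  }
  stats::setNames(x / sum(x), ids)
}
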