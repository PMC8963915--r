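#' Directed edge density
#'
#' Ratio of the number of edges to the number of possible directed edges,
#' `E / (N * (N - 1))`, for a simple directed graph.
#'
#' @param kg a `knowledge_graph` with at least two nodes.
#' @return density in `[0, 1]`.
#' @seealso [directed_density()] for the bare formula on counts.
#' @export
edge_density <- function(kg) {
  n <- nrow(kg$entities)
  if (n < 2L)
    kg_stop("edge density requires at least 2 nodes", "tissuehop_domain_error")
  directed_density(n, nrow(kg$edges))
}

#' @rdname edge_density
#' @param n_nodes,n_edges node and edge counts of a simple directed graph.
#' @export
directed_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2L)
    kg_stop("edge density requires at least 2 nodes", "tissuehop_domain_error")
  n_edges / (n_nodes * (n_nodes - 1))
}

#' Per-node, per-type degree tables
#'
#' @param kg a `knowledge_graph`.
#' @return data.table with columns `id`, `etype`, `deg_in`, `deg_out`,
#'   `deg_total` (one row per entity, sorted by id).
#' @export
degree_tables <- function(kg) {
  ents <- kg$entities
  out_n <- table(factor(kg$edges$source, levels = ents$id))
  in_n <- table(factor(kg$edges$target, levels = ents$id))
  dt <- data.table(id = ents$id, etype = ents$etype,
                   deg_in = as.integer(in_n[ents$id]),
                   deg_out = as.integer(out_n[ents$id]))
  dt[, deg_total := deg_in + deg_out]
  setorder(dt, id)
  dt[]
}

#' PageRank centrality by damped power iteration
#'
#' Random-surfer recursion with uniform teleportation and uniform
#' redistribution of dangling-node mass, iterated to a fixed point.
#'
#' @param kg a non-empty `knowledge_graph`.
#' @param damping damping factor in (0, 1); default 0.85.
#' @param tol L1 convergence tolerance on successive iterates.
#' @param max_iter iteration cap; exceeding it raises a convergence error
#'   reporting the residual.
#' @return named numeric vector of scores summing to 1 (names = entity ids).
#' @export
kg_pagerank <- function(kg, damping = 0.85, tol = 1e-10, max_iter = 1000L) {
  if (nrow(kg$entities) == 0L)
    kg_stop("pagerank requires a non-empty graph", "tissuehop_domain_error")
  if (damping <= 0 || damping >= 1)
    kg_stop("damping must lie strictly between 0 and 1", "tissuehop_usage_error")
  ids <- kg$entities$id
  n <- length(ids)
  si <- match(kg$edges$source, ids)
  ti <- match(kg$edges$target, ids)
  outdeg <- tabulate(si, nbins = n)
  # sparse transition: A[t, s] = 1/outdeg(s)
  A <- sparseMatrix(i = ti, j = si, x = 1 / outdeg[si], dims = c(n, n))
  dangling <- outdeg == 0L
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- as.numeric(A %*% x) * damping
    x_new <- x_new + damping * sum(x[dangling]) / n + (1 - damping) / n
    resid <- sum(abs(x_new - x))
    x <- x_new
    if (resid < tol) {
      names(x) <- ids
      return(x / sum(x))
    }
  }
  kg_stop(sprintf("pagerank did not converge in %d iterations (residual %.3e)",
                  max_iter, resid), "tissuehop_convergence_error")
}

#' Discrete power-law fit of a degree sequence
#'
#' Maximum-likelihood exponent for a discrete power law, with the lower
#' cutoff `xmin` chosen by Kolmogorov-Smirnov minimization (the plfit
#' procedure, via [igraph::fit_power_law()]).
#'
#' @param degrees integer vector of positive degrees; needs at least 10
#'   positive values with at least 2 distinct values.
#' @param xmin optional fixed lower cutoff; `NULL` (default) selects by KS.
#' @return list with `alpha`, `xmin` and `ks_stat`.
#' @export
powerlaw_fit <- function(degrees, xmin = NULL) {
  degrees <- degrees[!is.na(degrees) & degrees > 0]
  if (length(degrees) < 10L)
    kg_stop("power-law fit requires >= 10 positive degrees",
            "tissuehop_domain_error")
  if (length(unique(degrees)) < 2L)
    kg_stop("power-law fit is undefined for a constant degree sequence",
            "tissuehop_domain_error")
  fit <- igraph::fit_power_law(degrees, xmin = if (is.null(xmin)) NULL else xmin,
                               implementation = "plfit")
  list(alpha = fit$alpha, xmin = fit$xmin, ks_stat = fit$KS.stat)
}

#' Restrict a graph to edges first published up to a cutoff year
#'
#' Keeps the dated edges with `first_year <= cutoff_year`. Expression edges
#' are undated; a gene's expression edges survive if and only if the gene
#' retains at least one dated edge. Entities left without any edge are
#' dropped.
#'
#' @param kg a `knowledge_graph`.
#' @param cutoff_year integer year (inclusive).
#' @return the filtered `knowledge_graph` (possibly empty).
#' @export
subgraph_before <- function(kg, cutoff_year) {
  stopifnot(is.numeric(cutoff_year), length(cutoff_year) == 1L)
  eds <- kg$edges
  dated <- eds[rtype %in% DATED_RELATIONS & first_year <= cutoff_year]
  live_genes <- unique(c(dated$source, dated$target[dated$rtype == "Interaction"]))
  expr <- eds[!(rtype %in% DATED_RELATIONS) & source %in% live_genes]
  keep <- rbind(dated, expr)
  ids <- unique(c(keep$source, keep$target))
  knowledge_graph(kg$entities[id %in% ids], keep, validate = FALSE)
}

#' Largest weakly connected component over selected node types
#'
#' Induces the subgraph on the requested entity types, then returns the
#' component with the most nodes when edge direction is ignored. Ties are
#' broken in favour of the component containing the lexicographically
#' smallest entity id.
#'
#' @param kg a `knowledge_graph`.
#' @param node_types character vector of entity types to retain.
#' @return a `knowledge_graph` induced on the winning component.
#' @export
largest_weak_component <- function(kg, node_types = c("Gene", "Disease")) {
  stopifnot(length(node_types) >= 1L)
  ids <- kg$entities$id[kg$entities$etype %in% node_types]
  sub <- kg_induce(kg, ids)
  if (nrow(sub$entities) == 0L) return(sub)
  g <- as_igraph(sub)
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  winners <- which(sizes == max(sizes))
  if (length(winners) > 1L) {
    # smallest lexicographic member id decides
    first_member <- vapply(winners, function(w)
      min(igraph::V(g)$name[comp$membership == w]), character(1))
    winners <- winners[order(first_member)][1L]
  }
  keep <- igraph::V(g)$name[comp$membership == winners[1L]]
  kg_induce(sub, keep)
}

#' Yearly evolution of the gene-disease largest weak component
#'
#' For each year, the graph is filtered with [subgraph_before()], restricted
#' to gene and disease nodes, and reduced to its largest weakly connected
#' component; node count, edge count, edge density and the power-law
#' exponent of the total-degree sequence are reported.
#'
#' @param kg a `knowledge_graph`.
#' @param years nondecreasing integer vector of years.
#' @return data.table with columns `year`, `n_nodes`, `n_edges`,
#'   `edge_density`, `powerlaw_alpha` (`NA` where undefined).
#' @export
temporal_evolution <- function(kg, years) {
  if (is.unsorted(years))
    kg_stop("years must be nondecreasing", "tissuehop_usage_error")
  rows <- lapply(years, function(y) {
    comp <- largest_weak_component(subgraph_before(kg, y),
                                   node_types = c("Gene", "Disease"))
    n <- nrow(comp$entities); e <- nrow(comp$edges)
    dens <- if (n >= 2L) directed_density(n, e) else NA_real_
    deg <- if (n) degree_tables(comp)$deg_total else integer()
    alpha <- tryCatch(powerlaw_fit(deg)$alpha, tissuehop_error = function(cnd) NA_real_)
    data.table(year = as.integer(y), n_nodes = n, n_edges = e,
               edge_density = dens, powerlaw_alpha = alpha)
  })
  rbindlist(rows)
}

#' Topological summary of a knowledge graph
#'
#' Per-type node and edge counts (with totals), edge density and, when
#' `topology = TRUE`, the power-law exponent of the total-degree sequence,
#' PageRank centralities and the full degree table.
#'
#' @param kg a `knowledge_graph`.
#' @param topology include the heavier topological statistics.
#' @return object of class `kg_summary`.
#' @export
kg_summary <- function(kg, topology = FALSE) {
  n_by_type <- table(factor(kg$entities$etype, levels = ENTITY_TYPES))
  e_by_type <- table(factor(kg$edges$rtype, levels = RELATION_TYPES))
  out <- list(
    n_nodes_by_type = stats::setNames(as.integer(n_by_type), names(n_by_type)),
    n_edges_by_type = stats::setNames(as.integer(e_by_type), names(e_by_type)),
    n_nodes = nrow(kg$entities),
    n_edges = nrow(kg$edges),
    edge_density = if (nrow(kg$entities) >= 2L) edge_density(kg) else NA_real_)
  if (topology) {
    deg <- degree_tables(kg)
    out$degree <- deg
    out$powerlaw_alpha <- tryCatch(powerlaw_fit(deg$deg_total)$alpha,
                                   tissuehop_error = function(cnd) NA_real_)
    out$pagerank <- if (out$n_nodes) kg_pagerank(kg) else numeric()
  }
  structure(out, class = "kg_summary")
}

#' @export
print.kg_summary <- function(x, ...) {
  cat(sprintf("Knowledge-graph summary: %d nodes, %d edges, density %s\n",
              x$n_nodes, x$n_edges,
              ifelse(is.na(x$edge_density), "NA",
                     formatC(x$edge_density, format = "f", digits = 6))))
  cat("  nodes:", paste(sprintf("%s=%d", names(x$n_nodes_by_type),
                                x$n_nodes_by_type), collapse = " "), "\n")
  cat("  edges:", paste(sprintf("%s=%d", names(x$n_edges_by_type),
                                x$n_edges_by_type), collapse = " "), "\n")
  if (!is.null(x$powerlaw_alpha))
    cat(sprintf("  power-law alpha (total degree): %.3f\n", x$powerlaw_alpha))
  invisible(x)
}
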