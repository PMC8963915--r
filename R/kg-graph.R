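#' Construct a knowledge graph of genes, diseases and tissues
#'
#' The central container of the package: a typed, directed, simple graph
#' whose nodes are genes (Ensembl-style accessions), diseases (MeSH-style
#' identifiers) and tissues (RNA-level and protein-level expression
#' vocabularies), and whose edges are one of four relations:
#' `Interaction` (Gene -> Gene), `hasDisease` (Gene -> Disease),
#' `hasRNAExpression` (Gene -> RNATissue) and `hasProteinExpression`
#' (Gene -> ProteinTissue). Literature-derived relations (`Interaction`,
#' `hasDisease`) are dated (`first_year`, `last_year`) and weighted by the
#' number of supporting publications (`n_pubs`), optionally carrying PubMed
#' identifiers; expression relations are undated.
#'
#' @param entities data.frame with columns `id` (unique, non-empty character)
#'   and `etype` (one of `"Gene"`, `"Disease"`, `"RNATissue"`,
#'   `"ProteinTissue"`).
#' @param edges data.frame with columns `source`, `target`, `rtype`, and for
#'   dated relations `first_year`, `last_year`, `n_pubs` and optionally a
#'   list-column `pmids` of character vectors. Missing dated columns are
#'   created as `NA` (only valid if all edges are expression edges).
#' @param validate if `TRUE` (default) enforce all container invariants.
#' @return An object of class `knowledge_graph`: a list with data.tables
#'   `entities` and `edges`.
#' @examples
#' ents <- data.frame(id = c("G1", "G2", "D1"),
#'                    etype = c("Gene", "Gene", "Disease"))
#' eds <- data.frame(source = c("G1", "G2"), target = c("G2", "D1"),
#'                   rtype = c("Interaction", "hasDisease"),
#'                   first_year = c(2001L, 2005L),
#'                   last_year = c(2010L, 2006L), n_pubs = c(3L, 1L))
#' kg <- knowledge_graph(ents, eds)
#' kg
#' @export
knowledge_graph <- function(entities, edges, validate = TRUE) {
  entities <- as.data.table(entities)
  edges <- as.data.table(edges)
  if (nrow(edges) == 0L) {
    edges <- data.table(source = character(), target = character(),
                        rtype = character(), first_year = integer(),
                        last_year = integer(), n_pubs = integer(),
                        pmids = list())
  }
  for (col in c("first_year", "last_year", "n_pubs")) {
    if (!col %in% names(edges)) edges[, (col) := NA_integer_]
    edges[, (col) := as.integer(get(col))]
  }
  if (!"pmids" %in% names(edges)) edges[, pmids := list(rep(list(character()), .N))]
  entities[, id := as.character(id)]
  entities[, etype := as.character(etype)]
  edges[, source := as.character(source)]
  edges[, target := as.character(target)]
  edges[, rtype := as.character(rtype)]
  setcolorder(edges, c("source", "target", "rtype", "first_year",
                       "last_year", "n_pubs", "pmids"))
  kg <- structure(list(entities = entities, edges = edges),
                  class = "knowledge_graph")
  if (validate) validate_kg(kg)
  kg
}

#' Validate knowledge-graph invariants
#'
#' Checks entity-id uniqueness, entity/relation vocabularies, endpoint type
#' signatures, absence of self-edges and multi-edges, year ordering and
#' publication-count consistency. Called by [knowledge_graph()] and after
#' loading edge tables.
#'
#' @param kg a `knowledge_graph`.
#' @return `kg`, invisibly, if valid; otherwise signals a structured error
#'   of class `tissuehop_schema_error` or `tissuehop_validation_error`.
#' @export
validate_kg <- function(kg) {
  ents <- kg$entities
  eds <- kg$edges
  if (!all(c("id", "etype") %in% names(ents)))
    kg_stop("entities must have columns 'id' and 'etype'",
            "tissuehop_schema_error")
  if (anyNA(ents$id) || any(!nzchar(ents$id)))
    kg_stop("no entity may have a missing or empty id",
            "tissuehop_validation_error")
  if (anyDuplicated(ents$id))
    kg_stop(sprintf("duplicated entity ids: %s",
                    paste(unique(ents$id[duplicated(ents$id)]), collapse = ", ")),
            "tissuehop_validation_error")
  bad_t <- setdiff(unique(ents$etype), ENTITY_TYPES)
  if (length(bad_t))
    kg_stop(sprintf("unknown entity types: %s", paste(bad_t, collapse = ", ")),
            "tissuehop_validation_error")
  if (nrow(eds) == 0L) return(invisible(kg))
  bad_r <- setdiff(unique(eds$rtype), RELATION_TYPES)
  if (length(bad_r))
    kg_stop(sprintf("unknown relation types: %s", paste(bad_r, collapse = ", ")),
            "tissuehop_validation_error")
  missing_ep <- setdiff(c(eds$source, eds$target), ents$id)
  if (length(missing_ep))
    kg_stop(sprintf("edge endpoints absent from entities: %s",
                    paste(head(missing_ep, 5L), collapse = ", ")),
            "tissuehop_validation_error")
  etype_of <- ents$etype[match(eds$source, ents$id)]
  ttype_of <- ents$etype[match(eds$target, ents$id)]
  sig <- RELATION_SIGNATURES[eds$rtype]
  exp_s <- vapply(sig, `[`, character(1), 1L)
  exp_t <- vapply(sig, `[`, character(1), 2L)
  bad <- which(etype_of != exp_s | ttype_of != exp_t)
  if (length(bad))
    kg_stop(sprintf(
      "endpoint types violate relation signature in %d edge(s), e.g. rows: %s",
      length(bad), paste(head(bad, 5L), collapse = ", ")),
      "tissuehop_validation_error")
  if (any(eds$source == eds$target))
    kg_stop("self-edges are not allowed", "tissuehop_validation_error")
  if (anyDuplicated(eds, by = c("source", "target", "rtype")))
    kg_stop("at most one edge per (source, target, rtype) is allowed",
            "tissuehop_validation_error")
  dated <- eds[rtype %in% DATED_RELATIONS]
  if (nrow(dated)) {
    if (anyNA(dated$first_year) || anyNA(dated$last_year) || anyNA(dated$n_pubs))
      kg_stop("dated edges require first_year, last_year and n_pubs",
              "tissuehop_schema_error")
    bad_y <- which(dated$first_year > dated$last_year)
    if (length(bad_y))
      kg_stop(sprintf("first_year > last_year in dated edge rows: %s",
                      paste(head(bad_y, 5L), collapse = ", ")),
              "tissuehop_validation_error")
    if (any(dated$n_pubs < 0L))
      kg_stop("n_pubs must be non-negative", "tissuehop_validation_error")
    npm <- vapply(dated$pmids, length, integer(1))
    if (any(dated$n_pubs < npm))
      kg_stop("n_pubs must be >= number of listed pmids",
              "tissuehop_validation_error")
  }
  invisible(kg)
}

#' @export
print.knowledge_graph <- function(x, ...) {
  nt <- table(factor(x$entities$etype, levels = ENTITY_TYPES))
  ne <- table(factor(x$edges$rtype, levels = RELATION_TYPES))
  cat(sprintf("<knowledge_graph> %d entities, %d edges\n",
              nrow(x$entities), nrow(x$edges)))
  cat("  entities:", paste(sprintf("%s=%d", names(nt), nt), collapse = " "), "\n")
  cat("  edges:   ", paste(sprintf("%s=%d", names(ne), ne), collapse = " "), "\n")
  invisible(x)
}

#' Entity ids of a given type
#' @param kg a `knowledge_graph`.
#' @param etype entity type, one of `"Gene"`, `"Disease"`, `"RNATissue"`,
#'   `"ProteinTissue"`.
#' @return character vector of ids (sorted).
#' @export
entity_ids <- function(kg, etype) {
  stopifnot(etype %in% ENTITY_TYPES)
  sort(kg$entities$id[kg$entities$etype == etype])
}

# induced subgraph on a set of entity ids; keeps edges with both endpoints
# retained. Isolated retained entities are kept.
kg_induce <- function(kg, ids) {
  ents <- kg$entities[id %in% ids]
  eds <- kg$edges[source %in% ids & target %in% ids]
  knowledge_graph(ents, eds, validate = FALSE)
}

#' Drop expression edges (and then-isolated tissue nodes) from a graph
#'
#' Used to contrast pipelines trained with and without the tissue-expression
#' entity, mirroring the with-tissue vs no-tissue comparison of the method.
#'
#' @param kg a `knowledge_graph`.
#' @return a `knowledge_graph` containing only genes, diseases and the dated
#'   literature edges.
#' @export
strip_expression <- function(kg) {
  eds <- kg$edges[rtype %in% DATED_RELATIONS]
  ents <- kg$entities[etype %in% c("Gene", "Disease")]
  knowledge_graph(ents, eds, validate = FALSE)
}

#' Convert a knowledge graph to an igraph object
#'
#' @param kg a `knowledge_graph`.
#' @param directed logical; if `FALSE` edge direction is dropped.
#' @return an `igraph` graph with vertex attribute `etype` and edge
#'   attributes `rtype` and `n_pubs`.
#' @export
as_igraph <- function(kg, directed = TRUE) {
  g <- igraph::graph_from_data_frame(
    kg$edges[, .(from = source, to = target, rtype, n_pubs)],
    directed = directed,
    vertices = kg$entities[, .(name = id, etype)])
  g
}
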