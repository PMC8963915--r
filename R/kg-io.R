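#' Load a knowledge graph from delimited edge tables
#'
#' Reads up to four tab-separated tables: gene-gene interactions and
#' gene-disease associations (dated, publication-weighted) and gene-tissue
#' expression assignments at the RNA and protein level. Duplicate rows for
#' the same (source, target, relation) are collapsed by keeping the earliest
#' `first_year`, the latest `last_year`, the largest `n_pubs` and the union
#' of PubMed ids.
#'
#' Dated tables require columns `source_id`, `target_id`, `first_year`,
#' `last_year`, `n_pubs` and may carry `pmids` (semicolon-separated).
#' Expression tables require `gene_id` and `tissue_name`.
#'
#' @param interaction_path path to the gene-gene interaction table.
#' @param disease_path path to the gene-disease association table.
#' @param rna_path,protein_path optional paths to RNA-level / protein-level
#'   expression tables.
#' @param sep field separator (default tab).
#' @return a validated [knowledge_graph()].
#' @export
load_edge_tables <- function(interaction_path, disease_path,
                             rna_path = NULL, protein_path = NULL,
                             sep = "\t") {
  dated_cols <- c("source_id", "target_id", "first_year", "last_year", "n_pubs")
  read_dated <- function(path, rtype, target_type) {
    dt <- fread(path, sep = sep)
    miss <- setdiff(dated_cols, names(dt))
    if (length(miss))
      kg_stop(sprintf("%s: missing required column(s): %s", path,
                      paste(miss, collapse = ", ")), "tissuehop_schema_error")
    pm <- if ("pmids" %in% names(dt)) {
      lapply(as.character(dt$pmids), function(s)
        if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]])
    } else rep(list(character()), nrow(dt))
    out <- data.table(source = as.character(dt$source_id),
                      target = as.character(dt$target_id),
                      rtype = rtype,
                      first_year = as.integer(dt$first_year),
                      last_year = as.integer(dt$last_year),
                      n_pubs = as.integer(dt$n_pubs),
                      pmids = pm)
    bad <- which(out$first_year > out$last_year)
    if (length(bad))
      kg_stop(sprintf("%s: first_year > last_year in row(s): %s", path,
                      paste(head(bad, 5L), collapse = ", ")),
              "tissuehop_validation_error")
    out
  }
  read_expr <- function(path, rtype) {
    dt <- fread(path, sep = sep)
    miss <- setdiff(c("gene_id", "tissue_name"), names(dt))
    if (length(miss))
      kg_stop(sprintf("%s: missing required column(s): %s", path,
                      paste(miss, collapse = ", ")), "tissuehop_schema_error")
    data.table(source = as.character(dt$gene_id),
               target = as.character(dt$tissue_name),
               rtype = rtype,
               first_year = NA_integer_, last_year = NA_integer_,
               n_pubs = NA_integer_, pmids = rep(list(character()), nrow(dt)))
  }
  eds <- list(read_dated(interaction_path, "Interaction", "Gene"),
              read_dated(disease_path, "hasDisease", "Disease"))
  if (!is.null(rna_path)) eds <- c(eds, list(read_expr(rna_path, "hasRNAExpression")))
  if (!is.null(protein_path)) eds <- c(eds, list(read_expr(protein_path, "hasProteinExpression")))
  eds <- rbindlist(eds)
  eds <- collapse_duplicate_edges(eds)

  tt <- vapply(RELATION_SIGNATURES[eds$rtype], `[`, character(1), 2L)
  ents <- unique(rbind(
    data.table(id = eds$source, etype = "Gene"),
    data.table(id = eds$target, etype = tt)))
  kg <- knowledge_graph(ents, eds, validate = FALSE)
  validate_kg(kg)
  kg
}

# collapse rule: min first_year, max last_year, max n_pubs, union of pmids.
# The pmid union is itself evidence of distinct publications, so n_pubs is
# raised to the union size when the listed ids outnumber the largest count.
collapse_duplicate_edges <- function(eds) {
  out <- eds[, .(first_year = if (all(is.na(first_year))) NA_integer_ else
                   min(first_year, na.rm = TRUE),
                 last_year = if (all(is.na(last_year))) NA_integer_ else
                   max(last_year, na.rm = TRUE),
                 n_pubs = if (all(is.na(n_pubs))) NA_integer_ else
                   max(n_pubs, na.rm = TRUE),
                 pmids = list(sort(unique(unlist(pmids))))),
             by = .(source, target, rtype)]
  out[, n_pubs := pmax(n_pubs, vapply(pmids, length, integer(1)))]
  out
}

#' Write a knowledge graph back to its edge-table dialect
#'
#' Emits the same four tab-separated tables that [load_edge_tables()]
#' consumes, so that generated graphs round-trip exactly.
#'
#' @param kg a `knowledge_graph`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_edge_tables <- function(kg, dir, prefix = "kg") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eds <- kg$edges
  out <- c()
  wd <- function(rt, file) {
    d <- eds[eds$rtype == rt]
    dt <- data.table(source_id = d$source, target_id = d$target,
                     first_year = d$first_year, last_year = d$last_year,
                     n_pubs = d$n_pubs,
                     pmids = vapply(d$pmids, paste, character(1), collapse = ";"))
    setorder(dt, source_id, target_id)
    fwrite(dt, file, sep = "\t")
    file
  }
  we <- function(rt, file, modality) {
    d <- eds[eds$rtype == rt]
    dt <- data.table(gene_id = d$source, tissue_name = d$target,
                     modality = modality)
    setorder(dt, gene_id, tissue_name)
    fwrite(dt, file, sep = "\t")
    file
  }
  out["interaction"] <- wd("Interaction", file.path(dir, paste0(prefix, "_interaction.tsv")))
  out["disease"] <- wd("hasDisease", file.path(dir, paste0(prefix, "_disease.tsv")))
  out["rna"] <- we("hasRNAExpression", file.path(dir, paste0(prefix, "_rna_expression.tsv")), "rna")
  out["protein"] <- we("hasProteinExpression", file.path(dir, paste0(prefix, "_protein_expression.tsv")), "protein")
  invisible(out)
}
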