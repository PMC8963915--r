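#' Export a knowledge graph as RDF (Turtle or N-Triples)
#'
#' RDF has no edge properties, so each gene-disease association is
#' materialized through an intermediate `Publication` resource that carries
#' the publication count (and PubMed ids, when present) as data properties:
#' three triples per gene-disease edge (`gene -> publication`,
#' `publication -> disease`, `publication -> count`), plus one triple per
#' PubMed id. Interaction and expression edges become direct object
#' properties, and every entity gets one `rdf:type` triple. Entity URIs are
#' built from their ids under a fixed base namespace.
#'
#' @param kg a `knowledge_graph`.
#' @param path output file.
#' @param format `"turtle"` or `"ntriples"`.
#' @return `path`, invisibly. An empty graph yields a valid empty document.
#' @export
export_rdf <- function(kg, path, format = c("turtle", "ntriples")) {
  format <- match.arg(format)
  base <- "http://purl.example.org/tissuehop/"
  xsd_int <- "http://www.w3.org/2001/XMLSchema#integer"
  rdf_type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  uri_frag <- function(x) {
    # percent-encode anything outside the unreserved URI character set
    vapply(x, utils::URLencode, character(1), reserved = TRUE, USE.NAMES = FALSE)
  }
  ent_uri <- function(id, etype) {
    prefix <- c(Gene = "gene/", Disease = "disease/", RNATissue = "tissue/rna/",
                ProteinTissue = "tissue/protein/")[etype]
    paste0(base, prefix, uri_frag(id))
  }
  class_uri <- function(etype) paste0(base, "class/", etype)
  prop <- function(p) paste0(base, "prop/", p)

  triples <- list()
  add <- function(s, p, o, literal = FALSE, dtype = NULL) {
    triples[[length(triples) + 1L]] <<- data.table(
      s = s, p = p, o = o, literal = literal,
      dtype = if (is.null(dtype)) NA_character_ else dtype)
  }
  ents <- kg$entities
  if (nrow(ents))
    add(ent_uri(ents$id, ents$etype), rdf_type, class_uri(ents$etype))
  etype_of <- stats::setNames(ents$etype, ents$id)
  eds <- kg$edges
  gd <- eds[rtype == "hasDisease"]
  other <- eds[rtype != "hasDisease"]
  if (nrow(other)) {
    pmap <- c(Interaction = "interactsWith",
              hasRNAExpression = "hasRNAExpression",
              hasProteinExpression = "hasProteinExpression")
    add(ent_uri(other$source, etype_of[other$source]),
        prop(pmap[other$rtype]),
        ent_uri(other$target, etype_of[other$target]))
  }
  if (nrow(gd)) {
    pub <- paste0(base, "publication/", uri_frag(gd$source), "_",
                  uri_frag(gd$target))
    add(ent_uri(gd$source, "Gene"), prop("hasPublication"), pub)
    add(pub, prop("mentionsDisease"), ent_uri(gd$target, "Disease"))
    add(pub, prop("publicationCount"), as.character(gd$n_pubs),
        literal = TRUE, dtype = xsd_int)
    for (i in seq_len(nrow(gd))) {
      ids <- gd$pmids[[i]]
      if (length(ids))
        add(rep(pub[i], length(ids)), prop("pmid"), ids, literal = TRUE)
    }
  }
  tt <- if (length(triples)) rbindlist(triples) else
    data.table(s = character(), p = character(), o = character(),
               literal = logical(), dtype = character())

  fmt_obj <- function(o, literal, dtype) {
    ifelse(literal,
           ifelse(is.na(dtype),
                  paste0("\"", o, "\""),
                  paste0("\"", o, "\"^^<", dtype, ">")),
           paste0("<", o, ">"))
  }
  lines <- if (format == "ntriples") {
    if (nrow(tt))
      paste0("<", tt$s, "> <", tt$p, "> ",
             fmt_obj(tt$o, tt$literal, tt$dtype), " .")
    else character()
  } else {
    hdr <- c(sprintf("@prefix th: <%s> .", base),
             sprintf("@prefix xsd: <http://www.w3.org/2001/XMLSchema#> ."),
             "")
    body <- if (nrow(tt))
      paste0("<", tt$s, "> <", tt$p, "> ",
             fmt_obj(tt$o, tt$literal, tt$dtype), " .")
    else character()
    c(hdr, body)
  }
  ok <- tryCatch({ suppressWarnings(writeLines(lines, path)); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    kg_stop(sprintf("cannot write RDF to '%s'", path), "tissuehop_io_error")
  invisible(path)
}

#' Count the subject-predicate-object triples of an exported RDF file
#'
#' Convenience for round-trip checks: counts the statement lines of a
#' Turtle / N-Triples document written by [export_rdf()].
#'
#' @param path file path.
#' @return integer triple count.
#' @export
count_rdf_triples <- function(path) {
  lines <- readLines(path)
  sum(grepl(" \\.$", lines) & !startsWith(lines, "@prefix"))
}
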