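test_that("one-hop prediction applies the sum rule and the tissue filter", {
  kg <- toy_onehop_kg()
  p <- predict_links(kg, "onehop", "rna")
  expect_equal(nrow(p$pairs), 1L)
  expect_equal(p$pairs$gene, "X")
  expect_equal(p$pairs$disease, "D1")
  expect_equal(p$pairs$score, 7L)            # 5 + 2 publications
  expect_equal(p$pairs$n_paths, 1L)
  expect_equal(p$paths$shared_tissues[[1]], "cortex")
  # same graph without a shared tissue: no predictions under the rna filter
  kg2 <- toy_onehop_kg()
  kg2$edges <- kg2$edges[!(kg2$edges$source == "X" &
                             kg2$edges$target == "cortex"), ]
  expect_equal(nrow(predict_links(kg2, "onehop", "rna")$pairs), 0L)
  # but the unconstrained strategy still finds the path
  expect_equal(predict_links(kg2, "onehop", "none")$pairs$score, 7L)
  # no protein expression edges at all: protein mode is empty
  expect_equal(nrow(predict_links(kg, "onehop", "protein")$pairs), 0L)
})

test_that("directly linked pairs are never predicted", {
  kg <- toy_onehop_kg()
  eds <- rbind(kg$edges,
               data.table::data.table(source = "X", target = "D1",
                                      rtype = "hasDisease", first_year = 1999L,
                                      last_year = 2000L, n_pubs = 1L,
                                      pmids = list(character())))
  kg2 <- knowledge_graph(kg$entities, eds)
  expect_equal(nrow(predict_links(kg2, "onehop", "rna")$pairs), 0L)
})

test_that("predictions equal the exhaustive enumeration oracle", {
  for (seed in 1:40) {
    kg <- random_kg(seed)
    for (hops in c("onehop", "twohop")) for (mode in c("rna", "protein", "none")) {
      p <- predict_links(kg, hops, mode)
      ora <- oracle_pairs(oracle_paths(kg, if (hops == "onehop") 1L else 2L,
                                       mode))
      got <- as.data.frame(p$pairs[order(gene, disease),
                                   .(gene, disease, score)])
      rownames(got) <- rownames(ora) <- NULL
      expect_equal(got, ora)
    }
  }
})

test_that("undirected traversal expands on directed traversal", {
  for (seed in 1:10) {
    kg <- random_kg(seed)
    pd <- predict_links(kg, "onehop", "none")$pairs[, c("gene", "disease")]
    pu <- predict_links(kg, "onehop", "none", undirected_ppi = TRUE)$pairs
    miss <- pd[!pu[, c("gene", "disease")], on = c("gene", "disease")]
    expect_equal(nrow(miss), 0L)
    # undirected oracle agreement
    ora <- oracle_pairs(oracle_paths(kg, 1L, "none", undirected_ppi = TRUE))
    got <- as.data.frame(pu[order(gene, disease), .(gene, disease, score)])
    rownames(got) <- rownames(ora) <- NULL
    expect_equal(got, ora)
  }
})

test_that("tissue relaxation is monotone and union dominates components", {
  for (seed in 1:10) {
    kg <- random_kg(seed)
    keys <- function(p) paste(p$pairs$gene, p$pairs$disease)
    for (hops in c("onehop", "twohop")) {
      none <- predict_links(kg, hops, "none")
      rna <- predict_links(kg, hops, "rna")
      prot <- predict_links(kg, hops, "protein")
      expect_true(all(keys(rna) %in% keys(none)))
      expect_true(all(keys(prot) %in% keys(none)))
    }
    uni <- predict_links(kg, "union")
    parts <- list(predict_links(kg, "onehop", "rna"),
                  predict_links(kg, "onehop", "protein"),
                  predict_links(kg, "twohop", "rna"),
                  predict_links(kg, "twohop", "protein"))
    for (p in parts) {
      expect_true(all(keys(p) %in% keys(uni)))
      joined <- merge(p$pairs[, .(gene, disease, s = score)],
                      uni$pairs[, .(gene, disease, u = score)],
                      by = c("gene", "disease"))
      expect_true(all(joined$u >= joined$s))
    }
    # union score equals the max over constituent strategies
    best <- data.table::rbindlist(lapply(parts, function(p)
      p$pairs[, .(gene, disease, score)]))
    if (nrow(best)) {
      best <- best[, .(score = max(score)), by = .(gene, disease)]
      expect_equal(uni$pairs[order(gene, disease), .(gene, disease, score)],
                   best[order(gene, disease)])
    }
    # no path revisits a node; no predicted pair is directly linked
    direct <- kg$edges[kg$edges$rtype == "hasDisease", ]
    dk <- paste(direct$source, direct$target)
    expect_false(any(keys(uni) %in% dk))
    split_nodes <- strsplit(uni$paths$nodes, "|", fixed = TRUE)
    expect_true(all(vapply(split_nodes, anyDuplicated, integer(1)) == 0L))
  }
})

test_that("explain_pair enumerates and counts paths per hop level", {
  # constructed graph with exactly 2 one-hop and 3 two-hop rna-consistent
  # paths from X to D
  ents <- data.frame(
    id = c("X", "Y1", "Y2", "Z1", "Z2", "Z3", "D", "t"),
    etype = c(rep("Gene", 6), "Disease", "RNATissue"))
  gg <- data.frame(source = c("X", "X", "Y1", "Y1", "Y2"),
                   target = c("Y1", "Y2", "Z1", "Z2", "Z3"),
                   rtype = "Interaction")
  gd <- data.frame(source = c("Y1", "Y2", "Z1", "Z2", "Z3"), target = "D",
                   rtype = "hasDisease")
  expr <- data.frame(source = c("X", "Y1", "Y2", "Z1", "Z2", "Z3"),
                     target = "t", rtype = "hasRNAExpression")
  dated <- rbind(gg, gd)
  dated$first_year <- 2000L; dated$last_year <- 2001L
  dated$n_pubs <- c(5L, 4L, 3L, 2L, 1L, 10L, 20L, 30L, 40L, 50L)
  expr[, c("first_year", "last_year", "n_pubs")] <- NA_integer_
  kg <- knowledge_graph(ents, rbind(dated, expr))
  ex <- explain_pair(kg, "X", "D", "rna")
  expect_equal(ex$n_onehop, 2L)
  expect_equal(ex$n_twohop, 3L)
  # sorted by score descending; ties broken by node ids
  expect_equal(ex$paths$path_score, sort(ex$paths$path_score, decreasing = TRUE))
  # a gene with no outgoing interactions explains nothing
  ex0 <- explain_pair(kg, "Z3", "D", "rna")
  expect_equal(nrow(ex0$paths), 0L)
  expect_equal(c(ex0$n_onehop, ex0$n_twohop), c(0L, 0L))
  expect_error(explain_pair(kg, "nope", "D"), class = "tissuehop_lookup_error")
})

test_that("explain_pair counts match oracle enumeration per pair", {
  for (seed in 1:10) {
    kg <- random_kg(seed)
    genes <- entity_ids(kg, "Gene"); diseases <- entity_ids(kg, "Disease")
    o1 <- oracle_paths(kg, 1L, "rna")
    o2 <- oracle_paths(kg, 2L, "rna")
    for (g in genes[1:3]) for (d in diseases[1]) {
      ex <- explain_pair(kg, g, d, "rna")
      # oracle excludes direct pairs; mirror that for comparability
      direct <- any(kg$edges$rtype == "hasDisease" & kg$edges$source == g &
                      kg$edges$target == d)
      if (direct) next
      expect_equal(ex$n_onehop, sum(o1$gene == g & o1$disease == d))
      expect_equal(ex$n_twohop, sum(o2$gene == g & o2$disease == d))
    }
  }
})

test_that("path scores aggregate by max or sum", {
  expect_equal(score_paths(c(7L, 47L)), 47L)
  expect_equal(score_paths(c(7L, 47L), "sum"), 54L)
  expect_equal(score_paths(5L), 5L)
  expect_equal(score_paths(5L, "sum"), 5L)
  expect_error(score_paths(integer()), class = "tissuehop_domain_error")
  # sum aggregation equals the oracle sum over enumerated paths
  for (seed in 1:5) {
    kg <- random_kg(seed)
    p <- predict_links(kg, "onehop", "rna", aggregation = "sum")
    ora <- oracle_pairs(oracle_paths(kg, 1L, "rna"), aggregation = "sum")
    got <- as.data.frame(p$pairs[order(gene, disease), .(gene, disease, score)])
    rownames(got) <- rownames(ora) <- NULL
    expect_equal(got, ora)
  }
})
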