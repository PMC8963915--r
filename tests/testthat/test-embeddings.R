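test_that("triple extraction is one-to-one with the edge set", {
  kg <- random_kg(2)
  tri <- kg_triples(kg)
  expect_equal(nrow(tri$triples), nrow(kg$edges))
  back <- data.frame(source = tri$entity_ids[tri$triples[, "h"]],
                     rtype = tri$relation_ids[tri$triples[, "r"]],
                     target = tri$entity_ids[tri$triples[, "t"]])
  got <- back[order(back$rtype, back$source, back$target), ]
  want <- as.data.frame(kg$edges[order(rtype, source, target),
                                 .(source, rtype, target)])
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want[, c("source", "rtype", "target")])
  empty <- knowledge_graph(data.frame(id = "g", etype = "Gene"), data.frame())
  expect_error(kg_triples(empty), class = "tissuehop_domain_error")
})

test_that("scores have their closed forms at special configurations", {
  set.seed(1)
  par <- tissuehop:::.emb_init("transE", 4L, 8L)
  # h + r = t by construction gives a (floored) zero TransE score
  par$E[2, ] <- par$E[1, ] * 0.4
  par$R[1, ] <- par$E[2, ] - par$E[1, ]
  s <- tissuehop:::.emb_score_grad("transE", par, 1L, 1L, 2L,
                                   want_grad = FALSE)$s
  expect_lt(s, 1e-5)
  # DistMult with all-ones relation and h = t gives -||h||^2
  pd <- tissuehop:::.emb_init("distMult", 4L, 8L)
  pd$R[2, ] <- 1
  sd_ <- tissuehop:::.emb_score_grad("distMult", pd, 3L, 2L, 3L,
                                     want_grad = FALSE)$s
  expect_equal(sd_, -sum(pd$E[3, ]^2), tolerance = 1e-12)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(4)
  dim <- 5L
  for (method in c("transE", "transH", "transD", "distMult")) {
    par <- tissuehop:::.emb_init(method, 6L, dim)
    hi <- 2L; ri <- 3L; ti <- 5L
    res <- tissuehop:::.emb_score_grad(method, par, hi, ri, ti)
    blocks <- list(gH = c("E", hi), gT = c("E", ti))
    if (!is.null(res$gR)) blocks$gR <- c("R", ri)
    if (method == "transH") { blocks$gW <- c("W", ri); blocks$gD <- c("D", ri) }
    if (method == "transD") {
      blocks$gEp_h <- c("Ep", hi); blocks$gEp_t <- c("Ep", ti)
      blocks$gRp <- c("Rp", ri)
    }
    for (nm in names(blocks)) {
      blk <- blocks[[nm]][1]; row <- as.integer(blocks[[nm]][2])
      num <- vapply(seq_len(dim), function(k) {
        sp <- sm <- par
        sp[[blk]][row, k] <- sp[[blk]][row, k] + 1e-6
        sm[[blk]][row, k] <- sm[[blk]][row, k] - 1e-6
        (tissuehop:::.emb_score_grad(method, sp, hi, ri, ti, FALSE)$s -
           tissuehop:::.emb_score_grad(method, sm, hi, ri, ti, FALSE)$s) / 2e-6
      }, numeric(1))
      expect_equal(as.numeric(res[[nm]]), num, tolerance = 1e-5,
                   info = paste(method, nm))
    }
  }
})

test_that("training reduces the ranking loss and respects constraints", {
  kg <- random_kg(8)
  for (method in c("transE", "transH", "transD", "distMult")) {
    space <- train_embedding(kg, method, dim = 4L, epochs = 50L, lr = 0.01,
                             seed = 0L)
    expect_lt(tail(space$loss_trace, 1), space$loss_trace[1])
    expect_equal(dim(space$E), c(nrow(kg$entities), 4L))
    expect_setequal(rownames(space$E), kg$entities$id)
  }
  # TransE entity norms stay within the unit ball
  space <- train_embedding(kg, "transE", dim = 4L, epochs = 30L, seed = 1L)
  expect_true(all(sqrt(rowSums(space$E^2)) <= 1 + 1e-6))
  # determinism in the seed
  s1 <- train_embedding(kg, "transE", dim = 4L, epochs = 10L, seed = 3L)
  s2 <- train_embedding(kg, "transE", dim = 4L, epochs = 10L, seed = 3L)
  expect_identical(s1$E, s2$E)
  expect_error(train_embedding(kg, "transE", dim = 0L),
               class = "tissuehop_usage_error")
})

test_that("TransE scores are invariant under a global translation", {
  kg <- random_kg(3)
  space <- train_embedding(kg, "transE", dim = 6L, epochs = 5L, seed = 1L)
  tri <- kg_triples(kg)
  idx <- tri$triples[1:10, , drop = FALSE]
  s0 <- tissuehop:::.emb_score_grad("transE", space, idx[, "h"], idx[, "r"],
                                    idx[, "t"], FALSE)$s
  shifted <- space
  shifted$E <- shifted$E + matrix(rnorm(6), nrow(shifted$E), 6, byrow = TRUE)
  s1 <- tissuehop:::.emb_score_grad("transE", shifted, idx[, "h"], idx[, "r"],
                                    idx[, "t"], FALSE)$s
  expect_equal(s0, s1, tolerance = 1e-9)
})

test_that("pair metrics compute cosine and euclidean geometry", {
  sp <- structure(list(method = "transE", dim = 2L,
                       entity_ids = c("a", "b", "c", "z"),
                       E = rbind(a = c(1, 0), b = c(1, 0), c = c(3, 4),
                                 z = c(0, 0)),
                       config = list()), class = "embedding_space")
  prs <- data.frame(gene = c("a", "a", "a"), disease = c("b", "c", "b"))
  expect_equal(pair_metrics(sp, prs, "cosine")$value[1], 1)
  expect_equal(pair_metrics(sp, prs, "euclidean")$value[1], 0)
  # (0,0) vs (3,4) -> euclidean 5
  expect_equal(pair_metrics(sp, data.frame(gene = "z", disease = "c"),
                            "euclidean")$value, 5)
  # orthogonal unit vectors
  sp$E <- rbind(a = c(1, 0), b = c(0, 1), c = c(3, 4), z = c(0, 0))
  expect_equal(pair_metrics(sp, prs, "cosine")$value[1], 0)
  expect_equal(pair_metrics(sp, prs, "euclidean")$value[1], sqrt(2))
  expect_error(pair_metrics(sp, data.frame(gene = "z", disease = "b"),
                            "cosine"), class = "tissuehop_domain_error")
  expect_error(pair_metrics(sp, data.frame(gene = "missing", disease = "b")),
               class = "tissuehop_lookup_error")
  # hadamard mode appends the element-wise product
  had <- pair_metrics(sp, prs, "cosine", feature_mode = "hadamard")
  expect_equal(ncol(had), 3L + 2L)
})

test_that("balanced training sets are disjoint, labeled and reproducible", {
  train_pos <- data.table::CJ(gene = sprintf("g%d", 1:3), disease = "d1")
  gold <- data.table::data.table(gene = sprintf("g%d", 4:6), disease = "d2")
  cand <- data.table::CJ(gene = sprintf("g%d", 1:13),
                         disease = c("d2", "d3"))
  kg <- knowledge_graph(
    data.frame(id = c(sprintf("g%d", 1:13), "d1", "d2", "d3"),
               etype = c(rep("Gene", 13), rep("Disease", 3))),
    data.frame(source = train_pos$gene, target = train_pos$disease,
               rtype = "hasDisease", first_year = 2000L, last_year = 2001L,
               n_pubs = 1L))
  sets <- build_training_sets(kg, gold, cand, balance_seed = 1L)
  expect_equal(nrow(sets$train), 6L)    # 3 positives + 3 negatives
  expect_equal(nrow(sets$test), 6L)
  expect_equal(sum(sets$train$label), 3L)
  expect_equal(sum(sets$test$label), 3L)
  overlap <- merge(sets$train[sets$train$label == 0L, ],
                   sets$test[sets$test$label == 0L, ],
                   by = c("gene", "disease"))
  expect_equal(nrow(overlap), 0L)
  expect_identical(sets, build_training_sets(kg, gold, cand, balance_seed = 1L))
  expect_false(identical(sets$train,
                         build_training_sets(kg, gold, cand, 2L)$train))
  # explicit error when the negative pool is too small
  tiny <- rbind(gold, data.table::data.table(gene = c("g1", "g2"),
                                             disease = "d3"))
  expect_error(build_training_sets(kg, gold, tiny, 1L),
               regexp = "not enough negatives",
               class = "tissuehop_domain_error")
})

test_that("the classifier separates separable data and is seeded", {
  set.seed(1)
  n <- 300L
  x <- c(rnorm(n, -2), rnorm(n, 2))
  ftr <- data.table::data.table(gene = "g", disease = "d", value = x)
  y <- rep(c(0L, 1L), each = n)
  model <- train_classifier(ftr, y, n_trees = 100L, seed = 1L)
  sc <- predict_scores(model, ftr)
  expect_equal(classification_metrics(sc, y)$accuracy, 1, tolerance = 0.01)
  expect_identical(predict_scores(train_classifier(ftr, y, 100L, 1L), ftr), sc)
  expect_error(train_classifier(ftr, rep(1L, 2 * n)),
               class = "tissuehop_domain_error")
  # permuted labels give chance accuracy on balanced data
  set.seed(2)
  yp <- sample(y)
  mp <- train_classifier(ftr, yp, n_trees = 100L, seed = 1L)
  acc <- classification_metrics(predict_scores(mp, ftr), y)$accuracy
  expect_lt(abs(acc - 0.5), 0.06)
})

test_that("embedding QC bins conserve the overall gold fraction", {
  sp <- structure(list(method = "transE", dim = 1L,
                       entity_ids = c(sprintf("g%d", 1:10), "d"),
                       E = matrix(c(rep(0, 3), rep(1, 7), 0), ncol = 1,
                                  dimnames = list(c(sprintf("g%d", 1:10), "d"))),
                       config = list()), class = "embedding_space")
  cand <- data.frame(gene = sprintf("g%d", 1:10), disease = "d")
  gold <- data.frame(gene = sprintf("g%d", 1:3), disease = "d")
  qc <- embedding_qc(sp, gold, cand, n_bins = 2L)
  expect_equal(nrow(qc), 2L)
  expect_equal(sum(qc$n_gold), 3L)
  expect_equal(sum(qc$n), 10L)
  expect_equal(sum(qc$p_gold * qc$n, na.rm = TRUE) / sum(qc$n), 0.3)
  # gold at distance ~0, negatives far, 2 bins: probabilities (1, 0)
  expect_equal(qc$p_gold, c(1, 0))
  expect_error(embedding_qc(sp, gold, cand[0, ], 2L),
               class = "tissuehop_domain_error")
  expect_error(embedding_qc(sp, gold, cand, 1L),
               class = "tissuehop_usage_error")
})

test_that("embedding spaces round-trip through the text serialization", {
  kg <- random_kg(5)
  space <- train_embedding(kg, "distMult", dim = 5L, epochs = 5L, seed = 2L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_embedding(space, path)
  back <- read_embedding(path)
  expect_equal(back$method, "distMult")
  expect_equal(back$dim, 5L)
  expect_equal(back$entity_ids, space$entity_ids)
  expect_equal(back$E, space$E, tolerance = 1e-8)
})

test_that("walk embeddings train and cover every connected entity", {
  kg <- random_kg(6)
  space <- train_embedding(kg, "walk", dim = 6L, epochs = 2L, seed = 1L,
                           n_walks = 3L, walk_length = 3L)
  expect_equal(nrow(space$E), nrow(kg$entities))
  expect_true(all(is.finite(space$E)))
})
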