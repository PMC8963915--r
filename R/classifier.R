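#' All gene-disease pairs of a graph without a direct association
#'
#' The widest negative pool for classifier construction: the full
#' gene x disease cross product minus the directly linked pairs. Useful on
#' small benchmark graphs where the two-hop candidate universe leaves too
#' few pairs to balance the labeled sets.
#'
#' @param kg a `knowledge_graph`.
#' @return data.table of `gene`, `disease` pairs.
#' @export
unlinked_pairs <- function(kg) {
  allp <- CJ(gene = entity_ids(kg, "Gene"),
             disease = entity_ids(kg, "Disease"))
  direct <- kg$edges[rtype == "hasDisease", .(gene = source, disease = target)]
  allp[!direct, on = c("gene", "disease")]
}

#' Build balanced labeled train/test pair tables
#'
#' Training positives are the direct gene-disease edges of the pre-cutoff
#' graph; test positives are the post-cutoff gold-standard pairs. Negatives
#' are sampled without replacement from candidate pairs that are neither
#' training positives nor gold, balanced 1:1 within each set and disjoint
#' between the two sets.
#'
#' @param train_graph the pre-cutoff `knowledge_graph`.
#' @param gold a `gold_standard` or data.table of pairs.
#' @param candidates a `candidate_universe` or data.table of pairs.
#' @param balance_seed RNG seed for negative sampling.
#' @return list with data.tables `train` and `test`, each with columns
#'   `gene`, `disease`, `label` (1 = positive, 0 = negative).
#' @export
build_training_sets <- function(train_graph, gold, candidates, balance_seed = 1L) {
  gp <- gold_pairs_of(gold)
  cand <- if (inherits(candidates, "candidate_universe"))
    candidates$pairs[, .(gene, disease)] else
      unique(as.data.table(candidates)[, .(gene, disease)])
  if (nrow(gp[!cand, on = c("gene", "disease")]))
    kg_stop("gold standard must be a subset of the candidate pairs",
            "tissuehop_usage_error")
  train_pos <- unique(train_graph$edges[rtype == "hasDisease",
                                        .(gene = source, disease = target)])
  neg_pool <- cand[!gp, on = c("gene", "disease")]
  neg_pool <- neg_pool[!train_pos, on = c("gene", "disease")]
  need <- nrow(train_pos) + nrow(gp)
  if (nrow(neg_pool) < need)
    kg_stop(sprintf("not enough negatives: need %d, only %d available",
                    need, nrow(neg_pool)), "tissuehop_domain_error")
  set.seed(balance_seed)
  setorder(neg_pool, gene, disease)           # order-independent of input
  pick <- sample.int(nrow(neg_pool), need)
  train_neg <- neg_pool[pick[seq_len(nrow(train_pos))]]
  test_neg <- neg_pool[pick[nrow(train_pos) + seq_len(nrow(gp))]]
  train <- rbind(train_pos[, .(gene, disease, label = 1L)],
                 train_neg[, .(gene, disease, label = 0L)])
  test <- rbind(gp[, .(gene, disease, label = 1L)],
                test_neg[, .(gene, disease, label = 0L)])
  setorder(train, gene, disease)
  setorder(test, gene, disease)
  list(train = train[], test = test[])
}

#' Train a random-forest link classifier on pair features
#'
#' A bagged ensemble of decision trees with per-tree feature subsampling
#' (via \pkg{randomForest}); the prediction score of a pair is the fraction
#' of trees voting positive and class labels use a 0.5 threshold.
#' Deterministic given `seed`.
#'
#' @param features data.table from [pair_metrics()] (columns `gene`,
#'   `disease`, feature columns).
#' @param labels integer/numeric vector of 0/1 labels, one per feature row,
#'   containing both classes.
#' @param n_trees number of trees (default 500).
#' @param seed RNG seed.
#' @return object of class `link_classifier`.
#' @export
train_classifier <- function(features, labels, n_trees = 500L, seed = 1L) {
  x <- feature_matrix(features)
  if (!all(is.finite(as.matrix(x))))
    kg_stop("features must be finite", "tissuehop_domain_error")
  y <- factor(labels, levels = c(0L, 1L))
  if (length(unique(labels)) < 2L)
    kg_stop("training labels must contain both classes",
            "tissuehop_domain_error")
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
  structure(list(model = rf, feature_cols = colnames(x),
                 n_trees = n_trees, seed = seed),
            class = "link_classifier")
}

#' @rdname train_classifier
#' @param model a `link_classifier`.
#' @return `predict_scores`: numeric vector of positive-vote fractions in
#'   `[0, 1]`, one per feature row.
#' @export
predict_scores <- function(model, features) {
  x <- feature_matrix(features)
  x <- x[, model$feature_cols, drop = FALSE]
  unname(predict(model$model, newdata = x, type = "prob")[, "1"])
}

#' Classification metrics of scores against 0/1 labels at threshold 0.5
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels 0/1 labels.
#' @return list with `precision`, `recall`, `f1`, `accuracy`.
#' @export
classification_metrics <- function(scores, labels) {
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       accuracy = mean(pred == labels))
}

feature_matrix <- function(features) {
  dt <- as.data.table(features)
  cols <- setdiff(names(dt), c("gene", "disease", "label"))
  if (length(cols) == 0L)
    kg_stop("no feature columns found", "tissuehop_schema_error")
  as.data.frame(dt[, ..cols])
}
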