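#' Overall precision, recall and F1 of a predicted link set
#'
#' True positives are predicted pairs that appear in the gold standard;
#' false positives are predicted pairs that do not; false negatives are
#' gold pairs that were not predicted. Precision is reported as 0 (with a
#' `flag` noting the degenerate case) when nothing was predicted, so that
#' null distributions remain numeric.
#'
#' @param predictions a `link_predictions` object, or data.table of unique
#'   `gene`, `disease` pairs.
#' @param gold a `gold_standard` or data.table of `gene`, `disease` pairs
#'   (non-empty).
#' @return list with `precision`, `recall`, `f1`, counts `tp`, `fp`, `fn`
#'   and `flag` (`NA` or `"no_predictions"`).
#' @export
overall_metrics <- function(predictions, gold) {
  pred <- prediction_pairs_of(predictions)
  gp <- gold_pairs_of(gold)
  if (nrow(gp) == 0L)
    kg_stop("gold standard must be non-empty", "tissuehop_domain_error")
  if (anyDuplicated(pred, by = c("gene", "disease")))
    kg_stop("prediction pairs must be unique", "tissuehop_usage_error")
  tp <- nrow(pred[gp, on = c("gene", "disease"), nomatch = NULL])
  fp <- nrow(pred) - tp
  fn <- nrow(gp) - tp
  flag <- NA_character_
  if (nrow(pred) == 0L) {
    precision <- 0
    flag <- "no_predictions"
  } else precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if ((precision + recall) > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, flag = flag)
}

#' Precision among the top-k ranked predictions
#'
#' Predictions are ranked by score descending with deterministic
#' tie-breaking (gene id, then disease id); the fraction of gold pairs in
#' the top `min(k, n)` is returned (the full list is used when it is
#' shorter than `k`).
#'
#' @param predictions a `link_predictions` object or data.table with
#'   `gene`, `disease`, `score`.
#' @param gold gold pairs as in [overall_metrics()].
#' @param k number of top predictions considered (> 0); default 100.
#' @return precision in `[0, 1]` (0 for an empty prediction list).
#' @export
precision_at_k <- function(predictions, gold, k = 100L) {
  if (k <= 0L) kg_stop("k must be positive", "tissuehop_usage_error")
  pred <- prediction_pairs_of(predictions, need_score = TRUE)
  if (nrow(pred) == 0L) return(0)
  gp <- gold_pairs_of(gold)
  setorder(pred, -score, gene, disease)
  top <- head(pred, min(k, nrow(pred)))
  nrow(top[gp, on = c("gene", "disease"), nomatch = NULL]) / nrow(top)
}

#' ROC and precision-recall curves over a scored candidate universe
#'
#' Every candidate pair not present in `scores` receives a score of 0 (the
#' convention for pairs the hop-based methods did not predict, which makes
#' the terminal curve segment the random-rank tail). Thresholds sweep the
#' distinct score values in decreasing order with tie grouping: all pairs
#' of equal score enter together. AUROC is computed by the trapezoid rule,
#' AUPRC by step interpolation (precision held at each threshold over its
#' recall increment).
#'
#' @param candidates a `candidate_universe` or data.table of `gene`,
#'   `disease` pairs.
#' @param scores data.table with `gene`, `disease`, `score` (subset of the
#'   candidates; missing pairs scored 0).
#' @param gold gold pairs; must be a non-empty proper subset of the
#'   candidates.
#' @return list with `roc` (data.table `threshold`, `fpr`, `tpr`), `pr`
#'   (data.table `threshold`, `recall`, `precision`), `auroc`, `auprc`.
#' @export
ranked_curves <- function(candidates, scores, gold) {
  cand <- if (inherits(candidates, "candidate_universe"))
    candidates$pairs[, .(gene, disease)] else
      unique(as.data.table(candidates)[, .(gene, disease)])
  gp <- gold_pairs_of(gold)
  if (nrow(gp) == 0L || nrow(gp) >= nrow(cand))
    kg_stop("gold must be a non-empty proper subset of the candidates",
            "tissuehop_domain_error")
  if (nrow(gp[!cand, on = c("gene", "disease")]))
    kg_stop("every gold pair must be a candidate pair", "tissuehop_usage_error")
  sc <- unique(as.data.table(scores)[, .(gene, disease, score)],
               by = c("gene", "disease"))
  tab <- sc[cand, on = c("gene", "disease")]
  tab[is.na(score), score := 0]
  tab[, is_gold := FALSE]
  tab[gp, on = c("gene", "disease"), is_gold := TRUE]

  P <- sum(tab$is_gold); Neg <- nrow(tab) - P
  grp <- tab[, .(tp = sum(is_gold), n = .N), by = score]
  setorder(grp, -score)
  grp[, `:=`(cum_tp = cumsum(tp), cum_n = cumsum(n))]
  grp[, `:=`(tpr = cum_tp / P, fpr = (cum_n - cum_tp) / Neg,
             precision = cum_tp / cum_n)]
  roc <- rbind(data.table(threshold = Inf, fpr = 0, tpr = 0),
               grp[, .(threshold = score, fpr, tpr)])
  pr <- grp[, .(threshold = score, recall = tpr, precision)]
  auroc <- sum(diff(roc$fpr) * (head(roc$tpr, -1L) + tail(roc$tpr, -1L)) / 2)
  auprc <- sum(diff(c(0, pr$recall)) * pr$precision)
  list(roc = roc[], pr = pr[], auroc = auroc, auprc = auprc)
}

#' Per-disease performance breakdown
#'
#' One row per disease appearing in the gold standard or among the
#' predictions, with its gold count, prediction count, true positives and
#' precision/recall/F1. Diseases with no predictions get precision 0 and a
#' flag. Sorted by precision (descending), then disease id.
#'
#' @param predictions a `link_predictions` object or data.table of `gene`,
#'   `disease` pairs.
#' @param gold gold pairs as in [overall_metrics()].
#' @return data.table with columns `disease`, `n_gold`, `n_predicted`,
#'   `n_tp`, `precision`, `recall`, `f1`, `flag`.
#' @export
per_disease_report <- function(predictions, gold) {
  pred <- prediction_pairs_of(predictions)
  gp <- gold_pairs_of(gold)
  diseases <- sort(unique(c(pred$disease, gp$disease)))
  tp <- pred[gp, on = c("gene", "disease"), nomatch = NULL]
  tab <- data.table(disease = diseases)
  tab <- merge(tab, gp[, .(n_gold = .N), by = disease], by = "disease", all.x = TRUE)
  tab <- merge(tab, pred[, .(n_predicted = .N), by = disease], by = "disease", all.x = TRUE)
  tab <- merge(tab, tp[, .(n_tp = .N), by = disease], by = "disease", all.x = TRUE)
  for (col in c("n_gold", "n_predicted", "n_tp"))
    tab[is.na(get(col)), (col) := 0L]
  tab[, flag := fifelse(n_predicted == 0L, "no_predictions", NA_character_)]
  tab[, precision := fifelse(n_predicted > 0L, n_tp / n_predicted, 0)]
  tab[, recall := fifelse(n_gold > 0L, n_tp / n_gold, 0)]
  tab[, f1 := fifelse(precision + recall > 0,
                      2 * precision * recall / (precision + recall), 0)]
  setorder(tab, -precision, disease)
  setcolorder(tab, c("disease", "n_gold", "n_predicted", "n_tp",
                     "precision", "recall", "f1", "flag"))
  tab[]
}

prediction_pairs_of <- function(predictions, need_score = FALSE) {
  dt <- if (inherits(predictions, "link_predictions")) predictions$pairs
  else as.data.table(predictions)
  cols <- c("gene", "disease", if (need_score) "score")
  missing <- setdiff(cols, names(dt))
  if (length(missing))
    kg_stop(sprintf("predictions lack column(s): %s",
                    paste(missing, collapse = ", ")), "tissuehop_schema_error")
  copy(dt[, ..cols])
}
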