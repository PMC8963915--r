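#' Extract the triple set of a knowledge graph
#'
#' Entities are indexed in sorted-id order; the four relation types have
#' fixed indices (Interaction, hasDisease, hasRNAExpression,
#' hasProteinExpression). One triple per edge.
#'
#' @param kg a non-empty `knowledge_graph`.
#' @return list with `triples` (integer matrix, columns `h`, `r`, `t`),
#'   `entity_ids`, `entity_types`, `relation_ids`.
#' @export
kg_triples <- function(kg) {
  if (nrow(kg$edges) == 0L)
    kg_stop("cannot extract triples from a graph without edges",
            "tissuehop_domain_error")
  ids <- sort(kg$entities$id)
  etypes <- kg$entities$etype[match(ids, kg$entities$id)]
  tri <- cbind(h = match(kg$edges$source, ids),
               r = match(kg$edges$rtype, RELATION_TYPES),
               t = match(kg$edges$target, ids))
  list(triples = tri, entity_ids = ids, entity_types = etypes,
       relation_ids = RELATION_TYPES)
}

# ---------------------------------------------------------------------------
# Per-method scores and analytic gradients (vectorized over a batch).
# Convention: lower score = more plausible, for every method (DistMult's
# bilinear score is negated accordingly). Translational scores use the L2
# norm with a small floor to keep gradients finite at zero distance.
# Returns list(s, and gradients named by the parameter block they address).
# ---------------------------------------------------------------------------

.emb_score_grad <- function(method, par, hi, ri, ti, want_grad = TRUE) {
  H <- par$E[hi, , drop = FALSE]
  T_ <- par$E[ti, , drop = FALSE]
  R <- par$R[ri, , drop = FALSE]
  eps <- 1e-12
  if (method == "transE") {
    d <- H + R - T_
    s <- sqrt(rowSums(d * d) + eps)
    if (!want_grad) return(list(s = s))
    u <- d / s
    list(s = s, gH = u, gR = u, gT = -u)
  } else if (method == "transH") {
    W <- par$W[ri, , drop = FALSE]   # unit hyperplane normals
    D <- par$D[ri, , drop = FALSE]   # in-hyperplane translations
    wh <- rowSums(W * H); wt <- rowSums(W * T_)
    Hp <- H - wh * W
    Tp <- T_ - wt * W
    d <- Hp + D - Tp
    s <- sqrt(rowSums(d * d) + eps)
    if (!want_grad) return(list(s = s))
    u <- d / s
    uw <- rowSums(u * W)
    gH <- u - uw * W
    gT <- -(u - uw * W)
    A <- H - T_                       # d = A - (w.A) w + D
    gW <- -(uw * A + rowSums(W * A) * u)
    list(s = s, gH = gH, gR = NULL, gT = gT, gW = gW, gD = u)
  } else if (method == "transD") {
    Hp_e <- par$Ep[hi, , drop = FALSE]  # entity projection vectors
    Tp_e <- par$Ep[ti, , drop = FALSE]
    Rp <- par$Rp[ri, , drop = FALSE]    # relation projection vectors
    ph <- rowSums(Hp_e * H)             # h_p . h
    pt <- rowSums(Tp_e * T_)
    Hproj <- H + ph * Rp
    Tproj <- T_ + pt * Rp
    d <- Hproj + R - Tproj
    s <- sqrt(rowSums(d * d) + eps)
    if (!want_grad) return(list(s = s))
    u <- d / s
    ur <- rowSums(u * Rp)
    list(s = s,
         gH = u + ur * Hp_e,
         gR = u,
         gT = -(u + ur * Tp_e),
         gEp_h = ur * H,
         gEp_t = -ur * T_,
         gRp = ph * u - pt * u)
  } else if (method == "distMult") {
    s <- -rowSums(H * R * T_)
    if (!want_grad) return(list(s = s))
    list(s = s, gH = -R * T_, gR = -H * T_, gT = -H * R)
  } else kg_stop(sprintf("unknown embedding method '%s'", method),
                 "tissuehop_usage_error")
}

.emb_init <- function(method, n_ent, dim, n_rel = length(RELATION_TYPES)) {
  b <- 6 / sqrt(dim)
  rmat <- function(n) matrix(runif(n * dim, -b, b), nrow = n)
  unit_rows <- function(m) m / pmax(sqrt(rowSums(m * m)), 1e-12)
  par <- list(E = unit_rows(rmat(n_ent)), R = rmat(n_rel))
  if (method == "transH") {
    par$W <- unit_rows(rmat(n_rel))
    par$D <- rmat(n_rel)
  }
  if (method == "transD") {
    par$Ep <- rmat(n_ent)
    par$Rp <- rmat(n_rel)
  }
  par
}

# scatter-add accumulated gradients into a parameter matrix
.apply_grad <- function(M, idx, G, lr) {
  agg <- rowsum(G, group = idx)
  rows <- as.integer(rownames(agg))
  M[rows, ] <- M[rows, , drop = FALSE] - lr * agg
  M
}

#' Train knowledge-graph embeddings
#'
#' Learns fixed-dimension entity (and relation) vectors by minimizing a
#' margin-based ranking loss, `sum(max(0, margin + f(pos) - f(neg)))`, over
#' the graph's triples against negatives obtained by corrupting the head or
#' tail (chosen uniformly) with a random entity of the same type (typed
#' negative sampling). Scores `f` per method: TransE
#' `||h + r - t||`; TransH `||h_perp + d_r - t_perp||` with projection on
#' the relation hyperplane; TransD `||(I + r_p h_p^T) h + r - (I + r_p
#' t_p^T) t||` via projection vectors; DistMult the negated bilinear
#' diagonal form `-sum(h * r * t)`. The `walk` method instead runs
#' truncated random walks over the (undirected) graph and fits skip-gram
#' with negative sampling on the walk corpus; it is experimental.
#'
#' Optimization is mini-batch SGD; after each batch, entity vectors of the
#' translational models are projected back onto the unit ball and TransH
#' hyperplane normals are renormalized. Training is deterministic given
#' `seed`.
#'
#' @param kg a non-empty `knowledge_graph` (see [strip_expression()] to
#'   train without tissue-expression edges).
#' @param method one of `"transE"`, `"transH"`, `"transD"`, `"distMult"`,
#'   `"walk"`.
#' @param dim embedding dimension (default 200).
#' @param epochs training epochs (default 200).
#' @param lr SGD learning rate.
#' @param margin ranking-loss margin.
#' @param batch_size mini-batch size.
#' @param n_negatives negatives per positive triple.
#' @param seed RNG seed.
#' @param n_walks,walk_length,window,walk_negatives walk-method settings.
#' @return object of class `embedding_space`: list with `method`, `dim`,
#'   `entity_ids`, `entity_types`, `E` (entity matrix, rownames = ids),
#'   relation parameters, `config` and `loss_trace` (per-epoch loss).
#' @export
train_embedding <- function(kg, method = c("transE", "transH", "transD",
                                           "distMult", "walk"),
                            dim = 200L, epochs = 200L, lr = 0.01,
                            margin = 1, batch_size = 256L, n_negatives = 1L,
                            seed = 1L, n_walks = 10L, walk_length = 4L,
                            window = 2L, walk_negatives = 5L) {
  method <- match.arg(method)
  if (dim <= 0L) kg_stop("dim must be positive", "tissuehop_usage_error")
  tri <- kg_triples(kg)
  config <- list(dim = dim, epochs = epochs, lr = lr, margin = margin,
                 batch_size = batch_size, n_negatives = n_negatives,
                 seed = seed)
  if (method == "walk")
    return(train_walk_embedding(kg, tri, dim, epochs, lr, seed, n_walks,
                                walk_length, window, walk_negatives, config))
  set.seed(seed)
  n_ent <- length(tri$entity_ids)
  n_tri <- nrow(tri$triples)
  # typed negative sampling: corrupt an endpoint within its entity type so
  # negatives are informative (a disease replaced by a tissue is trivially
  # implausible and contributes no gradient signal)
  type_pool <- lapply(ENTITY_TYPES, function(tt) which(tri$entity_types == tt))
  names(type_pool) <- ENTITY_TYPES
  tri_htype <- tri$entity_types[tri$triples[, "h"]]
  tri_ttype <- tri$entity_types[tri$triples[, "t"]]
  par <- .emb_init(method, n_ent, dim)
  translational <- method %in% c("transE", "transH", "transD")
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_tri)
    ep_loss <- 0
    for (start in seq(1L, n_tri, by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1L, n_tri)]
      hb <- tri$triples[bi, "h"]; rb <- tri$triples[bi, "r"]
      tb <- tri$triples[bi, "t"]
      for (neg in seq_len(n_negatives)) {
        corrupt_head <- runif(length(bi)) < 0.5
        repl_h <- vapply(type_pool[tri_htype[bi]], function(p)
          p[sample.int(length(p), 1L)], integer(1))
        repl_t <- vapply(type_pool[tri_ttype[bi]], function(p)
          p[sample.int(length(p), 1L)], integer(1))
        hn <- ifelse(corrupt_head, repl_h, hb)
        tn <- ifelse(corrupt_head, tb, repl_t)
        pos <- .emb_score_grad(method, par, hb, rb, tb)
        ngt <- .emb_score_grad(method, par, hn, rb, tn)
        act <- (margin + pos$s - ngt$s) > 0
        ep_loss <- ep_loss + sum(pmax(0, margin + pos$s - ngt$s))
        if (!any(act)) next
        # d loss / d theta = grad_pos - grad_neg on active samples
        eidx <- c(hb[act], tb[act], hn[act], tn[act])
        egrad <- rbind(pos$gH[act, , drop = FALSE], pos$gT[act, , drop = FALSE],
                       -ngt$gH[act, , drop = FALSE], -ngt$gT[act, , drop = FALSE])
        par$E <- .apply_grad(par$E, eidx, egrad, lr)
        if (!is.null(pos$gR)) {
          par$R <- .apply_grad(par$R, c(rb[act], rb[act]),
                               rbind(pos$gR[act, , drop = FALSE],
                                     -ngt$gR[act, , drop = FALSE]), lr)
        }
        if (method == "transH") {
          par$W <- .apply_grad(par$W, c(rb[act], rb[act]),
                               rbind(pos$gW[act, , drop = FALSE],
                                     -ngt$gW[act, , drop = FALSE]), lr)
          par$D <- .apply_grad(par$D, c(rb[act], rb[act]),
                               rbind(pos$gD[act, , drop = FALSE],
                                     -ngt$gD[act, , drop = FALSE]), lr)
          par$W <- par$W / pmax(sqrt(rowSums(par$W^2)), 1e-12)
        }
        if (method == "transD") {
          par$Ep <- .apply_grad(par$Ep, c(hb[act], tb[act], hn[act], tn[act]),
                                rbind(pos$gEp_h[act, , drop = FALSE],
                                      pos$gEp_t[act, , drop = FALSE],
                                      -ngt$gEp_h[act, , drop = FALSE],
                                      -ngt$gEp_t[act, , drop = FALSE]), lr)
          par$Rp <- .apply_grad(par$Rp, c(rb[act], rb[act]),
                                rbind(pos$gRp[act, , drop = FALSE],
                                      -ngt$gRp[act, , drop = FALSE]), lr)
        }
        if (translational || method == "distMult") {
          nrm <- sqrt(rowSums(par$E^2))
          over <- nrm > 1
          if (any(over)) par$E[over, ] <- par$E[over, , drop = FALSE] / nrm[over]
        }
      }
    }
    loss_trace[ep] <- ep_loss
  }
  rownames(par$E) <- tri$entity_ids
  structure(c(list(method = method, dim = dim,
                   entity_ids = tri$entity_ids,
                   entity_types = tri$entity_types,
                   config = config, loss_trace = loss_trace), par),
            class = "embedding_space")
}

# skip-gram with negative sampling on truncated random walks
train_walk_embedding <- function(kg, tri, dim, epochs, lr, seed, n_walks,
                                 walk_length, window, walk_negatives, config) {
  set.seed(seed)
  ids <- tri$entity_ids
  n_ent <- length(ids)
  si <- match(kg$edges$source, ids); ti <- match(kg$edges$target, ids)
  adj <- split(c(ti, si), c(si, ti))   # undirected adjacency
  b <- 6 / sqrt(dim)
  Win <- matrix(runif(n_ent * dim, -b, b), nrow = n_ent)
  Wout <- matrix(0, n_ent, dim)
  # walk corpus; skip-gram pairs accumulated in lists (no quadratic appends)
  acc_c <- vector("list", n_ent * n_walks)
  acc_o <- vector("list", n_ent * n_walks)
  k <- 0L
  for (v in seq_len(n_ent)) {
    if (is.null(adj[[as.character(v)]])) next
    for (w in seq_len(n_walks)) {
      walk <- integer(walk_length + 1L)
      walk[1L] <- v
      L <- walk_length + 1L
      for (s in seq_len(walk_length)) {
        nb <- adj[[as.character(walk[s])]]
        if (is.null(nb)) { L <- s; break }
        walk[s + 1L] <- nb[sample.int(length(nb), 1L)]
      }
      walk <- walk[seq_len(L)]
      cc <- oo <- vector("list", L)
      for (s in seq_len(L)) {
        ctx <- setdiff(seq(max(1L, s - window), min(L, s + window)), s)
        cc[[s]] <- rep(walk[s], length(ctx))
        oo[[s]] <- walk[ctx]
      }
      k <- k + 1L
      acc_c[[k]] <- unlist(cc)
      acc_o[[k]] <- unlist(oo)
    }
  }
  centers <- unlist(acc_c[seq_len(k)])
  contexts <- unlist(acc_o[seq_len(k)])
  n_pairs <- length(centers)
  loss_trace <- numeric(epochs)
  if (n_pairs) {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_pairs)
      ep_loss <- 0
      for (start in seq(1L, n_pairs, by = 512L)) {
        bi <- ord[start:min(start + 511L, n_pairs)]
        ci <- centers[bi]; oi <- contexts[bi]
        Vc <- Win[ci, , drop = FALSE]; Uo <- Wout[oi, , drop = FALSE]
        sig <- 1 / (1 + exp(-rowSums(Vc * Uo)))
        ep_loss <- ep_loss - sum(log(pmax(sig, 1e-12)))
        gC <- (sig - 1) * Uo
        gO <- (sig - 1) * Vc
        for (k in seq_len(walk_negatives)) {
          ni <- sample.int(n_ent, length(bi), replace = TRUE)
          Un <- Wout[ni, , drop = FALSE]
          sn <- 1 / (1 + exp(-rowSums(Vc * Un)))
          ep_loss <- ep_loss - sum(log(pmax(1 - sn, 1e-12)))
          gC <- gC + sn * Un
          Wout <- .apply_grad(Wout, ni, sn * Vc, lr)
        }
        Win <- .apply_grad(Win, ci, gC, lr)
        Wout <- .apply_grad(Wout, oi, gO, lr)
      }
      loss_trace[ep] <- ep_loss
    }
  }
  rownames(Win) <- ids
  structure(list(method = "walk", dim = dim, entity_ids = ids,
                 entity_types = tri$entity_types, E = Win,
                 R = matrix(0, length(RELATION_TYPES), dim),
                 config = c(config, list(n_walks = n_walks,
                                         walk_length = walk_length,
                                         window = window,
                                         walk_negatives = walk_negatives)),
                 loss_trace = loss_trace),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space> %s, dim %d, %d entities (final loss %.3f)\n",
              x$method, x$dim, length(x$entity_ids),
              tail(x$loss_trace, 1L)))
  invisible(x)
}

#' Score a single triple in an embedding space
#'
#' Lower is more plausible for every method (the DistMult bilinear score is
#' negated to share this convention).
#'
#' @param space an `embedding_space` (not `"walk"`).
#' @param head,tail entity ids.
#' @param relation relation name.
#' @return numeric score.
#' @export
triple_score <- function(space, head, relation, tail) {
  hi <- match(head, space$entity_ids)
  ti <- match(tail, space$entity_ids)
  ri <- match(relation, RELATION_TYPES)
  if (is.na(hi) || is.na(ti) || is.na(ri))
    kg_stop("unknown entity or relation in triple_score", "tissuehop_lookup_error")
  if (space$method == "walk")
    kg_stop("triple_score is undefined for the walk method", "tissuehop_usage_error")
  .emb_score_grad(space$method, space, hi, ri, ti, want_grad = FALSE)$s
}

#' Pairwise embedding features for gene-disease pairs
#'
#' Cosine similarity is `dot(a, b) / (||a|| ||b||)`; Euclidean distance is
#' the L2 norm of `a - b`. The default `"scalar"` feature mode yields the
#' single metric value per pair; `"hadamard"` appends the element-wise
#' product of the two embeddings to the scalar.
#'
#' @param space an `embedding_space`.
#' @param pairs data.table/data.frame with columns `gene`, `disease` (ids
#'   must all be embedded).
#' @param metric `"cosine"` or `"euclidean"`.
#' @param feature_mode `"scalar"` or `"hadamard"`.
#' @return data.table `gene`, `disease`, then feature column(s) (`value`
#'   for scalar mode; `value` plus `f1..fdim` for hadamard).
#' @export
pair_metrics <- function(space, pairs, metric = c("cosine", "euclidean"),
                         feature_mode = c("scalar", "hadamard")) {
  metric <- match.arg(metric)
  feature_mode <- match.arg(feature_mode)
  pairs <- as.data.table(pairs)[, .(gene, disease)]
  ai <- match(pairs$gene, space$entity_ids)
  bi <- match(pairs$disease, space$entity_ids)
  if (anyNA(ai) || anyNA(bi))
    kg_stop(sprintf("entities not embedded: %s",
                    paste(head(unique(c(pairs$gene[is.na(ai)],
                                        pairs$disease[is.na(bi)])), 5L),
                          collapse = ", ")), "tissuehop_lookup_error")
  A <- space$E[ai, , drop = FALSE]
  B <- space$E[bi, , drop = FALSE]
  if (metric == "cosine") {
    na <- sqrt(rowSums(A * A)); nb <- sqrt(rowSums(B * B))
    zero <- c(pairs$gene[na == 0], pairs$disease[nb == 0])
    if (length(zero))
      kg_stop(sprintf("cosine undefined for zero-norm embedding(s): %s",
                      paste(unique(zero), collapse = ", ")),
              "tissuehop_domain_error")
    v <- rowSums(A * B) / (na * nb)
  } else {
    v <- sqrt(rowSums((A - B)^2))
  }
  out <- data.table(gene = pairs$gene, disease = pairs$disease, value = v)
  if (feature_mode == "hadamard") {
    had <- A * B
    colnames(had) <- paste0("f", seq_len(ncol(had)))
    out <- cbind(out, as.data.table(had))
  }
  out[]
}

#' Embedding quality control: gold probability by distance bin
#'
#' Bins the observed gene-disease distances into equal-width bins and
#' reports, per bin, the fraction of candidate pairs that are gold — a good
#' embedding shows this probability decreasing with distance.
#'
#' @param space an `embedding_space`.
#' @param gold gold pairs.
#' @param candidates a `candidate_universe` or data.table of pairs.
#' @param n_bins number of equal-width distance bins (>= 2).
#' @param metric `"euclidean"` (default) or `"cosine"` distance
#'   (`1 - similarity`).
#' @return data.table `bin`, `lower`, `upper`, `n`, `n_gold`, `p_gold`.
#' @export
embedding_qc <- function(space, gold, candidates, n_bins = 10L,
                         metric = "euclidean") {
  if (n_bins < 2L) kg_stop("n_bins must be >= 2", "tissuehop_usage_error")
  cand <- if (inherits(candidates, "candidate_universe"))
    candidates$pairs[, .(gene, disease)] else
      unique(as.data.table(candidates)[, .(gene, disease)])
  if (nrow(cand) == 0L)
    kg_stop("candidate set must be non-empty", "tissuehop_domain_error")
  gp <- gold_pairs_of(gold)
  d <- if (metric == "euclidean")
    pair_metrics(space, cand, "euclidean")$value
  else 1 - pair_metrics(space, cand, "cosine")$value
  rng <- range(d)
  if (rng[1] == rng[2]) rng[2] <- rng[1] + 1e-9
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(d, brk, rightmost.closed = TRUE), 1L), n_bins)
  cand[, `:=`(bin = bin, is_gold = FALSE)]
  cand[gp, on = c("gene", "disease"), is_gold := TRUE]
  out <- cand[, .(n = .N, n_gold = sum(is_gold)), keyby = bin]
  out <- out[data.table(bin = seq_len(n_bins)), on = "bin"]
  out[is.na(n), `:=`(n = 0L, n_gold = 0L)]
  out[, `:=`(lower = brk[bin], upper = brk[bin + 1L],
             p_gold = fifelse(n > 0L, n_gold / n, NA_real_))]
  setcolorder(out, c("bin", "lower", "upper", "n", "n_gold", "p_gold"))
  out[]
}

#' Serialize an embedding space to a plain-text file
#'
#' Header lines (prefixed `#`) record the method, dimension and training
#' configuration; then one line per entity: id followed by its
#' whitespace-separated coordinates.
#'
#' @param space an `embedding_space`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(space, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#method %s", space$method), con)
  writeLines(sprintf("#dim %d", space$dim), con)
  cfg <- space$config
  writeLines(sprintf("#config %s",
                     paste(sprintf("%s=%s", names(cfg),
                                   vapply(cfg, format, character(1))),
                           collapse = " ")), con)
  lines <- vapply(seq_along(space$entity_ids), function(i)
    paste(space$entity_ids[i],
          paste(formatC(space$E[i, ], format = "g", digits = 10),
                collapse = " ")), character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read an embedding space written by [write_embedding()]
#'
#' @param path file path.
#' @return an `embedding_space` (entity vectors and metadata only; relation
#'   parameters are not serialized).
#' @export
read_embedding <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  method <- sub("^#method ", "", hdr[grepl("^#method ", hdr)])
  dim <- as.integer(sub("^#dim ", "", hdr[grepl("^#dim ", hdr)]))
  parts <- strsplit(body, " +")
  ids <- vapply(parts, `[`, character(1), 1L)
  E <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  rownames(E) <- ids
  structure(list(method = method, dim = dim, entity_ids = ids,
                 entity_types = NULL, E = E, config = list(),
                 loss_trace = numeric()),
            class = "embedding_space")
}
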