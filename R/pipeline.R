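#' Parse a flat key=value run configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments are
#' ignored. Unknown keys raise a usage error. Defaults cover the full
#' synthetic benchmark.
#'
#' @param path configuration file, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return list of class `run_config`.
#' @export
parse_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    mode = "simulate",            # simulate | load
    out_dir = "tissuehop_run",
    seed = 1L, cutoff_year = 2010L,
    n_genes = 200L, n_diseases = 20L, n_rna_tissues = 6L,
    n_protein_tissues = 6L, p_signal = 0.5, p_noise = 0.01,
    interaction_path = NA_character_, disease_path = NA_character_,
    rna_path = NA_character_, protein_path = NA_character_,
    strategies = "onehop,twohop,union",
    tissue_modes = "rna,protein,none",
    aggregation = "max", undirected_ppi = FALSE,
    baseline_reps = 20L,
    embed_method = "transE", embed_dim = 50L, embed_epochs = 100L,
    embed_metric = "cosine", classifier_trees = 500L,
    temporal_years = "")
  int_keys <- c("seed", "cutoff_year", "n_genes", "n_diseases",
                "n_rna_tissues", "n_protein_tissues", "baseline_reps",
                "embed_dim", "embed_epochs", "classifier_trees")
  num_keys <- c("p_signal", "p_noise")
  lgl_keys <- "undirected_ppi"
  cfg <- defaults
  apply_kv <- function(cfg, key, value) {
    if (!key %in% names(defaults))
      kg_stop(sprintf("unknown config key '%s'", key), "tissuehop_usage_error")
    cfg[[key]] <-
      if (key %in% int_keys) as.integer(value)
      else if (key %in% num_keys) as.numeric(value)
      else if (key %in% lgl_keys) as.logical(value)
      else as.character(value)
    cfg
  }
  if (!is.null(path)) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L)
        kg_stop(sprintf("malformed config line: '%s'", ln),
                "tissuehop_usage_error")
      cfg <- apply_kv(cfg, trimws(kv[1L]), trimws(kv[2L]))
    }
    cfg$config_path <- path
  }
  for (key in names(overrides)) cfg <- apply_kv(cfg, key, overrides[[key]])
  structure(cfg, class = "run_config")
}

#' Run the prediction pipeline end to end
#'
#' Orchestrates the package modules under one seeded configuration.
#' Commands: `simulate` (write a synthetic benchmark), `build` (load and
#' validate edge tables), `characterize` (topology summary and temporal
#' evolution), `split` (time split, gold standard, candidates), `predict`
#' (hop-based predictions per strategy/tissue mode), `baseline`
#' (shuffled-label null distributions and z-tests), `embed` (embedding +
#' classifier track), `evaluate` (overall, ranked and per-disease
#' metrics), `explain` (path report for one pair), `all` (the whole
#' chain). Every command writes TSV artifacts plus a `manifest_<command>.json`
#' recording inputs, config, seed and package version.
#'
#' @param config a `run_config` (see [parse_run_config()]), or a path to a
#'   config file.
#' @param command one of the commands above.
#' @param gene,disease pair to explain (command `"explain"`).
#' @return named list of computed artifacts, invisibly.
#' @export
run_pipeline <- function(config = parse_run_config(), command = "all",
                         gene = NULL, disease = NULL) {
  if (is.character(config)) config <- parse_run_config(config)
  cmds <- c("simulate", "build", "characterize", "split", "predict",
            "baseline", "embed", "evaluate", "explain", "all")
  if (!command %in% cmds)
    kg_stop(sprintf("unknown command '%s' (expected one of %s)", command,
                    paste(cmds, collapse = ", ")), "tissuehop_usage_error")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(sprintf("[tissuehop] %s", sprintf(...)))

  state <- list(config = config, outputs = character())
  add_tsv <- function(state, name, dt) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    flat <- as.data.table(dt)
    for (col in names(flat))
      if (is.list(flat[[col]]))
        flat[[col]] <- vapply(flat[[col]], paste, character(1), collapse = ";")
    num <- names(flat)[vapply(flat, is.double, logical(1))]
    for (col in num) flat[[col]] <- formatC(flat[[col]], format = "f", digits = 6)
    fwrite(flat, path, sep = "\t")
    state$outputs <- c(state$outputs, path)
    state
  }

  get_kg <- function() {
    if (config$mode == "simulate") {
      gcfg <- generator_config(
        n_genes = config$n_genes, n_diseases = config$n_diseases,
        n_rna_tissues = config$n_rna_tissues,
        n_protein_tissues = config$n_protein_tissues,
        cutoff_year = config$cutoff_year,
        p_signal = config$p_signal, p_noise = config$p_noise,
        seed = config$seed)
      generate_kg(gcfg)$kg
    } else {
      load_edge_tables(config$interaction_path, config$disease_path,
                       rna_path = if (is.na(config$rna_path)) NULL else config$rna_path,
                       protein_path = if (is.na(config$protein_path)) NULL else config$protein_path)
    }
  }

  run_one <- function(cmd, state) {
    log_msg("running '%s' (seed %d)", cmd, config$seed)
    if (cmd == "simulate") {
      gcfg <- generator_config(
        n_genes = config$n_genes, n_diseases = config$n_diseases,
        n_rna_tissues = config$n_rna_tissues,
        n_protein_tissues = config$n_protein_tissues,
        cutoff_year = config$cutoff_year,
        p_signal = config$p_signal, p_noise = config$p_noise,
        seed = config$seed)
      bundle <- benchmark_bundle(gcfg, config$out_dir)
      state$bundle <- bundle
      state$kg <- bundle$kg
      state$outputs <- c(state$outputs, unname(bundle$files))
    } else if (cmd == "build") {
      state$kg <- state$kg %||% get_kg()
      s <- kg_summary(state$kg)
      state <- add_tsv(state, "kg_summary", data.table(
        measure = c(paste0("nodes_", names(s$n_nodes_by_type)),
                    paste0("edges_", names(s$n_edges_by_type)),
                    "nodes_total", "edges_total", "edge_density"),
        value = c(s$n_nodes_by_type, s$n_edges_by_type,
                  s$n_nodes, s$n_edges, s$edge_density)))
    } else if (cmd == "characterize") {
      state$kg <- state$kg %||% get_kg()
      s <- kg_summary(state$kg, topology = TRUE)
      state <- add_tsv(state, "degree_tables", s$degree)
      state <- add_tsv(state, "pagerank",
                       data.table(id = names(s$pagerank), score = s$pagerank))
      years <- if (nzchar(config$temporal_years)) {
        rng <- as.integer(strsplit(config$temporal_years, ",")[[1L]])
        seq(rng[1L], rng[2L])
      } else NULL
      if (!is.null(years))
        state <- add_tsv(state, "temporal_evolution",
                         temporal_evolution(state$kg, years))
    } else if (cmd == "split") {
      state$kg <- state$kg %||% get_kg()
      state$split <- time_split(state$kg, config$cutoff_year)
      state$gold <- build_gold_standard(state$split$train,
                                        state$split$post_edges,
                                        undirected_ppi = config$undirected_ppi)
      state$candidates <- enumerate_candidates(state$split$train,
                                               undirected_ppi = config$undirected_ppi)
      state <- add_tsv(state, "gold_standard", state$gold$pairs)
      state <- add_tsv(state, "candidates", state$candidates$pairs)
    } else if (cmd == "predict") {
      state <- ensure_split(state)
      preds <- list()
      for (strat in strsplit(config$strategies, ",")[[1L]]) {
        modes <- if (strat == "union") "none" else
          strsplit(config$tissue_modes, ",")[[1L]]
        for (mode in modes) {
          p <- predict_links(state$split$train, strat,
                             tissue_mode = if (strat == "union") "rna" else mode,
                             aggregation = config$aggregation,
                             undirected_ppi = config$undirected_ppi)
          preds[[p$strategy]] <- p
        }
      }
      state$predictions <- preds
      state <- add_tsv(state, "predictions",
                       rbindlist(lapply(preds, function(p)
                         p$pairs[, .(gene, disease, strategy, score, n_paths,
                                     best_path, shared_tissues)])))
    } else if (cmd == "baseline") {
      state <- ensure_split(state)
      state <- ensure_predictions(state)
      reports <- list()
      for (nm in names(state$predictions)) {
        p <- state$predictions[[nm]]
        if (p$strategy == "union") next
        sm <- strsplit(p$strategy, "_")[[1L]]
        obs <- overall_metrics(p, state$gold)
        bl <- random_baseline(state$split$train, state$gold,
                              strategy = sm[1L], tissue_mode = sm[2L],
                              n_reps = config$baseline_reps,
                              base_seed = config$seed,
                              undirected_ppi = config$undirected_ppi)
        reports[[nm]] <- baseline_report(obs, bl, strategy = p$strategy)
      }
      state$baselines <- reports
      state <- add_tsv(state, "baseline_report", rbindlist(reports))
    } else if (cmd == "embed") {
      state <- ensure_split(state)
      space <- train_embedding(state$split$train, config$embed_method,
                               dim = config$embed_dim,
                               epochs = config$embed_epochs,
                               seed = config$seed)
      sets <- build_training_sets(state$split$train, state$gold,
                                  unlinked_pairs(state$split$train),
                                  balance_seed = config$seed)
      ftr_train <- pair_metrics(space, sets$train, config$embed_metric)
      ftr_test <- pair_metrics(space, sets$test, config$embed_metric)
      model <- train_classifier(ftr_train, sets$train$label,
                                n_trees = config$classifier_trees,
                                seed = config$seed)
      scores <- predict_scores(model, ftr_test)
      state$embedding <- space
      state$classifier_metrics <- classification_metrics(scores, sets$test$label)
      emb_path <- file.path(config$out_dir, "embedding.txt")
      write_embedding(space, emb_path)
      state$outputs <- c(state$outputs, emb_path)
      state <- add_tsv(state, "classifier_scores",
                       data.table(sets$test[, .(gene, disease, label)],
                                  score = scores))
      state <- add_tsv(state, "classifier_metrics",
                       as.data.table(state$classifier_metrics))
    } else if (cmd == "evaluate") {
      state <- ensure_split(state)
      state <- ensure_predictions(state)
      rows <- lapply(state$predictions, function(p) {
        m <- overall_metrics(p, state$gold)
        curves <- tryCatch(
          ranked_curves(state$candidates, p$pairs[, .(gene, disease, score)],
                        state$gold),
          tissuehop_error = function(cnd) list(auroc = NA_real_, auprc = NA_real_))
        data.table(strategy = p$strategy, n_predicted = nrow(p$pairs),
                   precision = m$precision, recall = m$recall, f1 = m$f1,
                   precision_at_100 = precision_at_k(p, state$gold, 100L),
                   auroc = curves$auroc, auprc = curves$auprc)
      })
      state$eval_report <- rbindlist(rows)
      state <- add_tsv(state, "eval_report", state$eval_report)
      best <- names(state$predictions)[1L]
      state <- add_tsv(state, "per_disease",
                       per_disease_report(state$predictions[[best]], state$gold))
    } else if (cmd == "explain") {
      state$kg <- state$kg %||% get_kg()
      if (is.null(gene) || is.null(disease))
        kg_stop("explain requires gene and disease", "tissuehop_usage_error")
      ex <- explain_pair(state$kg, gene, disease)
      state$explanation <- ex
      cat(sprintf("%s -- %s: %d one-hop and %d two-hop path(s)\n",
                  gene, disease, ex$n_onehop, ex$n_twohop))
      if (nrow(ex$paths)) {
        shown <- head(ex$paths, 10L)
        for (i in seq_len(nrow(shown)))
          cat(sprintf("  %s  score=%d  pubs=%s  tissues=%s\n",
                      shown$nodes[i], shown$path_score[i],
                      paste(shown$edge_pubs[[i]], collapse = "+"),
                      paste(shown$shared_tissues[[i]], collapse = ";")))
      }
      state <- add_tsv(state, "explanation", ex$paths)
    }
    state
  }

  ensure_split <- function(state) {
    if (is.null(state$split)) state <- run_one("split", state)
    state
  }
  ensure_predictions <- function(state) {
    if (is.null(state$predictions)) state <- run_one("predict", state)
    state
  }

  chain <- if (command == "all") {
    c(if (config$mode == "simulate") "simulate" else "build",
      "characterize", "split", "predict", "baseline", "embed", "evaluate")
  } else command
  for (cmd in chain) state <- run_one(cmd, state)

  manifest <- list(
    command = command, seed = config$seed,
    config = unclass(config)[setdiff(names(config), "config_path")],
    config_hash = if (!is.null(config$config_path))
      unname(tools::md5sum(config$config_path)) else NA_character_,
    package_version = as.character(utils::packageVersion("tissuehop")),
    outputs = state$outputs)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir,
                                 paste0("manifest_", command, ".json")),
                       auto_unbox = TRUE, null = "null")
  invisible(state)
}
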