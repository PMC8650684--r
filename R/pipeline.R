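# Pipeline orchestration: run the full cascade from a structured config,
# write per-stage score tables, candidate lists, cluster reports and a
# reproducibility manifest.
#
# Two modes cover the two ways the cascade is used:
#   - "table": apply criteria (and optional chemotype clustering) to an
#     existing per-compound score table — the screening endgame.
#   - "synthetic": generate a planted-signal library, train the embedding
#     and both classifiers, mock-dock, score a held-out screening pool
#     end-to-end, and report enrichment of the planted binders.

#' Run the screening cascade from a configuration
#'
#' @param config A named list or the path of a YAML file. Top-level keys:
#'   `mode` ("synthetic" or "table"), `seed`, `outdir`, and a section named
#'   after the mode (see the package vignette for the full key reference).
#' @return Invisibly, a list with the per-stage outputs (score table,
#'   candidate list, enrichment, cluster assignment, manifest path).
#' @export
screen_run <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("no such config file: '%s'", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  mode <- config$mode %||% "synthetic"
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% stopf("config must name an 'outdir'")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  result <- switch(mode,
    synthetic = screen_run_synthetic(config$synthetic %||% list(), seed,
                                     outdir),
    table = screen_run_table(config$table %||%
                               stopf("mode 'table' needs a 'table' section"),
                             outdir),
    stopf("unknown mode '%s'", mode)
  )
  manifest <- list(
    package = "vscascade",
    version = as.character(utils::packageVersion("vscascade")),
    mode = mode, seed = seed, config = config,
    fixtures = fixture_checksums()[, c("file", "md5")],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  result$manifest <- manifest_path
  invisible(result)
}

screen_run_table <- function(tc, outdir) {
  records <- read_score_table(tc$scores %||%
                                stopf("table mode needs a 'scores' path"))
  criteria <- if (!is.null(tc$preset)) {
    criteria_preset(tc$preset, exclude = as.character(tc$exclude %||%
                                                        character()))
  } else {
    cascade_criteria(tc$min_deepbindbc, tc$max_docking, tc$min_dfcnn,
                     exclude = as.character(tc$exclude %||% character()))
  }
  kept <- apply_criteria(records, criteria)
  kept <- rank_candidates(kept, key = tc$rank_key %||% "deepbindbc")
  clusters <- NULL
  if (!is.null(tc$smiles) && nrow(kept) > 0) {
    lib <- read_library(tc$smiles, format = "smiles")
    lib <- lib[vapply(lib, `[[`, character(1), "id") %in% kept$name]
    if (length(lib) > 0) {
      clusters <- cluster_candidates(
        lib, similarity_threshold = tc$cluster_threshold %||% 0.6,
        scores = kept)
    }
  }
  write_candidate_report(kept, clusters, outdir)
  message(sprintf("%d candidate(s) kept", nrow(kept)))
  list(scores = records, candidates = kept, clusters = clusters)
}

screen_run_synthetic <- function(sc, seed, outdir) {
  spec <- planted_library_spec(
    n_pockets = sc$n_pockets %||% 20L,
    ligands_per_pocket = sc$ligands_per_pocket %||% 100L,
    signal_strength = sc$signal_strength %||% 0.9,
    alphabet_size = sc$alphabet_size %||% 8L,
    seed = seed)
  lib <- generate_planted_library(spec)
  n_pairs <- nrow(lib$pairs)

  # --- stage 1: embedding + pair-vector classifier -----------------------
  model <- train_embedding(
    c(lib$pocket_sentences, lib$ligand_sentences),
    dim = sc$embed_dim %||% 100L, epochs = sc$embed_epochs %||% 3L,
    seed = seed)
  holdout <- sc$holdout_fraction %||% 0.25
  test_idx <- with_seed(seed + 1L, {
    sort(sample.int(n_pairs, round(holdout * n_pairs)))
  })
  train_idx <- setdiff(seq_len(n_pairs), test_idx)
  pv <- t(vapply(lib$pocket_sentences, function(s) embed_molecule(model, s),
                 numeric(model$dim)))
  lv <- t(vapply(lib$ligand_sentences, function(s) embed_molecule(model, s),
                 numeric(model$dim)))
  Xraw <- cbind(pv[lib$pairs$pocket, , drop = FALSE], lv)
  stats <- pair_normalization_stats(Xraw[train_idx, , drop = FALSE])
  X <- sweep(sweep(Xraw, 2, stats$mean), 2, stats$std, `/`)
  y <- lib$pairs$label
  dfcnn <- train_dfcnn(X[train_idx, , drop = FALSE], y[train_idx],
                       stats = stats,
                       hidden = sc$hidden %||% c(512L, 256L, 128L, 64L),
                       epochs = sc$epochs %||% 40L, seed = seed)
  dfcnn_scores <- predict_binding_probability(dfcnn,
                                              X[test_idx, , drop = FALSE])
  # recovery is judged against the planted rule (ground truth); the noisy
  # labels are a training-time corruption, not the evaluation standard
  truth <- lib$pairs$bind_rule
  dfcnn_auc <- auc_score(dfcnn_scores, truth[test_idx])
  enr_cutoff <- sc$enrichment_cutoff %||% 0.9
  enr <- tryCatch(
    compute_enrichment(dfcnn_scores, truth[test_idx], cutoff = enr_cutoff),
    error = function(e) {
      message(sprintf("enrichment undefined at cutoff %g: %s", enr_cutoff,
                      conditionMessage(e)))
      NULL
    })

  # --- stage 2: mock docking + interface classifier ----------------------
  n_cpx <- sc$n_complexes %||% 12L
  cpx <- generate_complex_set(n_cpx, seed = seed + 2L)
  native_maps <- lapply(cpx, function(cx) {
    featurize_interface(cx$receptor, cx$ligand_coords)
  })
  decoys <- build_cross_docking_decoys(cpx, n_per_complex = 2L,
                                       seed = seed + 3L)
  decoy_maps <- lapply(decoys, function(d) {
    rec <- cpx[[match(d$receptor_id, vapply(cpx, `[[`, character(1),
                                            "id"))]]
    featurize_interface(rec$receptor, d$pose)
  })
  clf <- train_interface_classifier(
    c(native_maps, decoy_maps),
    c(rep(1, length(native_maps)), rep(0, length(decoy_maps))),
    epochs = sc$interface_epochs %||% 80L, seed = seed)

  # --- stage 3: score a held-out screening pool end-to-end ---------------
  n_screen <- min(sc$n_screen %||% 200L, length(test_idx))
  pool <- test_idx[seq_len(n_screen)]
  pool_cpx <- generate_complex_set(n_screen, seed = seed + 4L)
  records <- data.frame(name = sprintf("cand%04d", pool),
                        deepbindbc = NA_real_, docking = NA_real_,
                        dfcnn = dfcnn_scores[match(pool, test_idx)])
  for (k in seq_len(n_screen)) {
    cx <- pool_cpx[[k]]
    binder <- lib$pairs$bind_rule[pool[k]] == 1L
    pocket <- extract_pocket(cx$receptor, cx$ligand_coords, cutoff_nm = 1.0)
    cfg <- make_config(pocket)
    dock <- run_docking(cx$receptor, cx$ligand_coords, cfg, engine = "mock",
                        seed = seed, receptor_id = cx$id,
                        ligand_id = sprintf("cand%04d", pool[k]))
    # binders sit in their planted native pose; non-binders in the best
    # mock-docked (displaced) pose — the synthetic analogue of a compound
    # that does not really fit the pocket
    pose <- if (binder) cx$ligand_coords else dock$coords[[1]]
    records$docking[k] <- dock$best_affinity - if (binder) 2 else 0
    records$deepbindbc[k] <- predict_pose_score(
      clf, featurize_interface(cx$receptor, pose))
  }
  criteria <- cascade_criteria(
    sc$criteria$deepbindbc %||% 0.5, sc$criteria$docking %||% -2,
    sc$criteria$dfcnn %||% 0.5)
  kept <- rank_candidates(apply_criteria(records, criteria))

  write_score_table(records, file.path(outdir, "scores.csv"))
  write_candidate_report(kept, NULL, outdir)
  enr_df <- if (is.null(enr)) {
    data.frame(cutoff = enr_cutoff, n_c = NA, n_total = NA, nn_c = 0L,
               n_all = length(test_idx), tpr = NA, random_rate = 0,
               ratio = NA)
  } else {
    enrichment_summary(enr)
  }
  utils::write.csv(enr_df, file.path(outdir, "enrichment.csv"),
                   row.names = FALSE)
  message(sprintf(
    "%d candidate(s) kept; dfcnn held-out AUC %.3f, Ratio_%g %s",
    nrow(kept), dfcnn_auc, enr_cutoff,
    if (is.null(enr)) "undefined" else sprintf("%.1f", enr$ratio)))
  list(scores = records, candidates = kept, enrichment = enr,
       dfcnn_auc = dfcnn_auc, embedding = model, dfcnn = dfcnn,
       interface = clf, library = lib, test_idx = test_idx,
       dfcnn_scores = dfcnn_scores)
}
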