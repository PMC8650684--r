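# Dense fully connected binding-probability classifier (first screening
# stage). Positives are cognate pocket-ligand pairs; negatives are made by
# cross-combining pockets with ligands from other complexes.

#' Create a cognate pocket-ligand complex entry
#'
#' @param complex_id Unique complex identifier.
#' @param pocket_sentence Pocket substructure sentence (character vector).
#' @param ligand_sentence Ligand substructure sentence.
#' @param ligand_key Canonical ligand identity (e.g. canonical SMILES) used
#'   to exclude same-ligand pairs from the negative set; defaults to the
#'   ligand sentence hash.
#' @return Object of class `complex_entry`.
#' @export
complex_entry <- function(complex_id, pocket_sentence, ligand_sentence,
                          ligand_key = NULL) {
  stopifnot(is.character(complex_id), length(complex_id) == 1L)
  if (is.null(ligand_key)) {
    ligand_key <- as.character(fnv1a(paste(ligand_sentence, collapse = " ")))
  }
  structure(list(complex_id = complex_id,
                 pocket_sentence = pocket_sentence,
                 ligand_sentence = ligand_sentence,
                 ligand_key = ligand_key),
            class = "complex_entry")
}

#' Build cross-combination negative pairs
#'
#' Negative pocket-ligand pairs are sampled uniformly without replacement
#' from all (pocket_i, ligand_j) with i != j whose ligand differs from
#' pocket i's cognate ligand (by `ligand_key`), so a pocket is never paired
#' with its own ligand under another name.
#'
#' @param complexes List of [complex_entry()]s.
#' @param ratio Negatives per positive (>= 1).
#' @param seed RNG seed.
#' @return Object of class `training_pair_set`: `positives` and `negatives`
#'   are data.frames with columns `pocket` and `ligand` (complex indices),
#'   plus the seed.
#' @export
build_cross_combination_negatives <- function(complexes, ratio = 1L,
                                              seed = 1L) {
  n <- length(complexes)
  if (n < 2L) stopf("need at least 2 complexes to cross-combine")
  if (ratio < 1) stopf("ratio must be >= 1")
  keys <- vapply(complexes, `[[`, character(1), "ligand_key")
  grid <- expand.grid(pocket = seq_len(n), ligand = seq_len(n))
  admissible <- grid[grid$pocket != grid$ligand &
                       keys[grid$ligand] != keys[grid$pocket], , drop = FALSE]
  if (nrow(admissible) == 0L) {
    stopf("no admissible cross pairs (all ligands identical?)")
  }
  want <- min(nrow(admissible), as.integer(round(ratio * n)))
  neg <- with_seed(seed, {
    admissible[sample.int(nrow(admissible), want), , drop = FALSE]
  })
  rownames(neg) <- NULL
  structure(list(
    positives = data.frame(pocket = seq_len(n), ligand = seq_len(n)),
    negatives = neg,
    seed = as.integer(seed)
  ), class = "training_pair_set")
}

#' Assemble the normalized pair-vector design matrix for a pair set
#'
#' Embeds each complex's pocket and ligand sentence, concatenates them per
#' (pocket, ligand) pair, and z-normalizes with statistics computed from
#' these pairs (or supplied training statistics for test data).
#'
#' @param complexes List of [complex_entry()]s.
#' @param pair_set A `training_pair_set`.
#' @param model An `embedding_model`.
#' @param stats Optional precomputed [pair_normalization_stats()]; when
#'   `NULL`, statistics are computed from this pair set (training use).
#' @return List with `X` (matrix), `y` (0/1), `stats`.
#' @export
build_pair_dataset <- function(complexes, pair_set, model, stats = NULL) {
  stopifnot(inherits(pair_set, "training_pair_set"),
            inherits(model, "embedding_model"))
  pv <- t(vapply(complexes, function(cx) {
    embed_molecule(model, cx$pocket_sentence)
  }, numeric(model$dim)))
  lv <- t(vapply(complexes, function(cx) {
    embed_molecule(model, cx$ligand_sentence)
  }, numeric(model$dim)))
  pairs <- rbind(pair_set$positives, pair_set$negatives)
  y <- c(rep(1, nrow(pair_set$positives)), rep(0, nrow(pair_set$negatives)))
  X <- cbind(pv[pairs$pocket, , drop = FALSE], lv[pairs$ligand, , drop = FALSE])
  if (is.null(stats)) stats <- pair_normalization_stats(X)
  X <- sweep(sweep(X, 2, stats$mean), 2, stats$std, `/`)
  list(X = X, y = y, stats = stats)
}

#' Train the dense binding-probability classifier
#'
#' @param X Normalized pair-vector matrix (rows = pairs).
#' @param y 0/1 binding labels.
#' @param stats The [pair_normalization_stats()] the matrix was normalized
#'   with; stored on the model so prediction-time inputs can be normalized
#'   identically.
#' @param hidden Hidden layer widths (default `c(512, 256, 128, 64)`).
#' @param epochs,lr,batch_size,seed Training controls, see [mlp_train()].
#' @return Object of class `dfcnn_model`.
#' @export
train_dfcnn <- function(X, y, stats = NULL,
                        hidden = c(512L, 256L, 128L, 64L), epochs = 60L,
                        lr = 1e-3, batch_size = 128L, seed = 1L) {
  if (sum(y == 1) < 10L || sum(y == 0) < 10L) {
    stopf("need at least 10 positives and 10 negatives (got %d / %d)",
          sum(y == 1), sum(y == 0))
  }
  net <- mlp_train(X, y, hidden = hidden, epochs = epochs, lr = lr,
                   batch_size = batch_size, seed = seed)
  structure(list(net = net, stats = stats, hidden = hidden,
                 seed = as.integer(seed)),
            class = "dfcnn_model")
}

#' @export
print.dfcnn_model <- function(x, ...) {
  cat(sprintf("<dfcnn model: input %d, hidden [%s], final loss %.4f>\n",
              x$net$dim_in, paste(x$hidden, collapse = ", "),
              utils::tail(x$net$loss_history, 1)))
  invisible(x)
}

#' Predict binding probability for pair vectors
#'
#' A pure function of (model weights, input): scores are in \[0, 1\] and
#' batch prediction equals per-row prediction.
#'
#' @param model A `dfcnn_model`.
#' @param pairs A pair vector or a matrix of pair vectors (already
#'   normalized with the model's training statistics).
#' @return Numeric vector of binding probabilities.
#' @export
predict_binding_probability <- function(model, pairs) {
  stopifnot(inherits(model, "dfcnn_model"))
  nn_predict(model$net, pairs)
}

#' Save / load a dfcnn model (RDS with a config echo)
#' @param model A `dfcnn_model`.
#' @param path File path.
#' @return `path` invisibly ([save_dfcnn()]) or the model ([load_dfcnn()]).
#' @export
save_dfcnn <- function(model, path) {
  stopifnot(inherits(model, "dfcnn_model"))
  saveRDS(list(format = "vscascade_dfcnn_v1", model = model), path)
  invisible(path)
}

#' @rdname save_dfcnn
#' @export
load_dfcnn <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "vscascade_dfcnn_v1")) {
    stopf("'%s' is not a vscascade dfcnn model file", path)
  }
  obj$model
}
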