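# Interface featurization and the pose classifier (second screening stage).
#
# A protein-ligand pose is encoded as a fixed-size "figure-like" 2D matrix:
# one row per heavy-atom contact within a distance cutoff, sorted by
# distance, each row a one-hot protein element block, a one-hot ligand
# element block and the scaled distance; short interfaces are zero-padded,
# long ones keep the closest contacts. The layout is declared and versioned
# here (v1) and stored on trained models.

INTERFACE_ELEMENTS <- c("C", "N", "O", "S", "P", "HAL", "X")

interface_element_class <- function(element) {
  e <- ifelse(element %in% HALOGENS, "HAL",
              ifelse(element %in% c("C", "N", "O", "S", "P"), element, "X"))
  factor(e, levels = INTERFACE_ELEMENTS)
}

#' Featurize a protein-ligand interface into a fixed-size contact map
#'
#' @param struct A [structure_model()] (or data.frame with `element`,
#'   `x`, `y`, `z`) for the protein side.
#' @param pose Ligand pose coordinates: data.frame with `element`, `x`,
#'   `y`, `z`.
#' @param cutoff Contact distance cutoff, Angstrom (default 10).
#' @param max_rows Fixed number of rows (default 256): the `max_rows`
#'   closest contacts are kept, shorter interfaces are padded with all-zero
#'   rows.
#' @return Numeric matrix `max_rows x 15` of class `interface_map`
#'   (7 protein element columns, 7 ligand element columns, distance /
#'   cutoff), rows ascending by distance, ties broken by (protein atom
#'   index, ligand atom index).
#' @export
featurize_interface <- function(struct, pose, cutoff = 10, max_rows = 256L) {
  prot <- if (inherits(struct, "structure_model")) struct$atoms else struct
  prot <- prot[prot$element != "H", , drop = FALSE]
  lig <- as_coord_df(pose)
  lig <- lig[lig$element != "H", , drop = FALSE]
  if (nrow(lig) == 0L) stopf("pose has no heavy atoms")
  ncols <- 2L * length(INTERFACE_ELEMENTS) + 1L
  map <- matrix(0, nrow = max_rows, ncol = ncols)
  colnames(map) <- c(paste0("p_", INTERFACE_ELEMENTS),
                     paste0("l_", INTERFACE_ELEMENTS), "dist")
  if (nrow(prot) > 0L) {
    pm <- as.matrix(prot[, c("x", "y", "z")])
    lm <- as.matrix(lig[, c("x", "y", "z")])
    d2 <- outer(rowSums(pm^2), rowSums(lm^2), `+`) - 2 * pm %*% t(lm)
    d <- sqrt(pmax(d2, 0))
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      dd <- d[hit]
      ord <- order(dd, hit[, 1], hit[, 2])
      ord <- ord[seq_len(min(length(ord), max_rows))]
      pi_cls <- as.integer(interface_element_class(prot$element[hit[ord, 1]]))
      li_cls <- as.integer(interface_element_class(lig$element[hit[ord, 2]]))
      for (r in seq_along(ord)) {
        map[r, pi_cls[r]] <- 1
        map[r, length(INTERFACE_ELEMENTS) + li_cls[r]] <- 1
        map[r, ncols] <- dd[ord[r]] / cutoff
      }
    }
  }
  structure(map, class = c("interface_map", "matrix", "array"),
            cutoff = cutoff, layout = "v1")
}

#' Generate cross-docking decoy poses
#'
#' For each receptor, ligands from other complexes are docked (mock engine
#' by default) into the receptor's pocket box and the best-scoring pose per
#' (receptor, foreign ligand) pair is kept as a decoy. A receptor's cognate
#' ligand — or an identical ligand from another complex (same
#' `ligand_key`) — is never used as its decoy. Engine failures on a pair
#' are logged and the pair skipped.
#'
#' @param complexes List of complexes, each a list with `id`,
#'   `receptor` ([structure_model()]), `ligand_coords` (data.frame) and
#'   optionally `ligand_key`.
#' @param n_per_complex Decoys per receptor.
#' @param seed RNG seed (drives both pair sampling and the mock engine).
#' @param engine Docking engine, passed to [run_docking()].
#' @return List of decoy entries: `receptor_id`, `ligand_id`, `pose`
#'   (coordinates), `affinity`, `label = "decoy"`, `origin =
#'   "cross_docked"`.
#' @export
build_cross_docking_decoys <- function(complexes, n_per_complex = 2L,
                                       seed = 1L, engine = "mock") {
  n <- length(complexes)
  if (n < 2L) stopf("need at least 2 complexes for cross-docking")
  keys <- vapply(seq_len(n), function(i) {
    complexes[[i]]$ligand_key %||% complexes[[i]]$id
  }, character(1))
  picks <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      cand <- setdiff(which(keys != keys[i]), i)
      if (length(cand) == 0L) return(integer(0))
      cand[sample.int(length(cand), min(n_per_complex, length(cand)))]
    })
  })
  decoys <- list()
  for (i in seq_len(n)) {
    rec <- complexes[[i]]
    pocket <- tryCatch(
      extract_pocket(rec$receptor, rec$ligand_coords, cutoff_nm = 1.0),
      error = function(e) NULL)
    if (is.null(pocket)) next
    cfg <- make_config(pocket)
    for (j in picks[[i]]) {
      res <- tryCatch(
        run_docking(rec$receptor, complexes[[j]]$ligand_coords, cfg,
                    engine = engine, seed = seed,
                    receptor_id = rec$id, ligand_id = complexes[[j]]$id),
        error = function(e) {
          warnf("docking failed for (%s, %s): %s — pair skipped",
                rec$id, complexes[[j]]$id, conditionMessage(e))
          NULL
        })
      if (is.null(res)) next
      best <- which.min(res$poses$affinity)
      decoys[[length(decoys) + 1L]] <- list(
        receptor_id = rec$id, ligand_id = complexes[[j]]$id,
        pose = res$coords[[best]], affinity = res$best_affinity,
        label = "decoy", origin = "cross_docked")
    }
  }
  decoys
}

#' Train the interface pose classifier
#'
#' A residual dense network (identity-skip blocks, see [resnet_train()])
#' over flattened interface maps, scoring a pose's probability of being
#' native-like rather than a cross-docked decoy.
#'
#' @param maps List of `interface_map`s.
#' @param labels 0/1 (1 = native).
#' @param width,blocks,epochs,lr,batch_size,seed See [resnet_train()].
#' @return Object of class `interface_classifier`.
#' @export
train_interface_classifier <- function(maps, labels, width = 32L,
                                       blocks = 4L, epochs = 80L, lr = 1e-3,
                                       batch_size = 64L, seed = 1L) {
  if (length(unique(labels)) < 2L) {
    stopf("need both native and decoy poses in the training set")
  }
  X <- t(vapply(maps, function(m) as.vector(unclass(m)),
                numeric(length(as.vector(unclass(maps[[1]]))))))
  net <- resnet_train(X, as.numeric(labels), width = width, blocks = blocks,
                      epochs = epochs, lr = lr, batch_size = batch_size,
                      seed = seed)
  structure(list(net = net, layout = attr(maps[[1]], "layout") %||% "v1",
                 map_dim = dim(unclass(maps[[1]])), seed = as.integer(seed)),
            class = "interface_classifier")
}

#' Score a pose with the interface classifier
#'
#' @param classifier An `interface_classifier`.
#' @param map An `interface_map` (or list of maps).
#' @return Probability (or vector of probabilities) in \[0, 1\] that the
#'   pose is native-like.
#' @export
predict_pose_score <- function(classifier, map) {
  stopifnot(inherits(classifier, "interface_classifier"))
  maps <- if (inherits(map, "interface_map")) list(map) else map
  X <- t(vapply(maps, function(m) as.vector(unclass(m)),
                numeric(prod(classifier$map_dim))))
  nn_predict(classifier$net, X)
}
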