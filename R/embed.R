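# Substructure-sentence embeddings.
#
# A molecule is rendered as a "sentence" of circular-substructure identifier
# tokens (one token per heavy atom per radius 0..R, Morgan-style), embedded
# with a small skip-gram model trained on the screening corpus, and a
# pocket-ligand pair is the z-normalized concatenation of the two summed
# token vectors. This is the input representation of the dense binding
# classifier.

#' Circular substructure identifiers for a molecular graph
#'
#' Morgan-style iterative refinement: the radius-0 invariant of an atom is a
#' hash of (element, heavy degree, bond-order sum); the radius-r invariant
#' hashes the radius-(r-1) invariant of the atom together with the sorted
#' (bond order, neighbour invariant) pairs. One identifier string per atom
#' and radius.
#' @noRd
morgan_identifiers <- function(graph, radius) {
  n <- nrow(graph$atoms)
  ids <- matrix("", nrow = n, ncol = radius + 1L)
  inv <- fnv1a(paste(graph$atoms$element, graph$atoms$degree,
                     graph$atoms$order_sum, sep = "|"))
  ids[, 1] <- as.character(inv)
  if (radius >= 1L) {
    nbrs <- vector("list", n)
    if (nrow(graph$bonds) > 0) {
      for (r in seq_len(nrow(graph$bonds))) {
        i <- graph$bonds$i[r]; j <- graph$bonds$j[r]
        o <- graph$bonds$order[r]
        nbrs[[i]] <- rbind(nbrs[[i]], c(j, o))
        nbrs[[j]] <- rbind(nbrs[[j]], c(i, o))
      }
    }
    for (r in seq_len(radius)) {
      newinv <- numeric(n)
      for (a in seq_len(n)) {
        nb <- nbrs[[a]]
        env <- if (is.null(nb)) character(0) else {
          sort(paste(nb[, 2], inv[nb[, 1]], sep = ":"))
        }
        newinv[a] <- fnv1a(paste(c(inv[a], env), collapse = ";"))
      }
      inv <- newinv
      ids[, r + 1L] <- as.character(inv)
    }
  }
  ids
}

#' Convert a molecule to a substructure sentence
#'
#' @param molecule A [molecule_record()] or a SMILES string.
#' @param radius Maximum substructure radius R (tokens for radii 0..R).
#' @return Character vector of tokens, length n_heavy_atoms * (R + 1),
#'   ordered atom-by-atom (radius 0 first). The SMILES is canonicalized
#'   first, so two spellings of the same molecule give the same sentence.
#' @export
mol_to_sentence <- function(molecule, radius = 1L) {
  smiles <- if (inherits(molecule, "molecule_record")) molecule$smiles
            else molecule
  g <- molecule_graph(smiles)
  ids <- morgan_identifiers(g, radius)
  as.vector(t(ids))
}

#' Convert a binding pocket to a substructure sentence
#'
#' Pocket residues are treated as disconnected components of one molecular
#' graph: heavy atoms within a residue are bonded when closer than
#' `bond_cutoff` Angstrom, residues are never bonded to each other, and
#' sentences are generated per residue (in residue order) with the same
#' identifier scheme as ligands, then concatenated.
#'
#' @param pocket A [pocket_definition()] from [extract_pocket()].
#' @param radius Maximum substructure radius.
#' @param bond_cutoff Heavy-atom covalent bond inference cutoff, Angstrom.
#' @return Character vector of tokens.
#' @export
pocket_to_sentence <- function(pocket, radius = 1L, bond_cutoff = 1.9) {
  stopifnot(inherits(pocket, "pocket_definition"))
  atoms <- pocket$atoms
  if (nrow(atoms) == 0L) stopf("pocket is empty")
  tokens <- character(0)
  for (r in seq_len(nrow(pocket$residues))) {
    sel <- atoms$chain == pocket$residues$chain[r] &
      atoms$resno == pocket$residues$resno[r]
    res <- atoms[sel, , drop = FALSE]
    m <- as.matrix(res[, c("x", "y", "z")])
    n <- nrow(res)
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
    if (n > 1) {
      d <- as.matrix(stats::dist(m))
      idx <- which(upper.tri(d) & d <= bond_cutoff, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        bonds <- data.frame(i = idx[, 1], j = idx[, 2], order = 1L)
      }
    }
    degree <- tabulate(c(bonds$i, bonds$j), nbins = n)
    g <- list(atoms = data.frame(element = res$element, degree = degree,
                                 order_sum = degree),
              bonds = bonds)
    tokens <- c(tokens, as.vector(t(morgan_identifiers(g, radius))))
  }
  tokens
}

#' Train a skip-gram embedding model on substructure sentences
#'
#' A compact word2vec-style skip-gram with negative sampling, trained
#' single-threaded with a fixed seed so training is exactly reproducible.
#' Gradients are applied per (deterministically shuffled) minibatch.
#'
#' @param sentences List of token character vectors.
#' @param dim Embedding dimension (default 100).
#' @param window Context window size (default 10).
#' @param min_count Minimum token count for vocabulary inclusion (default 1);
#'   rarer tokens map to the unknown vector (all zeros).
#' @param epochs Training epochs.
#' @param lr Initial learning rate (linearly decayed).
#' @param negative Negative samples per context pair.
#' @param seed RNG seed.
#' @return Object of class `embedding_model` with fields `dim`, `vocab`
#'   (matrix, one row per token), `unk_vector`, `window`, `min_count`,
#'   `seed`.
#' @export
train_embedding <- function(sentences, dim = 100L, window = 10L,
                            min_count = 1L, epochs = 5L, lr = 0.05,
                            negative = 5L, seed = 1L) {
  if (length(sentences) == 0L) stopf("empty sentence corpus")
  counts <- table(unlist(sentences))
  vocab_tokens <- names(counts)[counts >= min_count]
  if (length(vocab_tokens) == 0L) {
    stopf("no token reaches min_count = %d", min_count)
  }
  V <- length(vocab_tokens)
  tok2id <- stats::setNames(seq_len(V), vocab_tokens)

  # (center, context) pairs within the window, vocabulary tokens only
  cen_l <- vector("list", length(sentences))
  ctx_l <- vector("list", length(sentences))
  for (si in seq_along(sentences)) {
    s <- sentences[[si]]
    ids <- unname(tok2id[s[s %in% vocab_tokens]])
    L <- length(ids)
    if (L < 2) next
    cc <- vector("list", L); xx <- vector("list", L)
    for (i in seq_len(L)) {
      lo <- max(1L, i - window); hi <- min(L, i + window)
      ctx <- setdiff(lo:hi, i)
      cc[[i]] <- rep.int(ids[i], length(ctx))
      xx[[i]] <- ids[ctx]
    }
    cen_l[[si]] <- unlist(cc); ctx_l[[si]] <- unlist(xx)
  }
  centers <- unlist(cen_l); contexts <- unlist(ctx_l)
  if (length(centers) == 0L) stopf("corpus yields no context pairs")

  noise <- as.numeric(counts[vocab_tokens])^0.75
  noise <- noise / sum(noise)

  with_seed(seed, {
    W <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, nrow = V)
    C <- matrix(0, nrow = V, ncol = dim)
    npairs <- length(centers)
    batch <- 256L
    steps_total <- epochs * ceiling(npairs / batch)
    step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(npairs)
      for (start in seq(1L, npairs, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, npairs)]
        b <- length(idx)
        step <- step + 1L
        eta <- lr * max(1e-4, 1 - step / steps_total)
        cen <- centers[idx]; pos <- contexts[idx]
        neg <- matrix(sample.int(V, b * negative, replace = TRUE,
                                 prob = noise), nrow = b)
        Wc <- W[cen, , drop = FALSE]
        # positive pairs
        gpos <- stats::plogis(rowSums(Wc * C[pos, , drop = FALSE])) - 1
        gradW <- gpos * C[pos, , drop = FALSE]
        dCpos <- gpos * Wc
        # negative pairs
        dCneg_i <- integer(0); dCneg <- NULL
        for (k in seq_len(negative)) {
          nk <- neg[, k]
          gneg <- stats::plogis(rowSums(Wc * C[nk, , drop = FALSE]))
          gradW <- gradW + gneg * C[nk, , drop = FALSE]
          dCneg_i <- c(dCneg_i, nk)
          dCneg <- rbind(dCneg, gneg * Wc)
        }
        W <- W - eta * rowsum_into(gradW, cen, V)
        C <- C - eta * rowsum_into(rbind(dCpos, dCneg), c(pos, dCneg_i), V)
      }
    }
    rownames(W) <- vocab_tokens
    structure(list(dim = as.integer(dim), vocab = W,
                   unk_vector = numeric(dim), window = as.integer(window),
                   min_count = as.integer(min_count), negative = negative,
                   epochs = epochs, seed = as.integer(seed)),
              class = "embedding_model")
  })
}

# scatter-add rows of `g` into an n-row accumulator at indices `idx`
rowsum_into <- function(g, idx, n) {
  acc <- rowsum(g, group = idx)
  out <- matrix(0, nrow = n, ncol = ncol(g))
  out[as.integer(rownames(acc)), ] <- acc
  out
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding model: %d tokens, dim %d, seed %d>\n",
              nrow(x$vocab), x$dim, x$seed))
  invisible(x)
}

#' Embed a sentence as the sum of its token vectors
#'
#' Out-of-vocabulary tokens contribute the model's unknown vector (zero).
#'
#' @param model An `embedding_model`.
#' @param sentence Character vector of tokens.
#' @return Numeric vector of length `model$dim`.
#' @export
embed_molecule <- function(model, sentence) {
  stopifnot(inherits(model, "embedding_model"))
  known <- sentence[sentence %in% rownames(model$vocab)]
  v <- model$unk_vector * (length(sentence) - length(known))
  if (length(known) > 0) {
    v <- v + colSums(model$vocab[known, , drop = FALSE])
  }
  v
}

#' Normalization statistics from training pair vectors
#'
#' Per-dimension mean and standard deviation of the raw concatenated
#' training pairs; the deviation is floored at `floor` to keep constant
#' dimensions from blowing up. Must be computed from training pairs only and
#' reused for test data.
#'
#' @param pairs Matrix of raw concatenated pair vectors (rows = pairs).
#' @param floor Lower bound for the standard deviation.
#' @return Object of class `normalization_stats` with `mean` and `std`.
#' @export
pair_normalization_stats <- function(pairs, floor = 1e-8) {
  stopifnot(is.matrix(pairs), nrow(pairs) >= 1)
  std <- apply(pairs, 2, stats::sd)
  std[!is.finite(std)] <- 0
  structure(list(mean = colMeans(pairs), std = pmax(std, floor)),
            class = "normalization_stats")
}

#' Assemble a normalized pocket-ligand pair vector
#'
#' Concatenates the pocket and ligand embedding vectors and applies
#' (x - mean) / std with training-set statistics.
#'
#' @param pocket_vec Pocket embedding (length dim).
#' @param ligand_vec Ligand embedding (length dim).
#' @param stats A [pair_normalization_stats()] of length 2*dim (or `NULL`
#'   for the raw concatenation).
#' @return Numeric vector of length 2*dim.
#' @export
make_pair_vector <- function(pocket_vec, ligand_vec, stats = NULL) {
  if (length(pocket_vec) != length(ligand_vec)) {
    stopf("pocket and ligand vectors must have equal dimension (%d vs %d)",
          length(pocket_vec), length(ligand_vec))
  }
  v <- c(pocket_vec, ligand_vec)
  if (!is.null(stats)) {
    stopifnot(inherits(stats, "normalization_stats"))
    if (length(stats$mean) != length(v)) {
      stopf("normalization stats length %d does not match pair length %d",
            length(stats$mean), length(v))
    }
    v <- (v - stats$mean) / stats$std
  }
  v
}

#' Save an embedding model as a versioned text key-value file
#'
#' @param model An `embedding_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_embedding_model <- function(model, path) {
  stopifnot(inherits(model, "embedding_model"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("#vscascade_embedding v1",
               sprintf("#dim %d", model$dim),
               sprintf("#window %d", model$window),
               sprintf("#min_count %d", model$min_count),
               sprintf("#seed %d", model$seed)), con)
  toks <- rownames(model$vocab)
  for (i in seq_along(toks)) {
    writeLines(paste(toks[i],
                     paste(sprintf("%.17g", model$vocab[i, ]),
                           collapse = " "), sep = "\t"), con)
  }
  invisible(path)
}

#' Load an embedding model saved by [save_embedding_model()]
#'
#' @param path Input file.
#' @return An `embedding_model`.
#' @export
load_embedding_model <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1] != "#vscascade_embedding v1") {
    stopf("'%s' is not a vscascade embedding file", path)
  }
  hdr <- lines[startsWith(lines, "#")]
  getv <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, " "))]
    as.integer(sub(paste0("^#", key, " "), "", ln[1]))
  }
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  toks <- vapply(parts, `[[`, character(1), 1)
  vecs <- t(vapply(parts, function(p) {
    as.numeric(strsplit(p[2], " +")[[1]])
  }, numeric(getv("dim"))))
  rownames(vecs) <- toks
  structure(list(dim = getv("dim"), vocab = vecs,
                 unk_vector = numeric(getv("dim")), window = getv("window"),
                 min_count = getv("min_count"), seed = getv("seed")),
            class = "embedding_model")
}
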