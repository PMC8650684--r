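# The threshold cascade over per-compound score tables, candidate ranking,
# and chemotype clustering of the survivors.
#
# A score table has one row per compound with the three stage scores:
# the interface-classifier probability (deepbindbc), the docking affinity in
# kcal/mol (docking; more negative is better) and the pair-vector classifier
# probability (dfcnn). Thresholds use strict ">" on the two probabilities
# and "<=" on the docking score, exactly as such criteria are conventionally
# written (e.g. "DeepBindBC>0.99, Docking<=-10, DFCNN>0.99"), so boundary
# docking values are kept.

#' Create a cascade criteria set
#'
#' @param min_deepbindbc Keep records with interface score strictly greater.
#' @param max_docking Keep records with docking score less than or equal.
#' @param min_dfcnn Keep records with pair-vector score strictly greater.
#' @param exclude Compound names to drop regardless of scores.
#' @return Object of class `cascade_criteria`.
#' @export
cascade_criteria <- function(min_deepbindbc, max_docking, min_dfcnn,
                             exclude = character()) {
  stopifnot(is_scalar_number(min_deepbindbc), is_scalar_number(max_docking),
            is_scalar_number(min_dfcnn))
  if (min_deepbindbc < 0 || min_deepbindbc > 1 ||
      min_dfcnn < 0 || min_dfcnn > 1) {
    stopf("probability thresholds must lie in [0, 1]")
  }
  structure(list(min_deepbindbc = min_deepbindbc, max_docking = max_docking,
                 min_dfcnn = min_dfcnn, exclude = as.character(exclude)),
            class = "cascade_criteria")
}

#' Named criteria presets
#'
#' Three selection stringencies commonly used together in a cascade:
#' `"list1"` (0.99 / -10 / 0.99), `"list2"` (0.99 / -8.5 / 0.998) and
#' `"tcm"` (0.9 / -6 / 0.9).
#'
#' @param name Preset name.
#' @param exclude Names to exclude (e.g. compounds already selected by a
#'   stricter preset).
#' @return A [cascade_criteria()].
#' @export
criteria_preset <- function(name = c("list1", "list2", "tcm"),
                            exclude = character()) {
  name <- match.arg(name)
  switch(name,
    list1 = cascade_criteria(0.99, -10, 0.99, exclude),
    list2 = cascade_criteria(0.99, -8.5, 0.998, exclude),
    tcm = cascade_criteria(0.9, -6, 0.9, exclude)
  )
}

#' Read / write a score table
#'
#' Delimited text with header `name,deepbindbc,docking,dfcnn` (comma or
#' tab separated on read).
#'
#' @param path File path.
#' @return A data.frame with the four columns.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stopf("no such score table: '%s'", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          check.names = FALSE)
  validate_score_table(df)
}

#' @rdname read_score_table
#' @param records Score table data.frame.
#' @export
write_score_table <- function(records, path) {
  utils::write.csv(validate_score_table(records), path, row.names = FALSE)
  invisible(path)
}

validate_score_table <- function(df) {
  req <- c("name", "deepbindbc", "docking", "dfcnn")
  if (!all(req %in% names(df))) {
    stopf("score table must have columns %s", paste(req, collapse = ", "))
  }
  df <- df[, req]
  if (anyDuplicated(df$name)) stopf("duplicate compound names in score table")
  num <- as.matrix(df[, c("deepbindbc", "docking", "dfcnn")])
  if (!all(is.finite(num))) stopf("score table contains non-finite scores")
  df
}

#' Apply cascade criteria to a score table
#'
#' Keeps a record iff `deepbindbc > min_deepbindbc` and
#' `docking <= max_docking` and `dfcnn > min_dfcnn` and the name is not
#' excluded. Comparisons are on the values as given, with no rounding. The
#' operation is monotone in each threshold and idempotent.
#'
#' @param records Score table (data.frame with `name`, `deepbindbc`,
#'   `docking`, `dfcnn`).
#' @param criteria A [cascade_criteria()].
#' @return The kept rows (possibly zero), with the criteria attached as
#'   attribute `criteria`.
#' @export
apply_criteria <- function(records, criteria) {
  stopifnot(inherits(criteria, "cascade_criteria"))
  records <- validate_score_table(records)
  if (nrow(records) == 0L) stopf("score table is empty")
  keep <- records$deepbindbc > criteria$min_deepbindbc &
    records$docking <= criteria$max_docking &
    records$dfcnn > criteria$min_dfcnn &
    !(records$name %in% criteria$exclude)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "criteria") <- criteria
  out
}

#' Rank a candidate list by one of the stage scores
#'
#' Stable sort: ties keep input order. Probabilities sort descending,
#' docking ascending (most negative first).
#'
#' @param records Score table rows.
#' @param key `"deepbindbc"`, `"docking"` or `"dfcnn"`.
#' @return The reordered data.frame.
#' @export
rank_candidates <- function(records,
                            key = c("deepbindbc", "docking", "dfcnn")) {
  key <- match.arg(key)
  records <- validate_score_table(records)
  v <- records[[key]]
  ord <- if (key == "docking") order(v) else order(-v)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "criteria") <- attr(records, "criteria")
  out
}

#' Hashed circular fingerprint of a molecule
#'
#' Substructure identifiers up to `radius` (the same Morgan-style tokens
#' used for embedding sentences) hashed onto `nbits` bits.
#'
#' @param smiles SMILES string or [molecule_record()].
#' @param nbits Fingerprint length (default 2048).
#' @param radius Substructure radius (default 2).
#' @return Logical vector of length `nbits`.
#' @export
morgan_fingerprint <- function(smiles, nbits = 2048L, radius = 2L) {
  tokens <- unique(mol_to_sentence(smiles, radius = radius))
  bits <- logical(nbits)
  bits[(fnv1a(tokens) %% nbits) + 1L] <- TRUE
  bits
}

#' Tanimoto similarity of two bit fingerprints
#'
#' @param a,b Logical vectors of equal length.
#' @return Intersection over union (1 when both are empty).
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

#' Cluster candidate molecules into chemotype groups
#'
#' Leader-style (Butina) clustering on hashed circular fingerprints at a
#' Tanimoto similarity threshold: the unassigned molecule with the most
#' unassigned neighbours (similarity >= threshold) becomes a cluster
#' centroid and claims its neighbours, repeating until everything is
#' assigned; ties are broken by input order, so the partition is
#' deterministic. Unparseable molecules are excluded with a warning.
#'
#' @param molecules List of [molecule_record()]s.
#' @param similarity_threshold Tanimoto threshold (default 0.6).
#' @param scores Optional score table; when given, each cluster's
#'   representative is its highest-`deepbindbc` member, otherwise the
#'   centroid.
#' @param nbits,radius Fingerprint parameters.
#' @return Object of class `cluster_assignment`: `assignments` (named
#'   integer vector: molecule id -> cluster), `representatives` (one id per
#'   cluster), `similarity_threshold`, `excluded`.
#' @export
cluster_candidates <- function(molecules, similarity_threshold = 0.6,
                               scores = NULL, nbits = 2048L, radius = 2L) {
  ids <- vapply(molecules, `[[`, character(1), "id")
  fps <- vector("list", length(molecules))
  ok <- logical(length(molecules))
  for (k in seq_along(molecules)) {
    fps[[k]] <- tryCatch(
      morgan_fingerprint(molecules[[k]], nbits = nbits, radius = radius),
      error = function(e) NULL)
    ok[k] <- !is.null(fps[[k]])
  }
  if (any(!ok)) {
    warnf("excluding %d unparseable molecule(s): %s", sum(!ok),
          paste(ids[!ok], collapse = ", "))
  }
  keep <- which(ok)
  if (length(keep) == 0L) stopf("no parseable molecules to cluster")
  n <- length(keep)
  sim <- diag(1, n)
  if (n > 1) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        sim[a, b] <- sim[b, a] <- tanimoto(fps[[keep[a]]], fps[[keep[b]]])
      }
    }
  }
  assigned <- rep(NA_integer_, n)
  cluster <- 0L
  centroids <- integer(0)
  while (anyNA(assigned)) {
    free <- which(is.na(assigned))
    nb_count <- vapply(free, function(a) {
      sum(sim[a, free] >= similarity_threshold)
    }, integer(1))
    centroid <- free[which.max(nb_count)]  # ties: first in input order
    cluster <- cluster + 1L
    members <- free[sim[centroid, free] >= similarity_threshold]
    assigned[members] <- cluster
    centroids[cluster] <- centroid
  }
  assignments <- stats::setNames(assigned, ids[keep])
  reps <- vapply(seq_len(cluster), function(cl) {
    members <- ids[keep][assigned == cl]
    if (!is.null(scores) && any(members %in% scores$name)) {
      sc <- scores[match(members, scores$name), "deepbindbc"]
      sc[is.na(sc)] <- -Inf
      members[which.max(sc)]
    } else {
      ids[keep][centroids[cl]]
    }
  }, character(1))
  structure(list(assignments = assignments, representatives = reps,
                 similarity_threshold = similarity_threshold,
                 excluded = ids[!ok]),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<%d molecules in %d clusters at Tanimoto >= %.2f>\n",
              length(x$assignments), length(x$representatives),
              x$similarity_threshold))
  invisible(x)
}

#' Write a candidate/cluster report
#'
#' CSV of the candidate table plus a short human-readable summary text.
#'
#' @param candidates Candidate score table.
#' @param clusters Optional `cluster_assignment`.
#' @param outdir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_candidate_report <- function(candidates, clusters = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(outdir, "candidates.csv")
  write_score_table(candidates, csv)
  txt <- file.path(outdir, "summary.txt")
  lines <- c(sprintf("%d candidate(s) kept", nrow(candidates)))
  cr <- attr(candidates, "criteria")
  if (!is.null(cr)) {
    lines <- c(lines, sprintf(
      "criteria: deepbindbc > %g, docking <= %g, dfcnn > %g",
      cr$min_deepbindbc, cr$max_docking, cr$min_dfcnn))
  }
  paths <- csv
  if (!is.null(clusters)) {
    cl_csv <- file.path(outdir, "clusters.csv")
    utils::write.csv(data.frame(name = names(clusters$assignments),
                                cluster = unname(clusters$assignments)),
                     cl_csv, row.names = FALSE)
    lines <- c(lines, sprintf("%d chemotype cluster(s); representatives: %s",
                              length(clusters$representatives),
                              paste(clusters$representatives,
                                    collapse = ", ")))
    paths <- c(paths, cl_csv)
  }
  writeLines(lines, txt)
  invisible(c(paths, txt))
}
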