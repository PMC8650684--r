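# Screening enrichment statistics.
#
# The enrichment ratio at a score cutoff c compares the recall of known
# actives above c with the fraction of the whole library above c:
#
#   Ratio_c = (N_c / N_total) / (NN_c / N_all)
#
# where N_c actives and NN_c compounds overall score strictly above c,
# N_total is the number of actives and N_all the library size. A ratio of 1
# is random; the default cutoff is 0.9.

#' Compute the enrichment ratio at a score cutoff
#'
#' Uses strict ">" at the cutoff. When no compound scores above the cutoff
#' the random rate is zero and the ratio undefined: this raises an error
#' rather than smoothing (no pseudocounts are defined for the statistic).
#'
#' @param scores Numeric prediction scores.
#' @param is_active Logical (or 0/1) activity labels, same length.
#' @param cutoff Score cutoff (default 0.9).
#' @return Object of class `enrichment_result` with fields `cutoff`, `n_c`,
#'   `n_total`, `nn_c`, `n_all`, `tpr`, `random_rate`, `ratio`.
#' @export
compute_enrichment <- function(scores, is_active, cutoff = 0.9) {
  stopifnot(length(scores) == length(is_active))
  is_active <- as.logical(is_active)
  n_all <- length(scores)
  n_total <- sum(is_active)
  if (n_all < 1L) stopf("empty score list")
  if (n_total < 1L) stopf("no active compounds (N_total = 0)")
  above <- scores > cutoff
  nn_c <- sum(above)
  if (nn_c == 0L) {
    stopf("no compound scores above %g: random rate is zero, ratio undefined",
          cutoff)
  }
  n_c <- sum(above & is_active)
  tpr <- n_c / n_total
  random_rate <- nn_c / n_all
  structure(list(cutoff = cutoff, n_c = n_c, n_total = n_total, nn_c = nn_c,
                 n_all = n_all, tpr = tpr, random_rate = random_rate,
                 ratio = tpr / random_rate),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment @ %g: tpr %d/%d = %.3f, random %d/%d = %.3f, ratio %.2f>\n",
    x$cutoff, x$n_c, x$n_total, x$tpr, x$nn_c, x$n_all, x$random_rate,
    x$ratio))
  invisible(x)
}

#' One-row data.frame summary of an enrichment result
#'
#' @param result An `enrichment_result`.
#' @return data.frame with one row.
#' @export
enrichment_summary <- function(result) {
  stopifnot(inherits(result, "enrichment_result"))
  data.frame(cutoff = result$cutoff, n_c = result$n_c,
             n_total = result$n_total, nn_c = result$nn_c,
             n_all = result$n_all, tpr = result$tpr,
             random_rate = result$random_rate, ratio = result$ratio)
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random active outscores
#' a random inactive, with ties counting one half.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) class labels; both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stopf("AUC requires both classes (got %d positives, %d negatives)",
          n_pos, n_neg)
  }
  r <- rank(scores)  # average ranks handle ties as 0.5
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
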