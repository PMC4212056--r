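#' Evaluate ranked predictions with AUROC and AUPR
#'
#' AUROC uses the rank (Mann-Whitney) formulation with midranks for ties.
#' AUPR is the step-function area under the precision-recall curve obtained
#' by sweeping thresholds from the highest score down, with tied scores
#' entering as one block and no interpolation; under that convention a
#' constant score gives AUROC 0.5 and AUPR equal to the positive prevalence.
#' AUPR is the more sensitive of the two under the extreme class imbalance
#' typical of link prediction.
#'
#' @param scores Numeric prediction scores (higher = more likely positive).
#' @param labels Binary labels (0/1 or logical), same length.
#' @return A `vcp_eval` object: fields `auroc`, `aupr`, curve tibbles `roc`
#'   and `pr`, and class counts.
#' @examples
#' ev <- evaluate_scores(c(.9, .8, .4, .2), c(1, 0, 1, 0))
#' glance(ev)
#' @export
evaluate_scores <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("both classes must be present to evaluate", call. = FALSE)
  r <- rank(scores)   # midranks
  auroc <- (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)

  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  block_end <- cumsum(rle(s)$lengths)   # tied scores enter together
  tp <- cumsum(y)[block_end]
  n_at <- block_end
  recall <- tp / np
  precision <- tp / n_at
  fp <- n_at - tp
  aupr <- sum(diff(c(0, recall)) * precision)
  structure(list(
    auroc = auroc, aupr = aupr, n_pos = np, n_neg = nn,
    roc = tibble::tibble(threshold = s[block_end],
                         fpr = fp / nn, tpr = recall),
    pr = tibble::tibble(threshold = s[block_end],
                        recall = recall, precision = precision)
  ), class = "vcp_eval")
}

#' @export
print.vcp_eval <- function(x, ...) {
  cat(sprintf("<evaluation> AUROC %.4f  AUPR %.4f  (%d pos / %d neg)\n",
              x$auroc, x$aupr, x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired sign test across seeds
#'
#' Significance of one pipeline beating another over paired replicates: an
#' exact binomial test on the number of wins among non-tied pairs.
#'
#' @param x,y Paired performance values (e.g. AUROC per seed).
#' @param alternative Passed to [stats::binom.test()].
#' @return The test's p-value.
#' @export
paired_sign_test <- function(x, y, alternative = "greater") {
  stopifnot(length(x) == length(y))
  wins <- sum(x > y)
  ties <- sum(x == y)
  n <- length(x) - ties
  if (n == 0L) return(1)
  stats::binom.test(wins, n, p = 0.5, alternative = alternative)$p.value
}
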