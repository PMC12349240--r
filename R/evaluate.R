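#' Evaluate presence/absence predictions
#'
#' AUC is computed as the rank statistic (probability that a random
#' presence outranks a random absence, ties counted half), and the True
#' Skill Statistic as the maximum of sensitivity + specificity - 1 over all
#' decision thresholds, scanning the sorted unique scores with a predicted
#' presence when `score >= threshold`. On TSS ties the smallest threshold
#' is reported.
#'
#' @param scores numeric prediction scores (higher = more presence-like).
#' @param labels 0/1 (or logical) observed classes; both classes required.
#' @return A list of class `model_evaluation`: `auc`, `tss`,
#'   `optimal_threshold`, `n_presence`, `n_absence`.
#' @export
evaluate_predictions <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(scores))
  # predicted positive iff score >= t; cumulative counts below t give FN/TN
  ord <- order(scores)
  y <- labels[ord]; s <- scores[ord]
  below_pos <- cumsum(y)          # positives with score <= s[i]
  below_neg <- cumsum(1 - y)      # negatives with score <= s[i]
  last_lt <- findInterval(th, s, left.open = TRUE)  # count of scores < t
  fn <- c(0, below_pos)[last_lt + 1]
  tn <- c(0, below_neg)[last_lt + 1]
  sens <- (n1 - fn) / n1
  spec <- tn / n0
  tss_all <- sens + spec - 1
  best <- which.max(tss_all)      # first index = smallest threshold on ties
  structure(list(auc = auc, tss = tss_all[best],
                 optimal_threshold = th[best],
                 n_presence = n1, n_absence = n0),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f, TSS %.3f (threshold %.3f); %d presences / %d absences\n",
    x$auc, x$tss, x$optimal_threshold, x$n_presence, x$n_absence))
  invisible(x)
}
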