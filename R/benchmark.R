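#' Area under the ROC curve
#'
#' Rank formulation of the probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties counted one half.
#'
#' @param scores numeric classifier scores.
#' @param labels logical (or 0/1) class labels, `TRUE` for positives; both
#'   classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    stop("auroc needs at least one positive and one negative")
  r <- rank(scores)                     # average ranks give half credit to ties
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Benchmark a substrate prior by balanced-resampling AUROC
#'
#' Gold-standard (kinase, condition) pairs are the positives; pairs with
#' unknown regulation form the negative pool. Because positives are far
#' outnumbered, each of `n_resamples` rounds draws (without replacement) a
#' negative set matched in size to the positives and scores the absolute
#' activities as a classifier. Optionally positives are subsampled to a
#' fixed size per round, equalising power across priors of different
#' coverage.
#'
#' @param activity kinase-by-condition activity matrix (absolute values are
#'   taken internally).
#' @param gold data.frame with `kinase` and `condition_id` columns marking
#'   known regulation events.
#' @param n_resamples number of balanced negative draws (default 100).
#' @param seed optional integer seed making the resampling reproducible.
#' @param subsample_positives optional per-round positive subsample size.
#' @return list with `aurocs` (per-resample values), `mean_auroc`,
#'   `n_positives` and `n_negatives_per_set`.
#' @export
evaluate_prior <- function(activity, gold,
                           n_resamples = sigact_config()$n_resamples,
                           seed = NULL, subsample_positives = NULL) {
  stopifnot(n_resamples >= 1)
  scored <- which(!is.na(activity), arr.ind = TRUE)
  keys <- paste(rownames(activity)[scored[, 1]],
                colnames(activity)[scored[, 2]], sep = "\r")
  scores <- abs(activity[scored])
  gold_keys <- paste(gold$kinase, gold$condition_id, sep = "\r")
  is_pos <- keys %in% gold_keys
  np <- sum(is_pos)
  if (np == 0L) stop("no gold-standard positives among scored pairs")
  neg_pool <- which(!is_pos)
  draw_pos <- if (is.null(subsample_positives)) np
              else min(subsample_positives, np)
  if (length(neg_pool) < draw_pos)
    stop("fewer unknown pairs (", length(neg_pool),
         ") than required negatives (", draw_pos, ")")
  if (!is.null(seed)) set.seed(seed)
  pos_idx <- which(is_pos)
  aucs <- vapply(seq_len(n_resamples), function(i) {
    p <- if (draw_pos < np) sample(pos_idx, draw_pos) else pos_idx
    n <- sample(neg_pool, draw_pos)
    auroc(c(scores[p], scores[n]),
          c(rep(TRUE, length(p)), rep(FALSE, length(n))))
  }, numeric(1))
  list(aurocs = aucs, mean_auroc = mean(aucs), n_positives = np,
       n_negatives_per_set = draw_pos)
}
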