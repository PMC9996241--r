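#' Sample-by-sample Spearman cross-correlation
#'
#' Correlates the combined kinase/TF activity profiles of every sample pair
#' on pairwise-complete observations. Pairs sharing fewer than `min_shared`
#' measured features yield a missing cell. The result is symmetric with a
#' unit diagonal.
#'
#' @param activity combined feature-by-sample activity matrix.
#' @param min_shared minimum shared features per sample pair (default 3).
#' @return sample-by-sample correlation matrix.
#' @export
sample_cross_correlation <- function(activity, min_shared = 3) {
  cc <- suppressWarnings(cor(activity, method = "spearman",
                             use = "pairwise.complete.obs"))
  obs <- !is.na(activity)
  shared <- crossprod(obs)                 # shared measured features per pair
  cc[shared < min_shared] <- NA_real_
  diag(cc) <- 1
  cc
}

#' Cluster samples by their correlation profiles
#'
#' Computes Euclidean distances between the rows of the sample
#' cross-correlation matrix, builds a complete-linkage hierarchical tree and
#' cuts it into exactly `k` groups. Missing correlation cells are imputed
#' with the column median beforehand. Cluster ids are relabelled by
#' decreasing cluster size for stable reporting; the partition is
#' deterministic and invariant to sample order.
#'
#' @param corr sample-by-sample correlation matrix from
#'   [sample_cross_correlation()].
#' @param k number of clusters, `2 <= k <= n_samples`.
#' @return list with `clusters` (named integer vector, ids 1..k by
#'   decreasing size), `k` and the `hclust` tree.
#' @export
cluster_samples <- function(corr, k = sigact_config()$n_clusters) {
  n <- ncol(corr)
  stopifnot(k >= 2, k <= n)
  corr <- corr[sort(rownames(corr)), sort(colnames(corr))]
  if (anyNA(corr)) {
    for (j in seq_len(ncol(corr))) {
      col <- corr[, j]
      col[is.na(col)] <- median(col, na.rm = TRUE)
      corr[, j] <- col
    }
  }
  tree <- hclust(dist(corr, method = "euclidean"), method = "complete")
  raw <- cutree(tree, k = k)
  sizes <- table(raw)
  remap <- setNames(seq_along(sizes),
                    names(sizes)[order(-sizes, as.integer(names(sizes)))])
  clusters <- setNames(unname(remap[as.character(raw)]), names(raw))
  list(clusters = clusters, k = k, tree = tree)
}

#' Cluster-level activity scores
#'
#' Summarises each protein within each sample cluster as the median activity
#' divided by the standard deviation of the member activities. Cells with
#' fewer than two measured members or zero spread are degenerate and carry
#' no score. Absolute scores at or above `dereg_threshold` mark the protein
#' as deregulated in that cluster.
#'
#' @param activity protein-by-sample activity matrix.
#' @param clusters named integer cluster map from [cluster_samples()].
#' @param dereg_threshold absolute score calling deregulation (2).
#' @return list with matrices `scores`, `degenerate` (logical) and
#'   `deregulated` (logical; `FALSE` where degenerate).
#' @export
cluster_activity_scores <- function(activity, clusters,
                                    dereg_threshold = sigact_config()$dereg_threshold) {
  ids <- sort(unique(clusters))
  scores <- matrix(NA_real_, nrow(activity), length(ids),
                   dimnames = list(rownames(activity), as.character(ids)))
  degen <- matrix(FALSE, nrow(activity), length(ids),
                  dimnames = dimnames(scores))
  for (ci in seq_along(ids)) {
    members <- intersect(names(clusters)[clusters == ids[ci]],
                         colnames(activity))
    block <- activity[, members, drop = FALSE]
    for (ri in seq_len(nrow(block))) {
      v <- block[ri, ]
      v <- v[!is.na(v)]
      if (length(v) < 2L || sd(v) == 0) {
        degen[ri, ci] <- TRUE
        next
      }
      scores[ri, ci] <- median(v) / sd(v)
    }
  }
  list(scores = scores, degenerate = degen,
       deregulated = !is.na(scores) & abs(scores) >= dereg_threshold)
}

#' Clinical feature over-representation in sample clusters
#'
#' Binarises BMI (`big`/`smol` at `bmi_cutoff`) and age
#' (`venerable`/`young` at `age_cutoff`), drops clinical levels populated by
#' fewer than `min_level_count` patients, and tests each remaining level for
#' over-representation in each cluster with a hypergeometric upper-tail
#' probability (at least the observed overlap given the cluster size, level
#' total and cohort size). BH adjustment is across all tests.
#'
#' @param clusters named integer cluster map from [cluster_samples()].
#' @param clinical clinical table with `sample_id` plus categorical columns;
#'   `age` and `bmi` are binarised when present.
#' @param features clinical columns to test (default: every categorical
#'   column present among study, tissue, gender, subtype, plus binarised
#'   bmi/age).
#' @param min_level_count minimum patients per retained level (5).
#' @param bmi_cutoff,age_cutoff binarisation cutoffs (37, 50).
#' @return data.frame (`feature`, `level`, `cluster`, `overlap`,
#'   `cluster_size`, `level_total`, `cohort_size`, `p`, `fdr`).
#' @export
clinical_overrepresentation <- function(clusters, clinical, features = NULL,
                                        min_level_count = sigact_config()$min_level_count,
                                        bmi_cutoff = sigact_config()$bmi_cutoff,
                                        age_cutoff = sigact_config()$age_cutoff) {
  cl <- clinical[clinical$sample_id %in% names(clusters), , drop = FALSE]
  if ("bmi" %in% names(cl))
    cl$bmi_group <- ifelse(is.na(cl$bmi), NA,
                           ifelse(cl$bmi > bmi_cutoff, "big", "smol"))
  if ("age" %in% names(cl))
    cl$age_group <- ifelse(is.na(cl$age), NA,
                           ifelse(cl$age >= age_cutoff, "venerable", "young"))
  if (is.null(features))
    features <- intersect(c("study", "tissue", "gender", "subtype",
                            "bmi_group", "age_group"), names(cl))
  n_cohort <- nrow(cl)
  memb <- clusters[cl$sample_id]
  rows <- list()
  for (ft in features) {
    vals <- as.character(cl[[ft]])
    for (lv in sort(unique(vals[!is.na(vals)]))) {
      in_level <- !is.na(vals) & vals == lv
      k_total <- sum(in_level)
      if (k_total < min_level_count) next
      for (ci in sort(unique(memb))) {
        in_cluster <- memb == ci
        q <- sum(in_level & in_cluster)
        m <- sum(in_cluster)
        p <- phyper(q - 1, k_total, n_cohort - k_total, m,
                    lower.tail = FALSE)
        rows[[paste(ft, lv, ci)]] <- data.frame(
          feature = ft, level = lv, cluster = ci, overlap = q,
          cluster_size = m, level_total = k_total, cohort_size = n_cohort,
          p = p, fdr = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(0), level = character(0),
               cluster = integer(0), overlap = integer(0),
               cluster_size = integer(0), level_total = integer(0),
               cohort_size = integer(0), p = numeric(0), fdr = numeric(0))
  rownames(out) <- NULL
  if (nrow(out)) out$fdr <- bh_adjust(out$p)
  out
}
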