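#' Convert non-negative abundances to log2 fold-changes
#'
#' Each value becomes `log2(v + pseudocount)` minus the per-feature median of
#' the same transform across samples (missing values ignored), so a feature's
#' fold-changes are relative to its own cohort median.
#'
#' @param x feature-by-sample matrix of non-negative abundances (FPKM-like).
#' @param pseudocount added before the log to keep zeros finite.
#' @return matrix of log2 fold-changes, same shape and dimnames.
#' @export
log2fc_from_abundance <- function(x, pseudocount = sigact_config()$pseudocount) {
  if (any(x < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  l <- log2(x + pseudocount)
  meds <- apply(l, 1L, median, na.rm = TRUE)
  out <- l - meds            # all-NA rows: median NA -> row stays NA
  attr(out, "layer") <- attr(x, "layer")
  out
}

#' Drop samples with extreme median fold-changes
#'
#' A sample whose absolute median log2 fold-change over all features is
#' strictly greater than `threshold` (default 1, i.e. two-fold) is removed.
#'
#' @param x feature-by-sample matrix.
#' @param threshold positive cutoff on the absolute sample median.
#' @return list with `matrix` (retained samples) and `dropped` (sample ids
#'   with their offending medians).
#' @export
remove_outlier_samples <- function(x,
                                   threshold = sigact_config()$outlier_threshold) {
  stopifnot(threshold > 0)
  med <- apply(x, 2L, median, na.rm = TRUE)
  drop <- !is.na(med) & abs(med) > threshold
  list(matrix = x[, !drop, drop = FALSE],
       dropped = data.frame(sample_id = colnames(x)[drop],
                            median_log2fc = unname(med[drop]),
                            stringsAsFactors = FALSE))
}

#' Quantile-normalize sample distributions
#'
#' Makes the per-sample value distributions identical (the per-rank mean of
#' the column quantiles) while preserving within-sample rank order. Missing
#' cells stay missing; ranks are computed on observed values only with the
#' target quantiles interpolated to each column's observed count.
#'
#' @param x feature-by-sample matrix with at least two samples.
#' @return normalized matrix, same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
  out <- limma::normalizeQuantiles(x)
  dimnames(out) <- dimnames(x)
  attr(out, "layer") <- attr(x, "layer")
  out
}

#' Regress confounders out of a measurement matrix
#'
#' Fits per-feature ordinary least squares of the target row on an optional
#' matched predictor row (e.g. a phosphosite on its host protein) plus
#' per-sample covariates (e.g. age, gender or study), returning residuals.
#' Fitting uses complete cases per row; cells whose predictors are missing
#' become `NA`. Rows with fewer than `min_samples` usable samples, or with no
#' matched predictor row, pass through unchanged and are flagged.
#'
#' @param target feature-by-sample matrix to residualize.
#' @param predictor optional matrix supplying one matched predictor row per
#'   target row; omit for covariate-only (batch) removal.
#' @param row_map named character vector mapping target row -> predictor row;
#'   defaults to identical row names.
#' @param covariates optional data.frame of per-sample covariates, rows
#'   aligned to `colnames(target)`. Single-level covariates are dropped with
#'   a warning.
#' @param min_samples minimum complete cases needed to fit a row.
#' @return matrix of residuals with attributes `provenance` (covariates
#'   removed), `passthrough` (unfitted row names) and `n_used` (samples per
#'   fitted row).
#' @export
regress_out <- function(target, predictor = NULL, row_map = NULL,
                        covariates = NULL, min_samples = 3) {
  samples <- colnames(target)
  cov_mat <- NULL
  removed <- character(0)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(samples))
    keep <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) > 1,
                   logical(1))
    if (any(!keep))
      warning("dropping single-level covariate(s): ",
              paste(names(covariates)[!keep], collapse = ", "))
    covariates <- covariates[, keep, drop = FALSE]
    if (ncol(covariates)) {
      cov_mat <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
      removed <- colnames(covariates)
    }
  }
  if (!is.null(predictor)) {
    if (is.null(row_map)) {
      shared <- intersect(rownames(target), rownames(predictor))
      row_map <- setNames(shared, shared)
    }
    removed <- c("matched_predictor", removed)
  }

  out <- target
  passthrough <- character(0)
  n_used <- setNames(integer(nrow(target)), rownames(target))
  for (i in seq_len(nrow(target))) {
    feat <- rownames(target)[i]
    y <- target[i, ]
    X <- NULL
    if (!is.null(predictor)) {
      pr <- row_map[feat]
      if (is.na(pr) || !(pr %in% rownames(predictor))) {
        passthrough <- c(passthrough, feat)
        next
      }
      X <- cbind(predictor_row = predictor[pr, ])
    }
    if (!is.null(cov_mat)) X <- cbind(X, cov_mat)
    if (is.null(X)) stop("regress_out needs a predictor and/or covariates")
    use <- !is.na(y) & complete.cases(X)
    if (sum(use) < min_samples) {
      passthrough <- c(passthrough, feat)
      next
    }
    Xu <- cbind(1, X[use, , drop = FALSE])
    fit <- lm.fit(Xu, y[use])
    res <- rep(NA_real_, length(y))
    res[use] <- fit$residuals
    out[i, ] <- res
    n_used[feat] <- sum(use)
  }
  attr(out, "provenance") <- removed
  attr(out, "passthrough") <- passthrough
  attr(out, "n_used") <- n_used
  out
}

#' Collapse duplicated phosphosite records
#'
#' Records from multiply-phosphorylated peptides (`multiplicity > 1`) are
#' discarded. Remaining records sharing a site key collapse to one row if
#' their value vectors are identical across samples (missing-aware); sites
#' with conflicting duplicates are dropped entirely.
#'
#' @param records data.frame with columns `protein`, `position`, `residue`,
#'   `multiplicity` followed by one numeric column per sample.
#' @return feature-by-sample matrix of unique single-site records, rows named
#'   by [site_key()].
#' @export
deduplicate_phosphosites <- function(records) {
  key_cols <- c("protein", "position", "residue", "multiplicity")
  stopifnot(all(key_cols %in% names(records)))
  sample_cols <- setdiff(names(records), key_cols)
  records <- records[as.integer(records$multiplicity) == 1L, , drop = FALSE]
  if (!nrow(records)) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(sample_cols),
                dimnames = list(character(0), sample_cols))
    return(feature_matrix(m, "phospho"))
  }
  keys <- site_key(records$protein, records$position, records$residue)
  vals <- as.matrix(records[, sample_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  keep <- logical(0)
  out_rows <- list()
  for (k in unique(keys)) {
    idx <- which(keys == k)
    block <- vals[idx, , drop = FALSE]
    same <- all(apply(block, 2L, function(col) {
      obs <- is.na(col)
      length(unique(obs)) == 1L && (all(obs) || length(unique(col)) == 1L)
    }))
    if (same) out_rows[[k]] <- block[1L, ]
  }
  m <- do.call(rbind, out_rows)
  if (is.null(m)) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(sample_cols))
  }
  dimnames(m) <- list(names(out_rows), sample_cols)
  feature_matrix(m, "phospho")
}

#' Validate site or mutation residues against protein sequences
#'
#' An item is kept when the FASTA sequence carries the declared residue at
#' the declared 1-based position. Splice-site mutation records carry no
#' residue and are kept unchecked. Items whose protein lacks a sequence are
#' rejected with reason `"no_sequence"`.
#'
#' @param items data.frame of phosphosites (`protein`, `position`, `residue`)
#'   or mutation records (`gene`, `position`, `ref_residue`, `mclass`).
#' @param fasta named character vector of sequences, as from [read_fasta()].
#' @return list with `kept` and `rejected` data.frames; both carry a
#'   `reason` column (`"match"`, `"not_checked"`, `"mismatch"`,
#'   `"out_of_range"`, `"no_sequence"`).
#' @export
validate_against_sequences <- function(items, fasta) {
  is_mut <- "mclass" %in% names(items)
  prot <- if (is_mut) items$gene else items$protein
  res <- if (is_mut) items$ref_residue else items$residue
  pos <- as.integer(items$position)
  reason <- character(nrow(items))
  for (i in seq_len(nrow(items))) {
    if (is_mut && items$mclass[i] == "splice_site") {
      reason[i] <- "not_checked"
      next
    }
    sq <- fasta[prot[i]]
    if (is.na(sq)) {
      reason[i] <- "no_sequence"
    } else if (pos[i] > nchar(sq)) {
      reason[i] <- "out_of_range"
    } else if (substr(sq, pos[i], pos[i]) == res[i]) {
      reason[i] <- "match"
    } else {
      reason[i] <- "mismatch"
    }
  }
  items$reason <- reason
  keep <- reason %in% c("match", "not_checked")
  list(kept = items[keep, , drop = FALSE],
       rejected = items[!keep, , drop = FALSE])
}

#' Build a binary gene-by-sample mutation matrix
#'
#' `M[g, s]` is 1 when sample `s` carries at least one qualifying mutation
#' (missense, nonsense, frameshift/in-frame indel or stop loss) in gene `g`,
#' 0 otherwise. Silent and splice-site records are excluded. The result is
#' invariant to record order.
#'
#' @param records mutation data.frame as from [read_mutations()].
#' @param samples,genes optional id vectors fixing the matrix extent (all
#'   observed ids by default, sorted).
#' @return binary integer matrix, genes as rows, samples as columns.
#' @export
build_mutation_matrix <- function(records, samples = NULL, genes = NULL) {
  rec <- records[records$mclass %in% QUALIFYING_CLASSES, , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(records$sample_id))
  if (is.null(genes)) genes <- sort(unique(rec$gene))
  m <- matrix(0L, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  rec <- rec[rec$gene %in% genes & rec$sample_id %in% samples, , drop = FALSE]
  if (nrow(rec)) m[cbind(rec$gene, rec$sample_id)] <- 1L
  m
}
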