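# one OLS fit of y on a focal term, adjusted for the experimental study.
# Singleton studies are merged into the reference level; a constant study
# term is dropped. Returns NULL when the fit is degenerate.
ols_term <- function(y, x, study = NULL) {
  use <- !is.na(y) & !is.na(x)
  if (!is.null(study)) use <- use & !is.na(study)
  y <- y[use]; x <- x[use]
  n <- length(y)
  if (n < 3L || sd(y) == 0 || sd(x) == 0) return(NULL)
  df <- data.frame(y = y, x = x)
  if (!is.null(study)) {
    st <- factor(as.character(study[use]))
    tab <- table(st)
    if (any(tab == 1L)) {
      warning("merging singleton stud(y/ies) into the reference level: ",
              paste(names(tab)[tab == 1L], collapse = ", "))
      lv <- levels(st)
      st <- as.character(st)
      st[st %in% names(tab)[tab == 1L]] <- lv[1]
      st <- factor(st)
    }
    if (nlevels(st) > 1L) df$study <- st
  }
  p_needed <- 1L + 1L + if (is.null(df$study)) 0L else nlevels(df$study) - 1L
  if (n < p_needed + 1L) return(NULL)
  fit <- lm(y ~ ., data = df)
  cf <- summary(fit)$coefficients
  if (!("x" %in% rownames(cf)) || is.na(cf["x", 1])) return(NULL)
  list(beta = unname(cf["x", 1]), se = unname(cf["x", 2]),
       t = unname(cf["x", 3]), p = max(unname(cf["x", 4]), .P_FLOOR), n = n)
}

assoc_record <- function(predictor, response, fit, tag) {
  data.frame(predictor_id = predictor, response_id = response,
             beta = fit$beta, se = fit$se, t = fit$t, p = fit$p,
             fdr = NA_real_, n_samples = fit$n, model_tag = tag,
             stringsAsFactors = FALSE)
}

#' Associate protein activities with gene mutation status
#'
#' For each (mutated gene X, protein Y) pair, fits across samples the
#' study-adjusted linear model `Y_act ~ study + X_mut` where `X_mut` is the
#' binary mutation indicator, and tests the mutation coefficient by a
#' t-test. Self pairs (the protein's own mutations, tagged `"self"`) are
#' included. Pairs are tested only when the gene is mutated in more than
#' `min_gene_mut` samples overall, the activity is measured in at least
#' `min_act_samples` samples, and the gene is mutated in at least
#' `min_pair_mut` of the pair's complete-case samples. P-values are
#' BH-adjusted across all tested pairs of the call.
#'
#' @param activity protein-by-sample activity matrix.
#' @param mutation_matrix binary gene-by-sample matrix from
#'   [build_mutation_matrix()].
#' @param study per-sample study labels, named by sample id (or aligned to
#'   `colnames(activity)`).
#' @param min_gene_mut,min_act_samples,min_pair_mut the three filters
#'   (defaults 20, 10, 5).
#' @param verbose log skipped pairs.
#' @return data.frame of association records (`predictor_id` = gene,
#'   `response_id` = protein, `beta`, `se`, `t`, `p`, `fdr`, `n_samples`,
#'   `model_tag`).
#' @export
fit_activity_mutation <- function(activity, mutation_matrix, study = NULL,
                                  min_gene_mut = sigact_config()$min_gene_mut,
                                  min_act_samples = sigact_config()$min_act_samples,
                                  min_pair_mut = sigact_config()$min_pair_mut,
                                  verbose = FALSE) {
  samples <- intersect(colnames(activity), colnames(mutation_matrix))
  if (!length(samples)) stop("no shared samples between activity and mutations")
  act <- activity[, samples, drop = FALSE]
  mut <- mutation_matrix[, samples, drop = FALSE]
  study <- align_study(study, samples)

  genes <- rownames(mut)[rowSums(mut, na.rm = TRUE) > min_gene_mut]
  prots <- rownames(act)[rowSums(!is.na(act)) >= min_act_samples]
  recs <- list()
  for (g in genes) {
    mg <- mut[g, ]
    for (pr in prots) {
      y <- act[pr, ]
      use <- !is.na(y) & !is.na(mg)
      if (sum(mg[use]) < min_pair_mut) next
      fit <- ols_term(y[use], mg[use],
                      if (is.null(study)) NULL else study[use])
      if (is.null(fit)) {
        sigact_log(verbose, "skipped pair ", g, " -> ", pr,
                   " (degenerate fit)")
        next
      }
      recs[[paste(g, pr)]] <-
        assoc_record(g, pr, fit, if (g == pr) "self" else "eq3")
    }
  }
  finish_assoc(recs)
}

align_study <- function(study, samples) {
  if (is.null(study)) return(NULL)
  if (!is.null(names(study))) {
    miss <- setdiff(samples, names(study))
    if (length(miss)) stop("study labels missing for samples: ",
                           paste(head(miss, 3), collapse = ", "))
    study <- study[samples]
  } else if (length(study) != length(samples)) {
    stop("study labels must be named by sample or aligned to samples")
  }
  as.character(study)
}

finish_assoc <- function(recs) {
  if (!length(recs)) {
    return(data.frame(predictor_id = character(0), response_id = character(0),
                      beta = numeric(0), se = numeric(0), t = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      n_samples = integer(0), model_tag = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out$fdr <- bh_adjust(out$p)
  out
}

#' Associate TF activities with kinase activities
#'
#' For each (kinase K, TF T) pair fits `T_act ~ study + K_act` over their
#' shared samples and tests the kinase coefficient; BH adjustment is across
#' all tested pairs of the call.
#'
#' @param tf_activity TF-by-sample activity matrix (responses).
#' @param kinase_activity kinase-by-sample activity matrix (predictors).
#' @param study per-sample study labels (optional, named by sample).
#' @param min_overlap minimum shared samples beyond the parameter count.
#' @return data.frame of association records tagged `"eq4"`.
#' @export
fit_kinase_tf <- function(tf_activity, kinase_activity, study = NULL,
                          min_overlap = 2) {
  samples <- intersect(colnames(tf_activity), colnames(kinase_activity))
  if (!length(samples)) stop("no shared samples")
  tfm <- tf_activity[, samples, drop = FALSE]
  kim <- kinase_activity[, samples, drop = FALSE]
  study <- align_study(study, samples)
  recs <- list()
  for (k in rownames(kim)) {
    xk <- kim[k, ]
    for (tf in rownames(tfm)) {
      y <- tfm[tf, ]
      use <- !is.na(y) & !is.na(xk)
      n_par <- 2L + if (is.null(study)) 0L
               else max(0L, length(unique(study[use])) - 1L)
      if (sum(use) < n_par + min_overlap) next
      fit <- ols_term(y, xk, study)
      if (is.null(fit)) next
      recs[[paste(k, tf)]] <- assoc_record(k, tf, fit, "eq4")
    }
  }
  finish_assoc(recs)
}

#' Joint effects of recurrent hotspot mutations on activities
#'
#' Fits, per response protein, one multiple regression of its activity on
#' all hotspot indicators entered jointly (e.g. BRAF V600E, KRAS G12C and
#' KRAS G12D), yielding one record per (hotspot, protein) coefficient.
#' Constant or collinear indicators are dropped with a warning. BH
#' adjustment is per coefficient family (within each hotspot, across
#' proteins).
#'
#' @param activity protein-by-sample activity matrix.
#' @param hotspots binary sample-by-indicator matrix; column names label the
#'   hotspot mutations.
#' @return data.frame of association records tagged `"eq2"`.
#' @export
fit_recurrent_mutations <- function(activity, hotspots) {
  stopifnot(is.matrix(hotspots), !is.null(colnames(hotspots)))
  samples <- intersect(colnames(activity), rownames(hotspots))
  if (!length(samples)) stop("no shared samples")
  hot <- hotspots[samples, , drop = FALSE]
  recs <- list()
  for (pr in rownames(activity)) {
    y <- activity[pr, samples]
    use <- !is.na(y) & complete.cases(hot)
    if (sum(use) < ncol(hot) + 3L) next
    X <- hot[use, , drop = FALSE]
    keep <- apply(X, 2L, function(v) length(unique(v)) > 1L)
    X <- X[, keep, drop = FALSE]
    if (!ncol(X) || sd(y[use]) == 0) next
    fit <- lm(y[use] ~ X)
    cf <- summary(fit)$coefficients
    dropped <- union(colnames(hot)[!keep],
                     colnames(X)[is.na(coef(fit)[-1])])
    if (length(dropped))
      warning("dropping constant/collinear hotspot indicator(s) for ", pr,
              ": ", paste(dropped, collapse = ", "))
    for (h in colnames(X)) {
      rn <- paste0("X", h)
      if (!(rn %in% rownames(cf))) next
      recs[[paste(h, pr)]] <- assoc_record(
        h, pr,
        list(beta = unname(cf[rn, 1]), se = unname(cf[rn, 2]),
             t = unname(cf[rn, 3]), p = max(unname(cf[rn, 4]), .P_FLOOR),
             n = sum(use)),
        "eq2")
    }
  }
  if (!length(recs)) return(finish_assoc(recs))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out$fdr <- stats::ave(out$p, out$predictor_id, FUN = bh_adjust)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; values are monotone
#' non-decreasing in sorted order and capped at 1.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Enrichment of significant associations in a confidence-filtered network
#'
#' The edge list is filtered at `min_score`; at each significance cutoff the
#' tested association pairs split into a 2x2 table of (significant vs not)
#' by (edge in the filtered network vs not), assessed by a one-sided
#' (greater) Fisher exact test. The background is always the full set of
#' tested pairs, so the table total is constant across cutoffs.
#'
#' @param records association data.frame with `predictor_id`, `response_id`
#'   and `fdr`.
#' @param edges canonical edge list from [read_edges()].
#' @param min_score minimum combined score for a confident edge (850).
#' @param cutoffs grid of -log10 adjusted-p cutoffs.
#' @return data.frame (`cutoff`, `p`, `a`, `b`, `c`, `d`) where `a` counts
#'   significant in-network pairs.
#' @export
string_enrichment <- function(records, edges,
                              min_score = sigact_config()$string_min_score,
                              cutoffs = seq(0.25, 3, by = 0.25)) {
  ed <- edges[edges$combined_score >= min_score, , drop = FALSE]
  if (!nrow(ed)) stop("no edges left after score filter")
  net_keys <- paste(ed$protein_a, ed$protein_b, sep = "\r")
  pair_keys <- paste(pmin(records$predictor_id, records$response_id),
                     pmax(records$predictor_id, records$response_id),
                     sep = "\r")
  in_net <- pair_keys %in% net_keys
  neglog <- -log10(pmax(records$fdr, .P_FLOOR))
  out <- lapply(cutoffs, function(cut) {
    sig <- neglog > cut
    a <- sum(sig & in_net);  b <- sum(sig & !in_net)
    cc <- sum(!sig & in_net); d <- sum(!sig & !in_net)
    p <- if (a + b == 0L) 1 else
      fisher.test(matrix(c(a, cc, b, d), 2), alternative = "greater")$p.value
    data.frame(cutoff = cut, p = p, a = a, b = b, c = cc, d = d)
  })
  do.call(rbind, out)
}

#' Split samples by the sign of a protein's activity
#'
#' Samples whose absolute activity is at or below `noise_cutoff` are
#' excluded; the rest are labelled `"low"` (negative activity) or `"high"`
#' (positive), the grouping used for differential expression contrasts.
#'
#' @param activity protein-by-sample activity matrix.
#' @param protein row to split on.
#' @param noise_cutoff absolute activity treated as noise (0.15).
#' @return factor with levels `low`, `high`, named by the retained samples.
#' @export
activity_sign_groups <- function(activity, protein,
                                 noise_cutoff = sigact_config()$noise_cutoff) {
  a <- activity[protein, ]
  keep <- !is.na(a) & abs(a) > noise_cutoff
  factor(ifelse(a[keep] > 0, "high", "low"), levels = c("low", "high"))
}

#' Differential expression between two sample groups
#'
#' Per feature: the log2 ratio of group means computed on the linear
#' (FPKM-like) scale as `log2(mean(first level) / mean(second level))`, a
#' two-sided Wilcoxon rank-sum p-value, and BH adjustment across features.
#'
#' @param expression feature-by-sample matrix on a linear scale.
#' @param groups factor with exactly two levels, named by sample id; the
#'   first level is the ratio numerator. Each group needs at least two
#'   samples.
#' @return data.frame (`feature`, `log2fc`, `p`, `fdr`, `n1`, `n2`,
#'   `flagged` for zero/absent denominator means).
#' @export
diff_expression_groups <- function(expression, groups) {
  stopifnot(is.factor(groups), nlevels(groups) == 2L)
  if (is.null(names(groups))) stop("groups must be named by sample id")
  g1 <- names(groups)[groups == levels(groups)[1]]
  g2 <- names(groups)[groups == levels(groups)[2]]
  g1 <- intersect(g1, colnames(expression))
  g2 <- intersect(g2, colnames(expression))
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each group needs at least two samples with expression data")
  out <- lapply(rownames(expression), function(f) {
    v1 <- expression[f, g1]; v2 <- expression[f, g2]
    v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
    if (length(v1) < 2L || length(v2) < 2L)
      return(data.frame(feature = f, log2fc = NA_real_, p = NA_real_,
                        n1 = length(v1), n2 = length(v2), flagged = TRUE))
    m1 <- mean(v1); m2 <- mean(v2)
    bad <- is.na(m2) || m2 == 0 || m1 == 0
    lfc <- if (bad) NA_real_ else log2(m1 / m2)
    p <- suppressWarnings(wilcox.test(v1, v2)$p.value)
    if (is.nan(p)) p <- 1          # fully tied groups carry no evidence
    data.frame(feature = f, log2fc = lfc, p = p,
               n1 = length(v1), n2 = length(v2), flagged = bad)
  })
  out <- do.call(rbind, out)
  tested <- !is.na(out$p)
  out$fdr <- NA_real_
  out$fdr[tested] <- bh_adjust(out$p[tested])
  out[, c("feature", "log2fc", "p", "fdr", "n1", "n2", "flagged")]
}

#' Average effect of mutation classes on protein abundance
#'
#' Groups mutations as loss-of-function (frameshift, nonsense, splice site,
#' stop loss), in-frame indels and missense, and contrasts the protein log2
#' fold-changes of carrier (gene, sample) cells against non-carrier cells of
#' the same genes by a rank-sum test. Silent mutations are ignored.
#'
#' @param protein_matrix gene-by-sample protein log2 fold-change matrix.
#' @param records mutation data.frame as from [read_mutations()].
#' @return data.frame (`class`, `n_carrier`, `mean_carrier`,
#'   `mean_background`, `effect`, `p`); classes with no measured carriers
#'   are absent.
#' @export
mutation_abundance_effect <- function(protein_matrix, records) {
  groups <- list(lof = LOF_CLASSES, inframe = "inframe_indel",
                 missense = "missense")
  out <- list()
  for (cls in names(groups)) {
    rec <- records[records$mclass %in% groups[[cls]], , drop = FALSE]
    rec <- rec[rec$gene %in% rownames(protein_matrix) &
                 rec$sample_id %in% colnames(protein_matrix), , drop = FALSE]
    if (!nrow(rec)) next
    carrier_idx <- unique(cbind(match(rec$gene, rownames(protein_matrix)),
                                match(rec$sample_id, colnames(protein_matrix))))
    carrier <- protein_matrix[carrier_idx]
    genes <- unique(rec$gene)
    is_carrier <- matrix(FALSE, nrow(protein_matrix), ncol(protein_matrix))
    is_carrier[carrier_idx] <- TRUE
    gene_rows <- matrix(rownames(protein_matrix) %in% genes,
                        nrow(protein_matrix), ncol(protein_matrix))
    bg <- protein_matrix[gene_rows & !is_carrier]
    carrier <- carrier[!is.na(carrier)]
    bg <- bg[!is.na(bg)]
    if (!length(carrier)) next
    p <- if (length(bg)) suppressWarnings(wilcox.test(carrier, bg)$p.value)
         else NA_real_
    out[[cls]] <- data.frame(class = cls, n_carrier = length(carrier),
                             mean_carrier = mean(carrier),
                             mean_background = mean(bg),
                             effect = mean(carrier) - mean(bg), p = p,
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(class = character(0), n_carrier = integer(0),
                      mean_carrier = numeric(0), mean_background = numeric(0),
                      effect = numeric(0), p = numeric(0)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
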