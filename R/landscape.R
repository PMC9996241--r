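#' Correlate protein activities with their own omics layers
#'
#' For each protein, Pearson-correlates its activity profile with its own
#' copy-number, mRNA, protein-abundance and phosphorylation values over the
#' shared samples. The phospho layer is summarised as the mean residual of
#' the protein's measured sites (rows named by [site_key()] are collapsed by
#' host protein). Correlation p-values are BH-adjusted within each layer;
#' proteins with fewer than `n_min` overlapping samples, or no data, are
#' labelled `"unknown"`.
#'
#' @param activity protein-by-sample activity matrix.
#' @param layers named list of feature-by-sample matrices; recognised names
#'   are `cnv`, `rna`, `protein`, `phospho`.
#' @param n_min minimum overlap for a defined correlation (default 10).
#' @param fdr_cutoff significance level on the adjusted p-value.
#' @return data.frame (`protein`, `layer`, `r`, `p`, `fdr`, `n`, `status`).
#' @export
correlate_activity_layers <- function(activity, layers,
                                      n_min = sigact_config()$n_min_correlation,
                                      fdr_cutoff = sigact_config()$fdr_cutoff) {
  stopifnot(is.list(layers), !is.null(names(layers)))
  out <- list()
  for (ly in names(layers)) {
    lm_ <- layers[[ly]]
    if (ly == "phospho" && any(grepl("_[STY][0-9]+$", rownames(lm_))))
      lm_ <- summarise_sites_by_protein(lm_)
    shared_samples <- intersect(colnames(activity), colnames(lm_))
    rows <- lapply(rownames(activity), function(pr) {
      rec <- data.frame(protein = pr, layer = ly, r = NA_real_, p = NA_real_,
                        fdr = NA_real_, n = 0L, status = "unknown",
                        stringsAsFactors = FALSE)
      if (!(pr %in% rownames(lm_))) return(rec)
      a <- activity[pr, shared_samples]
      v <- lm_[pr, shared_samples]
      use <- !is.na(a) & !is.na(v)
      rec$n <- sum(use)
      if (rec$n < n_min || sd(a[use]) == 0 || sd(v[use]) == 0) return(rec)
      ct <- cor.test(a[use], v[use], method = "pearson")
      rec$r <- unname(ct$estimate); rec$p <- ct$p.value
      rec$status <- "not_significant"
      rec
    })
    layer_df <- do.call(rbind, rows)
    tested <- !is.na(layer_df$p)
    if (any(tested)) {
      layer_df$fdr[tested] <- bh_adjust(layer_df$p[tested])
      layer_df$status[tested & layer_df$fdr < fdr_cutoff] <- "significant"
    }
    out[[ly]] <- layer_df
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Collapse a phosphosite matrix to host proteins
#'
#' @param phospho site-by-sample matrix with rows named by [site_key()].
#' @return protein-by-sample matrix of per-protein mean site values.
#' @export
summarise_sites_by_protein <- function(phospho) {
  host <- parse_site_key(rownames(phospho))$protein
  prots <- sort(unique(host))
  out <- matrix(NA_real_, length(prots), ncol(phospho),
                dimnames = list(prots, colnames(phospho)))
  for (pr in prots) {
    block <- phospho[host == pr, , drop = FALSE]
    mv <- colMeans(block, na.rm = TRUE)
    mv[is.nan(mv)] <- NA_real_
    out[pr, ] <- mv
  }
  out
}

#' Correlate known kinase regulatory pairs against a background
#'
#' Spearman-correlates the activities of annotated directed kinase pairs
#' over their shared samples, stratifies the pairs by the number of
#' annotation sources, and compares each stratum with the background of
#' kinase pairs without known relation by a rank-sum test.
#'
#' @param activity kinase-by-sample activity matrix.
#' @param pairs data.frame (`kinase_a`, `kinase_b`, `n_sources`) of known
#'   regulatory pairs.
#' @param min_shared minimum shared samples per pair (default 3).
#' @return list with `pairs` (per-pair rho, n, stratum) and `tests`
#'   (stratum vs background rank-sum p and medians).
#' @export
kinase_pair_correlation <- function(activity, pairs, min_shared = 3) {
  rho_of <- function(a, b) {
    x <- activity[a, ]; y <- activity[b, ]
    use <- !is.na(x) & !is.na(y)
    if (sum(use) < min_shared) return(c(NA_real_, sum(use)))
    c(cor(x[use], y[use], method = "spearman"), sum(use))
  }
  pairs <- pairs[pairs$kinase_a %in% rownames(activity) &
                   pairs$kinase_b %in% rownames(activity), , drop = FALSE]
  known_key <- unique(paste(pmin(pairs$kinase_a, pairs$kinase_b),
                            pmax(pairs$kinase_a, pairs$kinase_b), sep = "\r"))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    rv <- rho_of(pairs$kinase_a[i], pairs$kinase_b[i])
    data.frame(kinase_a = pairs$kinase_a[i], kinase_b = pairs$kinase_b[i],
               rho = rv[1], n = as.integer(rv[2]),
               stratum = if (as.integer(pairs$n_sources[i]) >= 2L)
                 "multi_source" else "single_source",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)

  ks <- rownames(activity)
  bg <- list()
  if (length(ks) >= 2L) {
    cmb <- utils::combn(sort(ks), 2L)
    for (i in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, i], cmb[2, i], sep = "\r")
      if (key %in% known_key) next
      rv <- rho_of(cmb[1, i], cmb[2, i])
      bg[[key]] <- data.frame(kinase_a = cmb[1, i], kinase_b = cmb[2, i],
                              rho = rv[1], n = as.integer(rv[2]),
                              stratum = "background",
                              stringsAsFactors = FALSE)
    }
  }
  res <- rbind(res, do.call(rbind, bg))
  rownames(res) <- NULL
  res <- res[!is.na(res$rho), , drop = FALSE]

  bg_rho <- res$rho[res$stratum == "background"]
  tests <- lapply(c("single_source", "multi_source"), function(st) {
    v <- res$rho[res$stratum == st]
    if (!length(v) || !length(bg_rho))
      return(data.frame(stratum = st, n = length(v),
                        median_rho = if (length(v)) median(v) else NA_real_,
                        median_background = if (length(bg_rho))
                          median(bg_rho) else NA_real_,
                        p = NA_real_))
    data.frame(stratum = st, n = length(v), median_rho = median(v),
               median_background = median(bg_rho),
               p = suppressWarnings(wilcox.test(v, bg_rho,
                                                alternative = "greater")$p.value))
  })
  list(pairs = res, tests = do.call(rbind, tests))
}

#' Reduce kinases redundant by substrate overlap
#'
#' Kinases are clustered by complete-linkage on the distance 1 - Jaccard
#' index of their substrate sets; the dendrogram is cut at `height` and one
#' kinase is kept per cluster: the one with the most substrates, ties broken
#' lexicographically. Kinases are sorted before clustering so the result is
#' independent of input order.
#'
#' @param prior prior list with `kinase_targets` (see [read_prior()]).
#' @param height dendrogram cut height on the 1 - Jaccard scale (0.85; 0.8
#'   for the stricter variant).
#' @return list with `kept` (character vector) and `clusters` (named
#'   integer cluster map).
#' @export
reduce_redundant_kinases <- function(prior,
                                     height = sigact_config()$jaccard_height) {
  stopifnot(height > 0, height <= 1)
  kt <- prior$kinase_targets
  sets <- lapply(split(kt$site, kt$kinase), unique)
  sets <- sets[sort(names(sets))]
  nk <- length(sets)
  if (nk == 0L) return(list(kept = character(0), clusters = integer(0)))
  if (nk == 1L) return(list(kept = names(sets),
                            clusters = setNames(1L, names(sets))))
  J <- matrix(0, nk, nk, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(nk - 1L)) for (j in (i + 1L):nk) {
    J[i, j] <- J[j, i] <- length(intersect(sets[[i]], sets[[j]])) /
      length(union(sets[[i]], sets[[j]]))
  }
  diag(J) <- 1
  cl <- cutree(hclust(as.dist(1 - J), method = "complete"), h = height)
  sizes <- vapply(sets, length, integer(1))
  kept <- vapply(split(names(cl), cl), function(members) {
    members[order(-sizes[members], members)][1]
  }, character(1))
  list(kept = unname(sort(kept)), clusters = cl)
}

#' Select highly variable kinases
#'
#' Keeps kinases whose activity standard deviation over measured samples is
#' strictly greater than the median SD across kinases.
#'
#' @param activity kinase-by-sample activity matrix; kinases with fewer than
#'   two measurements are excluded.
#' @return character vector of retained kinase ids.
#' @export
select_variable_kinases <- function(activity) {
  n_obs <- rowSums(!is.na(activity))
  sds <- apply(activity, 1L, sd, na.rm = TRUE)
  sds[n_obs < 2L] <- NA_real_
  med <- median(sds, na.rm = TRUE)
  rownames(activity)[!is.na(sds) & sds > med]
}

#' Classify kinases as tumour- or perturbation-specific
#'
#' Computes per kinase the percentage of tumour samples and of perturbation
#' conditions with absolute activity above `cutoff`, keeps kinases regulated
#' in at least one sample of either set, regresses one percentage on the
#' other and standardises the residuals. With tumour percentage as response
#' (the default), a residual z-score above `z_thresh` is tumour-specific and
#' below `-z_thresh` perturbation-specific; the `"perturbation"` orientation
#' swaps the rule accordingly.
#'
#' @param activity_tumour,activity_perturb kinase-by-sample activity
#'   matrices for the two condition sets.
#' @param cutoff absolute activity defining regulation (1.75).
#' @param z_thresh residual z-score threshold (2).
#' @param response which regulation percentage is the regression response.
#' @return data.frame (`kinase`, `pct_tumour`, `pct_perturbation`,
#'   `residual_z`, `call`).
#' @export
tumour_vs_perturbation <- function(activity_tumour, activity_perturb,
                                   cutoff = sigact_config()$activity_cutoff,
                                   z_thresh = sigact_config()$residual_z,
                                   response = c("tumour", "perturbation")) {
  response <- match.arg(response)
  shared <- intersect(rownames(activity_tumour), rownames(activity_perturb))
  pt <- regulation_percentage(activity_tumour[shared, , drop = FALSE], cutoff)
  pp <- regulation_percentage(activity_perturb[shared, , drop = FALSE], cutoff)
  keep <- pt > 0 | pp > 0
  if (sum(keep) < 3L) stop("fewer than 3 kinases regulated in either set")
  pt <- pt[keep]; pp <- pp[keep]
  if (response == "tumour") {
    fit <- lm(pt ~ pp)
  } else {
    fit <- lm(pp ~ pt)
  }
  rz <- as.numeric(scale(stats::residuals(fit)))
  call <- rep("shared", length(rz))
  if (response == "tumour") {
    call[rz > z_thresh] <- "tumour_specific"
    call[rz < -z_thresh] <- "perturbation_specific"
  } else {
    call[rz > z_thresh] <- "perturbation_specific"
    call[rz < -z_thresh] <- "tumour_specific"
  }
  data.frame(kinase = names(pt), pct_tumour = 100 * unname(pt),
             pct_perturbation = 100 * unname(pp), residual_z = rz,
             call = call, stringsAsFactors = FALSE)
}
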