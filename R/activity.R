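#' Kinase activities by a one-sample z-test on substrate fold-changes
#'
#' For kinase K in sample s the activity compares the mean residual log2
#' fold-change of K's measured substrate sites, x, against the background of
#' all phosphosites measured in s (mean mu, standard deviation sigma):
#' \deqn{z = (x - \mu) / (\sigma / \sqrt{N})}
#' with N the number of measured substrates. A two-tailed normal p-value is
#' signed by z to give the activity score `sign(z) * -log10(p)`: positive
#' when substrates are more phosphorylated than the sample background.
#' Scores backed by fewer than `min_targets` measured substrates are absent.
#'
#' @param phospho site-by-sample matrix of (protein-abundance-corrected)
#'   log2 fold-changes; rows named by [site_key()].
#' @param prior prior list as from [read_prior()]; `kinase_targets` is used.
#' @param min_targets minimum measured substrates per score (default 3).
#' @param mode `"substrates"` scores each kinase by its substrate sites;
#'   `"self_sites"` restricts targets to sites on the kinase itself that are
#'   regulatory or carry a functional score above `functional_cutoff`.
#' @param exclude_targets when `TRUE` the kinase's own substrates are left
#'   out of the background (the default keeps the background as all measured
#'   phosphosites in the sample).
#' @param site_annotations optional data.frame (`site`, `regulatory` logical,
#'   `functional_score` numeric) consulted in `self_sites` mode; sites
#'   without a score are treated as not passing the gate.
#' @param functional_cutoff functional-score gate for unannotated self sites.
#' @param details when `TRUE` also return the per-cell z-test components.
#' @return kinase-by-sample activity matrix with attributes `n_targets`
#'   (integer matrix of substrate counts) and `score_kind = "signed_log10p"`;
#'   with `details = TRUE`, a list of `activity` and a `details` data.frame
#'   (`kinase`, `sample`, `x`, `mu`, `sigma`, `n`, `z`, `p`, `activity`).
#' @export
kinase_activity_ztest <- function(phospho, prior,
                                  min_targets = sigact_config()$min_targets,
                                  mode = c("substrates", "self_sites"),
                                  exclude_targets = FALSE,
                                  site_annotations = NULL,
                                  functional_cutoff = 0.4,
                                  details = FALSE) {
  mode <- match.arg(mode)
  stopifnot(min_targets >= 1)
  kt <- prior$kinase_targets
  if (is.null(kt)) stop("prior carries no kinase_targets")
  if (mode == "self_sites") {
    kt <- kt[kt$protein == kt$kinase, , drop = FALSE]
    if (!is.null(site_annotations)) {
      ann <- site_annotations
      reg <- ann$site[isTRUE_vec(ann$regulatory)]
      fun <- ann$site[!is.na(ann$functional_score) &
                        ann$functional_score > functional_cutoff]
      kt <- kt[kt$site %in% union(reg, fun), , drop = FALSE]
    }
  }
  kt <- kt[kt$site %in% rownames(phospho), , drop = FALSE]
  kinases <- sort(unique(kt$kinase))
  target_rows <- lapply(setNames(kinases, kinases), function(k)
    match(unique(kt$site[kt$kinase == k]), rownames(phospho)))

  samples <- colnames(phospho)
  act <- matrix(NA_real_, length(kinases), length(samples),
                dimnames = list(kinases, samples))
  ntg <- matrix(0L, length(kinases), length(samples),
                dimnames = list(kinases, samples))
  det <- if (details) vector("list", length(samples)) else NULL

  for (j in seq_along(samples)) {
    col <- phospho[, j]
    measured <- which(!is.na(col))
    if (length(measured) < 2L) next
    mu_all <- mean(col[measured])
    sig_all <- sd(col[measured])
    if (!exclude_targets && (is.na(sig_all) || sig_all == 0)) {
      warning("degenerate background (sigma = 0) in sample ", samples[j],
              "; sample skipped")
      next
    }
    rows <- list()
    for (k in kinases) {
      t_idx <- target_rows[[k]]
      t_obs <- t_idx[!is.na(col[t_idx])]
      n <- length(t_obs)
      if (n < min_targets) next
      x <- mean(col[t_obs])
      if (exclude_targets) {
        bg <- setdiff(measured, t_obs)
        if (length(bg) < 2L) next
        mu <- mean(col[bg]); sig <- sd(col[bg])
        if (is.na(sig) || sig == 0) next
      } else {
        mu <- mu_all; sig <- sig_all
      }
      z <- (x - mu) / (sig / sqrt(n))
      p <- max(2 * pnorm(-abs(z)), .P_FLOOR)
      a <- sign(z) * -log10(p)
      act[k, j] <- a
      ntg[k, j] <- n
      if (details)
        rows[[k]] <- data.frame(kinase = k, sample = samples[j], x = x,
                                mu = mu, sigma = sig, n = n, z = z, p = p,
                                activity = a, stringsAsFactors = FALSE)
    }
    if (details && length(rows)) det[[j]] <- do.call(rbind, rows)
  }
  attr(act, "n_targets") <- ntg
  attr(act, "score_kind") <- "signed_log10p"
  if (details) {
    dd <- do.call(rbind, det[!vapply(det, is.null, logical(1))])
    rownames(dd) <- NULL
    return(list(activity = act, details = dd))
  }
  act
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' TF activities by signed regulon enrichment
#'
#' Per sample, measured gene statistics are rank-transformed to quantiles
#' `q = rank / (n + 1)` and mapped through the standard normal inverse. The
#' normalized enrichment score of a TF over its m measured regulon targets is
#' \deqn{NES = \sum_{t} mode_t \, \Phi^{-1}(q_t) / \sqrt{m}}
#' which is approximately standard normal under random ranks. Scores backed
#' by fewer than `min_regulon` measured targets are absent.
#'
#' @param mrna gene-by-sample matrix of log2 fold-changes.
#' @param regulons data.frame (`tf`, `target`, `mode` in -1/+1), e.g. the
#'   `regulons` component of [read_prior()].
#' @param min_regulon minimum measured targets per score (default 5).
#' @return TF-by-sample activity matrix with attributes `n_targets` and
#'   `score_kind = "nes"`.
#' @export
tf_activity_nes <- function(mrna, regulons,
                            min_regulon = sigact_config()$min_regulon) {
  stopifnot(min_regulon >= 1)
  if (is.null(regulons)) stop("no regulons supplied")
  if (!all(regulons$mode %in% c(-1, 1))) stop("regulon modes must be -1/+1")
  regulons <- regulons[regulons$target %in% rownames(mrna), , drop = FALSE]
  tfs <- sort(unique(regulons$tf))
  reg_split <- split(regulons[, c("target", "mode")], regulons$tf)

  samples <- colnames(mrna)
  act <- matrix(NA_real_, length(tfs), length(samples),
                dimnames = list(tfs, samples))
  ntg <- matrix(0L, length(tfs), length(samples),
                dimnames = list(tfs, samples))
  for (j in seq_along(samples)) {
    col <- mrna[, j]
    obs <- which(!is.na(col))
    if (!length(obs)) next
    t_stat <- rep(NA_real_, length(col))
    t_stat[obs] <- qnorm(rank(col[obs]) / (length(obs) + 1))
    names(t_stat) <- rownames(mrna)
    for (tf in tfs) {
      rg <- reg_split[[tf]]
      tv <- t_stat[rg$target]
      ok <- !is.na(tv)
      m <- sum(ok)
      if (m < min_regulon) next
      act[tf, j] <- sum(rg$mode[ok] * tv[ok]) / sqrt(m)
      ntg[tf, j] <- m
    }
  }
  attr(act, "n_targets") <- ntg
  attr(act, "score_kind") <- "nes"
  act
}

#' Select strongly regulated proteins
#'
#' The regulation threshold is a percentile of the pooled absolute activity
#' distribution (per-protein distributions optionally, via `pooled = FALSE`).
#' A protein is kept when the fraction of its measured samples with absolute
#' activity above the threshold is at least `min_fraction`.
#'
#' @param activity protein-by-sample activity matrix.
#' @param percentile percentile in (50, 100) defining strong regulation.
#' @param min_fraction minimum regulated-sample fraction.
#' @param pooled compute the threshold on all activities pooled (default) or
#'   per protein.
#' @return character vector of retained protein ids.
#' @export
select_regulated_proteins <- function(activity,
                                      percentile = sigact_config()$regulated_percentile,
                                      min_fraction = sigact_config()$regulated_min_fraction,
                                      pooled = TRUE) {
  stopifnot(percentile > 50, percentile < 100)
  a <- abs(activity)
  if (!length(a) || all(is.na(a))) return(character(0))
  frac <- if (pooled) {
    thr <- quantile(a, percentile / 100, na.rm = TRUE, names = FALSE)
    rowMeans(a > thr, na.rm = TRUE)
  } else {
    apply(a, 1L, function(v) {
      thr <- quantile(v, percentile / 100, na.rm = TRUE, names = FALSE)
      mean(v > thr, na.rm = TRUE)
    })
  }
  frac[is.nan(frac)] <- 0
  rownames(activity)[frac >= min_fraction]
}

#' Fraction of samples where each protein is strongly regulated
#'
#' @param activity protein-by-sample activity matrix.
#' @param cutoff absolute activity defining regulation (strict inequality).
#' @return named numeric vector: per protein, the fraction of its measured
#'   samples with `|activity| > cutoff` (0 when nothing is measured).
#' @export
regulation_percentage <- function(activity,
                                  cutoff = sigact_config()$activity_cutoff) {
  stopifnot(cutoff >= 0)
  frac <- rowMeans(abs(activity) > cutoff, na.rm = TRUE)
  frac[is.nan(frac)] <- 0
  frac
}
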