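#' Stratify samples by activity score
#'
#' A sample is `inactive` when the activity is strictly below `-cutoff`,
#' `active` when strictly above `cutoff`, and `neutral` otherwise (boundary
#' values are neutral). Unmeasured cells produce no row.
#'
#' @param activity protein-by-sample activity matrix.
#' @param cutoff stratification cutoff (1.75).
#' @return data.frame (`sample`, `protein`, `stratum`).
#' @export
stratify_by_activity <- function(activity,
                                 cutoff = sigact_config()$activity_cutoff) {
  idx <- which(!is.na(activity), arr.ind = TRUE)
  a <- activity[idx]
  stratum <- rep("neutral", length(a))
  stratum[a < -cutoff] <- "inactive"
  stratum[a > cutoff] <- "active"
  data.frame(sample = colnames(activity)[idx[, 2]],
             protein = rownames(activity)[idx[, 1]],
             stratum = factor(stratum,
                              levels = c("inactive", "neutral", "active")),
             stringsAsFactors = FALSE)
}

#' Log-rank tests of survival across activity strata
#'
#' Per protein and tissue, compares Kaplan-Meier curves across the populated
#' activity strata by a log-rank test. TF gating requires more than
#' `tf_min_deaths` deaths and more than `tf_min_strata` samples in each of
#' the active and inactive strata; kinase gating, reflecting the rarer
#' activation events, requires more than `kinase_min_strata` samples in the
#' active or the inactive stratum and more than `kinase_min_deaths` deaths.
#' P-values are BH-adjusted over the tested pairs.
#'
#' @param strata assignment table from [stratify_by_activity()].
#' @param clinical clinical table with `sample_id`, `tissue`,
#'   `os_time_days`, `os_event`.
#' @param protein_class `"tf"` or `"kinase"`, selecting the gate.
#' @param tf_min_deaths,tf_min_strata,kinase_min_deaths,kinase_min_strata
#'   gate parameters (10, 10, 5, 5).
#' @param emit_curves also return KM step tables per tested pair.
#' @return data.frame (`protein`, `tissue`, `model`, `statistic`, `p`,
#'   `fdr`, `n`, `n_events`, `n_strata`); with `emit_curves`, a list with
#'   `fits` and `curves`.
#' @export
km_logrank <- function(strata, clinical, protein_class = c("tf", "kinase"),
                       tf_min_deaths = 10, tf_min_strata = 10,
                       kinase_min_deaths = 5, kinase_min_strata = 5,
                       emit_curves = FALSE) {
  protein_class <- match.arg(protein_class)
  cl <- clinical[!is.na(clinical$os_time_days) & !is.na(clinical$os_event), ]
  if (!("tissue" %in% names(cl))) cl$tissue <- "all"
  fits <- list(); curves <- list()
  for (pr in unique(strata$protein)) {
    st_pr <- strata[strata$protein == pr, ]
    dat <- merge(st_pr, cl, by.x = "sample", by.y = "sample_id")
    for (ts in unique(dat$tissue)) {
      d <- dat[dat$tissue == ts, ]
      n_act <- sum(d$stratum == "active")
      n_inact <- sum(d$stratum == "inactive")
      n_death <- sum(d$os_event)
      pass <- if (protein_class == "tf") {
        n_death > tf_min_deaths && n_act > tf_min_strata &&
          n_inact > tf_min_strata
      } else {
        n_death > kinase_min_deaths &&
          (n_act > kinase_min_strata || n_inact > kinase_min_strata)
      }
      if (!pass) next
      d$stratum <- droplevels(d$stratum)
      if (nlevels(d$stratum) < 2L) next
      sd_ <- survival::survdiff(
        survival::Surv(os_time_days, os_event) ~ stratum, data = d)
      df <- length(sd_$n) - 1L
      p <- pchisq(sd_$chisq, df, lower.tail = FALSE)
      fits[[paste(pr, ts)]] <- data.frame(
        protein = pr, tissue = ts, model = "logrank",
        statistic = unname(sd_$chisq), p = p, fdr = NA_real_,
        n = nrow(d), n_events = n_death, n_strata = df + 1L,
        stringsAsFactors = FALSE)
      if (emit_curves) {
        sf <- survival::survfit(
          survival::Surv(os_time_days, os_event) ~ stratum, data = d)
        curves[[paste(pr, ts)]] <- data.frame(
          protein = pr, tissue = ts,
          stratum = rep(sub("^stratum=", "", names(sf$strata)),
                        sf$strata),
          time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
          surv = sf$surv, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(fits)) do.call(rbind, fits) else
    data.frame(protein = character(0), tissue = character(0),
               model = character(0), statistic = numeric(0), p = numeric(0),
               fdr = numeric(0), n = integer(0), n_events = integer(0),
               n_strata = integer(0))
  rownames(out) <- NULL
  if (nrow(out)) out$fdr <- bh_adjust(out$p)
  if (emit_curves) {
    cv <- if (length(curves)) do.call(rbind, curves) else NULL
    if (!is.null(cv)) rownames(cv) <- NULL
    return(list(fits = out, curves = cv))
  }
  out
}

#' Cox proportional-hazards models of survival on continuous activity
#'
#' Per protein and tissue, fits a Cox model (Efron ties) with the activity
#' score as a continuous predictor, adjusted for age, gender and the binary
#' genotype of recurrently mutated genes (those with at least `min_mut`
#' mutations in the cohort). Constant covariates are dropped with a warning;
#' non-converging fits are flagged and excluded from the BH family. The
#' hazard ratio is `exp(activity coefficient)` with its Wald 95% confidence
#' interval.
#'
#' @param activity protein-by-sample activity matrix.
#' @param clinical clinical table with `sample_id`, `os_time_days`,
#'   `os_event` and optionally `tissue`, `age`, `gender`.
#' @param genotype_matrix optional binary gene-by-sample mutation matrix.
#' @param min_mut minimum cohort-wide mutation count for a genotype
#'   covariate (100; scale down for small cohorts).
#' @param min_events minimum events required to attempt a fit.
#' @return data.frame (`protein`, `tissue`, `model`, `statistic`, `p`,
#'   `fdr`, `hr`, `hr_ci_low`, `hr_ci_high`, `n`, `n_events`, `converged`).
#' @export
cox_activity <- function(activity, clinical, genotype_matrix = NULL,
                         min_mut = sigact_config()$min_mut_genotype,
                         min_events = 5) {
  cl <- clinical[!is.na(clinical$os_time_days) & !is.na(clinical$os_event), ]
  if (!("tissue" %in% names(cl))) cl$tissue <- "all"
  panel <- NULL
  if (!is.null(genotype_matrix)) {
    counts <- rowSums(genotype_matrix, na.rm = TRUE)
    panel <- rownames(genotype_matrix)[counts >= min_mut]
  }
  # genotype covariates that vary within each tissue; warn once per tissue
  tissue_panel <- list()
  for (ts in unique(cl$tissue)) {
    keep <- character(0)
    for (g in panel) {
      v <- genotype_matrix[g, intersect(cl$sample_id[cl$tissue == ts],
                                        colnames(genotype_matrix))]
      if (length(unique(v[!is.na(v)])) > 1L) keep <- c(keep, g)
      else warning("genotype covariate ", g, " constant in tissue ", ts,
                   "; dropped")
    }
    tissue_panel[[ts]] <- keep
  }
  fits <- list()
  for (pr in rownames(activity)) {
    av <- activity[pr, ]
    for (ts in unique(cl$tissue)) {
      d <- cl[cl$tissue == ts, ]
      d$activity <- av[d$sample_id]
      d <- d[!is.na(d$activity), ]
      if (nrow(d) < 10L || sum(d$os_event) < min_events) next
      covs <- "activity"
      if ("age" %in% names(d) && length(unique(d$age[!is.na(d$age)])) > 1L)
        covs <- c(covs, "age")
      if ("gender" %in% names(d) &&
          length(unique(d$gender[!is.na(d$gender)])) > 1L)
        covs <- c(covs, "gender")
      for (g in tissue_panel[[ts]]) {
        v <- genotype_matrix[g, d$sample_id]
        if (length(unique(v[!is.na(v)])) > 1L) {
          gn <- paste0("mut_", make.names(g))
          d[[gn]] <- v
          covs <- c(covs, gn)
        }
      }
      if (sd(d$activity) == 0) next
      form <- as.formula(paste("survival::Surv(os_time_days, os_event) ~",
                               paste(covs, collapse = " + ")))
      converged <- TRUE
      fit <- withCallingHandlers(
        tryCatch(survival::coxph(form, data = d, ties = "efron"),
                 error = function(e) NULL),
        warning = function(w) {
          if (grepl("converge|infinite|singular", conditionMessage(w)))
            converged <<- FALSE
          invokeRestart("muffleWarning")
        })
      if (is.null(fit) || !("activity" %in% names(coef(fit))) ||
          is.na(coef(fit)["activity"]))
        next
      beta <- coef(fit)["activity"]
      se <- sqrt(diag(vcov(fit))["activity"])
      zv <- beta / se
      p <- max(2 * pnorm(-abs(zv)), .P_FLOOR)
      fits[[paste(pr, ts)]] <- data.frame(
        protein = pr, tissue = ts, model = "cox", statistic = unname(zv),
        p = unname(p), fdr = NA_real_, hr = unname(exp(beta)),
        hr_ci_low = unname(exp(beta - 1.959963984540054 * se)),
        hr_ci_high = unname(exp(beta + 1.959963984540054 * se)),
        n = nrow(d), n_events = sum(d$os_event), converged = converged,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(fits)) do.call(rbind, fits) else
    data.frame(protein = character(0), tissue = character(0),
               model = character(0), statistic = numeric(0), p = numeric(0),
               fdr = numeric(0), hr = numeric(0), hr_ci_low = numeric(0),
               hr_ci_high = numeric(0), n = integer(0),
               n_events = integer(0), converged = logical(0))
  rownames(out) <- NULL
  if (nrow(out) && any(out$converged))
    out$fdr[out$converged] <- bh_adjust(out$p[out$converged])
  out
}
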