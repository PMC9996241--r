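#' Run the full analysis pipeline on a synthetic cohort
#'
#' Chains every stage end to end: cohort and prior simulation,
#' preprocessing (outlier removal, quantile normalization, host-protein
#' residualization, sequence validation, mutation-matrix construction),
#' kinase/TF activity inference, prior benchmarking, mutation-activity and
#' kinase-TF associations with network enrichment, survival analysis and
#' activity clustering with clinical over-representation. All result tables
#' are written as tab-separated files under `outdir`; two runs with the same
#' configuration and seed produce byte-identical files.
#'
#' @param sim a [sim_config()]; its `seed` is overridden by `seed` when
#'   given.
#' @param config analysis thresholds from [sigact_config()]. For synthetic
#'   cohorts the Cox genotype-panel threshold is the scaled default
#'   `min_mut_genotype = 10`.
#' @param seed integer seed for the simulation and every resampling stage.
#' @param outdir output directory, created if absent.
#' @param k number of sample clusters (defaults to the simulated block
#'   count, keeping the partition comparable to the planted subtypes).
#' @param verbose log stage progress and record drops.
#' @return invisibly, a list with the principal in-memory results
#'   (`kinase_activity`, `tf_activity`, `benchmark`, `associations`,
#'   `enrichment`, `survival_km`, `survival_cox`, `clusters`,
#'   `cluster_scores`, `overrepresentation`, `specificity`).
#' @export
run_pipeline <- function(sim = sim_config(), config = sigact_config(min_mut_genotype = 10),
                         seed = NULL, outdir, k = NULL, verbose = FALSE) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(outdir, f)

  sigact_log(verbose, "simulating cohort (", sim$n_samples, " samples, seed ",
             sim$seed, ")")
  cohort <- generate_cohort(sim)
  priors <- generate_priors(sim)
  write_matrix(cohort$phospho, path("phospho_raw.tsv"))
  write_matrix(cohort$protein, path("protein.tsv"))
  write_matrix(cohort$mrna, path("mrna.tsv"))
  write_mutations(cohort$mutations, path("mutations.tsv"))
  write_clinical(cohort$clinical, path("clinical.tsv"))
  write_prior(priors$prior, path("kinase_prior.tsv"), path("tf_regulons.tsv"))
  write_edges(priors$edges, path("edges.tsv"))
  write_fasta(priors$sequences, path("proteins.fasta"))

  # --- preprocessing -------------------------------------------------------
  out <- remove_outlier_samples(cohort$phospho, config$outlier_threshold)
  sigact_log(verbose, "outlier removal dropped ", nrow(out$dropped),
             " sample(s)")
  phospho <- quantile_normalize(out$matrix)

  site_check <- validate_against_sequences(
    parse_site_key(rownames(phospho)), priors$sequences)
  keep_sites <- site_key(site_check$kept$protein, site_check$kept$position,
                         site_check$kept$residue)
  phospho <- phospho[rownames(phospho) %in% keep_sites, , drop = FALSE]

  resid <- regress_out(phospho, predictor = cohort$protein,
                       row_map = site_host_map(phospho))
  write_matrix(resid, path("phospho_residuals.tsv"))

  mut_check <- validate_against_sequences(cohort$mutations, priors$sequences)
  mut_matrix <- build_mutation_matrix(mut_check$kept,
                                      samples = colnames(cohort$protein))
  write_matrix(mut_matrix + 0, path("mutation_matrix.tsv"))

  # --- activities ----------------------------------------------------------
  kin_act <- kinase_activity_ztest(resid, priors$prior,
                                   min_targets = config$min_targets)
  tf_act <- tf_activity_nes(cohort$mrna, priors$prior$regulons,
                            min_regulon = config$min_regulon)
  write_matrix(kin_act, path("kinase_activity.tsv"))
  write_matrix(tf_act, path("tf_activity.tsv"))

  # --- benchmark -----------------------------------------------------------
  bench <- evaluate_prior(kin_act, priors$gold,
                          n_resamples = config$n_resamples, seed = sim$seed)
  write_tsv(data.frame(resample = seq_along(bench$aurocs),
                       auroc = bench$aurocs), path("benchmark_aurocs.tsv"))

  # --- associations --------------------------------------------------------
  study <- setNames(cohort$clinical$study, cohort$clinical$sample_id)
  assoc <- fit_activity_mutation(kin_act, mut_matrix, study,
                                 min_gene_mut = config$min_gene_mut,
                                 min_act_samples = config$min_act_samples,
                                 min_pair_mut = config$min_pair_mut)
  write_tsv(assoc, path("associations_mutation_kinase.tsv"))
  enr <- if (nrow(assoc)) {
    string_enrichment(assoc, priors$edges, min_score = config$string_min_score)
  } else NULL
  if (!is.null(enr)) write_tsv(enr, path("string_enrichment.tsv"))
  kin_tf <- fit_kinase_tf(tf_act, kin_act, study)
  write_tsv(kin_tf, path("associations_kinase_tf.tsv"))

  # --- landscape -----------------------------------------------------------
  red <- reduce_redundant_kinases(priors$prior, config$jaccard_height)
  variable <- select_variable_kinases(kin_act[red$kept, , drop = FALSE])
  write_tsv(data.frame(kinase = variable), path("variable_kinases.tsv"))
  layer_cor <- correlate_activity_layers(
    kin_act, list(cnv = cohort$cnv, rna = cohort$mrna,
                  protein = cohort$protein, phospho = resid),
    n_min = config$n_min_correlation)
  write_tsv(layer_cor, path("activity_layer_correlations.tsv"))

  # --- survival ------------------------------------------------------------
  strata <- stratify_by_activity(kin_act, config$activity_cutoff)
  km <- km_logrank(strata, cohort$clinical, protein_class = "kinase")
  write_tsv(km, path("survival_logrank.tsv"))
  cox <- cox_activity(kin_act, cohort$clinical, mut_matrix,
                      min_mut = config$min_mut_genotype)
  write_tsv(cox, path("survival_cox.tsv"))

  # --- clustering ----------------------------------------------------------
  combined <- rbind(kin_act, tf_act)
  cc <- sample_cross_correlation(combined)
  if (is.null(k)) k <- sim$n_blocks
  clu <- cluster_samples(cc, k = k)
  write_tsv(data.frame(sample_id = names(clu$clusters),
                       cluster = unname(clu$clusters)),
            path("clusters.tsv"))
  scores <- cluster_activity_scores(combined, clu$clusters,
                                    config$dereg_threshold)
  write_matrix(scores$scores, path("cluster_activity_scores.tsv"))
  over <- clinical_overrepresentation(clu$clusters, cohort$clinical,
                                      min_level_count = config$min_level_count,
                                      bmi_cutoff = config$bmi_cutoff,
                                      age_cutoff = config$age_cutoff)
  write_tsv(over, path("clinical_overrepresentation.tsv"))

  invisible(list(cohort = cohort, priors = priors,
                 kinase_activity = kin_act, tf_activity = tf_act,
                 benchmark = bench, associations = assoc,
                 kinase_tf = kin_tf, enrichment = enr,
                 layer_correlations = layer_cor, variable_kinases = variable,
                 survival_km = km, survival_cox = cox, clusters = clu,
                 cluster_scores = scores, overrepresentation = over))
}
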