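#' Configuration for the synthetic multiomics cohort
#'
#' The generator plants a block structure of regulator programmes: samples
#' belong to `n_blocks` activity blocks and each kinase/TF is active (with a
#' per-regulator sign) in exactly one block, shifting its substrates or
#' regulon targets by `activity_shift` log2FC units. Phosphosite signals are
#' confounded by host-protein abundance (slope
#' `protein_confounding_slope`), all layers carry additive per-study batch
#' effects, planted mutations add `beta` activity units to a target kinase
#' in carrier samples, and survival times follow an exponential model whose
#' per-sample hazard is `baseline_hazard * exp(sum(log_hr * activity))`
#' with uniform censoring.
#'
#' @param n_samples,n_studies,n_kinases,n_tfs,n_genes cohort dimensions.
#'   The first `n_kinases` genes are the kinases and the next `n_tfs` the
#'   TFs, so regulators are themselves part of the measured gene space.
#' @param substrates_per_kinase,targets_per_tf prior wiring sizes.
#' @param n_background_sites unregulated phosphosites added to the
#'   background.
#' @param n_blocks number of sample activity blocks (the planted subtypes).
#' @param kinase_active_fraction fraction of a kinase's block samples where
#'   its programme is actually on. The default 0.15 (about 5% of all
#'   samples with three blocks) mirrors the minority-sample regulation
#'   frequencies typical of tumour cohorts; TF programmes span their whole
#'   block, anchoring the subtype structure.
#' @param activity_shift planted activity shift (log2FC units, delta).
#' @param phospho_noise_sd site-level measurement noise SD.
#' @param protein_confounding_slope host-protein contribution to each site.
#' @param batch_effect_sd SD of the per-study, per-feature additive offsets.
#' @param mutation_effects data.frame (`gene`, `protein`, `beta`): carriers
#'   of a mutation in `gene` gain `beta` activity units of kinase
#'   `protein`. `NULL` plants the default three effects of size 1.5.
#' @param mutation_carrier_rate fraction of samples carrying each planted
#'   mutation.
#' @param n_mutated_background_genes genes receiving random passenger
#'   mutations.
#' @param hazards data.frame (`protein`, `log_hr`): per-activity-unit log
#'   hazard ratios. `NULL` plants log(2) on two kinases.
#' @param baseline_hazard,censor_max exponential survival parameters
#'   (per-day rate; uniform censoring horizon in days).
#' @param missingness_rate completely-at-random missingness applied to the
#'   mrna, protein and phospho layers.
#' @param n_gold gold-standard (kinase, sample) regulation pairs emitted.
#' @param n_decoy_edges low-confidence decoy edges added to the planted
#'   high-confidence pairs.
#' @param seed integer seed; identical configs generate identical cohorts.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300, n_studies = 3, n_kinases = 50,
                       n_tfs = 40, n_genes = 1500,
                       substrates_per_kinase = 10, targets_per_tf = 20,
                       n_background_sites = 1000, n_blocks = 3,
                       kinase_active_fraction = 0.15,
                       activity_shift = 1, phospho_noise_sd = 1,
                       protein_confounding_slope = 0.8,
                       batch_effect_sd = 0.3, mutation_effects = NULL,
                       mutation_carrier_rate = 0.15,
                       n_mutated_background_genes = 15, hazards = NULL,
                       baseline_hazard = 1 / 1500, censor_max = 3000,
                       missingness_rate = 0.1, n_gold = 200, n_decoy_edges = 200,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_samples", "n_studies", "n_kinases", "n_tfs", "n_genes",
              "substrates_per_kinase", "targets_per_tf", "n_blocks")
  for (nm in counts) if (cfg[[nm]] < 1) stop(nm, " must be >= 1")
  for (nm in c("missingness_rate", "mutation_carrier_rate",
               "kinase_active_fraction"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  if (n_genes < n_kinases + n_tfs + n_mutated_background_genes + 10)
    stop("n_genes too small for the requested regulators and mutated genes")
  # each protein offers up to 10 distinct site slots
  if (n_kinases * substrates_per_kinase + n_background_sites > n_genes * 10)
    stop("substrates_per_kinase x n_kinases exceeds the available site space")
  if (is.null(cfg$mutation_effects)) {
    n_eff <- min(3L, n_kinases)
    cfg$mutation_effects <- data.frame(
      gene = paste0("g", formatC(n_kinases + n_tfs + seq_len(n_eff),
                                 width = 4, flag = "0")),
      protein = paste0("K", formatC(seq_len(n_eff), width = 2, flag = "0")),
      beta = rep(1.5, n_eff), stringsAsFactors = FALSE)
  }
  if (is.null(cfg$hazards)) {
    n_hz <- min(2L, n_kinases)
    cfg$hazards <- data.frame(
      protein = paste0("K", formatC(seq_len(n_hz), width = 2, flag = "0")),
      log_hr = rep(log(2), n_hz), stringsAsFactors = FALSE)
  }
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic wiring shared by generate_cohort() and generate_priors():
# regulator names, block memberships, substrate/regulon assignments,
# protein sequences, planted effect pairs, edges and gold standard.
sim_wiring <- function(cfg) {
  set.seed(cfg$seed)
  kinases <- paste0("K", formatC(seq_len(cfg$n_kinases), width = 2, flag = "0"))
  tfs <- paste0("TF", formatC(seq_len(cfg$n_tfs), width = 2, flag = "0"))
  fillers <- paste0("g", formatC(seq_len(cfg$n_genes), width = 4, flag = "0"))
  genes <- c(kinases, tfs,
             fillers[(cfg$n_kinases + cfg$n_tfs + 1):cfg$n_genes])
  samples <- paste0("S", formatC(seq_len(cfg$n_samples), width = 4, flag = "0"))

  # blocks round-robin, studies in contiguous chunks: the planted subtype
  # structure is orthogonal to the batch structure, as in a multi-study
  # cohort where every study contains every subtype
  sample_block <- setNames(rep_len(seq_len(cfg$n_blocks), cfg$n_samples),
                           samples)
  sample_study <- setNames(
    paste0("study", sort(rep_len(seq_len(cfg$n_studies), cfg$n_samples))),
    samples)
  kinase_block <- setNames(rep_len(seq_len(cfg$n_blocks), cfg$n_kinases),
                           kinases)
  kinase_sign <- setNames(ifelse(seq_len(cfg$n_kinases) %% 2L == 0L, -1, 1),
                          kinases)
  tf_block <- setNames(rep_len(seq_len(cfg$n_blocks), cfg$n_tfs), tfs)
  tf_sign <- setNames(ifelse(seq_len(cfg$n_tfs) %% 2L == 0L, -1, 1), tfs)

  # site slots: up to 10 positions per protein, spread along the sequence
  n_sites <- cfg$n_kinases * cfg$substrates_per_kinase + cfg$n_background_sites
  slot_gene <- sample(rep(genes, 10))[seq_len(n_sites)]
  slot_pos <- integer(n_sites)
  for (g in unique(slot_gene)) {
    idx <- which(slot_gene == g)
    slot_pos[idx] <- sample(seq_len(10), length(idx)) * 4L  # distinct positions
  }
  slot_res <- sample(PHOSPHO_RESIDUES, n_sites, replace = TRUE)
  site_keys <- site_key(slot_gene, slot_pos, slot_res)
  sub_idx <- seq_len(cfg$n_kinases * cfg$substrates_per_kinase)
  kinase_targets <- data.frame(
    kinase = rep(kinases, each = cfg$substrates_per_kinase),
    protein = slot_gene[sub_idx], position = slot_pos[sub_idx],
    residue = slot_res[sub_idx],
    source = sample(c("database", "textmining"), length(sub_idx),
                    replace = TRUE),
    site = site_keys[sub_idx], stringsAsFactors = FALSE)
  background_sites <- site_keys[-sub_idx]

  regulons <- do.call(rbind, lapply(tfs, function(tf) {
    tg <- sample(genes, cfg$targets_per_tf)
    data.frame(tf = tf, target = tg,
               mode = sample(c(1, -1), cfg$targets_per_tf, replace = TRUE,
                             prob = c(0.8, 0.2)),
               confidence = sample(c("A", "B", "C"), cfg$targets_per_tf,
                                   replace = TRUE),
               stringsAsFactors = FALSE)
  }))

  effects <- cfg$mutation_effects
  if (!all(effects$gene %in% genes) || !all(effects$protein %in% kinases))
    stop("mutation_effects must name cohort genes and kinases")
  bg_pool <- setdiff(genes, c(kinases, tfs, effects$gene))
  bg_mut_genes <- sample(bg_pool, cfg$n_mutated_background_genes)

  # protein sequences covering every declared site and mutation position
  seq_proteins <- sort(unique(c(slot_gene, effects$gene, bg_mut_genes)))
  aa <- strsplit("ACDEFGHIKLMNPQRVW", "")[[1]]   # no S/T/Y in the filler
  sequences <- vapply(seq_proteins, function(p) {
    paste(sample(aa, 60, replace = TRUE), collapse = "")
  }, character(1))
  for (i in seq_len(n_sites)) {
    sq <- sequences[slot_gene[i]]
    substr(sq, slot_pos[i], slot_pos[i]) <- slot_res[i]
    sequences[slot_gene[i]] <- sq
  }

  # true activities in delta units: block programme + planted mutation
  # effects. A kinase programme is on only in a random subset of its block
  # (kinase_active_fraction), mirroring minority-sample regulation.
  true_kin <- outer(kinase_block, sample_block, function(kb, sb)
    as.numeric(kb == sb)) * kinase_sign * cfg$activity_shift
  dimnames(true_kin) <- list(kinases, samples)
  on_mask <- matrix(runif(length(true_kin)) < cfg$kinase_active_fraction,
                    nrow(true_kin), ncol(true_kin))
  true_kin <- true_kin * on_mask
  true_tf <- outer(tf_block, sample_block, function(tb, sb)
    as.numeric(tb == sb)) * tf_sign * cfg$activity_shift
  dimnames(true_tf) <- list(tfs, samples)

  # planted high-confidence edges plus random low-confidence decoys
  planted_edges <- data.frame(protein_a = effects$gene,
                              protein_b = effects$protein,
                              combined_score = 850L +
                                sample(0:149, nrow(effects), replace = TRUE))
  decoy_a <- sample(genes, cfg$n_decoy_edges, replace = TRUE)
  decoy_b <- sample(genes, cfg$n_decoy_edges, replace = TRUE)
  keep <- decoy_a != decoy_b
  decoys <- data.frame(protein_a = decoy_a[keep], protein_b = decoy_b[keep],
                       combined_score = sample(150:849, sum(keep),
                                               replace = TRUE))
  edges <- canonical_edges(rbind(planted_edges, decoys))

  # gold standard: (kinase, sample) pairs where the block programme is on
  pos <- which(true_kin != 0, arr.ind = TRUE)
  n_gold <- min(cfg$n_gold, nrow(pos))
  pick <- sample(nrow(pos), n_gold)
  gold <- data.frame(kinase = rownames(true_kin)[pos[pick, 1]],
                     condition_id = colnames(true_kin)[pos[pick, 2]],
                     direction = ifelse(true_kin[pos[pick, , drop = FALSE]] > 0,
                                        "up", "down"),
                     stringsAsFactors = FALSE)

  list(kinases = kinases, tfs = tfs, genes = genes, samples = samples,
       sample_block = sample_block, sample_study = sample_study,
       site_keys = site_keys, slot_gene = slot_gene, slot_pos = slot_pos,
       slot_res = slot_res, kinase_targets = kinase_targets,
       background_sites = background_sites, regulons = regulons,
       effects = effects, bg_mut_genes = bg_mut_genes,
       sequences = sequences, true_kin = true_kin, true_tf = true_tf,
       edges = edges, gold = gold)
}

#' Generate the prior knowledge matching a synthetic cohort
#'
#' Emits the kinase-substrate and TF-regulon priors consistent with the
#' planted wiring, an edge list containing every planted (mutated gene,
#' affected kinase) pair at combined score of at least 850 plus random
#' decoys below, the gold-standard (kinase, sample) regulation pairs, and
#' FASTA sequences carrying the declared residues at the declared positions.
#'
#' @param cfg a [sim_config()].
#' @return list with `prior` (as [read_prior()] returns), `edges`, `gold`
#'   and `sequences`.
#' @export
generate_priors <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  w <- sim_wiring(cfg)
  list(prior = list(kinase_targets = w$kinase_targets, regulons = w$regulons),
       edges = w$edges, gold = w$gold, sequences = w$sequences)
}

#' Generate a synthetic multiomics cohort with planted ground truth
#'
#' See [sim_config()] for the generative model. Identical configurations
#' (including the seed) produce identical cohorts.
#'
#' @param cfg a [sim_config()].
#' @return list with matrices `mrna`, `protein`, `phospho`, `cnv`, the
#'   `mutations` record table, the `clinical` table and `truth` (planted
#'   `true_kinase_activity`, `true_tf_activity`, `effects`, `hazards` and
#'   `cluster_labels`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  w <- sim_wiring(cfg)
  set.seed(cfg$seed + 1L)
  ns <- cfg$n_samples
  genes <- w$genes; samples <- w$samples
  studies <- sort(unique(w$sample_study))
  study_of <- w$sample_study

  batch <- function(n_feat) {
    b <- matrix(rnorm(n_feat * length(studies), 0, cfg$batch_effect_sd),
                n_feat, length(studies), dimnames = list(NULL, studies))
    b[, study_of, drop = FALSE]
  }

  protein <- matrix(rnorm(length(genes) * ns, 0, 0.5), length(genes), ns,
                    dimnames = list(genes, samples)) + batch(length(genes))

  mrna <- matrix(rnorm(length(genes) * ns, 0, 0.5), length(genes), ns,
                 dimnames = list(genes, samples)) + batch(length(genes))
  for (tf in w$tfs) {
    rg <- w$regulons[w$regulons$tf == tf, ]
    shift <- outer(rg$mode, w$true_tf[tf, ])
    mrna[rg$target, ] <- mrna[rg$target, ] + shift
  }

  n_sites <- length(w$site_keys)
  phospho <- cfg$protein_confounding_slope * protein[w$slot_gene, , drop = FALSE] +
    batch(n_sites) +
    matrix(rnorm(n_sites * ns, 0, cfg$phospho_noise_sd), n_sites, ns)
  rownames(phospho) <- w$site_keys
  kt <- w$kinase_targets
  for (k in w$kinases) {
    rows <- match(kt$site[kt$kinase == k], w$site_keys)
    phospho[rows, ] <- phospho[rows, ] +
      matrix(w$true_kin[k, ], length(rows), ns, byrow = TRUE)
  }

  cnv <- matrix(sample(-2:2, length(genes) * ns, replace = TRUE,
                       prob = c(0.02, 0.08, 0.8, 0.08, 0.02)),
                length(genes), ns, dimnames = list(genes, samples))

  mask <- function(m) {
    m[matrix(runif(length(m)) < cfg$missingness_rate, nrow(m), ncol(m))] <- NA
    m
  }
  mrna <- mask(mrna); protein <- mask(protein); phospho <- mask(phospho)

  # planted driver mutations and their activity consequences
  true_kin <- w$true_kin
  mut_rows <- list()
  mutation_record <- function(gene, sample_id, mclass) {
    sq <- w$sequences[gene]
    if (mclass == "splice_site")
      return(data.frame(sample_id = sample_id, gene = gene, mclass = mclass,
                        position = NA_integer_, ref_residue = NA_character_,
                        alt_residue = NA_character_, stringsAsFactors = FALSE))
    pos <- sample(nchar(sq), 1L)
    ref <- substr(sq, pos, pos)
    alt <- if (mclass == "silent") ref else
      sample(setdiff(c("A", "G", "L", "P", "V"), ref), 1L)
    data.frame(sample_id = sample_id, gene = gene, mclass = mclass,
               position = pos, ref_residue = ref, alt_residue = alt,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(w$effects))) {
    g <- w$effects$gene[i]; pr <- w$effects$protein[i]
    carriers <- samples[runif(ns) < cfg$mutation_carrier_rate]
    true_kin[pr, carriers] <- true_kin[pr, carriers] + w$effects$beta[i]
    for (s in carriers)
      mut_rows[[paste(g, s)]] <- mutation_record(g, s, "missense")
    # carriers also gain the corresponding substrate phosphorylation
    rows <- match(kt$site[kt$kinase == pr], w$site_keys)
    phospho[rows, carriers] <- phospho[rows, carriers] + w$effects$beta[i]
  }
  classes <- c("missense", "silent", "nonsense", "frameshift_indel",
               "splice_site")
  for (g in w$bg_mut_genes) {
    carriers <- samples[runif(ns) < 0.05]
    cls <- sample(classes, length(carriers), replace = TRUE,
                  prob = c(0.55, 0.15, 0.1, 0.12, 0.08))
    for (j in seq_along(carriers))
      mut_rows[[paste(g, carriers[j])]] <-
        mutation_record(g, carriers[j], cls[j])
  }
  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    data.frame(sample_id = character(0), gene = character(0),
               mclass = character(0), position = integer(0),
               ref_residue = character(0), alt_residue = character(0),
               stringsAsFactors = FALSE)
  mutations <- mutations[order(mutations$sample_id, mutations$gene), ]
  rownames(mutations) <- NULL

  # survival: exponential with activity-dependent hazard, uniform censoring
  log_hr <- setNames(cfg$hazards$log_hr, cfg$hazards$protein)
  lin <- colSums(true_kin[names(log_hr), , drop = FALSE] * log_hr)
  lambda <- cfg$baseline_hazard * exp(lin)
  t_event <- rexp(ns, rate = lambda)
  t_cens <- runif(ns, 0, cfg$censor_max)
  clinical <- data.frame(
    sample_id = samples, study = unname(study_of),
    tissue = sub("^study", "tissue", unname(study_of)),
    sample_type = "tumour",
    age = round(runif(ns, 30, 85)),
    gender = sample(c("F", "M"), ns, replace = TRUE),
    bmi = round(pmax(rnorm(ns, 28, 6), 15), 1),
    os_time_days = round(pmin(t_event, t_cens), 1),
    os_event = as.integer(t_event <= t_cens),
    subtype = paste0("block", unname(w$sample_block)),
    stringsAsFactors = FALSE)

  list(mrna = mrna, protein = protein, phospho = phospho, cnv = cnv,
       mutations = mutations, clinical = clinical,
       truth = list(true_kinase_activity = true_kin,
                    true_tf_activity = w$true_tf,
                    effects = w$effects, hazards = cfg$hazards,
                    cluster_labels = w$sample_block))
}

#' Host-protein map for a phosphosite matrix
#'
#' @param phospho site-by-sample matrix with rows named by [site_key()].
#' @return named character vector mapping each site key to its host protein,
#'   suitable as the `row_map` of [regress_out()].
#' @export
site_host_map <- function(phospho) {
  setNames(parse_site_key(rownames(phospho))$protein, rownames(phospho))
}
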