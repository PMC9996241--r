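# normal-equations oracle for the focal coefficient of y ~ 1 + X
ols_oracle <- function(y, X) {
  Xd <- cbind(1, X)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  res <- y - Xd %*% beta
  s2 <- sum(res^2) / (length(y) - ncol(Xd))
  se <- sqrt(diag(s2 * solve(t(Xd) %*% Xd)))
  list(beta = beta[, 1], se = se)
}

test_that("mutation-activity model recovers a planted effect and applies filters", {
  set.seed(11)
  n <- 200
  samples <- paste0("s", 1:n)
  study <- setNames(rep(c("a", "b"), each = n / 2), samples)
  mut <- named_matrix(rbind(rbinom(n, 1, 0.25)), features = "G1",
                      samples = samples)
  act <- named_matrix(
    rbind(1.5 * mut[1, ] + ifelse(study == "a", 0, 0.7) + rnorm(n, 0, 0.5)),
    features = "K1", samples = samples)
  res <- fit_activity_mutation(act, mut, study, min_gene_mut = 10,
                               min_act_samples = 10, min_pair_mut = 5)
  expect_equal(nrow(res), 1L)
  expect_gt(res$beta, 1.3); expect_lt(res$beta, 1.7)
  # matches the normal-equations oracle exactly
  X <- cbind(study = as.numeric(study == "b"), mut = mut[1, ])
  orc <- ols_oracle(act[1, ], X)
  expect_equal(res$beta, unname(orc$beta["mut"]), tolerance = 1e-8)
  expect_equal(res$se, unname(orc$se[3]), tolerance = 1e-8)

  # a gene mutated in fewer than min_pair_mut of the pair samples is skipped
  rare <- named_matrix(rbind(c(rep(1, 4), rep(0, n - 4))), features = "G2",
                       samples = samples)
  expect_equal(nrow(fit_activity_mutation(act, rare, study,
                                          min_gene_mut = 3,
                                          min_act_samples = 10,
                                          min_pair_mut = 5)), 0L)
  # self pairs are tagged
  self_act <- act; rownames(self_act) <- "G1"
  self <- fit_activity_mutation(self_act, mut, study, min_gene_mut = 10,
                                min_act_samples = 10, min_pair_mut = 5)
  expect_equal(self$model_tag, "self")
})

test_that("null mutation pairs produce uniform p-values", {
  set.seed(12)
  n <- 120
  samples <- paste0("s", 1:n)
  study <- setNames(rep(c("a", "b"), each = n / 2), samples)
  mut <- named_matrix(matrix(rbinom(20 * n, 1, 0.3), 20, n),
                      features = paste0("G", 1:20), samples = samples)
  act <- named_matrix(matrix(rnorm(10 * n), 10, n),
                      features = paste0("K", 1:10), samples = samples)
  res <- fit_activity_mutation(act, mut, study, min_gene_mut = 10,
                               min_act_samples = 10, min_pair_mut = 5)
  expect_equal(nrow(res), 200L)
  frac <- mean(res$p < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
  expect_true(all(res$fdr >= res$p))
})

test_that("kinase-TF model handles exact, null and planted relationships", {
  set.seed(13)
  n <- 300
  samples <- paste0("s", 1:n)
  study <- setNames(rep(c("a", "b", "c"), each = n / 3), samples)
  kin <- named_matrix(rbind(rnorm(n)), features = "K1", samples = samples)
  # exact identity -> beta 1, p at the floor
  tf_same <- named_matrix(kin, features = "T1", samples = samples)
  r1 <- suppressWarnings(fit_kinase_tf(tf_same, kin, study))
  expect_equal(r1$beta, 1, tolerance = 1e-12)
  expect_lte(r1$p, 1e-300)
  # independent -> small coefficient
  tf_null <- named_matrix(rbind(rnorm(n)), features = "T2", samples = samples)
  r2 <- fit_kinase_tf(tf_null, kin, study)
  expect_lt(abs(r2$beta), 0.2)
  # planted slope 0.5 with study offsets recovered
  off <- c(a = 0, b = 1, c = -0.5)[study]
  tf_p <- named_matrix(rbind(0.5 * kin[1, ] + off + rnorm(n, 0, 0.4)),
                       features = "T3", samples = samples)
  r3 <- fit_kinase_tf(tf_p, kin, study)
  expect_lt(abs(r3$beta - 0.5), 0.15)
})

test_that("joint hotspot fits isolate the causal indicator and flag collinearity", {
  set.seed(14)
  n <- 250
  samples <- paste0("s", 1:n)
  hot <- cbind(BRAF_V600E = rbinom(n, 1, 0.2),
               KRAS_G12C = rbinom(n, 1, 0.15),
               KRAS_G12D = rbinom(n, 1, 0.15))
  rownames(hot) <- samples
  act <- named_matrix(rbind(noise = rnorm(n),
                            braf = 1.2 * hot[, 1] + rnorm(n, 0, 0.5)),
                      features = c("Knull", "Kbraf"), samples = samples)
  res <- fit_recurrent_mutations(act, hot)
  expect_equal(sort(unique(res$model_tag)), "eq2")
  null_rows <- res[res$response_id == "Knull", ]
  expect_true(all(abs(null_rows$beta) < 0.3))
  braf <- res[res$response_id == "Kbraf", ]
  expect_lt(abs(braf$beta[braf$predictor_id == "BRAF_V600E"] - 1.2), 0.25)
  expect_true(all(abs(braf$beta[braf$predictor_id != "BRAF_V600E"]) < 0.3))
  # duplicated indicator columns exercise the warning path
  dup <- cbind(hot, KRAS_G12C2 = hot[, "KRAS_G12C"])
  w <- capture_warnings(fit_recurrent_mutations(act, dup))
  expect_true(any(grepl("collinear", w)))
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  brute_bh <- function(p) {
    m <- length(p); o <- order(p); out <- numeric(m)
    for (i in seq_len(m)) {
      j <- which(o == i)  # rank of p[i]
      out[i] <- min(1, min(p[o][j:m] * m / (j:m)))
    }
    out
  }
  set.seed(15)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("network enrichment matches hypergeometric enumeration", {
  # 3 significant in-network vs 3 non-significant out-of-network
  recs <- data.frame(predictor_id = paste0("A", 1:6),
                     response_id = paste0("B", 1:6),
                     fdr = c(rep(1e-4, 3), rep(0.5, 3)))
  edges <- data.frame(protein_a = paste0("A", 1:3),
                      protein_b = paste0("B", 1:3),
                      combined_score = 900L)
  curve <- string_enrichment(recs, edges, min_score = 850, cutoffs = 2)
  expect_equal(curve$a, 3); expect_equal(curve$d, 3)
  expect_equal(curve$p, choose(3, 3) * choose(3, 0) / choose(6, 3),
               tolerance = 1e-12)          # = 1/20 = 0.05
  # table total is constant across cutoffs
  multi <- string_enrichment(recs, edges, min_score = 850,
                             cutoffs = c(0.5, 1, 2, 3, 4))
  expect_true(all(rowSums(multi[, c("a", "b", "c", "d")]) == 6))
  # an empty significant set gives p = 1
  expect_equal(multi$p[multi$cutoff == 4], 1)
  expect_error(string_enrichment(recs, edges, min_score = 999),
               "no edges left")
})

test_that("differential expression uses linear-scale ratios and exact rank-sum p", {
  expr <- named_matrix(rbind(c(8, 9, 2, 3), c(5, 5, 5, 5),
                             c(1, 2, 10, 20)),
                       features = c("up", "flat", "dn"))
  grp <- setNames(factor(c("low", "low", "high", "high"),
                         levels = c("low", "high")), colnames(expr))
  res <- diff_expression_groups(expr, grp)
  expect_equal(res$log2fc[res$feature == "up"], log2(8.5 / 2.5))
  expect_equal(res$log2fc[res$feature == "flat"], 0)
  expect_equal(res$p[res$feature == "flat"], 1)
  # complete separation of 2 vs 2: exact two-sided rank-sum p = 1/3
  expect_equal(res$p[res$feature == "up"], 1 / 3, tolerance = 1e-12)
  # enumeration oracle: 2 of C(4,2)=6 assignments are as extreme
  expect_equal(2 / choose(4, 2), 1 / 3)
})

test_that("activity-sign splitting honours the noise gate", {
  act <- named_matrix(rbind(c(0.5, -0.4, 0.1, -0.05, 1.2)), features = "BRAF")
  grp <- activity_sign_groups(act, "BRAF", noise_cutoff = 0.15)
  expect_equal(unname(as.character(grp)), c("high", "low", "high"))
  expect_setequal(names(grp), c("s1", "s2", "s5"))
})

test_that("mutation classes shift protein abundance as planted", {
  set.seed(16)
  genes <- paste0("G", 1:30)
  samples <- paste0("s", 1:60)
  prot <- named_matrix(matrix(rnorm(30 * 60, 0, 0.3), 30, 60),
                       features = genes, samples = samples)
  rec <- do.call(rbind, lapply(1:40, function(i) {
    data.frame(sample_id = sample(samples, 1), gene = sample(genes, 1),
               mclass = "frameshift_indel", position = 1, ref_residue = "M",
               alt_residue = "L", stringsAsFactors = FALSE)
  }))
  rec <- rec[!duplicated(rec[, 1:2]), ]
  idx <- cbind(match(rec$gene, genes), match(rec$sample_id, samples))
  prot[idx] <- prot[idx] - 0.5
  eff <- mutation_abundance_effect(prot, rec)
  expect_equal(eff$class, "lof")
  se <- 0.3 * sqrt(1 / nrow(rec))
  expect_lt(abs(eff$effect + 0.5), 3 * se)
  expect_lt(eff$p, 0.01)
  # silent-only records produce an empty table
  sil <- transform(rec, mclass = "silent", alt_residue = ref_residue)
  expect_equal(nrow(mutation_abundance_effect(prot, sil)), 0L)
  expect_equal(nrow(mutation_abundance_effect(prot, rec[0, ])), 0L)
})
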