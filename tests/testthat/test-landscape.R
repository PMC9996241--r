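test_that("activity-layer correlations apply the minimum-overlap rule", {
  set.seed(17)
  n <- 30
  act <- named_matrix(rbind(rnorm(n), rnorm(n)), features = c("K1", "K2"),
                      samples = paste0("s", 1:n))
  # K1 protein layer duplicates the activity; K2 has only 9 shared samples
  prot <- named_matrix(rbind(act[1, ], c(rnorm(9), rep(NA, n - 9))),
                       features = c("K1", "K2"), samples = colnames(act))
  res <- correlate_activity_layers(act, list(protein = prot), n_min = 10)
  k1 <- res[res$protein == "K1", ]
  expect_equal(k1$r, 1, tolerance = 1e-12)
  expect_equal(k1$status, "significant")
  expect_equal(res$status[res$protein == "K2"], "unknown")

  # independent noise at n = 100 stays weak and unclassified as significant
  big <- named_matrix(rbind(rnorm(100)), features = "K3",
                      samples = paste0("t", 1:100))
  noise <- named_matrix(rbind(rnorm(100)), features = "K3",
                        samples = colnames(big))
  r2 <- correlate_activity_layers(big, list(rna = noise), n_min = 10)
  expect_lt(abs(r2$r), 0.3)

  # phospho layer is summarised per host protein before correlating
  sites <- named_matrix(rbind(act[1, ] + rnorm(n, 0, 0.01),
                              act[1, ] + rnorm(n, 0, 0.01)),
                        features = c("K1_S4", "K1_T8"),
                        samples = colnames(act))
  r3 <- correlate_activity_layers(act, list(phospho = sites), n_min = 10)
  expect_gt(r3$r[r3$protein == "K1"], 0.99)
})

test_that("kinase pair correlations stratify against the background", {
  set.seed(18)
  n <- 60
  latent <- rnorm(n)
  act <- named_matrix(rbind(latent + rnorm(n, 0, 0.3),
                            latent + rnorm(n, 0, 0.3),
                            -latent + rnorm(n, 0, 0.001),
                            rnorm(n), rnorm(n), rnorm(n)),
                      features = paste0("K", 1:6),
                      samples = paste0("s", 1:n))
  act["K2", ] <- act["K1", ]                       # identical pair
  act["K3", ] <- -act["K1", ]                      # exact sign flip
  pairs <- data.frame(kinase_a = c("K1", "K1"), kinase_b = c("K2", "K3"),
                      n_sources = c(2, 1))
  out <- kinase_pair_correlation(act, pairs)
  rho12 <- out$pairs$rho[out$pairs$kinase_a == "K1" &
                           out$pairs$kinase_b == "K2"]
  expect_equal(rho12, 1)
  rho13 <- out$pairs$rho[out$pairs$kinase_a == "K1" &
                           out$pairs$kinase_b == "K3" &
                           out$pairs$stratum == "single_source"]
  expect_lt(rho13, -0.99)                          # sign-flipped profile
  expect_true(all(c("single_source", "multi_source", "background") %in%
                    out$pairs$stratum))
  mt <- out$tests
  expect_gt(mt$median_rho[mt$stratum == "multi_source"],
            mt$median_background[mt$stratum == "multi_source"])
})

test_that("substrate-redundancy reduction merges by Jaccard distance", {
  kt <- function(k, sites) data.frame(kinase = k, protein = "P",
                                      position = seq_along(sites),
                                      residue = "S", source = "database",
                                      site = sites)
  # identical substrate sets merge; the larger set wins
  prior <- list(kinase_targets = rbind(
    kt("AKT1", paste0("a", 1:4)), kt("AKT2", paste0("a", 1:4)),
    kt("AKT2", "extra"), kt("FAR", paste0("z", 1:3))))
  red <- reduce_redundant_kinases(prior, height = 0.85)
  expect_setequal(red$kept, c("AKT2", "FAR"))
  # disjoint sets (distance 1) all survive
  prior2 <- list(kinase_targets = rbind(kt("A", "x1"), kt("B", "y1"),
                                        kt("C", "w1")))
  expect_setequal(reduce_redundant_kinases(prior2, 0.85)$kept,
                  c("A", "B", "C"))
  # moderate overlap below the cut merges, above it separates
  prior3 <- list(kinase_targets = rbind(
    kt("A", paste0("s", 1:10)),
    kt("B", c(paste0("s", 1:5), paste0("t", 1:5))),   # JI = 1/3, d = 2/3
    kt("C", paste0("u", 1:2))))
  r085 <- reduce_redundant_kinases(prior3, 0.85)
  expect_setequal(r085$kept, c("A", "C"))
  r05 <- reduce_redundant_kinases(prior3, 0.5)
  expect_setequal(r05$kept, c("A", "B", "C"))
  # result is independent of input row order
  prior_shuf <- list(kinase_targets =
                       prior3$kinase_targets[rev(seq_len(nrow(prior3$kinase_targets))), ])
  expect_identical(reduce_redundant_kinases(prior_shuf, 0.85)$kept,
                   r085$kept)
})

test_that("variable-kinase selection is strictly above the median SD", {
  act <- named_matrix(rbind(rep(c(-1, 1), 5) * 1,
                            rep(c(-2, 2), 5),
                            rep(c(-3, 3), 5)),
                      features = c("K1", "K2", "K3"))
  expect_identical(select_variable_kinases(act), "K3")
  flat <- named_matrix(matrix(rep(c(-1, 1), 15), 3, 10, byrow = TRUE),
                       features = c("K1", "K2", "K3"))
  expect_length(select_variable_kinases(flat), 0)
  act2 <- act
  act2["K1", ] <- 0                      # constant kinase is never kept
  expect_false("K1" %in% select_variable_kinases(act2))
})

test_that("tumour-vs-perturbation calls follow the residual z rule and symmetry", {
  set.seed(19)
  nk <- 30
  kin <- paste0("K", 1:nk)
  base <- runif(nk, 0.05, 0.6)
  make_act <- function(pct) {
    # each kinase regulated (|activity| = 3) in round(pct * 100) of 100 samples
    t(vapply(pct, function(p) {
      v <- c(rep(3, round(p * 100)), rep(0, 100 - round(p * 100)))
      sample(v)
    }, numeric(100))) -> m
    rownames(m) <- kin; colnames(m) <- paste0("s", 1:100)
    m
  }
  pct_t <- base; pct_p <- base + rnorm(nk, 0, 0.02)
  pct_t[1] <- 0.9; pct_p[1] <- 0.1        # strongly tumour-shifted kinase
  at <- make_act(pct_t); ap <- make_act(pct_p)
  res <- tumour_vs_perturbation(at, ap, cutoff = 1.75, z_thresh = 2,
                                response = "tumour")
  expect_equal(res$call[res$kinase == "K1"], "tumour_specific")
  expect_true(all(res$call[abs(res$residual_z) <= 2] == "shared"))
  # kinases regulated nowhere are excluded
  at0 <- rbind(at, KZZ = rep(0, 100)); ap0 <- rbind(ap, KZZ = rep(0, 100))
  expect_false("KZZ" %in%
                 tumour_vs_perturbation(at0, ap0, response = "tumour")$kinase)
  # swapping the matrices and the regression orientation exchanges labels
  swap <- tumour_vs_perturbation(ap, at, response = "perturbation")
  expect_equal(swap$call[swap$kinase == "K1"], "perturbation_specific")
  expect_equal(res$residual_z, swap$residual_z, tolerance = 1e-12)
})

test_that("spearman correlations equal a rank-then-pearson oracle", {
  set.seed(20)
  act <- named_matrix(matrix(rnorm(5 * 20), 5, 20),
                      features = paste0("K", 1:5))
  pairs <- data.frame(kinase_a = "K1", kinase_b = "K2", n_sources = 1)
  out <- kinase_pair_correlation(act, pairs)
  rho <- out$pairs$rho[out$pairs$kinase_a == "K1" &
                         out$pairs$kinase_b == "K2"]
  expect_equal(rho, cor(rank(act["K1", ]), rank(act["K2", ])),
               tolerance = 1e-12)
})
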