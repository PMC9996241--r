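make_phospho_fixture <- function(targets, mu, sigma, kinase = "KIN") {
  col <- column_with_background(targets, mu, sigma)
  keys <- c(paste0("T", seq_along(targets), "_S1"),
            paste0("B", seq_len(length(col) - length(targets)), "_S1"))
  ph <- named_matrix(cbind(col), features = keys, samples = "s1")
  pr <- prior_from_sites(setNames(list(keys[seq_along(targets)]), kinase))
  list(phospho = ph, prior = pr)
}

test_that("z-test reproduces the closed-form examples", {
  # three targets at 1, background mean 0 sd 1
  fx <- make_phospho_fixture(c(1, 1, 1), mu = 0, sigma = 1)
  out <- kinase_activity_ztest(fx$phospho, fx$prior, details = TRUE)
  d <- out$details
  expect_equal(d$z, sqrt(3), tolerance = 1e-9)           # 1.7320508
  expect_equal(d$p, 2 * pnorm(-sqrt(3)), tolerance = 1e-9)   # 0.083265
  expect_equal(d$activity, -log10(2 * pnorm(-sqrt(3))), tolerance = 1e-9)
  expect_equal(d$activity, 1.07955, tolerance = 5e-5)
  expect_equal(attr(out$activity, "n_targets")["KIN", "s1"], 3L)

  # sixteen targets at -0.5, background mean 0 sd 2 -> z = -1
  fx2 <- make_phospho_fixture(rep(-0.5, 16), mu = 0, sigma = 2)
  d2 <- kinase_activity_ztest(fx2$phospho, fx2$prior, details = TRUE)$details
  expect_equal(d2$z, -1, tolerance = 1e-9)
  expect_equal(d2$p, 2 * pnorm(-1), tolerance = 1e-9)        # 0.31731
  expect_equal(d2$activity, log10(2 * pnorm(-1)), tolerance = 1e-9)
  expect_equal(d2$activity, -0.49850, tolerance = 5e-5)

  # targets at the background mean -> zero activity, p = 1
  fx3 <- make_phospho_fixture(c(0, 0, 0), mu = 0, sigma = 1)
  d3 <- kinase_activity_ztest(fx3$phospho, fx3$prior, details = TRUE)$details
  expect_equal(d3$z, 0, tolerance = 1e-9)
  expect_equal(d3$p, 1)
  expect_equal(d3$activity, 0)
})

test_that("z-test agrees with an independent erf-based oracle on random data", {
  skip_if_not_installed("pracma")
  set.seed(4)
  n_sites <- 80; n_samples <- 25
  keys <- paste0("P", seq_len(n_sites), "_S1")
  ph <- named_matrix(matrix(rnorm(n_sites * n_samples), n_sites, n_samples),
                     features = keys)
  ph[sample(length(ph), 150)] <- NA
  site_sets <- lapply(1:20, function(i) sample(keys, sample(3:8, 1)))
  names(site_sets) <- paste0("K", 1:20)
  pr <- prior_from_sites(site_sets)
  d <- kinase_activity_ztest(ph, pr, details = TRUE)$details
  expect_gt(nrow(d), 300)
  for (i in seq_len(nrow(d))) {
    col <- ph[, d$sample[i]]
    tv <- col[pr$kinase_targets$site[pr$kinase_targets$kinase == d$kinase[i]]]
    tv <- tv[!is.na(tv)]
    mu <- mean(col, na.rm = TRUE); sig <- sd(col, na.rm = TRUE)
    z <- (mean(tv) - mu) / (sig / sqrt(length(tv)))
    p <- pracma::erfc(abs(z) / sqrt(2))      # independent two-tailed normal
    expect_equal(d$z[i], z, tolerance = 1e-9)
    expect_equal(d$p[i], p, tolerance = 1e-9)
    expect_equal(d$activity[i], sign(z) * -log10(p), tolerance = 1e-9)
  }
})

test_that("activity never decreases when every target value increases", {
  set.seed(5)
  for (rep in 1:20) {
    keys <- paste0("P", 1:40, "_S1")
    ph <- named_matrix(cbind(rnorm(40)), features = keys)
    t_keys <- sample(keys, 5)
    pr <- prior_from_sites(list(K = t_keys))
    a0 <- kinase_activity_ztest(ph, pr)["K", 1]
    ph2 <- ph
    ph2[t_keys, 1] <- ph2[t_keys, 1] + runif(1, 0.1, 2)
    a1 <- kinase_activity_ztest(ph2, pr)["K", 1]
    expect_gte(a1, a0 - 1e-12)
  }
})

test_that("min-target filter and degenerate backgrounds are handled", {
  keys <- paste0("P", 1:10, "_S1")
  ph <- named_matrix(cbind(c(rep(1, 2), rnorm(8))), features = keys)
  pr <- prior_from_sites(list(K = keys[1:2]))
  expect_true(all(is.na(kinase_activity_ztest(ph, pr, min_targets = 3))))
  expect_false(anyNA(kinase_activity_ztest(ph, pr, min_targets = 2)))
  flat <- named_matrix(cbind(rep(1, 10)), features = keys)
  expect_warning(kinase_activity_ztest(flat, prior_from_sites(list(K = keys[1:4]))),
                 "degenerate background")
})

test_that("self-site mode restricts targets to annotated sites on the kinase", {
  keys <- c("KIN_S4", "KIN_S8", "KIN_T12", "OTH_S4", "OTH_S8")
  ph <- named_matrix(matrix(rnorm(5 * 30), 5, 30), features = keys)
  kt <- data.frame(kinase = "KIN",
                   protein = c("KIN", "KIN", "KIN", "OTH", "OTH"),
                   position = c(4, 8, 12, 4, 8),
                   residue = c("S", "S", "T", "S", "S"),
                   source = "database", site = keys)
  ann <- data.frame(site = keys,
                    regulatory = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                    functional_score = c(NA, 0.9, 0.1, NA, NA))
  out <- kinase_activity_ztest(ph, list(kinase_targets = kt),
                               mode = "self_sites", min_targets = 2,
                               site_annotations = ann)
  # only KIN_S4 (regulatory) and KIN_S8 (score > 0.4) qualify
  expect_equal(unname(attr(out, "n_targets")["KIN", 1]), 2L)
})

test_that("NES matches the inverse-normal closed form and its symmetries", {
  genes <- paste0("g", 1:100)
  stat <- seq_len(100) / 10
  m <- named_matrix(cbind(stat), features = genes)
  top <- genes[97:100]
  reg_up <- data.frame(tf = "TF1", target = top, mode = 1)
  nes <- tf_activity_nes(m, reg_up, min_regulon = 4)["TF1", 1]
  closed <- sum(qnorm((97:100) / 101)) / 2
  expect_equal(nes, closed, tolerance = 1e-12)
  expect_equal(nes, 4, tolerance = 0.1)
  # repressive regulon flips the sign
  reg_dn <- transform(reg_up, mode = -1)
  expect_equal(tf_activity_nes(m, reg_dn, min_regulon = 4)["TF1", 1], -closed)
  # targets symmetric around the median rank cancel
  sym <- data.frame(tf = "TF1", target = genes[c(1, 100, 2, 99)], mode = 1)
  expect_equal(tf_activity_nes(m, sym, min_regulon = 4)["TF1", 1], 0,
               tolerance = 1e-12)
  # regulon smaller than the floor yields no score
  expect_true(is.na(tf_activity_nes(m, reg_up, min_regulon = 5)["TF1", 1]))
})

test_that("NES is calibrated to the standard normal under permuted statistics", {
  set.seed(6)
  genes <- paste0("g", 1:200)
  draws <- named_matrix(matrix(rnorm(200 * 1000), 200, 1000),
                        features = genes)
  reg <- data.frame(tf = "TF1", target = sample(genes, 10), mode = 1)
  nes <- tf_activity_nes(draws, reg)["TF1", ]
  expect_gt(mean(nes), -0.05); expect_lt(mean(nes), 0.05)
  expect_gt(sd(nes), 0.9); expect_lt(sd(nes), 1.1)
})

test_that("strong-regulation selection and regulation percentages follow the rules", {
  set.seed(7)
  act <- named_matrix(rbind(c(rep(9, 10), rep(0, 90)), matrix(0, 9, 100)),
                      features = paste0("K", 1:10))
  act[2:10, ] <- rnorm(900, 0, 0.1)
  kept <- select_regulated_proteins(act, percentile = 96.7,
                                    min_fraction = 0.05)
  # brute-force recount with the same rule
  thr <- quantile(abs(act), 0.967, na.rm = TRUE)
  brute <- rownames(act)[sapply(seq_len(nrow(act)), function(i)
    mean(abs(act[i, ]) > thr, na.rm = TRUE) >= 0.05)]
  expect_setequal(kept, brute)
  expect_true("K1" %in% kept)

  expect_equal(unname(regulation_percentage(
    named_matrix(rbind(c(2, -2, 0, 0)), features = "K"), 1.75)), 0.5)
  expect_equal(unname(regulation_percentage(
    named_matrix(rbind(rep(0, 4)), features = "K"), 1.75)), 0)
  expect_equal(unname(regulation_percentage(
    named_matrix(rbind(c(0, 0, 1, -1)), features = "K"), 0)), 0.5)
})
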