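# shared fixture builders; all randomness is locally seeded

named_matrix <- function(values, features = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(features)) features <- paste0("f", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(features, samples)
  m
}

# a phospho column engineered so that the full measured set has an exact
# mean and (sample) SD while `targets` keep their stated values
column_with_background <- function(targets, mu, sigma, n_background = 97) {
  u <- qnorm(seq_len(n_background) / (n_background + 1))
  u <- (u - mean(u)) / sd(u)                      # exact mean 0, sd 1
  beta <- (mu * (length(targets) + n_background) - sum(targets)) / n_background
  f <- function(alpha) sd(c(targets, beta + alpha * u)) - sigma
  alpha <- uniroot(f, c(1e-6, 10 * sigma), tol = 1e-14)$root
  c(targets, beta + alpha * u)
}

# minimal kinase prior: one kinase per list element of site keys
prior_from_sites <- function(site_lists) {
  rows <- lapply(names(site_lists), function(k) {
    ps <- parse_keys(site_lists[[k]])
    data.frame(kinase = k, protein = ps$protein, position = ps$position,
               residue = ps$residue, source = "database",
               site = site_lists[[k]], stringsAsFactors = FALSE)
  })
  list(kinase_targets = do.call(rbind, rows), regulons = NULL)
}

parse_keys <- function(keys) {
  m <- regmatches(keys, regexec("^(.*)_([STY])([0-9]+)$", keys))
  data.frame(protein = vapply(m, `[`, "", 2L),
             position = as.integer(vapply(m, `[`, "", 4L)),
             residue = vapply(m, `[`, "", 3L), stringsAsFactors = FALSE)
}

# exponential survival fixture with a binary hazard group
survival_fixture <- function(n_per_group, hr, seed, base = 1 / 500,
                             cens = 2000) {
  set.seed(seed)
  grp <- rep(c(0, 1), each = n_per_group)
  te <- rexp(2 * n_per_group, rate = base * hr^grp)
  tc <- runif(2 * n_per_group, 0, cens)
  data.frame(sample_id = paste0("s", seq_along(grp)), study = "study1",
             tissue = "t1", group = grp,
             os_time_days = pmin(te, tc),
             os_event = as.integer(te <= tc), stringsAsFactors = FALSE)
}

# three-block activity fixture for clustering recovery
block_activity <- function(n_per_block = 10, n_feat = 60, noise = 0.05,
                           seed = 30) {
  set.seed(seed)
  centers <- matrix(rnorm(n_feat * 3, 0, 2), n_feat, 3)
  m <- centers[, rep(1:3, each = n_per_block)] +
    matrix(rnorm(n_feat * 3 * n_per_block, 0, noise), n_feat)
  dimnames(m) <- list(paste0("f", 1:n_feat),
                      paste0("s", seq_len(3 * n_per_block)))
  list(activity = m, labels = setNames(rep(1:3, each = n_per_block),
                                       colnames(m)))
}
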