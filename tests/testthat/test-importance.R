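make_fit <- function(seed = 1, n = 60, p = 8, sep = 4) {
  set.seed(seed)
  g <- rep(1:2, each = n / 2)
  x <- matrix(stats::rnorm(n * p), n, p)
  x[, 1] <- x[, 1] + sep * (g - 1.5)        # feature 1 carries the groups
  dimnames(x) <- list(sprintf("S%03d", 1:n), sprintf("F%03d", 1:p))
  m <- as_std_pm(x)
  fit <- final_kmeans(m, k = 2, seed = seed, n_init = 10)
  list(m = m, fit = fit)
}

test_that("a constant feature scores exactly zero importance", {
  d <- make_fit(seed = 1)
  x <- d$m$values
  x <- cbind(x, FCONST = 0)
  m <- as_std_pm(x)
  cent <- cbind(d$fit$centroids, FCONST = 0)
  imp <- permutation_importance(m, d$fit$assignment, cent,
                                n_permutations = 10, seed = 2)
  expect_equal(imp$scores$importance[imp$scores$feature_id == "FCONST"], 0)
})

test_that("the single discriminating feature ranks first", {
  top_ranks <- vapply(1:5, function(s) {
    d <- make_fit(seed = 100 + s, sep = 6)
    imp <- permutation_importance(d$m, d$fit$assignment, d$fit$centroids,
                                  n_permutations = 30, seed = s)
    imp$scores$feature_id[1]
  }, character(1))
  expect_true(all(top_ranks == "F001"))
})

test_that("duplicated feature columns earn equal importance up to MC error", {
  set.seed(3)
  n <- 60
  g <- rep(1:2, each = n / 2)
  base <- stats::rnorm(n) + 2.5 * (g - 1.5)
  x <- cbind(FA = base, FB = base, FC = stats::rnorm(n), FD = stats::rnorm(n))
  rownames(x) <- sprintf("S%03d", 1:n)
  m <- as_std_pm(x)
  fit <- final_kmeans(m, k = 2, seed = 3, n_init = 10)
  nperm <- 200
  imp <- permutation_importance(m, fit$assignment, fit$centroids,
                                n_permutations = nperm, seed = 4)
  sc <- stats::setNames(imp$scores$importance, imp$scores$feature_id)
  # per-permutation change fractions are in [0,1]; bound SE by 0.5/sqrt(nperm)
  se <- 0.5 / sqrt(nperm)
  expect_lt(abs(sc["FA"] - sc["FB"]), 2 * sqrt(2) * se)
})

test_that("importance is invariant under joint sample reordering", {
  d <- make_fit(seed = 5)
  imp1 <- permutation_importance(d$m, d$fit$assignment, d$fit$centroids,
                                 n_permutations = 15, seed = 6)
  perm <- sample(nrow(d$m$values))
  m2 <- as_std_pm(d$m$values[perm, ])
  imp2 <- permutation_importance(m2, d$fit$assignment, d$fit$centroids,
                                 n_permutations = 15, seed = 6)
  # same feature x permutation draws on reordered rows: identical scores
  expect_equal(stats::setNames(imp2$scores$importance, imp2$scores$feature_id)[
                 imp1$scores$feature_id],
               stats::setNames(imp1$scores$importance, imp1$scores$feature_id),
               tolerance = 1e-12)
})

test_that("clustering on all top-m = p features reproduces the primary labels", {
  d <- make_fit(seed = 7)
  imp <- permutation_importance(d$m, d$fit$assignment, d$fit$centroids,
                                n_permutations = 10, seed = 8)
  res <- cluster_on_top(d$m, imp, m = ncol(d$m$values),
                        primary = d$fit$assignment, k = 2, seed = 7)
  expect_equal(res$agreement$rand, 1)
  expect_identical(res$assignment$labels, d$fit$assignment$labels)
  expect_error(cluster_on_top(d$m, imp, m = 1, primary = d$fit$assignment, k = 2),
               "at least k")
})

test_that("feature-covariate correlations behave at the limits", {
  co <- small_cohort(seed = 21, n = 50, p = 20, n_modules = 2, informative = 1)
  std <- log_standardize(co$matrix)
  f1 <- feature_ids(std)[1]
  self <- feature_covariate_correlations(std, f1, f1)
  expect_equal(self$rho, 1)

  neg <- data.frame(sample_id = sample_ids(std), negated = -std$values[, f1])
  expect_equal(feature_covariate_correlations(std, f1, neg)$rho, -1)

  const <- data.frame(sample_id = sample_ids(std), flat = 1)
  expect_true(is.na(feature_covariate_correlations(std, f1, const)$rho))
})

test_that("a feature built as noisy monotone function of eGFR recovers rho", {
  set.seed(22)
  n <- 500
  egfr <- stats::rnorm(n, 60, 18)
  # scale noise so the true Pearson correlation is -0.6
  rho_true <- -0.6
  feat <- rho_true * scale(egfr)[, 1] + sqrt(1 - rho_true^2) * stats::rnorm(n)
  x <- cbind(FX = feat, FY = stats::rnorm(n))
  rownames(x) <- sprintf("S%04d", 1:n)
  m <- as_std_pm(x)
  cov <- data.frame(sample_id = rownames(x), egfr = egfr)
  got <- feature_covariate_correlations(m, "FX", cov, method = "pearson")
  expect_lt(abs(got$rho - rho_true), 0.1)
})

test_that("phenogroup expression profiles recover planted shifts and recompose zero", {
  co <- small_cohort(seed = 23, n = 120, p = 100, n_modules = 10, informative = 6)
  std <- log_standardize(co$matrix)
  truth <- phenogroup_assignment(co$true_labels, k = 3)
  tm <- co$truth_manifest
  shifted <- tm$modules[[tm$informative_modules[1]]]
  shifted <- intersect(shifted, feature_ids(std))
  elevated <- which.max(tm$group_shifts[tm$informative_modules[1], ])
  prof <- phenogroup_expression_profile(std, truth, shifted)
  expect_true(mean(prof$argmax_group == elevated) >= 0.5)

  # group means weighted by sizes recompose the global (zero) mean
  prof_all <- phenogroup_expression_profile(std, truth)
  sizes <- table(factor(truth$labels[sample_ids(std)], levels = 1:3))
  recomposed <- as.matrix(prof_all[, paste0("mean_g", 1:3)]) %*%
    (as.numeric(sizes) / sum(sizes))
  expect_true(all(abs(recomposed) < 1e-8))

  one <- phenogroup_assignment(stats::setNames(rep(1L, nrow(std$values)),
                                               sample_ids(std)), k = 1)
  p1 <- phenogroup_expression_profile(std, one, feature_ids(std)[1:3])
  expect_equal(unname(p1$mean_g1), unname(colMeans(std$values[, 1:3])))
})
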