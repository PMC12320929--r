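test_that("Rand index matches hand-enumerated examples", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)  # label-permutation invariant
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1 / 3)  # a=0, d=2 of 6 pairs
  expect_error(rand_index(c(a = 1, b = 2), c(a = 1, c = 2)), "different sample sets")
})

test_that("concordance maximizes agreement over label matchings", {
  expect_equal(concordance(c(1, 1, 2, 2), c(2, 2, 1, 1))$concordance, 1)
  expect_equal(concordance(c(1, 1, 2, 2), c(1, 2, 2, 2))$concordance, 0.75)
  # unequal k: best injection of the 2-label set into the 3-label set
  a <- c(1, 1, 2, 2, 3, 3)
  b <- c(1, 1, 1, 2, 2, 2)
  st <- concordance(a, b)
  expect_equal(st$concordance, oracle_concordance(a, b))
  expect_lte(st$concordance, 1)
  expect_gte(st$concordance, max(table(b)) / length(b))
})

test_that("agreement statistics equal brute-force enumeration on random partitions", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    a <- sample.int(sample(2:4, 1), n, replace = TRUE)
    b <- sample.int(sample(2:4, 1), n, replace = TRUE)
    if (length(unique(a)) < 1 || n < 2) next
    expect_equal(rand_index(a, b), unname(oracle_rand(a, b)))
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b))
    expect_equal(concordance(a, b)$concordance, oracle_concordance(a, b))
  }
})

test_that("adjusted Rand agrees with the mclust reference implementation", {
  set.seed(12)
  for (i in 1:25) {
    a <- sample.int(3, 40, replace = TRUE)
    b <- sample.int(4, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 unname(mclust::adjustedRandIndex(a, b)), tolerance = 1e-12)
  }
})

test_that("both metrics hit 1 exactly when partitions match up to relabeling", {
  set.seed(13)
  for (i in 1:10) {
    a <- sample.int(3, 12, replace = TRUE)
    perm <- sample(3)
    b <- perm[a]
    st <- concordance(a, b)
    expect_equal(st$concordance, 1)
    expect_equal(st$adjusted_rand, 1)
    # and conversely, a genuinely different partition cannot score double 1
    b2 <- b; b2[1] <- setdiff(1:3, b2[1])[1]
    if (length(unique(a)) > 1) {
      st2 <- concordance(a, b2)
      expect_true(st2$concordance < 1 || st2$adjusted_rand < 1)
    }
  }
})

test_that("in-group proportion matches hand computation and the O(n^2) oracle", {
  # 1-D points 0^A, 1^A, 1.5^B, 11^B: NN of 1 is 1.5 (B), NN of 11 is 1.5 (B)
  x <- matrix(c(0, 1, 1.5, 11), ncol = 1,
              dimnames = list(paste0("S", 1:4), "F1"))
  asg <- phenogroup_assignment(c(S1 = 1L, S2 = 1L, S3 = 2L, S4 = 2L), k = 2)
  igp <- in_group_proportion(as_std_pm(x), asg)
  expect_equal(unname(igp$per_group_igp), c(0.5, 0.5))

  # well-separated groups reach IGP 1
  y <- matrix(c(0, 1, 10, 11), ncol = 1, dimnames = list(paste0("S", 1:4), "F1"))
  expect_equal(unname(in_group_proportion(as_std_pm(y), asg)$per_group_igp), c(1, 1))

  # singleton group errors, naming the group
  asg3 <- phenogroup_assignment(c(S1 = 1L, S2 = 1L, S3 = 1L, S4 = 2L), k = 2)
  expect_error(in_group_proportion(as_std_pm(y), asg3), "singleton")

  set.seed(14)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    z <- matrix(stats::rnorm(n * 3), n, 3, dimnames = list(sprintf("S%03d", 1:n), NULL))
    colnames(z) <- paste0("F", 1:3)
    labels <- c(rep(1L, ceiling(n / 2)), rep(2L, floor(n / 2)))
    asgn <- phenogroup_assignment(stats::setNames(labels, rownames(z)), k = 2)
    got <- in_group_proportion(as_std_pm(z), asgn)$per_group_igp
    expect_equal(unname(got), as.numeric(oracle_igp(z, labels)))
  }
})

test_that("random labels on isotropic data sit near chance-level IGP", {
  set.seed(15)
  n <- 200
  z <- matrix(stats::rnorm(n * 5), n, 5, dimnames = list(sprintf("S%03d", 1:n), paste0("F", 1:5)))
  labels <- sample(rep(1:2, each = n / 2))
  asgn <- phenogroup_assignment(stats::setNames(labels, rownames(z)), k = 2)
  igp <- in_group_proportion(as_std_pm(z), asgn)$per_group_igp
  expect_true(all(abs(igp - 0.5) < 0.1))
})

test_that("train/validation splits are exact, seeded, and partition the cohort", {
  co <- small_cohort(seed = 17, n = 1351, p = 20, n_modules = 2, informative = 1)
  halves <- split_train_validation(co, fraction = 0.5, seed = 3)
  expect_equal(nrow(halves$train$matrix$values), 676)        # ceiling(n/2)
  expect_equal(nrow(halves$validation$matrix$values), 675)
  expect_setequal(c(sample_ids(halves$train$matrix),
                    sample_ids(halves$validation$matrix)), sample_ids(co$matrix))
  expect_length(intersect(sample_ids(halves$train$matrix),
                          sample_ids(halves$validation$matrix)), 0)
  again <- split_train_validation(co, fraction = 0.5, seed = 3)
  expect_identical(sample_ids(again$train$matrix), sample_ids(halves$train$matrix))
  expect_error(split_train_validation(co, 1e-9), NA)  # tiny but nonempty train
  expect_error(split_train_validation(co, 1), "fraction")
})

test_that("hub randomization is degenerate-safe and reproducible", {
  set.seed(16)
  x <- matrix(stats::rnorm(80 * 10), 80, 10,
              dimnames = list(sprintf("S%03d", 1:80), sprintf("F%03d", 1:10)))
  logm <- protein_matrix(x, transform_state = "log2")
  red <- reduce_features(logm, mad_fraction = 1, tau = 0.95)  # all singletons
  std <- standardize(logm)
  primary <- final_kmeans(std, k = 2, seed = 1)$assignment
  expect_warning(res <- hub_randomization_sensitivity(logm, red, primary,
                                                      n_reps = 3, k = 2, seed = 1),
                 "degenerate")
  expect_equal(res$median_concordance, 1)

  co <- small_cohort(seed = 18, n = 80, p = 60, n_modules = 6, informative = 4)
  logm2 <- log_transform(co$matrix)
  red2 <- reduce_features(logm2, mad_fraction = 0.6, tau = 0.6)
  std2 <- standardize(pm_subset(logm2, features = red2$selected))
  prim2 <- final_kmeans(std2, k = 3, seed = 2)$assignment
  a <- hub_randomization_sensitivity(logm2, red2, prim2, n_reps = 2, k = 3, seed = 7)
  b <- hub_randomization_sensitivity(logm2, red2, prim2, n_reps = 2, k = 3, seed = 7)
  expect_identical(a$concordance, b$concordance)
  expect_identical(a$rand, b$rand)
})

test_that("the threshold grid reruns the pipeline and flags degenerate cells", {
  co <- small_cohort(seed = 19, n = 90, p = 60, n_modules = 6, informative = 4)
  logm <- log_transform(co$matrix)
  red <- reduce_features(logm, mad_fraction = 0.5, tau = 0.7)
  std <- standardize(pm_subset(logm, features = red$selected))
  primary <- final_kmeans(std, k = 3, seed = 4)$assignment

  grid <- data.frame(mad_fraction = c(0.5, 0.02), tau = c(0.7, 0.7))
  res <- threshold_grid_sensitivity(logm, primary, grid = grid, k = 3, seed = 4)
  expect_equal(res$concordance[1], 1)        # the primary cell reproduces itself
  expect_true(res$failed[2])                 # ceiling(0.02*60)=2 features < k
  expect_equal(nrow(res), 2)
})

test_that("excluding nothing reproduces the primary assignment exactly", {
  co <- small_cohort(seed = 20, n = 80, p = 50, n_modules = 5, informative = 3)
  std <- log_standardize(co$matrix)
  primary <- final_kmeans(std, k = 3, seed = 5)$assignment
  st <- feature_exclusion_sensitivity(std, primary, exclude = character(0),
                                      k = 3, seed = 5)
  expect_equal(st$concordance, 1)
  expect_error(feature_exclusion_sensitivity(std, primary,
                                             exclude = feature_ids(std), k = 3),
               "empties")
  expect_error(feature_exclusion_sensitivity(std, primary, exclude = "nope", k = 3),
               "non-selected")
})
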