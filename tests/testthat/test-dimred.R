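log_pm <- function(x) {
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  protein_matrix(x, transform_state = "log2")
}

test_that("MAD ranking matches hand computation and the ceiling rule", {
  x <- cbind(FA = c(1, 2, 3, 4, 100), FB = c(1, 1, 1, 1, 1),
             FC = c(0, 10, 20, 30, 40))
  m <- log_pm(x)
  sel <- mad_select(m, fraction = 1)
  expect_equal(unname(sel$mad_values["FA"]), 1)   # median |x - 3| of {2,1,0,1,97}
  expect_equal(unname(sel$mad_values["FB"]), 0)

  sel2 <- mad_select(m, fraction = 0.4)           # ceiling(0.4 * 3) = 2
  expect_length(sel2$selected, 2)
  expect_false("FB" %in% sel2$selected)           # constant never beats others

  x10 <- matrix(stats::rnorm(50), 5, 10,
                dimnames = list(NULL, sprintf("F%02d", 1:10)))
  expect_length(mad_select(log_pm(x10), 0.3)$selected, 3)
  expect_error(mad_select(m, 0), "fraction")
})

test_that("MAD selection is invariant to sample and feature order", {
  set.seed(4)
  x <- matrix(stats::rnorm(200), 20, 10,
              dimnames = list(sprintf("S%02d", 1:20), sprintf("F%02d", 1:10)))
  a <- mad_select(log_pm(x), 0.3)$selected
  b <- mad_select(log_pm(x[sample(20), sample(10)]), 0.3)$selected
  expect_setequal(a, b)
})

test_that("modules are connected components at |r| >= tau", {
  set.seed(2)
  base <- stats::rnorm(30)
  x <- cbind(FA = base, FB = base * 2 + 1, FC = -base,        # pairwise |r| = 1
             FD = stats::rnorm(30), FE = stats::rnorm(30))
  mods <- build_modules(log_pm(x), colnames(x), tau = 0.7)
  sizes <- sort(lengths(lapply(mods, `[[`, "members")))
  expect_equal(sizes, c(1, 1, 3))
  expect_setequal(mods[[1]]$members, c("FA", "FB", "FC"))

  mods2 <- build_modules(log_pm(x), colnames(x), tau = 0.999999)
  expect_true(all(lengths(lapply(mods2, `[[`, "members")) %in%
                    c(1, 3)))  # the |r|=1 trio still merges; noise stays single

  x[, "FD"] <- 5
  expect_error(build_modules(log_pm(x), colnames(x), tau = 0.7), "FD")
})

test_that("correlation chains merge transitively into one module", {
  # A-B and B-C correlated above tau, A-C below: still one component
  set.seed(3)
  u <- stats::rnorm(400); v <- stats::rnorm(400)
  x <- cbind(FA = u, FB = 0.75 * u + 0.75 * v + 0.2 * stats::rnorm(400), FC = v)
  r <- stats::cor(x)
  expect_gt(abs(r["FA", "FB"]), 0.6)
  expect_gt(abs(r["FB", "FC"]), 0.6)
  expect_lt(abs(r["FA", "FC"]), 0.6)
  mods <- build_modules(log_pm(x), colnames(x), tau = 0.6, method = "pearson")
  expect_length(mods, 1)
  expect_setequal(mods[[1]]$members, c("FA", "FB", "FC"))
})

test_that("modules partition the post-MAD feature set", {
  co <- small_cohort(seed = 14, n = 80, p = 120, n_modules = 10, informative = 4)
  logm <- log_transform(co$matrix)
  sel <- mad_select(logm, 0.5)
  mods <- build_modules(logm, sel$selected, tau = 0.6)
  members <- unlist(lapply(mods, `[[`, "members"))
  expect_equal(sort(members), sort(sel$selected))  # no overlap, no omission
  expect_equal(anyDuplicated(members), 0)
})

test_that("hub selection follows the documented rules", {
  # toy 3-feature module: FA most connected by construction
  set.seed(5)
  base <- stats::rnorm(200)
  x <- cbind(FA = base + 0.1 * stats::rnorm(200),
             FB = base + 0.45 * stats::rnorm(200),
             FC = base + 0.45 * stats::rnorm(200))
  m <- log_pm(x)
  mods <- build_modules(m, colnames(x), tau = 0.5, method = "pearson")
  expect_length(mods, 1)
  conn <- rowSums(abs(mods[[1]]$corr)) - 1
  expect_equal(names(which.max(conn)), "FA")
  mads <- mad_select(m, 1)$mad_values
  red <- select_hubs(mods, mads, rule = "max_connectivity")
  expect_equal(red$selected, "FA")

  single <- build_modules(m, "FB", tau = 0.5)
  for (rule in c("max_connectivity", "max_mad", "random")) {
    expect_equal(select_hubs(single, mads, rule = rule)$selected, "FB")
  }

  r1 <- select_hubs(mods, mads, rule = "random", seed = 42)$selected
  r2 <- select_hubs(mods, mads, rule = "random", seed = 42)$selected
  expect_identical(r1, r2)
})

test_that("iterated reduction reaches a fixed point and can shrink further", {
  co <- small_cohort(seed = 15, n = 100, p = 80, n_modules = 6, informative = 2)
  logm <- log_transform(co$matrix)
  one <- reduce_features(logm, mad_fraction = 0.5, tau = 0.65, n_rounds = 1)
  again <- reduce_features(logm, mad_fraction = 0.5, tau = 0.65, n_rounds = 3)
  expect_true(length(again$selected) <= length(one$selected))

  # data with no correlated pairs: output invariant in n_rounds
  set.seed(6)
  x <- matrix(stats::rnorm(60 * 12), 60, 12,
              dimnames = list(sprintf("S%02d", 1:60), sprintf("F%02d", 1:12)))
  ind1 <- reduce_features(log_pm(x), mad_fraction = 1, tau = 0.9, n_rounds = 1)
  ind3 <- reduce_features(log_pm(x), mad_fraction = 1, tau = 0.9, n_rounds = 3)
  expect_identical(sort(ind1$selected), sort(ind3$selected))

  # under connected-component modules, surviving hubs sit in different
  # components, so all pairwise |r| < tau and round 2 is already a fixed point
  set.seed(7)
  core <- stats::rnorm(300)
  x2 <- cbind(FA = core + 0.30 * stats::rnorm(300),
              FB = core + 0.30 * stats::rnorm(300),
              FC = core + 1.40 * stats::rnorm(300),
              FD = core + 1.40 * stats::rnorm(300))
  m2 <- log_pm(x2)
  r1 <- reduce_features(m2, mad_fraction = 1, tau = 0.8, method = "pearson",
                        n_rounds = 1)
  r2 <- reduce_features(m2, mad_fraction = 1, tau = 0.8, method = "pearson",
                        n_rounds = 3)
  expect_identical(sort(r1$selected), sort(r2$selected))
  hub_r <- stats::cor(x2[, r1$selected])
  expect_true(all(abs(hub_r[upper.tri(hub_r)]) < 0.8))
})
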