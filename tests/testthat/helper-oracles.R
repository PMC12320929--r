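# Independent brute-force oracles used to verify the implementation.
# These deliberately share no code with R/: pair statistics by explicit
# double loops, matching by explicit permutation enumeration, the Cox
# partial likelihood by direct evaluation.

# pair-count table (n11 together/together, n10, n01, n00) by O(n^2) loop
oracle_pair_counts <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
}

oracle_rand <- function(a, b) {
  pc <- oracle_pair_counts(a, b)
  (pc["n11"] + pc["n00"]) / sum(pc)
}

# Hubert-Arabie adjusted Rand from pair counts (closed form)
oracle_ari <- function(a, b) {
  pc <- oracle_pair_counts(a, b)
  num <- 2 * (pc["n11"] * pc["n00"] - pc["n10"] * pc["n01"])
  den <- (pc["n11"] + pc["n10"]) * (pc["n10"] + pc["n00"]) +
    (pc["n11"] + pc["n01"]) * (pc["n01"] + pc["n00"])
  if (den == 0) return(1)
  unname(num / den)
}

oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_permutations(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# max matched-agreement fraction over all injections of the smaller label
# set into the larger, by enumerating permutations of the larger set
oracle_concordance <- function(a, b) {
  ua <- sort(unique(a)); ub <- sort(unique(b))
  if (length(ua) > length(ub)) { tmp <- a; a <- b; b <- tmp
                                 tmp <- ua; ua <- ub; ub <- tmp }
  best <- 0
  for (perm in oracle_permutations(ub)) {
    map <- perm[seq_along(ua)]           # image of ua under this injection
    agreed <- sum(map[match(a, ua)] == b)
    best <- max(best, agreed)
  }
  best / length(a)
}

# nearest-neighbour in-group proportion by explicit double loop
oracle_igp <- function(x, labels) {
  n <- nrow(x)
  same <- logical(n)
  for (i in seq_len(n)) {
    best_d <- Inf; best_j <- NA
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt(sum((x[i, ] - x[j, ])^2))
      if (d < best_d) { best_d <- d; best_j <- j }
    }
    same[i] <- labels[best_j] == labels[i]
  }
  tapply(same, labels, mean)
}

# exact Cox partial log-likelihood for one covariate, no ties
oracle_cox_loglik <- function(beta, time, event, z) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; z <- z[ord]
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * z[i] - log(sum(exp(beta * z[risk])))
  }
  ll
}

oracle_cox_beta <- function(time, event, z) {
  stats::optimize(function(b) -oracle_cox_loglik(b, time, event, z),
                  interval = c(-8, 8), tol = 1e-10)$minimum
}

# small well-separated standardized matrix with g groups for cluster tests
toy_groups <- function(n_per = 10, g = 2, p = 4, sep = 50, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(g), function(i) {
    matrix(stats::rnorm(n_per * p, mean = i * sep), n_per, p)
  }))
  dimnames(x) <- list(sprintf("S%03d", seq_len(g * n_per)),
                      sprintf("F%03d", seq_len(p)))
  protein_matrix(x, transform_state = "standardized",
                 transform_params = list(
                   center = stats::setNames(rep(0, p), colnames(x)),
                   scale = stats::setNames(rep(1, p), colnames(x))))
}

# wrap a bare numeric matrix as a standardized protein_matrix
as_std_pm <- function(x) {
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("F%03d", seq_len(ncol(x)))
  protein_matrix(x, transform_state = "standardized",
                 transform_params = list(
                   center = stats::setNames(rep(0, ncol(x)), colnames(x)),
                   scale = stats::setNames(rep(1, ncol(x)), colnames(x))))
}

small_cohort <- function(seed = 1, n = 150, p = 200, effect = 2,
                         n_modules = 20, informative = 6) {
  generate_cohort(cohort_config(
    n_samples = n, n_features = p, n_modules = n_modules,
    module_size_range = c(3, min(8, max(3, floor(p / n_modules)))),
    n_informative_modules = informative,
    effect_size = effect, seed = seed))
}
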