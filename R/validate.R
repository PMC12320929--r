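# Partition-agreement statistics, internal validation, and the sensitivity
# analyses that probe how stable the phenogroups are to analytic choices.

align_labels <- function(labels_a, labels_b) {
  a <- if (inherits(labels_a, "phenogroup_assignment")) labels_a$labels else labels_a
  b <- if (inherits(labels_b, "phenogroup_assignment")) labels_b$labels else labels_b
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("label vectors cover different sample sets")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("label vectors differ in length and carry no sample IDs")
  }
  list(a = as.integer(factor(a)), b = as.integer(factor(b)))
}

#' Rand index and adjusted Rand index between two partitions
#'
#' The Rand index is the fraction of sample pairs on which the two
#' partitions agree (co-clustered in both, or separated in both):
#' `(a + d) / C(n,2)`. The adjusted Rand index applies the usual
#' expected-index correction under the permutation null. Both are
#' label-permutation invariant. Inputs may be named vectors or
#' [phenogroup_assignment]s; alignment is by sample ID when names are
#' present.
#'
#' @param labels_a,labels_b partitions of the same sample set.
#' @return for `rand_index`, a single value in `[0, 1]`; for
#'   `adjusted_rand_index`, a value in `(-1, 1]`.
#' @export
rand_index <- function(labels_a, labels_b) {
  al <- align_labels(labels_a, labels_b)
  n <- length(al$a)
  if (n < 2) stop("need at least two samples")
  tab <- table(al$a, al$b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  # agreements = co-clustered in both + separated in both
  (total + 2 * sum_ij - sum_i - sum_j) / total
}

#' @rdname rand_index
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  al <- align_labels(labels_a, labels_b)
  n <- length(al$a)
  if (n < 2) stop("need at least two samples")
  tab <- table(al$a, al$b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- sum_i * sum_j / total
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

all_injections <- function(from, into) {
  # all injective maps from `from` (indices) into `into` (indices)
  if (length(from) == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(into)) {
    rest <- all_injections(from[-1], into[-i])
    out <- c(out, lapply(rest, function(r) c(into[i], r)))
  }
  out
}

#' Optimal-matching concordance between two partitions
#'
#' The maximum fraction of samples with matching labels over all injections
#' of the smaller label set into the larger one (exhaustive search on the
#' confusion matrix, exact for up to 8 groups). Handles partitions with
#' unequal numbers of groups. Identical partitions (up to label permutation)
#' give concordance, Rand and adjusted Rand of exactly 1.
#'
#' @inheritParams rand_index
#' @return an `agreement_stats` list: `concordance`, `rand`,
#'   `adjusted_rand`, and `matching` (the optimal label map, smaller set ->
#'   larger set as used internally).
#' @export
concordance <- function(labels_a, labels_b) {
  al <- align_labels(labels_a, labels_b)
  n <- length(al$a)
  tab <- table(factor(al$a), factor(al$b))
  swap <- nrow(tab) > ncol(tab)
  conf <- if (swap) t(tab) else tab
  s <- nrow(conf); l <- ncol(conf)
  if (l > 8) stop("exhaustive matching supports at most 8 groups")
  best <- -1; best_map <- NULL
  for (inj in all_injections(seq_len(s), seq_len(l))) {
    agreed <- sum(conf[cbind(seq_len(s), inj)])
    if (agreed > best) { best <- agreed; best_map <- inj }
  }
  structure(list(concordance = best / n,
                 rand = rand_index(labels_a, labels_b),
                 adjusted_rand = adjusted_rand_index(labels_a, labels_b),
                 matching = best_map,
                 matching_swapped = swap),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> concordance = %.4f, Rand = %.4f, adjusted Rand = %.4f\n",
              x$concordance, x$rand, x$adjusted_rand))
  invisible(x)
}

#' In-group proportion (IGP) of each phenogroup
#'
#' The in-group proportion of group g is the fraction of its samples whose
#' Euclidean nearest neighbour (excluding self) also belongs to g — the
#' Kapp–Tibshirani cluster-reproducibility statistic. Distances are taken on
#' the supplied (standardized, selected-feature) matrix.
#'
#' @param matrix a [protein_matrix] on the analysis scale.
#' @param assignment a [phenogroup_assignment] covering the matrix samples.
#' @return list with `per_group_igp` (named by group), `n_per_group`, and
#'   `distance_metric`.
#' @export
in_group_proportion <- function(matrix, assignment) {
  stopifnot(inherits(matrix, "protein_matrix"),
            inherits(assignment, "phenogroup_assignment"))
  labels <- assignment$labels[sample_ids(matrix)]
  if (anyNA(labels)) stop("assignment does not cover all matrix samples")
  sizes <- table(factor(labels, levels = seq_len(assignment$k)))
  single <- names(sizes)[sizes == 1]
  if (length(single)) stop("singleton group(s): ", paste(single, collapse = ", "))
  d <- as.matrix(stats::dist(matrix$values))
  diag(d) <- Inf
  nn <- max.col(-d, ties.method = "first")
  same <- labels[nn] == labels
  igp <- tapply(same, factor(labels, levels = seq_len(assignment$k)), mean)
  list(per_group_igp = stats::setNames(as.numeric(igp), names(igp)),
       n_per_group = stats::setNames(as.integer(sizes), names(sizes)),
       distance_metric = "euclidean")
}

#' Split a cohort into training and validation halves
#'
#' Seeded uniform random split without replacement; the training side gets
#' `ceiling(fraction * n)` samples. Downstream, transform parameters must be
#' re-estimated on the training side only and frozen for the validation side
#' (see [standardize()] and [internal_validation()]).
#'
#' @param cohort a `synthetic_cohort` (all tables are split consistently).
#' @param fraction training fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with elements `train` and `validation`, each a
#'   `synthetic_cohort`.
#' @export
split_train_validation <- function(cohort, fraction = 0.5, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  ids <- sample_ids(cohort$matrix)
  n_train <- ceiling(fraction * length(ids))
  if (n_train == length(ids)) stop("validation side is empty")
  set.seed(seed)
  train_ids <- sort(sample(ids, n_train))
  valid_ids <- setdiff(ids, train_ids)
  take <- function(keep) {
    out <- cohort
    out$matrix <- pm_subset(cohort$matrix, samples = keep)
    out$clinical <- cohort$clinical[cohort$clinical$sample_id %in% keep, , drop = FALSE]
    out$survival <- cohort$survival[cohort$survival$sample_id %in% keep, , drop = FALSE]
    out$true_labels <- cohort$true_labels[keep]
    rownames(out$clinical) <- rownames(out$survival) <- NULL
    out
  }
  list(train = take(train_ids), validation = take(valid_ids))
}

run_reduce_cluster <- function(log_matrix, mad_fraction, tau, method,
                               hub_rule, k, seed, n_rounds = 1L) {
  red <- reduce_features(log_matrix, mad_fraction = mad_fraction, tau = tau,
                         method = method, hub_rule = hub_rule,
                         seed = seed, n_rounds = n_rounds)
  if (length(red$selected) < k) return(NULL)
  std <- standardize(pm_subset(log_matrix, features = red$selected))
  fit <- final_kmeans(std, k = k, seed = seed)
  list(reduction = red, std = std, fit = fit)
}

#' Hub-randomization sensitivity of the phenogroups
#'
#' Repeats hub selection with random (rather than deterministic) hubs in
#' every module of size >= 3, re-runs k-means at fixed `k`, and measures the
#' concordance and Rand index of each repetition against the primary
#' assignment. High medians indicate the phenogroups do not depend on which
#' member represents a correlated set.
#'
#' @param log_matrix a log2 [protein_matrix] (the reduction input scale).
#' @param reduction the primary `reduction_result`.
#' @param primary the primary [phenogroup_assignment].
#' @param n_reps repetitions (the full analysis uses 1000).
#' @param k fixed number of phenogroups.
#' @param seed RNG seed (each repetition derives its own stream).
#' @return list with `median_concordance`, `iqr_concordance`, `median_rand`,
#'   `iqr_rand`, and per-repetition vectors `concordance`, `rand`.
#' @export
hub_randomization_sensitivity <- function(log_matrix, reduction, primary,
                                          n_reps = 1000, k, seed = 1L) {
  stopifnot(inherits(reduction, "reduction_result"))
  sizes <- lengths(lapply(reduction$modules, `[[`, "members"))
  if (!any(sizes >= 3)) {
    warning("no module of size >= 3; hub randomization is degenerate, all stats = 1")
    ones <- rep(1, n_reps)
    return(list(median_concordance = 1, iqr_concordance = c(1, 1),
                median_rand = 1, iqr_rand = c(1, 1),
                concordance = ones, rand = ones))
  }
  conc <- rand <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- seed + r
    set.seed(rep_seed)
    hubs <- vapply(reduction$modules, function(m) {
      if (length(m$members) >= 3) m$members[sample.int(length(m$members), 1)]
      else reduction$hubs[[as.character(m$module_id)]]
    }, character(1))
    std <- standardize(pm_subset(log_matrix, features = unname(hubs)))
    fit <- final_kmeans(std, k = k, seed = rep_seed, n_init = 10)
    st <- concordance(fit$assignment, primary)
    conc[r] <- st$concordance
    rand[r] <- st$rand
  }
  list(median_concordance = stats::median(conc),
       iqr_concordance = stats::quantile(conc, c(0.25, 0.75), names = FALSE),
       median_rand = stats::median(rand),
       iqr_rand = stats::quantile(rand, c(0.25, 0.75), names = FALSE),
       concordance = conc, rand = rand)
}

#' Sensitivity of the phenogroups to dimension-reduction thresholds
#'
#' Re-runs the full reduce-then-cluster pipeline for every (MAD fraction,
#' correlation threshold) cell of a grid and reports agreement with the
#' primary assignment. The default grid crosses fractions {0.2, 0.3, 0.4}
#' with thresholds {0.6, 0.7, 0.8, 0.9} — 12 combinations. Cells that leave
#' fewer than `k` features are flagged as failed, not fatal.
#'
#' @param log_matrix a log2 [protein_matrix].
#' @param primary the primary [phenogroup_assignment].
#' @param grid data.frame with columns `mad_fraction` and `tau`.
#' @param k fixed number of phenogroups.
#' @param seed RNG seed.
#' @param method correlation method for module construction.
#' @param hub_rule hub rule (primary default `max_connectivity`).
#' @return data.frame: one row per cell with `mad_fraction`, `tau`,
#'   `n_selected`, `concordance`, `rand`, `adjusted_rand`, `failed`.
#' @export
threshold_grid_sensitivity <- function(log_matrix, primary,
                                       grid = expand.grid(
                                         mad_fraction = c(0.2, 0.3, 0.4),
                                         tau = c(0.6, 0.7, 0.8, 0.9)),
                                       k, seed = 1L,
                                       method = "spearman",
                                       hub_rule = "max_connectivity") {
  if (!nrow(grid)) stop("empty sensitivity grid")
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- run_reduce_cluster(log_matrix, grid$mad_fraction[i], grid$tau[i],
                               method, hub_rule, k, seed)
    if (is.null(cell)) {
      return(data.frame(mad_fraction = grid$mad_fraction[i], tau = grid$tau[i],
                        n_selected = NA_integer_, concordance = NA_real_,
                        rand = NA_real_, adjusted_rand = NA_real_, failed = TRUE))
    }
    st <- concordance(cell$fit$assignment, primary)
    data.frame(mad_fraction = grid$mad_fraction[i], tau = grid$tau[i],
               n_selected = length(cell$reduction$selected),
               concordance = st$concordance, rand = st$rand,
               adjusted_rand = st$adjusted_rand, failed = FALSE)
  })
  do.call(rbind, res)
}

#' Sensitivity of the phenogroups to excluding named features
#'
#' Re-clusters on the selected feature set minus `exclude` at fixed `k` and
#' reports agreement with the primary assignment — e.g. dropping the reagent
#' targeting a natriuretic peptide to check the phenogroups are not driven by
#' one canonical biomarker.
#'
#' @param std_matrix the standardized selected-feature [protein_matrix] used
#'   for the primary clustering.
#' @param primary the primary [phenogroup_assignment].
#' @param exclude feature IDs to drop (must be among the matrix's features).
#' @param k fixed number of phenogroups.
#' @param seed RNG seed.
#' @return an `agreement_stats` (see [concordance()]).
#' @export
feature_exclusion_sensitivity <- function(std_matrix, primary, exclude, k, seed = 1L) {
  stopifnot(inherits(std_matrix, "protein_matrix"))
  miss <- setdiff(exclude, feature_ids(std_matrix))
  if (length(miss)) stop("exclude list contains non-selected feature(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  keep <- setdiff(feature_ids(std_matrix), exclude)
  if (!length(keep)) stop("exclusion empties the feature set")
  fit <- final_kmeans(pm_subset(std_matrix, features = keep), k = k, seed = seed)
  concordance(fit$assignment, primary)
}

#' Internal validation by split-sample clustering and centroid assignment
#'
#' Splits the cohort, runs the full reduce-and-cluster pipeline on the
#' training half (transform parameters estimated there and frozen), assigns
#' the validation half by training centroids, and reports the in-group
#' proportion of every phenogroup on both sides plus agreement with the
#' cohort's true labels where available.
#'
#' @param cohort a `synthetic_cohort`.
#' @param fraction training fraction (default 0.5).
#' @param k number of phenogroups (`NULL` = select by consensus PAC).
#' @param seed RNG seed.
#' @param ... passed to [phenomap()] (e.g. `mad_fraction`, `tau`,
#'   `n_resamples`).
#' @return list with `fit` (the training [phenomap]), `train_igp`,
#'   `validation_igp` (IGP results), `train_assignment`,
#'   `validation_assignment`.
#' @export
internal_validation <- function(cohort, fraction = 0.5, k = NULL, seed = 1L, ...) {
  halves <- split_train_validation(cohort, fraction, seed)
  fit <- phenomap(halves$train$matrix, k = k, seed = seed, ...)
  train_igp <- in_group_proportion(fit$std_matrix, fit$assignment)
  valid_assign <- stats::predict(fit, halves$validation$matrix)
  valid_std <- log_standardize(
    pm_subset(halves$validation$matrix, features = intersect(feature_ids(halves$validation$matrix), names(fit$transform_params$center))),
    params = fit$transform_params)
  valid_igp <- in_group_proportion(valid_std, valid_assign)
  list(fit = fit, train_igp = train_igp, validation_igp = valid_igp,
       train_assignment = fit$assignment, validation_assignment = valid_assign)
}
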