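# Permutation variable importance for unsupervised phenogroups: how much
# does scrambling one feature perturb nearest-centroid assignment?

#' Permutation variable importance for phenogroup definition
#'
#' For each feature, its column is permuted across samples
#' `n_permutations` times; after each permutation all samples are
#' re-assigned to their nearest centroid, and the importance is the mean
#' fraction of samples whose label changes relative to the unpermuted
#' assignment. The measure is self-contained (no classifier fit), exactly
#' zero for a constant feature, and invariant under joint reordering of
#' samples and labels. Squared distances are updated incrementally per
#' feature, so one permutation costs O(n k) rather than O(n k p).
#'
#' @param matrix the standardized selected-feature [protein_matrix] the
#'   centroids live in.
#' @param assignment the primary [phenogroup_assignment].
#' @param centroids k x p centroid matrix (from [final_kmeans()]).
#' @param n_permutations permutations per feature (>= 1).
#' @param seed RNG seed.
#' @return an `importance_ranking`: data.frame `scores` (feature_id,
#'   target_name, importance, rank; rank ties broken by feature ID),
#'   `n_permutations`, `seed`.
#' @export
permutation_importance <- function(matrix, assignment, centroids,
                                   n_permutations = 100, seed = 1L) {
  stopifnot(inherits(matrix, "protein_matrix"),
            inherits(assignment, "phenogroup_assignment"))
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  x <- matrix$values[, colnames(centroids), drop = FALSE]
  base_labels <- assignment$labels[rownames(x)]
  if (anyNA(base_labels)) stop("assignment does not cover all matrix samples")
  n <- nrow(x); k <- nrow(centroids); p <- ncol(x)
  d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centroids) +
    outer(rep(1, n), rowSums(centroids^2))
  set.seed(seed)
  # permutations are drawn over samples in sorted-ID order, so the scores are
  # exactly invariant under joint reordering of matrix rows and labels
  sorted_idx <- order(rownames(x))
  pos <- match(rownames(x), rownames(x)[sorted_idx])
  scores <- numeric(p)
  for (j in seq_len(p)) {
    cj <- centroids[, j]
    xj_sorted <- x[sorted_idx, j]
    contrib <- outer(x[, j], cj, function(a, b) (a - b)^2)
    frac_changed <- numeric(n_permutations)
    for (b in seq_len(n_permutations)) {
      perm <- sample.int(n)
      contrib_p <- outer(xj_sorted[perm][pos], cj, function(a, b2) (a - b2)^2)
      d2p <- d2 - contrib + contrib_p
      labels_p <- max.col(-d2p, ties.method = "first")
      frac_changed[b] <- mean(labels_p != base_labels)
    }
    scores[j] <- mean(frac_changed)
  }
  fid <- colnames(x)
  ord <- order(-scores, fid)
  ranks <- integer(p); ranks[ord] <- seq_len(p)
  meta <- matrix$feature_meta
  df <- data.frame(feature_id = fid,
                   target_name = meta$target_name[match(fid, meta$feature_id)],
                   importance = scores, rank = ranks,
                   stringsAsFactors = FALSE)
  structure(list(scores = df[order(df$rank), ],
                 n_permutations = n_permutations, seed = seed),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, n = 10, ...) {
  cat(sprintf("<importance_ranking> %d features, %d permutations; top %d:\n",
              nrow(x$scores), x$n_permutations, min(n, nrow(x$scores))))
  print(utils::head(x$scores, n), row.names = FALSE)
  invisible(x)
}

#' Re-cluster using only the top-ranked features
#'
#' Runs the final k-means on the `m` highest-importance features alone and
#' reports agreement with the primary assignment — quantifying how much of
#' the phenogroup structure the top features carry.
#'
#' @param matrix the standardized selected-feature [protein_matrix].
#' @param ranking an `importance_ranking`.
#' @param m number of top features to use (`k <= m <= p`).
#' @param primary the primary [phenogroup_assignment].
#' @param k number of phenogroups.
#' @param seed RNG seed.
#' @return list with `assignment` and `agreement` (an `agreement_stats`).
#' @export
cluster_on_top <- function(matrix, ranking, m, primary, k, seed = 1L) {
  stopifnot(inherits(ranking, "importance_ranking"))
  p <- nrow(ranking$scores)
  if (m > p) stop("m exceeds the number of ranked features")
  if (m < k) stop("m must be at least k")
  top <- ranking$scores$feature_id[seq_len(m)]
  fit <- final_kmeans(pm_subset(matrix, features = top), k = k, seed = seed)
  list(assignment = fit$assignment,
       agreement = concordance(fit$assignment, primary))
}

#' Correlations between features and clinical covariates (or other features)
#'
#' @param matrix a [protein_matrix] on the analysis scale.
#' @param features feature IDs (rows of the output).
#' @param covariates either a data.frame keyed by `sample_id` whose remaining
#'   numeric columns are covariates, or a character vector of other feature
#'   IDs from `matrix`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame `feature_id`, `covariate`, `rho`, `n`; a constant
#'   covariate yields `NA` with a note in `rho`.
#' @export
feature_covariate_correlations <- function(matrix, features, covariates,
                                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "protein_matrix"))
  fx <- matrix$values[, features, drop = FALSE]
  if (is.character(covariates)) {
    cov_mat <- matrix$values[, covariates, drop = FALSE]
  } else {
    cov_df <- align_samples(matrix, covariates)
    num <- vapply(cov_df, is.numeric, logical(1)) & names(cov_df) != "sample_id"
    cov_mat <- as.matrix(cov_df[, num, drop = FALSE])
    rownames(cov_mat) <- cov_df$sample_id
  }
  if (nrow(fx) < 10) stop("need >= 10 paired observations")
  out <- expand.grid(feature_id = features, covariate = colnames(cov_mat),
                     stringsAsFactors = FALSE)
  out$rho <- NA_real_
  out$n <- nrow(fx)
  for (i in seq_len(nrow(out))) {
    y <- cov_mat[, out$covariate[i]]
    if (stats::sd(y) == 0) next  # constant covariate: undefined, left NA
    out$rho[i] <- stats::cor(fx[, out$feature_id[i]], y, method = method)
  }
  out
}

#' Mean expression of features by phenogroup
#'
#' Group-wise mean (in the matrix's units, typically standardized) of each
#' requested feature, with the argmax group per feature. With standardized
#' input, group means weighted by group sizes recompose the global (zero)
#' mean.
#'
#' @param matrix a [protein_matrix].
#' @param assignment a [phenogroup_assignment] covering the samples.
#' @param features feature IDs (default: all).
#' @return data.frame with one row per feature: per-group means
#'   (`mean_g1`, ...) and `argmax_group`.
#' @export
phenogroup_expression_profile <- function(matrix, assignment,
                                          features = feature_ids(matrix)) {
  stopifnot(inherits(matrix, "protein_matrix"),
            inherits(assignment, "phenogroup_assignment"))
  labels <- assignment$labels[sample_ids(matrix)]
  if (anyNA(labels)) stop("assignment does not cover all matrix samples")
  sub <- matrix$values[, features, drop = FALSE]
  gm <- vapply(seq_len(assignment$k), function(g) {
    colMeans(sub[labels == g, , drop = FALSE])
  }, numeric(ncol(sub)))
  if (!is.matrix(gm)) gm <- matrix(gm, nrow = 1, dimnames = list(features, NULL))
  colnames(gm) <- paste0("mean_g", seq_len(assignment$k))
  data.frame(feature_id = features, gm,
             argmax_group = max.col(gm, ties.method = "first"),
             stringsAsFactors = FALSE, row.names = NULL)
}
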