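# Consensus k-means phenogroup discovery: subsampled co-clustering matrices,
# PAC-based selection of k, a k-means++/Lloyd final fit, and nearest-centroid
# assignment of new samples.

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2 / sum(d2))
    centers[j + 1, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  centers
}

lloyd_kmeans <- function(x, centers, iter_max = 100) {
  k <- nrow(centers)
  obj_trace <- numeric(0)
  labels <- integer(nrow(x))
  for (it in seq_len(iter_max)) {
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
      outer(rep(1, nrow(x)), rowSums(centers^2))
    new_labels <- max.col(-d2, ties.method = "first")
    obj <- sum(d2[cbind(seq_len(nrow(x)), new_labels)])
    obj_trace <- c(obj_trace, obj)
    if (length(unique(new_labels)) < k) {
      return(list(degenerate = TRUE))
    }
    if (it > 1 && identical(new_labels, labels)) break
    labels <- new_labels
    for (g in seq_len(k)) centers[g, ] <- colMeans(x[labels == g, , drop = FALSE])
  }
  # objective at the final centers (post-update), for the converged fit
  d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  labels <- max.col(-d2, ties.method = "first")
  wss <- sum(d2[cbind(seq_len(nrow(x)), labels)])
  list(degenerate = FALSE, labels = labels, centers = centers,
       tot_withinss = wss, obj_trace = c(obj_trace, wss), iterations = length(obj_trace))
}

#' Final k-means phenogroup definition
#'
#' Lloyd's algorithm with k-means++ initialization, `n_init` restarts, and
#' the lowest within-cluster sum of squares kept. Restarts that collapse to
#' an empty cluster are discarded. Groups are renumbered 1..k by descending
#' size (ties by previous index), so phenogroup 1 is always the largest —
#' making labels comparable across runs. Centroids are returned in the
#' (standardized) feature units of the input.
#'
#' @param matrix a standardized [protein_matrix] (features = the selected
#'   hub set).
#' @param k number of phenogroups (>= 2).
#' @param seed RNG seed.
#' @param n_init number of k-means++ restarts (default 50).
#' @param iter_max Lloyd iteration cap per restart.
#' @return list with `assignment` (a [phenogroup_assignment]),
#'   `centroids` (k x p matrix, rownames `"1"` to `"k"`), `tot_withinss`, and
#'   `obj_trace` (objective per iteration of the winning restart,
#'   non-increasing).
#' @export
final_kmeans <- function(matrix, k, seed = 1L, n_init = 50, iter_max = 100) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (k < 2) stop("k must be >= 2")
  x <- matrix$values
  if (k > nrow(x)) stop("k exceeds the number of samples")
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    fit <- lloyd_kmeans(x, kmeanspp_centers(x, k), iter_max)
    if (fit$degenerate) next
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
  }
  if (is.null(best)) stop("all k-means restarts degenerate (empty cluster); is k too large?")
  sizes <- tabulate(best$labels, k)
  ord <- order(-sizes, seq_len(k))             # descending size, stable
  relab <- match(seq_len(k), ord)              # old label -> new label
  labels <- relab[best$labels]
  centroids <- best$centers[ord, , drop = FALSE]
  dimnames(centroids) <- list(as.character(seq_len(k)), colnames(x))
  assignment <- phenogroup_assignment(
    stats::setNames(labels, rownames(x)), k = k,
    provenance = list(feature_hash = fnv1a_hash(colnames(x)), seed = seed,
                      method = "kmeans++/lloyd", n_init = n_init))
  list(assignment = assignment, centroids = centroids,
       tot_withinss = best$tot_withinss, obj_trace = best$obj_trace)
}

#' Consensus clustering over subsampled k-means runs
#'
#' For each candidate `k`, draws `n_resamples` subsamples of
#' `ceiling(subsample_fraction * n)` samples, clusters each with k-means, and
#' records for every pair of samples the fraction of co-samplings in which
#' they co-clustered (the consensus matrix). Stability of each `k` is scored
#' by the proportion of ambiguous clustering, `PAC(k) = F(0.9) - F(0.1)` of
#' the empirical CDF of off-diagonal consensus entries. The chosen `k` is the
#' largest candidate whose PAC lies within `pac_band` of the minimum:
#' because merging well-separated clusters is itself a stable operation
#' under subsampling, the raw PAC minimum systematically favours k below the
#' true group number, and PAC differences finer than the resampling
#' granularity carry no information. The CDF-area increment
#' (`delta_area`) is reported alongside for inspection. Pairs never
#' co-sampled are excluded from the CDF (with a warning if they exceed 1% of
#' pairs). Fully reproducible under a fixed seed.
#'
#' @param matrix a standardized [protein_matrix] (selected features).
#' @param k_range integer vector of candidate k (within `[2, n/3]`).
#' @param n_resamples subsampling repetitions per k (default 1000).
#' @param subsample_fraction fraction of samples per draw, in (0,1).
#' @param seed RNG seed.
#' @param inner_nstart random restarts of the inner k-means (stats::kmeans);
#'   too few restarts let the inner fits misconverge and inflate PAC at the
#'   true k.
#' @param pac_band tolerance for treating two PAC values as tied (default
#'   0.05, the scale of the resampling granularity).
#' @param keep_matrices keep the n x n consensus matrices (memory!).
#' @return object of class `consensus_result`: `k_range`, `pac`,
#'   `delta_area`, `cdf_curves` (per k: sorted consensus entries), `chosen_k`,
#'   and (if kept) `consensus_matrices`. Run [final_kmeans()] at `chosen_k`
#'   for the final labels (the [phenomap()] wrapper does both).
#' @export
consensus_cluster <- function(matrix, k_range = 2:8, n_resamples = 1000,
                              subsample_fraction = 0.8, seed = 1L,
                              inner_nstart = 5, pac_band = 0.05,
                              keep_matrices = FALSE) {
  stopifnot(inherits(matrix, "protein_matrix"))
  x <- matrix$values
  n <- nrow(x)
  if (any(k_range < 2) || any(k_range > floor(n / 3))) {
    stop("k_range must lie within [2, n/3]")
  }
  if (subsample_fraction <= 0 || subsample_fraction >= 1) {
    stop("subsample_fraction must lie in (0, 1)")
  }
  m <- ceiling(subsample_fraction * n)
  pac <- stats::setNames(numeric(length(k_range)), k_range)
  areas <- stats::setNames(numeric(length(k_range)), k_range)
  cdfs <- list()
  cons_mats <- list()
  set.seed(seed)
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    conn <- matrix(0, n, n)
    both <- matrix(0, n, n)
    for (r in seq_len(n_resamples)) {
      idx <- sort(sample.int(n, m))
      km <- suppressWarnings(
        stats::kmeans(x[idx, , drop = FALSE], centers = k,
                      nstart = inner_nstart, iter.max = 30))
      co <- outer(km$cluster, km$cluster, "==")
      conn[idx, idx] <- conn[idx, idx] + co
      both[idx, idx] <- both[idx, idx] + 1
    }
    never <- both == 0 & upper.tri(both)
    if (any(never)) {
      frac_missing <- mean(never[upper.tri(both)])
      if (frac_missing > 0.01) {
        warning(sprintf("k=%d: %.1f%% of sample pairs never co-sampled; increase n_resamples",
                        k, 100 * frac_missing))
      }
    }
    cons <- ifelse(both > 0, conn / pmax(both, 1), NA_real_)
    diag(cons) <- 1
    entries <- cons[upper.tri(cons)]
    entries <- entries[!is.na(entries)]
    entries <- sort(entries)
    cdfs[[as.character(k)]] <- entries
    pac[ki] <- mean(entries <= 0.9) - mean(entries <= 0.1)
    # area under the empirical CDF over [0,1]
    areas[ki] <- mean(1 - entries)
    if (keep_matrices) cons_mats[[as.character(k)]] <- cons
  }
  delta_area <- c(NA_real_, diff(areas) / pmax(utils::head(areas, -1), .Machine$double.eps))
  names(delta_area) <- k_range
  # Merging well-separated clusters is itself stable under subsampling, so the
  # raw PAC minimum systematically underestimates k (it rewards k < k_true).
  # PAC differences below the resampling granularity are also not meaningful.
  # Rule: among k whose PAC lies within `pac_band` of the minimum, take the
  # largest -- the finest partition whose ambiguity is statistically
  # indistinguishable from the most stable one.
  candidates <- k_range[pac <= min(pac) + pac_band]
  chosen <- max(candidates)
  structure(list(k_range = k_range, pac = pac, delta_area = delta_area,
                 cdf_curves = cdfs, chosen_k = chosen,
                 consensus_matrices = if (keep_matrices) cons_mats else NULL,
                 params = list(n_resamples = n_resamples,
                               subsample_fraction = subsample_fraction,
                               seed = seed)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> PAC by k:\n")
  print(round(x$pac, 4))
  cat("chosen k =", x$chosen_k, "\n")
  invisible(x)
}

#' Assign samples to phenogroups by nearest centroid
#'
#' New samples must be on the training scale (frozen log2 + z-score
#' parameters; see [standardize()]) and carry exactly the training feature
#' set. Each sample goes to the closest centroid in Euclidean distance,
#' ties to the lower group index. For a converged k-means, re-assigning the
#' training samples reproduces their training labels exactly.
#'
#' @param matrix a standardized [protein_matrix].
#' @param centroids k x p centroid matrix (from [final_kmeans()]).
#' @param provenance optional provenance list.
#' @return a [phenogroup_assignment].
#' @export
assign_by_centroid <- function(matrix, centroids, provenance = list()) {
  stopifnot(inherits(matrix, "protein_matrix"))
  x <- matrix$values
  missing_f <- setdiff(colnames(centroids), colnames(x))
  extra_f <- setdiff(colnames(x), colnames(centroids))
  if (length(missing_f) || length(extra_f)) {
    stop("feature mismatch with centroids; missing: [",
         paste(utils::head(missing_f, 5), collapse = ", "),
         "]; extra: [", paste(utils::head(extra_f, 5), collapse = ", "), "]")
  }
  x <- x[, colnames(centroids), drop = FALSE]
  d2 <- outer(rowSums(x^2), rep(1, nrow(centroids))) - 2 * x %*% t(centroids) +
    outer(rep(1, nrow(x)), rowSums(centroids^2))
  labels <- max.col(-d2, ties.method = "first")  # ties -> lower group index
  phenogroup_assignment(stats::setNames(labels, rownames(x)),
                        k = nrow(centroids),
                        provenance = utils::modifyList(
                          list(feature_hash = fnv1a_hash(colnames(centroids)),
                               method = "nearest_centroid"), provenance))
}
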