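#' Fit a molecular phenomap: reduce, consensus-cluster, define phenogroups
#'
#' The package's core fitting function. Starting from a raw (or log2)
#' samples-by-features abundance matrix it:
#'
#' 1. applies sample QC rules ([filter_samples()]);
#' 2. log2-transforms and ranks features by median absolute deviation,
#'    keeping the top `mad_fraction` ([mad_select()]);
#' 3. collapses sets of mutually correlated features (`|r| >= tau`,
#'    connected components) to one hub each ([build_modules()],
#'    [select_hubs()]), optionally over several rounds;
#' 4. standardizes the selected features (z-score; parameters frozen for
#'    later assignment of new samples);
#' 5. selects the number of phenogroups k by consensus clustering and the
#'    proportion of ambiguous clustering (PAC), unless `k` is given
#'    ([consensus_cluster()]);
#' 6. defines the final phenogroups by k-means++ with multiple restarts,
#'    renumbered so phenogroup 1 is the largest ([final_kmeans()]).
#'
#' @param x a [protein_matrix] (raw or log2 scale).
#' @param k number of phenogroups; `NULL` (default) selects k by minimum PAC
#'   over `k_range`.
#' @param qc_rules sample QC rule list for [filter_samples()] (default: no
#'   exclusions).
#' @param mad_fraction,tau,corr_method,hub_rule,n_rounds dimension-reduction
#'   settings; see [reduce_features()].
#' @param k_range candidate k for consensus selection.
#' @param n_resamples,subsample_fraction,inner_nstart consensus-clustering
#'   settings; see [consensus_cluster()].
#' @param n_init k-means++ restarts for the final fit.
#' @param seed integer seed governing every stochastic step.
#' @return an object of class `phenomap` with components `assignment` (a
#'   [phenogroup_assignment]), `centroids`, `consensus` (a
#'   `consensus_result`, or `NULL` when `k` was fixed), `reduction` (a
#'   `reduction_result`), `qc_report`, `std_matrix` (the standardized
#'   selected-feature matrix the fit lives in), `transform_params` (frozen
#'   per-feature log2 mean/SD), `k`, `seed`, and `call`.
#' @seealso [predict.phenomap()] to assign new samples,
#'   [in_group_proportion()], [hub_randomization_sensitivity()],
#'   [permutation_importance()], [cox_fit()].
#' @export
phenomap <- function(x, k = NULL,
                     qc_rules = list(),
                     mad_fraction = 0.3, tau = 0.7,
                     corr_method = c("spearman", "pearson"),
                     hub_rule = c("max_connectivity", "max_mad", "random"),
                     n_rounds = 1L,
                     k_range = 2:8, n_resamples = 1000,
                     subsample_fraction = 0.8, inner_nstart = 5,
                     n_init = 50, seed = 1L) {
  corr_method <- match.arg(corr_method)
  hub_rule <- match.arg(hub_rule)
  stopifnot(inherits(x, "protein_matrix"))
  cl <- match.call()

  qc <- if (length(qc_rules)) filter_samples(x, qc_rules) else
    list(matrix = x, report = NULL)
  logm <- if (qc$matrix$transform_state == "raw") log_transform(qc$matrix) else qc$matrix
  red <- reduce_features(logm, mad_fraction = mad_fraction, tau = tau,
                         method = corr_method, hub_rule = hub_rule,
                         seed = seed, n_rounds = n_rounds)
  std <- standardize(pm_subset(logm, features = red$selected))

  consensus <- NULL
  if (is.null(k)) {
    consensus <- consensus_cluster(std, k_range = k_range,
                                   n_resamples = n_resamples,
                                   subsample_fraction = subsample_fraction,
                                   inner_nstart = inner_nstart, seed = seed)
    k <- consensus$chosen_k
  }
  fit <- final_kmeans(std, k = k, seed = seed, n_init = n_init)

  structure(list(assignment = fit$assignment,
                 centroids = fit$centroids,
                 consensus = consensus,
                 reduction = red,
                 qc_report = qc$report,
                 std_matrix = std,
                 transform_params = std$transform_params,
                 tot_withinss = fit$tot_withinss,
                 obj_trace = fit$obj_trace,
                 k = k, seed = seed, call = cl),
            class = "phenomap")
}

#' @export
print.phenomap <- function(x, ...) {
  cat("Molecular phenomap\n")
  cat(sprintf("  %d samples, %d selected features (of %d modules), k = %d\n",
              length(x$assignment$labels), length(x$reduction$selected),
              length(x$reduction$modules), x$k))
  tab <- table(factor(x$assignment$labels, levels = seq_len(x$k)))
  cat("  phenogroup sizes:", paste(as.integer(tab), collapse = " / "), "\n")
  if (!is.null(x$consensus)) {
    cat(sprintf("  k selected by consensus PAC (PAC = %.4f)\n",
                x$consensus$pac[as.character(x$k)]))
  }
  invisible(x)
}

#' @export
summary.phenomap <- function(object, ...) {
  igp <- tryCatch(in_group_proportion(object$std_matrix, object$assignment),
                  error = function(e) NULL)
  out <- list(k = object$k,
              sizes = as.integer(table(factor(object$assignment$labels,
                                              levels = seq_len(object$k)))),
              n_selected = length(object$reduction$selected),
              n_modules = length(object$reduction$modules),
              pac = if (!is.null(object$consensus)) object$consensus$pac else NULL,
              igp = if (!is.null(igp)) igp$per_group_igp else NULL,
              tot_withinss = object$tot_withinss)
  class(out) <- "summary.phenomap"
  out
}

#' @export
print.summary.phenomap <- function(x, ...) {
  cat(sprintf("Phenomap summary: k = %d, %d selected features (%d modules)\n",
              x$k, x$n_selected, x$n_modules))
  cat("  sizes:", paste(x$sizes, collapse = " / "), "\n")
  if (!is.null(x$pac)) {
    cat("  PAC by k:", paste(sprintf("%s:%.3f", names(x$pac), x$pac), collapse = "  "), "\n")
  }
  if (!is.null(x$igp)) {
    cat("  in-group proportion:",
        paste(sprintf("g%s:%.3f", names(x$igp), x$igp), collapse = "  "), "\n")
  }
  cat(sprintf("  within-cluster SS: %.2f\n", x$tot_withinss))
  invisible(x)
}

#' Assign new samples to fitted phenogroups
#'
#' Applies the training log2 + z-score transform (frozen per-feature
#' parameters) to `newdata` and assigns each sample to the nearest training
#' centroid. The new matrix must contain every selected feature.
#'
#' @param object a fitted [phenomap].
#' @param newdata a raw or log2 [protein_matrix].
#' @param ... unused.
#' @return a [phenogroup_assignment].
#' @export
predict.phenomap <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "protein_matrix"))
  sel <- colnames(object$centroids)
  miss <- setdiff(sel, feature_ids(newdata))
  if (length(miss)) {
    stop("newdata is missing selected feature(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  sub <- pm_subset(newdata, features = sel)
  std <- switch(sub$transform_state,
                raw = log_standardize(sub, params = object$transform_params),
                log2 = standardize(sub, params = object$transform_params),
                standardized = sub)
  assign_by_centroid(std, object$centroids,
                     provenance = list(seed = object$seed, source = "predict.phenomap"))
}

#' Phenogroup labels of a fitted phenomap
#' @param fit a [phenomap].
#' @return named integer vector of 1-based phenogroup labels.
#' @export
phenogroups <- function(fit) {
  stopifnot(inherits(fit, "phenomap"))
  fit$assignment$labels
}

#' Plot consensus diagnostics of a phenomap
#'
#' Left: empirical CDFs of the consensus-matrix entries for each candidate
#' k. Right: PAC by k with the chosen k marked. Requires the fit to have
#' run consensus selection.
#'
#' @param x a [phenomap].
#' @param ... passed to [graphics::plot()].
#' @export
plot.phenomap <- function(x, ...) {
  if (is.null(x$consensus)) {
    stop("this fit used a fixed k; no consensus diagnostics to plot")
  }
  cons <- x$consensus
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "consensus index", ylab = "empirical CDF",
                 main = "Consensus CDFs", ...)
  cols <- grDevices::hcl.colors(length(cons$k_range), "Dark 3")
  for (i in seq_along(cons$k_range)) {
    e <- cons$cdf_curves[[as.character(cons$k_range[i])]]
    graphics::lines(e, seq_along(e) / length(e), col = cols[i])
  }
  graphics::legend("bottomright", legend = paste0("k=", cons$k_range),
                   col = cols, lty = 1, cex = 0.8, bty = "n")
  graphics::plot(cons$k_range, cons$pac, type = "b", xlab = "k", ylab = "PAC",
                 main = "Proportion of ambiguous clustering")
  graphics::abline(v = cons$chosen_k, lty = 2)
  invisible(x)
}
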