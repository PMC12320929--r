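# Sample/feature quality control and transformation to the analysis scale.

#' Per-feature intraassay coefficient of variation from replicates
#'
#' For each replicate group (>= 2 measurements of the same specimen) the CV of
#' a feature is `100 * SD / mean` on the raw scale; per-feature CVs are then
#' averaged across replicate groups. The summary reports the median and IQR
#' across features — the intraassay precision figure quoted for aptamer
#' panels (median ~9% on this platform class).
#'
#' @param matrix a raw-scale [protein_matrix] whose rows are replicate
#'   measurements.
#' @param replicate_of named character vector mapping each row (replicate ID)
#'   to its source specimen ID.
#' @return list with `per_feature_cv` (named, %), `median_cv`, `cv_iqr`
#'   (named length-2, %).
#' @export
compute_feature_cv <- function(matrix, replicate_of) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (matrix$transform_state != "raw") stop("CV is computed on the raw scale")
  vals <- matrix$values
  groups <- split(rownames(vals), replicate_of[rownames(vals)])
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop("replicate group(s) of size 1: ", paste(names(groups)[sizes < 2], collapse = ", "))
  }
  per_group <- vapply(groups, function(rows) {
    sub <- vals[rows, , drop = FALSE]
    m <- colMeans(sub)
    if (any(m == 0)) stop("zero replicate mean for feature ",
                          colnames(sub)[which(m == 0)[1]])
    100 * apply(sub, 2, stats::sd) / m
  }, numeric(ncol(vals)))
  per_group <- matrix(per_group, nrow = ncol(vals),
                      dimnames = list(colnames(vals), names(groups)))
  per_feature <- rowMeans(per_group)
  list(per_feature_cv = per_feature,
       median_cv = stats::median(per_feature),
       cv_iqr = stats::quantile(per_feature, c(0.25, 0.75), names = FALSE))
}

#' Remove samples failing quality-control rules
#'
#' Rules mirror platform-style sample QC: an explicit exclusion list and/or
#' per-sample total-signal scale-factor bounds (total signal divided by the
#' cohort median total; samples outside `[lo, hi]` fail). The exact criteria
#' of commercial platforms are proprietary; this rule set is the package's
#' documented stand-in. Every exclusion carries a reason string; the input
#' matrix is left untouched. Idempotent for a fixed rule set.
#'
#' @param matrix a raw-scale [protein_matrix].
#' @param rules list with optional elements `exclude_ids` (character) and
#'   `scale_factor_bounds` (numeric `c(lo, hi)`). An empty list excludes
#'   nothing.
#' @return list with `matrix` (filtered [protein_matrix]) and `report`
#'   (`qc_report`: counts, excluded samples with reasons).
#' @export
filter_samples <- function(matrix, rules = list()) {
  stopifnot(inherits(matrix, "protein_matrix"))
  known <- setdiff(names(rules), c("exclude_ids", "scale_factor_bounds"))
  if (length(known)) stop("unknown QC rule(s): ", paste(known, collapse = ", "))
  ids <- sample_ids(matrix)
  reasons <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(rules$exclude_ids)) {
    hit <- intersect(rules$exclude_ids, ids)
    reasons[hit] <- "explicit_exclusion"
  }
  if (!is.null(rules$scale_factor_bounds)) {
    b <- rules$scale_factor_bounds
    if (length(b) != 2 || b[1] >= b[2]) stop("scale_factor_bounds must be c(lo, hi), lo < hi")
    tot <- rowSums(matrix$values)
    # the reference median is that of the retained cohort, so exclusion is
    # iterated to a fixed point; this makes the rule idempotent
    repeat {
      keep_now <- ids[is.na(reasons)]
      if (!length(keep_now)) break
      sf <- tot[keep_now] / stats::median(tot[keep_now])
      out <- keep_now[sf < b[1] | sf > b[2]]
      if (!length(out)) break
      reasons[out] <- sprintf("scale_factor_out_of_bounds (%.3f)",
                              sf[match(out, keep_now)])
    }
  }
  excluded <- ids[!is.na(reasons)]
  if (length(excluded) == length(ids)) stop("QC rules exclude every sample (empty cohort)")
  kept <- setdiff(ids, excluded)
  report <- structure(list(
    n_samples_in = length(ids),
    n_samples_out = length(kept),
    excluded_samples = data.frame(sample_id = excluded,
                                  reason = unname(reasons[excluded]),
                                  stringsAsFactors = FALSE),
    dropped_features = character(0)), class = "qc_report")
  list(matrix = pm_subset(matrix, samples = kept), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d -> %d samples (%d excluded)\n",
              x$n_samples_in, x$n_samples_out, nrow(x$excluded_samples)))
  if (length(x$dropped_features)) {
    cat("  zero-variance features dropped:", length(x$dropped_features), "\n")
  }
  invisible(x)
}

#' Log2-transform a raw protein matrix
#' @param matrix a raw-scale [protein_matrix].
#' @return a [protein_matrix] with `transform_state == "log2"`.
#' @export
log_transform <- function(matrix) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (matrix$transform_state != "raw") stop("log_transform expects a raw matrix")
  out <- matrix
  out$values <- log2(matrix$values)
  out$transform_state <- "log2"
  out
}

#' Standardize features (z-score), with a frozen-parameter path
#'
#' Centres and scales every feature column using the sample SD (divisor
#' n − 1, the [scale()] convention). The (mean, SD) pairs are retained in the
#' result so the identical training-scale transform can be re-applied to new
#' samples via `params` — required for centroid-based assignment of a
#' validation set. Zero-variance features cannot be scaled and are dropped
#' with a warning (recorded in the returned matrix's `dropped_features`
#' attribute) rather than aborting the run.
#'
#' @param matrix a log2-scale [protein_matrix].
#' @param params optional frozen `list(center=, scale=)` from a previous
#'   standardization; when supplied, those parameters are applied verbatim.
#' @return a [protein_matrix] with `transform_state == "standardized"` and
#'   `transform_params` set.
#' @export
standardize <- function(matrix, params = NULL) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (matrix$transform_state != "log2") stop("standardize expects a log2 matrix")
  vals <- matrix$values
  if (is.null(params)) {
    ctr <- colMeans(vals)
    scl <- apply(vals, 2, stats::sd)
    drop <- names(scl)[scl == 0]
    if (length(drop)) {
      warning("dropping ", length(drop), " zero-variance feature(s): ",
              paste(utils::head(drop, 5), collapse = ", "))
      keep <- setdiff(colnames(vals), drop)
      vals <- vals[, keep, drop = FALSE]
      ctr <- ctr[keep]; scl <- scl[keep]
    }
  } else {
    if (!all(colnames(vals) %in% names(params$center))) {
      stop("frozen parameters missing for feature(s): ",
           paste(utils::head(setdiff(colnames(vals), names(params$center)), 5), collapse = ", "))
    }
    keep <- intersect(names(params$center), colnames(vals))
    vals <- vals[, keep, drop = FALSE]
    ctr <- params$center[keep]; scl <- params$scale[keep]
    drop <- character(0)
  }
  z <- sweep(sweep(vals, 2, ctr, "-"), 2, scl, "/")
  out <- protein_matrix(z,
                        feature_meta = matrix$feature_meta[matrix$feature_meta$feature_id %in% colnames(z), , drop = FALSE],
                        sample_flags = matrix$sample_flags,
                        transform_state = "standardized",
                        transform_params = list(center = ctr, scale = scl))
  attr(out, "dropped_features") <- drop
  out
}

#' Log2 + z-score in one step
#'
#' Composition of [log_transform()] and [standardize()]; see those for the
#' conventions (sample-SD z-score, zero-variance features dropped with a
#' warning, frozen parameters retained for new-sample assignment).
#'
#' @inheritParams standardize
#' @param matrix a raw-scale [protein_matrix].
#' @return a standardized [protein_matrix].
#' @export
log_standardize <- function(matrix, params = NULL) {
  standardize(log_transform(matrix), params = params)
}
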