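#' Construct a protein abundance matrix
#'
#' The central container of the pipeline: a samples-by-features matrix of
#' aptamer-reagent abundances (RFU-like, strictly positive on the raw scale)
#' with sample and feature identifiers, optional per-feature metadata
#' (target protein names), per-sample QC flags, and a transform state that
#' tracks whether values are raw, log2, or per-feature standardized.
#'
#' @param values numeric matrix, samples as rows and features as columns, with
#'   unique row and column names. Raw values must be finite and strictly
#'   positive.
#' @param feature_meta optional data.frame with columns `feature_id` and
#'   `target_name` (extra columns are kept).
#' @param sample_flags optional data.frame with columns `sample_id`, `flagged`
#'   (logical) and `reason` (character); defaults to all-unflagged.
#' @param transform_state one of `"raw"`, `"log2"`, `"standardized"`.
#' @param transform_params for `"standardized"` matrices, a list with numeric
#'   vectors `center` and `scale` (per retained feature) so the identical
#'   transform can be applied to new samples.
#' @return an object of class `protein_matrix`.
#' @export
protein_matrix <- function(values, feature_meta = NULL, sample_flags = NULL,
                           transform_state = c("raw", "log2", "standardized"),
                           transform_params = NULL) {
  transform_state <- match.arg(transform_state)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x features)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample IDs as rownames and feature IDs as colnames")
  }
  dup_s <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_s)) stop("duplicate sample ID(s): ", paste(unique(dup_s), collapse = ", "))
  dup_f <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_f)) stop("duplicate feature ID(s): ", paste(unique(dup_f), collapse = ", "))
  if (!all(is.finite(values))) stop("`values` must be finite (no NA/NaN/Inf)")
  if (transform_state == "raw" && any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("raw abundances must be strictly positive; offending cell sample '%s', feature '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (is.null(feature_meta)) {
    feature_meta <- data.frame(feature_id = colnames(values),
                               target_name = colnames(values),
                               stringsAsFactors = FALSE)
  } else {
    if (!all(c("feature_id", "target_name") %in% names(feature_meta))) {
      stop("`feature_meta` needs columns feature_id and target_name")
    }
    feature_meta <- feature_meta[match(colnames(values), feature_meta$feature_id), , drop = FALSE]
    if (anyNA(feature_meta$feature_id)) stop("`feature_meta` is missing some feature IDs")
    rownames(feature_meta) <- NULL
  }
  if (is.null(sample_flags)) {
    sample_flags <- data.frame(sample_id = rownames(values),
                               flagged = FALSE, reason = "",
                               stringsAsFactors = FALSE)
  } else {
    if (!all(c("sample_id", "flagged", "reason") %in% names(sample_flags))) {
      stop("`sample_flags` needs columns sample_id, flagged, reason")
    }
    sample_flags <- sample_flags[match(rownames(values), sample_flags$sample_id), , drop = FALSE]
    if (anyNA(sample_flags$sample_id)) stop("`sample_flags` is missing some sample IDs")
    rownames(sample_flags) <- NULL
  }
  if (transform_state == "standardized") {
    if (is.null(transform_params) ||
        !all(c("center", "scale") %in% names(transform_params))) {
      stop("standardized matrices must carry transform_params$center and $scale")
    }
  }
  structure(list(values = values,
                 feature_meta = feature_meta,
                 sample_flags = sample_flags,
                 transform_state = transform_state,
                 transform_params = transform_params),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("<protein_matrix> %d samples x %d features [%s]\n",
              nrow(x$values), ncol(x$values), x$transform_state))
  nf <- sum(x$sample_flags$flagged)
  if (nf) cat(sprintf("  %d sample(s) flagged by QC\n", nf))
  invisible(x)
}

#' @export
dim.protein_matrix <- function(x) dim(x$values)

#' Sample and feature identifiers of a protein matrix
#' @param x a `protein_matrix`.
#' @return character vector of IDs in stored order.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
feature_ids <- function(x) colnames(x$values)

#' Subset a protein matrix by sample and/or feature IDs
#'
#' Keeps metadata, flags and (column-subset) transform parameters aligned.
#'
#' @param x a `protein_matrix`.
#' @param samples,features character vectors of IDs to keep (default: all).
#' @return a `protein_matrix`.
#' @export
pm_subset <- function(x, samples = sample_ids(x), features = feature_ids(x)) {
  miss_s <- setdiff(samples, sample_ids(x))
  if (length(miss_s)) stop("unknown sample ID(s): ", paste(miss_s, collapse = ", "))
  miss_f <- setdiff(features, feature_ids(x))
  if (length(miss_f)) stop("unknown feature ID(s): ", paste(miss_f, collapse = ", "))
  tp <- x$transform_params
  if (!is.null(tp) && !is.null(tp$center)) {
    tp$center <- tp$center[features]
    tp$scale <- tp$scale[features]
  }
  protein_matrix(x$values[samples, features, drop = FALSE],
                 feature_meta = x$feature_meta[x$feature_meta$feature_id %in% features, , drop = FALSE],
                 sample_flags = x$sample_flags[x$sample_flags$sample_id %in% samples, , drop = FALSE],
                 transform_state = x$transform_state,
                 transform_params = tp)
}
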