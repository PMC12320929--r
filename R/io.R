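# Readers reject malformed input rather than coercing; alignment across the
# matrix / clinical / survival tables is always by sample_id, never row order.

fnv1a_hash <- function(ids) {
  # 32-bit FNV-1a over the concatenated IDs; stable provenance fingerprint
  h <- 2166136261 %% 2147483648
  for (b in utf8ToInt(paste(ids, collapse = "\x1f"))) {
    h <- bitwXor(as.integer(h), b)
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

parse_numeric_body <- function(df, path) {
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop(sprintf("%s: duplicate sample ID(s): %s", path,
                                paste(unique(dup), collapse = ", ")))
  fids <- names(df)[-1]
  dupf <- fids[duplicated(fids)]
  if (length(dupf)) stop(sprintf("%s: duplicate feature ID(s): %s", path,
                                 paste(unique(dupf), collapse = ", ")))
  vals <- matrix(NA_real_, nrow(df), length(fids), dimnames = list(ids, fids))
  for (j in seq_along(fids)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric cell at row %d (sample '%s'), column '%s': '%s'",
                   path, bad[1], ids[bad[1]], fids[j], col[bad[1]]))
    }
    if (anyNA(num)) {
      stop(sprintf("%s: missing value at row %d, column '%s'",
                   path, which(is.na(num))[1], fids[j]))
    }
    vals[, j] <- num
  }
  vals
}

#' Read a protein abundance matrix
#'
#' Two text dialects are supported: `tsv_wide` (header row of feature IDs,
#' first column `sample_id`, samples as rows) and `adat_like`, a minimal
#' aptamer-platform-style layout with a caret-prefixed key/value header block
#' (`^TransformState`, `^TargetNames`, ...) followed by the same tab-separated
#' wide body. The `adat_like` dialect exists to round-trip this package's own
#' output, not to implement the full commercial ADAT specification.
#'
#' Malformed input (duplicate IDs, non-numeric cells, nonpositive raw values)
#' is rejected with a message naming the offender, never silently coerced.
#'
#' @param path file path.
#' @param dialect `"tsv_wide"` or `"adat_like"`.
#' @return a [protein_matrix].
#' @export
read_matrix <- function(path, dialect = c("tsv_wide", "adat_like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- list()
  if (dialect == "adat_like") {
    lines <- readLines(path)
    is_hdr <- grepl("^\\^", lines)
    if (!is_hdr[1]) stop(path, ": adat_like file must start with a ^-prefixed header block")
    hdr <- seq_len(which.min(is_hdr) - 1L)  # leading contiguous block
    for (ln in lines[hdr]) {
      kv <- strsplit(sub("^\\^", "", ln), "\t")[[1]]
      meta[[kv[1]]] <- if (length(kv) > 1) kv[-1] else character(0)
    }
    body <- paste(lines[-hdr], collapse = "\n")
    df <- utils::read.delim(text = body, check.names = FALSE,
                            colClasses = "character", sep = "\t")
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character", sep = "\t")
  }
  if (ncol(df) < 2) stop(path, ": expected a sample_id column plus >= 1 feature column")
  vals <- parse_numeric_body(df, path)
  state <- if (length(meta$TransformState)) meta$TransformState[1] else "raw"
  fm <- NULL
  if (length(meta$TargetNames)) {
    if (length(meta$TargetNames) != ncol(vals)) {
      stop(path, ": ^TargetNames length does not match feature count")
    }
    fm <- data.frame(feature_id = colnames(vals), target_name = meta$TargetNames,
                     stringsAsFactors = FALSE)
  }
  protein_matrix(vals, feature_meta = fm, transform_state = state,
                 transform_params = if (state == "standardized") {
                   list(center = stats::setNames(rep(0, ncol(vals)), colnames(vals)),
                        scale = stats::setNames(rep(1, ncol(vals)), colnames(vals)))
                 } else NULL)
}

#' Write a protein abundance matrix
#'
#' @param x a [protein_matrix].
#' @param path output file path.
#' @param dialect see [read_matrix()].
#' @export
write_matrix <- function(x, path, dialect = c("tsv_wide", "adat_like")) {
  dialect <- match.arg(dialect)
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "adat_like") {
    writeLines(c("^ADATLike\tphenoproteo-minimal",
                 paste0("^TransformState\t", x$transform_state),
                 paste(c("^TargetNames", x$feature_meta$target_name), collapse = "\t")),
               con)
  }
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a phenogroup assignment
#'
#' Maps each sample to a phenogroup label in `1..k` and records provenance:
#' a fingerprint of the feature set used, the seed, and the method.
#'
#' @param labels named integer vector (names = sample IDs, values in 1..k).
#' @param k number of groups.
#' @param provenance list with elements such as `feature_hash`, `seed`, `method`.
#' @return object of class `phenogroup_assignment`.
#' @export
phenogroup_assignment <- function(labels, k = max(labels), provenance = list()) {
  if (is.null(names(labels))) stop("`labels` must be named by sample ID")
  labels <- stats::setNames(as.integer(labels), names(labels))
  if (any(labels < 1L) || any(labels > k)) stop("labels must lie in 1..k")
  structure(list(labels = labels, k = as.integer(k), provenance = provenance),
            class = "phenogroup_assignment")
}

#' @export
print.phenogroup_assignment <- function(x, ...) {
  tab <- table(factor(x$labels, levels = seq_len(x$k)))
  cat(sprintf("<phenogroup_assignment> %d samples, k = %d\n", length(x$labels), x$k))
  cat("  sizes:", paste(sprintf("g%d=%d", seq_len(x$k), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' Write a phenogroup assignment with provenance sidecar
#'
#' Writes a CSV (`sample_id`, `phenogroup`, 1-based labels) and a JSON sidecar
#' (`<path>.json`) carrying the feature-set hash, seed and parameters.
#'
#' @param assignment a [phenogroup_assignment].
#' @param path output CSV path.
#' @export
write_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "phenogroup_assignment"))
  if (!length(assignment$labels)) stop("assignment is empty")
  df <- data.frame(sample_id = names(assignment$labels),
                   phenogroup = as.integer(assignment$labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(assignment$provenance, list(k = assignment$k)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phenogroup assignment written by [write_assignment()]
#' @param path CSV path.
#' @return a [phenogroup_assignment].
#' @export
read_assignment <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "integer"))
  prov <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) prov <- jsonlite::read_json(side, simplifyVector = TRUE)
  k <- if (!is.null(prov$k)) prov$k else max(df$phenogroup)
  prov$k <- NULL
  phenogroup_assignment(stats::setNames(df$phenogroup, df$sample_id),
                        k = k, provenance = prov)
}

validate_clinical <- function(df) {
  need <- c("sample_id", "age", "sex", "egfr", "nt_probnp", "maggic",
            "ef_lt40", "afib", "hf_duration_ge18mo")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("clinical table has duplicate sample_id")
  if (any(df$egfr <= 0)) stop("clinical table: egfr must be > 0")
  if (any(df$nt_probnp <= 0)) stop("clinical table: nt_probnp must be > 0")
  for (b in c("sex", "ef_lt40", "afib", "hf_duration_ge18mo")) {
    if (!all(df[[b]] %in% c(0L, 1L))) stop("clinical table: ", b, " must be 0/1")
  }
  df
}

validate_survival <- function(df) {
  need <- c("sample_id", "time_years", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("survival table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("survival table has duplicate sample_id")
  if (any(df$time_years <= 0)) stop("survival table: time_years must be > 0")
  if (!all(df$event %in% c(0L, 1L))) stop("survival table: event must be 0/1")
  df
}

#' Read clinical / survival tables (CSV)
#'
#' Columns are validated, never coerced: the clinical table needs
#' `sample_id, age, sex, egfr, nt_probnp, maggic, ef_lt40, afib,
#' hf_duration_ge18mo`; the survival table needs
#' `sample_id, time_years, event`.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_clinical <- function(path) validate_clinical(utils::read.csv(path))

#' @rdname read_clinical
#' @export
read_survival <- function(path) validate_survival(utils::read.csv(path))

#' Align clinical / survival rows to a matrix's samples by sample_id
#'
#' @param x a [protein_matrix].
#' @param table clinical or survival data.frame with a `sample_id` column.
#' @return the table reordered to `sample_ids(x)`; errors on any mismatch.
#' @export
align_samples <- function(x, table) {
  idx <- match(sample_ids(x), table$sample_id)
  if (anyNA(idx)) {
    stop("table is missing sample ID(s): ",
         paste(utils::head(sample_ids(x)[is.na(idx)], 5), collapse = ", "))
  }
  out <- table[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a cohort configuration from YAML or JSON
#'
#' The file's entries are passed to [cohort_config()]; unknown keys error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(cohort_config, cfg)
}
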