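# Feature-space reduction: MAD ranking, then collapsing sets of mutually
# correlated features (connected components at |r| >= tau) to one hub each.

#' Select the highest-MAD features
#'
#' Retains the `ceiling(fraction * n_features)` features with the largest
#' median absolute deviation, `median(|x - median(x)|)` (unscaled), computed
#' on the log2 scale (a raw matrix is log2-transformed internally; a
#' standardized matrix is rejected because z-scoring flattens dispersion).
#' Ties are broken deterministically by lexicographic feature ID, and the
#' result is invariant to sample and feature order up to that tie-break.
#'
#' @param matrix a raw or log2 [protein_matrix].
#' @param fraction fraction of features to keep, in (0, 1].
#' @return list with `selected` (feature IDs, original matrix order) and
#'   `mad_values` (named, all features).
#' @export
mad_select <- function(matrix, fraction = 0.3) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (fraction <= 0 || fraction > 1) stop("`fraction` must lie in (0, 1]")
  if (matrix$transform_state == "standardized") {
    stop("MAD selection must run on the log2 (pre-z-score) scale")
  }
  vals <- if (matrix$transform_state == "raw") log2(matrix$values) else matrix$values
  mads <- apply(vals, 2, stats::mad, constant = 1)
  n_keep <- ceiling(fraction * ncol(vals))
  ord <- order(-mads, colnames(vals))
  keep <- sort(match(colnames(vals)[ord[seq_len(n_keep)]], colnames(vals)))
  list(selected = colnames(vals)[keep], mad_values = mads)
}

connected_components <- function(adj_list, nodes) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj_list[[v]]
      new <- nb[is.na(comp[nb])]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

#' Group correlated features into modules
#'
#' Builds the graph on the feature subset with an edge wherever
#' `|r| >= tau`, and returns its connected components as feature modules —
#' an order-independent reading of "sets of correlated features". Every
#' feature lands in exactly one module; features correlated with nothing are
#' singletons.
#'
#' @param matrix a log2 or standardized [protein_matrix] (correlations are
#'   invariant to the per-feature affine z-score; Spearman additionally to
#'   any monotone transform).
#' @param features character vector of feature IDs to consider.
#' @param tau absolute-correlation threshold in (0, 1).
#' @param method `"spearman"` (default; robust to residual skew) or
#'   `"pearson"`.
#' @return list of `feature_module` objects: `module_id`, `members`
#'   (feature IDs), `corr` (members' correlation submatrix), plus the
#'   threshold and method. Modules are numbered in order of their first
#'   member's position in `features`.
#' @export
build_modules <- function(matrix, features, tau = 0.7,
                          method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "protein_matrix"), length(features) >= 1)
  if (tau <= 0 || tau >= 1) stop("`tau` must lie in (0, 1)")
  miss <- setdiff(features, feature_ids(matrix))
  if (length(miss)) stop("unknown feature(s): ", paste(utils::head(miss, 5), collapse = ", "))
  sub <- matrix$values[, features, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance feature(s) make correlations undefined: ",
         paste(names(sds)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(sub, method = method)
  adj <- abs(r) >= tau
  diag(adj) <- FALSE
  adj_list <- lapply(stats::setNames(features, features),
                     function(f) features[adj[f, ]])
  comp <- connected_components(adj_list, features)
  lapply(seq_len(max(comp)), function(i) {
    members <- names(comp)[comp == i]
    structure(list(module_id = i, members = members,
                   corr = r[members, members, drop = FALSE],
                   tau = tau, method = method),
              class = "feature_module")
  })
}

#' Pick one hub (representative) feature per module
#'
#' `max_connectivity` (the deterministic primary rule) takes the member with
#' the largest sum of `|r|` to its co-members, breaking ties by larger MAD
#' and then lexicographic ID. `max_mad` takes the largest-MAD member.
#' `random` draws uniformly per module from a seeded stream — the basis of
#' the hub-randomization sensitivity analysis. Singleton modules always
#' yield their sole member.
#'
#' @param modules list of `feature_module`s (from [build_modules()]).
#' @param mad_values named numeric vector of MADs (from [mad_select()]).
#' @param rule `"max_connectivity"`, `"max_mad"` or `"random"`.
#' @param seed RNG seed, used only for `rule = "random"`.
#' @param params provenance list merged into the result's `parameters`.
#' @return a `reduction_result`: `selected` (hub feature IDs in module-ID
#'   order), `modules`, `hubs` (module_id -> hub), `mad_values`, `parameters`.
#' @export
select_hubs <- function(modules, mad_values,
                        rule = c("max_connectivity", "max_mad", "random"),
                        seed = 1L, params = list()) {
  rule <- match.arg(rule)
  if (rule == "random") set.seed(seed)
  hubs <- vapply(modules, function(m) {
    if (length(m$members) == 1) return(m$members)
    if (rule == "random") return(m$members[sample.int(length(m$members), 1)])
    if (rule == "max_mad") {
      ord <- order(-mad_values[m$members], m$members)
      return(m$members[ord[1]])
    }
    conn <- rowSums(abs(m$corr)) - 1  # drop self-correlation
    ord <- order(-conn, -mad_values[m$members], m$members)
    m$members[ord[1]]
  }, character(1))
  structure(list(selected = unname(hubs),
                 modules = modules,
                 hubs = stats::setNames(hubs, vapply(modules, function(m) as.character(m$module_id), character(1))),
                 mad_values = mad_values,
                 parameters = utils::modifyList(list(hub_rule = rule, seed = seed), params)),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  sizes <- lengths(lapply(x$modules, `[[`, "members"))
  cat(sprintf("<reduction_result> %d features selected from %d modules (%d of size >= 2; largest %d)\n",
              length(x$selected), length(x$modules), sum(sizes >= 2), max(sizes)))
  invisible(x)
}

#' Full dimension-reduction pass (MAD filter + module hubs), optionally iterated
#'
#' One round = MAD selection at `mad_fraction`, module construction at
#' threshold `tau`, hub selection. Rounds 2..`n_rounds` re-apply module
#' construction and hub selection to the surviving hub set; the process is at
#' a fixed point once no module has two or more members.
#'
#' @param matrix a raw or log2 [protein_matrix].
#' @param mad_fraction MAD fraction for round 1 (default 0.30).
#' @param tau,method see [build_modules()].
#' @param hub_rule,seed see [select_hubs()].
#' @param n_rounds number of reduction rounds (>= 1).
#' @return a `reduction_result` (modules are those of the final round).
#' @export
reduce_features <- function(matrix, mad_fraction = 0.3, tau = 0.7,
                            method = c("spearman", "pearson"),
                            hub_rule = c("max_connectivity", "max_mad", "random"),
                            seed = 1L, n_rounds = 1L) {
  method <- match.arg(method)
  hub_rule <- match.arg(hub_rule)
  if (n_rounds < 1) stop("n_rounds must be >= 1")
  logm <- if (matrix$transform_state == "raw") log_transform(matrix) else matrix
  sel <- mad_select(logm, mad_fraction)
  current <- sel$selected
  res <- NULL
  for (round in seq_len(n_rounds)) {
    modules <- build_modules(logm, current, tau = tau, method = method)
    res <- select_hubs(modules, sel$mad_values, rule = hub_rule,
                       seed = seed + round - 1L,
                       params = list(mad_fraction = mad_fraction, tau = tau,
                                     corr_method = method, n_rounds = n_rounds,
                                     round = round))
    if (identical(sort(res$selected), sort(current))) break  # fixed point
    current <- res$selected
    if (all(lengths(lapply(modules, `[[`, "members")) == 1)) break
  }
  res
}
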