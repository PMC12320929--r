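# Survival layer: Kaplan-Meier curves with log(-log) Greenwood intervals,
# reverse-KM follow-up, Cox proportional-hazards models with staged
# adjustment presets, and likelihood-ratio interaction tests. Estimation is
# delegated to the survival package (Efron ties).

as_surv_df <- function(records) {
  df <- validate_survival(as.data.frame(records))
  df
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with pointwise 95% confidence intervals from the
#' Greenwood variance on the log(-log) scale (bounds stay inside [0, 1]).
#' With no events the curve is identically 1 and the CI is flagged
#' undefined. `survival_at()` reads the right-continuous step function.
#'
#' @param records survival data.frame (`sample_id`, `time_years`, `event`).
#' @param group_label optional label carried on the curve.
#' @return a `km_curve`: data.frame `time`, `n_risk`, `n_event`, `surv`,
#'   `lower`, `upper` plus attributes `group_label`, `n`, `n_events`.
#' @export
km_estimate <- function(records, group_label = NULL) {
  df <- as_surv_df(records)
  fit <- survival::survfit(survival::Surv(time_years, event) ~ 1, data = df,
                           conf.type = "log-log")
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      lower = fit$lower, upper = fit$upper)
  structure(curve, class = c("km_curve", "data.frame"),
            group_label = group_label, n = nrow(df),
            n_events = sum(df$event),
            ci_defined = sum(df$event) > 0)
}

#' Read a KM step function at time t (right-continuous)
#' @param curve a `km_curve`.
#' @param t time (years); `S(t) = 1` for `t` before the first event time.
#' @return list with `surv`, `lower`, `upper` at `t`.
#' @export
survival_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  pick <- function(col) ifelse(idx == 0, 1, col[pmax(idx, 1)])
  list(surv = unname(pick(curve$surv)),
       lower = unname(ifelse(idx == 0, NA_real_, curve$lower[pmax(idx, 1)])),
       upper = unname(ifelse(idx == 0, NA_real_, curve$upper[pmax(idx, 1)])))
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Inverts the event indicator (censoring becomes the event, deaths are
#' censored) and reads the median of the resulting follow-up distribution:
#' the first time the reverse-KM curve drops to 0.5 or below, with its 95%
#' CI. If the curve never reaches 0.5 the median is reported unreached with
#' the largest observed time as a lower bound.
#'
#' @param records survival data.frame.
#' @return list with `median`, `ci` (length 2), `reached` (logical),
#'   `lower_bound` (max observed time, when unreached).
#' @export
reverse_km_followup <- function(records) {
  df <- as_surv_df(records)
  df$rev_event <- 1L - df$event
  fit <- survival::survfit(survival::Surv(time_years, rev_event) ~ 1, data = df,
                           conf.type = "log-log")
  first_at_or_below <- function(s) {
    hit <- which(!is.na(s) & s <= 0.5)
    if (!length(hit)) NA_real_ else fit$time[hit[1]]
  }
  med <- first_at_or_below(fit$surv)   # first time S_reverse drops to <= 0.5
  if (is.na(med)) {
    return(list(median = NA_real_, ci = c(NA_real_, NA_real_),
                reached = FALSE, lower_bound = max(df$time_years)))
  }
  # Brookmeyer-Crowley style interval: times where the pointwise band
  # straddles 0.5 (lower band crosses first, upper band last)
  list(median = med,
       ci = c(first_at_or_below(fit$lower), first_at_or_below(fit$upper)),
       reached = TRUE, lower_bound = NA_real_)
}

cox_preset_terms <- function(preset) {
  switch(preset,
         M1 = c("age", "sex", "egfr"),
         M2 = c("age", "sex", "egfr", "log_nt_probnp", "maggic"),
         M3 = c("age", "sex", "egfr", "log_nt_probnp", "maggic", "ef_lt40"),
         M2_afib = c("age", "sex", "egfr", "log_nt_probnp", "maggic", "afib"),
         M2_hfdur = c("age", "sex", "egfr", "log_nt_probnp", "maggic",
                      "hf_duration_ge18mo"),
         stop("unknown model preset: ", preset))
}

build_cox_data <- function(records, assignment, clinical = NULL) {
  df <- as_surv_df(records)
  labels <- assignment$labels[df$sample_id]
  if (anyNA(labels)) stop("assignment does not cover all survival records")
  df$phenogroup <- factor(labels, levels = seq_len(assignment$k))
  if (!is.null(clinical)) {
    cl <- validate_clinical(clinical)
    idx <- match(df$sample_id, cl$sample_id)
    if (anyNA(idx)) stop("clinical table does not cover all survival records")
    cl <- cl[idx, , drop = FALSE]
    cl$log_nt_probnp <- log(cl$nt_probnp)  # standard given its skew
    df <- cbind(df, cl[, setdiff(names(cl), "sample_id"), drop = FALSE])
  }
  df
}

#' Cox proportional-hazards model of phenogroup and mortality
#'
#' Partial-likelihood fit (Efron tie handling) with phenogroup as a
#' categorical covariate, reference = phenogroup 1, plus staged adjustment
#' presets: `M1` = age + sex + eGFR; `M2` = M1 + log(NT-proBNP) + MAGGIC;
#' `M3` = M2 + EF category; `M2_afib` / `M2_hfdur` add atrial fibrillation
#' or the HF-duration flag to M2. `preset = "unadjusted"` fits phenogroup
#' alone; `covariates` overrides the preset with explicit column names.
#'
#' @param records survival data.frame.
#' @param assignment a [phenogroup_assignment].
#' @param clinical clinical data.frame (required for adjusted presets).
#' @param preset one of `"unadjusted"`, `"M1"`, `"M2"`, `"M3"`,
#'   `"M2_afib"`, `"M2_hfdur"`.
#' @param covariates optional explicit covariate column names.
#' @return a `cox_fit`: `coefficients`, `hr` (data.frame term / hr / lower /
#'   upper / p), `loglik`, `n`, `n_events`, `ties_method`, `formula`, and
#'   the underlying `survival::coxph` fit (`object`).
#' @export
cox_fit <- function(records, assignment, clinical = NULL,
                    preset = "unadjusted", covariates = NULL) {
  df <- build_cox_data(records, assignment, clinical)
  if (sum(df$event) < 10) stop("need >= 10 events to fit a Cox model")
  terms <- if (!is.null(covariates)) covariates
           else if (identical(preset, "unadjusted")) character(0)
           else cox_preset_terms(preset)
  miss <- setdiff(terms, names(df))
  if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  const <- terms[vapply(terms, function(v) stats::sd(as.numeric(df[[v]])) == 0, logical(1))]
  if (length(const)) stop("constant covariate(s): ", paste(const, collapse = ", "))
  rhs <- paste(c("phenogroup", terms), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time_years, event) ~", rhs))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (any(!is.finite(stats::coef(fit)))) stop("Cox fit did not converge")
  if (any(abs(stats::coef(fit)) > 15)) {
    warning("coefficient(s) very large; possible separation: ",
            paste(names(stats::coef(fit))[abs(stats::coef(fit)) > 15], collapse = ", "))
  }
  s <- summary(fit)
  hr <- data.frame(term = rownames(s$coefficients),
                   coef = s$coefficients[, "coef"],
                   hr = s$conf.int[, "exp(coef)"],
                   lower = s$conf.int[, "lower .95"],
                   upper = s$conf.int[, "upper .95"],
                   p = s$coefficients[, "Pr(>|z|)"],
                   row.names = NULL)
  structure(list(coefficients = stats::coef(fit), hr = hr,
                 loglik = fit$loglik[2], n = s$n, n_events = s$nevent,
                 ties_method = "efron", formula = deparse(fml),
                 object = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d (Efron ties)\n", x$n, x$n_events))
  df <- x$hr
  df$hr <- sprintf("%.2f (%.2f-%.2f)", df$hr, df$lower, df$upper)
  print(df[, c("term", "hr", "p")], row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test of a phenogroup-by-factor interaction
#'
#' Compares nested Cox models with and without `phenogroup:factor` product
#' terms; the LRT statistic is chi-squared with `(k - 1) * (levels - 1)`
#' degrees of freedom. Per-term Wald p-values are reported alongside.
#'
#' @param records survival data.frame.
#' @param assignment a [phenogroup_assignment].
#' @param clinical clinical data.frame.
#' @param factor_name name of the (binary or categorical) clinical column to
#'   interact with phenogroup.
#' @param preset adjustment preset for the base model (see [cox_fit()]).
#' @return list with `chisq`, `df`, `p`, `wald` (per-product-term
#'   data.frame), `base`, `full` (the two `coxph` fits).
#' @export
interaction_test <- function(records, assignment, clinical, factor_name,
                             preset = "M2") {
  df <- build_cox_data(records, assignment, clinical)
  if (!factor_name %in% names(df)) stop("unknown factor: ", factor_name)
  fac <- df[[factor_name]]
  n_levels <- length(unique(fac))
  if (n_levels < 2) stop("interaction factor has a single level")
  df[[factor_name]] <- if (n_levels == 2) as.numeric(fac) else factor(fac)
  terms <- if (identical(preset, "unadjusted")) character(0) else cox_preset_terms(preset)
  terms <- union(terms, factor_name)
  base_fml <- stats::as.formula(paste("survival::Surv(time_years, event) ~",
                                      paste(c("phenogroup", terms), collapse = " + ")))
  full_fml <- stats::as.formula(paste("survival::Surv(time_years, event) ~",
                                      paste(c("phenogroup", terms,
                                              paste0("phenogroup:", factor_name)),
                                            collapse = " + ")))
  base <- survival::coxph(base_fml, data = df, ties = "efron")
  full <- survival::coxph(full_fml, data = df, ties = "efron")
  if (any(!is.finite(stats::coef(base))) || any(!is.finite(stats::coef(full)))) {
    stop("nested models did not both converge")
  }
  chisq <- 2 * (full$loglik[2] - base$loglik[2])
  dfree <- length(stats::coef(full)) - length(stats::coef(base))
  s <- summary(full)$coefficients
  wald_rows <- grep(":", rownames(s))
  list(chisq = chisq, df = dfree,
       p = stats::pchisq(chisq, dfree, lower.tail = FALSE),
       wald = data.frame(term = rownames(s)[wald_rows],
                         p = s[wald_rows, "Pr(>|z|)"], row.names = NULL),
       base = base, full = full)
}

#' Kaplan-Meier curves per phenogroup-by-stratum cell
#'
#' One KM curve per (phenogroup, stratum level) cell with the 5-year
#' survival probability and CI; empty cells are omitted with a warning.
#'
#' @param records survival data.frame.
#' @param assignment a [phenogroup_assignment].
#' @param stratum named vector (by sample_id) or single-level constant;
#'   typically a binary clinical column such as EF < 40%.
#' @param at time (years) at which to tabulate survival (default 5).
#' @return list with `curves` (named list of `km_curve`s, names
#'   `"g<group>|<stratum>"`) and `summary` (data.frame: phenogroup, stratum,
#'   n, n_events, surv_at, lower, upper).
#' @export
survival_by_strata <- function(records, assignment, stratum, at = 5) {
  df <- as_surv_df(records)
  labels <- assignment$labels[df$sample_id]
  if (anyNA(labels)) stop("assignment does not cover all survival records")
  sv <- if (length(stratum) == 1) rep(stratum, nrow(df)) else stratum[df$sample_id]
  if (anyNA(sv)) stop("stratum does not cover all survival records")
  cells <- split(seq_len(nrow(df)), list(g = labels, s = sv), drop = FALSE, sep = "|")
  curves <- list(); rows <- list()
  for (nm in names(cells)) {
    idx <- cells[[nm]]
    if (!length(idx)) { warning("empty cell omitted: ", nm); next }
    cv <- km_estimate(df[idx, c("sample_id", "time_years", "event")], group_label = nm)
    curves[[paste0("g", nm)]] <- cv
    s_at <- survival_at(cv, at)
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    rows[[nm]] <- data.frame(phenogroup = as.integer(parts[1]), stratum = parts[2],
                             n = attr(cv, "n"), n_events = attr(cv, "n_events"),
                             surv_at = s_at$surv, lower = s_at$lower,
                             upper = s_at$upper)
  }
  list(curves = curves, summary = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
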