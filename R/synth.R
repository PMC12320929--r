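#' Configuration for a synthetic proteomics cohort
#'
#' Defines the generating conditions the pipeline is tested against: a
#' population-scale heart-failure cohort profiled on an aptamer platform.
#' Defaults emulate the target study design: 1351 patients, 7151 reagents,
#' three latent phenogroups at proportions 0.45 / 0.245 / 0.305, ~9%
#' technical coefficient of variation, block-correlated feature modules, and
#' phenogroup-graded all-cause mortality followed for ~14 years.
#'
#' @param n_samples,n_features cohort dimensions.
#' @param n_groups number of latent phenogroups (`k_true`).
#' @param group_proportions simplex vector of length `n_groups`.
#' @param n_modules number of correlated feature modules.
#' @param module_size_range integer interval `c(min,max)` of module sizes.
#' @param within_module_corr target pairwise correlation of log-abundances
#'   within a module, in `[0, 1)` (induced by one shared latent factor per
#'   module, i.e. equicorrelation).
#' @param n_informative_modules modules whose members carry group mean shifts.
#' @param effect_size group shift on informative-module members, in
#'   within-group SD units on the log2 scale.
#' @param technical_cv coefficient of variation of multiplicative
#'   (lognormal) assay noise, as a fraction (default 0.088, i.e. 8.8%).
#' @param n_qc_fail_samples samples to corrupt so downstream QC flags them.
#' @param hazard_scale_per_group per-group baseline hazard rates (1/years),
#'   strictly positive, length `n_groups`. Defaults (0.10, 0.15, 0.22)/yr give
#'   a ~50% 5-year event rate with hazard ratios 1 : 1.5 : 2.2.
#' @param weibull_shape survival-time shape; 1 (default) is exponential,
#'   otherwise Weibull with `S(t) = exp(-lambda * t^shape)`.
#' @param censoring_rate rate (1/years) of independent exponential censoring;
#'   0 disables random censoring (administrative only).
#' @param followup_horizon administrative censoring time (years).
#' @param covariate_spec list of per-covariate parameters; see Details. Pass
#'   partial lists to override individual entries.
#' @param seed integer RNG seed; fixed seed gives a bit-identical cohort.
#'
#' @details `covariate_spec` entries (each a list): `age` (`mean`, `sd`,
#'   `group_shift`), `sex` (`p`), `egfr` (`mean`, `sd`, `group_shift`, floored
#'   at 5), `log_nt_probnp` (`mean`, `sd`, `group_shift`; stored as pg/mL on
#'   the natural scale), `maggic` (`mean`, `sd`, `group_shift`, rounded and
#'   clipped to 1..50), `ef_lt40` (`p`), `afib` (`p_per_group`),
#'   `hf_duration_ge18mo` (`p`). Default group shifts follow the qualitative
#'   ordering observed across phenogroups in population HF cohorts: the
#'   worst-survival group is older, with lower eGFR and higher NT-proBNP,
#'   MAGGIC and atrial-fibrillation prevalence.
#' @return a validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 1351,
                          n_features = 7151,
                          n_groups = 3,
                          group_proportions = c(0.45, 0.245, 0.305),
                          n_modules = 60,
                          module_size_range = c(3, 12),
                          within_module_corr = 0.8,
                          n_informative_modules = 10,
                          effect_size = 2.0,
                          technical_cv = 0.088,
                          n_qc_fail_samples = 0,
                          hazard_scale_per_group = c(0.10, 0.15, 0.22),
                          weibull_shape = 1,
                          censoring_rate = 0.02,
                          followup_horizon = 14,
                          covariate_spec = list(),
                          seed = 1L) {
  default_cov <- list(
    age = list(mean = 76, sd = 10, group_shift = c(0, 1, 5)),
    sex = list(p = 0.48),
    egfr = list(mean = 60, sd = 18, group_shift = c(0, -5, -15)),
    log_nt_probnp = list(mean = log(1500), sd = 1.0, group_shift = c(0, 0.4, 0.9)),
    maggic = list(mean = 22, sd = 6, group_shift = c(0, 2, 5)),
    ef_lt40 = list(p = 0.31),
    afib = list(p_per_group = c(0.32, 0.30, 0.46)),
    hf_duration_ge18mo = list(p = 0.5)
  )
  cov <- utils::modifyList(default_cov, covariate_spec)
  cfg <- structure(list(
    n_samples = as.integer(n_samples), n_features = as.integer(n_features),
    n_groups = as.integer(n_groups), group_proportions = group_proportions,
    n_modules = as.integer(n_modules),
    module_size_range = as.integer(module_size_range),
    within_module_corr = within_module_corr,
    n_informative_modules = as.integer(n_informative_modules),
    effect_size = effect_size, technical_cv = technical_cv,
    n_qc_fail_samples = as.integer(n_qc_fail_samples),
    hazard_scale_per_group = hazard_scale_per_group,
    weibull_shape = weibull_shape, censoring_rate = censoring_rate,
    followup_horizon = followup_horizon, covariate_spec = cov,
    seed = as.integer(seed)), class = "cohort_config")
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 1 || n_features < 1) stop("configuration error: empty cohort dimensions")
    if (length(group_proportions) != n_groups) {
      stop("configuration error: group_proportions must have length n_groups")
    }
    if (abs(sum(group_proportions) - 1) > 1e-9 || any(group_proportions <= 0)) {
      stop("configuration error: group_proportions must be positive and sum to 1")
    }
    if (within_module_corr < 0 || within_module_corr >= 1) {
      stop("configuration error: within_module_corr must lie in [0, 1)")
    }
    if (length(module_size_range) != 2 || module_size_range[1] > module_size_range[2] ||
        module_size_range[1] < 1) {
      stop("configuration error: bad module_size_range")
    }
    if (n_modules * module_size_range[1] > n_features) {
      stop("configuration error: infeasible module packing (sum of module sizes exceeds n_features)")
    }
    if (n_informative_modules > n_modules) {
      stop("configuration error: n_informative_modules exceeds n_modules")
    }
    if (length(hazard_scale_per_group) != n_groups || any(hazard_scale_per_group <= 0)) {
      stop("configuration error: hazard_scale_per_group must be positive, length n_groups")
    }
    if (technical_cv < 0) stop("configuration error: technical_cv must be >= 0")
    if (censoring_rate < 0) stop("configuration error: censoring_rate must be >= 0")
    if (n_qc_fail_samples >= n_samples) stop("configuration error: n_qc_fail_samples >= n_samples")
  })
  cfg
}

draw_module_sizes <- function(cfg) {
  lo <- cfg$module_size_range[1]; hi <- cfg$module_size_range[2]
  sizes <- if (lo == hi) rep(lo, cfg$n_modules) else
    sample(lo:hi, cfg$n_modules, replace = TRUE)
  if (sum(sizes) > cfg$n_features) {
    stop("configuration error: infeasible module packing (drawn module sizes sum to ",
         sum(sizes), " > n_features = ", cfg$n_features, ")")
  }
  sizes
}

rlognorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean exactly 1
}

#' Generate a synthetic proteomics cohort with known ground truth
#'
#' Log2 abundances are Gaussian with one shared latent factor per correlated
#' module (equicorrelation `within_module_corr`) and unit within-group SD.
#' Each informative module is assigned one elevated phenogroup (cycled over
#' groups) and every member receives the centred shift
#' `effect_size * (1[g = g_m] - 1/k)`, so group mean differences on the log2
#' scale equal `effect_size` SD units. Values are exponentiated and
#' multiplied by lognormal technical noise of the configured CV, yielding
#' strictly positive RFU-like abundances. Survival times are per-group
#' exponential (or Weibull) with independent exponential censoring truncated
#' at the follow-up horizon; clinical covariates are drawn with configurable
#' group coupling. Fixed seed gives a bit-identical cohort.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: list with `matrix`
#'   (a [protein_matrix], raw scale), `clinical`, `survival` (data.frames
#'   sharing the matrix's sample IDs in order), `true_labels` (named integer)
#'   and `truth_manifest` (module memberships, informative hubs, group-shift
#'   matrix, generating config, QC-failure IDs).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_samples; p <- cfg$n_features; k <- cfg$n_groups
  sid <- sprintf("S%05d", seq_len(n))
  fid <- sprintf("F%05d", seq_len(p))

  # latent group labels: multinomial at the configured proportions, but every
  # group is guaranteed >= 1 member by seeding one sample per group
  g <- c(seq_len(k), sample.int(k, n - k, replace = TRUE, prob = cfg$group_proportions))
  g <- sample(g, n)  # shuffle so seeded members are not the first rows

  sizes <- draw_module_sizes(cfg)
  member_pool <- sample(fid, sum(sizes))
  modules <- split(member_pool, rep(seq_len(cfg$n_modules), sizes))
  names(modules) <- sprintf("M%03d", seq_len(cfg$n_modules))
  informative <- if (cfg$n_informative_modules > 0) {
    sort(sample(cfg$n_modules, cfg$n_informative_modules))
  } else integer(0)

  rho <- cfg$within_module_corr
  mu <- stats::runif(p, 8, 14)                       # baseline log2 RFU level
  x <- matrix(stats::rnorm(n * p), n, p, dimnames = list(sid, fid))
  shift_mat <- matrix(0, cfg$n_modules, k,
                      dimnames = list(names(modules), paste0("g", seq_len(k))))
  for (m in seq_along(modules)) {
    cols <- match(modules[[m]], fid)
    latent <- stats::rnorm(n)
    x[, cols] <- sqrt(rho) * latent + sqrt(1 - rho) * x[, cols]
    if (m %in% informative) {
      gm <- ((match(m, informative) - 1L) %% k) + 1L   # elevated group, cycled
      shifts <- cfg$effect_size * ((seq_len(k) == gm) - 1 / k)
      shift_mat[m, ] <- shifts
      x[, cols] <- x[, cols] + shifts[g]
    }
  }
  x <- sweep(x, 2, mu, "+")
  raw <- 2^x * matrix(rlognorm_cv(n * p, cfg$technical_cv), n, p)
  dimnames(raw) <- list(sid, fid)

  hubs <- vapply(modules, `[`, character(1), 1L)  # designated hub = first member

  clinical <- draw_clinical(cfg, g, sid)
  surv <- draw_survival(cfg, g, sid)

  mat <- protein_matrix(raw,
                        feature_meta = data.frame(feature_id = fid,
                                                  target_name = paste0("target_", fid),
                                                  stringsAsFactors = FALSE))
  cohort <- structure(list(
    matrix = mat, clinical = clinical, survival = surv,
    true_labels = stats::setNames(as.integer(g), sid),
    truth_manifest = list(modules = modules, hubs = hubs,
                          informative_modules = names(modules)[informative],
                          group_shifts = shift_mat,
                          config = cfg, qc_fail_ids = character(0))),
    class = "synthetic_cohort")
  if (cfg$n_qc_fail_samples > 0) {
    cohort <- inject_qc_failures(cohort, cfg$n_qc_fail_samples,
                                 seed = cfg$seed + 1L)
  }
  cohort
}

draw_clinical <- function(cfg, g, sid) {
  cs <- cfg$covariate_spec
  n <- length(g)
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  age <- cs$age$mean + cs$age$group_shift[g] + stats::rnorm(n, 0, cs$age$sd)
  egfr <- pmax(cs$egfr$mean + cs$egfr$group_shift[g] + stats::rnorm(n, 0, cs$egfr$sd), 5)
  lnt <- cs$log_nt_probnp$mean + cs$log_nt_probnp$group_shift[g] +
    stats::rnorm(n, 0, cs$log_nt_probnp$sd)
  maggic <- clip(round(cs$maggic$mean + cs$maggic$group_shift[g] +
                         stats::rnorm(n, 0, cs$maggic$sd)), 1, 50)
  data.frame(sample_id = sid,
             age = round(age, 1),
             sex = stats::rbinom(n, 1, cs$sex$p),
             egfr = round(egfr, 1),
             nt_probnp = round(exp(lnt), 1),
             maggic = as.integer(maggic),
             ef_lt40 = stats::rbinom(n, 1, cs$ef_lt40$p),
             afib = stats::rbinom(n, 1, cs$afib$p_per_group[g]),
             hf_duration_ge18mo = stats::rbinom(n, 1, cs$hf_duration_ge18mo$p),
             stringsAsFactors = FALSE)
}

draw_survival <- function(cfg, g, sid) {
  n <- length(g)
  lam <- cfg$hazard_scale_per_group[g]
  a <- cfg$weibull_shape
  u <- stats::runif(n)
  t_event <- (-log(u) / lam)^(1 / a)       # S(t) = exp(-lambda t^a)
  cens <- if (cfg$censoring_rate > 0) {
    pmin(stats::rexp(n, cfg$censoring_rate), cfg$followup_horizon)
  } else rep(cfg$followup_horizon, n)
  time <- pmin(t_event, cens)
  time <- pmax(time, 1e-6)                  # times strictly positive
  data.frame(sample_id = sid,
             time_years = time,
             event = as.integer(t_event <= cens),
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$truth_manifest$config
  cat(sprintf("<synthetic_cohort> %d samples x %d features, %d latent groups\n",
              cfg$n_samples, cfg$n_features, cfg$n_groups))
  cat("  group sizes:", paste(as.integer(table(x$true_labels)), collapse = "/"), "\n")
  if (length(x$truth_manifest$qc_fail_ids)) {
    cat("  injected QC failures:", length(x$truth_manifest$qc_fail_ids), "\n")
  }
  invisible(x)
}

#' Corrupt samples so that downstream QC flags them
#'
#' Randomly chosen samples have all abundances multiplied by an extreme
#' scale factor, mimicking a hybridisation/plate failure that per-sample
#' total-signal QC detects. The corrupted IDs are recorded in the truth
#' manifest (and in the matrix's sample flags as ground-truth provenance;
#' the QC stage must rediscover them from the data alone).
#'
#' @param cohort a `synthetic_cohort`.
#' @param n_fail number of samples to corrupt; must be `< n_samples`.
#' @param seed RNG seed.
#' @param scale_factor multiplicative corruption (default 8).
#' @return the modified `synthetic_cohort`.
#' @export
inject_qc_failures <- function(cohort, n_fail, seed = 1L, scale_factor = 8) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n <- nrow(cohort$matrix$values)
  if (n_fail >= n) stop("n_fail must be smaller than the number of samples")
  if (n_fail == 0) return(cohort)
  set.seed(seed)
  ids <- sample(sample_ids(cohort$matrix), n_fail)
  vals <- cohort$matrix$values
  vals[ids, ] <- vals[ids, , drop = FALSE] * scale_factor
  cohort$matrix$values <- vals
  hit <- cohort$matrix$sample_flags$sample_id %in% ids
  cohort$matrix$sample_flags$flagged[hit] <- TRUE
  cohort$matrix$sample_flags$reason[hit] <- "injected_qc_failure"
  cohort$truth_manifest$qc_fail_ids <- sort(ids)
  cohort
}

#' Simulate replicate re-measurements of cohort samples
#'
#' Re-measures chosen samples `n_reps` times with independent lognormal
#' technical noise at the cohort's configured CV, producing the replicate
#' structure that intraassay-CV QC expects.
#'
#' @param cohort a `synthetic_cohort`.
#' @param sample_ids IDs to replicate (default: first 20 samples).
#' @param n_reps replicates per sample (>= 2).
#' @param seed RNG seed.
#' @return list with `matrix` (a raw-scale [protein_matrix] of all replicate
#'   rows) and `replicate_of` (named character: replicate row -> source ID).
#' @export
generate_replicates <- function(cohort, sample_ids = NULL, n_reps = 3, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"), n_reps >= 2)
  if (is.null(sample_ids)) {
    sample_ids <- utils::head(rownames(cohort$matrix$values), 20)
  }
  set.seed(seed)
  cv <- cohort$truth_manifest$config$technical_cv
  base <- cohort$matrix$values[sample_ids, , drop = FALSE]
  p <- ncol(base)
  rows <- lapply(seq_len(n_reps), function(r) {
    base * matrix(rlognorm_cv(length(sample_ids) * p, cv), nrow(base), p)
  })
  vals <- do.call(rbind, rows)
  rep_of <- rep(sample_ids, times = n_reps)
  rownames(vals) <- sprintf("%s_rep%d", rep_of, rep(seq_len(n_reps), each = length(sample_ids)))
  list(matrix = protein_matrix(vals, feature_meta = cohort$matrix$feature_meta),
       replicate_of = stats::setNames(rep_of, rownames(vals)))
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes the abundance matrix (wide TSV), clinical CSV, survival CSV and a
#' truth-manifest JSON into `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix(cohort$matrix, file.path(dir, "abundance.tsv"))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(cohort$survival, file.path(dir, "survival.csv"), row.names = FALSE)
  tm <- cohort$truth_manifest
  jsonlite::write_json(list(modules = tm$modules, hubs = as.list(tm$hubs),
                            informative_modules = tm$informative_modules,
                            qc_fail_ids = tm$qc_fail_ids,
                            true_labels = as.list(cohort$true_labels),
                            config = unclass(tm$config)),
                       file.path(dir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
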