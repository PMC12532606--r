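#' @useDynLib msevo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rpois pnorm dnorm sd var cov kmeans
#'   quantile median complete.cases setNames aggregate optim lm predict glm
#'   binomial coef plogis qnorm rexp mahalanobis cor
#' @importFrom utils read.csv write.csv head modifyList
NULL

# Canonical feature set, in column order, and the composite dimensions.
MS_FEATURES <- c("edss", "t25fwt", "nhpt", "pasat",
                 "t2_volume", "nbv", "gd_count", "relapse")
MS_DIMENSIONS <- c("disability", "brain_damage", "relapse", "asymptomatic_activity")
META_LEVELS <- c("EME", "asymptomatic_activity", "relapse", "advanced")

#' Default synthetic-cohort generator configuration
#'
#' Returns the calibrated configuration of the synthetic multiple sclerosis
#' cohort generator. The generator mirrors the generative assumptions of the
#' factor-analytic hidden Markov model: per patient, a hidden 8-state Markov
#' chain on a monthly visit grid; per visit, a 4-dimensional composite score
#' drawn from the state's Gaussian emission; observed features obtained by
#' pushing a sparse loading matrix plus feature noise through per-feature
#' observation links (log-normal times/volumes, half-point-rounded EDSS,
#' rounded/clamped PASAT, Poisson lesion counts, Bernoulli-probit relapse
#' flag).
#'
#' The eight states are grouped 3+1+1+3 into the clinical meta-states
#' EME (early/mild/evolving), asymptomatic radiological activity, relapse and
#' advanced MS. The default monthly transition matrix is constructed so that
#' its meta-state aggregates equal the published reference values: relapse
#' persistence 37%, relapse to advanced 18%, asymptomatic activity to advanced
#' 11%, asymptomatic activity to relapse 6%, EME persistence 94.5% (> 90%),
#' and no direct EME to advanced transitions. Every row within a meta-group
#' shares the same aggregate profile, so occupancy weighting does not alter
#' the aggregated matrix.
#'
#' Default per-feature missing rates are the published ones (T25FWT 32.3%,
#' 9HPT 43.6%, PASAT 53.9%, T2 volume 72.5%, brain volume 69.9%, Gd count
#' 73.1%); EDSS and relapse are always complete.
#'
#' @param n_patients number of patients to simulate.
#' @param n_months number of monthly grid visits per patient (months
#'   `0 .. n_months - 1`).
#' @param treatment_multiplier multiplicative effect of treatment on the
#'   off-diagonal transition probabilities into the activity and relapse
#'   states (1 = no effect; 0.5 halves them).
#' @param treated_fraction fraction of patients simulated under the treated
#'   transition matrix.
#' @param seed default random seed used when `generate_cohort()` is called
#'   without one.
#' @return an object of class `msevo_config`; a list whose components follow
#'   the generator contract (`loading`, `uniquenesses`, `state_means`,
#'   `state_covs`, `transition`, `initial`, `missing_rates`, `feature_links`,
#'   `feature_location`, `feature_scale`, `state_meta`, ...).
#' @export
default_config <- function(n_patients = 500L, n_months = 24L,
                           treatment_multiplier = 1, treated_fraction = 0,
                           seed = 20260925L) {
  features <- MS_FEATURES
  dims <- MS_DIMENSIONS

  loading <- matrix(0, 8, 4, dimnames = list(features, dims))
  loading["edss",      "disability"] <- 0.90
  loading["t25fwt",    "disability"] <- 0.80
  loading["nhpt",      "disability"] <- 0.80
  loading["pasat",     "brain_damage"] <- -0.60
  loading["t2_volume", "brain_damage"] <- 0.85
  loading["nbv",       "brain_damage"] <- -0.80
  loading["gd_count",  "asymptomatic_activity"] <- 0.90
  loading["t2_volume", "asymptomatic_activity"] <- 0.25
  loading["relapse",   "relapse"] <- 1.00
  loading["edss",      "relapse"] <- 0.20
  loading["t25fwt",    "relapse"] <- 0.15

  uniquenesses <- c(edss = 0.12, t25fwt = 0.30, nhpt = 0.30, pasat = 0.45,
                    t2_volume = 0.20, nbv = 0.30, gd_count = 0.25,
                    relapse = 0.10)

  # Severity gradient with deliberately non-collinear disability/brain-damage
  # profiles (state 2 lesion-heavy, state 3 disability-heavy, likewise 6/7),
  # one asymptomatic-activity state (4) and one relapse state (5).
  state_means <- matrix(c(
    # disability, brain_damage, relapse, asymptomatic_activity
    -1.6, -1.4, -3.5, -2.0,   # 1 EME mild
    -1.1,  0.2, -3.5, -2.0,   # 2 EME lesion-heavy
     0.2, -1.0, -3.5, -2.0,   # 3 EME older/disability-heavy
     0.0,  0.3, -3.5,  3.0,   # 4 asymptomatic activity
     0.3,  0.2,  3.0,  0.5,   # 5 relapse
     1.2,  1.8, -3.5, -2.5,   # 6 advanced lesion-heavy
     2.4,  0.4, -3.5, -2.5,   # 7 advanced disability-heavy
     3.2,  2.2, -3.5, -2.5    # 8 advanced severe
  ), nrow = 8, byrow = TRUE, dimnames = list(NULL, dims))

  state_covs <- lapply(1:8, function(s)
    diag(c(0.45, 0.45, 0.35, 0.35)^2, 4))

  transition <- matrix(c(
    .870, .075, .000, .025, .030, .000, .000, .000,
    .050, .845, .050, .025, .030, .000, .000, .000,
    .000, .075, .870, .025, .030, .000, .000, .000,
    .100, .165, .165, .400, .060, .080, .020, .010,
    .050, .150, .150, .100, .370, .130, .040, .010,
    .000, .000, .000, .004, .006, .870, .100, .020,
    .000, .000, .000, .004, .006, .020, .890, .080,
    .000, .000, .000, .004, .006, .000, .020, .970
  ), nrow = 8, byrow = TRUE)

  # trial-entry state mix: eligibility criteria over-represent recent
  # inflammatory activity relative to the chain's long-run occupancy
  initial <- c(.22, .20, .14, .12, .10, .10, .07, .05)

  missing_rates <- c(edss = 0, t25fwt = 0.323, nhpt = 0.436, pasat = 0.539,
                     t2_volume = 0.725, nbv = 0.699, gd_count = 0.731,
                     relapse = 0)

  feature_links <- c(edss = "continuous-identity", t25fwt = "continuous-log",
                     nhpt = "continuous-log", pasat = "continuous-identity",
                     t2_volume = "continuous-log", nbv = "continuous-identity",
                     gd_count = "count", relapse = "binary")

  # location/scale of each feature on its link scale (log scale for the
  # log-normal features, linear predictor scale for counts/binary); calibrated
  # to the published per-state summary tables.
  feature_location <- c(edss = 3.6, t25fwt = 1.75, nhpt = 3.10, pasat = 46,
                        t2_volume = 1.45, nbv = 1.50, gd_count = -2.2,
                        relapse = 0)
  feature_scale <- c(edss = 1.1, t25fwt = 0.40, nhpt = 0.25, pasat = 7,
                     t2_volume = 0.75, nbv = 0.05, gd_count = 1.4,
                     relapse = 1)
  feature_round <- c(edss = 0.5, pasat = 1)   # grid rounding on output scale
  feature_range <- list(edss = c(0, 10), pasat = c(0, 60))

  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    n_months = as.integer(n_months),
    features = features,
    dimensions = dims,
    loading = loading,
    uniquenesses = uniquenesses,
    state_means = state_means,
    state_covs = state_covs,
    transition = transition,
    initial = initial,
    missing_rates = missing_rates,
    baseline_complete = TRUE,         # trial baselines measure all features
    relapse_duration_mean = 47,       # days; consistent with 37% persistence
    treatment_multiplier = treatment_multiplier,
    treated_fraction = treated_fraction,
    feature_links = feature_links,
    feature_location = feature_location,
    feature_scale = feature_scale,
    feature_round = feature_round,
    feature_range = feature_range,
    state_meta = c("EME", "EME", "EME", "asymptomatic_activity", "relapse",
                   "advanced", "advanced", "advanced"),
    seed = as.integer(seed)
  ), class = "msevo_config")
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the structural invariants of a generator configuration: transition
#' rows and the initial distribution sum to one, covariances are symmetric
#' positive definite, missing rates lie in `[0, 1]`, and all numeric entries
#' are finite.
#'
#' @param config an `msevo_config` object.
#' @return `config`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "msevo_config"))
  num <- c(config$loading, config$uniquenesses, unlist(config$state_covs),
           config$state_means, config$transition, config$initial,
           config$missing_rates, config$treatment_multiplier)
  if (!all(is.finite(num)))
    stop("invalid config: non-finite numeric entries")
  A <- config$transition
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-12))
    stop("invalid config: transition rows must be nonnegative and sum to 1")
  if (any(config$initial < 0) || abs(sum(config$initial) - 1) > 1e-12)
    stop("invalid config: initial distribution must sum to 1")
  for (S in config$state_covs) {
    if (!isSymmetric(unname(S)) || inherits(try(chol(S), silent = TRUE), "try-error"))
      stop("invalid config: state covariance not symmetric positive definite")
  }
  if (any(config$missing_rates < 0 | config$missing_rates > 1))
    stop("invalid config: missing_rates must lie in [0, 1]")
  if (any(config$uniquenesses <= 0))
    stop("invalid config: uniquenesses must be positive")
  if (config$treatment_multiplier < 0)
    stop("invalid config: treatment_multiplier must be nonnegative")
  invisible(config)
}

#' Scale transition probabilities into active states
#'
#' Returns a configuration whose off-diagonal transition probabilities into
#' the asymptomatic-activity and relapse states are multiplied by
#' `multiplier`, with each row renormalized through its diagonal entry. This
#' is the generative counterpart of a proportional treatment effect on the
#' intensities of transitions into active states; `multiplier = 0.5`
#' corresponds to a hazard ratio of 0.5 for becoming active.
#'
#' @param config an `msevo_config` object.
#' @param multiplier positive scaling factor (values in `(0, 1)` are
#'   protective; `0` switches transitions into active states off entirely).
#' @return a new `msevo_config` with the rescaled transition matrix.
#' @export
apply_treatment_effect <- function(config, multiplier) {
  validate_config(config)
  if (!is.numeric(multiplier) || length(multiplier) != 1 ||
      !is.finite(multiplier) || multiplier < 0)
    stop("multiplier must be a single nonnegative number")
  if (multiplier == 1) return(config)
  active <- which(config$state_meta %in% c("asymptomatic_activity", "relapse"))
  A <- config$transition
  S <- nrow(A)
  for (r in seq_len(S)) {
    cols <- setdiff(active, r)
    delta <- sum(A[r, cols]) * (multiplier - 1)
    if (A[r, r] - delta < -1e-12)
      stop("multiplier too large: row ", r, " diagonal would become negative")
    A[r, cols] <- A[r, cols] * multiplier
    A[r, r] <- A[r, r] - delta
  }
  A <- A / rowSums(A)   # absorb rounding at machine precision
  config$transition <- A
  validate_config(config)
  config
}

#' Stationary distribution of a transition matrix
#'
#' @param A row-stochastic matrix.
#' @return probability vector `p` with `p A = p`.
#' @export
stationary_distribution <- function(A) {
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' @export
print.msevo_config <- function(x, ...) {
  cat("Synthetic MS cohort generator configuration\n")
  cat(sprintf("  %d patients x %d monthly visits, %d states (%s)\n",
              x$n_patients, x$n_months, nrow(x$transition),
              paste(table(factor(x$state_meta, levels = META_LEVELS)),
                    collapse = "+")))
  cat(sprintf("  treatment multiplier %.2f on %.0f%% of patients\n",
              x$treatment_multiplier, 100 * x$treated_fraction))
  invisible(x)
}

#' Write / read a generator configuration as YAML
#'
#' Matrices are stored row-wise; the file round-trips through
#' [read_config()] to an identical configuration.
#'
#' @param config an `msevo_config`.
#' @param path file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   the validated `msevo_config`.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  ser <- lapply(config, function(x) {
    if (is.matrix(x)) {
      lapply(seq_len(nrow(x)), function(i) as.numeric(x[i, ]))
    } else if (is.list(x) && all(vapply(x, is.matrix, TRUE))) {
      lapply(x, function(m) lapply(seq_len(nrow(m)),
                                   function(i) as.numeric(m[i, ])))
    } else x
  })
  ser$.names <- lapply(config, function(x)
    if (is.matrix(x)) dimnames(x) else if (!is.null(names(x))) names(x) else NULL)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ser <- yaml::read_yaml(path)
  nm <- ser$.names
  ser$.names <- NULL
  mat_fields <- c("loading", "state_means", "transition")
  for (f in mat_fields) {
    m <- do.call(rbind, lapply(ser[[f]], unlist))
    dimnames(m) <- nm[[f]]
    ser[[f]] <- m
  }
  ser$state_covs <- lapply(ser$state_covs, function(m)
    do.call(rbind, lapply(m, unlist)))
  for (f in setdiff(names(ser), c(mat_fields, "state_covs", "feature_range"))) {
    if (!is.null(nm[[f]]) && !is.list(nm[[f]]))
      ser[[f]] <- setNames(unlist(ser[[f]]), nm[[f]])
  }
  ser$feature_range <- lapply(ser$feature_range, unlist)
  for (f in c("n_patients", "n_months", "seed"))
    ser[[f]] <- as.integer(ser[[f]])
  cfg <- structure(ser, class = "msevo_config")
  validate_config(cfg)
  cfg
}
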