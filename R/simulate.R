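#' Simulate a longitudinal synthetic MS cohort
#'
#' Draws, per patient, a hidden state path from the configured initial
#' distribution and monthly transition matrix (treated patients use the
#' transition matrix rescaled by the configured treatment multiplier), then
#' per visit a composite-score vector from the state's Gaussian emission, and
#' finally the eight observed features through the sparse loading matrix,
#' per-feature noise, and the per-feature observation links:
#' \itemize{
#'   \item `continuous-log`: log-normal (T25FWT, 9HPT seconds; T2 volume ml),
#'   \item `continuous-identity`: Gaussian, optionally rounded and clamped
#'     (EDSS to half points on `[0, 10]`; PASAT to integers on `[0, 60]`;
#'     normalized brain volume in liters),
#'   \item `count`: Poisson with log-linear rate (Gd-enhancing lesion count),
#'   \item `binary`: Bernoulli through a probit link (relapse flag).
#' }
#' Feature-specific missingness is applied at the configured rates; EDSS and
#' relapse are never missing. Latent truth columns (`true_state`,
#' `true_score_*`) are attached when `truth = TRUE`.
#'
#' @param config an `msevo_config` from [default_config()].
#' @param seed integer seed; identical `(config, seed)` give byte-identical
#'   output. Defaults to `config$seed`.
#' @param truth logical; attach latent ground-truth columns.
#' @return a `data.frame` ("cohort table"): one row per patient-visit with
#'   columns `patient_id`, `month`, the eight features, `relapse`, `treated`,
#'   per-feature observation-mask columns `obs_<feature>`, and optional truth
#'   columns.
#' @export
generate_cohort <- function(config, seed = config$seed, truth = TRUE) {
  validate_config(config)
  p <- length(config$features)
  empty <- function() {
    cols <- c("patient_id", "month", config$features, "treated",
              paste0("obs_", config$features),
              if (truth) c("true_state",
                           paste0("true_score_", seq_along(config$dimensions))))
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df$patient_id <- character(0)
    df
  }
  n <- config$n_patients
  m <- config$n_months
  if (n == 0L || m == 0L) return(empty())
  set.seed(as.integer(seed))

  treated <- rbinom(n, 1, config$treated_fraction)
  A0 <- config$transition
  A1 <- apply_treatment_effect(config, config$treatment_multiplier)$transition
  S <- nrow(A0)

  # state paths: vectorized over patients, one step per month
  states <- matrix(0L, n, m)
  states[, 1] <- 1L + findInterval(runif(n), cumsum(config$initial),
                                   left.open = TRUE)
  if (m > 1) {
    cum0 <- t(apply(A0, 1, cumsum))
    cum1 <- t(apply(A1, 1, cumsum))
    for (t in 2:m) {
      u <- runif(n)
      prev <- states[, t - 1]
      nxt <- integer(n)
      for (s in seq_len(S)) {
        idx0 <- which(prev == s & treated == 0)
        idx1 <- which(prev == s & treated == 1)
        if (length(idx0))
          nxt[idx0] <- 1L + findInterval(u[idx0], cum0[s, ], left.open = TRUE)
        if (length(idx1))
          nxt[idx1] <- 1L + findInterval(u[idx1], cum1[s, ], left.open = TRUE)
      }
      states[, t] <- pmin(nxt, S)
    }
  }

  nv <- n * m
  st <- as.integer(t(states))                       # visit-major, patient blocks
  K <- length(config$dimensions)
  eta <- matrix(0, nv, K)
  for (s in seq_len(S)) {
    idx <- which(st == s)
    if (!length(idx)) next
    L <- chol(config$state_covs[[s]])
    z <- matrix(rnorm(length(idx) * K), ncol = K)
    eta[idx, ] <- sweep(z %*% L, 2, config$state_means[s, ], "+")
  }

  xstd <- eta %*% t(config$loading) +
    matrix(rnorm(nv * p), nv, p) %*% diag(sqrt(config$uniquenesses))
  colnames(xstd) <- config$features

  obs <- matrix(NA_real_, nv, p, dimnames = list(NULL, config$features))
  for (f in config$features) {
    z <- config$feature_location[f] + config$feature_scale[f] * xstd[, f]
    obs[, f] <- switch(config$feature_links[[f]],
      "continuous-log" = exp(z),
      "continuous-identity" = z,
      "count" = rpois(nv, exp(pmin(z, 8))),   # cap rate for numeric safety
      "binary" = rbinom(nv, 1, pnorm(z)),
      stop("unknown link tag for feature ", f))
    step <- config$feature_round[f]
    if (!is.na(step)) obs[, f] <- round(obs[, f] / step) * step
    rng <- config$feature_range[[f]]
    if (!is.null(rng)) obs[, f] <- pmin(pmax(obs[, f], rng[1]), rng[2])
  }

  mask <- matrix(1L, nv, p, dimnames = list(NULL, config$features))
  for (f in config$features) {
    r <- config$missing_rates[f]
    if (f %in% c("relapse")) r <- 0      # relapse status is never missing
    if (r > 0) mask[, f] <- 1L - rbinom(nv, 1, r)
  }
  if (isTRUE(config$baseline_complete %||% TRUE)) {
    # trial protocols measure every feature at the baseline visit
    mask[rep.int(c(TRUE, rep(FALSE, m - 1L)), n), ] <- 1L
  }
  obs[mask == 0L] <- NA_real_

  out <- data.frame(
    patient_id = rep(sprintf("P%05d", seq_len(n)), each = m),
    month = rep.int(0:(m - 1), n),
    obs,
    treated = rep(treated, each = m),
    stringsAsFactors = FALSE
  )
  colnames(mask) <- paste0("obs_", config$features)
  out <- cbind(out, as.data.frame(mask))
  if (truth) {
    out$true_state <- st
    ts <- as.data.frame(eta)
    names(ts) <- paste0("true_score_", seq_len(K))
    out <- cbind(out, ts)
  }
  rownames(out) <- NULL
  out
}

#' Add raw visit-day offsets to a gridded cohort
#'
#' Converts the monthly grid back to irregular calendar days, emulating raw
#' trial exports: scheduled visits jittered around `month * 30.44` days and
#' relapse visits treated as unscheduled (additional mid-interval jitter).
#' Useful for exercising [map_to_grid()].
#'
#' @param cohort a cohort table with a `month` column.
#' @param seed integer seed.
#' @param jitter_sd s.d. (days) of the scheduled-visit jitter.
#' @return the cohort with a `day` column prepended (baseline pinned to 0).
#' @export
ungrid_cohort <- function(cohort, seed = 1L, jitter_sd = 3) {
  set.seed(as.integer(seed))
  day <- cohort$month * 30.44 + rnorm(nrow(cohort), 0, jitter_sd)
  unsched <- !is.na(cohort$relapse) & cohort$relapse == 1 & cohort$month > 0
  day[unsched] <- cohort$month[unsched] * 30.44 +
    runif(sum(unsched), -12, 12)
  day[cohort$month == 0] <- 0
  day <- pmax(day, 0)
  cbind(day = day, cohort)
}

#' Link-scale transform of cohort features for the Gaussian factor layer
#'
#' Applies the per-feature modelling transforms: `log` for log-normal
#' times/volumes, `log1p` for counts, identity otherwise. The result is the
#' scale on which the probabilistic factor analysis and the HMM emissions
#' operate.
#'
#' @param cohort cohort table.
#' @param config generator/model configuration carrying `feature_links`.
#' @return the cohort with feature columns replaced by transformed values.
#' @export
transform_features <- function(cohort, config = default_config()) {
  for (f in config$features) {
    if (!f %in% names(cohort)) next
    cohort[[f]] <- switch(config$feature_links[[f]],
      "continuous-log" = log(pmax(cohort[[f]], 1e-6)),
      "count" = log1p(cohort[[f]]),
      cohort[[f]])
  }
  cohort
}

#' Write / read a cohort table as CSV
#'
#' UTF-8 CSV with a header row and `NA` for missing cells; `truth = FALSE`
#' drops the latent ground-truth columns.
#'
#' @param cohort cohort table.
#' @param path file path.
#' @param truth keep latent truth columns when writing.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path, truth = TRUE) {
  if (!truth)
    cohort <- cohort[, !grepl("^true_", names(cohort)), drop = FALSE]
  write.csv(cohort, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
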