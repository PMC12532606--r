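# Data preparatory steps: mapping raw visits to the analysis grid, smooth
# imputation of partially observed visits, longitudinal brain-volume
# maintenance, PIRA derivation, and clustered discovery/holdout splits.

DAYS_PER_MONTH <- 30.44   # calendar-average month

round_half_up <- function(x) floor(x + 0.5)

#' Map raw visit days onto a regular monthly grid
#'
#' Assigns each raw visit (with a `day` offset from baseline) to the nearest
#' grid slot, `month = round(day / 30.44 / interval) * interval` with ties
#' rounded half-up, and merges collisions within a patient-slot: non-missing
#' values are preferred, relapse flags are OR-ed, and when two visits carry
#' the same feature the value from the unscheduled/relapse visit wins.
#' Already-gridded data (a `month` column, no `day` column) map to
#' themselves.
#'
#' @param raw_visits cohort table with a `day` column (days from baseline,
#'   `>= 0`).
#' @param interval_months grid interval: 1 (clinical-trial mode) or 6
#'   (real-world mode).
#' @return gridded cohort table with one row per (patient, month).
#' @export
map_to_grid <- function(raw_visits, interval_months = 1L) {
  stopifnot(interval_months %in% c(1L, 6L))
  v <- raw_visits
  if (!"day" %in% names(v)) {
    if (!"month" %in% names(v)) stop("need a day or month column")
    v$day <- v$month * DAYS_PER_MONTH
  }
  if (any(v$day < 0, na.rm = TRUE)) stop("negative day offsets")
  v$month <- as.integer(round_half_up(v$day / (DAYS_PER_MONTH * interval_months)) *
                          interval_months)
  v$day <- NULL

  feat <- intersect(MS_FEATURES, names(v))
  maskc <- intersect(paste0("obs_", MS_FEATURES), names(v))
  keycols <- c("patient_id", "month")
  dup <- duplicated(v[keycols]) | duplicated(v[keycols], fromLast = TRUE)
  out_unique <- v[!dup, , drop = FALSE]
  if (any(dup)) {
    vd <- v[dup, , drop = FALSE]
    # relapse/unscheduled rows last so their values win the tie-break
    pr <- if ("relapse" %in% names(vd)) ifelse(!is.na(vd$relapse) & vd$relapse == 1, 1L, 0L) else 0L
    vd <- vd[order(vd$patient_id, vd$month, pr), , drop = FALSE]
    merged <- lapply(split(vd, list(vd$patient_id, vd$month), drop = TRUE),
      function(g) {
        row <- g[nrow(g), , drop = FALSE]
        for (f in feat) {
          vals <- g[[f]][!is.na(g[[f]])]
          row[[f]] <- if (length(vals)) vals[length(vals)] else NA_real_
        }
        if ("relapse" %in% feat)
          row$relapse <- as.numeric(any(g$relapse == 1, na.rm = TRUE))
        for (m in maskc) row[[m]] <- as.integer(any(g[[m]] == 1))
        row
      })
    out_unique <- rbind(out_unique, do.call(rbind, merged))
  }
  out <- out_unique[order(out_unique$patient_id, out_unique$month), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Impute one trajectory on its modelling scale. Penalized spline when enough
# support, linear regression with >= 2 points, carry-forward/constant with 1.
impute_trajectory <- function(month, y, target_months, min_spline = 6L) {
  obs <- !is.na(y)
  n_obs <- sum(obs)
  if (n_obs == 0L) return(rep(NA_real_, length(target_months)))
  if (n_obs == 1L) return(rep(y[obs], length(target_months)))
  xo <- month[obs]; yo <- y[obs]
  if (n_obs >= min_spline && length(unique(xo)) >= min_spline) {
    k <- min(length(unique(xo)) - 1L, 8L)
    fit <- try(mgcv::gam(yo ~ s(xo, k = k)), silent = TRUE)
    if (!inherits(fit, "try-error"))
      return(as.numeric(predict(fit, newdata = data.frame(xo = target_months))))
  }
  fit <- lm(yo ~ xo)
  as.numeric(predict(fit, newdata = data.frame(xo = target_months)))
}

#' Impute partially observed visits
#'
#' For each patient and feature, missing values are filled from the
#' observed trajectory over time with a penalized-spline (GAM) regression,
#' falling back to a linear fit and then to carrying a single observation,
#' depending on support. Imputation happens only at visits where at least
#' one other feature is observed; rows with nothing observed are left
#' untouched, observed values are never altered, and imputed cells are
#' flagged in `imp_<feature>` columns. Times, volumes and counts are imputed
#' on their log / log1p scale and back-transformed; EDSS and PASAT are
#' snapped back to their reporting grids.
#'
#' @param cohort gridded cohort table with `obs_<feature>` masks (features
#'   carrying `NA` where unobserved).
#' @param config configuration supplying feature links and ranges.
#' @param min_spline minimum observed points for the spline stage.
#' @return the cohort with missing cells filled where possible; attribute
#'   `unimputable` counts cells left missing per feature.
#' @export
impute_partial_visits <- function(cohort, config = default_config(),
                                  min_spline = 6L) {
  feats <- intersect(config$features, names(cohort))
  out <- cohort[order(cohort$patient_id, cohort$month), , drop = FALSE]
  rownames(out) <- NULL
  any_obs <- rowSums(!is.na(out[, feats, drop = FALSE])) > 0
  for (f in feats) out[[paste0("imp_", f)]] <- 0L

  fwd <- function(x, f) switch(config$feature_links[[f]],
    "continuous-log" = log(pmax(x, 1e-6)), "count" = log1p(x), x)
  bwd <- function(z, f) {
    x <- switch(config$feature_links[[f]],
                "continuous-log" = exp(z), "count" = pmax(expm1(z), 0), z)
    step <- config$feature_round[f]
    if (!is.null(step) && !is.na(step)) x <- round(x / step) * step
    if (config$feature_links[[f]] == "count") x <- round(x)
    rng <- config$feature_range[[f]]
    if (!is.null(rng)) x <- pmin(pmax(x, rng[1]), rng[2])
    x
  }

  unimputable <- setNames(integer(length(feats)), feats)
  idx_by_pat <- split(seq_len(nrow(out)), out$patient_id)
  for (rows in idx_by_pat) {
    mon <- out$month[rows]
    for (f in feats) {
      y <- out[[f]][rows]
      need <- is.na(y) & any_obs[rows]
      if (!any(need)) next
      if (all(is.na(y))) {
        unimputable[f] <- unimputable[f] + sum(need)
        next
      }
      z <- fwd(y, f)
      zi <- impute_trajectory(mon, z, mon[need], min_spline)
      out[[f]][rows[need]] <- bwd(zi, f)
      out[[paste0("imp_", f)]][rows[need]] <- 1L
    }
  }
  attr(out, "unimputable") <- unimputable
  out
}

#' Hold-out evaluation of the imputation model
#'
#' Masks a random fraction of the observed cells of each imputable feature,
#' re-imputes them, and reports the mean absolute error on the standardized
#' modelling scale (absolute error on the link scale divided by the
#' feature's observed s.d. on that scale).
#'
#' @param cohort gridded cohort table.
#' @param holdout_fraction fraction of observed cells to mask, in `(0, 1)`.
#' @param seed integer seed.
#' @param config configuration supplying links.
#' @return named numeric vector: standardized MAE per feature (NA when no
#'   cell could be evaluated).
#' @export
evaluate_imputation <- function(cohort, holdout_fraction = 0.1, seed = 1L,
                                config = default_config()) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1)
  set.seed(as.integer(seed))
  feats <- setdiff(intersect(config$features, names(cohort)), "relapse")
  masked <- cohort
  held <- list()
  for (f in feats) {
    obs_idx <- which(!is.na(cohort[[f]]))
    n_h <- floor(length(obs_idx) * holdout_fraction)
    if (n_h == 0L) next
    h <- sample(obs_idx, n_h)
    held[[f]] <- h
    masked[[f]][h] <- NA_real_
    mc <- paste0("obs_", f)
    if (mc %in% names(masked)) masked[[mc]][h] <- 0L
  }
  imp <- impute_partial_visits(masked, config)
  fwd <- function(x, f) switch(config$feature_links[[f]],
    "continuous-log" = log(pmax(x, 1e-6)), "count" = log1p(x), x)
  mae <- setNames(rep(NA_real_, length(feats)), feats)
  for (f in names(held)) {
    h <- held[[f]]
    truth <- fwd(cohort[[f]][h], f)
    est <- fwd(imp[[f]][h], f)
    ok <- !is.na(est)
    s <- sd(fwd(cohort[[f]][!is.na(cohort[[f]])], f))
    if (any(ok) && is.finite(s) && s > 0)
      mae[f] <- mean(abs(est[ok] - truth[ok])) / s
    else if (any(ok))
      mae[f] <- mean(abs(est[ok] - truth[ok]))
  }
  mae
}

#' Update normalized brain volume from percent change
#'
#' `nbv_t = baseline_nbv * (1 + pbvc_t / 100)` — the longitudinal brain
#' volume series maintained from the baseline measurement and the percentage
#' brain-volume change from baseline.
#'
#' @param baseline_nbv baseline normalized brain volume (liters, `> 0`).
#' @param pbvc_series percent change from baseline per visit.
#' @return normalized brain volume series (liters).
#' @export
update_brain_volume <- function(baseline_nbv, pbvc_series) {
  if (!is.finite(baseline_nbv) || baseline_nbv <= 0)
    stop("baseline_nbv must be positive")
  if (any(pbvc_series <= -100, na.rm = TRUE))
    stop("percent change <= -100 is outside the domain")
  baseline_nbv * (1 + pbvc_series / 100)
}

pira_threshold <- function(baseline_edss) {
  if (baseline_edss == 0) 1.5
  else if (baseline_edss >= 5.5) 0.5
  else 1.0
}

#' Derive progression independent of relapse activity (PIRA)
#'
#' A PIRA event is a 3-month-confirmed, irreversible EDSS worsening not
#' attributable to a relapse. The worsening threshold over baseline depends
#' on baseline EDSS (+1.5 from 0; +1.0 from 0.5-5.0; +0.5 from >= 5.5).
#' A worsening episode qualifies when (i) every assessment from onset through
#' the confirmatory assessment at least `confirm_months` later stays at or
#' above threshold, (ii) no relapse occurs within `relapse_window_pre` months
#' before onset or before confirmation, and (iii) the EDSS never drops below
#' threshold afterwards within follow-up (irreversibility). Episodes failing
#' any condition are discarded; a later distinct episode may still qualify.
#'
#' @param edss_series EDSS per grid month.
#' @param relapse_series relapse flag per grid month (same grid).
#' @param baseline_edss baseline EDSS (half-point scale).
#' @param months grid month indices (default `0, 1, ...`).
#' @param confirm_months confirmation lag in months (default 3).
#' @param relapse_window_pre pre-onset relapse exclusion window, months
#'   (default 1, i.e. 30 days).
#' @return a one-row `data.frame` (`onset_month`, `confirmed`,
#'   `baseline_edss`) or `NULL` when no event qualifies.
#' @export
derive_pira <- function(edss_series, relapse_series, baseline_edss,
                        months = seq_along(edss_series) - 1L,
                        confirm_months = 3L, relapse_window_pre = 1L) {
  if (!length(edss_series)) stop("empty EDSS series")
  stopifnot(length(edss_series) == length(relapse_series),
            length(months) == length(edss_series))
  thr <- baseline_edss + pira_threshold(baseline_edss)
  above <- !is.na(edss_series) & edss_series >= thr
  rel <- !is.na(relapse_series) & relapse_series == 1
  n <- length(months)
  i <- 1L
  while (i <= n) {
    if (!above[i] || (i > 1L && above[i - 1L])) { i <- i + 1L; next }
    # episode start at index i
    t0 <- months[i]
    epi_end <- i
    while (epi_end < n && above[epi_end + 1L]) epi_end <- epi_end + 1L
    conf_idx <- which(above & months >= t0 + confirm_months &
                        seq_len(n) <= epi_end)
    confirmed <- length(conf_idx) > 0L
    sustained_to_end <- epi_end == n   # irreversible within follow-up
    conf_month <- if (confirmed) months[conf_idx[1L]] else months[epi_end]
    relapse_hit <- any(rel & months >= t0 - relapse_window_pre &
                         months <= conf_month)
    if (confirmed && sustained_to_end && !relapse_hit) {
      return(data.frame(onset_month = t0, confirmed = TRUE,
                        baseline_edss = baseline_edss))
    }
    i <- epi_end + 1L
  }
  NULL
}

#' Derive PIRA events for every patient in a cohort
#'
#' @param cohort gridded cohort table with `edss` and `relapse` columns.
#' @param baseline_month month used as disability baseline (default 0).
#' @param ... passed to [derive_pira()].
#' @return `data.frame` with one row per patient: `patient_id`,
#'   `onset_month` (NA if censored), `confirmed`, `baseline_edss`,
#'   `followup_months`.
#' @export
derive_pira_cohort <- function(cohort, baseline_month = 0L, ...) {
  res <- lapply(split(cohort, cohort$patient_id), function(g) {
    g <- g[order(g$month), , drop = FALSE]
    base <- g$edss[g$month == baseline_month][1]
    fup <- max(g$month)
    if (is.na(base))
      return(data.frame(patient_id = g$patient_id[1], onset_month = NA_real_,
                        confirmed = FALSE, baseline_edss = NA_real_,
                        followup_months = fup))
    ev <- derive_pira(g$edss, g$relapse, base, months = g$month, ...)
    data.frame(patient_id = g$patient_id[1],
               onset_month = if (is.null(ev)) NA_real_ else ev$onset_month,
               confirmed = !is.null(ev),
               baseline_edss = base, followup_months = fup)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-patient mean composite scores
#'
#' @param scores score table from [score_visits()].
#' @return matrix (patients x dimensions) of longitudinal means.
#' @export
patient_mean_scores <- function(scores) {
  sc_cols <- setdiff(names(scores), c("patient_id", "month"))
  sc_cols <- sc_cols[vapply(scores[sc_cols], is.numeric, TRUE)]
  m <- aggregate(scores[sc_cols], by = list(patient_id = scores$patient_id),
                 FUN = mean)
  out <- as.matrix(m[, sc_cols, drop = FALSE])
  rownames(out) <- m$patient_id
  out
}

#' Elbow curve for the patient-clustering step
#'
#' @param mean_scores matrix of per-patient mean scores.
#' @param k_range candidate cluster counts.
#' @param seed integer seed.
#' @return `data.frame` with `k` and total within-cluster sum of squares.
#' @export
kmeans_elbow <- function(mean_scores, k_range = 1:10, seed = 1L) {
  set.seed(as.integer(seed))
  tot <- vapply(k_range, function(k) {
    suppressWarnings(kmeans(mean_scores, centers = k, nstart = 5,
                            iter.max = 50)$tot.withinss)
  }, numeric(1))
  data.frame(k = k_range, tot_withinss = tot)
}

#' Clustered discovery/holdout split of patients
#'
#' Clusters patients by k-means on their longitudinal mean composite scores
#' and assigns, within each cluster, `round(holdout_frac * size)` randomly
#' chosen patients to the holdout set, the rest to discovery.
#'
#' @param mean_scores matrix of per-patient mean scores (rownames = ids), or
#'   a score table accepted by [patient_mean_scores()].
#' @param k number of clusters (default 5).
#' @param holdout_frac holdout fraction in `(0, 1)` (default 0.2).
#' @param seed integer seed.
#' @return `data.frame` with `patient_id`, `cluster`, `set`
#'   (`"discovery"`/`"holdout"`).
#' @export
split_discovery_holdout <- function(mean_scores, k = 5L, holdout_frac = 0.2,
                                    seed = 1L) {
  if (is.data.frame(mean_scores)) mean_scores <- patient_mean_scores(mean_scores)
  stopifnot(k >= 1L, holdout_frac > 0, holdout_frac < 1)
  n <- nrow(mean_scores)
  if (k > n) stop("more clusters than patients")
  set.seed(as.integer(seed))
  cl <- if (k == 1L) rep(1L, n) else
    suppressWarnings(kmeans(mean_scores, centers = k, nstart = 5,
                            iter.max = 50)$cluster)
  set <- rep("discovery", n)
  for (g in unique(cl)) {
    idx <- which(cl == g)
    n_h <- round(holdout_frac * length(idx))
    if (n_h > 0) set[sample(idx, n_h)] <- "holdout"
  }
  data.frame(patient_id = rownames(mean_scores) %||% as.character(seq_len(n)),
             cluster = cl, set = set, stringsAsFactors = FALSE)
}
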