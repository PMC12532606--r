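# Downstream analyses on decoded state paths: Kaplan-Meier time-to-event by
# baseline meta-state, continuous-time Markov treatment effects on
# panel-observed meta-state paths, and discrete-time prognostication of the
# transition to advanced MS.

#' Meta-state path table from decoded states
#'
#' @param decoded decoded paths from [viterbi_decode()].
#' @param map an `ms_meta_map` (or per-state label vector).
#' @return `data.frame` with `patient_id`, `month`, `meta`.
#' @export
meta_state_paths <- function(decoded, map) {
  meta <- if (inherits(map, "ms_meta_map")) map$meta else as.character(map)
  data.frame(patient_id = decoded$patient_id, month = decoded$month,
             meta = meta[decoded$state], stringsAsFactors = FALSE)
}

#' Per-patient time to first advanced state
#'
#' @param decoded decoded paths.
#' @param map meta-state map.
#' @return `data.frame` with `patient_id`, `baseline_meta`, `time` (months
#'   from baseline to first advanced visit, or last follow-up), `event`
#'   (1 = reached advanced). Patients already advanced at baseline are
#'   flagged with `time = 0`.
#' @export
advanced_event_table <- function(decoded, map) {
  paths <- meta_state_paths(decoded, map)
  res <- lapply(split(paths, paths$patient_id), function(g) {
    g <- g[order(g$month), , drop = FALSE]
    adv <- which(g$meta == "advanced")
    data.frame(patient_id = g$patient_id[1], baseline_meta = g$meta[1],
               time = if (length(adv)) g$month[adv[1]] - g$month[1]
                      else g$month[nrow(g)] - g$month[1],
               event = as.integer(length(adv) > 0))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier curves for time-to-event data, by stratum
#'
#' Product-limit estimator with Greenwood variance and log-log 95%
#' confidence bands, via the survival package.
#'
#' @param time event/censoring times (`> 0`).
#' @param event event indicator (1 = event, 0 = censored).
#' @param strata optional stratum labels (e.g. baseline meta-state).
#' @return an object of class `ms_km`: a `data.frame` (`stratum`, `time`,
#'   `n_risk`, `n_event`, `surv`, `lower`, `upper`) with the underlying
#'   `survfit` object as attribute `fit`.
#' @export
km_time_to_event <- function(time, event, strata = NULL) {
  if (any(time < 0, na.rm = TRUE)) stop("negative times")
  if (any(time == 0, na.rm = TRUE)) stop("times must be positive")
  df <- data.frame(time = time, event = event,
                   stratum = if (is.null(strata)) "all" else as.character(strata))
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = df,
                           conf.type = "log-log")
  sm <- summary(fit, censored = TRUE)
  strat <- if (is.null(sm$strata)) rep("all", length(sm$time)) else
    sub("^stratum=", "", as.character(sm$strata))
  out <- data.frame(stratum = strat, time = sm$time, n_risk = sm$n.risk,
                    n_event = sm$n.event, surv = sm$surv,
                    lower = sm$lower, upper = sm$upper)
  attr(out, "fit") <- fit
  class(out) <- c("ms_km", "data.frame")
  out
}

#' Survival probability at a time point from an `ms_km` curve
#'
#' @param km an `ms_km`.
#' @param at time points.
#' @return survival values of the step function: a vector over `at` when the
#'   curve has a single stratum, otherwise a stratum-by-time matrix (dropped
#'   to a named per-stratum vector for a single time point).
#' @export
km_surv_at <- function(km, at) {
  res <- vapply(split(as.data.frame(km), km$stratum), function(g) {
    g <- g[order(g$time), , drop = FALSE]
    i <- findInterval(at, g$time)
    ifelse(i == 0, 1.0, g$surv[pmax(i, 1)])
  }, numeric(length(at)))
  if (length(at) == 1L) return(res)            # named per-stratum vector
  if (is.matrix(res) && ncol(res) == 1L) return(drop(res))  # vector over at
  t(res)                                        # stratum x time matrix
}

# ---- continuous-time Markov model with proportional treatment effects ----

ctmc_build_counts <- function(paths, treated) {
  paths <- paths[order(paths$patient_id, paths$month), , drop = FALSE]
  n <- nrow(paths)
  if (n < 2) stop("need at least two observations")
  same <- paths$patient_id[-n] == paths$patient_id[-1]
  tr <- treated[match(paths$patient_id[-n], names(treated))]
  d <- data.frame(from = paths$meta[-n][same], to = paths$meta[-1][same],
                  gap = (paths$month[-1] - paths$month[-n])[same],
                  treated = as.numeric(tr)[same])
  aggregate(list(count = rep(1L, nrow(d))),
            by = list(from = d$from, to = d$to, gap = d$gap,
                      treated = d$treated), FUN = sum)
}

ctmc_expm <- function(Q, t) {
  as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
}

#' Fit a continuous-time Markov model to panel-observed meta-state paths
#'
#' Maximum-likelihood estimation of the transition intensity matrix `Q` from
#' panel observations (states seen only at visit times): the likelihood of
#' each observed pair is the matrix exponential `exp(Q * gap)` entry.
#' Treatment acts proportionally on the intensities of transitions into the
#' activity states, `q_rs * exp(beta_rs * treated)`; the hazard ratio per
#' transition is `exp(beta_rs)` and the percentage risk reduction
#' `1 - HR`. Standard errors come from the numerically evaluated observed
#' information.
#'
#' @param paths meta-state path table ([meta_state_paths()]), observation
#'   times in months.
#' @param treated named (by patient id) 0/1 treatment indicator.
#' @param states state space ordering (defaults to the levels present).
#' @param treatment_on `"activity"` (default: transitions into
#'   asymptomatic-activity/relapse states) or `"all"` off-diagonal
#'   transitions.
#' @param share_beta single shared treatment effect across affected
#'   transitions instead of one per transition.
#' @param allowed optional logical matrix of allowed instantaneous
#'   transitions; defaults to pairs observed in the panel data. Transition
#'   types never observed are fixed at intensity 0 and flagged.
#' @return an object of class `ms_ctmc`: `Q` (reference arm), `effects`
#'   (`data.frame` of per-transition `beta`, `se`, `hr`, CI and
#'   `risk_reduction` = 1 - HR in percent), `loglik`, `convergence`,
#'   `fixed_zero`.
#' @export
fit_ctmc <- function(paths, treated, states = NULL,
                     treatment_on = c("activity", "all"),
                     share_beta = FALSE, allowed = NULL) {
  treatment_on <- match.arg(treatment_on)
  counts <- ctmc_build_counts(paths, treated)
  states <- states %||% intersect(META_LEVELS, unique(c(counts$from, counts$to)))
  if (!length(states)) states <- sort(unique(c(counts$from, counts$to)))
  S <- length(states)
  counts$from <- factor(counts$from, levels = states)
  counts$to <- factor(counts$to, levels = states)

  obs_pairs <- matrix(FALSE, S, S, dimnames = list(states, states))
  for (i in seq_len(nrow(counts)))
    obs_pairs[counts$from[i], counts$to[i]] <- TRUE
  if (is.null(allowed)) allowed <- obs_pairs
  diag(allowed) <- FALSE
  fixed_zero <- which(!allowed & !diag(S), arr.ind = TRUE)

  act_cols <- which(states %in% c("asymptomatic_activity", "relapse"))
  treat_mask <- allowed
  if (treatment_on == "activity") {
    treat_mask[] <- FALSE
    if (length(act_cols)) treat_mask[, act_cols] <- allowed[, act_cols]
  }
  idx_q <- which(allowed, arr.ind = TRUE)
  idx_b <- which(treat_mask, arr.ind = TRUE)
  n_q <- nrow(idx_q)
  n_b <- if (share_beta) as.integer(nrow(idx_b) > 0) else nrow(idx_b)

  build_Q <- function(logq, beta, arm) {
    Q <- matrix(0, S, S)
    q <- exp(logq)
    if (arm == 1 && length(beta)) {
      bfull <- numeric(n_q)
      for (i in seq_len(nrow(idx_b))) {
        j <- which(idx_q[, 1] == idx_b[i, 1] & idx_q[, 2] == idx_b[i, 2])
        bfull[j] <- if (share_beta) beta[1] else beta[i]
      }
      q <- q * exp(bfull)
    }
    Q[idx_q] <- q
    diag(Q) <- -rowSums(Q)
    Q
  }
  negll <- function(par) {
    logq <- par[seq_len(n_q)]
    beta <- if (n_b > 0) par[n_q + seq_len(n_b)] else numeric(0)
    ll <- 0
    for (arm in sort(unique(counts$treated))) {
      Q <- build_Q(logq, beta, arm)
      sub <- counts[counts$treated == arm, , drop = FALSE]
      for (gp in unique(sub$gap)) {
        P <- ctmc_expm(Q, gp)
        P <- pmax(P, 1e-300)
        ss <- sub[sub$gap == gp, , drop = FALSE]
        ll <- ll + sum(ss$count *
                         log(P[cbind(as.integer(ss$from), as.integer(ss$to))]))
      }
    }
    -ll
  }
  # moment-style start: empirical one-step frequencies
  start_q <- rep(log(0.05), n_q)
  tab1 <- counts[counts$gap == min(counts$gap), , drop = FALSE]
  tot <- tapply(tab1$count, tab1$from, sum)
  for (i in seq_len(n_q)) {
    r <- idx_q[i, 1]; s <- idx_q[i, 2]
    c_rs <- sum(tab1$count[as.integer(tab1$from) == r & as.integer(tab1$to) == s])
    if (!is.na(tot[states[r]]) && c_rs > 0)
      start_q[i] <- log(max(c_rs / tot[states[r]] / min(counts$gap), 1e-5))
  }
  par0 <- c(start_q, rep(0, n_b))
  opt <- optim(par0, negll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-10))
  if (opt$convergence != 0)
    warning("CTMC optimisation did not fully converge (code ",
            opt$convergence, ")")

  logq <- opt$par[seq_len(n_q)]
  beta <- if (n_b > 0) opt$par[n_q + seq_len(n_b)] else numeric(0)
  Q <- build_Q(logq, beta, arm = 0)
  dimnames(Q) <- list(states, states)
  se_all <- tryCatch(sqrt(diag(solve(opt$hessian))), error = function(e)
    rep(NA_real_, length(opt$par)))
  effects <- NULL
  if (n_b > 0) {
    se_b <- se_all[n_q + seq_len(n_b)]
    eff_from <- if (share_beta) "(shared)" else states[idx_b[, 1]]
    eff_to <- if (share_beta) "(activity)" else states[idx_b[, 2]]
    effects <- data.frame(
      from = eff_from, to = eff_to, beta = beta, se = se_b,
      hr = exp(beta),
      hr_lower = exp(beta - 1.96 * se_b), hr_upper = exp(beta + 1.96 * se_b))
    effects$risk_reduction <- 100 * (1 - effects$hr)
  }
  structure(list(Q = Q, effects = effects, loglik = -opt$value,
                 convergence = opt$convergence, states = states,
                 fixed_zero = fixed_zero, share_beta = share_beta),
            class = "ms_ctmc")
}

#' @export
print.ms_ctmc <- function(x, digits = 4, ...) {
  cat("Continuous-time Markov model (reference-arm intensities, per month):\n")
  print(round(x$Q, digits))
  if (!is.null(x$effects)) {
    cat("Treatment effects (HR = exp(beta); risk reduction = 1 - HR, %):\n")
    print(x$effects, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

# ---- discrete-time prognostication ----

expand_person_period <- function(time, event, X, max_interval) {
  idx <- rep(seq_along(time), pmin(ceiling(time), max_interval))
  interval <- unlist(lapply(seq_along(time), function(i)
    seq_len(min(ceiling(time[i]), max_interval))))
  y <- as.integer(interval == ceiling(time[idx]) & event[idx] == 1 &
                    time[idx] <= max_interval)
  list(X = X[idx, , drop = FALSE], interval = interval, y = y, id = idx)
}

#' Fit a discrete-time logistic hazard prognostication model
#'
#' Expands (time, event) data into person-month records and fits a logistic
#' hazard with a smooth baseline (natural spline in the interval index) plus
#' linear effects of the baseline features. Predicted per-interval hazards
#' combine to per-patient survival curves; risk at a horizon is
#' `1 - S(horizon)`.
#'
#' @param features `data.frame`/matrix of baseline predictors.
#' @param time time to advanced transition (months, `> 0`).
#' @param event event indicator (1 = transitioned).
#' @param max_interval maximum modelled interval (months).
#' @param baseline_df spline degrees of freedom for the baseline hazard.
#' @return an object of class `ms_prognosis` with `fit` (a `glm`),
#'   `predict_survival(newdata, horizon)` closure and metadata.
#' @export
fit_prognosis <- function(features, time, event, max_interval = 60L,
                          baseline_df = 3L) {
  if (!any(event == 1)) stop("all observations censored; cannot fit hazards")
  X <- as.data.frame(features)
  pp <- expand_person_period(time, event, X, max_interval)
  d <- cbind(pp$X, .interval = pp$interval, .y = pp$y)
  rhs <- paste(c(sprintf("splines::ns(.interval, df = %d)", baseline_df),
                 colnames(X)), collapse = " + ")
  fit <- suppressWarnings(glm(stats::as.formula(paste(".y ~", rhs)),
                              family = binomial(), data = d))
  structure(list(fit = fit, feature_names = colnames(X),
                 max_interval = max_interval, baseline_df = baseline_df),
            class = "ms_prognosis")
}

#' Predicted survival probability at a horizon
#'
#' @param model an `ms_prognosis`.
#' @param newdata baseline features.
#' @param horizon months.
#' @return vector of `S(horizon)` per patient.
#' @export
predict_survival <- function(model, newdata, horizon) {
  newdata <- as.data.frame(newdata)
  horizon <- min(horizon, model$max_interval)
  n <- nrow(newdata)
  idx <- rep(seq_len(n), each = horizon)
  d <- cbind(newdata[idx, , drop = FALSE],
             .interval = rep(seq_len(horizon), n))
  h <- suppressWarnings(predict(model$fit, newdata = d, type = "response"))
  s <- tapply(log(pmax(1 - h, 1e-12)), idx, sum)
  exp(as.numeric(s))
}

#' Evaluate prognostication on held-out patients
#'
#' Harrell-type concordance over comparable pairs under censoring, and the
#' inverse-probability-of-censoring-weighted Brier score at `horizon` (with
#' an integrated version over `[0, horizon]`). Risk is `1 - S(horizon)`
#' under the fitted model.
#'
#' @param model an `ms_prognosis`.
#' @param features held-out baseline features.
#' @param time,event held-out outcomes.
#' @param horizon evaluation horizon in months (default 24).
#' @return list with `concordance`, `brier`, `brier_integrated`, `horizon`.
#' @export
evaluate_prognosis <- function(model, features, time, event, horizon = 24) {
  risk <- 1 - predict_survival(model, features, horizon)
  conc <- concordance_index(time, event, risk)
  surv_h <- function(h) predict_survival(model, features, h)
  br <- brier_ipcw(time, event, surv_h(horizon), horizon)
  grid <- seq(1, horizon, length.out = min(horizon, 24))
  bs <- vapply(grid, function(h) brier_ipcw(time, event, surv_h(h), h),
               numeric(1))
  ibs <- mean(bs, na.rm = TRUE)
  list(concordance = conc, brier = br, brier_integrated = ibs,
       horizon = horizon)
}

#' Harrell concordance index for right-censored data
#'
#' Pairs are comparable when the patient with the shorter time had an
#' event; concordant when the higher risk score belongs to the shorter
#' time; score ties count 1/2.
#'
#' @param time,event outcomes.
#' @param risk risk scores (higher = worse prognosis).
#' @return concordance in `[0, 1]`, `NA` (with a warning) when no pair is
#'   comparable.
#' @export
concordance_index <- function(time, event, risk) {
  n <- length(time)
  num <- den <- 0
  for (i in which(event == 1)) {
    comp <- which(time > time[i] | (time == time[i] & event == 0))
    if (!length(comp)) next
    den <- den + length(comp)
    num <- num + sum(risk[i] > risk[comp]) + 0.5 * sum(risk[i] == risk[comp])
  }
  if (den == 0) {
    warning("no comparable pairs")
    return(NA_real_)
  }
  num / den
}

#' IPCW Brier score at a horizon
#'
#' Graf-style weighting: patients with an event by the horizon contribute
#' `(0 - S_hat)^2 / G(t-)`, patients under follow-up at the horizon
#' `(1 - S_hat)^2 / G(h)`, where `G` is the Kaplan-Meier estimate of the
#' censoring distribution.
#'
#' @param time,event outcomes.
#' @param surv_hat predicted `S(horizon)` per patient.
#' @param horizon time point.
#' @return Brier score.
#' @export
brier_ipcw <- function(time, event, surv_hat, horizon) {
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- function(t) {
    i <- findInterval(t, cens_fit$time)
    ifelse(i == 0, 1, pmax(cens_fit$surv[pmax(i, 1)], 1e-6))
  }
  contrib <- numeric(length(time))
  ev <- time <= horizon & event == 1
  at <- time > horizon
  contrib[ev] <- (0 - surv_hat[ev])^2 / G(pmax(time[ev] - 1e-9, 0))
  contrib[at] <- (1 - surv_hat[at])^2 / G(horizon)
  mean(contrib)
}
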