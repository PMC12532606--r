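# From fitted HMM to the clinical picture: state labelling by score
# signatures, meta-state grouping from the transition structure, aggregated
# transition probabilities, state characterization on the measurement scale,
# and the predefined validation criteria.

#' Label hidden states from their score signatures
#'
#' The relapse state is the state with the maximal mean relapse-dimension
#' emission AND a majority of relapse-flagged visits among its decoded
#' visits; the asymptomatic-activity state has the maximal
#' asymptomatic-activity emission (relapse-flag minority). The remaining
#' states are ranked by mean disability + brain-damage emission — the
#' disease severity gradient; the EME/advanced split along it is made by
#' [group_meta_states()]. If the model's composite dimensions carry no
#' relapse or activity dimension (degenerate configurations), the
#' corresponding roles are skipped and all states lie on the severity axis.
#'
#' @param model an `ms_hmm`.
#' @param dim_labels character vector labelling the score dimensions (from
#'   the loading fit; defaults to `model$dimensions`).
#' @param decoded decoded state paths from [viterbi_decode()].
#' @param cohort cohort table (for relapse-flag prevalence per state).
#' @return an object of class `ms_state_labels`: `data.frame` with `state`,
#'   `role` (`relapse` / `asymptomatic_activity` / `severity`),
#'   `severity_score`, `severity_rank`, `relapse_prevalence`.
#' @export
label_states <- function(model, dim_labels = model$dimensions, decoded = NULL,
                         cohort = NULL) {
  S <- model$n_states
  means <- model$means
  prev <- rep(NA_real_, S)
  if (!is.null(decoded) && !is.null(cohort) && "relapse" %in% names(cohort)) {
    m <- merge(decoded[, c("patient_id", "month", "state")],
               cohort[, c("patient_id", "month", "relapse")],
               by = c("patient_id", "month"))
    tab <- tapply(m$relapse, factor(m$state, levels = seq_len(S)),
                  mean, na.rm = TRUE)
    prev <- as.numeric(tab)
  }
  role <- rep("severity", S)

  pick_max <- function(v, what) {
    o <- order(-v)
    if (length(v) > 1 && abs(v[o[1]] - v[o[2]]) < 1e-6)
      stop("ambiguous ", what, " state: two states tie within 1e-6; ",
           "label manually")
    o[1]
  }
  if ("relapse" %in% dim_labels) {
    v <- means[, which(dim_labels == "relapse")[1]]
    cand <- pick_max(v, "relapse")
    if (is.na(prev[cand]) || prev[cand] > 0.5) role[cand] <- "relapse"
  }
  if ("asymptomatic_activity" %in% dim_labels) {
    v <- means[, which(dim_labels == "asymptomatic_activity")[1]]
    v[role == "relapse"] <- -Inf
    cand <- pick_max(v, "asymptomatic-activity")
    if (is.na(prev[cand]) || prev[cand] <= 0.5) role[cand] <- "asymptomatic_activity"
  }
  sev_dims <- which(dim_labels %in% c("disability", "brain_damage"))
  if (!length(sev_dims)) sev_dims <- seq_len(ncol(means))
  sev <- rowSums(means[, sev_dims, drop = FALSE])
  rank <- rep(NA_integer_, S)
  sevs <- which(role == "severity")
  rank[sevs][order(sev[sevs])] <- seq_along(sevs)
  structure(data.frame(state = seq_len(S), role = role, severity_score = sev,
                       severity_rank = rank, relapse_prevalence = prev),
            class = c("ms_state_labels", "data.frame"))
}

#' Group states into clinical meta-states from the transition structure
#'
#' Among the non-activity (severity) states, the advanced block is the
#' largest upper segment `B` of the severity ordering such that (i) every
#' transition from `B` back to a non-`B` severity state is at most
#' `epsilon`, (ii) every direct transition into `B` from a non-`B` severity
#' state is at most `epsilon` (entry only via the activity states), and
#' (iii) the activity states feed `B` with total mass above `epsilon`
#' (without an absorbing-entry structure there is no advanced block). The
#' remaining severity states form EME. If no block satisfies (i)-(ii), the
#' segment minimizing the total violating mass is returned with a warning
#' flag.
#'
#' @param A estimated state transition matrix.
#' @param labels an `ms_state_labels`.
#' @param epsilon "close to zero" probability threshold (default 0.005).
#' @return an object of class `ms_meta_map`: `meta` (per-state label among
#'   EME / asymptomatic_activity / relapse / advanced), `epsilon`,
#'   `warning` flag, `violation` mass, `severity_order`.
#' @export
group_meta_states <- function(A, labels, epsilon = 0.005) {
  S <- nrow(A)
  stopifnot(nrow(labels) == S)
  role <- labels$role
  act <- which(role %in% c("relapse", "asymptomatic_activity"))
  sevs <- which(role == "severity")
  ord <- sevs[order(labels$severity_rank[sevs])]   # mild -> severe

  n <- length(ord)
  best_B <- integer(0); best_viol <- 0; found <- FALSE
  if (n >= 2) {
    for (size in (n - 1):1) {     # largest block first; EME stays non-empty
      B <- ord[(n - size + 1):n]
      nonB <- setdiff(ord, B)
      exits <- A[B, nonB, drop = FALSE]
      viol <- sum(exits[exits > epsilon])
      if (length(act)) {
        # entry to advanced only via the activity states
        entries <- A[nonB, B, drop = FALSE]
        viol <- viol + sum(entries[entries > epsilon])
        inflow <- sum(A[act, B, drop = FALSE])
      } else {
        # degenerate model without activity states: advanced is the absorbing
        # upper block, entered directly along the severity axis
        inflow <- sum(A[nonB, B, drop = FALSE])
      }
      if (viol == 0 && inflow > epsilon) { best_B <- B; found <- TRUE; break }
      if (!found && (length(best_B) == 0 || viol < best_viol) &&
          inflow > epsilon) {
        best_B <- B; best_viol <- viol
      }
    }
  }
  warning_flag <- !found && length(best_B) > 0
  if (!found && length(best_B) == 0) best_B <- integer(0)

  meta <- character(S)
  meta[role == "relapse"] <- "relapse"
  meta[role == "asymptomatic_activity"] <- "asymptomatic_activity"
  meta[setdiff(sevs, best_B)] <- "EME"
  meta[best_B] <- "advanced"
  structure(list(meta = meta, epsilon = epsilon, warning = warning_flag,
                 violation = if (found) 0 else best_viol,
                 severity_order = ord),
            class = "ms_meta_map")
}

#' @export
print.ms_meta_map <- function(x, ...) {
  cat("Meta-state map:",
      paste(sprintf("%d=%s", seq_along(x$meta), x$meta), collapse = ", "), "\n")
  if (x$warning)
    cat(sprintf("  WARNING: no clean partition; violating mass %.4f above epsilon %.3f\n",
                x$violation, x$epsilon))
  invisible(x)
}

#' Aggregate the transition matrix over meta-states
#'
#' `meta[g, h] = sum_{s in g} w_s sum_{t in h} A[s, t]` with `w_s` the
#' occupancy share of state `s` within its group; rows remain exactly
#' stochastic.
#'
#' @param A state transition matrix.
#' @param map an `ms_meta_map` (or character vector of per-state labels).
#' @param occupancy per-state visit counts (e.g. Viterbi counts).
#' @return an object of class `ms_transition_summary`: `meta_transition`,
#'   `occupancy`, `A`, `groups`.
#' @export
aggregate_meta_transitions <- function(A, map, occupancy) {
  meta <- if (inherits(map, "ms_meta_map")) map$meta else as.character(map)
  stopifnot(length(meta) == nrow(A), length(occupancy) == nrow(A))
  groups <- intersect(META_LEVELS, unique(meta))
  M <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (g in groups) {
    sg <- which(meta == g)
    w <- occupancy[sg]
    if (sum(w) <= 0) stop("empty occupancy for meta-group ", g)
    w <- w / sum(w)
    for (h in groups) {
      th <- which(meta == h)
      M[g, h] <- sum(w * rowSums(A[sg, th, drop = FALSE]))
    }
  }
  structure(list(meta_transition = M, occupancy = occupancy, A = A,
                 groups = groups),
            class = "ms_transition_summary")
}

#' @export
print.ms_transition_summary <- function(x, digits = 3, ...) {
  cat("Aggregated meta-state transition matrix (per grid step):\n")
  print(round(x$meta_transition, digits))
  invisible(x)
}

#' Characterize states on the original measurement scale
#'
#' Mean, s.d., median and IQR of the original variables per decoded state
#' and per meta-state, visit-weighted (patients counted each time they
#' occupy a state).
#'
#' @param decoded decoded state paths from [viterbi_decode()].
#' @param cohort cohort table with the original-scale features.
#' @param map optional `ms_meta_map` for the meta-state tables.
#' @param features variables to summarize.
#' @return list with `per_state` and (if `map` given) `per_meta`
#'   `data.frame`s; states with zero visits yield `NA` rows.
#' @export
characterize_states <- function(decoded, cohort, map = NULL,
                                features = intersect(MS_FEATURES, names(cohort))) {
  m <- merge(decoded[, c("patient_id", "month", "state")], cohort,
             by = c("patient_id", "month"))
  summarize_by <- function(fac, levels) {
    do.call(rbind, lapply(levels, function(lv) {
      gi <- m[fac == lv, , drop = FALSE]
      row <- data.frame(group = lv, n_visits = nrow(gi))
      for (f in features) {
        v <- gi[[f]]
        v <- v[!is.na(v)]
        row[[paste0(f, "_mean")]] <- if (length(v)) mean(v) else NA_real_
        row[[paste0(f, "_sd")]] <- if (length(v) > 1) sd(v) else NA_real_
        row[[paste0(f, "_median")]] <- if (length(v)) median(v) else NA_real_
        row[[paste0(f, "_iqr")]] <- if (length(v))
          diff(quantile(v, c(.25, .75), names = FALSE)) else NA_real_
      }
      row
    }))
  }
  S <- max(decoded$state)
  out <- list(per_state = summarize_by(factor(m$state, levels = seq_len(S)),
                                       as.character(seq_len(S))))
  if (!is.null(map)) {
    meta <- if (inherits(map, "ms_meta_map")) map$meta else as.character(map)
    fac <- factor(meta[m$state], levels = intersect(META_LEVELS, unique(meta)))
    out$per_meta <- summarize_by(fac, levels(fac))
  }
  out
}

#' Check the predefined validation criteria
#'
#' Criterion 1: the loading fit re-identifies the four composite dimensions
#' (physical disability, brain damage, relapse, asymptomatic activity).
#' Criterion 2: in the aggregated meta transition matrix, the direct
#' EME-to-advanced probability is at most `epsilon` while the routes through
#' the focal inflammatory states (EME to activity/relapse, and
#' activity/relapse to advanced) each exceed `epsilon`.
#'
#' @param dim_labels dimension labels from the loading fit.
#' @param map an `ms_meta_map`.
#' @param summary an `ms_transition_summary`.
#' @param epsilon threshold (defaults to the map's).
#' @return an object of class `ms_validation`: `criterion1`, `criterion2`,
#'   and an `evidence` list.
#' @export
check_validation_criteria <- function(dim_labels, map, summary,
                                      epsilon = map$epsilon) {
  needed <- c("disability", "brain_damage", "relapse", "asymptomatic_activity")
  c1 <- all(needed %in% dim_labels)
  M <- summary$meta_transition
  g <- rownames(M)
  act <- intersect(c("asymptomatic_activity", "relapse"), g)
  c2 <- FALSE
  ev <- list(dimensions = dim_labels)
  if (all(c("EME", "advanced") %in% g) && length(act)) {
    eme_adv <- M["EME", "advanced"]
    eme_act <- sum(M["EME", act])
    act_adv <- sum(sapply(act, function(a) M[a, "advanced"]))
    c2 <- eme_adv <= epsilon && eme_act > epsilon && act_adv > epsilon
    ev <- c(ev, list(eme_to_advanced = eme_adv, eme_to_activity = eme_act,
                     activity_to_advanced = act_adv))
  }
  structure(list(criterion1 = c1, criterion2 = c2, evidence = ev,
                 epsilon = epsilon), class = "ms_validation")
}

#' @export
print.ms_validation <- function(x, ...) {
  cat(sprintf("Validation criterion 1 (four dimensions): %s\n",
              if (x$criterion1) "PASS" else "FAIL"))
  cat(sprintf("Validation criterion 2 (entry to advanced via activity): %s\n",
              if (x$criterion2) "PASS" else "FAIL"))
  invisible(x)
}
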