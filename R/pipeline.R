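# End-to-end orchestration: simulate (or load) -> preprocess -> factor
# analysis -> HMM -> meta-states -> downstream analyses, with persisted
# artifacts and a reproducibility manifest.

#' Run the full disease-evolution analysis pipeline
#'
#' Executes every stage on a synthetic (or supplied) cohort: cohort
#' generation, imputation, the factor-analytic HMM fit ([fahmm()]),
#' optional BIC state-count selection, time-to-PIRA Kaplan-Meier curves by
#' baseline meta-state, the continuous-time Markov treatment-effect model
#' (when both arms are present), and discrete-time prognostication of the
#' transition to advanced MS with held-out evaluation. All randomness
#' derives from `seed`; rerunning with the same inputs reproduces every
#' table. When `outdir` is given, each artifact is written (CSV for tables,
#' JSON for models) together with a run manifest.
#'
#' @param config an `msevo_config` (used to simulate when `cohort` is NULL,
#'   and for feature links throughout).
#' @param cohort optional pre-built cohort table; otherwise simulated from
#'   `config`.
#' @param n_states number of hidden states for the main fit.
#' @param S_range optional integer vector; when given, BIC selection over
#'   this range replaces the fixed `n_states`.
#' @param epsilon meta-grouping threshold.
#' @param seed master seed.
#' @param holdout_frac held-out patient fraction for prognostication.
#' @param outdir optional output directory for artifacts.
#' @param pfa_args,hmm_args passed through to [fahmm()].
#' @return an object of class `msevo_report`: `model` (the `fahmm`),
#'   `bic` (optional `ms_bic`), `pira`, `km`, `ctmc`, `prognosis`,
#'   `prognosis_metrics`, `characterization`, `split`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), cohort = NULL,
                         n_states = 8L, S_range = NULL, epsilon = 0.005,
                         seed = 1L, holdout_frac = 0.2, outdir = NULL,
                         pfa_args = list(), hmm_args = list()) {
  if (is.null(cohort)) cohort <- generate_cohort(config, seed = seed)
  cohort_imp <- impute_partial_visits(cohort, config)

  bic <- NULL
  if (!is.null(S_range)) {
    base <- baseline_matrix(cohort_imp, config)
    pfa0 <- do.call(fit_pfa, c(list(x = base, seed = seed + 11L,
                                    link_tags = config$feature_links),
                               pfa_args))
    sc0 <- score_visits(pfa0, cohort_imp, config)
    bic <- do.call(select_states_bic,
                   c(list(scores = sc0, S_range = S_range, seed = seed + 37L),
                     hmm_args))
    n_states <- bic$best_s
  }
  model <- fahmm(cohort_imp, n_states = n_states, config = config,
                 impute = FALSE, epsilon = epsilon, seed = seed,
                 pfa_args = pfa_args, hmm_args = hmm_args)

  meta <- model$meta_map
  paths <- meta_state_paths(model$decoded, meta)

  # time to first confirmed PIRA, stratified by baseline meta-state
  pira <- derive_pira_cohort(cohort_imp)
  base_meta <- paths$meta[paths$month == 0][match(pira$patient_id,
                                                  paths$patient_id[paths$month == 0])]
  pira$baseline_meta <- base_meta
  pira$time <- ifelse(pira$confirmed, pira$onset_month, pira$followup_months)
  ok <- !is.na(pira$time) & pira$time > 0
  km <- if (any(ok)) km_time_to_event(pira$time[ok],
                                      as.integer(pira$confirmed[ok]),
                                      strata = pira$baseline_meta[ok]) else NULL

  # continuous-time Markov treatment model (needs both arms)
  treated <- tapply(cohort$treated, cohort$patient_id, max)
  ctmc <- NULL
  if (length(unique(treated)) > 1) {
    ctmc <- fit_ctmc(paths, treated, states = model$transitions$groups,
                     share_beta = TRUE)
  }

  # prognostication: time to advanced from baseline scores + treatment
  adv <- advanced_event_table(model$decoded, meta)
  progn <- NULL; progn_metrics <- NULL; split <- NULL
  eligible <- adv[adv$baseline_meta != "advanced" & adv$time > 0, ]
  if (nrow(eligible) >= 50 && sum(eligible$event) >= 10) {
    sc0 <- model$scores[model$scores$month == 0, , drop = FALSE]
    feat <- sc0[match(eligible$patient_id, sc0$patient_id), , drop = FALSE]
    fx <- feat[, setdiff(names(feat), c("patient_id", "month")), drop = FALSE]
    names(fx) <- make.names(names(fx))
    fx$treated <- as.numeric(treated[match(eligible$patient_id, names(treated))])
    split <- split_discovery_holdout(patient_mean_scores(model$scores),
                                     k = 5L, holdout_frac = holdout_frac,
                                     seed = seed + 101L)
    hold_ids <- split$patient_id[split$set == "holdout"]
    is_h <- eligible$patient_id %in% hold_ids
    if (sum(eligible$event[!is_h]) >= 10 && sum(is_h) >= 10) {
      progn <- fit_prognosis(fx[!is_h, , drop = FALSE],
                             eligible$time[!is_h], eligible$event[!is_h])
      progn_metrics <- evaluate_prognosis(progn, fx[is_h, , drop = FALSE],
                                          eligible$time[is_h],
                                          eligible$event[is_h])
    }
  }

  chars <- characterize_states(model$decoded, cohort_imp, map = meta)

  report <- structure(list(
    model = model, bic = bic, pira = pira, km = km, ctmc = ctmc,
    prognosis = progn, prognosis_metrics = progn_metrics,
    characterization = chars, split = split,
    manifest = list(package_version = as.character(utils::packageVersion("msevo")),
                    seed = seed, n_states = n_states, epsilon = epsilon,
                    n_patients = length(unique(cohort$patient_id)),
                    n_visits = nrow(cohort),
                    timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "msevo_report")

  if (!is.null(outdir)) write_report(report, outdir, cohort = cohort)
  report
}

#' Persist a report bundle
#'
#' Writes the pipeline artifacts: loading model (JSON), transition matrices
#' (CSV), decoded paths, BIC table, state characterization tables, PIRA
#' events, KM curves, treatment effects, prognostication metrics, the
#' validation-criteria report, and a manifest (JSON).
#'
#' @param report an `msevo_report`.
#' @param outdir directory (created if needed).
#' @param cohort optional cohort to persist alongside.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir, cohort = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  m <- report$model
  write_loading_model(m$pfa, p("loading_model.json"))
  write.csv(m$hmm$transition, p("transition_matrix.csv"), row.names = FALSE)
  write.csv(as.data.frame(m$transitions$meta_transition),
            p("meta_transition_matrix.csv"))
  write.csv(m$decoded[, c("patient_id", "month", "state", "max_posterior")],
            p("state_paths.csv"), row.names = FALSE)
  write.csv(data.frame(state = seq_along(m$meta_map$meta),
                       meta = m$meta_map$meta),
            p("meta_state_map.csv"), row.names = FALSE)
  if (!is.null(report$bic))
    write.csv(report$bic$table, p("bic_table.csv"), row.names = FALSE)
  write.csv(report$characterization$per_state, p("state_characterization.csv"),
            row.names = FALSE)
  if (!is.null(report$characterization$per_meta))
    write.csv(report$characterization$per_meta,
              p("meta_characterization.csv"), row.names = FALSE)
  write.csv(report$pira, p("pira_events.csv"), row.names = FALSE)
  if (!is.null(report$km))
    write.csv(as.data.frame(report$km), p("km_curves.csv"), row.names = FALSE)
  if (!is.null(report$ctmc)) {
    write.csv(as.data.frame(report$ctmc$Q), p("ctmc_intensities.csv"))
    if (!is.null(report$ctmc$effects))
      write.csv(report$ctmc$effects, p("treatment_effects.csv"),
                row.names = FALSE)
  }
  if (!is.null(report$split))
    write.csv(report$split[, c("patient_id", "set")], p("split.csv"),
              row.names = FALSE)
  jsonlite::write_json(
    list(validation = list(criterion1 = m$validation$criterion1,
                           criterion2 = m$validation$criterion2,
                           evidence = m$validation$evidence),
         prognosis = report$prognosis_metrics,
         manifest = report$manifest),
    p("report.json"), digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(cohort)) write_cohort(cohort, p("cohort.csv"), truth = FALSE)
  invisible(outdir)
}

#' @export
print.msevo_report <- function(x, ...) {
  cat("== MS disease-evolution pipeline report ==\n")
  print(x$model)
  if (!is.null(x$bic)) print(x$bic)
  if (!is.null(x$ctmc) && !is.null(x$ctmc$effects)) {
    cat("\nTreatment effect (shared HR on transitions into active states):\n")
    print(x$ctmc$effects, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$prognosis_metrics))
    cat(sprintf("\nPrognostication (held-out): C = %.3f, Brier(%d mo) = %.3f\n",
                x$prognosis_metrics$concordance, x$prognosis_metrics$horizon,
                x$prognosis_metrics$brier))
  print(x$model$validation)
  invisible(x)
}
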