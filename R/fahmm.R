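#' Fit the factor-analytic hidden Markov model of MS disease evolution
#'
#' The single entry point composing the full modelling chain on a
#' longitudinal cohort table: (1) partially observed visits are imputed from
#' each patient's trajectories; (2) the sparse probabilistic factor analysis
#' is fitted to the per-patient complete baseline rows, yielding the loading
#' matrix and the number of composite dimensions; (3) every visit is scored
#' (posterior factor means under the fixed loading matrix); (4) a Gaussian
#' hidden Markov model with `n_states` states is fitted to the score
#' sequences by multi-sequence Baum-Welch; (5) state paths are decoded by
#' the Viterbi algorithm; (6) states are labelled from their score
#' signatures and grouped into clinical meta-states from the transition
#' structure, and the meta-aggregated transition matrix and the predefined
#' validation criteria are computed.
#'
#' @param cohort a cohort table (see [generate_cohort()] for the layout):
#'   one row per patient-visit on a regular grid, eight features, `obs_*`
#'   masks for missingness.
#' @param n_states number of hidden states (default 8).
#' @param config generator/model configuration supplying feature links.
#' @param impute impute partially observed visits first (default TRUE).
#' @param epsilon "close to zero" transition threshold for meta-grouping.
#' @param seed master seed (PFA and HMM restart seeds derive from it).
#' @param pfa_args,hmm_args named lists of extra arguments for [fit_pfa()] /
#'   [fit_hmm()] (e.g. `restarts`).
#' @return an object of class `fahmm` with components `pfa` (`ms_pfa`),
#'   `hmm` (`ms_hmm`), `scores`, `decoded`, `labels`, `meta_map`,
#'   `transitions` (`ms_transition_summary`), `validation`, `config`.
#' @seealso [predict.fahmm()], [simulate.fahmm()], [run_pipeline()]
#' @export
fahmm <- function(cohort, n_states = 8L, config = default_config(),
                  impute = TRUE, epsilon = 0.005, seed = 1L,
                  pfa_args = list(), hmm_args = list()) {
  cl <- match.call()
  feats <- config$features
  if (impute && anyNA(cohort[, intersect(feats, names(cohort))]))
    cohort <- impute_partial_visits(cohort, config)

  base <- baseline_matrix(cohort, config)
  pfa <- do.call(fit_pfa, c(list(x = base, seed = seed + 11L,
                                 link_tags = config$feature_links),
                            pfa_args))
  if (pfa$active_dimensions == 0L)
    stop("no active composite dimensions; cannot fit state model")
  scores <- score_visits(pfa, cohort, config)
  hmm <- do.call(fit_hmm, c(list(scores = scores, n_states = n_states,
                                 seed = seed + 23L), hmm_args))
  decoded <- viterbi_decode(hmm, scores)
  labels <- label_states(hmm, dim_labels = pfa$dimension_labels,
                         decoded = decoded, cohort = cohort)
  map <- group_meta_states(hmm$transition, labels, epsilon = epsilon)
  occ <- as.numeric(table(factor(decoded$state, levels = seq_len(n_states))))
  trans <- aggregate_meta_transitions(hmm$transition, map, occ)
  val <- check_validation_criteria(pfa$dimension_labels, map, trans)

  structure(list(pfa = pfa, hmm = hmm, scores = scores, decoded = decoded,
                 labels = labels, meta_map = map, transitions = trans,
                 validation = val, config = config, n_states = n_states,
                 seed = seed, call = cl),
            class = "fahmm")
}

#' @export
print.fahmm <- function(x, ...) {
  cat("Factor-analytic hidden Markov model of MS disease evolution\n")
  cat(sprintf("  %d composite dimensions: %s\n", x$pfa$active_dimensions,
              paste(x$pfa$dimension_labels, collapse = ", ")))
  cat(sprintf("  %d states decoded over %d visits (%d patients); log-likelihood %.1f\n",
              x$n_states, x$hmm$n_visits, x$hmm$n_sequences,
              x$hmm$log_likelihood))
  cat("  meta-states:",
      paste(sprintf("%d=%s", seq_along(x$meta_map$meta), x$meta_map$meta),
            collapse = " "), "\n")
  cat("  aggregated monthly transition matrix (%):\n")
  print(round(100 * x$transitions$meta_transition, 1))
  invisible(x)
}

#' @export
summary.fahmm <- function(object, ...) {
  out <- list(pfa = object$pfa, hmm_loglik = object$hmm$log_likelihood,
              bic = -2 * object$hmm$log_likelihood +
                object$hmm$n_params * log(object$hmm$n_visits),
              meta = object$meta_map, transitions = object$transitions,
              validation = object$validation,
              occupancy = table(object$meta_map$meta[object$decoded$state]))
  class(out) <- "summary.fahmm"
  out
}

#' @export
print.summary.fahmm <- function(x, ...) {
  print(x$pfa)
  cat(sprintf("\nHMM log-likelihood %.1f (BIC %.1f)\n", x$hmm_loglik, x$bic))
  print(x$meta)
  cat("meta-state visit occupancy:\n"); print(x$occupancy)
  print(x$transitions)
  print(x$validation)
  invisible(x)
}

#' @export
coef.fahmm <- function(object, ...) {
  list(loadings = object$pfa$loadings,
       uniquenesses = object$pfa$uniquenesses,
       initial = object$hmm$initial,
       transition = object$hmm$transition,
       state_means = object$hmm$means)
}

#' @export
logLik.fahmm <- function(object, ...) logLik(object$hmm)

#' Decode disease states for new visits
#'
#' Scores new cohort rows under the fitted loading matrix and decodes their
#' state paths under the fitted HMM.
#'
#' @param object a fitted `fahmm`.
#' @param newdata cohort table (complete or imputable).
#' @param type `"state"` (decoded path table), `"meta"` (with meta-state
#'   labels), or `"scores"` (composite scores only).
#' @param impute impute partial visits first.
#' @param ... unused.
#' @return a `data.frame` according to `type`.
#' @export
predict.fahmm <- function(object, newdata, type = c("state", "meta", "scores"),
                          impute = TRUE, ...) {
  type <- match.arg(type)
  if (impute && anyNA(newdata[, intersect(object$config$features,
                                          names(newdata))]))
    newdata <- impute_partial_visits(newdata, object$config)
  sc <- score_visits(object$pfa, newdata, object$config)
  if (type == "scores") return(sc)
  dec <- viterbi_decode(object$hmm, sc)
  if (type == "meta") {
    dec$meta <- object$meta_map$meta[dec$state]
  }
  dec
}

#' Simulate score sequences and state paths from a fitted model
#'
#' Draws new patients from the fitted HMM: state paths from the estimated
#' initial/transition distributions and composite scores from the state
#' emissions. (The observation layer is not re-simulated; the fitted model
#' lives on the composite-score scale.)
#'
#' @param object a fitted `fahmm` or `ms_hmm`.
#' @param nsim number of patients.
#' @param seed integer seed.
#' @param n_months visits per patient.
#' @param ... unused.
#' @return `data.frame` with `patient_id`, `month`, `state` and one column
#'   per composite dimension.
#' @export
simulate.fahmm <- function(object, nsim = 100L, seed = 1L, n_months = 24L, ...) {
  h <- if (inherits(object, "fahmm")) object$hmm else object
  set.seed(as.integer(seed))
  S <- h$n_states
  K <- ncol(h$means)
  chol_covs <- lapply(h$covs, chol)
  res <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    st <- integer(n_months)
    st[1] <- sample.int(S, 1, prob = h$initial)
    for (t in seq_len(n_months - 1L))
      st[t + 1L] <- sample.int(S, 1, prob = h$transition[st[t], ])
    eta <- t(vapply(st, function(s)
      h$means[s, ] + drop(rnorm(K) %*% chol_covs[[s]]), numeric(K)))
    colnames(eta) <- colnames(h$means) %||% paste0("dim", seq_len(K))
    res[[i]] <- data.frame(patient_id = sprintf("S%05d", i),
                           month = 0:(n_months - 1L), state = st, eta,
                           check.names = FALSE)
  }
  do.call(rbind, res)
}

#' @export
simulate.ms_hmm <- simulate.fahmm

#' Plot a fitted disease-evolution model
#'
#' Two panels: the loading matrix (features x composite dimensions) and the
#' state transition matrix, as shaded images.
#'
#' @param x a fitted `fahmm`.
#' @param ... unused.
#' @export
plot.fahmm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(6, 6, 3, 1))
  on.exit(graphics::par(op))
  L <- x$pfa$loadings
  graphics::image(seq_len(ncol(L)), seq_len(nrow(L)), t(L[nrow(L):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(25, "Blue-Red 2"),
                  axes = FALSE, xlab = "", ylab = "", main = "loadings")
  graphics::axis(1, seq_len(ncol(L)), colnames(L), las = 2, cex.axis = .7)
  graphics::axis(2, seq_len(nrow(L)), rev(rownames(L)), las = 2, cex.axis = .7)
  A <- x$hmm$transition
  graphics::image(seq_len(ncol(A)), seq_len(nrow(A)), t(A[nrow(A):1, ]),
                  col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "to", ylab = "from",
                  main = "monthly transitions")
  graphics::axis(1, seq_len(ncol(A)), seq_len(ncol(A)))
  graphics::axis(2, seq_len(nrow(A)), rev(seq_len(nrow(A))))
  invisible(x)
}
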