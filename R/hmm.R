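# Multi-sequence Gaussian hidden Markov model: Baum-Welch estimation,
# BIC state-count selection, Viterbi decoding. Each patient contributes an
# independent chain sharing (initial, transition, emission) parameters.

# Stack a score table (patient_id, month, score columns) into the matrix
# representation used by the C++ core.
as_score_sequences <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores)) {
    X <- do.call(rbind, scores)
    lengths <- vapply(scores, NROW, 1L)
    ids <- names(scores) %||% as.character(seq_along(scores))
    return(list(X = as.matrix(X), lengths = as.integer(lengths),
                patient_id = rep(ids, lengths),
                month = unlist(lapply(lengths, function(l) seq_len(l) - 1L))))
  }
  stopifnot(is.data.frame(scores), all(c("patient_id", "month") %in% names(scores)))
  sc_cols <- setdiff(names(scores), c("patient_id", "month"))
  sc_cols <- sc_cols[vapply(scores[sc_cols], is.numeric, TRUE)]
  sc_cols <- sc_cols[!grepl("^var_", sc_cols)]
  o <- order(scores$patient_id, scores$month)
  scores <- scores[o, , drop = FALSE]
  X <- as.matrix(scores[, sc_cols, drop = FALSE])
  if (!all(is.finite(X))) stop("scores contain non-finite values")
  lengths <- as.integer(table(factor(scores$patient_id,
                                     levels = unique(scores$patient_id))))
  list(X = X, lengths = lengths,
       patient_id = scores$patient_id, month = scores$month)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

floor_spd <- function(S, floor = 1e-6) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, floor)
  e$vectors %*% (v * t(e$vectors))
}

#' Fit a Gaussian hidden Markov model to composite-score sequences
#'
#' Baum-Welch (EM) estimation over all patients' score sequences, each an
#' independent chain with shared parameters. Emissions are full-covariance
#' multivariate normals; the transition matrix is unconstrained (all
#' transitions a priori possible). Inference runs in the log domain; EM stops
#' when the relative log-likelihood change falls below `tol` or after
#' `max_iter` iterations. Each restart initializes state means by seeded
#' k-means on the pooled scores (jittered after the first restart), pooled
#' covariances, a 0.9-diagonal transition matrix and a uniform initial
#' distribution; the restart with the highest log-likelihood is kept.
#'
#' @param scores a score table (`patient_id`, `month`, one numeric column per
#'   composite dimension), e.g. from [score_visits()], or a list of per-patient
#'   score matrices.
#' @param n_states number of hidden states `S >= 1`.
#' @param restarts number of seeded initializations.
#' @param seed master seed; restart seeds are derived from it.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param cov_floor eigenvalue floor applied to emission covariances.
#' @return an object of class `ms_hmm`: `n_states`, `initial`, `transition`,
#'   `means` (S x K), `covs` (list of K x K), `log_likelihood`, `n_params`,
#'   `converged`, `n_visits`, `n_sequences`, `iterations`, `loglik_trace`.
#' @export
fit_hmm <- function(scores, n_states, restarts = 5L, seed = 1L,
                    max_iter = 500L, tol = 1e-6, cov_floor = 1e-6) {
  seqs <- as_score_sequences(scores)
  X <- seqs$X
  K <- ncol(X)
  S <- as.integer(n_states)
  if (S < 1L) stop("n_states must be >= 1")
  if (S > nrow(X)) stop("n_states exceeds the total number of visits")

  pooled_cov <- floor_spd(cov(X) + diag(1e-8, K), cov_floor)
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(as.integer(seed) + 7919L * (r - 1L))
    centers <- if (S == 1L) matrix(colMeans(X), 1) else {
      km <- suppressWarnings(kmeans(X, centers = S, nstart = 1, iter.max = 50))
      km$centers
    }
    if (r > 1L) centers <- centers + matrix(rnorm(S * K, 0, 0.25), S, K)
    fit <- hmm_em_run(X, seqs$lengths, centers, pooled_cov, S,
                      max_iter, tol, cov_floor)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  best$n_params <- (S - 1L) + S * (S - 1L) + S * (K + K * (K + 1L) %/% 2L)
  best$n_visits <- nrow(X)
  best$n_sequences <- sum(seqs$lengths > 0L)
  best$dimensions <- colnames(X) %||% paste0("dim", seq_len(K))
  class(best) <- "ms_hmm"
  best
}

hmm_em_run <- function(X, lengths, centers, pooled_cov, S,
                       max_iter, tol, cov_floor) {
  K <- ncol(X)
  means <- unname(as.matrix(centers))
  covs <- replicate(S, pooled_cov, simplify = FALSE)
  A <- matrix(0.1 / max(S - 1, 1), S, S); diag(A) <- if (S > 1) 0.9 else 1
  pi0 <- rep(1 / S, S)

  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    cube <- array(unlist(covs), dim = c(K, K, S))
    logB <- cpp_gauss_logdens(X, means, cube)
    fb <- cpp_forward_backward(logB, log(pi0), log(A), lengths)
    ll <- fb$loglik
    trace <- c(trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll

    g <- fb$gamma
    pi0 <- as.numeric(fb$gamma_first); pi0 <- pi0 / sum(pi0)
    xi <- fb$xi
    rs <- rowSums(xi)
    for (s in seq_len(S)) {
      A[s, ] <- if (rs[s] > 0) xi[s, ] / rs[s] else rep(1 / S, S)
    }
    w <- colSums(g)
    means <- t(g) %*% X / w
    for (s in seq_len(S)) {
      D <- sweep(X, 2, means[s, ])
      covs[[s]] <- floor_spd(crossprod(D * g[, s], D) / w[s], cov_floor)
    }
    if (it >= max_iter) break
  }
  list(n_states = S, initial = pi0, transition = A, means = means,
       covs = covs, log_likelihood = ll, converged = converged,
       iterations = it, loglik_trace = trace)
}

#' Forward log-likelihood of score sequences under a fitted HMM
#'
#' @param model an `ms_hmm`.
#' @param scores score table or list of matrices (as in [fit_hmm()]).
#' @return total log-likelihood over all sequences.
#' @export
hmm_loglik <- function(model, scores) {
  seqs <- as_score_sequences(scores)
  if (ncol(seqs$X) != ncol(model$means))
    stop("score dimension does not match the model")
  K <- ncol(seqs$X)
  cube <- array(unlist(model$covs), dim = c(K, K, model$n_states))
  logB <- cpp_gauss_logdens(seqs$X, model$means, cube)
  cpp_hmm_loglik(logB, log(model$initial), log(model$transition), seqs$lengths)
}

#' @export
logLik.ms_hmm <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_params, class = "logLik")
}

#' Select the number of hidden states by BIC
#'
#' Fits the HMM for each candidate state count and computes
#' `BIC(S) = -2 logL + n_params * log(n)` with `n` the total number of visits
#' (a patient-based BIC column is reported alongside). The selected `S` is the
#' BIC argmin among converged fits, ties broken toward smaller `S`.
#'
#' @param scores score table (as in [fit_hmm()]).
#' @param S_range integer vector of candidate state counts.
#' @param restarts,seed,... passed to [fit_hmm()].
#' @return an object of class `ms_bic`: `best_s`, `table` (S, loglik,
#'   n_params, bic, bic_patients, converged), and `model`, the fit at
#'   `best_s`.
#' @export
select_states_bic <- function(scores, S_range, restarts = 5L, seed = 1L, ...) {
  if (!length(S_range)) stop("S_range must be non-empty")
  S_range <- sort(unique(as.integer(S_range)))
  fits <- vector("list", length(S_range))
  tab <- data.frame(S = S_range, loglik = NA_real_, n_params = NA_integer_,
                    bic = NA_real_, bic_patients = NA_real_, converged = FALSE)
  for (i in seq_along(S_range)) {
    f <- fit_hmm(scores, S_range[i], restarts = restarts,
                 seed = seed + 1000L * i, ...)
    fits[[i]] <- f
    tab$loglik[i] <- f$log_likelihood
    tab$n_params[i] <- f$n_params
    tab$bic[i] <- -2 * f$log_likelihood + f$n_params * log(f$n_visits)
    tab$bic_patients[i] <- -2 * f$log_likelihood + f$n_params * log(f$n_sequences)
    tab$converged[i] <- f$converged
  }
  ok <- which(tab$converged)
  if (!length(ok)) ok <- seq_len(nrow(tab))   # all flagged; still report argmin
  best <- ok[which.min(tab$bic[ok])]
  structure(list(best_s = tab$S[best], table = tab, model = fits[[best]]),
            class = "ms_bic")
}

#' @export
print.ms_bic <- function(x, ...) {
  cat("HMM state-count selection by BIC (n = visits)\n")
  print(x$table, row.names = FALSE)
  cat("selected S =", x$best_s, "\n")
  invisible(x)
}

#' Decode maximum a posteriori state paths
#'
#' Runs the Viterbi algorithm per patient (log-space dynamic programming,
#' ties broken toward the lowest state index) and attaches forward-backward
#' posterior state probabilities per visit.
#'
#' @param model an `ms_hmm`.
#' @param scores score table (as in [fit_hmm()]).
#' @return a `data.frame` with `patient_id`, `month`, decoded `state`,
#'   `max_posterior`, and per-state posterior columns `p_state_<s>`.
#' @export
viterbi_decode <- function(model, scores) {
  seqs <- as_score_sequences(scores)
  if (nrow(seqs$X) == 0L)
    return(data.frame(patient_id = character(0), month = integer(0),
                      state = integer(0), max_posterior = numeric(0)))
  if (ncol(seqs$X) != ncol(model$means))
    stop("score dimension does not match the model")
  K <- ncol(seqs$X)
  cube <- array(unlist(model$covs), dim = c(K, K, model$n_states))
  logB <- cpp_gauss_logdens(seqs$X, model$means, cube)
  lpi <- log(model$initial); lA <- log(model$transition)
  path <- cpp_viterbi(logB, lpi, lA, seqs$lengths)
  fb <- cpp_forward_backward(logB, lpi, lA, seqs$lengths)
  post <- fb$gamma
  colnames(post) <- paste0("p_state_", seq_len(model$n_states))
  out <- data.frame(patient_id = seqs$patient_id, month = seqs$month,
                    state = as.integer(path),
                    max_posterior = apply(post, 1, max))
  cbind(out, as.data.frame(post))
}

#' @export
print.ms_hmm <- function(x, digits = 3, ...) {
  cat(sprintf("Gaussian HMM: %d states, %d-dimensional emissions\n",
              x$n_states, ncol(x$means)))
  cat(sprintf("  log-likelihood %.2f on %d visits (%d patients); %s after %d EM iterations\n",
              x$log_likelihood, x$n_visits, x$n_sequences,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat("  transition matrix:\n")
  print(round(x$transition, digits))
  invisible(x)
}
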