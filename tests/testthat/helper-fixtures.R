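# Shared fixtures: small cohorts and hand-built model objects.

small_config <- function(n_patients = 60L, n_months = 12L, ...) {
  default_config(n_patients = n_patients, n_months = n_months, ...)
}

complete_config <- function(...) {
  cfg <- small_config(...)
  cfg$missing_rates[] <- 0
  cfg
}

# a hand-specified two-state HMM used by the exact-oracle tests
toy_hmm <- function() {
  structure(list(
    n_states = 2L,
    initial = c(0.6, 0.4),
    transition = matrix(c(0.7, 0.3, 0.2, 0.8), 2, byrow = TRUE),
    means = matrix(c(-1, 0, 1, 0.5), 2, byrow = TRUE),
    covs = list(diag(c(0.5, 0.8)), matrix(c(1, 0.3, 0.3, 0.6), 2)),
    log_likelihood = NA_real_, n_params = 11L, converged = TRUE,
    n_visits = 0L, n_sequences = 0L, dimensions = c("d1", "d2")
  ), class = "ms_hmm")
}

# brute-force HMM log-likelihood by enumerating all state paths
brute_loglik <- function(model, X) {
  S <- model$n_states
  T_ <- nrow(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  total <- -Inf
  for (i in seq_len(nrow(paths))) {
    p <- paths[i, ]
    lp <- log(model$initial[p[1]])
    if (T_ > 1) for (t in 2:T_) lp <- lp + log(model$transition[p[t - 1], p[t]])
    for (t in seq_len(T_))
      lp <- lp + mvn_logdens(X[t, ], model$means[p[t], ], model$covs[[p[t]]])
    total <- logsum2(total, lp)
  }
  total
}

# brute-force Viterbi path by enumeration (ties toward lexicographically
# smallest path, matching the lowest-state-index tie-break)
brute_viterbi <- function(model, X) {
  S <- model$n_states
  T_ <- nrow(X)
  grid <- expand.grid(rep(list(seq_len(S)), T_))
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  paths <- as.matrix(grid)
  best <- NULL; best_lp <- -Inf
  for (i in seq_len(nrow(paths))) {
    p <- paths[i, ]
    lp <- log(model$initial[p[1]])
    if (T_ > 1) for (t in 2:T_) lp <- lp + log(model$transition[p[t - 1], p[t]])
    for (t in seq_len(T_))
      lp <- lp + mvn_logdens(X[t, ], model$means[p[t], ], model$covs[[p[t]]])
    if (lp > best_lp + 1e-12) { best_lp <- lp; best <- p }
  }
  as.integer(best)
}

mvn_logdens <- function(x, mu, S) {
  k <- length(x)
  -0.5 * (k * log(2 * pi) + determinant(S)$modulus[1] +
            mahalanobis(matrix(x, 1), mu, S))
}

logsum2 <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(m)
  m + log(exp(a - m) + exp(b - m))
}

score_table <- function(X, lengths, dims = paste0("d", seq_len(ncol(X)))) {
  colnames(X) <- dims
  month <- if (length(lengths))
    unlist(lapply(lengths, function(l) seq_len(l) - 1L)) else integer(0)
  data.frame(patient_id = rep(sprintf("P%03d", seq_along(lengths)), lengths),
             month = month, X, check.names = FALSE)
}

# hand-computed product-limit estimator (independent oracle for the KM path)
manual_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = tt, surv = out)
}
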