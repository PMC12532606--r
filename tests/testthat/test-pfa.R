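make_sparse_data <- function(n, lambda, psi, seed = 1) {
  set.seed(seed)
  K <- ncol(lambda)
  eta <- matrix(rnorm(n * K), n, K)
  X <- eta %*% t(lambda) +
    matrix(rnorm(n * nrow(lambda)), n) %*% diag(sqrt(psi))
  colnames(X) <- rownames(lambda)
  X
}

test_that("a known sparse 2-factor structure is recovered", {
  lam <- matrix(0, 8, 2, dimnames = list(paste0("f", 1:8), NULL))
  lam[1:4, 1] <- c(0.9, 0.8, 0.7, 0.6)
  lam[5:8, 2] <- c(0.9, -0.8, 0.7, 0.6)
  psi <- rep(0.05, 8)
  X <- make_sparse_data(3000, lam, psi, seed = 11)
  fit <- fit_pfa(X, restarts = 3, seed = 1)
  expect_equal(fit$active_dimensions, 2L)
  # match columns by absolute correlation of loadings, fix signs
  L <- fit$loadings
  sc <- diag(fit$feature_scaling$scale)   # loadings are on standardized scale
  L_raw <- sc %*% L
  for (k in 1:2) {
    j <- which.max(abs(L_raw[, k]))
    tru <- lam[, which.max(abs(lam[j, ]))]
    if (sum(L_raw[, k] * tru) < 0) L_raw[, k] <- -L_raw[, k]
    expect_lt(max(abs(L_raw[, k] - tru)), 0.1)
  }
})

test_that("independent noise yields zero active dimensions", {
  set.seed(12)
  X <- matrix(rnorm(5000 * 8), ncol = 8)
  colnames(X) <- paste0("f", 1:8)
  fit <- fit_pfa(X, restarts = 2, seed = 2)
  expect_equal(fit$active_dimensions, 0L)
})

test_that("a duplicated feature collapses to a single dimension", {
  set.seed(13)
  z <- rnorm(400)
  X <- matrix(rep(z, 8), ncol = 8) + matrix(rnorm(3200, sd = 0.02), ncol = 8)
  colnames(X) <- paste0("f", 1:8)
  fit <- fit_pfa(X, restarts = 2, seed = 3)
  expect_equal(fit$active_dimensions, 1L)
  expect_true(all(fit$inclusion_prob[, 1] > 0.5))
})

test_that("the penalized EM objective is monotone", {
  cfg <- complete_config(n_patients = 300L, n_months = 1L)
  co <- generate_cohort(cfg, seed = 14)
  fit <- fit_pfa(baseline_matrix(co, cfg), restarts = 1, seed = 4)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) > -1e-8 * (abs(tr[-length(tr)]) + 1)))
})

test_that("flipping a feature's sign flips only its loading row", {
  lam <- matrix(0, 6, 2, dimnames = list(paste0("f", 1:6), NULL))
  lam[1:3, 1] <- 0.8; lam[4:6, 2] <- 0.8
  X <- make_sparse_data(2000, lam, rep(0.1, 6), seed = 15)
  f1 <- fit_pfa(X, restarts = 1, seed = 5)
  X2 <- X; X2[, 2] <- -X2[, 2]
  f2 <- fit_pfa(X2, restarts = 1, seed = 5)
  # align columns then compare: row 2 flips, all others agree
  match_col <- function(L, ref) {
    sapply(seq_len(ncol(ref)), function(k) which.max(abs(cor(L, ref[, k]))))
  }
  expect_equal(f1$active_dimensions, f2$active_dimensions)
  L1 <- f1$loadings; L2 <- f2$loadings
  for (k in seq_len(ncol(L1))) {
    kk <- which.max(abs(colSums(L2 * L1[, k])))
    s <- sign(sum(L2[, kk] * L1[, k]))
    d <- L1[, k] - s * L2[, kk]
    d[2] <- L1[2, k] + s * L2[2, kk]     # row 2 expected sign-flipped
    expect_lt(max(abs(d)), 0.05)
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  X <- matrix(rnorm(200), ncol = 4)
  colnames(X) <- paste0("f", 1:4)
  Xb <- X; Xb[3, 2] <- Inf
  expect_error(fit_pfa(Xb), "non-finite")
  Xz <- X; Xz[, 3] <- 2
  expect_error(fit_pfa(Xz), "f3")
})

test_that("exact-boundary inclusion probabilities do not assign a feature", {
  m <- structure(list(
    loadings = matrix(c(0.8, 0.4), 2, 1, dimnames = list(c("edss", "nhpt"), NULL)),
    inclusion_prob = matrix(c(0.9, 0.5), 2, 1,
                            dimnames = list(c("edss", "nhpt"), NULL))
  ), class = "ms_pfa")
  a <- assign_dimensions(m, feature_names = c("edss", "nhpt"))
  expect_equal(a$assignments$edss, "disability")
  expect_length(a$assignments$nhpt, 0)    # 0.5 exactly is excluded
})

test_that("dimension labels follow the clinical signature rules", {
  cfg <- complete_config(n_patients = 1200L, n_months = 1L)
  co <- generate_cohort(cfg, seed = 16)
  fit <- fit_pfa(baseline_matrix(co, cfg), restarts = 3, seed = 6,
                 link_tags = cfg$feature_links)
  labs <- fit$dimension_labels
  expect_true(all(c("disability", "brain_damage", "relapse",
                    "asymptomatic_activity") %in% labs))
  a <- fit$assignments
  expect_true("disability" %in% unlist(a[c("edss", "t25fwt", "nhpt")]))
  expect_true(all(c("t2_volume", "nbv") %in%
                    names(Filter(function(x) "brain_damage" %in% x, a))))
  expect_true("relapse" %in% a$relapse)
  expect_true("asymptomatic_activity" %in% a$gd_count)
})

test_that("visit scores reproduce the Gaussian posterior", {
  # noiseless square loading: scores invert the loadings exactly
  lam <- diag(c(1, 0.5))
  m <- structure(list(
    loadings = matrix(lam, 2, 2, dimnames = list(c("a", "b"), c("d1", "d2"))),
    uniquenesses = c(a = 1e-10, b = 1e-10),
    feature_scaling = list(center = c(a = 0, b = 0), scale = c(a = 1, b = 1)),
    link_tags = NULL, active_dimensions = 2L
  ), class = "ms_pfa")
  X <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  sc <- score_visits(m, X)
  eta_hat <- as.matrix(sc[, c("d1", "d2")])
  expect_equal(unname(eta_hat), unname(X %*% t(solve(lam))), tolerance = 1e-6)
  # zero input maps to zero posterior mean
  sc0 <- score_visits(m, matrix(0, 1, 2, dimnames = list(NULL, c("a", "b"))))
  expect_equal(as.numeric(sc0[, c("d1", "d2")]), c(0, 0))

  # with noise, score RMSE stays within the analytic posterior s.d.
  lam2 <- matrix(0, 6, 2); lam2[1:3, 1] <- 0.9; lam2[4:6, 2] <- 0.9
  rownames(lam2) <- paste0("f", 1:6)
  psi <- rep(0.05, 6)
  set.seed(17)
  eta <- matrix(rnorm(4000), ncol = 2)
  X2 <- eta %*% t(lam2) + matrix(rnorm(12000, sd = sqrt(0.05)), ncol = 6)
  colnames(X2) <- rownames(lam2)
  m2 <- structure(list(
    loadings = lam2, uniquenesses = setNames(psi, rownames(lam2)),
    feature_scaling = list(center = setNames(rep(0, 6), rownames(lam2)),
                           scale = setNames(rep(1, 6), rownames(lam2))),
    link_tags = NULL, active_dimensions = 2L
  ), class = "ms_pfa")
  sc2 <- score_visits(m2, X2)
  V <- attr(sc2, "posterior_cov")
  rmse <- sqrt(mean((as.matrix(sc2[, 3:4]) - eta)^2))
  expect_lt(rmse, sqrt(mean(diag(V))) * 1.1)
})

test_that("scoring rejects incomplete visits, naming offenders", {
  cfg <- small_config(n_patients = 6L, n_months = 3L)
  co <- generate_cohort(cfg, seed = 18)
  coc <- generate_cohort(complete_config(n_patients = 200L, n_months = 2L), seed = 18)
  fit <- fit_pfa(baseline_matrix(coc, cfg), restarts = 1, seed = 7,
                 link_tags = cfg$feature_links)
  expect_error(score_visits(fit, co, cfg), "missing features")
})

test_that("loading models serialize to JSON and back", {
  cfg <- complete_config(n_patients = 400L, n_months = 1L)
  co <- generate_cohort(cfg, seed = 19)
  fit <- fit_pfa(baseline_matrix(co, cfg), restarts = 1, seed = 8,
                 link_tags = cfg$feature_links)
  f <- tempfile(fileext = ".json")
  write_loading_model(fit, f)
  back <- read_loading_model(f)
  expect_equal(back$loadings, fit$loadings, tolerance = 1e-12)
  expect_equal(back$uniquenesses, fit$uniquenesses, tolerance = 1e-12)
  expect_equal(back$dimension_labels, fit$dimension_labels)
  sc1 <- score_visits(fit, generate_cohort(cfg, seed = 20), cfg)
  sc2 <- score_visits(back, generate_cohort(cfg, seed = 20), cfg)
  expect_equal(sc1[[3]], sc2[[3]], tolerance = 1e-10)
  unlink(f)
})
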