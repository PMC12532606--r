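# Sparse probabilistic factor analysis with a spike-and-slab prior built from
# two Laplace components and an Indian-buffet-process column-inclusion
# penalty (finite truncation). MAP estimation by EM: the E-step integrates
# factor scores (Gaussian) and spike/slab responsibilities exactly; the
# M-step solves a responsibility-weighted L1 problem for each loading row by
# coordinate descent, with closed-form uniqueness and inclusion-weight
# updates. The penalized observed-data objective is monotone across
# iterations.

#' Extract the per-patient baseline feature matrix
#'
#' Baseline is each patient's first visit at which all model features are
#' observed. Features are returned on the modelling (link) scale: log for
#' times/volumes, log1p for counts, identity otherwise.
#'
#' @param cohort cohort table.
#' @param config configuration carrying `features` and `feature_links`.
#' @return numeric matrix (patients x features), rownames = patient ids.
#' @export
baseline_matrix <- function(cohort, config = default_config()) {
  feats <- config$features
  ok <- complete.cases(cohort[, feats, drop = FALSE])
  cb <- cohort[ok, , drop = FALSE]
  cb <- cb[order(cb$patient_id, cb$month), , drop = FALSE]
  cb <- cb[!duplicated(cb$patient_id), , drop = FALSE]
  cb <- transform_features(cb, config)
  m <- as.matrix(cb[, feats, drop = FALSE])
  rownames(m) <- cb$patient_id
  m
}

pfa_objective <- function(X, lambda, psi, nu, spike, slab, a_ibp) {
  n <- nrow(X); p <- ncol(X)
  Sigma <- lambda %*% t(lambda) + diag(psi, p)
  R <- chol(Sigma)
  logdet <- 2 * sum(log(diag(R)))
  Q <- backsolve(R, t(X), transpose = TRUE)      # R^T Q = X^T
  quad <- sum(Q^2)
  ll <- -0.5 * n * (p * log(2 * pi) + logdet) - 0.5 * quad
  f0 <- dlaplace(lambda, spike); f1 <- dlaplace(lambda, slab)
  mix <- sweep(f1, 2, nu, "*") + sweep(f0, 2, 1 - nu, "*")
  pen <- sum(log(mix)) + sum((a_ibp - 1) * log(nu))
  ll + pen
}

dlaplace <- function(x, b) exp(-abs(x) / b) / (2 * b)

#' Fit the sparse probabilistic factor analysis
#'
#' MAP/EM estimation of the Gaussian factor model `x = Lambda eta + eps`,
#' `eta ~ N(0, I)`, `eps ~ N(0, diag(psi))`, under a spike-and-slab prior with
#' Laplace components on each loading (spike scale `spike`, slab scale
#' `slab`) and a finite-truncation Indian buffet process prior
#' (`Beta(alpha / k_max, 1)`) on the per-column inclusion weights. Each
#' loading's posterior probability of the slab component is reported;
#' columns in which no entry exceeds inclusion probability 0.5 are pruned,
#' and the number of surviving columns is the estimated number of composite
#' dimensions. The best of `restarts` seeded initializations (SVD-based,
#' jittered) by penalized objective is returned; every retained column is
#' oriented so that its largest-magnitude loading is positive.
#'
#' @param x complete numeric matrix (observations x features) on the
#'   modelling scale, e.g. from [baseline_matrix()]. Standardized internally
#'   (centering/scaling stored in the fit).
#' @param k_max truncation level for the number of candidate dimensions.
#' @param spike,slab Laplace scales of the spike and slab components
#'   (standardized-loading units).
#' @param alpha IBP concentration.
#' @param restarts number of seeded initializations.
#' @param seed master seed.
#' @param max_iter,tol EM cap and relative objective tolerance.
#' @param link_tags optional named per-feature observation-model tags carried
#'   into the fit for downstream scoring.
#' @return an object of class `ms_pfa`: `loadings` (features x active dims),
#'   `inclusion_prob`, `uniquenesses`, `active_dimensions`,
#'   `feature_scaling` (`center`, `scale`), `dimension_labels`, `objective`,
#'   `objective_trace`, `converged`.
#' @export
fit_pfa <- function(x, k_max = 10L, spike = 0.01, slab = 1.0, alpha = 1.0,
                    restarts = 10L, seed = 1L, max_iter = 500L, tol = 1e-8,
                    link_tags = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("fit_pfa: input contains non-finite values")
  p <- ncol(x); n <- nrow(x)
  feat <- colnames(x) %||% paste0("f", seq_len(p))
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  bad <- which(scl < 1e-12)
  if (length(bad))
    stop("fit_pfa: zero-variance feature(s): ", paste(feat[bad], collapse = ", "))
  X <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  a_ibp <- alpha / k_max

  # initialize at varimax-rotated principal-component loadings: EM with the
  # bistable spike/slab weights is basin-sensitive, and the rotated solution
  # starts near the sparse representation when one exists
  sv <- svd(X, nu = 0, nv = min(p, k_max))
  eigvals <- sv$d[seq_len(ncol(sv$v))]^2 / n
  keep0 <- which(eigvals > 0.7)         # Jolliffe's relaxed Kaiser criterion
  if (!length(keep0)) keep0 <- 1L
  L0 <- matrix(0, p, k_max)
  L0[, keep0] <- sv$v[, keep0, drop = FALSE] %*%
    diag(sv$d[keep0] / sqrt(n), length(keep0))
  if (length(keep0) >= 2) {
    # near-degenerate eigenvalues make the PC basis an arbitrary rotation and
    # varimax from the identity can stall in a local optimum; restart it from
    # seeded random rotations and keep the best simple-structure criterion
    set.seed(as.integer(seed))
    B <- L0[, keep0, drop = FALSE]
    vari_crit <- function(L) sum(apply(L^2, 2, var))
    best_rot <- B; best_c <- -Inf
    for (t in 1:15) {
      R0 <- if (t == 1) diag(length(keep0)) else
        qr.Q(qr(matrix(rnorm(length(keep0)^2), length(keep0))))
      vm <- stats::varimax(B %*% R0, normalize = FALSE)
      cand <- B %*% R0 %*% vm$rotmat
      if (vari_crit(cand) > best_c) { best_c <- vari_crit(cand); best_rot <- cand }
    }
    L0[, keep0] <- best_rot
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(as.integer(seed) + 104729L * (r - 1L))
    lambda <- L0 + if (r == 1L) 0 else matrix(rnorm(p * k_max, 0, 0.1), p, k_max)
    fit <- pfa_em_run(X, lambda, spike, slab, a_ibp, max_iter, tol)
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }

  # absorption pass: a column whose variance contribution the uniquenesses
  # can carry at equal likelihood but lower prior cost (single-feature or
  # noise-locked columns) is zeroed out; accepted only on objective gain
  repeat {
    improved <- FALSE
    for (k in which(colSums(abs(best$lambda)) > 0)) {
      lam2 <- best$lambda; psi2 <- best$psi + lam2[, k]^2; lam2[, k] <- 0
      obj2 <- pfa_objective(X, lam2, psi2, best$nu, spike, slab, a_ibp)
      if (obj2 > best$objective) {
        best$lambda <- lam2; best$psi <- psi2; best$objective <- obj2
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  f0 <- dlaplace(best$lambda, spike); f1 <- dlaplace(best$lambda, slab)
  num <- sweep(f1, 2, best$nu, "*")
  best$inclusion <- num / (num + sweep(f0, 2, 1 - best$nu, "*"))

  r_incl <- best$inclusion
  keep <- which(apply(r_incl, 2, max) > 0.5)
  lambda <- best$lambda[, keep, drop = FALSE]
  r_incl <- r_incl[, keep, drop = FALSE]
  for (k in seq_along(keep)) {        # sign convention
    j <- which.max(abs(lambda[, k]))
    if (lambda[j, k] < 0) lambda[, k] <- -lambda[, k]
  }
  rownames(lambda) <- rownames(r_incl) <- feat
  model <- structure(list(
    loadings = lambda,
    inclusion_prob = r_incl,
    uniquenesses = setNames(best$psi, feat),
    active_dimensions = length(keep),
    feature_scaling = list(center = setNames(ctr, feat),
                           scale = setNames(scl, feat)),
    link_tags = link_tags,
    k_max = k_max, spike = spike, slab = slab, alpha = alpha,
    objective = best$objective, objective_trace = best$trace,
    converged = best$converged, n = n
  ), class = "ms_pfa")
  lab <- assign_dimensions(model)
  # anchor labelled columns to their canonical clinical direction (EDSS up =
  # more disability, T2 up = more damage, ...): the magnitude rule alone is
  # unstable when two marker features load near-equally with opposite signs
  markers <- c(disability = "edss", brain_damage = "t2_volume",
               relapse = "relapse", asymptomatic_activity = "gd_count")
  for (k in seq_along(lab$labels)) {
    mk <- markers[lab$labels[k]]
    if (!is.na(mk) && model$loadings[mk, k] < 0)
      model$loadings[, k] <- -model$loadings[, k]
  }
  colnames(model$loadings) <- colnames(model$inclusion_prob) <- lab$labels
  model$dimension_labels <- lab$labels
  model$assignments <- lab$assignments
  model
}

pfa_em_run <- function(X, lambda, spike, slab, a_ibp, max_iter, tol) {
  n <- nrow(X); p <- ncol(X); K <- ncol(lambda)
  psi <- rep(0.5, p)
  nu <- rep(0.5, K)
  sxx <- colSums(X^2)
  obj_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step: factor scores
    PsiInvL <- lambda / psi
    V <- solve(diag(1, K) + crossprod(lambda, PsiInvL))
    V <- (V + t(V)) / 2
    Eeta <- X %*% (PsiInvL %*% V)           # n x K
    S_ee <- n * V + crossprod(Eeta)         # sum E[eta eta^T]
    S_xe <- crossprod(X, Eeta)              # p x K
    # E-step: spike/slab responsibilities
    f0 <- dlaplace(lambda, spike); f1 <- dlaplace(lambda, slab)
    num <- sweep(f1, 2, nu, "*")
    rr <- num / (num + sweep(f0, 2, 1 - nu, "*"))
    w <- rr / slab + (1 - rr) / spike       # weighted-L1 penalty weights

    # M-step: loadings, row-wise coordinate descent (exact for the bound)
    for (j in seq_len(p)) {
      lj <- lambda[j, ]
      for (sweep_i in 1:8) {
        delta <- 0
        for (k in seq_len(K)) {
          rho <- S_xe[j, k] - sum(S_ee[k, -k] * lj[-k])
          new <- sign(rho) * max(abs(rho) - psi[j] * w[j, k], 0) / S_ee[k, k]
          delta <- delta + abs(new - lj[k])
          lj[k] <- new
        }
        if (delta < 1e-10) break
      }
      lambda[j, ] <- lj
    }
    # M-step: uniquenesses and inclusion weights
    for (j in seq_len(p)) {
      lj <- lambda[j, ]
      psi[j] <- max((sxx[j] - 2 * sum(lj * S_xe[j, ]) +
                       drop(lj %*% S_ee %*% lj)) / n, 1e-6)
    }
    nu <- pmin(pmax((colSums(rr) + a_ibp - 1) / (p + a_ibp - 1), 1e-4), 1 - 1e-4)

    obj <- pfa_objective(X, lambda, psi, nu, spike, slab, a_ibp)
    trace <- c(trace, obj)
    if (is.finite(obj_prev) && abs(obj - obj_prev) < tol * (abs(obj_prev) + 1)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  # final responsibilities at the returned parameters
  f0 <- dlaplace(lambda, spike); f1 <- dlaplace(lambda, slab)
  num <- sweep(f1, 2, nu, "*")
  rr <- num / (num + sweep(f0, 2, 1 - nu, "*"))
  list(lambda = lambda, psi = psi, nu = nu, inclusion = rr,
       objective = obj, trace = trace, converged = converged)
}

#' Map features to composite dimensions and label the dimensions
#'
#' A feature belongs to a dimension iff its posterior slab-inclusion
#' probability exceeds 0.5 (strictly). Dimensions are auto-labelled from
#' their feature signature, in priority order: a dimension including the
#' relapse flag is `relapse`; including the Gd lesion count (without relapse)
#' is `asymptomatic_activity`; including EDSS/T25FWT/9HPT is `disability`;
#' including T2 volume or brain volume is `brain_damage`; otherwise
#' `unassigned`. Duplicate labels are suffixed by rank of total absolute
#' loading.
#'
#' @param model an `ms_pfa`.
#' @param feature_names optional feature names overriding the fit's.
#' @return list with `labels` (per retained dimension) and `assignments`
#'   (named list: feature -> character vector of dimension labels).
#' @export
assign_dimensions <- function(model, feature_names = rownames(model$loadings)) {
  r <- model$inclusion_prob
  L <- model$loadings
  rownames(r) <- rownames(L) <- feature_names
  K <- ncol(r)
  sig <- list(relapse = "relapse",
              asymptomatic_activity = "gd_count",
              disability = c("edss", "t25fwt", "nhpt"),
              brain_damage = c("t2_volume", "nbv"))
  # signature strength of each column for each label: total |loading| over
  # the label's included signature features
  strength <- function(lbl, k) {
    f <- intersect(sig[[lbl]], feature_names)
    sum(abs(L[f, k]) * (r[f, k] > 0.5))
  }
  labels <- rep(NA_character_, K)
  # canonical labels claimed greedily in priority order; when several columns
  # include a signature feature, the column loading it most strongly wins and
  # the others fall through to their next signature
  for (lbl in names(sig)) {
    cand <- which(is.na(labels))
    cand <- cand[vapply(cand, function(k) strength(lbl, k) > 0, TRUE)]
    if (!length(cand)) next
    win <- cand[which.max(vapply(cand, function(k) strength(lbl, k), 1))]
    labels[win] <- lbl
  }
  # leftovers: per-column priority cascade, suffixed when duplicating
  for (k in which(is.na(labels))) {
    fk <- feature_names[r[, k] > 0.5]
    labels[k] <-
      if ("relapse" %in% fk) "relapse"
      else if ("gd_count" %in% fk) "asymptomatic_activity"
      else if (any(c("edss", "t25fwt", "nhpt") %in% fk)) "disability"
      else if (any(c("t2_volume", "nbv") %in% fk)) "brain_damage"
      else "unassigned"
  }
  labels <- make.unique(labels, sep = "_")
  assignments <- lapply(setNames(feature_names, feature_names),
                        function(f) labels[which(r[f, ] > 0.5)])
  list(labels = labels, assignments = assignments)
}

#' Compute per-visit composite scores under a fitted loading model
#'
#' Posterior mean (and shared posterior covariance) of the factor scores
#' given the loadings and uniquenesses, in the ridge-regression form
#' `E[eta | x] = (I + L' Psi^-1 L)^-1 L' Psi^-1 x` on the standardized
#' feature scale. Visits must be complete on the model's features
#' (impute first; see [impute_partial_visits()]).
#'
#' @param model an `ms_pfa`.
#' @param visits cohort table with complete feature columns, or a numeric
#'   matrix already on the modelling scale.
#' @param config configuration supplying `feature_links` when `visits` is a
#'   cohort table and the fit carries no `link_tags`.
#' @return a `data.frame` (`patient_id`, `month`, one column per composite
#'   dimension) with attributes `posterior_cov` (K x K) and `posterior_var`.
#' @export
score_visits <- function(model, visits, config = NULL) {
  feats <- rownames(model$loadings)
  if (is.matrix(visits)) {
    M <- visits[, feats, drop = FALSE]
    ids <- rownames(visits) %||% as.character(seq_len(nrow(visits)))
    months <- rep(0L, nrow(visits))
  } else {
    miss <- !complete.cases(visits[, feats, drop = FALSE])
    if (any(miss))
      stop("score_visits: missing features after imputation in rows: ",
           paste(utils::head(which(miss), 10), collapse = ", "))
    links <- model$link_tags
    tcfg <- if (!is.null(config)) config else
      list(features = feats,
           feature_links = links %||% default_config()$feature_links)
    tv <- transform_features(visits, tcfg)
    M <- as.matrix(tv[, feats, drop = FALSE])
    ids <- visits$patient_id
    months <- visits$month
  }
  X <- sweep(sweep(M, 2, model$feature_scaling$center[feats]), 2,
             model$feature_scaling$scale[feats], "/")
  L <- model$loadings
  K <- ncol(L)
  if (K == 0L) {
    out <- data.frame(patient_id = ids, month = months)
    attr(out, "posterior_cov") <- matrix(0, 0, 0)
    return(out)
  }
  psi <- model$uniquenesses[feats]
  PsiInvL <- L / psi
  V <- solve(diag(1, K) + crossprod(L, PsiInvL))
  V <- (V + t(V)) / 2
  Eeta <- X %*% (PsiInvL %*% V)
  colnames(Eeta) <- colnames(L)
  out <- data.frame(patient_id = ids, month = months,
                    Eeta, check.names = FALSE)
  attr(out, "posterior_cov") <- V
  attr(out, "posterior_var") <- diag(V)
  out
}

#' @export
print.ms_pfa <- function(x, digits = 2, ...) {
  cat(sprintf("Sparse probabilistic factor analysis: %d active dimension(s) of %d candidates (n = %d)\n",
              x$active_dimensions, x$k_max, x$n))
  if (x$active_dimensions > 0) {
    cat("  loadings (included entries marked *):\n")
    L <- round(x$loadings, digits)
    marks <- ifelse(x$inclusion_prob > 0.5, "*", " ")
    disp <- matrix(paste0(format(L), marks), nrow(L), ncol(L),
                   dimnames = dimnames(L))
    print(disp, quote = FALSE)
  }
  invisible(x)
}

#' Serialize / restore a loading model as JSON
#'
#' @param model an `ms_pfa`.
#' @param path file path.
#' @return `write_loading_model()` returns `path` invisibly;
#'   `read_loading_model()` the restored `ms_pfa`.
#' @export
write_loading_model <- function(model, path) {
  obj <- list(
    loadings = model$loadings, inclusion_prob = model$inclusion_prob,
    uniquenesses = as.list(model$uniquenesses),
    feature_names = rownames(model$loadings),
    dimension_labels = model$dimension_labels,
    center = as.list(model$feature_scaling$center),
    scale = as.list(model$feature_scaling$scale),
    link_tags = as.list(model$link_tags %||% list()),
    active_dimensions = model$active_dimensions,
    k_max = model$k_max, spike = model$spike, slab = model$slab,
    alpha = model$alpha, objective = model$objective, n = model$n)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_loading_model
#' @export
read_loading_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lam <- matrix(unlist(obj$loadings), nrow = length(obj$feature_names),
                dimnames = list(obj$feature_names, obj$dimension_labels))
  ip <- matrix(unlist(obj$inclusion_prob), nrow = length(obj$feature_names),
               dimnames = list(obj$feature_names, obj$dimension_labels))
  structure(list(
    loadings = lam, inclusion_prob = ip,
    uniquenesses = unlist(obj$uniquenesses),
    active_dimensions = obj$active_dimensions,
    feature_scaling = list(center = unlist(obj$center),
                           scale = unlist(obj$scale)),
    link_tags = if (length(obj$link_tags)) unlist(obj$link_tags) else NULL,
    k_max = obj$k_max, spike = obj$spike, slab = obj$slab, alpha = obj$alpha,
    objective = obj$objective, dimension_labels = obj$dimension_labels,
    n = obj$n, converged = TRUE
  ), class = "ms_pfa")
}
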