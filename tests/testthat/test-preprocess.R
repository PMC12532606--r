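test_that("grid mapping follows the rounding rule and merges collisions", {
  mk <- function(day, edss = 2, relapse = 0) {
    data.frame(day = day, patient_id = "P1", edss = edss, relapse = relapse,
               obs_edss = 1L, obs_relapse = 1L)
  }
  expect_equal(map_to_grid(mk(0))$month, 0L)
  expect_equal(map_to_grid(mk(183), interval_months = 6L)$month, 6L)

  two <- rbind(mk(29, edss = 2), mk(33, edss = NA))
  g <- map_to_grid(two)
  expect_equal(nrow(g), 1L)
  expect_equal(g$month, 1L)
  expect_equal(g$edss, 2)          # non-missing preferred in the merge

  # ties on the same feature resolve toward the relapse (unscheduled) visit
  tie <- rbind(mk(29, edss = 2, relapse = 0), mk(33, edss = 4.5, relapse = 1))
  g <- map_to_grid(tie)
  expect_equal(g$edss, 4.5)
  expect_equal(g$relapse, 1)       # relapse flags OR-ed

  expect_error(map_to_grid(mk(-3)), "negative")
})

test_that("grid mapping is idempotent on gridded data", {
  cfg <- complete_config(n_patients = 10L, n_months = 8L)
  co <- generate_cohort(cfg, seed = 1)
  g1 <- map_to_grid(co)
  expect_equal(g1$month, co[order(co$patient_id, co$month), "month"])
  g2 <- map_to_grid(g1)
  expect_equal(g2$edss, g1$edss)
})

test_that("jittered raw days map back to the generating grid", {
  cfg <- complete_config(n_patients = 25L, n_months = 10L)
  co <- generate_cohort(cfg, seed = 2)
  raw <- ungrid_cohort(co, seed = 3)
  g <- map_to_grid(raw)
  m <- merge(co, g, by = c("patient_id", "month"))
  expect_gt(nrow(m) / nrow(co), 0.95)      # near-total grid agreement
  expect_equal(m$edss.x, m$edss.y)
})

test_that("imputation reproduces exact trends and alters nothing observed", {
  months <- 0:11
  lin <- 1.40 + 0.005 * months           # exact linear NBV decline
  co <- data.frame(patient_id = "P1", month = months, edss = 2, nbv = lin,
                   relapse = 0, obs_edss = 1L, obs_nbv = 1L, obs_relapse = 1L)
  gap <- co; gap$nbv[6] <- NA; gap$obs_nbv[6] <- 0L
  cfg <- default_config()
  out <- impute_partial_visits(gap, cfg)
  expect_equal(out$nbv[6], lin[6], tolerance = 1e-6)
  expect_equal(out$nbv[-6], lin[-6])          # observed cells untouched
  expect_equal(out$imp_nbv, as.integer(seq_along(months) == 6))

  # fully observed input comes back unchanged
  out2 <- impute_partial_visits(co, cfg)
  expect_equal(out2$nbv, co$nbv)
  expect_true(all(out2$imp_nbv == 0L))

  # constant series with a gap imputes the constant
  con <- gap; con$nbv <- 1.5; con$nbv[6] <- NA
  expect_equal(impute_partial_visits(con, cfg)$nbv[6], 1.5, tolerance = 1e-9)
})

test_that("imputation fills only rows with some other observation", {
  cfg <- small_config(n_patients = 30L, n_months = 12L)
  co <- generate_cohort(cfg, seed = 4)
  out <- impute_partial_visits(co, cfg)
  # every row has observed EDSS/relapse, so all imputable gaps are filled
  # unless the patient never had the feature observed at all
  for (f in c("t25fwt", "pasat")) {
    some <- tapply(!is.na(co[[f]]), co$patient_id, any)
    fixed <- out[out$patient_id %in% names(some)[some], ]
    expect_false(anyNA(fixed[[f]]))
  }
  expect_true(all(out$edss == co[order(co$patient_id, co$month), "edss"]))
})

test_that("holdout imputation error is near zero for noiseless trends and finite by default", {
  months <- 0:17
  co <- do.call(rbind, lapply(1:8, function(i)
    data.frame(patient_id = sprintf("P%d", i), month = months,
               edss = 2, nbv = 1.4 + 0.002 * i * months, relapse = 0,
               obs_edss = 1L, obs_nbv = 1L, obs_relapse = 1L)))
  mae <- evaluate_imputation(co, holdout_fraction = 0.15, seed = 1,
                             config = default_config())
  expect_lt(mae["nbv"], 1e-6)

  cfg <- small_config(n_patients = 40L, n_months = 14L)
  co2 <- generate_cohort(cfg, seed = 5)
  mae2 <- evaluate_imputation(co2, holdout_fraction = 0.1, seed = 2, config = cfg)
  imputable <- c("t25fwt", "nhpt", "pasat", "t2_volume", "nbv", "gd_count")
  expect_true(all(is.finite(mae2[imputable])))
})

test_that("brain volume updates from percent change", {
  expect_equal(update_brain_volume(1.5, 0), 1.5)
  expect_equal(update_brain_volume(1.5, -1.0), 1.485)
  expect_equal(update_brain_volume(1.44, 2.0), 1.4688)
  expect_equal(update_brain_volume(1.5, c(0, -1, -2)), c(1.5, 1.485, 1.47))
  expect_error(update_brain_volume(0, 1), "positive")
  expect_error(update_brain_volume(1.5, -101), "domain")
})

test_that("PIRA derivation applies confirmation and relapse exclusion", {
  months <- 0:23
  flat <- rep(2, 24)
  none <- rep(0, 24)
  expect_null(derive_pira(flat, none, 2))
  expect_error(derive_pira(numeric(0), numeric(0), 2), "empty")

  worse <- c(rep(3, 6), rep(4, 18))      # baseline 3.0, +1.0 from month 6
  ev <- derive_pira(worse, none, 3)
  expect_equal(ev$onset_month, 6)
  expect_true(ev$confirmed)

  rel <- none; rel[6] <- 1               # relapse at onset window
  expect_null(derive_pira(worse, rel, 3))

  # reversible worsening does not count
  rev <- c(rep(3, 6), rep(4, 6), rep(3, 12))
  expect_null(derive_pira(rev, none, 3))

  # baseline-dependent thresholds
  expect_null(derive_pira(c(0, rep(1, 23)), none, 0))       # needs +1.5 from 0
  expect_false(is.null(derive_pira(c(0, rep(1.5, 23)), none, 0)))
  expect_false(is.null(derive_pira(c(6, rep(6.5, 23)), none, 6)))  # +0.5 at 5.5+
})

test_that("PIRA onset shifts month-for-month with the worsening", {
  none <- rep(0, 30)
  for (lag in c(4, 7, 11)) {
    e <- c(rep(2, lag), rep(3.5, 30 - lag))
    ev <- derive_pira(e, none, 2)
    expect_equal(ev$onset_month, lag)
  }
})

test_that("cohort-level PIRA table flags events and censoring", {
  cfg <- complete_config(n_patients = 40L, n_months = 24L)
  co <- generate_cohort(cfg, seed = 6)
  tab <- derive_pira_cohort(co)
  expect_equal(nrow(tab), 40L)
  expect_true(all(tab$followup_months == 23))
  expect_true(all(tab$confirmed %in% c(TRUE, FALSE)))
})

test_that("discovery/holdout split is stratified, seeded and exhaustive", {
  set.seed(1)
  m1 <- matrix(rnorm(40, 0, 0.1), 10, 4)
  sp <- split_discovery_holdout(m1, k = 1, holdout_frac = 0.2, seed = 5)
  expect_equal(sum(sp$set == "holdout"), 2L)
  expect_equal(sum(sp$set == "discovery"), 8L)

  two <- rbind(matrix(0, 20, 4), matrix(5, 20, 4)) +
    matrix(rnorm(160, 0, 0.01), 40, 4)
  rownames(two) <- sprintf("P%02d", 1:40)
  sp2 <- split_discovery_holdout(two, k = 2, holdout_frac = 0.25, seed = 5)
  expect_equal(length(unique(sp2$cluster[1:20])), 1L)   # clusters recovered
  expect_equal(length(unique(sp2$cluster[21:40])), 1L)
  expect_false(sp2$cluster[1] == sp2$cluster[21])
  expect_equal(as.vector(table(sp2$set, sp2$cluster)["holdout", ]), c(5L, 5L))

  expect_identical(split_discovery_holdout(two, 2, 0.25, seed = 5), sp2)
  expect_error(split_discovery_holdout(m1, k = 11, holdout_frac = 0.2, seed = 1),
               "more clusters")
})
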