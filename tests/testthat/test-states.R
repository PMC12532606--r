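# Construct a decoded-path + cohort pair where the decoded states ARE the
# generator's true states; labelling and grouping must then reproduce the
# configured structure.
truth_decoded <- function(co) {
  co <- co[order(co$patient_id, co$month), ]
  data.frame(patient_id = co$patient_id, month = co$month,
             state = co$true_state, max_posterior = 1)
}

truth_hmm <- function(cfg) {
  structure(list(
    n_states = 8L, initial = cfg$initial, transition = cfg$transition,
    means = cfg$state_means, covs = cfg$state_covs,
    dimensions = cfg$dimensions, n_params = 0L,
    log_likelihood = NA_real_, converged = TRUE
  ), class = "ms_hmm")
}

test_that("states are labelled by their clinical score signatures", {
  cfg <- complete_config(n_patients = 400L, n_months = 12L)
  co <- generate_cohort(cfg, seed = 21)
  dec <- truth_decoded(co)
  lab <- label_states(truth_hmm(cfg), decoded = dec, cohort = co)
  expect_equal(lab$role[5], "relapse")
  expect_equal(lab$role[4], "asymptomatic_activity")
  expect_equal(sum(lab$role == "severity"), 6L)
  expect_gt(lab$relapse_prevalence[5], 0.5)
  # severity ranks order the states by disability + brain damage
  sev <- which(lab$role == "severity")
  expect_equal(sev[order(lab$severity_rank[sev])], c(1L, 2L, 3L, 7L, 6L, 8L))
})

test_that("the relapse state has majority relapse visits and the activity state peak Gd", {
  cfg <- complete_config(n_patients = 400L, n_months = 12L)
  co <- generate_cohort(cfg, seed = 22)
  dec <- truth_decoded(co)
  m <- merge(dec, co[, c("patient_id", "month", "relapse", "gd_count")],
             by = c("patient_id", "month"))
  prev <- tapply(m$relapse, m$state, mean)
  expect_gt(prev["5"], 0.5)
  expect_true(all(prev[names(prev) != "5"] < 0.05))
  gd <- tapply(m$gd_count, m$state, mean)
  expect_equal(names(which.max(gd)), "4")
})

test_that("a degenerate two-state severity model labels EME and advanced only", {
  h <- structure(list(
    n_states = 2L, initial = c(.5, .5),
    transition = matrix(c(.9, .1, .01, .99), 2, byrow = TRUE),
    means = matrix(c(-1, 1), 2, 1), covs = list(diag(1), diag(1)),
    dimensions = "disability", n_params = 0L,
    log_likelihood = NA_real_, converged = TRUE
  ), class = "ms_hmm")
  lab <- label_states(h, dim_labels = "disability")
  expect_true(all(lab$role == "severity"))
  map <- group_meta_states(h$transition, lab, epsilon = 0.02)
  expect_equal(map$meta, c("EME", "advanced"))
})

test_that("tied state signatures are flagged as ambiguous", {
  h <- toy_hmm()
  h$means <- matrix(c(1, 1, 1, 1), 2, 2)     # exact tie on every dimension
  h$dimensions <- c("relapse", "disability")
  expect_error(label_states(h, dim_labels = h$dimensions), "ambiguous")
})

test_that("meta-state grouping recovers the configured block structure", {
  cfg <- default_config()
  lab <- label_states(truth_hmm(cfg))
  map <- group_meta_states(cfg$transition, lab, epsilon = 0.005)
  expect_equal(map$meta, cfg$state_meta)
  expect_false(map$warning)
})

test_that("identity dynamics leave all severity states in EME", {
  cfg <- default_config()
  lab <- label_states(truth_hmm(cfg))
  map <- group_meta_states(diag(8), lab, epsilon = 0.005)
  expect_true(all(map$meta[lab$role == "severity"] == "EME"))
})

test_that("an above-threshold EME-to-advanced entry raises the warning flag", {
  cfg <- default_config()
  A <- cfg$transition
  A[1, 8] <- 0.05                      # direct jump into the severest state
  A[1, ] <- A[1, ] / sum(A[1, ])
  lab <- label_states(truth_hmm(cfg))
  map <- group_meta_states(A, lab, epsilon = 0.005)
  expect_true(map$warning)
  expect_gt(map$violation, 0)
})

test_that("meta aggregation is occupancy-weighted and exactly stochastic", {
  cfg <- default_config()
  lab <- label_states(truth_hmm(cfg))
  map <- group_meta_states(cfg$transition, lab)
  # any occupancy reproduces the configured aggregates (identical row
  # profiles within groups); rows stay stochastic
  occ <- c(5, 1, 3, 2, 2, 7, 1, 1)
  ts <- aggregate_meta_transitions(cfg$transition, map, occ)
  M <- ts$meta_transition
  expect_equal(rowSums(M), setNames(rep(1, 4), rownames(M)), tolerance = 1e-12)
  expect_equal(M["relapse", "relapse"], 0.37, tolerance = 1e-12)
  expect_equal(M["relapse", "advanced"], 0.18, tolerance = 1e-12)
  expect_equal(M["asymptomatic_activity", "advanced"], 0.11, tolerance = 1e-12)
  expect_equal(M["asymptomatic_activity", "relapse"], 0.06, tolerance = 1e-12)
  expect_equal(M["EME", "advanced"], 0, tolerance = 1e-12)

  # singleton groups reproduce the raw matrix
  ts1 <- aggregate_meta_transitions(matrix(c(.6, .4, .3, .7), 2, byrow = TRUE),
                                    c("EME", "advanced"), occupancy = c(3, 9))
  expect_equal(unname(ts1$meta_transition),
               matrix(c(.6, .4, .3, .7), 2, byrow = TRUE))
  expect_error(aggregate_meta_transitions(diag(2), c("EME", "advanced"),
                                          occupancy = c(0, 1)), "empty")
})

test_that("permuting state indices permutes but does not change the grouping", {
  cfg <- default_config()
  perm <- c(3, 5, 1, 8, 2, 7, 4, 6)
  A_p <- cfg$transition[perm, perm]
  h <- truth_hmm(cfg)
  h$means <- cfg$state_means[perm, ]
  lab <- label_states(h)
  map <- group_meta_states(A_p, lab)
  expect_equal(map$meta, cfg$state_meta[perm])
})

test_that("state characterization summarizes on the measurement scale", {
  co <- data.frame(patient_id = rep("P1", 6), month = 0:5,
                   edss = c(6, 6, 6, 2, 2, 2), relapse = 0)
  dec <- data.frame(patient_id = rep("P1", 6), month = 0:5,
                    state = c(1, 1, 1, 2, 2, 2))
  ch <- characterize_states(dec, co, features = "edss")
  expect_equal(ch$per_state$edss_mean, c(6, 2))
  expect_equal(ch$per_state$edss_sd, c(0, 0))
  expect_equal(ch$per_state$n_visits, c(3L, 3L))

  # advanced meta-state shows higher EDSS than EME on generated data
  cfg <- complete_config(n_patients = 300L, n_months = 12L)
  cog <- generate_cohort(cfg, seed = 23)
  decg <- truth_decoded(cog)
  map <- group_meta_states(cfg$transition, label_states(truth_hmm(cfg)))
  chg <- characterize_states(decg, cog, map = map)
  pm <- chg$per_meta
  expect_gt(pm$edss_mean[pm$group == "advanced"],
            pm$edss_mean[pm$group == "EME"])
  expect_gt(pm$gd_count_mean[pm$group == "asymptomatic_activity"],
            pm$gd_count_mean[pm$group == "EME"])
})

test_that("zero-visit states yield NA characterization rows", {
  co <- data.frame(patient_id = "P1", month = 0, edss = 3, relapse = 0)
  dec <- data.frame(patient_id = "P1", month = 0, state = 2)
  ch <- characterize_states(dec, co, features = "edss")
  expect_true(is.na(ch$per_state$edss_mean[1]))
  expect_equal(ch$per_state$n_visits[1], 0L)
})

test_that("validation criteria react to dimensions and transition routes", {
  cfg <- default_config()
  lab <- label_states(truth_hmm(cfg))
  map <- group_meta_states(cfg$transition, lab)
  ts <- aggregate_meta_transitions(cfg$transition, map, rep(1, 8))
  good <- check_validation_criteria(
    c("disability", "brain_damage", "relapse", "asymptomatic_activity"),
    map, ts)
  expect_true(good$criterion1)
  expect_true(good$criterion2)

  few <- check_validation_criteria(c("disability", "brain_damage", "relapse"),
                                   map, ts)
  expect_false(few$criterion1)

  M <- ts$meta_transition
  M["EME", "advanced"] <- 0.10
  bad <- ts; bad$meta_transition <- M
  expect_false(check_validation_criteria(
    c("disability", "brain_damage", "relapse", "asymptomatic_activity"),
    map, bad)$criterion2)
})
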