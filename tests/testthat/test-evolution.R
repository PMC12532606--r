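test_that("Kaplan-Meier estimates equal the hand-computed product limit", {
  # toy: events at 2 and 4, censored at 3, 5, 6
  km <- km_time_to_event(c(2, 4, 3, 5, 6), c(1, 1, 0, 0, 0))
  s_at <- km_surv_at(km, c(2, 3, 4))
  expect_equal(unname(s_at), c(0.8, 0.8, 0.8 * (1 - 1 / 3)), tolerance = 1e-10)

  set.seed(31)
  time <- rexp(60, 0.1); event <- rbinom(60, 1, 0.6)
  km2 <- km_time_to_event(time, event)
  oracle <- manual_km(time, event)
  got <- km_surv_at(km2, oracle$time)
  expect_equal(unname(got), oracle$surv, tolerance = 1e-10)
})

test_that("all-censored data give flat survival at one", {
  km <- km_time_to_event(rep(12, 8), rep(0, 8))
  expect_true(all(km$surv == 1))
  expect_error(km_time_to_event(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM strata order survival by baseline severity on generated cohorts", {
  cfg <- complete_config(n_patients = 800L, n_months = 24L)
  co <- generate_cohort(cfg, seed = 32)
  co <- co[order(co$patient_id, co$month), ]
  dec <- data.frame(patient_id = co$patient_id, month = co$month,
                    state = co$true_state)
  map <- structure(list(meta = cfg$state_meta), class = "ms_meta_map")
  pira <- derive_pira_cohort(co)
  base_meta <- cfg$state_meta[co$true_state[co$month == 0]]
  pira$meta <- base_meta[match(pira$patient_id, co$patient_id[co$month == 0])]
  pira$time <- ifelse(pira$confirmed, pira$onset_month, pira$followup_months)
  ok <- pira$time > 0 & pira$meta %in% c("EME", "advanced")
  km <- km_time_to_event(pira$time[ok], as.integer(pira$confirmed[ok]),
                         strata = pira$meta[ok])
  s <- km_surv_at(km, 23)
  expect_gt(s["EME"], s["advanced"])
})

test_that("two-state panel intensities are recovered", {
  set.seed(33)
  q12 <- 0.1
  n <- 400; T_ <- 24
  paths <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- "EME"
    st <- character(T_)
    for (t in seq_len(T_)) {
      st[t] <- s
      if (s == "EME" && runif(1) < 1 - exp(-q12)) s <- "advanced"
    }
    data.frame(patient_id = sprintf("P%03d", i), month = seq_len(T_) - 1,
               meta = st)
  }))
  treated <- setNames(rep(0, n), sprintf("P%03d", seq_len(n)))
  fit <- fit_ctmc(paths, treated, states = c("EME", "advanced"))
  expect_lt(abs(fit$Q["EME", "advanced"] - q12), 0.02)
  expect_equal(rowSums(fit$Q), c(EME = 0, advanced = 0), tolerance = 1e-10)
  expect_true(all(fit$Q[row(fit$Q) != col(fit$Q)] >= 0))
})

test_that("a null treatment effect is estimated near zero with covering CI", {
  cfg <- default_config(n_patients = 600L, n_months = 24L,
                        treatment_multiplier = 1, treated_fraction = 0.5)
  co <- generate_cohort(cfg, seed = 34)
  co <- co[order(co$patient_id, co$month), ]
  paths <- data.frame(patient_id = co$patient_id, month = co$month,
                      meta = cfg$state_meta[co$true_state])
  treated <- tapply(co$treated, co$patient_id, max)
  fit <- fit_ctmc(paths, treated, share_beta = TRUE)
  eff <- fit$effects
  expect_lt(abs(eff$beta[1]), 0.25)
  expect_true(eff$hr_lower[1] < 1 && eff$hr_upper[1] > 1)
})

test_that("discrete-time hazards separate perfectly separable risks", {
  n <- 200
  x <- rep(c(1, 0), each = n / 2)
  time <- ifelse(x == 1, 1, 24)
  event <- ifelse(x == 1, 1, 0)
  fit <- fit_prognosis(data.frame(x = x), time, event, max_interval = 24)
  ev <- evaluate_prognosis(fit, data.frame(x = x), time, event, horizon = 12)
  expect_equal(ev$concordance, 1.0)
})

test_that("null features give chance-level held-out concordance", {
  set.seed(35)
  n <- 2000
  x <- rnorm(n)
  time <- rexp(n, 0.08) + 1
  event <- as.integer(time < 24); time <- pmin(time, 24)
  half <- seq_len(n) <= n / 2
  fit <- fit_prognosis(data.frame(x = x[half]), time[half], event[half],
                       max_interval = 24)
  ev <- evaluate_prognosis(fit, data.frame(x = x[!half]), time[!half],
                           event[!half], horizon = 24)
  expect_lt(abs(ev$concordance - 0.5), 0.05)
})

test_that("a strong baseline effect yields informative held-out concordance", {
  set.seed(36)
  n <- 1200
  x <- rnorm(n)
  haz <- plogis(-3.2 + 1.6 * x)
  time <- numeric(n); event <- integer(n)
  for (i in seq_len(n)) {
    t <- which(runif(36) < haz[i])[1]
    if (is.na(t)) { time[i] <- 36; event[i] <- 0L }
    else { time[i] <- t; event[i] <- 1L }
  }
  half <- seq_len(n) <= n / 2
  fit <- fit_prognosis(data.frame(x = x[half]), time[half], event[half],
                       max_interval = 36)
  ev <- evaluate_prognosis(fit, data.frame(x = x[!half]), time[!half],
                           event[!half], horizon = 24)
  expect_gt(ev$concordance, 0.7)
  expect_lt(ev$brier, 0.25)
})

test_that("concordance agrees with the survival package and is antisymmetric", {
  set.seed(37)
  n <- 150
  time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.7); risk <- rnorm(n)
  mine <- concordance_index(time, event, risk)
  ref <- survival::concordance(survival::Surv(time, event) ~ risk,
                               reverse = TRUE)$concordance
  expect_equal(mine, ref, tolerance = 1e-10)
  expect_equal(concordance_index(time, event, -risk), 1 - mine,
               tolerance = 1e-10)
  expect_warning(c0 <- concordance_index(c(5, 6), c(0, 0), c(1, 2)),
                 "no comparable")
  expect_true(is.na(c0))
})

test_that("the IPCW Brier score matches the closed form without censoring", {
  set.seed(38)
  n <- 400
  p_event <- 0.3
  event_by_h <- rbinom(n, 1, p_event)
  time <- ifelse(event_by_h == 1, 5, 30)   # everyone followed past horizon
  pi_hat <- 0.6                             # constant predicted S(h)
  bs <- brier_ipcw(time, rep(1, n), rep(pi_hat, n), horizon = 10)
  q <- mean(event_by_h)
  expect_equal(bs, q * pi_hat^2 + (1 - q) * (1 - pi_hat)^2, tolerance = 1e-10)
})

test_that("advanced-event tables track first entry and censoring", {
  dec <- data.frame(patient_id = rep(c("A", "B"), each = 4),
                    month = rep(0:3, 2),
                    state = c(1, 1, 6, 6, 2, 2, 2, 2))
  map <- structure(list(meta = c("EME", "EME", "EME", "asymptomatic_activity",
                                 "relapse", "advanced", "advanced", "advanced")),
                   class = "ms_meta_map")
  adv <- advanced_event_table(dec, map)
  expect_equal(adv$time[adv$patient_id == "A"], 2)
  expect_equal(adv$event[adv$patient_id == "A"], 1L)
  expect_equal(adv$time[adv$patient_id == "B"], 3)
  expect_equal(adv$event[adv$patient_id == "B"], 0L)
})
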