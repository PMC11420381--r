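test_that("Kaplan-Meier matches hand product-limit computations", {
  # three events, no censoring
  km <- km_fit(data.frame(time_months = 1:3, event = 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)
  # times {1+, 2, 3+, 4}: risk sets {3, 1} at the event times
  km2 <- km_fit(data.frame(time_months = 1:4, event = c(0, 1, 0, 1)))
  expect_equal(km2$surv[km2$time == 2], 2 / 3)
  expect_equal(km2$surv[km2$time == 4], 0)
  # all censored: survival stays at 1, median undefined
  expect_warning(km3 <- km_fit(data.frame(time_months = 1:3, event = 0)),
                 "no events")
  expect_true(all(km3$surv == 1))
  expect_true(is.na(km3$median))
})

test_that("KM with no censoring equals the empirical survivor function", {
  set.seed(14)
  tt <- round(rexp(40, 0.1), 1) + 0.1
  km <- km_fit(data.frame(time_months = tt, event = 1))
  ecdf_surv <- sapply(km$time, function(u) mean(tt > u))
  expect_equal(km$surv, ecdf_surv)
})

test_that("reverse Kaplan-Meier estimates follow-up", {
  expect_equal(reverse_km_followup(data.frame(time_months = rep(10, 4),
                                              event = 0)), 10)
  # identity with km_fit on flipped indicators
  d <- data.frame(time_months = c(3, 8, 12, 20, 25), event = c(1, 0, 1, 0, 0))
  flip <- d; flip$event <- 1 - flip$event
  expect_equal(reverse_km_followup(d), km_fit(flip)$median)
  expect_error(reverse_km_followup(data.frame(time_months = 5, event = 1)),
               "undefined")
})

test_that("Cox partial likelihood matches brute-force risk-set enumeration", {
  for (d in toy_surv_datasets()) {
    fit <- cox_fit(d, "x")
    ora <- bf_cox_fit(rep(0, nrow(d)), d$time_months, d$event, d$x)
    expect_equal(fit$table$coef, ora$coef, tolerance = 1e-6)
    expect_equal(fit$loglik, ora$loglik, tolerance = 1e-8)
    # loglik agreement at the fitted point, evaluated independently
    expect_equal(bf_cox_loglik(fit$table$coef, rep(0, nrow(d)),
                               d$time_months, d$event, d$x),
                 fit$loglik, tolerance = 1e-9)
  }
})

test_that("duplicating a dataset shrinks SEs by sqrt(2) at identical coef", {
  # exact only under Breslow ties: duplication creates ties, and the Efron
  # correction then perturbs the score equation
  d <- toy_surv_datasets()[[1]]
  d2 <- rbind(d, d)
  f1 <- cox_fit(d, "x", ties = "breslow")
  f2 <- cox_fit(d2, "x", ties = "breslow")
  expect_equal(f1$table$coef, f2$table$coef, tolerance = 1e-6)
  expect_equal(f2$table$se, f1$table$se / sqrt(2), tolerance = 1e-4)
})

test_that("constant covariates contribute a zero coefficient", {
  d <- toy_surv_datasets()[[2]]
  d$cst <- 1
  f <- cox_fit(d, "cst")
  expect_equal(f$table$coef, 0)
  expect_equal(f$loglik, f$loglik_null)
})

test_that("LVCF expansion builds the expected counting-process rows", {
  surv <- data.frame(patient_id = 1, time_months = 5, event = 1,
                     prior_alki = 1)
  long <- data.frame(patient_id = 1, t_obs_months = c(0, 3),
                     ttc = c(40, 55), trough_ng_ml = c(400, 600))
  rows <- expand_lvcf(surv, long)
  expect_equal(rows$start, c(0, 3))
  expect_equal(rows$stop, c(3, 5))
  expect_equal(rows$ttc, c(40, 55))
  expect_equal(rows$event, c(0, 1))
  expect_equal(rows$prior_alki, c(1, 1))
  # single measurement at t = 0 reduces to the baseline layout
  rows1 <- expand_lvcf(surv, long[1, ])
  expect_equal(nrow(rows1), 1)
  expect_equal(c(rows1$start, rows1$stop, rows1$event), c(0, 5, 1))
  # first value carried backward from a late first measurement
  rows2 <- expand_lvcf(surv, data.frame(patient_id = 1, t_obs_months = 2,
                                        ttc = 33, trough_ng_ml = 350))
  expect_equal(c(rows2$start, rows2$stop), c(0, 5))
  # measurement after the event time is dropped with a warning
  expect_warning(
    rows3 <- expand_lvcf(surv, data.frame(patient_id = 1,
                                          t_obs_months = c(1, 9),
                                          ttc = c(40, 50),
                                          trough_ng_ml = c(1, 2))),
    "dropped")
  expect_equal(nrow(rows3), 1)
  # patient with no longitudinal data is excluded
  s2 <- rbind(surv, data.frame(patient_id = 2, time_months = 4, event = 0,
                               prior_alki = 0))
  expect_message(rows4 <- expand_lvcf(s2, long), "excluded")
  expect_true(all(rows4$patient_id == 1))
})

test_that("time-dependent Cox reduces to the baseline fit on single rows", {
  d <- toy_surv_datasets()[[3]]
  rows <- data.frame(patient_id = d$patient_id, start = 0,
                     stop = d$time_months, event = d$event, x = d$x)
  f_td <- td_cox_fit(rows, "x")
  f_base <- cox_fit(d, "x")
  expect_equal(f_td$table$coef, f_base$table$coef, tolerance = 1e-10)
  expect_equal(f_td$loglik, f_base$loglik, tolerance = 1e-10)
})

test_that("time-dependent Cox matches brute-force risk-set enumeration", {
  # four patients, one covariate switch mid-follow-up
  rows <- data.frame(patient_id = c(1, 1, 2, 3, 4),
                     start = c(0, 2, 0, 0, 0),
                     stop = c(2, 6, 4, 5, 3),
                     event = c(0, 1, 1, 0, 1),
                     x = c(0, 1, 1, 0, 0))
  fit <- td_cox_fit(rows, "x")
  ora <- bf_cox_fit(rows$start, rows$stop, rows$event, rows$x)
  expect_equal(fit$table$coef, ora$coef, tolerance = 1e-6)
  expect_equal(fit$loglik, ora$loglik, tolerance = 1e-8)
  # a switch after the last event time (6) cannot change the fit
  rows2 <- rbind(rows, data.frame(patient_id = 3, start = 6.5, stop = 9,
                                  event = 0, x = 1))
  f2 <- td_cox_fit(rows2, "x")
  expect_equal(f2$table$coef, fit$table$coef, tolerance = 1e-10)
  # overlapping intervals are rejected
  bad <- rows; bad$start[2] <- 1
  expect_error(td_cox_fit(bad, "x"), "overlap")
})

test_that("exposure dichotomization uses the inclusive 435 boundary", {
  lab <- dichotomize_exposure(c(435, 434.9, 1000, 100))
  expect_equal(as.character(lab),
               c("adequate", "inadequate", "adequate", "inadequate"))
  expect_equal(levels(lab), c("inadequate", "adequate"))
  # sensitivity thresholds relabel consistently
  expect_equal(as.character(dichotomize_exposure(c(480, 520), 500)),
               c("inadequate", "adequate"))
  expect_equal(as.character(dichotomize_exposure(c(680, 720), 700)),
               c("inadequate", "adequate"))
})

test_that("backward elimination drops null covariates and keeps the exposure", {
  set.seed(15)
  n <- 150
  x_strong <- rbinom(n, 1, 0.5)
  x_null <- rnorm(n)
  expo <- rnorm(n)
  tt <- rexp(n, 0.05 * exp(1.2 * x_strong))
  cens <- runif(n, 5, 40)
  d <- data.frame(patient_id = 1:n, time_months = pmin(tt, cens),
                  event = as.integer(tt <= cens),
                  x_strong = x_strong, x_null = x_null, expo = expo)
  fit <- backward_eliminate(d, exposure = "expo",
                            candidates = c("x_strong", "x_null"))
  expect_true("x_null" %in% fit$eliminated)
  expect_true(all(c("expo", "x_strong") %in% fit$table$variable))
  # all-null candidates leave the exposure-only model
  fit2 <- backward_eliminate(d, exposure = "expo", candidates = "x_null")
  expect_equal(fit2$eliminated, "x_null")
  expect_equal(fit2$table$variable, "expo")
  # alpha = 1 retains the full model
  fit3 <- backward_eliminate(d, exposure = "expo",
                             candidates = c("x_strong", "x_null"), alpha = 1)
  expect_equal(length(fit3$eliminated), 0)
  expect_equal(nrow(fit3$table), 3)
})

test_that("per-patient exposure aggregation takes medians on both scales", {
  la <- data.frame(patient_id = c(1, 1, 1, 2),
                   trough_ng_ml = c(300, 400, 500, 700),
                   ttc = c(20, 30, 40, 55))
  ag <- aggregate_exposure(la)
  expect_equal(ag$median_trough, c(400, 700))
  expect_equal(ag$median_ttc, c(30, 55))
})
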