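test_that("average exposure has the expected closed forms", {
  # constant trajectory
  cst <- make_trajectory(37, 0)
  expect_equal(average_exposure(cst, c(0.5, 3, 20)), rep(37, 3))
  # linear trajectory: a + b t / 2
  lin <- make_trajectory(30, 0.8)
  tt <- c(0.1, 1, 7, 25)
  expect_equal(average_exposure(lin, tt), 30 + 0.8 * tt / 2)
  # continuity limit at t = 0
  expect_equal(average_exposure(lin, 0), 30)
  expect_error(average_exposure(lin, -1), "negative")
})

test_that("average exposure with dose steps matches 64-node quadrature", {
  traj <- make_trajectory(42, 0.4, step_times = c(0, 5, 11),
                          step_values = c(0, -8, -16))
  for (tt in c(2, 5, 7.3, 11, 30))
    expect_equal(average_exposure(traj, tt), gl_average_oracle(traj, tt),
                 tolerance = 1e-8)
})

test_that("the hazard composes baseline, covariates, and associations", {
  traj <- make_trajectory(45, 0.2)
  lr <- log(c(0.02, 0.03, 0.025))
  kn <- c(6, 18)
  # association off: proportional hazards in the baseline covariates only
  expect_equal(jm_hazard(c(2, 10, 30), traj, lr, kn, eta = 0.7),
               exp(lr[c(1, 2, 3)] + 0.7))
  # one TTC unit higher at the same time multiplies the hazard by exp(alpha)
  tr_hi <- make_trajectory(46, 0.2)
  a <- log(0.891)
  expect_equal(jm_hazard(8, tr_hi, lr, kn, alpha_current = a) /
                 jm_hazard(8, traj, lr, kn, alpha_current = a),
               0.891, tolerance = 1e-12)
  # piecewise log-linearity in t for a linear trajectory
  tg <- seq(7, 17, length.out = 9)  # inside one baseline piece
  lh <- log(jm_hazard(tg, traj, lr, kn, alpha_current = 0.03))
  expect_equal(diff(lh, differences = 2), rep(0, 7), tolerance = 1e-10)
})

test_that("the joint log-likelihood matches a dense-trapezoid oracle", {
  toy <- make_toy_prep()
  prep <- toy$prep; pars <- toy$pars
  got <- jm_loglik_subjects(prep, pars)
  for (i in seq_len(prep$n)) {
    d <- toy$rec[toy$rec$patient_id == i, ]
    # longitudinal part: direct Gaussian density
    mu <- pars$beta0 + pars$b[i, 1] + (pars$beta1 + pars$b[i, 2]) * d$t +
      pars$dc[d$dose_level + 1]
    expect_equal(got$long[i], sum(dnorm(d$ttc_value, mu, pars$sigma,
                                        log = TRUE)), tolerance = 1e-10)
    # survival part: hazard at the event time minus trapezoid cumulative
    h <- prep$hist[[i]]
    traj <- make_trajectory(pars$beta0 + pars$b[i, 1],
                            pars$beta1 + pars$b[i, 2],
                            h$st, pars$dc[h$lev])
    m_fun <- function(t) traj_eval(traj, t)
    avg_fun <- function(t) average_exposure(traj, t)
    Ti <- toy$surv$time_months[i]
    wl <- pars$phi * toy$surv$prior_alki[i]
    cum <- trap_cumhaz(Ti, m_fun, avg_fun, pars$logh0, prep$knots, wl,
                       pars$alpha_current, pars$alpha_average, prep$center,
                       breaks = h$st)
    ev <- toy$surv$event[i] *
      log(jm_hazard(Ti, traj, pars$logh0 +
                      (pars$alpha_current + pars$alpha_average) *
                        (-prep$center),
                    prep$knots, eta = wl,
                    alpha_current = pars$alpha_current,
                    alpha_average = pars$alpha_average))
    expect_lt(abs(got$surv[i] - (ev - cum)), 1e-6)  # absolute, on the log scale
  }
})

test_that("with no longitudinal terms the survival part is piecewise exponential", {
  # single subject, constant hazard lambda, event at T: log lambda - lambda T
  rec <- data.frame(patient_id = 1:2, t = 0, ttc_value = 50, dose_level = 0)
  surv <- data.frame(patient_id = 1:2, time_months = c(7, 4), event = c(1, 0),
                     prior_alki = 0)
  prep <- jm_prepare(rec, surv, jm_spec(n_pieces = 1))
  lam <- 0.08
  pars <- list(beta0 = 50, beta1 = 0, dc = 0, sigma = 1,
               b = matrix(0, 2, 2), logh0 = log(lam), phi = 0,
               alpha_current = 0, alpha_average = 0)
  got <- jm_loglik_subjects(prep, pars)
  expect_equal(got$surv, c(log(lam) - lam * 7, -lam * 4), tolerance = 1e-10)
})

test_that("WAIC and LPML have their degenerate closed forms", {
  ll <- matrix(rep(c(-3.2, -1.7, -2.5), each = 40), nrow = 40)
  fake <- structure(list(pointwise = ll), class = "jm_fit")
  # identical draws: no effective parameters
  expect_equal(as.numeric(waic(fake)), -2 * sum(ll[1, ]))
  expect_equal(attr(waic(fake), "p_waic"), 0)
  expect_equal(lpml(fake), sum(ll[1, ]))
})

test_that("WAIC and LPML are invariant to draw order", {
  set.seed(16)
  ll <- matrix(rnorm(200 * 6, -3, 0.5), 200, 6)
  f1 <- structure(list(pointwise = ll), class = "jm_fit")
  f2 <- structure(list(pointwise = ll[sample(200), ]), class = "jm_fit")
  expect_equal(as.numeric(waic(f1)), as.numeric(waic(f2)))
  expect_equal(lpml(f1), lpml(f2))
})

test_that("hazard-ratio summaries transform posterior draws correctly", {
  draws <- cbind(alpha_average = log(0.891) + rnorm(4000, 0, 1e-8),
                 phi_prior_alki = rep(0.8, 4000))
  fake <- structure(list(draws = draws), class = "jm_fit")
  hr <- summarize_hr(fake)
  a <- hr[hr$variable == "alpha_average", ]
  expect_equal(a$hr, 0.891, tolerance = 1e-6)
  expect_equal(a$pct_reduction, 11)
  # per-unit scaling law
  hr10 <- summarize_hr(fake, per_unit = 10)
  expect_equal(hr10$hr[hr10$variable == "alpha_average"], 0.891^10,
               tolerance = 1e-5)
  # alpha = 0 gives HR 1 and 0% reduction
  fake0 <- structure(list(draws = cbind(alpha_current = rnorm(4000, 0, 1e-9))),
                     class = "jm_fit")
  hr0 <- summarize_hr(fake0)
  expect_equal(hr0$hr, 1, tolerance = 1e-6)
  expect_equal(hr0$pct_reduction, 0)
})

test_that("a degenerate single-chain short run works end to end", {
  inp <- make_fitted_inputs(91, config = cohort_config(n_patients = 25))
  sp <- jm_spec(association = "current_value", chains = 1, warmup = 10,
                draws = 10)
  fit <- suppressWarnings(fit_joint(inp$records, inp$surv, sp, seed = 91))
  expect_s3_class(fit, "jm_fit")
  expect_equal(nrow(fit$draws), 10)
  expect_true(is.finite(as.numeric(fit$waic)))
  expect_true(is.finite(fit$lpml))
  expect_output(print(fit), "Bayesian joint model")
})

test_that("the same seed reproduces a fit draw for draw", {
  inp <- make_fitted_inputs(92, config = cohort_config(n_patients = 20))
  sp <- jm_spec(chains = 1, warmup = 50, draws = 50)
  f1 <- suppressWarnings(fit_joint(inp$records, inp$surv, sp, seed = 5))
  f2 <- suppressWarnings(fit_joint(inp$records, inp$surv, sp, seed = 5))
  expect_identical(f1$draws, f2$draws)
})

test_that("with the association fixed off, phi matches the standalone Cox fit", {
  inp <- make_fitted_inputs(93, truth = synthetic_truth(assoc_current = 0,
                                                        assoc_average = 0))
  sp <- jm_spec(association = "none", chains = 2, warmup = 400, draws = 800)
  fit <- suppressWarnings(fit_joint(inp$records, inp$surv, sp, seed = 93))
  cox <- cox_fit(inp$surv, "prior_alki")
  post <- median(fit$draws[, "phi_prior_alki"])
  # agreement within Monte-Carlo and estimation error
  expect_lt(abs(post - cox$table$coef), 2.5 * cox$table$se)
})
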