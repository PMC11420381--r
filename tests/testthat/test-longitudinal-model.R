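# direct marginal-likelihood oracle: per-subject multivariate normal density
# with V_i = Z_i D Z_i' + sigma^2 I, optimized over all parameters
oracle_lmm <- function(records) {
  sp <- split(records, records$patient_id)
  nll <- function(th) {
    beta <- th[1:2]
    sd0 <- exp(th[3]); sd1 <- exp(th[4]); rho <- tanh(th[5]); sg <- exp(th[6])
    D <- matrix(c(sd0^2, rho * sd0 * sd1, rho * sd0 * sd1, sd1^2), 2, 2)
    ll <- tryCatch({
      acc <- 0
      for (d in sp) {
        Z <- cbind(1, d$t)
        V <- Z %*% D %*% t(Z) + diag(sg^2 + 1e-10, nrow(d))
        r <- d$ttc_value - Z %*% beta
        acc <- acc - 0.5 * (nrow(d) * log(2 * pi) + determinant(V)$modulus +
                              drop(t(r) %*% solve(V, r)))
      }
      as.numeric(acc)
    }, error = function(e) -1e10)
    -ll
  }
  opt <- optim(c(mean(records$ttc_value), 0, log(5), log(0.5), 0, log(3)),
               nll, method = "BFGS", control = list(maxit = 500,
                                                    reltol = 1e-14))
  list(beta = opt$par[1:2], loglik = -opt$value)
}

make_lmm_toy <- function(seed = 8, n = 15, k = 6) {
  set.seed(seed)
  b0 <- rnorm(n, 0, 6); b1 <- rnorm(n, 0, 1.2)
  do.call(rbind, lapply(seq_len(n), function(i) {
    t <- seq(0, 8, length.out = k)
    data.frame(patient_id = i, t = t,
               ttc_value = 40 + b0[i] + (1.5 + b1[i]) * t + rnorm(k, 0, 2),
               dose_level = 0)
  }))
}

test_that("ML fit matches direct optimization of the marginal likelihood", {
  rec <- make_lmm_toy()
  fit <- fit_lmm(rec, include_dose = FALSE)
  ora <- oracle_lmm(rec)
  expect_equal(unname(fit$fixed), ora$beta, tolerance = 1e-4)
  expect_equal(fit$loglik, ora$loglik, tolerance = 1e-6)
})

test_that("empirical Bayes modes equal the analytic conditional means", {
  rec <- make_lmm_toy(seed = 9)
  fit <- fit_lmm(rec, include_dose = FALSE)
  D <- fit$random_cov; s2 <- fit$resid_var
  for (i in unique(rec$patient_id)) {
    d <- rec[rec$patient_id == i, ]
    Z <- cbind(1, d$t)
    V <- Z %*% D %*% t(Z) + diag(s2, nrow(d))
    r <- d$ttc_value - Z %*% fit$fixed
    blup <- unname(drop(D %*% t(Z) %*% solve(V, r)))
    expect_equal(unname(fit$per_subject_modes[as.character(i), ]), blup,
                 tolerance = 1e-5)
  }
})

test_that("noiseless common-slope data give exact fixed effects", {
  set.seed(10)
  rec <- do.call(rbind, lapply(1:10, function(i) {
    t <- 0:3
    data.frame(patient_id = i, t = t,
               ttc_value = (40 + rnorm(1, 0, 5)) + 0.5 * t, dose_level = 0)
  }))
  fit <- suppressWarnings(fit_lmm(rec, include_dose = FALSE))
  expect_equal(unname(fit$fixed["t"]), 0.5, tolerance = 1e-6)
  expect_lt(fit$resid_var, 1e-6)
})

test_that("fixed effects are recovered from generated cohorts", {
  # association off so that dropout is uninformative for the trajectory
  truth <- synthetic_truth(assoc_current = 0, assoc_average = 0)
  co <- generate_cohort(cohort_config(n_patients = 200), truth, seed = 71)
  la <- transform_troughs(co$longitudinal)
  fit <- fit_lmm(as_longitudinal_records(la))
  est <- fit$fixed; se <- fit$fixed_se
  expect_lt(abs(est[["(Intercept)"]] - truth$beta0), 3 * se[1])
  expect_lt(abs(est[["t"]] - truth$beta1), 3 * se[2])
  # dose levels 1 and 2 correspond to -8 and -16 TTC under the linear truth
  if (fit$use_dose && "1" %in% names(fit$dose_coefs)) {
    k <- which(names(fit$fixed) == "dose_f1")
    expect_lt(abs(fit$dose_coefs[["1"]] - truth$beta_dose), 3 * se[k])
  }
})

test_that("single-observation patients are retained and shrink to the mean", {
  rec <- make_lmm_toy(seed = 11)
  rec <- rec[!(rec$patient_id == 1 & rec$t > 0), ]  # patient 1: one record
  fit <- fit_lmm(rec, include_dose = FALSE)
  expect_true("1" %in% rownames(fit$per_subject_modes))
  # the single observation is shrunk toward the population line: the EB
  # intercept is strictly smaller than the raw residual it derives from
  d1 <- rec[rec$patient_id == 1, ]
  raw <- d1$ttc_value - (fit$fixed[["(Intercept)"]] + fit$fixed[["t"]] * d1$t)
  expect_lt(abs(fit$per_subject_modes["1", 1]), abs(raw))
  expect_gt(abs(raw), 0)
})

test_that("more samples per patient tighten the EB estimates", {
  set.seed(12)
  n <- 40; b0 <- rnorm(n, 0, 8)
  gen <- function(k) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      t <- seq(0, 6, length.out = k)
      data.frame(patient_id = i, t = t,
                 ttc_value = 45 + b0[i] + 0.3 * t + rnorm(k, 0, 6),
                 dose_level = 0)
    }))
  }
  err <- sapply(c(2, 10), function(k) {
    fit <- suppressWarnings(fit_lmm(gen(k), include_dose = FALSE))
    mean(abs(fit$per_subject_modes[as.character(seq_len(n)), 1] - b0))
  })
  expect_lt(err[2], err[1])
})

test_that("subject trajectories combine fixed, random, and dose effects", {
  inp <- make_fitted_inputs(81, truth = synthetic_truth(assoc_current = 0,
                                                        assoc_average = 0))
  fit <- fit_lmm(inp$records)
  pid <- inp$records$patient_id[1]
  traj <- subject_trajectory(fit, pid)
  b <- fit$per_subject_modes[as.character(pid), ]
  expect_equal(traj_eval(traj, 0),
               unname(fit$fixed["(Intercept)"] + b[1]) +
                 traj$step_values[1])
  # dose step of exactly the fitted coefficient at a change point
  dh <- data.frame(time = c(0, 5), dose_level = c(0, 1))
  if (fit$use_dose && "1" %in% names(fit$dose_coefs)) {
    tr2 <- subject_trajectory(fit, pid, dh)
    expect_equal(traj_eval(tr2, 5.000001) - traj_eval(tr2, 4.999999),
                 fit$dose_coefs[["1"]], tolerance = 1e-3)
  }
  expect_error(subject_trajectory(fit, "no-such-patient"), "unknown")
})

test_that("fit_lmm validates its inputs", {
  rec <- make_lmm_toy()
  expect_error(fit_lmm(rec[rec$patient_id == 1, ]), "2 patients")
  bad <- rec; bad$ttc_value[1] <- 150
  expect_error(fit_lmm(bad), "100")
})
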