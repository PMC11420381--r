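# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths (and the survival package's fitters):
# partial likelihoods are enumerated directly from their definition, and
# integrals are done on dense trapezoid grids.

# Efron-ties Cox partial log-likelihood for counting-process data,
# enumerated risk set by risk set from the definition.
bf_cox_loglik <- function(beta, start, stop, event, X) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  ll <- 0
  for (tt in sort(unique(stop[event == 1]))) {
    D <- which(event == 1 & stop == tt)
    R <- which(start < tt & stop >= tt)
    d <- length(D)
    sumR <- sum(exp(eta[R]))
    sumD <- sum(exp(eta[D]))
    ll <- ll + sum(eta[D])
    for (r in seq_len(d) - 1)
      ll <- ll - log(sumR - (r / d) * sumD)
  }
  ll
}

# maximizer of the brute-force partial likelihood (1-2 covariates)
bf_cox_fit <- function(start, stop, event, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  f <- function(b) -bf_cox_loglik(b, start, stop, event, X)
  if (p == 1) {
    opt <- stats::optimize(f, c(-10, 10), tol = 1e-10)
    list(coef = opt$minimum, loglik = -opt$objective)
  } else {
    opt <- stats::optim(rep(0, p), f, method = "BFGS",
                        control = list(reltol = 1e-14))
    list(coef = opt$par, loglik = -opt$value)
  }
}

# dense-grid cumulative hazard oracle for the joint-model hazard, with the
# same TTC centring convention as jm_loglik_subjects. The integrand jumps
# at baseline knots and dose-change times, so the grid is split there and a
# dense midpoint rule applied within each smooth piece (midpoints never
# touch a discontinuity, where the left-continuous trajectory would give
# the wrong one-sided value).
trap_cumhaz <- function(Ti, m_fun, avg_fun, logh0, knots, wlin, ac, aa,
                        center, breaks = numeric(0), nstep = 20000) {
  cuts <- sort(unique(c(0, knots[knots < Ti], breaks[breaks < Ti &
                                                       breaks > 0], Ti)))
  tot <- 0
  for (j in seq_len(length(cuts) - 1)) {
    tg <- seq(cuts[j], cuts[j + 1], length.out = nstep + 1)
    mid <- (tg[-1] + tg[-length(tg)]) / 2
    piece <- findInterval(mid[1], c(0, knots))
    h <- exp(logh0[piece] + wlin + ac * (m_fun(mid) - center) +
               aa * (avg_fun(mid) - center))
    tot <- tot + sum(h * diff(tg))
  }
  tot
}

# 64-node Gauss-Legendre average of a trajectory, split at its dose steps
# (the integrand is piecewise smooth, not smooth)
gl_average_oracle <- function(traj, tt) {
  cuts <- sort(unique(c(0, traj$step_times[traj$step_times < tt &
                                             traj$step_times > 0], tt)))
  tot <- 0
  for (j in seq_len(length(cuts) - 1)) {
    g <- pracma::gaussLegendre(64, cuts[j], cuts[j + 1])
    tot <- tot + sum(g$w * traj_eval(traj, g$x))
  }
  tot / tt
}

# small fixed collection of survival toy datasets (n <= 6), with and
# without ties; candidates with a monotone partial likelihood (separation,
# a flagged error path tested on its own) are rejected so the interior
# maximum is well defined for both routes
toy_surv_datasets <- function() {
  set.seed(4711)
  out <- list()
  while (length(out) < 12) {
    n <- sample(4:6, 1)
    tie <- length(out) %% 3 == 0
    time <- if (tie) as.numeric(sample(1:3, n, replace = TRUE))
            else round(stats::rexp(n, 0.3), 2) + 0.5
    event <- stats::rbinom(n, 1, 0.8)
    if (sum(event) < 2) event[sample(n, 2)] <- 1
    x <- stats::rbinom(n, 1, 0.5)
    if (length(unique(x)) == 1) x[1] <- 1 - x[1]
    ll <- function(b) bf_cox_loglik(b, rep(0, n), time, event, x)
    opt <- stats::optimize(function(b) -ll(b), c(-8, 8), tol = 1e-10)
    if (abs(opt$minimum) > 4) next  # monotone or near-monotone likelihood
    out[[length(out) + 1]] <- data.frame(patient_id = seq_len(n),
                                         time_months = time, event = event,
                                         x = x, z = round(stats::rnorm(n), 2))
  }
  out
}

# a tiny hand-built prep + parameter set used by the likelihood oracles;
# event indicators fixed so the event-time quantile knots are well defined
make_toy_prep <- function(seed = 3, n = 4) {
  set.seed(seed)
  rec <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(2:4, 1)
    data.frame(patient_id = i, t = sort(runif(k, 0, 10)),
               ttc_value = runif(k, 20, 70),
               dose_level = sample(0:1, k, replace = TRUE))
  }))
  surv <- data.frame(patient_id = seq_len(n),
                     time_months = runif(n, 5, 15),
                     event = rep(c(1, 1, 1, 0), length.out = n),
                     prior_alki = rbinom(n, 1, 0.5))
  prep <- jm_prepare(rec, surv, jm_spec(n_pieces = 3, quad_nodes = 15))
  pars <- list(beta0 = 45, beta1 = 0.3, dc = c(0, -7), sigma = 5,
               b = cbind(rnorm(n, 0, 4), rnorm(n, 0, 0.2)),
               logh0 = log(c(0.02, 0.05, 0.03))[seq_len(prep$n_pieces)],
               phi = 0.6, alpha_current = -0.04, alpha_average = -0.06)
  list(rec = rec, surv = surv, prep = prep, pars = pars)
}

# simulate a transformed cohort ready for model fitting
make_fitted_inputs <- function(seed, truth = synthetic_truth(),
                               config = cohort_config()) {
  co <- generate_cohort(config, truth, seed = seed)
  la <- transform_troughs(co$longitudinal)
  list(cohort = co, long_aug = la,
       records = as_longitudinal_records(la), surv = co$survival)
}
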