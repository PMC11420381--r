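#' Running average of a TTC trajectory
#'
#' The average-exposure functional form of the joint model:
#' \eqn{\bar m(t) = \frac{1}{t}\int_0^t m(s)\,ds}, the area under the
#' historical TTC trajectory divided by elapsed time. For the
#' piecewise-linear trajectories used throughout the package the integral is
#' evaluated in closed form per linear/stepped segment. At `t = 0` the
#' continuity limit `m(0)` is returned.
#'
#' @param traj A [make_trajectory()] object.
#' @param t Time(s) since treatment start (months, >= 0).
#' @return Average TTC over `[0, t]`.
#' @export
average_exposure <- function(traj, t) {
  stopifnot(inherits(traj, "ttc_trajectory"))
  if (any(t < 0)) stop("negative time")
  out <- numeric(length(t))
  zero <- t == 0
  out[zero] <- traj_eval(traj, 0)
  tz <- t[!zero]
  if (length(tz))
    out[!zero] <- traj$intercept + traj$slope * tz / 2 +
      traj_step_integral(traj, tz) / tz
  out
}

#' Hazard under the joint model
#'
#' Evaluates \eqn{h(t) = h_0(t)\exp(\eta + \alpha_c m(t) + \alpha_a \bar
#' m(t))} for a subject with trajectory `traj`, piecewise-constant baseline
#' log-rates, baseline-covariate linear predictor `eta`, and association
#' coefficients per TTC unit.
#'
#' @param t Time(s) in months (> 0).
#' @param traj A [make_trajectory()] object.
#' @param base_log_rates Log baseline rates on the pieces.
#' @param base_knots Interior knots of the baseline hazard (months).
#' @param eta Baseline-covariate linear predictor (scalar).
#' @param alpha_current,alpha_average Association coefficients.
#' @return Hazard rate(s) per month.
#' @export
jm_hazard <- function(t, traj, base_log_rates, base_knots = numeric(0),
                      eta = 0, alpha_current = 0, alpha_average = 0) {
  stopifnot(length(base_log_rates) == length(base_knots) + 1, all(t > 0))
  lh <- base_log_rates[findInterval(t, c(0, base_knots))] + eta +
    alpha_current * traj_eval(traj, t) +
    alpha_average * average_exposure(traj, t)
  exp(lh)
}

#' Specification of the Bayesian joint model
#'
#' @param association Association structure linking the TTC trajectory to
#'   the hazard: the current value \eqn{m(t)}, the running average
#'   \eqn{\bar m(t)}, or both together (each with its own coefficient).
#'   `"none"` fixes both coefficients at zero (the two sub-models decouple
#'   given the random effects); it is mainly useful for consistency checks
#'   against a standalone Cox fit.
#' @param n_pieces Number of piecewise-constant baseline-hazard pieces;
#'   knots are placed at the observed event-time quantiles.
#' @param quad_nodes Gauss-Legendre nodes per integration segment for the
#'   cumulative hazard (>= 7).
#' @param chains Number of MCMC chains (>= 2 for convergence checks; a
#'   single chain is allowed for smoke tests).
#' @param warmup,draws Adaptation iterations discarded, and kept draws, per
#'   chain.
#' @param prior_beta_sd Normal prior SD for the longitudinal fixed effects
#'   (TTC scale).
#' @param prior_surv_sd Normal prior SD for log-hazard-scale coefficients
#'   (baseline log-rates, covariate log-HRs, association coefficients).
#' @param prior_sd_scale Half-t(3) scales for the random-intercept SD, the
#'   random-slope SD, and the residual SD.
#' @return An object of class `jm_spec`.
#' @export
jm_spec <- function(association = c("current_plus_average", "current_value",
                                    "average_exposure", "none"),
                    n_pieces = 5, quad_nodes = 15,
                    chains = 3, warmup = 1000, draws = 2000,
                    prior_beta_sd = 100, prior_surv_sd = 10,
                    prior_sd_scale = c(25, 5, 10)) {
  association <- match.arg(association)
  stopifnot(n_pieces >= 1, quad_nodes >= 7, chains >= 1,
            warmup >= 10, draws >= 10, length(prior_sd_scale) == 3)
  structure(list(association = association, n_pieces = n_pieces,
                 quad_nodes = quad_nodes, chains = chains,
                 warmup = warmup, draws = draws,
                 prior_beta_sd = prior_beta_sd,
                 prior_surv_sd = prior_surv_sd,
                 prior_sd_scale = prior_sd_scale),
            class = "jm_spec")
}

# Occupancy durations: time spent at each dose level (1..K) on [0, t].
.occupancy <- function(step_times, step_levels, K, t) {
  ends <- c(step_times[-1], Inf)
  out <- numeric(K)
  len <- pmax(0, pmin(ends, t) - pmin(step_times, t))
  for (j in seq_along(step_times))
    out[step_levels[j]] <- out[step_levels[j]] + len[j]
  out
}

#' Prepare linked data for the joint model likelihood
#'
#' Internal-but-exported data builder: aligns the longitudinal records and
#' survival table, derives per-patient dose histories (last observed dose
#' carried forward, first carried back to 0), places baseline-hazard knots
#' at event-time quantiles, and precomputes the Gauss-Legendre integration
#' grid for the cumulative hazard. Used by [fit_joint()] and by the
#' likelihood oracle checks.
#'
#' @param records Longitudinal records ([as_longitudinal_records()] layout).
#' @param surv Survival table with `patient_id`, `time_months`, `event` and
#'   the covariate columns.
#' @param spec A [jm_spec()] object.
#' @param covariates Baseline covariate columns entering the survival
#'   sub-model.
#' @return A list of class `jm_prep` of precomputed arrays.
#' @export
jm_prepare <- function(records, surv, spec = jm_spec(),
                       covariates = "prior_alki") {
  stopifnot(all(c("patient_id", "t", "ttc_value", "dose_level") %in%
                  names(records)),
            all(c("patient_id", "time_months", "event") %in% names(surv)),
            all(covariates %in% names(surv)),
            all(surv$time_months > 0))
  ids <- surv$patient_id
  if (anyDuplicated(ids)) stop("duplicate patients in the survival table")
  orphan <- setdiff(unique(records$patient_id), ids)
  if (length(orphan))
    stop("longitudinal patients missing from the survival table: ",
         paste(orphan, collapse = ", "))
  n <- length(ids)
  subj_of <- match(records$patient_id, ids)

  dose_levels <- sort(unique(records$dose_level))
  K <- max(1L, length(dose_levels))
  dose_idx <- if (length(dose_levels)) match(records$dose_level, dose_levels)
              else rep(1L, nrow(records))

  # Dose history per subject: LVCF of observed levels, first carried back.
  hist <- vector("list", n)
  for (i in seq_len(n)) {
    ri <- which(subj_of == i)
    if (!length(ri)) { hist[[i]] <- list(st = 0, lev = 1L); next }
    o <- ri[order(records$t[ri])]
    st <- records$t[o]; lv <- dose_idx[o]
    st[1] <- 0
    keep <- c(TRUE, diff(lv) != 0)
    hist[[i]] <- list(st = st[keep], lev = lv[keep])
  }

  ev_t <- surv$time_months
  delta <- as.integer(surv$event)
  probs <- seq_len(spec$n_pieces - 1) / spec$n_pieces
  knots <- if (spec$n_pieces > 1 && sum(delta) >= spec$n_pieces)
    unique(unname(stats::quantile(ev_t[delta == 1], probs = probs, type = 1)))
  else numeric(0)
  piece_of <- function(t) findInterval(t, c(0, knots))

  node_t <- node_w <- numeric(0)
  node_piece <- node_dose <- node_subj <- integer(0)
  sdur_list <- list()
  ev_dose <- integer(n); ev_sdur <- matrix(0, n, K)
  for (i in seq_len(n)) {
    h <- hist[[i]]; Ti <- ev_t[i]
    cuts <- sort(unique(c(0, knots[knots < Ti], h$st[h$st > 0 & h$st < Ti], Ti)))
    for (j in seq_len(length(cuts) - 1)) {
      g <- gl_nodes(spec$quad_nodes, cuts[j], cuts[j + 1])
      node_t <- c(node_t, g$x); node_w <- c(node_w, g$w)
      node_piece <- c(node_piece, piece_of(g$x))
      li <- findInterval(g$x, h$st, left.open = TRUE)
      li[li == 0L] <- 1L
      node_dose <- c(node_dose, h$lev[li])
      node_subj <- c(node_subj, rep(i, length(g$x)))
      sdur_list[[length(sdur_list) + 1L]] <-
        t(vapply(g$x, function(x) .occupancy(h$st, h$lev, K, x), numeric(K)))
    }
    li <- findInterval(Ti, h$st, left.open = TRUE); if (li == 0L) li <- 1L
    ev_dose[i] <- h$lev[li]
    ev_sdur[i, ] <- .occupancy(h$st, h$lev, K, Ti)
  }
  node_sdur <- do.call(rbind, sdur_list)

  W <- as.matrix(surv[, covariates, drop = FALSE])
  storage.mode(W) <- "double"

  structure(list(
    n = n, ids = ids, K = K, dose_levels = dose_levels, hist = hist,
    long = list(y = records$ttc_value, t = records$t,
                dose = dose_idx - 1L, subj = subj_of - 1L),
    node = list(t = node_t, w = node_w, piece = node_piece - 1L,
                dose = node_dose - 1L, subj = node_subj - 1L,
                sdur = node_sdur),
    ev = list(t = ev_t, piece = piece_of(ev_t) - 1L, dose = ev_dose - 1L,
              sdur = ev_sdur, delta = delta),
    W = W, covariates = covariates, knots = knots,
    center = if (nrow(records)) mean(records$ttc_value) else 0,
    n_pieces = length(knots) + 1L), class = "jm_prep")
}

#' Per-subject conditional joint log-likelihood
#'
#' Evaluates, for each subject, the log-density of the observed data
#' conditional on the random effects: the Gaussian longitudinal term plus
#' the survival term \eqn{\delta_i \log h_i(T_i) - \int_0^{T_i} h_i}. The
#' cumulative hazard uses the precomputed Gauss-Legendre grid of `prep`.
#'
#' For numerical stability the hazard is parameterized with the TTC terms
#' centred at the sample mean `prep$center`:
#' \eqn{h_i(t) = \exp(\log h_0 + \varphi^T w_i + \alpha_c (m_i(t) - \bar y)
#' + \alpha_a (\bar m_i(t) - \bar y))}. The association coefficients are
#' unaffected; only the baseline log-rates are shifted by
#' \eqn{(\alpha_c + \alpha_a)\bar y} relative to the uncentred form.
#'
#' @param prep A [jm_prepare()] object.
#' @param pars Named list: `beta0`, `beta1`, `dc` (dose coefficients,
#'   length `prep$K`, first element 0), `sigma`, `b` (n x 2 matrix of random
#'   effects), `logh0` (length `prep$n_pieces`), `phi` (covariate log-HRs),
#'   `alpha_current`, `alpha_average`.
#' @return List with per-subject vectors `long`, `surv`, `total`.
#' @export
jm_loglik_subjects <- function(prep, pars) {
  stopifnot(inherits(prep, "jm_prep"))
  b0 <- pars$b[, 1]; b1 <- pars$b[, 2]
  wlin <- drop(prep$W %*% pars$phi)
  ll_l <- cpp_long_loglik(prep$long$y, prep$long$t, prep$long$dose,
                          prep$long$subj, prep$n, pars$beta0, pars$beta1,
                          pars$dc, b0, b1, pars$sigma)
  ll_s <- cpp_surv_loglik(prep$node$t, prep$node$w, prep$node$piece,
                          prep$node$dose, prep$node$subj, prep$node$sdur,
                          prep$ev$t, prep$ev$piece, prep$ev$dose,
                          prep$ev$sdur, prep$ev$delta, wlin,
                          pars$beta0, pars$beta1, pars$dc, b0, b1,
                          pars$logh0, pars$alpha_current, pars$alpha_average,
                          prep$center)
  list(long = ll_l, surv = ll_s, total = ll_l + ll_s)
}

# log prior pieces ------------------------------------------------------

.lp_halft <- function(sd, scale) {
  # half-t(3) on an SD, density evaluated at sd > 0
  log(2) + stats::dt(sd / scale, df = 3, log = TRUE) - log(scale)
}

.lp_ranef <- function(b, sd0, sd1, rho) {
  # sum over subjects of log N(b_i; 0, D)
  det <- (sd0 * sd1)^2 * (1 - rho^2)
  q <- (b[, 1] / sd0)^2 - 2 * rho * (b[, 1] / sd0) * (b[, 2] / sd1) +
    (b[, 2] / sd1)^2
  sum(-log(2 * pi) - 0.5 * log(det) - 0.5 * q / (1 - rho^2))
}

# crude piecewise-exponential rates for initialization
.init_logh0 <- function(ev_t, delta, knots) {
  bounds <- c(0, knots, Inf)
  np <- length(bounds) - 1
  out <- numeric(np)
  for (j in seq_len(np)) {
    expo <- sum(pmax(0, pmin(ev_t, bounds[j + 1]) - bounds[j]))
    d <- sum(delta[ev_t > bounds[j] & ev_t <= bounds[j + 1]])
    out[j] <- log(max(d, 0.5) / max(expo, 1e-8))
  }
  out
}

# one adaptive Metropolis-within-Gibbs chain
.jm_chain <- function(prep, spec, init, seed, chain_id) {
  set.seed(new_seed(seed, 1000L * chain_id))
  n <- prep$n; K <- prep$K; np <- prep$n_pieces
  p <- ncol(prep$W)
  use_ac <- spec$association %in% c("current_value", "current_plus_average")
  use_aa <- spec$association %in% c("average_exposure", "current_plus_average")

  beta <- c(init$beta0, init$beta1, if (K > 1) init$dc[-1])
  nb <- length(beta)
  b <- init$b
  lsig <- log(init$sigma)
  dpar <- c(log(init$sd0), log(init$sd1), atanh(init$rho))
  logh0 <- init$logh0
  sc <- c(init$phi, if (use_ac) 0, if (use_aa) 0)  # phi then alphas
  nsc <- length(sc)
  iac <- if (use_ac) p + 1L else 0L
  iaa <- if (use_aa) p + use_ac + 1L else 0L

  if (chain_id > 1) {  # overdispersed starts
    beta <- beta + stats::rnorm(nb, 0, c(2, 0.1, rep(1, nb - 2))[seq_len(nb)])
    lsig <- lsig + stats::rnorm(1, 0, 0.1)
    dpar <- dpar + stats::rnorm(3, 0, 0.1)
    logh0 <- logh0 + stats::rnorm(np, 0, 0.3)
    sc <- sc + stats::rnorm(nsc, 0, 0.05)
  }

  get_pars <- function() {
    list(beta0 = beta[1], beta1 = beta[2],
         dc = c(0, if (nb > 2) beta[3:nb]),
         sigma = exp(lsig), b = b, logh0 = logh0,
         phi = sc[seq_len(p)],
         alpha_current = if (use_ac) sc[iac] else 0,
         alpha_average = if (use_aa) sc[iaa] else 0)
  }

  ll_long_fun <- function(beta., b., lsig.) {
    cpp_long_loglik(prep$long$y, prep$long$t, prep$long$dose, prep$long$subj,
                    n, beta.[1], beta.[2], c(0, if (nb > 2) beta.[3:nb]),
                    b.[, 1], b.[, 2], exp(lsig.))
  }
  ll_surv_fun <- function(beta., b., logh0., sc.) {
    wlin <- drop(prep$W %*% sc.[seq_len(p)])
    cpp_surv_loglik(prep$node$t, prep$node$w, prep$node$piece, prep$node$dose,
                    prep$node$subj, prep$node$sdur, prep$ev$t, prep$ev$piece,
                    prep$ev$dose, prep$ev$sdur, prep$ev$delta, wlin,
                    beta.[1], beta.[2], c(0, if (nb > 2) beta.[3:nb]),
                    b.[, 1], b.[, 2], logh0.,
                    if (use_ac) sc.[iac] else 0, if (use_aa) sc.[iaa] else 0,
                    prep$center)
  }

  ll_long <- ll_long_fun(beta, b, lsig)
  ll_surv <- ll_surv_fun(beta, b, logh0, sc)

  lp_beta <- function(x) sum(stats::dnorm(x, 0, spec$prior_beta_sd, log = TRUE))
  lp_surv_coefs <- function(x) sum(stats::dnorm(x, 0, spec$prior_surv_sd,
                                                log = TRUE))
  lp_lsig <- function(x) .lp_halft(exp(x), spec$prior_sd_scale[3]) + x
  lp_dpar <- function(x) {
    rho <- tanh(x[3])
    .lp_halft(exp(x[1]), spec$prior_sd_scale[1]) + x[1] +
      .lp_halft(exp(x[2]), spec$prior_sd_scale[2]) + x[2] +
      log1p(-rho^2)
  }

  base_beta <- c(1, 0.05, rep(0.5, max(0, nb - 2)))
  base_sc <- c(rep(0.15, p), rep(0.015, nsc - p))
  scales <- list(beta = 0.3, b = c(1.5, 0.05), sig = 0.1, dpar = 0.15,
                 h0 = 0.3, sc = 0.5)
  acc <- list(beta = 0, b = 0, sig = 0, dpar = 0, h0 = 0, sc = 0)
  adapt_every <- 25L
  # warmup histories for covariance-adaptive proposals (Haario-style):
  # the association coefficients are collinear with each other and with phi,
  # so a diagonal random walk mixes poorly without them
  hist_beta <- matrix(NA_real_, spec$warmup, nb)
  hist_sc <- matrix(NA_real_, spec$warmup, nsc)
  chol_beta <- NULL; chol_sc <- NULL
  upd_chol <- function(hist, it) {
    win <- hist[max(1, it - 499):it, , drop = FALSE]
    cv <- stats::cov(win)
    ridge <- 1e-8 + 1e-6 * mean(diag(cv))
    tryCatch(chol(cv + diag(ridge, ncol(cv))), error = function(e) NULL)
  }

  n_iter <- spec$warmup + spec$draws
  par_names <- c("beta0", "beta_t",
                 if (nb > 2) paste0("dose_", prep$dose_levels[-1]),
                 "sigma", "sd_b0", "sd_b1", "cor_b",
                 paste0("logh0_", seq_len(np)),
                 paste0("phi_", prep$covariates),
                 if (use_ac) "alpha_current", if (use_aa) "alpha_average")
  draws <- matrix(NA_real_, spec$draws, length(par_names),
                  dimnames = list(NULL, par_names))
  pointwise <- matrix(NA_real_, spec$draws, n)
  ranef <- array(NA_real_, c(spec$draws, n, 2))

  for (it in seq_len(n_iter)) {
    # fixed effects (longitudinal side)
    bp <- if (is.null(chol_beta))
      beta + scales$beta * base_beta * stats::rnorm(nb)
    else
      beta + scales$beta * drop(stats::rnorm(nb) %*% chol_beta)
    llp <- ll_long_fun(bp, b, lsig); lsp <- ll_surv_fun(bp, b, logh0, sc)
    logr <- sum(llp - ll_long) + sum(lsp - ll_surv) +
      lp_beta(bp) - lp_beta(beta)
    if (is.finite(logr) && log(stats::runif(1)) < logr) {
      beta <- bp; ll_long <- llp; ll_surv <- lsp
      acc$beta <- acc$beta + 1
    }

    # random effects, all subjects in parallel with per-subject accept
    sd0 <- exp(dpar[1]); sd1 <- exp(dpar[2]); rho <- tanh(dpar[3])
    bp2 <- b + cbind(scales$b[1] * stats::rnorm(n), scales$b[2] * stats::rnorm(n))
    llp <- ll_long_fun(beta, bp2, lsig); lsp <- ll_surv_fun(beta, bp2, logh0, sc)
    det <- (sd0 * sd1)^2 * (1 - rho^2)
    qf <- function(bb) (bb[, 1] / sd0)^2 -
      2 * rho * (bb[, 1] / sd0) * (bb[, 2] / sd1) + (bb[, 2] / sd1)^2
    lpr_new <- -0.5 * qf(bp2) / (1 - rho^2)
    lpr_old <- -0.5 * qf(b) / (1 - rho^2)
    ai <- log(stats::runif(n)) < (llp + lsp + lpr_new) -
      (ll_long + ll_surv + lpr_old)
    if (any(ai)) {
      b[ai, ] <- bp2[ai, ]
      ll_long[ai] <- llp[ai]; ll_surv[ai] <- lsp[ai]
      lpr_old[ai] <- lpr_new[ai]
    }
    acc$b <- acc$b + mean(ai)

    # slope-only refresh: the random slopes are weakly identified and mix
    # slowly inside the joint (b0, b1) proposal
    bp2 <- b; bp2[, 2] <- b[, 2] + 0.5 * scales$b[2] * stats::rnorm(n)
    llp <- ll_long_fun(beta, bp2, lsig); lsp <- ll_surv_fun(beta, bp2, logh0, sc)
    lpr_new <- -0.5 * qf(bp2) / (1 - rho^2)
    ai <- log(stats::runif(n)) < (llp + lsp + lpr_new) -
      (ll_long + ll_surv + lpr_old)
    if (any(ai)) {
      b[ai, ] <- bp2[ai, ]
      ll_long[ai] <- llp[ai]; ll_surv[ai] <- lsp[ai]
      lpr_old[ai] <- lpr_new[ai]
    }

    # recentring moves: shift mass between a fixed effect and all random
    # effects (likelihood-invariant; only the priors change), which breaks
    # the beta0 / mean(b0) and beta1 / mean(b1) posterior ridges
    sd0 <- exp(dpar[1]); sd1 <- exp(dpar[2]); rho <- tanh(dpar[3])
    for (comp in 1:2) {
      del <- stats::rnorm(1, 0, c(0.5, 0.02)[comp])
      beta_new <- beta; beta_new[comp] <- beta[comp] + del
      b_new <- b; b_new[, comp] <- b[, comp] - del
      logr <- .lp_ranef(b_new, sd0, sd1, rho) - .lp_ranef(b, sd0, sd1, rho) +
        lp_beta(beta_new) - lp_beta(beta)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        beta <- beta_new; b <- b_new
      }
    }

    # residual SD
    lsp2 <- lsig + scales$sig * stats::rnorm(1)
    llp <- ll_long_fun(beta, b, lsp2)
    logr <- sum(llp - ll_long) + lp_lsig(lsp2) - lp_lsig(lsig)
    if (is.finite(logr) && log(stats::runif(1)) < logr) {
      lsig <- lsp2; ll_long <- llp; acc$sig <- acc$sig + 1
    }

    # random-effects covariance (only the b prior depends on it)
    dp <- dpar + scales$dpar * stats::rnorm(3)
    logr <- .lp_ranef(b, exp(dp[1]), exp(dp[2]), tanh(dp[3])) -
      .lp_ranef(b, exp(dpar[1]), exp(dpar[2]), tanh(dpar[3])) +
      lp_dpar(dp) - lp_dpar(dpar)
    if (is.finite(logr) && log(stats::runif(1)) < logr) {
      dpar <- dp; acc$dpar <- acc$dpar + 1
    }

    # baseline log-rates
    hp <- logh0 + scales$h0 * stats::rnorm(np)
    lsp <- ll_surv_fun(beta, b, hp, sc)
    logr <- sum(lsp - ll_surv) + lp_surv_coefs(hp) - lp_surv_coefs(logh0)
    if (is.finite(logr) && log(stats::runif(1)) < logr) {
      logh0 <- hp; ll_surv <- lsp; acc$h0 <- acc$h0 + 1
    }

    # covariate and association coefficients
    scp <- if (is.null(chol_sc))
      sc + scales$sc * base_sc * stats::rnorm(nsc)
    else
      sc + scales$sc * drop(stats::rnorm(nsc) %*% chol_sc)
    lsp <- ll_surv_fun(beta, b, logh0, scp)
    logr <- sum(lsp - ll_surv) + lp_surv_coefs(scp) - lp_surv_coefs(sc)
    if (is.finite(logr) && log(stats::runif(1)) < logr) {
      sc <- scp; ll_surv <- lsp; acc$sc <- acc$sc + 1
    }

    if (it <= spec$warmup) {
      hist_beta[it, ] <- beta
      hist_sc[it, ] <- sc
      if (it >= 200L && it %% 100L == 0L) {
        nb_chol <- upd_chol(hist_beta, it)
        ns_chol <- upd_chol(hist_sc, it)
        if (!is.null(nb_chol)) {
          if (is.null(chol_beta)) scales$beta <- 2.38 / sqrt(nb)
          chol_beta <- nb_chol
        }
        if (!is.null(ns_chol)) {
          if (is.null(chol_sc)) scales$sc <- 2.38 / sqrt(nsc)
          chol_sc <- ns_chol
        }
      }
    }

    # proposal adaptation toward 0.25-0.45 acceptance, warmup only
    if (it <= spec$warmup && it %% adapt_every == 0L) {
      tune <- function(s, a) {
        r <- a / adapt_every
        if (r > 0.45) s * exp(0.25) else if (r < 0.25) s * exp(-0.25) else s
      }
      scales$beta <- tune(scales$beta, acc$beta)
      scales$sig <- tune(scales$sig, acc$sig)
      scales$dpar <- tune(scales$dpar, acc$dpar)
      scales$h0 <- tune(scales$h0, acc$h0)
      scales$sc <- tune(scales$sc, acc$sc)
      rb <- acc$b / adapt_every
      if (rb > 0.45) scales$b <- scales$b * exp(0.25)
      else if (rb < 0.25) scales$b <- scales$b * exp(-0.25)
      acc <- list(beta = 0, b = 0, sig = 0, dpar = 0, h0 = 0, sc = 0)
    }

    if (it > spec$warmup) {
      k <- it - spec$warmup
      draws[k, ] <- c(beta[1], beta[2], if (nb > 2) beta[3:nb],
                      exp(lsig), exp(dpar[1]), exp(dpar[2]), tanh(dpar[3]),
                      logh0, sc)
      pointwise[k, ] <- ll_long + ll_surv
      ranef[k, , ] <- b
    }
  }
  accept_rates <- vapply(acc, function(a) a / (n_iter - spec$warmup),
                         numeric(1))
  list(draws = draws, pointwise = pointwise, ranef = ranef,
       accept = accept_rates)
}

# split-R-hat over chains (each chain split in half)
.split_rhat <- function(mat_list) {
  halves <- list()
  for (m in mat_list) {
    L <- floor(nrow(m) / 2)
    halves <- c(halves, list(m[seq_len(L), , drop = FALSE],
                             m[(nrow(m) - L + 1):nrow(m), , drop = FALSE]))
  }
  nchain <- length(halves); L <- nrow(halves[[1]])
  vapply(seq_len(ncol(halves[[1]])), function(j) {
    x <- vapply(halves, function(h) h[, j], numeric(L))
    mu <- colMeans(x); s2 <- apply(x, 2, stats::var)
    W <- mean(s2); B <- L * stats::var(mu)
    if (W < 1e-12) return(1)
    sqrt(((L - 1) / L * W + B / L) / W)
  }, numeric(1))
}

# crude effective sample size: initial positive-sum autocorrelation estimator
.ess <- function(mat_list) {
  vapply(seq_len(ncol(mat_list[[1]])), function(j) {
    tot <- 0
    for (m in mat_list) {
      x <- m[, j]; L <- length(x)
      if (stats::var(x) < 1e-12) { tot <- tot + L; next }
      rho <- stats::acf(x, lag.max = min(100, L - 1), plot = FALSE,
                        demean = TRUE)$acf[-1]
      s <- 0
      for (r in rho) { if (r < 0.05) break; s <- s + r }
      tot <- tot + L / (1 + 2 * s)
    }
    tot
  }, numeric(1))
}

#' Fit the Bayesian joint longitudinal-survival model
#'
#' Links the linear mixed-effects TTC trajectory to the progression hazard
#' through the chosen association structure and samples the joint posterior
#' by adaptive Metropolis-within-Gibbs: blocked random-walk updates for the
#' longitudinal fixed effects, all subject random effects (independent
#' per-subject acceptance), the residual SD, the random-effects covariance,
#' the piecewise-constant baseline log-rates, and the covariate/association
#' coefficients. Chains are initialized from [fit_lmm()] and [cox_fit()]
#' estimates, with overdispersed starts after the first chain. Convergence
#' is monitored with split-R-hat; a warning is raised if any association
#' coefficient has R-hat above 1.05.
#'
#' @param records Longitudinal records ([as_longitudinal_records()] layout).
#' @param surv Survival table (one row per patient).
#' @param spec A [jm_spec()] object.
#' @param covariates Baseline covariates of the survival sub-model.
#' @param seed Integer seed (mandatory: every run is reproducible).
#' @return An object of class `jm_fit`: combined posterior `draws` (kept
#'   draws x parameters, with a `chain` attribute), per-subject random
#'   effect draws, per-subject pointwise log-likelihoods, `waic`, `lpml`,
#'   `rhat`, `ess`, acceptance rates, and the `jm_prep` data.
#' @export
fit_joint <- function(records, surv, spec = jm_spec(),
                      covariates = "prior_alki", seed) {
  if (missing(seed)) stop("'seed' is mandatory for fit_joint")
  stopifnot(inherits(spec, "jm_spec"))
  prep <- jm_prepare(records, surv, spec, covariates)

  lmm <- suppressWarnings(fit_lmm(records))
  cox <- cox_fit(surv, covariates)
  dc0 <- numeric(prep$K)
  if (prep$K > 1 && lmm$use_dose) {
    for (k in 2:prep$K) {
      l <- as.character(prep$dose_levels[k])
      if (l %in% names(lmm$dose_coefs)) dc0[k] <- lmm$dose_coefs[[l]]
    }
  }
  b0 <- matrix(0, prep$n, 2)
  idx <- match(as.character(prep$ids), rownames(lmm$per_subject_modes))
  ok <- !is.na(idx)
  b0[ok, ] <- lmm$per_subject_modes[idx[ok], , drop = FALSE]
  rho0 <- if (lmm$random_cov[2, 2] > 0)
    lmm$random_cov[1, 2] / sqrt(lmm$random_cov[1, 1] * lmm$random_cov[2, 2])
  else 0
  init <- list(beta0 = unname(lmm$fixed["(Intercept)"]),
               beta1 = unname(lmm$fixed["t"]), dc = dc0,
               sigma = sqrt(lmm$resid_var), b = b0,
               sd0 = max(sqrt(lmm$random_cov[1, 1]), 0.5),
               sd1 = max(sqrt(lmm$random_cov[2, 2]), 0.02),
               rho = min(max(rho0, -0.9), 0.9),
               phi = stats::setNames(coef(cox)[seq_along(covariates)],
                                     covariates),
               logh0 = .init_logh0(prep$ev$t, prep$ev$delta, prep$knots))

  chains <- lapply(seq_len(spec$chains), function(cid)
    .jm_chain(prep, spec, init, seed, cid))

  draw_list <- lapply(chains, `[[`, "draws")
  draws <- do.call(rbind, draw_list)
  attr(draws, "chain") <- rep(seq_len(spec$chains), each = spec$draws)
  pointwise <- do.call(rbind, lapply(chains, `[[`, "pointwise"))
  ranef <- do.call(abind2, lapply(chains, `[[`, "ranef"))

  rhat <- if (spec$chains >= 2)
    stats::setNames(.split_rhat(draw_list), colnames(draws))
  else stats::setNames(rep(NA_real_, ncol(draws)), colnames(draws))
  ess <- stats::setNames(.ess(draw_list), colnames(draws))

  a_cols <- grep("^alpha_", colnames(draws), value = TRUE)
  if (spec$chains >= 2 && any(rhat[a_cols] > 1.05, na.rm = TRUE))
    warning("association coefficient split-R-hat above 1.05: ",
            "chains may not have converged; increase warmup/draws")

  fit <- structure(list(draws = draws, ranef = ranef, pointwise = pointwise,
                        rhat = rhat, ess = ess,
                        accept = lapply(chains, `[[`, "accept"),
                        spec = spec, prep = prep, init = init, seed = seed),
                   class = "jm_fit")
  fit$waic <- waic(fit)
  fit$lpml <- lpml(fit)
  fit$hr <- summarize_hr(fit)
  fit
}

# bind 3-d arrays along the first dimension
abind2 <- function(...) {
  arrs <- list(...)
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1], 0L)),
                           dim(arrs[[1]])[2], dim(arrs[[1]])[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Watanabe-Akaike information criterion of a joint model fit
#'
#' \eqn{WAIC = -2(\widehat{lppd} - p_{WAIC})} with one pointwise term per
#' subject, using the conditional (given the subject's random effects) joint
#' density of that subject's longitudinal and survival data, and the
#' variance-based effective parameter count. Smaller is better. Computed
#' with a stabilized log-mean-exp.
#'
#' @param fit A [fit_joint()] object.
#' @return WAIC (scalar) with attributes `lppd` and `p_waic`.
#' @export
waic <- function(fit) {
  stopifnot(inherits(fit, "jm_fit"))
  ll <- fit$pointwise
  lppd <- sum(apply(ll, 2, logmeanexp))
  p <- sum(apply(ll, 2, stats::var))
  structure(-2 * (lppd - p), lppd = lppd, p_waic = p)
}

#' Log pseudo-marginal likelihood of a joint model fit
#'
#' \eqn{LPML = \sum_i \log CPO_i}, where each conditional predictive
#' ordinate is the harmonic-mean estimator
#' \eqn{CPO_i = (\mathrm{mean}_s\, 1/p(y_i \mid \theta_s))^{-1}} over
#' posterior draws, computed with a stabilized log-mean-exp. Larger is
#' better.
#'
#' @param fit A [fit_joint()] object.
#' @return LPML (scalar).
#' @export
lpml <- function(fit) {
  stopifnot(inherits(fit, "jm_fit"))
  sum(apply(fit$pointwise, 2, function(x) -logmeanexp(-x)))
}

#' Hazard-ratio summary of a joint model fit
#'
#' Posterior medians and 95% credible intervals of the hazard ratios, with
#' association coefficients scaled per `per_unit` TTC units and the
#' corresponding percent risk reduction `(1 - HR) * 100` rounded to the
#' nearest integer. The two-sided posterior tail probability of the
#' coefficient crossing zero is reported as `p`.
#'
#' @param fit A [fit_joint()] object.
#' @param per_unit TTC units per step for the association coefficients.
#' @return Data frame: variable, hr, ci_low, ci_high, pct_reduction, p.
#' @export
summarize_hr <- function(fit, per_unit = 1) {
  stopifnot(inherits(fit, "jm_fit"))
  cols <- c(grep("^alpha_", colnames(fit$draws), value = TRUE),
            grep("^phi_", colnames(fit$draws), value = TRUE))
  rows <- lapply(cols, function(cn) {
    x <- fit$draws[, cn]
    mult <- if (startsWith(cn, "alpha_")) per_unit else 1
    q <- stats::quantile(mult * x, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(variable = cn, hr = exp(q[1]), ci_low = exp(q[2]),
               ci_high = exp(q[3]),
               pct_reduction = round((1 - exp(q[1])) * 100),
               p = 2 * min(mean(x > 0), mean(x < 0)))
  })
  do.call(rbind, rows)
}

#' @export
print.jm_fit <- function(x, ...) {
  cat(sprintf("Bayesian joint model (%s association)\n", x$spec$association))
  cat(sprintf("  %d patients, %d TTC observations, %d events; %d chains x %d draws\n",
              x$prep$n, length(x$prep$long$y), sum(x$prep$ev$delta),
              x$spec$chains, x$spec$draws))
  cat(sprintf("  WAIC %.1f   LPML %.1f   max R-hat %.3f\n",
              as.numeric(x$waic), x$lpml, suppressWarnings(max(x$rhat, na.rm = TRUE))))
  cat("Hazard ratios (posterior median, 95% CrI):\n")
  tab <- x$hr
  tab[c("hr", "ci_low", "ci_high")] <- lapply(tab[c("hr", "ci_low", "ci_high")],
                                              round, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.jm_fit <- function(object, ...) {
  apply(object$draws, 2, stats::median)
}

#' @export
summary.jm_fit <- function(object, ...) {
  qs <- t(apply(object$draws, 2, stats::quantile,
                probs = c(0.5, 0.025, 0.975)))
  data.frame(parameter = colnames(object$draws),
             median = qs[, 1], ci_low = qs[, 2], ci_high = qs[, 3],
             rhat = object$rhat, ess = round(object$ess),
             row.names = NULL)
}
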