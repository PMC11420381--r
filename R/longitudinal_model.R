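#' Build longitudinal model records from an augmented PK table
#'
#' Converts the augmented sample table (output of [transform_troughs()]) to
#' the record layout consumed by [fit_lmm()]: one row per TTC observation
#' with the time since treatment start and the dose level at sampling.
#' Dose levels are coded as reduction steps below the standard dose
#' (0 = standard, 1 = first reduction, ...).
#'
#' @param long_aug Data frame with at least `patient_id`, `t_obs_months`,
#'   `ttc`, `dose_mg`.
#' @param dose_levels_mg Dose ladder, highest first; defaults to the sorted
#'   unique doses observed.
#' @return Data frame with columns `patient_id`, `t`, `ttc_value`,
#'   `dose_level`.
#' @export
as_longitudinal_records <- function(long_aug, dose_levels_mg = NULL) {
  need <- c("patient_id", "t_obs_months", "ttc", "dose_mg")
  miss <- setdiff(need, names(long_aug))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(dose_levels_mg))
    dose_levels_mg <- sort(unique(long_aug$dose_mg), decreasing = TRUE)
  lev <- match(long_aug$dose_mg, dose_levels_mg) - 1L
  if (anyNA(lev))
    stop("doses not on the supplied ladder: ",
         paste(unique(long_aug$dose_mg[is.na(lev)]), collapse = ", "))
  data.frame(patient_id = long_aug$patient_id,
             t = long_aug$t_obs_months,
             ttc_value = long_aug$ttc,
             dose_level = lev)
}

#' Fit the linear mixed-effects sub-model for TTC trajectories
#'
#' Fits, by maximum likelihood, the Gaussian linear mixed model
#' \deqn{y_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i}) t_{ij}
#'   + \beta_d[\mathrm{dose}_{ij}] + \varepsilon_{ij}}
#' with a correlated subject-level random intercept and slope and, when the
#' data contain more than one dose level, a categorical dose covariate
#' (reference = standard dose). Patients with a single observation are
#' retained; their empirical Bayes effects shrink to the population mean.
#' If the random-effects covariance is singular the model is refitted with a
#' random intercept only and flagged.
#'
#' @param records Data frame from [as_longitudinal_records()]: columns
#'   `patient_id`, `t` (months), `ttc_value`, `dose_level`.
#' @param include_dose Include the dose covariate when it varies. Default TRUE.
#' @return An object of class `lmm_fit` with elements `fixed`, `fixed_se`,
#'   `random_cov` (2x2 covariance of intercept/slope effects), `resid_var`,
#'   `loglik`, `per_subject_modes` (empirical Bayes intercept/slope modes),
#'   `dose_coefs` (named by level, reference 0), `singular`, and the
#'   underlying `lme4` fit in `model`.
#' @export
fit_lmm <- function(records, include_dose = TRUE) {
  need <- c("patient_id", "t", "ttc_value", "dose_level")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(records$patient_id)) < 2)
    stop("need at least 2 patients")
  if (any(records$ttc_value < 0 | records$ttc_value >= 100))
    stop("ttc_value outside [0, 100)")
  if (any(records$t < 0)) stop("negative observation times")

  d <- records
  d$patient_id <- factor(d$patient_id)
  use_dose <- include_dose && length(unique(d$dose_level)) > 1
  d$dose_f <- factor(d$dose_level, levels = sort(unique(d$dose_level)))

  form <- if (use_dose) ttc_value ~ t + dose_f + (1 + t | patient_id)
          else ttc_value ~ t + (1 + t | patient_id)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            check.nobs.vs.nlev = "ignore")
  fit <- suppressWarnings(lme4::lmer(form, data = d, REML = FALSE,
                                     control = ctrl))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  slope_random <- TRUE
  if (singular) {
    form2 <- if (use_dose) ttc_value ~ t + dose_f + (1 | patient_id)
             else ttc_value ~ t + (1 | patient_id)
    fit <- suppressWarnings(lme4::lmer(form2, data = d, REML = FALSE,
                                       control = ctrl))
    slope_random <- FALSE
    warning("singular random-effects covariance; refitted with random intercept only")
  }

  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  if (slope_random) {
    sd0 <- vc$sdcor[vc$grp == "patient_id" & vc$var1 == "(Intercept)" &
                      is.na(vc$var2)]
    sd1 <- vc$sdcor[vc$grp == "patient_id" & vc$var1 == "t" & is.na(vc$var2)]
    rho <- vc$sdcor[vc$grp == "patient_id" & !is.na(vc$var2)]
    if (!length(rho)) rho <- 0
    D <- matrix(c(sd0^2, rho * sd0 * sd1, rho * sd0 * sd1, sd1^2), 2, 2)
  } else {
    sd0 <- vc$sdcor[vc$grp == "patient_id" & vc$var1 == "(Intercept)" &
                      is.na(vc$var2)]
    D <- matrix(c(sd0^2, 0, 0, 0), 2, 2)
  }
  dimnames(D) <- list(c("intercept", "slope"), c("intercept", "slope"))
  resid_var <- vc$sdcor[vc$grp == "Residual"]^2

  re <- lme4::ranef(fit)$patient_id
  modes <- matrix(0, nrow(re), 2,
                  dimnames = list(rownames(re), c("b0", "b1")))
  modes[, 1] <- re[["(Intercept)"]]
  if (slope_random) modes[, 2] <- re[["t"]]

  dose_coefs <- c("0" = 0)
  if (use_dose) {
    lev <- levels(d$dose_f)
    dc <- stats::setNames(numeric(length(lev)), lev)
    for (l in lev[-1]) dc[l] <- fe[[paste0("dose_f", l)]]
    dose_coefs <- dc
  }

  structure(list(fixed = fe, fixed_se = se, random_cov = D,
                 resid_var = resid_var,
                 loglik = as.numeric(stats::logLik(fit)),
                 per_subject_modes = modes, dose_coefs = dose_coefs,
                 use_dose = use_dose, slope_random = slope_random,
                 singular = singular, data = d, model = fit),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed-effects TTC sub-model (ML)\n")
  cat(sprintf("  %d observations, %d patients; logLik %.2f%s\n",
              nrow(x$data), nrow(x$per_subject_modes), x$loglik,
              if (x$singular) " [random intercept only]" else ""))
  tab <- data.frame(estimate = x$fixed, se = x$fixed_se)
  print(round(tab, 4))
  cat(sprintf("  Random effects: SD(intercept) %.3f, SD(slope) %.3f, corr %.3f; residual SD %.3f\n",
              sqrt(x$random_cov[1, 1]), sqrt(x$random_cov[2, 2]),
              if (x$random_cov[2, 2] > 0)
                x$random_cov[1, 2] / sqrt(x$random_cov[1, 1] * x$random_cov[2, 2])
              else 0,
              sqrt(x$resid_var)))
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) object$fixed

#' @export
summary.lmm_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$fixed, se = object$fixed_se,
                    z = object$fixed / object$fixed_se)
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  tab
}

#' Per-subject TTC trajectory from a fitted mixed model
#'
#' Combines the fixed effects with the patient's empirical Bayes modes and a
#' dose history into the piecewise-linear trajectory
#' \eqn{m_i(t)}: linear in time between dose changes, with a step of the
#' fitted dose coefficient at each change, evaluated left-continuously.
#'
#' @param fit An [fit_lmm()] object.
#' @param patient_id A patient present in the fit.
#' @param dose_history Optional data frame `(time, dose_level)` of
#'   piecewise-constant dose levels from time 0. Defaults to carrying the
#'   patient's observed sampling doses forward (and the first backward).
#' @return A `ttc_trajectory` (see [make_trajectory()], [traj_eval()]).
#' @export
subject_trajectory <- function(fit, patient_id, dose_history = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  pid <- as.character(patient_id)
  if (!pid %in% rownames(fit$per_subject_modes))
    stop("unknown patient: ", pid)
  b <- fit$per_subject_modes[pid, ]
  if (is.null(dose_history)) {
    rows <- fit$data[as.character(fit$data$patient_id) == pid, ]
    rows <- rows[order(rows$t), ]
    dose_history <- data.frame(time = rows$t, dose_level = rows$dose_level)
    dose_history$time[1] <- 0  # first observed dose carried backward
    keep <- c(TRUE, diff(dose_history$dose_level) != 0)
    dose_history <- dose_history[keep, ]
  }
  stopifnot(all(c("time", "dose_level") %in% names(dose_history)),
            dose_history$time[1] == 0)
  sv <- vapply(as.character(dose_history$dose_level), function(l) {
    if (!fit$use_dose) 0 else {
      if (!l %in% names(fit$dose_coefs))
        stop("dose level ", l, " not present in the fitted model")
      fit$dose_coefs[[l]]
    }
  }, numeric(1))
  make_trajectory(intercept = unname(fit$fixed["(Intercept)"] + b[1]),
                  slope = unname(fit$fixed["t"] + b[2]),
                  step_times = dose_history$time,
                  step_values = unname(sv))
}
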