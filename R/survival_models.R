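#' Kaplan-Meier estimate of progression-free survival
#'
#' Product-limit estimator with Greenwood variance and log-log transformed
#' 95% confidence intervals; the median is the first time the estimated
#' survival drops to or below 0.5.
#'
#' @param records Survival table: columns `time_months` (> 0) and `event`
#'   (1 = progression/death, 0 = censored).
#' @return An object of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `surv`, `lower`, `upper`, `median`, `median_ci`, and the underlying
#'   `survfit` object in `model`.
#' @export
km_fit <- function(records) {
  stopifnot(all(c("time_months", "event") %in% names(records)),
            all(records$time_months > 0), all(records$event %in% 0:1))
  if (sum(records$event) < 1) warning("no events: median undefined")
  sf <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                          data = records, conf.type = "log-log")
  q <- stats::quantile(sf, probs = 0.5)
  structure(list(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                 surv = sf$surv, lower = sf$lower, upper = sf$upper,
                 median = unname(q$quantile), median_ci = c(unname(q$lower),
                                                            unname(q$upper)),
                 model = sf),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier: %d events / %d subjects; median %.1f months (95%% CI %.1f-%s)\n",
              sum(x$n_event), x$n_risk[1], x$median, x$median_ci[1],
              ifelse(is.na(x$median_ci[2]), "NA",
                     sprintf("%.1f", x$median_ci[2]))))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(x$model, xlab = "Months since treatment start",
       ylab = "Progression-free survival", ...)
  invisible(x)
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Kaplan-Meier with the event indicator flipped, so that censoring is the
#' "event": the resulting median estimates the median follow-up duration.
#'
#' @param records As in [km_fit()]; needs at least one censored subject.
#' @return Median follow-up in months.
#' @export
reverse_km_followup <- function(records) {
  if (sum(records$event == 0) < 1)
    stop("no censored subjects: reverse Kaplan-Meier follow-up undefined")
  flipped <- records
  flipped$event <- 1 - flipped$event
  km_fit(flipped)$median
}

#' Cox proportional hazards fit
#'
#' Maximizes the partial likelihood with Efron's tie handling by
#' Newton-Raphson (via the survival package) and reports hazard ratios with
#' Wald 95% confidence intervals.
#'
#' @param records Survival table with `time_months`, `event`, and the
#'   requested covariate columns.
#' @param covariates Character vector of covariate column names (or
#'   transformed terms) to include.
#' @param ties Tie-handling method; `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_fit`: a `table` data frame (variable,
#'   coef, se, HR, ci_low, ci_high, p), `loglik`, `loglik_null`,
#'   `separation` flag, and the `coxph` fit in `model`.
#' @export
cox_fit <- function(records, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time_months", "event") %in% names(records)),
            length(covariates) >= 1)
  if (sum(records$event) < 2) stop("need at least 2 events")
  .fit_cox(records, covariates, ties, "survival::Surv(time_months, event)")
}

# shared fitting path for baseline and counting-process data; covariates
# that are constant columns contribute coefficient 0 (null model) rather
# than a collinearity failure
.fit_cox <- function(data, covariates, ties, lhs) {
  is_const <- vapply(covariates, function(cv)
    cv %in% names(data) && length(unique(data[[cv]])) == 1L, TRUE)
  fit_cov <- covariates[!is_const]
  n_events <- sum(data$event)
  if (length(fit_cov)) {
    form <- stats::as.formula(paste(lhs, "~",
                                    paste(fit_cov, collapse = " + ")))
    fit <- withCallingHandlers(
      survival::coxph(form, data = data, ties = ties),
      warning = function(w) {
        if (grepl("infinite|converge", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    out <- .cox_result(fit, n_events)
  } else {
    form <- stats::as.formula(paste(lhs, "~ 1"))
    fit <- survival::coxph(form, data = data, ties = ties)
    ll <- fit$loglik[1]
    out <- structure(list(table = NULL, loglik = ll, loglik_null = ll,
                          n_events = n_events, separation = FALSE,
                          model = fit),
                     class = "cox_fit")
  }
  if (any(is_const)) {
    zero <- data.frame(variable = covariates[is_const], coef = 0,
                       se = NA_real_, hr = 1, ci_low = NA_real_,
                       ci_high = NA_real_, p = NA_real_)
    out$table <- rbind(out$table, zero)
  }
  out
}

.cox_result <- function(fit, n_events) {
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("collinear covariates: ", paste(names(cf)[is.na(cf)], collapse = ", "))
  se <- sqrt(diag(fit$var))
  separation <- any(abs(cf) > 15) || any(se > 1e3)
  if (separation) warning("possible monotone likelihood (separation) detected")
  tab <- data.frame(variable = names(cf), coef = unname(cf), se = se,
                    hr = exp(unname(cf)),
                    ci_low = exp(unname(cf) - 1.96 * se),
                    ci_high = exp(unname(cf) + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(unname(cf) / se)),
                    row.names = NULL)
  structure(list(table = tab, loglik = fit$loglik[2],
                 loglik_null = fit$loglik[1], n_events = n_events,
                 separation = separation, model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional hazards fit (Efron ties): %d events, partial logLik %.2f\n",
              x$n_events, x$loglik))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  stats::setNames(object$table$coef, object$table$variable)
}

#' Per-patient exposure summaries
#'
#' Median trough concentration and median TTC per patient, the exposure
#' metrics entering the baseline Cox models.
#'
#' @param long_aug Augmented longitudinal table (from [transform_troughs()]).
#' @return Data frame: `patient_id`, `median_trough`, `median_ttc`.
#' @export
aggregate_exposure <- function(long_aug) {
  stopifnot(all(c("patient_id", "trough_ng_ml", "ttc") %in% names(long_aug)))
  sp <- split(long_aug, long_aug$patient_id)
  out <- data.frame(
    patient_id = names(sp),
    median_trough = vapply(sp, function(d) stats::median(d$trough_ng_ml), 0),
    median_ttc = vapply(sp, function(d) stats::median(d$ttc), 0),
    row.names = NULL)
  if (is.numeric(long_aug$patient_id))
    out$patient_id <- as.numeric(out$patient_id)
  out[order(out$patient_id), , drop = FALSE]
}

#' Dichotomize exposure at the therapeutic target
#'
#' Labels each patient's (median) trough concentration as `adequate`
#' (>= threshold, boundary included) or `inadequate` (the reference level).
#'
#' @param median_trough Numeric vector of per-patient median troughs (ng/mL).
#' @param threshold Target trough (ng/mL); default 435.
#' @return Factor with levels `inadequate` (reference), `adequate`.
#' @export
dichotomize_exposure <- function(median_trough, threshold = 435) {
  stopifnot(is.numeric(median_trough), threshold > 0)
  factor(ifelse(median_trough >= threshold, "adequate", "inadequate"),
         levels = c("inadequate", "adequate"))
}

#' Expand survival data to counting-process rows (last value carried forward)
#'
#' Builds `(start, stop]` rows in which each time-varying exposure column is
#' held constant at its most recent measured value (LVCF). By default the
#' interval before a patient's first measurement carries the first value
#' backward to time 0; with `carry_back = FALSE` that interval is excluded
#' (delayed entry). Measurements at or after the event/censoring time are
#' dropped with a warning; patients without longitudinal data are excluded.
#'
#' @param records Survival table (one row per patient) including baseline
#'   covariates.
#' @param long_aug Augmented longitudinal table with `patient_id`,
#'   `t_obs_months`, and the `value_cols`.
#' @param value_cols Time-varying columns to carry forward.
#' @param carry_back Carry the first value back to time 0 (default TRUE).
#' @return Data frame of counting-process rows: `patient_id`, `start`,
#'   `stop`, `event`, the LVCF `value_cols`, and the baseline covariates.
#' @export
expand_lvcf <- function(records, long_aug,
                        value_cols = c("ttc", "trough_ng_ml"),
                        carry_back = TRUE) {
  stopifnot(all(c("patient_id", "time_months", "event") %in% names(records)),
            all(c("patient_id", "t_obs_months") %in% names(long_aug)),
            all(value_cols %in% names(long_aug)))
  base_cols <- setdiff(names(records), c("time_months", "event"))
  out <- vector("list", nrow(records))
  dropped_late <- 0L; excluded <- character(0)
  for (r in seq_len(nrow(records))) {
    pid <- records$patient_id[r]
    Ti <- records$time_months[r]
    ev <- records$event[r]
    li <- long_aug[long_aug$patient_id == pid, , drop = FALSE]
    li <- li[order(li$t_obs_months), , drop = FALSE]
    late <- li$t_obs_months >= Ti
    dropped_late <- dropped_late + sum(late)
    li <- li[!late, , drop = FALSE]
    if (nrow(li) == 0) { excluded <- c(excluded, as.character(pid)); next }
    # one interval per inter-measurement gap; duplicate times keep the last
    li <- li[!duplicated(li$t_obs_months, fromLast = TRUE), , drop = FALSE]
    tm <- li$t_obs_months
    k <- length(tm)
    starts <- if (carry_back) c(0, tm[-1]) else tm
    stops <- c(tm[-1], Ti)
    keep <- starts < stops
    rows <- data.frame(patient_id = pid, start = starts[keep],
                       stop = stops[keep],
                       event = c(rep(0L, sum(keep) - 1L), ev))
    for (vc in value_cols) rows[[vc]] <- li[[vc]][keep]
    for (bc in setdiff(base_cols, "patient_id"))
      rows[[bc]] <- records[[bc]][r]
    out[[r]] <- rows
  }
  if (dropped_late > 0)
    warning(dropped_late, " measurement(s) at or after the event time dropped")
  if (length(excluded))
    message("excluded patients without usable longitudinal data: ",
            paste(excluded, collapse = ", "))
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Time-dependent Cox fit on counting-process data
#'
#' Partial-likelihood fit with risk sets defined by interval membership at
#' each event time. With one interval per patient this reduces exactly to
#' [cox_fit()].
#'
#' @param rows Counting-process rows from [expand_lvcf()].
#' @param covariates Covariate terms (may reference LVCF columns).
#' @param ties As in [cox_fit()].
#' @return A `cox_fit` object.
#' @export
td_cox_fit <- function(rows, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("patient_id", "start", "stop", "event") %in% names(rows)))
  if (any(rows$start >= rows$stop)) stop("degenerate interval (start >= stop)")
  for (p in split(rows, rows$patient_id)) {
    p <- p[order(p$start), ]
    if (nrow(p) > 1 && any(p$start[-1] < p$stop[-nrow(p)] - 1e-12))
      stop("overlapping intervals for patient ", p$patient_id[1])
    if (any(p$event[-nrow(p)] == 1))
      stop("event on a non-terminal interval for patient ", p$patient_id[1])
  }
  .fit_cox(rows, covariates, ties, "survival::Surv(start, stop, event)")
}

#' Backward elimination for Cox models
#'
#' Starting from the exposure variable plus all candidate covariates,
#' repeatedly removes the candidate with the largest Wald p-value at or above
#' `alpha` and refits, until all remaining candidates are significant.
#' Forced terms (the exposure, and any covariates listed in `forced`) are
#' never removed.
#'
#' @param data Survival table (baseline Cox) or counting-process rows
#'   (time-dependent Cox; detected by `start`/`stop` columns).
#' @param exposure The exposure term (always retained).
#' @param candidates Candidate covariate terms subject to elimination.
#' @param alpha Retention threshold on the Wald p-value (default 0.05).
#' @param forced Additional terms never removed.
#' @return The final `cox_fit`, with the eliminated terms (in removal order)
#'   in `$eliminated`.
#' @export
backward_eliminate <- function(data, exposure, candidates, alpha = 0.05,
                               forced = character(0)) {
  td <- all(c("start", "stop") %in% names(data))
  fitter <- if (td) td_cox_fit else cox_fit
  keep <- unique(c(exposure, forced))
  cand <- setdiff(candidates, keep)
  eliminated <- character(0)
  repeat {
    fit <- fitter(data, c(keep, cand))
    if (!length(cand)) break
    # worst p among rows belonging to candidate terms (factor terms may span rows)
    worst_p <- vapply(cand, function(tm) {
      rows <- startsWith(fit$table$variable, tm)
      if (!any(rows)) return(0)
      min(fit$table$p[rows])  # a term is retained if any of its levels is significant
    }, numeric(1))
    if (max(worst_p) < alpha) break
    drop_term <- cand[which.max(worst_p)]
    eliminated <- c(eliminated, drop_term)
    cand <- setdiff(cand, drop_term)
  }
  fit$eliminated <- eliminated
  fit
}
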