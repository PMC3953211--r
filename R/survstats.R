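#' Derive the three survival endpoints from clinical records
#'
#' Computes, per patient, time (months, day counts / 30.44) and event status
#' for progression-free survival (PFS), overall survival (OS) and
#' lymphoma-specific OS:
#' \itemize{
#'   \item PFS: event at progression/relapse; death from other causes is
#'     censored at the death date; patients in remission are censored at the
#'     last date known alive. A lymphoma death with no recorded progression
#'     is treated as a PFS event at the death date.
#'   \item OS: event at death from any cause; survivors censored at last
#'     follow-up.
#'   \item Lymphoma-specific OS: event only for lymphoma deaths; other
#'     deaths censored at the death date.
#' }
#'
#' @param clinical data.frame with columns `sample_id`,
#'   `registration_date`, `progression_date`, `death_date`,
#'   `last_followup_date` (Date or coercible), `cause` (one of "lymphoma",
#'   "other", "alive"). Records with a missing registration date are dropped
#'   with a warning.
#' @return data.frame: `sample_id`, `pfs_time`, `pfs_event`, `os_time`,
#'   `os_event`, `lsos_time`, `lsos_event` (times in months, events 0/1).
#' @export
derive_endpoints <- function(clinical) {
  stopifnot_cols(clinical, c("sample_id", "registration_date",
                             "progression_date", "death_date",
                             "last_followup_date", "cause"), "clinical")
  as_date <- function(x) if (inherits(x, "Date")) x else as.Date(x)
  reg <- as_date(clinical$registration_date)
  bad <- is.na(reg)
  if (any(bad)) {
    warning("dropping ", sum(bad), " record(s) with missing registration date")
    clinical <- clinical[!bad, , drop = FALSE]
    reg <- reg[!bad]
  }
  prog <- as_date(clinical$progression_date)
  death <- as_date(clinical$death_date)
  fu <- as_date(clinical$last_followup_date)
  fu[is.na(fu)] <- death[is.na(fu)]
  cause <- clinical$cause
  m <- function(d) pmax(months_between(reg, d), 1 / 30.44)

  has_prog <- !is.na(prog)
  died <- cause %in% c("lymphoma", "other") & !is.na(death)

  pfs_time <- ifelse(has_prog, m(prog),
                     ifelse(died, m(death), m(fu)))
  pfs_event <- as.integer(has_prog | (died & cause == "lymphoma"))
  os_time <- ifelse(died, m(death), m(fu))
  os_event <- as.integer(died)
  lsos_time <- os_time
  lsos_event <- as.integer(died & cause == "lymphoma")

  data.frame(sample_id = clinical$sample_id,
             pfs_time = pfs_time, pfs_event = pfs_event,
             os_time = os_time, os_event = os_event,
             lsos_time = lsos_time, lsos_event = lsos_event,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times Follow-up times (> 0).
#' @param events Event indicators (1 = event, 0 = censored).
#' @return data.frame with one row per distinct time: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (the product-limit estimate; `S(0) = 1`
#'   and the curve drops only at event times). The underlying
#'   `survival::survfit` object is attached as attribute `fit`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) >= 1, length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  attr(out, "fit") <- fit
  class(out) <- c("km_fit", "data.frame")
  out
}

#' Survival probability at a time point
#'
#' Reads the step-function value of a [km_estimate()] curve at `t` (e.g.
#' `t = 60` months for 5-year survival).
#'
#' @param km A `km_fit` object.
#' @param t Time point(s).
#' @return Numeric survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  c(1, km$surv)[findInterval(t, km$time) + 1]
}

#' Log-rank test between two groups
#'
#' Standard (O - E)^2 / V chi-square test with 1 degree of freedom.
#'
#' @param times,events Follow-up times and event indicators.
#' @param group Two-level grouping per sample.
#' @return List: `chisq`, `p`, `n` (per-group sizes).
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0))
    stop("need two non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  list(chisq = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = sd$n)
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood Cox regression (via `survival::coxph`) with Breslow
#' tie handling by default and Wald p-values. One row per covariate.
#'
#' @param covariates Numeric vector, matrix or data.frame of per-sample
#'   covariates.
#' @param times,events Follow-up times and event indicators.
#' @param ties "breslow" (default) or "efron".
#' @return data.frame: `term`, `log_hr`, `se`, `z`, `p`.
#' @export
cox_fit <- function(covariates, times, events,
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (sum(events) < 1) stop("need at least one event")
  if (is.null(dim(covariates)))
    covariates <- data.frame(x = covariates)
  covariates <- as.data.frame(covariates)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v[!is.na(v)])) < 2)
      stop("covariate '", nm, "' is constant")
  }
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fit <- survival::coxph(
    survival::Surv(.time, .event) ~ ., data = dat, ties = ties)
  co <- summary(fit)$coefficients
  if (any(is.na(stats::coef(fit))))
    warning("collinear covariates: some coefficients are not estimable")
  if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE))
    warning("very large coefficient: possible complete separation")
  data.frame(term = rownames(co), log_hr = co[, "coef"],
             se = co[, "se(coef)"], z = co[, "z"],
             p = co[, "Pr(>|z|)"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' ROC-derived cutoff for a continuous marker
#'
#' AUC by the rank statistic (fraction of case/control pairs where the case
#' has the higher marker value, ties counted 0.5), 95% CI by the
#' Hanley-McNeil normal approximation, and the cutoff chosen among observed
#' marker values to maximize Youden's J (sensitivity + specificity - 1) for
#' the rule "positive if marker > cutoff". High marker is treated as the
#' risk direction.
#'
#' @param marker Numeric marker values.
#' @param outcome Binary outcome (1/TRUE = event); both classes required.
#' @param criterion Cutoff criterion; only "youden" is implemented.
#' @param conf_level Confidence level for the AUC CI.
#' @param name Marker name carried in the result.
#' @return List of class `cutoff_result`: `marker`, `cutoff`, `auc`,
#'   `auc_ci`, `auc_se`, `j` (Youden's J at the cutoff), `sensitivity`,
#'   `specificity`, `direction` ("high_risk").
#' @export
roc_cutoff <- function(marker, outcome, criterion = "youden",
                       conf_level = 0.95, name = "marker") {
  criterion <- match.arg(criterion, "youden")
  outcome <- as.logical(outcome)
  if (length(marker) != length(outcome)) stop("lengths differ")
  keep <- !is.na(marker) & !is.na(outcome)
  marker <- marker[keep]; outcome <- outcome[keep]
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")

  r <- rank(marker)
  auc <- (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(c(auc - zq * se, auc + zq * se), 0), 1)

  thr <- sort(unique(marker))
  sens <- vapply(thr, function(cc) sum(marker > cc & outcome) / n1,
                 numeric(1))
  spec <- vapply(thr, function(cc) sum(marker <= cc & !outcome) / n0,
                 numeric(1))
  j <- sens + spec - 1
  best <- which.max(j)  # ties: smallest qualifying cutoff
  structure(list(marker = name, cutoff = thr[best], auc = auc,
                 auc_ci = ci, auc_se = se, j = j[best],
                 sensitivity = sens[best], specificity = spec[best],
                 direction = "high_risk", criterion = criterion),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "ROC cutoff for %s: %.4g (Youden J = %.3f)\nAUC %.3f (%.0f%% CI %.3f-%.3f), high = risk\n",
    x$marker, x$cutoff, x$j, x$auc, 95, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}
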