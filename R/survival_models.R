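#' Z-score a vector against the analysis cohort
#'
#' `(x - mean(x)) / sd(x)` with the sample standard deviation, so hazard
#' ratios and regression slopes can be reported per Z-unit of the cohort.
#'
#' @param values numeric with at least 2 distinct finite values.
#' @return Standardized numeric vector.
#' @export
zscore <- function(values) {
  if (length(values) < 2L || any(!is.finite(values)))
    stop("need >= 2 finite values to Z-score")
  s <- sd(values)
  if (s == 0) stop("cannot Z-score a constant vector (zero variance)")
  (values - mean(values)) / s
}

#' Cox proportional-hazards model of cognitive conversion
#'
#' Fits a proportional-hazards model of conversion from normal cognition on
#' demographic covariates plus exactly one brain factor, which is Z-scored
#' against the analysis cohort so its hazard ratio is per unit Z increase
#' (age stays in years, so its hazard ratio is per year). Ties are handled
#' by the Efron approximation. The brain factor's evidence is summarized by
#' a likelihood-ratio test of the full model against the model without the
#' factor (1 df). Wald 95% confidence intervals are reported on the
#' hazard-ratio scale.
#'
#' @param records data.frame of subject records: the time/event columns, the
#'   brain factor, and the covariates. No missing values are allowed.
#' @param brain_factor name of the brain-factor column (e.g. `"fornix_fa"`
#'   or a significant-region mean log-Jacobian).
#' @param time_col,event_col names of the follow-up time (years, > 0) and
#'   conversion indicator (0/1) columns.
#' @param covariates covariate column names; default age, gender, education,
#'   ethnicity. Categorical covariates are treatment-coded with the most
#'   frequent level as reference.
#' @param zscore_factor Z-score the brain factor first (default `TRUE`).
#' @return An object of class `cox_fit`: `coefficients` (data.frame: term,
#'   coef, hr, hr_lo, hr_hi, p_wald), `lr_stat`, `lr_df`, `lr_p` (the brain
#'   factor's likelihood-ratio test), `brain_factor`, `n`, `n_events`, and
#'   the underlying `survival::coxph` fit as `model`.
#' @examples
#' rec <- simulate_survival_records(120, c(fa = 0.5), 0.12, 8, seed = 9)
#' fit <- fit_cox(rec, "fa", zscore_factor = FALSE)
#' fit
#' @export
fit_cox <- function(records, brain_factor,
                    time_col = "time_years", event_col = "event",
                    covariates = c("age", "gender", "education", "ethnicity"),
                    zscore_factor = TRUE) {
  needed <- c(time_col, event_col, brain_factor, covariates)
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  dat <- records[, needed, drop = FALSE]
  if (anyNA(dat)) stop("missing values in model columns (no imputation)")
  time <- dat[[time_col]]
  event <- dat[[event_col]]
  if (any(time <= 0)) stop("follow-up times must be > 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) < 1) stop("no conversion events: cannot fit a Cox model")

  # treatment coding with the most frequent level as reference
  for (cv in covariates) {
    if (is.character(dat[[cv]]) || is.factor(dat[[cv]])) {
      tb <- sort(table(as.character(dat[[cv]])), decreasing = TRUE)
      dat[[cv]] <- factor(as.character(dat[[cv]]), levels = names(tb))
    }
  }
  dat$.bf <- if (zscore_factor) zscore(dat[[brain_factor]])
             else dat[[brain_factor]]

  rhs_cov <- if (length(covariates)) paste(covariates, collapse = " + ")
             else "1"
  f_full <- stats::as.formula(sprintf(
    "survival::Surv(%s, %s) ~ %s + .bf", time_col, event_col, rhs_cov))
  f_red <- stats::as.formula(sprintf(
    "survival::Surv(%s, %s) ~ %s", time_col, event_col, rhs_cov))

  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(f_full, data = dat, ties = "efron"),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop(sprintf("collinear term(s) in the Cox model: %s",
                 paste(bad, collapse = ", ")))
  }
  if (any(grepl("converged before|infinite", warn)) ||
      any(abs(coef(fit)) > 15))
    stop("Cox fit did not converge (possible perfect separation)")
  fit_red <- survival::coxph(f_red, data = dat, ties = "efron")

  sm <- summary(fit)
  co <- sm$coefficients
  terms <- rownames(co)
  terms[terms == ".bf"] <- brain_factor
  ctab <- data.frame(term = terms,
                     coef = co[, "coef"],
                     hr = exp(co[, "coef"]),
                     hr_lo = exp(co[, "coef"] - qnorm(0.975) * co[, "se(coef)"]),
                     hr_hi = exp(co[, "coef"] + qnorm(0.975) * co[, "se(coef)"]),
                     p_wald = co[, "Pr(>|z|)"],
                     row.names = NULL, stringsAsFactors = FALSE)
  lr_stat <- as.numeric(2 * (logLik(fit) - logLik(fit_red)))
  lr_df <- 1L
  lr_p <- pchisq(lr_stat, df = lr_df, lower.tail = FALSE)
  structure(list(coefficients = ctab, lr_stat = lr_stat, lr_df = lr_df,
                 lr_p = lr_p, brain_factor = brain_factor,
                 zscored = zscore_factor, n = nrow(dat),
                 n_events = sum(event), model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  unit <- if (x$zscored) "per unit Z increase" else "per unit increase"
  cat(sprintf("Cox proportional-hazards fit: n = %d, events = %d\n",
              x$n, x$n_events))
  cat(sprintf("Brain factor '%s' (%s): LR chi^2 = %.3f (df %d), p = %.4g\n",
              x$brain_factor, unit, x$lr_stat, x$lr_df, x$lr_p))
  bf <- x$coefficients[x$coefficients$term == x$brain_factor, ]
  cat(sprintf("  hazard ratio %.3f (95%% CI %.3f-%.3f)\n",
              bf$hr, bf$hr_lo, bf$hr_hi))
  cat("Covariates:\n")
  cv <- x$coefficients[x$coefficients$term != x$brain_factor, ]
  for (i in seq_len(nrow(cv)))
    cat(sprintf("  %-20s HR %.3f (%.3f-%.3f), p = %.3g\n",
                cv$term[i], cv$hr[i], cv$hr_lo[i], cv$hr_hi[i], cv$p_wald[i]))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  setNames(object$coefficients$coef, object$coefficients$term)
}

#' @export
summary.cox_fit <- function(object, ...) {
  print(object)
  invisible(object$coefficients)
}
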