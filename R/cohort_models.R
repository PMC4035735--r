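#' Multiple regression of an ROI outcome on brain and demographic terms
#'
#' Ordinary least squares (with intercept) of a per-subject outcome — e.g.
#' the mean normalized log-Jacobian over the significant-association region —
#' on a set of predictors that may mix continuous and categorical columns.
#' Categorical terms are treatment-coded with the most frequent level as
#' reference, matching [fit_cox()]. Reports R-squared and two-sided t-test
#' p-values per term. Rank deficiency is an error naming the collinear
#' terms, never a silent fit.
#'
#' @param data data.frame holding outcome and terms; no missing values.
#' @param outcome name of the outcome column.
#' @param terms character vector of predictor column names.
#' @return An object of class `regression_fit`: `r_squared`, `coefficients`
#'   (data.frame: term, estimate, se, t, p), `n`, `df_residual`, and the
#'   underlying `lm` fit as `model`.
#' @examples
#' d <- data.frame(y = rnorm(30), a = rnorm(30), g = sample(c("x", "y"), 30, TRUE))
#' fit_multi_regression(d, "y", c("a", "g"))
#' @export
fit_multi_regression <- function(data, outcome, terms) {
  needed <- c(outcome, terms)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  dat <- data[, needed, drop = FALSE]
  if (anyNA(dat)) stop("missing values in model columns")
  for (tm in terms) {
    if (is.character(dat[[tm]]) || is.factor(dat[[tm]])) {
      tb <- sort(table(as.character(dat[[tm]])), decreasing = TRUE)
      dat[[tm]] <- factor(as.character(dat[[tm]]), levels = names(tb))
    }
  }
  f <- stats::as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
  fit <- lm(f, data = dat)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop(sprintf("rank-deficient design; collinear term(s): %s",
                 paste(bad, collapse = ", ")))
  }
  n <- nrow(dat)
  if (fit$df.residual < 1) stop("not enough subjects for the number of terms")
  sm <- summary(fit)
  co <- sm$coefficients
  ctab <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                     t = co[, 3], p = co[, 4],
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(r_squared = sm$r.squared, coefficients = ctab, n = n,
                 df_residual = fit$df.residual, outcome = outcome,
                 model = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("Multiple regression of '%s': n = %d, R^2 = %.3f\n",
              x$outcome, x$n, x$r_squared))
  for (i in seq_len(nrow(x$coefficients)))
    cat(sprintf("  %-20s %10.4g  (p = %.3g)\n", x$coefficients$term[i],
                x$coefficients$estimate[i], x$coefficients$p[i]))
  invisible(x)
}

#' @export
coef.regression_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Pearson correlation matrix of cohort factors
#'
#' Pairwise Pearson correlations of named per-subject factors (brain
#' measurements, ROI means, volumes). Any zero-variance factor is an error
#' naming the offending column.
#'
#' @param factors data.frame or named numeric matrix, >= 3 subjects (rows).
#' @return A symmetric `correlation_matrix` (also a plain matrix) with unit
#'   diagonal.
#' @export
correlation_matrix <- function(factors) {
  m <- as.matrix(as.data.frame(factors))
  if (!is.numeric(m)) stop("all factors must be numeric")
  if (nrow(m) < 3L) stop("need >= 3 subjects")
  if (anyNA(m)) stop("missing values in factors")
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop(sprintf("zero-variance factor(s): %s",
                 paste(colnames(m)[sds == 0], collapse = ", ")))
  cm <- cor(m)
  diag(cm) <- 1
  class(cm) <- c("correlation_matrix", class(cm))
  cm
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("Factor correlation matrix (Pearson):\n")
  y <- unclass(x)
  print(round(y, digits))
  invisible(x)
}
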