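# Prediction metrics and residual diagnostics.

#' Root mean square error of prediction
#'
#' `sqrt(mean((ref - pred)^2))`, in umol/L.
#'
#' @param ref Reference concentrations.
#' @param pred Predicted concentrations.
#' @return RMSEP.
#' @export
rmsep <- function(ref, pred) {
  ref <- as.numeric(ref); pred <- as.numeric(pred)
  if (length(ref) == 0) stop("empty input")
  if (length(ref) != length(pred)) stop("ref and pred lengths differ")
  sqrt(mean((ref - pred)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares about the mean of the
#' reference values.
#'
#' @param ref Reference concentrations; must not be all equal.
#' @param pred Predicted concentrations.
#' @return R^2 (unitless, `<= 1`).
#' @export
r_squared <- function(ref, pred) {
  ref <- as.numeric(ref); pred <- as.numeric(pred)
  if (length(ref) != length(pred)) stop("ref and pred lengths differ")
  sst <- sum((ref - mean(ref))^2)
  if (sst == 0) stop("reference values have zero variance; R^2 undefined")
  1 - sum((ref - pred)^2) / sst
}

#' Residual report with tolerance fractions and covariate correlations
#'
#' Residuals use the convention `predicted - reference`. For each tolerance
#' tau the fraction of samples with `|residual| <= tau` is reported, along
#' with the residual range and the Pearson correlation of the residuals with
#' temperature and salinity (reported as `NA` when the covariate is constant
#' or absent).
#'
#' @param ref Reference concentrations, umol/L.
#' @param pred Predicted concentrations, umol/L.
#' @param T Optional per-sample temperatures, degC.
#' @param S Optional per-sample salinities, psu.
#' @param tolerances Tolerances in umol/L; default `2`, the headline
#'   error-band of the method.
#' @return An `eval_report` list: `rmsep`, `r2`, `residuals`, `error_range`,
#'   `frac_within` (named by tolerance), `corr_T`, `corr_S`, `n`.
#' @export
residual_report <- function(ref, pred, T = NULL, S = NULL, tolerances = 2) {
  ref <- as.numeric(ref); pred <- as.numeric(pred)
  if (length(ref) != length(pred)) stop("ref and pred lengths differ")
  if (!is.null(T) && length(T) != length(ref)) stop("T length differs from ref")
  if (!is.null(S) && length(S) != length(ref)) stop("S length differs from ref")
  res <- pred - ref
  frac <- vapply(tolerances, function(tau) mean(abs(res) <= tau), numeric(1))
  names(frac) <- as.character(tolerances)
  safe_cor <- function(v) {
    if (is.null(v) || stats::sd(v) == 0 || stats::sd(res) == 0) return(NA_real_)
    stats::cor(res, v)
  }
  structure(list(
    rmsep = rmsep(ref, pred),
    r2 = if (stats::sd(ref) > 0) r_squared(ref, pred) else NA_real_,
    residuals = res,
    error_range = c(min = min(res), max = max(res)),
    frac_within = frac,
    corr_T = safe_cor(T),
    corr_S = safe_cor(S),
    n = length(ref)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, RMSEP = %.4g umol/L, R2 = %.6f\n",
              x$n, x$rmsep, x$r2))
  cat(sprintf("  error range [%.3g, %.3g] umol/L; frac within +/-%s umol/L: %s\n",
              x$error_range[1], x$error_range[2],
              paste(names(x$frac_within), collapse = "/"),
              paste(sprintf("%.3f", x$frac_within), collapse = "/")))
  if (!is.na(x$corr_T)) cat(sprintf("  corr(residual, T) = %.4f\n", x$corr_T))
  if (!is.na(x$corr_S)) cat(sprintf("  corr(residual, S) = %.4f\n", x$corr_S))
  invisible(x)
}
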