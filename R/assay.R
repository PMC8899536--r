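# Esterification assay analytics: linear standard curves from serial
# dilutions, ester quantification by curve inversion, conversion ratios,
# optimization fold improvements, and relative/residual activity profiles.

#' Fit a linear standard curve
#'
#' Ordinary least-squares line `response = slope * conc + intercept` through
#' a serial-dilution series. Replicate responses at the same concentration
#' are averaged before fitting, mirroring triplicate detection of serially
#' diluted standards.
#'
#' @param conc_mM Standard concentrations in mM (replicates as repeated
#'   values); at least 3 distinct concentrations are required.
#' @param response Detector responses, same length as `conc_mM`.
#' @param analyte Name of the calibrated compound.
#' @return An object of class `"standard_curve"`: list with `analyte`,
#'   `slope` (response per mM), `intercept`, `r_squared`, `n_points`.
#' @examples
#' fit_standard_curve(c(1, 2, 5, 10), c(2, 4, 10, 20))
#' @export
fit_standard_curve <- function(conc_mM, response, analyte = "analyte") {
  if (length(conc_mM) != length(response))
    stop("'conc_mM' and 'response' must have the same length")
  mean_resp <- tapply(response, conc_mM, mean)
  conc <- as.numeric(names(mean_resp))
  if (length(conc) < 3)
    stop("need at least 3 distinct concentrations, got ", length(conc))
  y <- as.numeric(mean_resp)
  fit <- stats::lm(y ~ x, data = data.frame(x = conc, y = y))
  # r^2 from the residuals directly: summary.lm warns on noiseless
  # dilution series, which are a legitimate calibration input here
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(analyte = analyte,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_points = length(conc)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve for %s: response = %.6g * conc + %.6g (r^2 = %.4f, %d points)\n",
              x$analyte, x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Quantify a concentration from a detector response
#'
#' Inverts a standard curve: `conc = (response - intercept) / slope`.
#' Negative concentrations (possible from blank drift near the detection
#' limit) are clipped to 0 with a warning; the `"clipped"` attribute flags
#' which values were affected.
#'
#' @param response Detector response(s).
#' @param curve A `"standard_curve"` object.
#' @param clip_negative Clip negative estimates to 0 (default `TRUE`).
#' @return Concentration(s) in mM.
#' @export
quantify <- function(response, curve, clip_negative = TRUE) {
  if (!inherits(curve, "standard_curve")) stop("'curve' must be a standard_curve")
  if (curve$slope == 0) stop("standard curve has zero slope; not invertible")
  conc <- (response - curve$intercept) / curve$slope
  clipped <- conc < 0
  if (clip_negative && any(clipped)) {
    warning(sum(clipped), " negative concentration(s) clipped to 0")
    conc[clipped] <- 0
    attr(conc, "clipped") <- clipped
  }
  conc
}

#' Esterification conversion ratio
#'
#' Percentage of the initially supplied fatty acid converted to its ethyl
#' ester: `100 * ester_mM / initial_acid_mM` (mol ester formed per mol acid
#' supplied). Returned at full precision; round with [round_half_up()] for
#' reporting.
#'
#' @param ester_mM Ester concentration formed, mM (>= 0).
#' @param initial_acid_mM Initially supplied acid concentration, mM (> 0).
#' @return Conversion percentage(s).
#' @examples
#' conversion_ratio(8.52, 10)   # 85.2 %
#' @export
conversion_ratio <- function(ester_mM, initial_acid_mM) {
  if (any(initial_acid_mM <= 0)) stop("'initial_acid_mM' must be positive")
  if (any(ester_mM < 0)) stop("'ester_mM' must be non-negative")
  100 * ester_mM / initial_acid_mM
}

#' Fold improvement of a conversion ratio
#'
#' Ratio of a conversion percentage after an intervention (e.g. culture
#' optimization) to the value before it.
#'
#' @param after_pct,before_pct Positive conversion percentages.
#' @param digits If non-`NULL`, round half-up to this many decimals for
#'   reporting; default `NULL` returns the full-precision fold.
#' @return Fold improvement(s).
#' @examples
#' fold_improvement(7.87, 2.23, digits = 2)   # 3.53
#' @export
fold_improvement <- function(after_pct, before_pct, digits = NULL) {
  if (any(before_pct <= 0)) stop("'before_pct' must be positive")
  if (any(after_pct <= 0)) stop("'after_pct' must be positive")
  out <- after_pct / before_pct
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Relative activity profile
#'
#' Rescales an activity series measured across a condition sweep (pH,
#' temperature, ...) to percent of its maximum; uncertainties are scaled by
#' the same factor, so the optimum point reads exactly 100%.
#'
#' @param condition Condition values (pH units, degrees C, ...).
#' @param activity Non-negative activities; at least one must be positive.
#' @param uncertainty Optional non-negative uncertainties (same length).
#' @return Data frame with `condition`, `relative_activity_pct` and, when
#'   given, `uncertainty_pct`.
#' @export
relative_activity <- function(condition, activity, uncertainty = NULL) {
  if (length(condition) != length(activity))
    stop("'condition' and 'activity' must have the same length")
  if (any(activity < 0)) stop("activities must be non-negative")
  mx <- max(activity)
  if (mx <= 0) stop("all activities are zero; profile undefined")
  out <- data.frame(condition = condition,
                    relative_activity_pct = 100 * activity / mx)
  if (!is.null(uncertainty)) {
    if (any(uncertainty < 0)) stop("uncertainties must be non-negative")
    out$uncertainty_pct <- 100 * uncertainty / mx
  }
  out
}

#' Residual activity after a stability treatment
#'
#' Activity remaining after an incubation (pH, temperature, additive),
#' as percent of the untreated control.
#'
#' @param treated Activity after treatment (>= 0).
#' @param control Untreated control activity (> 0).
#' @return Percentage(s).
#' @export
residual_activity <- function(treated, control) {
  if (any(control <= 0)) stop("'control' must be positive")
  if (any(treated < 0)) stop("'treated' must be non-negative")
  100 * treated / control
}

#' Substrate-preference fold over the negative control
#'
#' Ratio of the product concentration in the enzyme reaction to the
#' enzyme-free negative control.
#'
#' @param enzyme_conc Product concentration with enzyme (>= 0).
#' @param control_conc Product concentration in the negative control (> 0).
#' @return Fold(s).
#' @export
preference_fold <- function(enzyme_conc, control_conc) {
  if (any(control_conc <= 0)) stop("'control_conc' must be positive")
  if (any(enzyme_conc < 0)) stop("'enzyme_conc' must be non-negative")
  enzyme_conc / control_conc
}

#' Quantify an assay table against its standard curves
#'
#' Fits one standard curve per analyte from a dilution table, inverts each
#' measurement's detector response to an ester concentration, and computes
#' conversion ratios. Measurements that already carry `ester_mM` instead of
#' `response` are used as-is.
#'
#' @param standards Data frame with columns `analyte`, `conc_mM`, `response`
#'   (replicates as repeated rows).
#' @param measurements Data frame with columns `sample_id`, `substrate_acid`,
#'   `ester`, `initial_acid_mM`, and `response` or `ester_mM`.
#' @return `measurements` with columns `ester_mM` and `conversion_pct`
#'   appended (full precision).
#' @export
analyze_assay <- function(standards, measurements) {
  if (!all(c("analyte", "conc_mM", "response") %in% names(standards)))
    stop("'standards' must have columns analyte, conc_mM, response")
  req <- c("sample_id", "substrate_acid", "ester", "initial_acid_mM")
  if (!all(req %in% names(measurements)))
    stop("'measurements' must have columns ", paste(req, collapse = ", "))
  has_resp <- "response" %in% names(measurements)
  has_conc <- "ester_mM" %in% names(measurements)
  if (!has_resp && !has_conc)
    stop("'measurements' needs a 'response' or 'ester_mM' column")

  curves <- lapply(split(standards, standards$analyte), function(d)
    fit_standard_curve(d$conc_mM, d$response, analyte = d$analyte[1]))

  out <- measurements
  if (!has_conc) out$ester_mM <- NA_real_
  if (has_resp) {
    need <- if (has_conc) is.na(out$ester_mM) & !is.na(out$response)
            else rep(TRUE, nrow(out))
    for (i in which(need)) {
      cv <- curves[[as.character(out$ester[i])]]
      if (is.null(cv))
        stop("no standard curve for analyte '", out$ester[i], "'")
      out$ester_mM[i] <- suppressWarnings(quantify(out$response[i], cv))
    }
  }
  out$conversion_pct <- conversion_ratio(out$ester_mM, out$initial_acid_mM)
  attr(out, "curves") <- curves
  out
}
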