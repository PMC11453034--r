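# Accuracy metrics: CD spectrum RMSD with optimal scaling, SS-fraction RMSD
# and chi-square, SAXS chi, chemical-shift RMSD, group summaries.

#' Construct a CD spectrum
#'
#' @param wavelengths Strictly increasing wavelength grid in nm.
#' @param I Intensities in kMRE, finite.
#' @param role `"exp"` (measured) or `"calc"` (predicted).
#' @return Object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, I, role = c("calc", "exp")) {
  role <- match.arg(role)
  if (length(wavelengths) != length(I))
    stop("wavelengths and intensities must align", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (any(!is.finite(I))) stop("intensities must be finite", call. = FALSE)
  structure(list(wavelengths = as.numeric(wavelengths), I = as.numeric(I),
                 role = role),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum[%s]: %d points, %.0f-%.0f nm\n", x$role,
              length(x$I), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Interpolate a spectrum onto a new wavelength grid
#'
#' Linear interpolation; grid points outside the spectrum's span are
#' dropped (no extrapolation).
#'
#' @param s A [spectrum].
#' @param grid Target wavelengths in nm.
#' @return A [spectrum] on the overlapping part of `grid`.
#' @export
regrid_spectrum <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"))
  grid <- sort(grid)
  keep <- grid >= min(s$wavelengths) & grid <= max(s$wavelengths)
  if (!any(keep)) stop("empty overlap between spectrum and grid", call. = FALSE)
  g <- grid[keep]
  spectrum(g, stats::approx(s$wavelengths, s$I, xout = g)$y, role = s$role)
}

#' RMSD between measured and predicted CD spectra
#'
#' Compares the two spectra on the wavelengths of the experimental spectrum
#' that fall inside the predicted spectrum's span, as
#' `RMSD = sqrt(mean((alpha * I_exp - I_calc)^2))` in kMRE.  With
#' `scale = TRUE` (default) the scaling factor
#' `alpha = sum(I_exp * I_calc) / sum(I_exp^2)` minimises the RMSD and is
#' applied to the *experimental* intensities, absorbing normalization
#' errors of the measurement (concentration, path length); note the
#' deliberate asymmetry with the refinement chi-square, where the scaling
#' multiplies the calculated observables instead.
#'
#' @param I_exp Measured [spectrum].
#' @param I_calc Predicted [spectrum].
#' @param scale Optimise the scaling factor (default) or fix `alpha = 1`.
#' @return List with `rmsd` (kMRE), `alpha`, and `n` (overlap points).
#' @export
rmsd_cd <- function(I_exp, I_calc, scale = TRUE) {
  stopifnot(inherits(I_exp, "spectrum"), inherits(I_calc, "spectrum"))
  keep <- I_exp$wavelengths >= min(I_calc$wavelengths) &
    I_exp$wavelengths <= max(I_calc$wavelengths)
  if (sum(keep) < 2)
    stop("need at least two overlapping wavelengths", call. = FALSE)
  ie <- I_exp$I[keep]
  ic <- regrid_spectrum(I_calc, I_exp$wavelengths[keep])$I
  if (scale) {
    if (all(ie == 0))
      stop("cannot scale an all-zero experimental spectrum", call. = FALSE)
    alpha <- sum(ie * ic) / sum(ie^2)
  } else alpha <- 1
  list(rmsd = sqrt(mean((alpha * ie - ic)^2)), alpha = alpha, n = sum(keep))
}

#' RMSD between estimated and reference SS compositions
#'
#' Root-mean-square deviation over the class fractions of a common scheme.
#'
#' @param F_est,F_ref [ss_composition]s with the same scheme and classes.
#' @return Scalar RMSD in fraction units, in `[0, 1]`.
#' @export
rmsd_ss <- function(F_est, F_ref) {
  stopifnot(inherits(F_est, "ss_composition"), inherits(F_ref, "ss_composition"))
  if (!identical(F_est$scheme, F_ref$scheme) ||
      !identical(sort(names(F_est$fractions)), sort(names(F_ref$fractions))))
    stop("scheme mismatch between compositions", call. = FALSE)
  k <- names(F_ref$fractions)
  sqrt(mean((F_est$fractions[k] - F_ref$fractions[k])^2))
}

#' Chi-square deviation between SS compositions with per-class uncertainty
#'
#' `(1/M) * sum_k ((F_ref_k - F_est_k) / sigma_k)^2`, without any scaling
#' factor: used to judge whether estimator uncertainties are realistic.
#'
#' @param F_est,F_ref [ss_composition]s with the same scheme.
#' @param sigma_est Per-class uncertainties of the estimate, > 0, named or
#'   in the order of `F_est`.
#' @return Scalar chi-square.
#' @export
chi2_ss <- function(F_est, F_ref, sigma_est) {
  stopifnot(inherits(F_est, "ss_composition"), inherits(F_ref, "ss_composition"))
  if (!identical(F_est$scheme, F_ref$scheme))
    stop("scheme mismatch between compositions", call. = FALSE)
  k <- names(F_est$fractions)
  if (!is.null(names(sigma_est))) sigma_est <- sigma_est[k]
  if (any(sigma_est <= 0)) stop("uncertainties must be positive", call. = FALSE)
  mean(((F_ref$fractions[k] - F_est$fractions[k]) / sigma_est)^2)
}

#' SAXS chi (square root of the scaled chi-square)
#'
#' Reports the deviation from a measured SAXS curve in units of the
#' experimental uncertainty, with the beam-intensity scaling factor at its
#' optimum, so the value is insensitive to any multiplicative rescaling of
#' the predicted intensities.
#'
#' @param block A SAXS [observable_block] with free scaling.
#' @param w Weight vector on the simplex.
#' @return Scalar chi, >= 0.
#' @export
saxs_chi <- function(block, w) {
  stopifnot(inherits(block, "observable_block"))
  if (block$scale_mode != "free_positive")
    stop("SAXS chi requires a free-scaling block", call. = FALSE)
  sqrt(chi2_block(block, w))
}

#' Chemical-shift RMSD per atom type
#'
#' Root-mean-square over residues of (measured - ensemble-average
#' predicted), split by atom type; residues with a missing measurement are
#' skipped.
#'
#' @param block A CS [observable_block] whose `meta$atom_type` labels each
#'   observable.
#' @param w Weight vector on the simplex.
#' @return Named vector of RMSDs in ppm, one per atom type present.
#' @export
rmsd_cs <- function(block, w) {
  stopifnot(inherits(block, "observable_block"))
  at <- block$meta$atom_type
  if (is.null(at)) stop("block carries no atom_type metadata", call. = FALSE)
  d <- block$O - ensemble_average(w, block$P)
  vapply(split(d, at), function(x) sqrt(mean(x^2)), numeric(1))
}

#' Group metric values into mean and standard error
#'
#' `sem` is the sample standard deviation (n-1 denominator) divided by
#' `sqrt(n)`; `NA` values are excluded and `n` reduced accordingly.  With
#' fewer than two non-missing values the mean is returned with `sem = NA`.
#'
#' @param values Numeric metric values (may contain `NA`).
#' @param round_to Optional number of decimals for half-up rounding of the
#'   reported `mean` and `sem` (raw values are kept alongside).
#' @return Object of class `group_summary`: list with `values`, `mean`,
#'   `sem`, `n`, and (if rounded) `mean_rounded`, `sem_rounded`.
#' @export
summarize_metrics <- function(values, round_to = NULL) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n == 0) stop("no non-missing values", call. = FALSE)
  out <- list(values = values, mean = mean(v),
              sem = if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_,
              n = n)
  if (!is.null(round_to)) {
    out$mean_rounded <- round_half_up(out$mean, round_to)
    out$sem_rounded <- round_half_up(out$sem, round_to)
  }
  structure(out, class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("group_summary: %.4g +/- %.4g (n = %d)\n", x$mean, x$sem, x$n))
  invisible(x)
}

#' Half-up decimal rounding
#'
#' Rounds halves away from zero (0.275 -> 0.28 at 2 decimals), the
#' convention of printed report tables, unlike the banker's rounding of
#' [round()].
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
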