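# Linear forward models: basis-set CD prediction and ensemble averaging.

#' Construct a CD basis set
#'
#' A basis set holds one "pure" CD spectrum per secondary-structure (or
#' side-chain correction) class; a predicted spectrum is the linear
#' combination of basis spectra weighted by class fractions.
#'
#' @param class_names Character labels of the classes (rows of `B`).
#' @param wavelengths Strictly increasing wavelength grid in nm.
#' @param B Matrix of basis intensities, classes x wavelengths, in kMRE per
#'   unit fraction.
#' @return Object of class `basis_set`.
#' @export
basis_set <- function(class_names, wavelengths, B) {
  B <- as.matrix(B)
  if (nrow(B) != length(class_names))
    stop("B must have one row per class", call. = FALSE)
  if (ncol(B) != length(wavelengths))
    stop("B must have one column per wavelength", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  structure(list(class_names = as.character(class_names),
                 wavelengths = as.numeric(wavelengths), B = B),
            class = "basis_set")
}

#' Construct a secondary-structure composition
#'
#' Fractions of residues per class under a named classification scheme.
#' For pure-SS schemes the fractions must sum to 1 (tolerance 1e-6);
#' schemes that carry side-chain correction channels are exempt from the
#' sum constraint and flagged with `pure = FALSE`.
#'
#' @param fractions Named numeric vector of class fractions, all >= 0.
#' @param scheme Scheme name (e.g. `"DISICL3"`, `"BESTSEL8"`).
#' @param pure If `TRUE` (default) enforce the unit-sum constraint.
#' @return Object of class `ss_composition`.
#' @export
ss_composition <- function(fractions, scheme, pure = TRUE) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("fractions must be a named vector", call. = FALSE)
  if (any(fractions < 0)) stop("fractions must be non-negative", call. = FALSE)
  if (pure && abs(sum(fractions) - 1) > 1e-6)
    stop("pure-scheme fractions must sum to 1", call. = FALSE)
  structure(list(scheme = scheme, fractions = fractions, pure = pure),
            class = "ss_composition")
}

#' @export
print.ss_composition <- function(x, ...) {
  cat(sprintf("ss_composition [%s]%s\n", x$scheme,
              if (x$pure) "" else " (with correction channels)"))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Predict a CD spectrum from a composition and a basis set
#'
#' `I_calc(lambda) = sum_k F_k * B_k(lambda)` on the basis wavelength grid.
#'
#' @param comp An [ss_composition] whose class names match the basis.
#' @param basis A [basis_set].
#' @return A [spectrum] with role `"calc"`.
#' @export
predict_spectrum <- function(comp, basis) {
  stopifnot(inherits(comp, "ss_composition"), inherits(basis, "basis_set"))
  if (!identical(sort(names(comp$fractions)), sort(basis$class_names)))
    stop("class-mapping error: composition classes do not match basis classes",
         call. = FALSE)
  f <- comp$fractions[basis$class_names]
  spectrum(basis$wavelengths, as.numeric(f %*% basis$B), role = "calc")
}

#' Ensemble-average an observable matrix
#'
#' Column-wise weighted mean `sum_j w_j * P[j, ]` over conformers.
#'
#' @param w Weight vector on the simplex (or a [weighted_ensemble]).
#' @param P Per-conformer matrix, conformers x observables.
#' @return Numeric vector of ensemble-averaged observables.
#' @export
ensemble_average <- function(w, P) {
  if (inherits(w, "weighted_ensemble")) w <- w$w
  P <- as.matrix(P)
  if (nrow(P) != length(w))
    stop("rows of P must match length of w", call. = FALSE)
  as.numeric(crossprod(P, w))
}

#' Ensemble-average secondary-structure compositions
#'
#' @param w Weight vector on the simplex.
#' @param comps List of [ss_composition] objects sharing one scheme.
#' @return The weighted-mean [ss_composition].
#' @export
ensemble_ss <- function(w, comps) {
  if (inherits(w, "weighted_ensemble")) w <- w$w
  if (length(comps) != length(w))
    stop("one composition per conformer required", call. = FALSE)
  schemes <- vapply(comps, function(x) x$scheme, character(1))
  if (length(unique(schemes)) != 1)
    stop("scheme mismatch across conformers", call. = FALSE)
  Fm <- do.call(rbind, lapply(comps, function(x) x$fractions))
  ss_composition(colSums(Fm * w), scheme = schemes[[1]],
                 pure = all(vapply(comps, function(x) x$pure, logical(1))))
}

#' CD intensity uncertainty model
#'
#' `sigma = delta * |O| + sigma0`: a relative term for intensity
#' normalization uncertainty (concentration, path length) plus an absolute
#' machine-error floor.
#'
#' @param O Measured CD intensities in kMRE (signed).
#' @param delta Relative normalization uncertainty; default 0.2.
#' @param sigma0 Machine error floor in kMRE; default 0.75.
#' @return Uncertainty vector in kMRE.
#' @export
cd_sigma <- function(O, delta = 0.2, sigma0 = 0.75) {
  stopifnot(delta >= 0, sigma0 > 0)
  delta * abs(O) + sigma0
}

#' Chemical-shift uncertainty by atom type
#'
#' Conservative per-atom-type uncertainties of predicted backbone carbon
#' shifts: 0.95 (Calpha), 1.03 (Cbeta), 1.13 (carbonyl C) ppm.
#'
#' @param atom_type Character vector with entries in `c("CA","CB","CO")`.
#' @return Uncertainty in ppm, one per entry.
#' @export
cs_sigma <- function(atom_type) {
  tab <- c(CA = 0.95, CB = 1.03, CO = 1.13)
  bad <- setdiff(unique(atom_type), names(tab))
  if (length(bad))
    stop("unknown atom type: ", paste(bad, collapse = ", "), call. = FALSE)
  unname(tab[atom_type])
}
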