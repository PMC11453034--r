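# Core domain types: weighted ensembles, observable blocks, refinement results.

#' Normalize a non-negative vector to the probability simplex
#'
#' @param raw Numeric vector with non-negative entries, at least one positive.
#' @return Numeric vector proportional to `raw` summing to exactly 1.
#' @examples
#' normalize_weights(c(2, 2))   # 0.5 0.5
#' normalize_weights(c(1, 3))   # 0.25 0.75
#' @export
normalize_weights <- function(raw) {
  if (!is.numeric(raw) || length(raw) == 0)
    stop("invalid weights: need a non-empty numeric vector", call. = FALSE)
  if (anyNA(raw) || any(raw < 0))
    stop("invalid weights: entries must be non-negative and non-missing",
         call. = FALSE)
  s <- sum(raw)
  if (s <= 0)
    stop("invalid weights: at least one entry must be positive", call. = FALSE)
  raw / s
}

#' Construct a weighted conformational ensemble
#'
#' An ensemble is a set of conformer labels with current weights `w` and
#' prior weights `w0`, both on the probability simplex.  Conformer
#' coordinates are never stored; only labels and (elsewhere) per-conformer
#' observables.
#'
#' @param w Weights, one per conformer; non-negative, summing to 1
#'   (tolerance 1e-9).
#' @param w0 Prior weights; strictly positive, summing to 1.  Default:
#'   uniform.
#' @param conformer_ids Optional labels; default `"c1"..."cn"`.
#' @return Object of class `weighted_ensemble` with fields `conformer_ids`,
#'   `w`, `w0`.
#' @export
weighted_ensemble <- function(w, w0 = NULL, conformer_ids = NULL) {
  n <- length(w)
  if (n == 0) stop("empty ensemble", call. = FALSE)
  if (is.null(w0)) w0 <- rep(1 / n, n)
  if (is.null(conformer_ids)) conformer_ids <- paste0("c", seq_len(n))
  if (length(w0) != n || length(conformer_ids) != n)
    stop("w, w0 and conformer_ids must have equal length", call. = FALSE)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1", call. = FALSE)
  if (any(w0 <= 0)) stop("prior weights must be strictly positive", call. = FALSE)
  if (abs(sum(w0) - 1) > 1e-9) stop("prior weights must sum to 1", call. = FALSE)
  structure(list(conformer_ids = as.character(conformer_ids),
                 w = as.numeric(w), w0 = as.numeric(w0)),
            class = "weighted_ensemble")
}

#' @export
print.weighted_ensemble <- function(x, ...) {
  cat(sprintf("weighted_ensemble: %d conformers\n", length(x$w)))
  cat(sprintf("  S_rel = %.4g nats, effective size ratio exp(S_rel) = %.3f\n",
              relative_entropy(x$w, x$w0), exp(relative_entropy(x$w, x$w0))))
  invisible(x)
}

#' Relative entropy of weights against a prior
#'
#' Computes `S_rel = -sum_j w_j * ln(w_j / w0_j)` in nats, the (negated)
#' Kullback-Leibler divergence of the reweighted ensemble from the prior.
#' It is non-positive and equals 0 exactly when `w == w0`; `0 * ln 0` is
#' taken as 0 so weights may sit on the simplex boundary.
#'
#' @param w Weight vector on the simplex.
#' @param w0 Prior weight vector on the simplex, strictly positive.
#' @return `S_rel` in nats (<= 0).
#' @examples
#' relative_entropy(c(1, 0), c(0.5, 0.5))  # -log(2)
#' @export
relative_entropy <- function(w, w0) {
  if (length(w) != length(w0))
    stop("w and w0 must have equal length", call. = FALSE)
  if (any(w0 <= 0)) stop("prior weights must be strictly positive", call. = FALSE)
  nz <- w > 0
  -sum(w[nz] * log(w[nz] / w0[nz]))
}

#' Construct an observable block
#'
#' One block holds all measured observables of a single type (CD intensity,
#' SAXS intensity or chemical shift) together with their uncertainties and
#' the per-conformer prediction matrix.  Measured values that are `NA`
#' (unresolved residues, truncated wavelengths) are dropped together with
#' their sigma and prediction columns and do not count towards `M`.
#'
#' The scaling mode follows the physics of each observable: SAXS intensities
#' carry a free positive scaling factor alpha compensating machine-dependent
#' beam intensity; CD intensities and chemical shifts are absolute, so alpha
#' is fixed to 1.
#'
#' @param kind One of `"CD"`, `"SAXS"`, `"CS"`.
#' @param O Measured values (kMRE, intensity a.u., or ppm); `NA` allowed.
#' @param sigma Uncertainties, same length and units as `O`; strictly
#'   positive.
#' @param P Per-conformer prediction matrix, conformers x observables.
#' @param scale_mode `"fixed_one"` or `"free_positive"`; default chosen by
#'   `kind`.
#' @param meta Optional list of axis metadata (wavelengths, q values,
#'   residue/atom labels).
#' @return Object of class `observable_block` with fields `kind`, `O`,
#'   `sigma`, `P`, `M`, `scale_mode`, `alpha`, `meta`.
#' @export
observable_block <- function(kind, O, sigma, P,
                             scale_mode = NULL, meta = list()) {
  kind <- match.arg(kind, c("CD", "SAXS", "CS"))
  if (is.null(scale_mode))
    scale_mode <- if (kind == "SAXS") "free_positive" else "fixed_one"
  scale_mode <- match.arg(scale_mode, c("fixed_one", "free_positive"))
  P <- as.matrix(P)
  if (length(O) != length(sigma) || length(O) != ncol(P))
    stop("O, sigma and columns of P must align", call. = FALSE)
  keep <- !is.na(O)
  if (!any(keep)) stop("block has no non-missing observables", call. = FALSE)
  O <- as.numeric(O[keep]); sigma <- as.numeric(sigma[keep])
  P <- P[, keep, drop = FALSE]
  meta <- lapply(meta, function(v) if (length(v) == length(keep)) v[keep] else v)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be strictly positive", call. = FALSE)
  structure(list(kind = kind, O = O, sigma = sigma, P = P,
                 M = length(O), scale_mode = scale_mode, alpha = 1,
                 meta = meta),
            class = "observable_block")
}

#' @export
print.observable_block <- function(x, ...) {
  cat(sprintf("observable_block[%s]: M = %d, %d conformers, alpha %s\n",
              x$kind, x$M, nrow(x$P),
              if (x$scale_mode == "fixed_one") "fixed at 1" else "free > 0"))
  invisible(x)
}

# internal: refinement result container with consistency checks
new_refinement_result <- function(weights, theta, chi2_per_block,
                                  alpha_per_block, s_rel, loss) {
  stopifnot(inherits(weights, "weighted_ensemble"))
  if (s_rel > 1e-12)
    stop("relative entropy must be non-positive", call. = FALSE)
  structure(list(weights = weights, theta = theta,
                 chi2_per_block = chi2_per_block,
                 alpha_per_block = alpha_per_block,
                 s_rel = s_rel, loss = loss),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement_result: theta = %g, L = %.6g, S_rel = %.4g\n",
              x$theta, x$loss, x$s_rel))
  for (nm in names(x$chi2_per_block))
    cat(sprintf("  %-6s chi2 = %.4g  alpha = %.4g\n",
                nm, x$chi2_per_block[[nm]], x$alpha_per_block[[nm]]))
  invisible(x)
}

# internal: run a block with a locally-seeded RNG, restoring global state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
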