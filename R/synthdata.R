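# Synthetic refinement problems with known ground-truth weights.

# internal: Dirichlet draw via normalized gammas
rdirichlet1 <- function(n, concentration) {
  g <- stats::rgamma(n, shape = concentration, rate = 1)
  if (sum(g) <= 0) g <- rep(1, n)
  g / sum(g)
}

# internal: smooth synthetic CD basis spectra (kMRE-scale sums of Gaussian
# bands, loosely shaped like helix/sheet/coil signatures plus jitter)
gen_basis <- function(wavelengths, n_classes = 3) {
  centers <- list(c(192, 208, 222), c(196, 216), c(198, 220))
  amps <- list(c(60, -20, -20), c(35, -12), c(-40, 6))
  B <- matrix(0, n_classes, length(wavelengths))
  for (k in seq_len(n_classes)) {
    ki <- ((k - 1) %% 3) + 1
    mu <- centers[[ki]] + stats::rnorm(length(centers[[ki]]), 0, 1.5)
    a <- amps[[ki]] * stats::runif(length(mu), 0.8, 1.2)
    width <- stats::runif(length(mu), 6, 10)
    for (p in seq_along(mu))
      B[k, ] <- B[k, ] + a[p] * exp(-((wavelengths - mu[p]) / width[p])^2)
  }
  basis_set(paste0("class", seq_len(n_classes)), wavelengths, B)
}

#' Generate a synthetic refinement problem
#'
#' Builds a complete BME refinement problem with known ground truth:
#' Dirichlet ground-truth weights; per-conformer CD spectra as linear
#' combinations of a smooth synthetic basis with random per-conformer SS
#' compositions; per-conformer SAXS curves as smooth positive Guinier-like
#' decays with conformer-specific radii of gyration; per-conformer
#' chemical shifts as residue base values plus conformer offsets.  The
#' "measured" data are the truth-weighted averages plus Gaussian noise
#' whose standard deviation is the block's uncertainty model
#' (CD: `delta * |O| + sigma0`; CS: per-atom-type constants; SAXS:
#' per-point relative errors in the 2-20 % range) multiplied by
#' `noise_scale`.  The stored block uncertainties are the *unscaled* model
#' values, so at `noise_scale = 1` the truth weights give chi-square
#' deviations near 1, and at `noise_scale = 0` the measured data equal the
#' truth averages exactly.
#'
#' @param n_conformers Number of conformers, >= 1.
#' @param n_cd,n_saxs,n_cs Number of observables per type (0 disables a
#'   block; at least one must be positive).
#' @param concentration Dirichlet concentration of the truth weights;
#'   1 = uniform over the simplex, 0.1 = heavy-tailed (dominant
#'   conformers).
#' @param noise_scale Multiplier on the noise standard deviation;
#'   default 1.
#' @param seed Integer seed; the problem is fully reproducible from it.
#' @return Object of class `synthetic_truth`: list with `w_true`, `blocks`
#'   (named list of [observable_block]s), `truth_avg` (noiseless truth
#'   averages per block), `noise` (recorded draws per block), `basis`,
#'   `ss_comps`, `noise_params`, `seed`.
#' @export
gen_problem <- function(n_conformers, n_cd = 30, n_saxs = 25, n_cs = 20,
                        concentration = 1, noise_scale = 1, seed = 1) {
  stopifnot(n_conformers >= 1, n_cd >= 0, n_saxs >= 0, n_cs >= 0,
            noise_scale >= 0)
  if (n_cd + n_saxs + n_cs == 0)
    stop("at least one observable block must be non-empty", call. = FALSE)
  with_seed(seed, {
    w_true <- rdirichlet1(n_conformers, concentration)
    blocks <- list(); truth_avg <- list(); noise <- list()
    basis <- NULL; ss_comps <- NULL

    if (n_cd > 0) {
      wl <- seq(185, 260, length.out = n_cd)
      basis <- gen_basis(wl)
      Fm <- t(replicate(n_conformers,
                        rdirichlet1(length(basis$class_names), 1)))
      ss_comps <- lapply(seq_len(n_conformers), function(j)
        ss_composition(stats::setNames(Fm[j, ], basis$class_names),
                       scheme = "SYN3"))
      P <- Fm %*% basis$B
      avg <- as.numeric(crossprod(P, w_true))
      sig <- cd_sigma(avg)
      eps <- stats::rnorm(n_cd, 0, sig * noise_scale)
      blocks$CD <- observable_block("CD", avg + eps, sig, P,
                                    meta = list(wavelengths = wl))
      truth_avg$CD <- avg; noise$CD <- eps
    }
    if (n_saxs > 0) {
      q <- seq(0.01, 0.25, length.out = n_saxs)
      rg <- stats::runif(n_conformers, 15, 35)          # Angstrom
      i0 <- exp(stats::rnorm(n_conformers, 0, 0.1))
      P <- t(vapply(seq_len(n_conformers),
                    function(j) i0[j] * exp(-(q * rg[j])^2 / 3),
                    numeric(n_saxs)))
      avg <- as.numeric(crossprod(P, w_true))
      rel <- seq(0.02, 0.20, length.out = n_saxs)       # 2-20 %, mean ~12 %
      sig <- rel * pmax(abs(avg), 1e-8)
      eps <- stats::rnorm(n_saxs, 0, sig * noise_scale)
      blocks$SAXS <- observable_block("SAXS", avg + eps, sig, P,
                                      meta = list(q = q))
      truth_avg$SAXS <- avg; noise$SAXS <- eps
    }
    if (n_cs > 0) {
      atoms <- rep(c("CA", "CB", "CO"), length.out = n_cs)
      base <- c(CA = 58, CB = 35, CO = 176)[atoms] + stats::rnorm(n_cs, 0, 2)
      P <- t(vapply(seq_len(n_conformers),
                    function(j) base + stats::rnorm(n_cs, 0, 1.2),
                    numeric(n_cs)))
      avg <- as.numeric(crossprod(P, w_true))
      sig <- cs_sigma(atoms)
      eps <- stats::rnorm(n_cs, 0, sig * noise_scale)
      blocks$CS <- observable_block("CS", avg + eps, sig, P,
                                    meta = list(atom_type = atoms,
                                                residue = seq_len(n_cs)))
      truth_avg$CS <- avg; noise$CS <- eps
    }
    structure(list(w_true = w_true, blocks = blocks, truth_avg = truth_avg,
                   noise = noise, basis = basis, ss_comps = ss_comps,
                   noise_params = list(delta = 0.2, sigma0 = 0.75,
                                       noise_scale = noise_scale),
                   seed = as.integer(seed)),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d conformers, blocks: %s (seed %d)\n",
              length(x$w_true), paste(names(x$blocks), collapse = ", "),
              x$seed))
  invisible(x)
}

#' Compare a refinement result against the synthetic ground truth
#'
#' Reports, per observable block, the mean and maximum relative error of
#' the refined ensemble averages against the noiseless truth averages, and
#' the chi-square of the refined ensemble against the noiseless truth
#' signal (measured values replaced by the truth averages).
#'
#' @param truth A `synthetic_truth`.
#' @param result A `refinement_result` on the same conformer set.
#' @return Data frame with one row per block: `block`, `mean_rel_err`,
#'   `max_rel_err`, `chi2_vs_truth`.
#' @export
recovery_check <- function(truth, result) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(result, "refinement_result"))
  w <- result$weights$w
  rows <- lapply(names(truth$blocks), function(nm) {
    b <- truth$blocks[[nm]]
    if (nrow(b$P) != length(w))
      stop("conformer count mismatch between truth and result", call. = FALSE)
    avg <- ensemble_average(w, b$P)
    ta <- truth$truth_avg[[nm]]
    rel <- abs(avg - ta) / pmax(abs(ta), 1e-8)
    bt <- b; bt$O <- ta
    data.frame(block = nm, mean_rel_err = mean(rel), max_rel_err = max(rel),
               chi2_vs_truth = chi2_block(bt, w))
  })
  do.call(rbind, rows)
}
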