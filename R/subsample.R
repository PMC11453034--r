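# Integer-weight sub-ensembles: drawing, size evaluation, final selection.

#' Draw one integer-weight sub-ensemble
#'
#' Draws `size` conformers with replacement with probability proportional
#' to the refined weights (a categorical sampler, equivalent in law to
#' rejection sampling against `w / max(w)`).  Conformers with large weights
#' may therefore enter multiple times; multiplicities sum to `size`.
#' Reproducible: identical seeds give identical member lists.
#'
#' @param w Refined weight vector on the simplex (or [weighted_ensemble]).
#' @param size Number of conformers to draw, >= 1.
#' @param seed Integer RNG seed for this draw.
#' @param replica_id Index of the draw within a replica set; default 1.
#' @return Object of class `subensemble` with fields `size`, `members`
#'   (data frame `conformer`, `multiplicity`), `n_conformers`,
#'   `replica_id`, `seed`.
#' @export
draw_subensemble <- function(w, size, seed, replica_id = 1L) {
  if (inherits(w, "weighted_ensemble")) w <- w$w
  if (size < 1) stop("size must be >= 1", call. = FALSE)
  counts <- with_seed(seed, {
    idx <- sample.int(length(w), size, replace = TRUE, prob = w)
    tabulate(idx, nbins = length(w))
  })
  sel <- which(counts > 0)
  structure(list(size = as.integer(size),
                 members = data.frame(conformer = sel,
                                      multiplicity = counts[sel]),
                 n_conformers = length(w),
                 replica_id = as.integer(replica_id),
                 seed = as.integer(seed)),
            class = "subensemble")
}

#' Uniform weights of a sub-ensemble over the full conformer set
#'
#' Each drawn copy carries weight `1/size`, so a conformer with
#' multiplicity m gets weight `m/size`; conformers not drawn get 0.
#'
#' @param se A `subensemble`.
#' @return Weight vector of length `se$n_conformers` on the simplex.
#' @export
subensemble_weights <- function(se) {
  stopifnot(inherits(se, "subensemble"))
  w <- numeric(se$n_conformers)
  w[se$members$conformer] <- se$members$multiplicity / se$size
  w
}

#' Evaluate sub-ensemble sizes by replicate draws
#'
#' For each candidate size, draws `replicas` independent sub-ensembles,
#' evaluates the per-block chi-square of each (uniform weights within the
#' draw, free scaling factors re-optimised), and reports mean and standard
#' error over replicas, together with the chi-square of the concatenated
#' ensemble (the multiset union of all replicas of that size).
#'
#' @param blocks List of [observable_block]s.
#' @param w Refined weight vector to draw from.
#' @param sizes Candidate sizes; default `c(5, 10, 20, 50, 100, 200)`.
#' @param replicas Draws per size, >= 2; default 5.
#' @param seed Master seed; per-draw seeds are derived deterministically.
#' @return Object of class `size_table`: a data frame with one row per
#'   size x block (`size`, `block`, `mean_chi2`, `se_chi2`,
#'   `concat_chi2`), with the drawn sub-ensembles in attribute `"draws"`.
#' @export
evaluate_sizes <- function(blocks, w, sizes = c(5, 10, 20, 50, 100, 200),
                           replicas = 5, seed = 1) {
  if (inherits(blocks, "observable_block")) blocks <- list(blocks)
  if (inherits(w, "weighted_ensemble")) w <- w$w
  if (!length(sizes)) stop("sizes must be non-empty", call. = FALSE)
  if (replicas < 2) stop("need at least 2 replicas", call. = FALSE)
  if (is.null(names(blocks)))
    names(blocks) <- make.unique(vapply(blocks, `[[`, "", "kind"))
  sizes <- sort(unique(sizes))
  draw_seeds <- with_seed(seed,
    matrix(sample.int(.Machine$integer.max, length(sizes) * replicas),
           nrow = length(sizes)))
  rows <- list(); draws <- list()
  for (si in seq_along(sizes)) {
    size <- sizes[[si]]
    reps <- lapply(seq_len(replicas), function(r)
      draw_subensemble(w, size, seed = draw_seeds[si, r], replica_id = r))
    draws[[as.character(size)]] <- reps
    chi2 <- vapply(reps, function(se) {
      ws <- subensemble_weights(se)
      vapply(blocks, chi2_block, numeric(1), w = ws)
    }, numeric(length(blocks)))
    chi2 <- matrix(chi2, nrow = length(blocks))  # blocks x replicas
    # concatenation: multiset union of replicas = mean of replica weights
    wcat <- rowMeans(vapply(reps, subensemble_weights, numeric(length(w))))
    concat <- vapply(blocks, chi2_block, numeric(1), w = wcat)
    rows[[si]] <- data.frame(
      size = size, block = names(blocks),
      mean_chi2 = rowMeans(chi2),
      se_chi2 = apply(chi2, 1, stats::sd) / sqrt(replicas),
      concat_chi2 = concat, row.names = NULL)
  }
  structure(do.call(rbind, rows), draws = draws, replicas = replicas,
            class = c("size_table", "data.frame"))
}

#' Select the final sub-ensemble size
#'
#' Chooses the smallest size for which (i) going to the next larger size
#' improves the mean chi-square of every block by less than `improve_tol`
#' (relative), and (ii) the replica-mean chi-square of every block agrees
#' with the concatenated-ensemble chi-square within `agree_tol` standard
#' errors.  If no size qualifies, the largest size is returned with a
#' warning.
#'
#' @param table A `size_table` from [evaluate_sizes()] covering >= 2 sizes.
#' @param improve_tol Relative improvement threshold; default 0.05.
#' @param agree_tol Agreement tolerance in units of the standard error;
#'   default 1.0.
#' @return List with `size` (chosen), `draws` (the sub-ensembles of that
#'   size, all replicas; the first is marked `selected`), and `qualified`
#'   (logical: criterion met or fallback).
#' @export
select_final <- function(table, improve_tol = 0.05, agree_tol = 1.0) {
  stopifnot(inherits(table, "size_table"))
  sizes <- sort(unique(table$size))
  if (length(sizes) < 2) stop("table must cover at least two sizes", call. = FALSE)
  ok <- function(size, nxt) {
    cur <- table[table$size == size, ]
    nx <- table[table$size == nxt, ]
    impr <- (cur$mean_chi2 - nx$mean_chi2[match(cur$block, nx$block)]) /
      pmax(cur$mean_chi2, .Machine$double.eps)
    agree <- abs(cur$mean_chi2 - cur$concat_chi2) <=
      agree_tol * pmax(cur$se_chi2, .Machine$double.eps)
    all(impr < improve_tol) && all(agree)
  }
  chosen <- NA_integer_; qualified <- FALSE
  for (i in seq_len(length(sizes) - 1)) {
    if (ok(sizes[[i]], sizes[[i + 1]])) {
      chosen <- sizes[[i]]; qualified <- TRUE; break
    }
  }
  if (!qualified) {
    chosen <- sizes[[length(sizes)]]
    warning("no size met the plateau and agreement criteria; ",
            "returning the largest size")
  }
  draws <- attr(table, "draws")[[as.character(chosen)]]
  if (!is.null(draws)) attr(draws[[1]], "selected") <- TRUE
  list(size = chosen, draws = draws, qualified = qualified)
}
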