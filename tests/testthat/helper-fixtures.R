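# Shared fixture builders: tiny deterministic refinement problems.

# one-observable block with per-conformer predictions (0, 1)
two_conformer_block <- function(O = 1, sigma = 1, kind = "CD") {
  observable_block(kind, O = O, sigma = sigma, P = matrix(c(0, 1), 2, 1))
}

# small seeded problem with all three block kinds
small_problem <- function(n = 10, seed = 42, noise_scale = 1) {
  gen_problem(n, n_cd = 15, n_saxs = 12, n_cs = 9,
              noise_scale = noise_scale, seed = seed)
}

# random point on the simplex
rsimplex <- function(n) {
  g <- stats::rexp(n)
  g / sum(g)
}

# hand-written BME loss (independent of the package computation path):
# blocks as list(list(O=, sigma=, P=, free=)), alpha re-optimised for free
# blocks by direct formula
loss_by_hand <- function(blocks, w, w0, theta) {
  total <- 0
  for (b in blocks) {
    obar <- as.numeric(t(b$P) %*% w)
    a <- if (isTRUE(b$free))
      sum(b$O * obar / b$sigma^2) / sum(obar^2 / b$sigma^2) else 1
    total <- total + 0.5 * sum(((b$O - a * obar) / b$sigma)^2)
  }
  nz <- w > 0
  total + theta * sum(w[nz] * log(w[nz] / w0[nz]))
}
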