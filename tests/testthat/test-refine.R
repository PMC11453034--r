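test_that("optimal_scale matches the weighted least-squares closed form", {
  b <- observable_block("SAXS", O = c(1, 2), sigma = c(1, 1),
                        P = rbind(c(2, 4), c(2, 4)))
  expect_equal(optimal_scale(b, c(0.5, 0.5)), 0.5)
  b2 <- observable_block("SAXS", O = c(1, 1), sigma = c(1, 1),
                         P = rbind(c(1, 1), c(1, 1)))
  expect_equal(optimal_scale(b2, c(0.5, 0.5)), 1)
  b3 <- observable_block("SAXS", O = c(1, 0), sigma = c(1, 1),
                         P = rbind(c(1, 1), c(1, 1)))
  expect_equal(optimal_scale(b3, c(0.5, 0.5)), 0.5)
  bz <- observable_block("SAXS", O = 1, sigma = 1, P = matrix(c(0, 0), 2))
  expect_error(optimal_scale(bz, c(0.5, 0.5)), "degenerate")
})

test_that("chi2_block applies the scale mode and normalises by M", {
  bfit <- observable_block("CD", O = c(1, 2), sigma = c(1, 1),
                           P = rbind(c(1, 2), c(1, 2)))
  expect_equal(chi2_block(bfit, c(0.4, 0.6)), 0)
  b0 <- observable_block("CD", O = c(1, 2), sigma = c(1, 1),
                         P = rbind(c(0, 0), c(0, 0)))
  expect_equal(chi2_block(b0, c(0.5, 0.5)), 2.5)
  bf <- observable_block("SAXS", O = c(1, 0), sigma = c(1, 1),
                         P = rbind(c(1, 1), c(1, 1)))
  expect_equal(chi2_block(bf, c(0.5, 0.5)), 0.25)  # alpha* = 0.5
})

test_that("bme_loss combines misfit and entropy terms", {
  bfit <- observable_block("CD", O = 0.5, sigma = 1, P = matrix(c(0, 1), 2))
  w0 <- c(0.5, 0.5)
  expect_equal(bme_loss(list(bfit), w0, w0, theta = 3), 0)
  b0 <- observable_block("CD", O = c(1, 2), sigma = c(1, 1),
                         P = rbind(c(0, 0), c(0, 0)))
  expect_equal(bme_loss(list(b0), w0, w0, theta = 1), 2.5)
  # block fitting perfectly at any weights: only the entropy term remains
  bany <- observable_block("CD", O = c(1, 2), sigma = c(1, 1),
                           P = rbind(c(1, 2), c(1, 2)))
  expect_equal(bme_loss(list(bany), c(1, 0), w0, theta = 2), 2 * log(2))
})

test_that("bme_refine reproduces the one-dimensional stationarity oracle", {
  blk <- two_conformer_block(O = 1)
  w0 <- c(0.5, 0.5)
  # stationarity condition theta * log(p / (1 - p)) = 1 - p, solved
  # independently by uniroot
  oracle <- function(theta)
    uniroot(function(p) theta * log(p / (1 - p)) - (1 - p),
            c(0.5, 1 - 1e-12), tol = 1e-12)$root
  for (theta in c(0.1, 1, 10)) {
    r <- bme_refine(list(blk), w0, theta)
    expect_equal(r$weights$w[2], oracle(theta), tolerance = 1e-6)
  }
  # frozen values from the oracle
  expect_equal(bme_refine(list(blk), w0, 1)$weights$w[2], 0.5989, tolerance = 1e-3)
  expect_equal(bme_refine(list(blk), w0, 10)$weights$w[2], 0.5122, tolerance = 1e-3)
  expect_equal(bme_refine(list(blk), w0, 0.1)$weights$w[2], 0.8366, tolerance = 1e-3)
  # prior already optimal at the midpoint
  mid <- bme_refine(list(two_conformer_block(O = 0.5)), w0, 7)
  expect_equal(mid$weights$w, w0, tolerance = 1e-6)
  expect_equal(mid$chi2_per_block[["CD"]], 0, tolerance = 1e-10)
})

test_that("refinement never increases the loss relative to the prior", {
  for (seed in 1:5) {
    p <- small_problem(seed = seed)
    w0 <- rep(0.1, 10)
    for (theta in c(0.5, 5, 50)) {
      r <- bme_refine(p$blocks, w0, theta)
      expect_lte(r$loss, bme_loss(p$blocks, w0, w0, theta) + 1e-10)
    }
  }
})

test_that("free-block scaling factors are optimal at the solution", {
  p <- small_problem(seed = 9)
  r <- bme_refine(p$blocks, rep(0.1, 10), theta = 2)
  w <- r$weights$w
  a <- r$alpha_per_block[["SAXS"]]
  chi_opt <- chi2_block(p$blocks$SAXS, w, alpha = a)
  expect_lte(chi_opt, chi2_block(p$blocks$SAXS, w, alpha = a * 1.01))
  expect_lte(chi_opt, chi2_block(p$blocks$SAXS, w, alpha = a * 0.99))
})

test_that("theta_scan reports descending thetas consistent with bme_refine", {
  blk <- two_conformer_block(O = 1)
  w0 <- c(0.5, 0.5)
  sc1 <- theta_scan(list(blk), w0, thetas = 2)
  expect_equal(length(sc1$results), 1)
  expect_equal(sc1$results[[1]]$weights$w,
               bme_refine(list(blk), w0, 2)$weights$w, tolerance = 1e-9)
  sc <- theta_scan(list(blk), w0, thetas = c(1, 0.1, 10))
  expect_equal(sc$thetas, c(10, 1, 0.1))
  w2 <- vapply(sc$results, function(r) r$weights$w[2], numeric(1))
  expect_equal(unname(w2), c(0.5122, 0.5989, 0.8366), tolerance = 1e-3)
  # perfect prior: identical results at every theta
  scp <- theta_scan(list(two_conformer_block(O = 0.5)), w0,
                    thetas = c(0.1, 1, 10))
  for (r in scp$results) expect_equal(r$weights$w, w0, tolerance = 1e-6)
})

test_that("select_theta applies the largest-theta improvement rule", {
  p <- small_problem(seed = 21)
  w0 <- rep(0.1, 10)
  sc <- theta_scan(p$blocks, w0, thetas = c(0.1, 1, 5, 20, 100))
  th <- select_theta(sc, frac = 0.5)
  # independent re-application of the rule on the emitted scan table
  delta <- vapply(sc$results, function(r)
    sum(sc$block_sizes * (sc$prior_chi2 - r$chi2_per_block)), numeric(1))
  expected <- sc$thetas[which(delta >= 0.5 * max(delta))[1]]
  expect_equal(th, expected)
  # degenerate: perfect prior, no improvement possible
  scp <- theta_scan(list(two_conformer_block(O = 0.5)), c(0.5, 0.5),
                    thetas = c(1, 10))
  expect_warning(thp <- select_theta(scp), "no theta improves")
  expect_equal(thp, 10)
})
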