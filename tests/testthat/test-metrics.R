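test_that("regrid_spectrum interpolates linearly and drops outside points", {
  s <- spectrum(c(178, 180), c(0, 2))
  expect_equal(regrid_spectrum(s, c(178, 180))$I, c(0, 2))
  expect_equal(regrid_spectrum(s, 179)$I, 1)
  expect_equal(regrid_spectrum(s, c(170, 179, 200))$wavelengths, 179)
  expect_error(regrid_spectrum(s, c(300, 310)), "overlap")
  # idempotent on a subset grid
  s2 <- spectrum(seq(180, 220, 5), sin(seq(180, 220, 5) / 7))
  g <- c(185, 200, 215)
  once <- regrid_spectrum(s2, g)
  expect_equal(regrid_spectrum(once, g)$I, once$I)
})

test_that("rmsd_cd scales the experimental spectrum to minimise the RMSD", {
  e <- spectrum(c(200, 210), c(2, 4), role = "exp")
  c1 <- spectrum(c(200, 210), c(1, 2), role = "calc")
  r <- rmsd_cd(e, c1)
  expect_equal(r$alpha, 0.5)
  expect_equal(r$rmsd, 0)
  r0 <- rmsd_cd(e, c1, scale = FALSE)
  expect_equal(r0$alpha, 1)
  expect_equal(r0$rmsd, sqrt(2.5))
  ident <- rmsd_cd(e, e)
  expect_equal(ident$rmsd, 0)
  expect_equal(ident$alpha, 1)
  expect_error(rmsd_cd(spectrum(c(200, 210), c(0, 0), role = "exp"), c1),
               "all-zero")
})

test_that("the closed-form CD scaling beats any grid alternative and scaled
           RMSD never exceeds unscaled", {
  set.seed(8)
  for (i in 1:10) {
    wl <- seq(190, 250, 5)
    e <- spectrum(wl, rnorm(length(wl), 0, 5), role = "exp")
    k <- spectrum(wl, rnorm(length(wl), 0, 5), role = "calc")
    r <- rmsd_cd(e, k)
    grid <- seq(r$alpha - 0.5, r$alpha + 0.5, length.out = 201)
    rms_at <- vapply(grid, function(a)
      sqrt(mean((a * e$I - k$I)^2)), numeric(1))
    expect_lte(r$rmsd, min(rms_at) + 1e-12)
    expect_lte(r$rmsd, rmsd_cd(e, k, scale = FALSE)$rmsd + 1e-12)
  }
})

test_that("rmsd_ss matches closed forms and is a metric", {
  f1 <- ss_composition(c(a = 1, b = 0, c = 0), "s")
  f2 <- ss_composition(c(a = 0, b = 1, c = 0), "s")
  expect_equal(rmsd_ss(f1, f1), 0)
  expect_equal(rmsd_ss(f1, f2), sqrt(2 / 3))
  g1 <- ss_composition(c(a = 0.5, b = 0.5), "t")
  g2 <- ss_composition(c(a = 0.6, b = 0.4), "t")
  expect_equal(rmsd_ss(g1, g2), 0.1)
  expect_error(rmsd_ss(f1, g1), "scheme")
  set.seed(14)
  for (i in 1:20) {
    fr <- replicate(3, ss_composition(setNames(rsimplex(4),
                                               letters[1:4]), "q"),
                    simplify = FALSE)
    expect_equal(rmsd_ss(fr[[1]], fr[[2]]), rmsd_ss(fr[[2]], fr[[1]]))
    expect_lte(rmsd_ss(fr[[1]], fr[[3]]),
               rmsd_ss(fr[[1]], fr[[2]]) + rmsd_ss(fr[[2]], fr[[3]]) + 1e-12)
  }
})

test_that("chi2_ss normalises squared deviations by the class count", {
  f1 <- ss_composition(c(a = 0.5, b = 0.5), "t")
  f2 <- ss_composition(c(a = 0.6, b = 0.4), "t")
  expect_equal(chi2_ss(f1, f1, c(0.1, 0.1)), 0)
  expect_equal(chi2_ss(f1, f2, c(0.05, 0.1)), 2.5)
  off1 <- ss_composition(c(a = 0.55, b = 0.45), "t")
  expect_equal(chi2_ss(f1, off1, c(0.05, 0.05)), 1)  # each class off by 1 sigma
  expect_error(chi2_ss(f1, f2, c(0, 0.1)), "positive")
})

test_that("group_classes applies the published grouping rules", {
  bs <- ss_composition(c(Helix1 = 0.10, Helix2 = 0.15, Anti1 = 0.05,
                         Anti2 = 0.05, Anti3 = 0.20, Parallel = 0.05,
                         Turn = 0.20, Others = 0.20), "BESTSEL8")
  g <- group_classes(bs, shipped_class_map("bestsel6"))
  expect_equal(g$fractions,
               c(Helix = 0.25, Anti1 = 0.05, Anti2 = 0.05, Anti3 = 0.20,
                 Parallel = 0.05, Other = 0.40))
  idm <- class_map("s", "s", c(a = "a", b = "b"))
  f <- ss_composition(c(a = 0.3, b = 0.7), "s")
  expect_equal(group_classes(f, idm)$fractions, f$fractions)
  # coil completion from structured fractions only
  k <- ss_composition(c(Alpha = 0.3, Beta = 0.2, Coil = 0.5), "DISICL3")
  expect_equal(group_classes(k, shipped_class_map("k2d3"))$fractions[["Coil"]],
               0.5)
  expect_error(group_classes(ss_composition(c(zz = 1), "DISICL3"),
                             shipped_class_map("k2d3")), "unmapped")
})

test_that("grouping conserves total fraction mass on random compositions", {
  maps <- lapply(c("bestsel6", "dssp4", "hbss5", "disicl3"),
                 shipped_class_map)
  set.seed(6)
  for (m in maps) {
    for (i in 1:10) {
      src <- names(m$assignment)
      f <- ss_composition(setNames(rsimplex(length(src)), src),
                          m$source_scheme)
      g <- group_classes(f, m)
      expect_equal(sum(g$fractions), sum(f$fractions), tolerance = 1e-9)
    }
  }
})

test_that("saxs_chi is the root chi-square and scale invariant", {
  b <- observable_block("SAXS", O = c(2, 4), sigma = c(1, 1),
                        P = rbind(c(1, 2), c(1, 2)))
  expect_equal(saxs_chi(b, c(0.5, 0.5)), 0)
  b2 <- observable_block("SAXS", O = c(2, -2), sigma = c(1, 1),
                         P = rbind(c(0, 0.1), c(0, 0.1)))
  expect_equal(saxs_chi(b2, c(0.5, 0.5)), sqrt(chi2_block(b2, c(0.5, 0.5))))
  p <- small_problem(seed = 77)
  blk <- p$blocks$SAXS
  w <- rsimplex(10)
  chi1 <- saxs_chi(blk, w)
  blk10 <- observable_block("SAXS", blk$O, blk$sigma, blk$P * 10)
  expect_equal(saxs_chi(blk10, w), chi1, tolerance = 1e-9)
  # joint rescaling of measurement and sigma also leaves chi unchanged
  blkm <- observable_block("SAXS", blk$O * 3, blk$sigma * 3, blk$P)
  expect_equal(saxs_chi(blkm, w), chi1, tolerance = 1e-9)
  cd <- observable_block("CD", 1, 1, matrix(c(0, 1), 2))
  expect_error(saxs_chi(cd, c(0.5, 0.5)), "free-scaling")
})

test_that("rmsd_cs splits residue deviations by atom type", {
  P <- rbind(c(10, 20, 30, 40), c(14, 24, 30, 44))
  b <- observable_block("CS", O = c(12, 23, 30, 41), sigma = rep(1, 4), P = P,
                        meta = list(atom_type = c("CA", "CB", "CA", "CO")))
  r <- rmsd_cs(b, c(0.5, 0.5))
  expect_equal(r[["CA"]], sqrt(mean(c(0, 0)^2)))
  expect_equal(r[["CB"]], 1)
  expect_equal(r[["CO"]], 1)
})

test_that("summarize_metrics reports group mean and SEM as published", {
  s <- summarize_metrics(c(0.39, 1.94, 1.65, 0.92, 1.03), round_to = 2)
  expect_equal(s$mean, 1.186)
  expect_equal(s$sem, 0.2750018, tolerance = 1e-6)
  expect_equal(s$n, 5)
  g0 <- summarize_metrics(c(0.71, 1.72, 2.94, 0.92, 1.67))
  expect_equal(round_half_up(g0$mean, 2), 1.59)
  expect_equal(round_half_up(g0$sem, 2), 0.39)
  con <- summarize_metrics(rep(2, 4))
  expect_equal(con$sem, 0)
  na <- summarize_metrics(c(1, NA, 3))
  expect_equal(na$n, 2)
  single <- summarize_metrics(c(5, NA))
  expect_true(is.na(single$sem))
  expect_equal(single$mean, 5)
})

test_that("half-up rounding rounds halves away from zero", {
  expect_equal(round_half_up(0.275, 2), 0.28)
  expect_equal(round_half_up(-0.275, 2), -0.28)
  expect_equal(round_half_up(1.25, 1), 1.3)
  expect_equal(round_half_up(2.4, 0), 2)
})
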