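# deeper tests on a shared small simulated cohort (300 markers, 100
# diplotypes); EM settings reduced relative to the defaults to keep the
# suite fast — accuracy checks at the full documented settings live in
# the acceptance suite

test_that("weighted EM log-likelihood is non-decreasing", {
  co <- toy_cohort()
  fit <- two_layer_fit(co, co$training, em_runs = 2, em_steps = 8,
                       seed = 51)
  for (r in 1:2)
    expect_true(all(diff(fit$loglik[, r]) >= -1e-8 *
                      abs(fit$loglik[-1, r])))
  # structure mode (free ancestries, kmeans start) is monotone too
  sp <- generate_source_panels(n_markers = 120, n_haps_per_pop = 50,
                               differentiation = 0.2, seed = 52)
  mp <- haplotype_panel(rbind(sp$panels$EUR$haplotypes,
                              sp$panels$AFR$haplotypes), sp$markers)
  sf <- two_layer_fit(mp, n_upper = 2, n_lower = 6, em_runs = 2,
                      em_steps = 8, seed = 53)
  for (r in 1:2)
    expect_true(all(diff(sf$loglik[, r]) >= -1e-8 *
                      abs(sf$loglik[-1, r])))
})

test_that("dosages normalize to the ploidy everywhere", {
  co <- toy_cohort()
  fit <- two_layer_fit(co, co$training, em_runs = 2, em_steps = 6,
                       seed = 54)
  sums <- apply(fitted(fit), c(1, 2), sum)
  expect_equal(max(abs(sums - 2)), 0, tolerance = 1e-6)
  expect_equal(unname(rowSums(coef(fit))), rep(1, nrow(coef(fit))),
               tolerance = 1e-6)
})

test_that("supervised fit recovers the true African dosage field", {
  co <- toy_cohort()
  fit <- two_layer_fit(co, co$training, em_runs = 3, em_steps = 12,
                       seed = 55)
  tavg <- apply(truth_dosages(co), c(2, 3), mean)
  avg <- apply(fitted(fit), c(2, 3), mean)
  # truth jumps discontinuously at the two hotspots while the chain
  # transitions over a few markers: judge the plateaus, not the cliff edges
  edges <- which(abs(diff(co$segment)) > 0)
  interior <- setdiff(seq_len(nrow(avg)), c(edges - 1, edges, edges + 1,
                                            edges + 2))
  expect_lt(max(abs(avg[interior, "AFR"] - tavg[interior, "AFR"])), 0.05)
  expect_lt(mean(abs(avg[, "AFR"] - tavg[, "AFR"])), 0.02)
  # global admixture proportions recovered
  expect_equal(unname(colMeans(coef(fit))),
               c(0.50, 0.45, 0.05), tolerance = 0.08)
})

test_that("withholding the Amerindian panel barely moves African dosages", {
  co <- toy_cohort()
  sup <- two_layer_fit(co, co$training, em_runs = 3, em_steps = 12,
                       seed = 56)
  par <- two_layer_fit(co, co$training[c("EUR", "AFR")], em_runs = 3,
                       em_steps = 12, seed = 56)
  expect_identical(par$mode, "partial")
  a_sup <- apply(fitted(sup), c(2, 3), mean)[, "AFR"]
  a_par <- apply(fitted(par), c(2, 3), mean)[, "AFR"]
  expect_lt(mean(abs(a_sup - a_par)), 0.03)
})

test_that("two partial fits with different seeds agree closely", {
  co <- toy_cohort()
  f1 <- two_layer_fit(co, co$training[c("EUR", "AFR")], em_runs = 6,
                      em_steps = 15, seed = 57)
  f2 <- two_layer_fit(co, co$training[c("EUR", "AFR")], em_runs = 6,
                      em_steps = 15, seed = 58)
  d <- dosage_difference(apply(fitted(f1), c(2, 3), mean),
                         apply(fitted(f2), c(2, 3), mean),
                         ancestry = "AFR")
  expect_lt(mean(abs(d)), 0.02)
})

test_that("structure mode separates two merged source panels", {
  sp <- generate_source_panels(n_markers = 400, n_haps_per_pop = 80,
                               differentiation = 0.25, seed = 59)
  mp <- haplotype_panel(rbind(sp$panels$EUR$haplotypes,
                              sp$panels$AFR$haplotypes), sp$markers)
  sf <- two_layer_fit(mp, n_upper = 2, n_lower = 10, em_runs = 4,
                      em_steps = 20, seed = 60)
  expect_identical(sf$mode, "structure")
  comp <- coef(sf)[, 1]
  expect_gt(abs(mean(comp[1:80]) - mean(comp[81:160])), 0.5)
})

test_that("diplotype-mode fit matches the phased fit on average dosages", {
  co <- toy_cohort()
  # subset for speed: 30 diplotypes, first 80 markers
  keep_h <- 1:60; keep_m <- 1:80
  sub_markers <- co$haplotypes$markers[keep_m, ]
  hp <- haplotype_panel(co$haplotypes$haplotypes[keep_h, keep_m],
                        sub_markers)
  gp <- as_genotypes(hp)
  tr <- lapply(co$training, function(p)
    haplotype_panel(p$haplotypes[1:60, keep_m], sub_markers, pop = p$pop[1:60]))
  fh <- two_layer_fit(hp, tr, em_runs = 2, em_steps = 6, n_lower = 9,
                      pairing = rep(1:30, each = 2), seed = 61)
  fg <- two_layer_fit(gp, tr, em_runs = 2, em_steps = 6, n_lower = 9,
                      seed = 61)
  expect_identical(fh$ploidy, 2L)
  expect_identical(fg$ploidy, 2L)
  ah <- apply(fitted(fh), c(2, 3), mean)
  ag <- apply(fitted(fg), c(2, 3), mean)
  expect_lt(mean(abs(ah - ag)), 0.05)
  sums <- apply(fitted(fg), c(1, 2), sum)
  expect_equal(max(abs(sums - 2)), 0, tolerance = 1e-6)
})

test_that("fit interface guards", {
  co <- toy_cohort()
  expect_error(two_layer_fit(co, co$training, n_upper = 1), "n_upper")
  expect_error(two_layer_fit(co, co$training, n_lower = 2), "n_lower")
  expect_error(two_layer_fit(co, list(), mode = "supervised"),
               "training panel")
  expect_error(two_layer_fit(co, co$training, mode = "structure"),
               "no training")
})
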