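# a small shared panel set: the admixture machinery only needs segment
# structure, so a sparse marker grid keeps these tests fast
small_panels <- function(seed = 30)
  generate_source_panels(n_markers = 60, n_haps_per_pop = 260, seed = seed)

test_that("neutral admixture preserves the founding proportions", {
  sp <- small_panels()
  cfg <- sim_config(n_pool = 20000, snp_density = 20,
                    n_cohort_diplotypes = 500,
                    n_training_haps_per_pop = 50,
                    selection_coefficient = 0, seed = 31)
  co <- simulate_admixture(sp, cfg)
  # mid-section selected-ancestry frequency stays at its founding value
  expect_lt(abs(co$pool_selected_freq[21] - 0.05),
            3 * drift_se(0.05, 0, 20, 20000))
  # genome-wide ancestry proportions conserved across all three segments
  props <- colMeans(apply(co$truth_ancestry, 2, function(a)
    c(mean(a == 1), mean(a == 2), mean(a == 3))) |> t())
  se2 <- sqrt(20 * 0.5 * 0.5 / 20000) + sqrt(0.25 / 1000)
  expect_lt(abs(props[1] - 0.50), 3 * se2)
  expect_lt(abs(props[2] - 0.45), 3 * se2)
  expect_lt(abs(props[3] - 0.05), 3 * se2)
})

test_that("selection drives the mid-section along the haploid recursion", {
  sp <- small_panels()
  cfg <- sim_config(n_pool = 20000, snp_density = 20,
                    n_cohort_diplotypes = 200,
                    n_training_haps_per_pop = 50,
                    selection_coefficient = 0.05, seed = 32)
  co <- simulate_admixture(sp, cfg)
  p0 <- co$pool_selected_freq[1]
  expected <- haploid_recursion(p0, 0.05, 20)
  expect_lt(abs(co$pool_selected_freq[21] - expected),
            3 * drift_se(p0, 0.05, 20, 20000))
})

test_that("final frequency is monotone in the selection coefficient", {
  sp <- small_panels()
  finals <- vapply(c(0, 0.02, 0.05, 0.10), function(s) {
    cfg <- sim_config(n_pool = 20000, snp_density = 20,
                      n_cohort_diplotypes = 200,
                      n_training_haps_per_pop = 50,
                      selection_coefficient = s, seed = 33)
    simulate_admixture(sp, cfg)$pool_selected_freq[21]
  }, 0)
  expect_true(all(diff(finals) > 0))
})

test_that("selection leaves the flanking segments neutral", {
  sp <- small_panels()
  out_freq <- function(s) {
    cfg <- sim_config(n_pool = 20000, snp_density = 20,
                      n_cohort_diplotypes = 1000,
                      n_training_haps_per_pop = 50,
                      selection_coefficient = s, seed = 34)
    co <- simulate_admixture(sp, cfg)
    mean(co$truth_ancestry[, c(1, 3)] == 3)
  }
  se <- sqrt(20 * 0.05 * 0.95 / 20000) + sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(out_freq(0.10) - out_freq(0)), 3 * sqrt(2) * se)
})

test_that("disabled hotspots give single-ancestry haplotypes", {
  sp <- small_panels()
  cfg <- sim_config(n_pool = 2000, snp_density = 20,
                    n_cohort_diplotypes = 100,
                    n_training_haps_per_pop = 50,
                    hotspot_probs = c(0, 0), seed = 35)
  co <- simulate_admixture(sp, cfg)
  expect_true(all(co$truth_ancestry[, 1] == co$truth_ancestry[, 2] &
                    co$truth_ancestry[, 2] == co$truth_ancestry[, 3]))
})

test_that("cohort haplotypes, truth and pairing are consistent", {
  sp <- small_panels()
  cfg <- sim_config(n_pool = 2000, snp_density = 20,
                    n_cohort_diplotypes = 50,
                    n_training_haps_per_pop = 50, seed = 36)
  co <- simulate_admixture(sp, cfg)
  expect_equal(dim(co$haplotypes$haplotypes), c(100, 60))
  expect_true(all(co$haplotypes$haplotypes %in% 0:1))
  td <- truth_dosages(co)
  expect_true(all(apply(td, c(1, 2), sum) == 2))
  expect_equal(dim(td), c(50, 60, 3))
  # training panels were set aside on the same grid
  expect_equal(nrow(co$training$EUR$haplotypes), 50)
  expect_equal(co$training$AFR$markers$bp, co$haplotypes$markers$bp)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_pool = 999), "even")
  expect_error(sim_config(admix_proportions = c(0.6, 0.3, 0.2)), "sum")
  expect_error(sim_config(hotspot_probs = c(0.6, 0.1)), "hotspot")
  expect_error(sim_config(selection_coefficient = -0.1), ">= 0")
  expect_error(sim_config(n_pool = 100, n_cohort_diplotypes = 100),
               "larger than")
})
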