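test_that("haplotype forward-backward equals exhaustive path enumeration", {
  set.seed(21)
  map <- c(0, 0.3, 0.8, 1.4)
  for (rep in 1:3) {
    C <- 6; anc_of <- c(1, 1, 2, 2, 3, 3)
    theta <- matrix(runif(4 * C), 4, C)
    beta <- runif(C, 0.5, 1.5)
    a <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.6, 0.3))
    h <- rbind(rbinom(4, 1, 0.5), c(0, NA, 1, 0))
    params <- two_layer_params(theta, anc_of, a, map, beta = beta,
                               generations = 5, lambda = 40)
    es <- e_step(params, h)
    for (i in 1:2) {
      o <- enum_haplotype(h[i, ], theta, anc_of, beta, a[i, ], 5, 40, map)
      expect_lt(max(abs(es$q[i, , ] - o$q)), 1e-10)
      expect_equal(es$loglik[i], o$loglik, tolerance = 1e-12)
    }
  }
})

test_that("diplotype product-state chain equals pair enumeration", {
  set.seed(22)
  map <- c(0, 0.4, 1.1)
  C <- 4; anc_of <- c(1, 1, 2, 2)
  theta <- matrix(runif(3 * C), 3, C)
  beta <- runif(C, 0.5, 1.5)
  a <- c(0.4, 0.6)
  for (g in list(c(1, 2, 0), c(2, NA, 1))) {
    params <- two_layer_params(theta, anc_of, a, map, beta = beta,
                               generations = 6, lambda = 30)
    gp <- genotype_panel(matrix(g, 1), toy_markers(3))
    # marker frame spacing differs from map: supply matching map instead
    params$map_cM <- map
    es <- e_step(params, gp)
    o <- enum_diplotype(g, theta, anc_of, beta, a, 6, 30, map)
    expect_lt(max(abs(es$q[1, , ] - o$q)), 1e-10)
    expect_equal(es$loglik[1], o$loglik, tolerance = 1e-12)
    # diplotype posteriors carry ploidy 2
    expect_equal(rowSums(es$q[1, , ]), rep(2, 3), tolerance = 1e-9)
  }
})

test_that("perfectly informative and uninformative emissions", {
  map <- c(0, 0.5)
  anc_of <- c(1, 2)
  a <- c(0.3, 0.7)
  # theta=1 for cluster 1, 0 for cluster 2; allele 1 observed -> cluster 1
  params <- two_layer_params(matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE),
                             anc_of, a, map, generations = 5)
  es <- e_step(params, matrix(c(1, 0), 1))
  expect_equal(es$q[1, 1, ], c(1, 0))
  # uniform theta = 0.5: posteriors equal the chain prior marginals
  params2 <- two_layer_params(matrix(0.5, 3, 2), anc_of, a, c(0, 0.5, 1),
                              generations = 5)
  es2 <- e_step(params2, matrix(c(1, 0, 1), 1))
  for (m in 1:3) expect_equal(es2$q[1, m, ], a, tolerance = 1e-12)
  expect_equal(es2$loglik[1], 3 * log(0.5))
})

test_that("posteriors normalize to ploidy and dosages to ancestries", {
  set.seed(23)
  M <- 10; C <- 6; anc_of <- rep(1:3, each = 2)
  theta <- matrix(runif(M * C), M, C)
  map <- seq(0, 2, length.out = M)
  a <- matrix(rexp(5 * 3), 5); a <- a / rowSums(a)
  X <- matrix(rbinom(5 * M, 1, 0.5), 5, M)
  params <- two_layer_params(theta, anc_of, a, map)
  es <- e_step(params, X)
  expect_equal(apply(es$q, c(1, 2), sum), matrix(1, 5, M),
               tolerance = 1e-9)
  expect_equal(apply(es$dosage, c(1, 2), sum), matrix(1, 5, M),
               tolerance = 1e-9)
})
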