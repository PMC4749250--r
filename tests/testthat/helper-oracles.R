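# Independent oracles and small fixture builders shared across tests.

# normalize lower-cluster weights within each ancestry (textbook arithmetic,
# independent of the package internals)
oracle_betaN <- function(beta, anc_of) {
  out <- beta
  for (s in unique(anc_of))
    out[anc_of == s] <- beta[anc_of == s] / sum(beta[anc_of == s])
  out
}

# dense one-chain transition matrix (rows = from) of the layered model
oracle_transition <- function(m, anc_of, betaN, a_i, ru, rl) {
  C <- length(anc_of)
  c1 <- (1 - ru[m]) * (1 - rl[m])
  c2 <- (1 - ru[m]) * rl[m]
  u <- a_i[anc_of] * betaN
  c1 * diag(C) +
    c2 * outer(anc_of, anc_of, "==") * matrix(betaN, C, C, byrow = TRUE) +
    ru[m] * matrix(u, C, C, byrow = TRUE)
}

# brute-force posterior marginals for one haplotype by path enumeration
enum_haplotype <- function(h, theta, anc_of, beta, a_i, generations,
                           lambda, map_cM) {
  M <- length(h); C <- length(anc_of)
  betaN <- oracle_betaN(beta, anc_of)
  d <- diff(map_cM) / 100
  ru <- 1 - exp(-generations * d)
  rl <- 1 - exp(-lambda * d)
  em <- function(m, j) {
    if (is.na(h[m])) 1 else if (h[m] == 1) theta[m, j] else 1 - theta[m, j]
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(C)), M)))
  pr <- apply(paths, 1, function(z) {
    p <- a_i[anc_of[z[1]]] * betaN[z[1]] * em(1, z[1])
    for (m in 2:M)
      p <- p * oracle_transition(m - 1, anc_of, betaN, a_i, ru, rl)[
        z[m - 1], z[m]] * em(m, z[m])
    p
  })
  lik <- sum(pr)
  q <- sapply(seq_len(C), function(j)
    sapply(seq_len(M), function(m) sum(pr[paths[, m] == j]))) / lik
  list(q = q, loglik = log(lik))
}

# brute-force ordered-pair enumeration for one unphased diploid individual
enum_diplotype <- function(g, theta, anc_of, beta, a_i, generations,
                           lambda, map_cM) {
  M <- length(g); C <- length(anc_of)
  betaN <- oracle_betaN(beta, anc_of)
  d <- diff(map_cM) / 100
  ru <- 1 - exp(-generations * d)
  rl <- 1 - exp(-lambda * d)
  emg <- function(m, j1, j2) {
    if (is.na(g[m])) return(1)
    th <- theta[m, ]
    switch(as.character(g[m]),
           "0" = (1 - th[j1]) * (1 - th[j2]),
           "1" = th[j1] * (1 - th[j2]) + (1 - th[j1]) * th[j2],
           "2" = th[j1] * th[j2])
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(C)), 2 * M)))
  pr <- apply(paths, 1, function(z) {
    z1 <- z[1:M]; z2 <- z[M + 1:M]
    p <- a_i[anc_of[z1[1]]] * betaN[z1[1]] *
      a_i[anc_of[z2[1]]] * betaN[z2[1]] * emg(1, z1[1], z2[1])
    for (m in 2:M) {
      Tm <- oracle_transition(m - 1, anc_of, betaN, a_i, ru, rl)
      p <- p * Tm[z1[m - 1], z1[m]] * Tm[z2[m - 1], z2[m]] *
        emg(m, z1[m], z2[m])
    }
    p
  })
  lik <- sum(pr)
  q <- sapply(seq_len(C), function(j)
    sapply(seq_len(M), function(m)
      sum(pr * ((paths[, m] == j) + (paths[, M + m] == j))))) / lik
  list(q = q, loglik = log(lik))
}

# equally spaced marker frame over a region
toy_markers <- function(M, region = 3e6, cm_per_mb = 1) {
  bp <- round(seq(1, region, length.out = M))
  data.frame(id = sprintf("m%04d", seq_len(M)), bp = bp,
             cM = bp / 1e6 * cm_per_mb)
}

# small simulated cohort reused by several tests (built once per session)
toy_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panels <- generate_source_panels(n_markers = 300, n_haps_per_pop = 300,
                                       seed = 3)
      cfg <- sim_config_reduced(n_pool = 8000, snp_density = 100,
                                n_cohort_diplotypes = 100,
                                n_training_haps_per_pop = 100,
                                selection_coefficient = 0.05, seed = 7)
      cache <<- simulate_admixture(panels, cfg)
    }
    cache
  }
})

# deterministic haploid selection recursion: p' = p(1+s) / (1+ps)
haploid_recursion <- function(p0, s, n) {
  p <- p0
  for (i in seq_len(n)) p <- p * (1 + s) / (1 + p * s)
  p
}

# accumulated drift SE of the final frequency around the deterministic
# path: per-generation binomial noise p_t(1-p_t)/N propagated through the
# recursion (dp_n/dp_t = p_n(1-p_n) / (p_t(1-p_t)) for logistic growth)
drift_se <- function(p0, s, n, N) {
  path <- vapply(0:(n - 1), function(t) haploid_recursion(p0, s, t), 0)
  pn <- haploid_recursion(p0, s, n)
  sqrt((pn * (1 - pn))^2 * sum(1 / (path * (1 - path))) / N)
}
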