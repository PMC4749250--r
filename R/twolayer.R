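#' Parameters of the two-layer haplotype-cluster model
#'
#' The latent state at a marker is a pair (upper, lower): the upper cluster
#' is the ancestral population of the segment, the lower cluster a
#' contemporary haplotype group nested within that ancestry.  Along the
#' chromosome the upper state switches between ancestries at rate
#' `1 - exp(-g d)` (d the map distance in Morgans, g the admixture age in
#' generations), drawing the new ancestry from the individual's admixture
#' proportions; conditional on no ancestry switch, the lower state switches
#' among that ancestry's clusters at rate `1 - exp(-lambda d)`.  Emission at
#' a marker is Bernoulli in the cluster's allele frequency `theta`.
#'
#' @param theta markers x clusters matrix of cluster allele frequencies in
#'   \[0, 1\].
#' @param cluster_ancestry integer vector assigning each lower cluster to an
#'   upper cluster (ancestry).
#' @param admix admixture proportions: either a single vector of length S
#'   (shared) or an individuals x S matrix; rows must sum to 1.
#' @param map_cM genetic map positions of the markers (cM).
#' @param beta within-ancestry lower-cluster weights (normalized internally);
#'   uniform by default.
#' @param generations admixture age g (default 20).
#' @param lambda lower-layer switch intensity per Morgan (default 100).
#'
#' @return An object of class `two_layer_params`.
#' @export
two_layer_params <- function(theta, cluster_ancestry, admix, map_cM,
                             beta = NULL, generations = 20, lambda = 100) {
  theta <- as.matrix(theta)
  C <- ncol(theta)
  if (length(cluster_ancestry) != C)
    stop("cluster_ancestry must assign every theta column")
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]")
  if (length(map_cM) != nrow(theta))
    stop("map_cM must match the marker count of theta")
  S <- max(cluster_ancestry)
  if (is.null(dim(admix))) admix <- matrix(admix, 1)
  admix <- as.matrix(admix)
  if (ncol(admix) != S) stop("admix needs one column per ancestry")
  if (any(abs(rowSums(admix) - 1) > 1e-6))
    stop("admixture proportions must sum to 1 per individual")
  if (is.null(beta)) beta <- rep(1, C)
  if (length(beta) != C || any(beta < 0)) stop("invalid beta")
  structure(list(theta = theta, cluster_ancestry = as.integer(cluster_ancestry),
                 beta = beta, admix = admix, generations = generations,
                 lambda = lambda, map_cM = map_cM),
            class = "two_layer_params")
}

# normalize beta within each ancestry
beta_normalize <- function(beta, anc_of) {
  tot <- rowsum(beta, anc_of)[anc_of]
  out <- ifelse(tot > 0, beta / tot, NA)
  for (s in unique(anc_of[is.na(out)]))
    out[anc_of == s] <- 1 / sum(anc_of == s)
  out
}

transition_rates <- function(map_cM, generations, lambda) {
  d <- diff(map_cM) / 100  # Morgans
  if (any(d < 0)) stop("map positions must be non-decreasing")
  list(ru = 1 - exp(-generations * d), rl = 1 - exp(-lambda * d))
}

emission_matrix <- function(alleles, theta_m) {
  n <- length(alleles)
  miss <- is.na(alleles)
  a0 <- ifelse(miss, 0, alleles)
  E <- matrix(1 - theta_m, n, length(theta_m), byrow = TRUE) +
    outer(a0, 2 * theta_m - 1)
  if (any(miss)) E[miss, ] <- 1
  E
}

# Forward-backward over the layered chain, vectorized across haplotypes.
# X: n x M alleles (0/1/NA); a: n x S admixture; returns loglik, ancestry
# dosages and (optionally) full posteriors and the weighted sufficient
# statistics for the M-step.
fb_haplotypes <- function(X, theta, anc_of, betaN, a, ru, rl,
                          w = NULL, keep_q = FALSE) {
  n <- nrow(X); M <- ncol(X); C <- length(anc_of); S <- ncol(a)
  G <- matrix(0, C, S); G[cbind(seq_len(C), anc_of)] <- 1
  P0 <- a[, anc_of, drop = FALSE] *
    matrix(betaN, n, C, byrow = TRUE)
  f_arr <- array(0, dim = c(n, C, M))
  logc <- matrix(0, n, M)
  Es <- vector("list", M)
  f <- P0 * emission_matrix(X[, 1], theta[1, ])
  cs <- rowSums(f)
  f <- f / cs
  logc[, 1] <- log(cs)
  f_arr[, , 1] <- f
  if (keep_q) Es[[1]] <- TRUE
  for (m in 2:M) {
    c1 <- (1 - ru[m - 1]) * (1 - rl[m - 1])
    c2 <- (1 - ru[m - 1]) * rl[m - 1]
    Fanc <- f %*% G
    pred <- c1 * f +
      c2 * Fanc[, anc_of, drop = FALSE] * matrix(betaN, n, C, byrow = TRUE) +
      ru[m - 1] * P0
    f <- pred * emission_matrix(X[, m], theta[m, ])
    cs <- rowSums(f)
    f <- f / cs
    logc[, m] <- log(cs)
    f_arr[, , m] <- f
  }
  loglik <- rowSums(logc)

  if (is.null(w)) w <- rep(1, n)
  thn <- matrix(0, M, C); thd <- matrix(0, M, C)
  occ <- numeric(C); aocc <- matrix(0, n, S)
  D <- array(0, dim = c(n, M, S))
  q_arr <- if (keep_q) array(0, dim = c(n, M, C)) else NULL
  bRow <- matrix(betaN, n, C, byrow = TRUE)

  b <- matrix(1, n, C)
  for (m in M:1) {
    q <- f_arr[, , m] * b
    q <- q / rowSums(q)
    if (keep_q) q_arr[, m, ] <- q
    miss <- is.na(X[, m])
    wm <- w * !miss
    a0 <- ifelse(miss, 0, X[, m])
    thn[m, ] <- colSums(q * (wm * a0))
    thd[m, ] <- colSums(q * wm)
    occ <- occ + colSums(q * w)
    qG <- q %*% G
    aocc <- aocc + qG
    D[, m, ] <- qG
    if (m > 1) {
      Btil <- b * emission_matrix(X[, m], theta[m, ])
      c1 <- (1 - ru[m - 1]) * (1 - rl[m - 1])
      c2 <- (1 - ru[m - 1]) * rl[m - 1]
      U <- (Btil * bRow) %*% G
      V <- rowSums(a * U)
      b <- (c1 * Btil + c2 * U[, anc_of, drop = FALSE] + ru[m - 1] * V) /
        exp(logc[, m])
    }
  }
  list(loglik = loglik, D = D, thn = thn, thd = thd, occ = occ,
       aocc = aocc / M, q = q_arr)
}

# Product-state forward-backward for one unphased diploid individual.
# Exact ordered-pair chain with phase integrated out.  Returns per-chain
# summed cluster posteriors (scale [0,2]) and M-step statistics.
fb_diplotype <- function(g, theta, anc_of, betaN, a_i, ru, rl,
                         keep_q = FALSE) {
  M <- length(g); C <- length(anc_of); S <- max(anc_of)
  G <- matrix(0, C, S); G[cbind(seq_len(C), anc_of)] <- 1
  p0 <- a_i[anc_of] * betaN
  u <- p0  # ancestry-jump arrival distribution, same as the initial law
  M1 <- (outer(anc_of, anc_of, "==")) * matrix(betaN, C, C, byrow = TRUE)
  emis <- function(m) {
    if (is.na(g[m])) return(matrix(1, C, C))
    th <- theta[m, ]
    switch(as.character(g[m]),
           "0" = outer(1 - th, 1 - th),
           "1" = outer(th, 1 - th) + outer(1 - th, th),
           "2" = outer(th, th),
           stop("genotypes must be 0/1/2/NA for the diplotype chain"))
  }
  Tm <- function(m) {  # dense one-chain transition, rows = from
    c1 <- (1 - ru[m]) * (1 - rl[m])
    c2 <- (1 - ru[m]) * rl[m]
    c1 * diag(C) + c2 * M1 + ru[m] * matrix(u, C, C, byrow = TRUE)
  }
  f_list <- vector("list", M)
  logc <- numeric(M)
  f <- outer(p0, p0) * emis(1)
  cs <- sum(f); f <- f / cs; logc[1] <- log(cs)
  f_list[[1]] <- f
  for (m in 2:M) {
    T1 <- Tm(m - 1)
    f <- (t(T1) %*% f %*% T1) * emis(m)
    cs <- sum(f); f <- f / cs; logc[m] <- log(cs)
    f_list[[m]] <- f
  }
  b <- matrix(1, C, C)
  thn <- matrix(0, M, C); thd <- matrix(0, M, C)
  occ <- numeric(C); aocc <- numeric(S)
  D <- matrix(0, M, S)
  q_out <- if (keep_q) matrix(0, M, C) else NULL
  for (m in M:1) {
    Gam <- f_list[[m]] * b
    Gam <- Gam / sum(Gam)
    q1 <- rowSums(Gam); q2 <- colSums(Gam)
    qt <- q1 + q2
    if (keep_q) q_out[m, ] <- qt
    D[m, ] <- as.vector(qt %*% G)
    occ <- occ + qt
    aocc <- aocc + as.vector(qt %*% G)
    if (!is.na(g[m])) {
      thd[m, ] <- qt
      if (g[m] == 2) thn[m, ] <- qt
      if (g[m] == 1) {
        th <- theta[m, ]
        e1 <- outer(th, 1 - th) + outer(1 - th, th)
        A <- outer(th, 1 - th) / e1  # P(chain 1 carries the 1-allele)
        thn[m, ] <- rowSums(Gam * A) + colSums(Gam * (1 - A))
      }
    }
    if (m > 1) {
      T1 <- Tm(m - 1)
      Btil <- b * emis(m)
      b <- (T1 %*% Btil %*% t(T1)) / exp(logc[m])
    }
  }
  list(loglik = sum(logc), D = D, thn = thn, thd = thd, occ = occ,
       aocc = aocc / (2 * M), q = q_out)
}

#' Exact posterior decoding under fixed two-layer parameters
#'
#' Runs the scaled forward-backward recursions of the layered chain and
#' returns exact marginal posteriors over lower clusters, ancestry dosages,
#' and the observed-data log-likelihood.  Haplotype input uses the
#' single-chain model; genotype input uses the ordered product-state chain
#' over haplotype pairs with phase integrated out (posteriors then sum to
#' 2 per marker).
#'
#' @param params a [two_layer_params()] object.
#' @param panel a [haplotype_panel()], [genotype_panel()], or a plain
#'   allele matrix (rows = haplotypes).
#' @return List with `q` (individuals x markers x clusters posterior,
#'   summing to the ploidy over clusters at each marker), `dosage`
#'   (individuals x markers x ancestries), and `loglik` (per individual).
#' @export
e_step <- function(params, panel) {
  stopifnot(inherits(params, "two_layer_params"))
  anc_of <- params$cluster_ancestry
  betaN <- beta_normalize(params$beta, anc_of)
  tr <- transition_rates(params$map_cM, params$generations, params$lambda)
  S <- max(anc_of)
  diploid <- inherits(panel, "genotype_panel")
  X <- if (inherits(panel, "haplotype_panel")) panel$haplotypes
       else if (diploid) panel$genotypes
       else as.matrix(panel)
  if (ncol(X) != nrow(params$theta))
    stop("panel markers do not match params")
  n <- nrow(X)
  a <- params$admix
  if (nrow(a) == 1) a <- a[rep(1, n), , drop = FALSE]
  if (nrow(a) != n) stop("admix rows do not match panel")
  if (!diploid) {
    res <- fb_haplotypes(X, params$theta, anc_of, betaN, a,
                         tr$ru, tr$rl, keep_q = TRUE)
    return(list(q = res$q, dosage = res$D, loglik = res$loglik))
  }
  M <- ncol(X)
  q <- array(0, dim = c(n, M, length(anc_of)))
  D <- array(0, dim = c(n, M, S))
  ll <- numeric(n)
  for (i in seq_len(n)) {
    res <- fb_diplotype(X[i, ], params$theta, anc_of, betaN, a[i, ],
                        tr$ru, tr$rl, keep_q = TRUE)
    q[i, , ] <- res$q
    D[i, , ] <- res$D
    ll[i] <- res$loglik
  }
  list(q = q, dosage = D, loglik = ll)
}

#' Weighted cluster allele-frequency update
#'
#' One M-step update of a cluster allele frequency from marginal posteriors
#' at a single marker, with differential training/cohort weights: cluster
#' j's frequency estimate is the weighted posterior mass on the 1-allele
#' over the weighted posterior mass on observed alleles,
#' `t_j = (w_t S1t + w_c S1c) / (w_t (S0t + S1t) + w_c (S0c + S1c))`,
#' where `Skt`/`Skc` sum `q_ij` over training/cohort haplotypes carrying
#' allele k.  With equal weights this reduces to the unweighted estimator,
#' and with no training haplotypes the cohort weight cancels.
#'
#' @param q haplotypes x clusters matrix of marginal posteriors at the
#'   marker (rows sum to 1).
#' @param alleles 0/1 alleles of the haplotypes at the marker (`NA` =
#'   missing, excluded).
#' @param is_training logical vector marking training haplotypes.
#' @param w_t,w_c non-negative training and cohort weights (not both 0).
#' @param theta_prev previous frequencies, retained (with a warning) for
#'   clusters with zero weighted occupancy.
#' @param floor clamp bound: the estimate is restricted to
#'   `[floor, 1 - floor]`.
#' @return Numeric vector of updated frequencies, one per cluster.
#' @export
update_theta <- function(q, alleles, is_training, w_t = 1, w_c = 1,
                         theta_prev = NULL, floor = 1e-4) {
  q <- as.matrix(q)
  n <- nrow(q)
  stopifnot(length(alleles) == n, length(is_training) == n)
  if (w_t < 0 || w_c < 0 || (w_t == 0 && w_c == 0))
    stop("weights must be non-negative and not both zero")
  w <- ifelse(is_training, w_t, w_c)
  keep <- !is.na(alleles)
  num <- colSums(q * (w * keep * ifelse(keep, alleles, 0)))
  den <- colSums(q * (w * keep))
  t_j <- num / den
  bad <- den <= 0 | !is.finite(t_j)
  if (any(bad)) {
    warning(sum(bad), " unoccupied cluster(s): previous theta retained")
    t_j[bad] <- if (is.null(theta_prev)) 0.5 else theta_prev[bad]
  }
  pmin(pmax(t_j, floor), 1 - floor)
}

#' Align ancestry labels across independent EM runs
#'
#' Independent EM runs may permute the labels of ancestries that are not
#' anchored by a training panel (label switching).  Anchored ancestries are
#' fixed by construction; the remaining labels of each run are matched to
#' the first run by greedily maximizing the correlation of the per-marker
#' dosage fields.  Degenerate (constant) fields are matched in run order.
#'
#' @param runs list of dosage arrays (individuals x markers x ancestries)
#'   of identical shape, one per EM run.
#' @param anchors logical vector: which ancestries are anchored by a
#'   training panel.
#' @return List of integer permutations, one per run; permutation `p` means
#'   `runs[[r]][, , p]` is label-aligned with `runs[[1]]`.
#' @export
align_labels <- function(runs, anchors) {
  stopifnot(length(runs) >= 1)
  S <- dim(runs[[1]])[3]
  stopifnot(length(anchors) == S)
  free <- which(!anchors)
  perms <- rep(list(seq_len(S)), length(runs))
  if (length(free) < 2 || length(runs) < 2) return(perms)
  ref <- runs[[1]]
  for (r in seq_along(runs)[-1]) {
    cc <- matrix(-Inf, length(free), length(free))
    for (i in seq_along(free)) for (j in seq_along(free)) {
      v <- suppressWarnings(stats::cor(as.vector(ref[, , free[i]]),
                                       as.vector(runs[[r]][, , free[j]])))
      cc[i, j] <- if (is.finite(v)) v else -Inf
    }
    assign <- integer(length(free))
    rows_left <- seq_along(free)
    cols_left <- seq_along(free)
    while (length(rows_left)) {
      sub <- cc[rows_left, cols_left, drop = FALSE]
      if (all(!is.finite(sub))) {  # degenerate fields: keep run order
        assign[rows_left] <- cols_left
        break
      }
      k <- which(sub == max(sub[is.finite(sub)]), arr.ind = TRUE)[1, ]
      ri <- rows_left[k[1]]; cj <- cols_left[k[2]]
      assign[ri] <- cj
      rows_left <- setdiff(rows_left, ri)
      cols_left <- setdiff(cols_left, cj)
    }
    p <- seq_len(S)
    p[free] <- free[assign]
    perms[[r]] <- p
  }
  perms
}
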