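#' Simulation configuration for the admixture-under-selection generator
#'
#' Defaults reproduce the study conditions of the forward simulation: a 3 Mb
#' region at 1 cM/Mb split into three segments by two recombination
#' hotspots, one-pulse 50/45/5 admixture of Amerindian-, European- and
#' African-proxy source populations, 20 generations of random mating with
#' haploid viability selection favouring the African-origin mid-section,
#' and a cohort of 1,000 diplotypes sampled at the end.
#'
#' @param n_pool even number of haplotypes in the admixed pool (50,000).
#' @param admix_proportions length-3 proportions (sum 1) for the
#'   Amerindian/European/African proxies (0.50, 0.45, 0.05).
#' @param generations admixture generations (20).
#' @param region_length region size in bp (3e6).
#' @param midsection_length size in bp of the selected mid-section (5e5 or
#'   1e6 in the study; default 5e5, the harder setting).
#' @param hotspot_probs per-generation crossover probability at the two
#'   segment boundaries (study values 0.1, 0.2 or 0.5 at both).
#' @param selection_coefficient s per generation (study values 0.02, 0.05,
#'   0.10; 0 for neutral).
#' @param selected_ancestry index (or name) of the favoured ancestry
#'   (default 3, the African proxy).
#' @param snp_density SNPs per cM (1000).
#' @param cm_per_mb genetic map scale (1 cM/Mb).
#' @param n_cohort_diplotypes diplotypes sampled at the end (1,000).
#' @param n_training_haps_per_pop haplotypes set aside per source population
#'   before admixture (200).
#' @param seed optional RNG seed recorded in outputs.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pool = 50000,
                       admix_proportions = c(0.50, 0.45, 0.05),
                       generations = 20,
                       region_length = 3e6,
                       midsection_length = 5e5,
                       hotspot_probs = c(0.2, 0.2),
                       selection_coefficient = 0,
                       selected_ancestry = 3,
                       snp_density = 1000,
                       cm_per_mb = 1,
                       n_cohort_diplotypes = 1000,
                       n_training_haps_per_pop = 200,
                       seed = NULL) {
  cfg <- list(n_pool = n_pool, admix_proportions = admix_proportions,
              generations = generations, region_length = region_length,
              midsection_length = midsection_length,
              hotspot_probs = hotspot_probs,
              selection_coefficient = selection_coefficient,
              selected_ancestry = selected_ancestry,
              snp_density = snp_density, cm_per_mb = cm_per_mb,
              n_cohort_diplotypes = n_cohort_diplotypes,
              n_training_haps_per_pop = n_training_haps_per_pop,
              seed = seed)
  if (n_pool < 2 || n_pool %% 2 != 0) stop("n_pool must be even and positive")
  if (length(admix_proportions) != 3 ||
      abs(sum(admix_proportions) - 1) > 1e-8)
    stop("admix_proportions must be 3 values summing to 1")
  if (any(admix_proportions < 0)) stop("admix_proportions must be >= 0")
  if (generations < 1) stop("generations must be >= 1")
  if (length(hotspot_probs) != 2 || any(hotspot_probs < 0) ||
      any(hotspot_probs > 0.5))
    stop("hotspot_probs must be two values in [0, 0.5]")
  if (selection_coefficient < 0) stop("selection_coefficient must be >= 0")
  if (midsection_length <= 0 || midsection_length >= region_length)
    stop("midsection_length must be in (0, region_length)")
  if (n_cohort_diplotypes < 1 || n_training_haps_per_pop < 0)
    stop("counts must be positive")
  if (2 * n_cohort_diplotypes > n_pool)
    stop("cohort larger than the admixed pool")
  structure(cfg, class = "sim_config")
}

#' Reduced simulation configuration for desk-scale runs
#'
#' The study-scale defaults of [sim_config()] (50,000-haplotype pool,
#' 3,000 SNPs, 1,000 diplotypes) are larger than needed to exercise the
#' method; this documented reduced setting (5,000-haplotype pool, 600
#' markers, 200 cohort diplotypes, crossover probability 0.2) preserves
#' the qualitative behaviour at a fraction of the cost.
#'
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_reduced <- function(...) {
  args <- list(...)
  base <- list(n_pool = 5000, snp_density = 200,
               n_cohort_diplotypes = 200, n_training_haps_per_pop = 200,
               hotspot_probs = c(0.2, 0.2))
  do.call(sim_config, utils::modifyList(base, args))
}

n_markers_of <- function(config)
  max(2L, round(config$region_length / 1e6 * config$cm_per_mb *
                  config$snp_density))

marker_grid <- function(config) {
  M <- n_markers_of(config)
  bp <- round(seq(1, config$region_length, length.out = M))
  data.frame(id = sprintf("m%04d", seq_len(M)), bp = bp,
             cM = bp / 1e6 * config$cm_per_mb)
}

#' Generate differentiated source-population haplotype panels
#'
#' Per-SNP population allele frequencies follow a Balding-Nichols
#' hierarchy: an ancestral frequency is drawn uniformly on (0.05, 0.95)
#' and each population's frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with its differentiation parameter `F`.
#' Haplotypes are then drawn by a founder-mosaic copying process — each
#' haplotype copies a small panel of founder haplotypes, switching founders
#' along the genetic map — and founder alleles follow a latent AR(1)
#' Gaussian copula, so panels exhibit linkage disequilibrium that decays
#' with map distance both through haplotype sharing and through
#' marker-to-marker allele correlation.
#'
#' @param n_markers number of SNPs (>= 2), on an equally spaced grid.
#' @param n_haps_per_pop haplotypes generated per population.
#' @param differentiation Balding-Nichols `F` per population, each in
#'   (0, 1); recycled to length 3.
#' @param n_founders founder haplotypes per population for the mosaic
#'   process (controls haplotype diversity).
#' @param switch_rate founder-switch intensity per Morgan.
#' @param region_length,cm_per_mb marker grid geometry.
#' @param pop_names population names.
#' @param seed optional RNG seed.
#'
#' @return An object of class `source_panels`: a list with `panels` (three
#'   [haplotype_panel()]s on an identical marker grid), `freqs` (realized
#'   per-SNP sample frequencies, markers x populations), `pop_freqs` (the
#'   Balding-Nichols draws), `ancestral_freq`, and the parameters used.
#' @export
generate_source_panels <- function(n_markers = 3000, n_haps_per_pop = 600,
                                   differentiation = 0.12,
                                   n_founders = 20, switch_rate = 100,
                                   region_length = 3e6, cm_per_mb = 1,
                                   pop_names = c("AMR", "EUR", "AFR"),
                                   seed = NULL) {
  if (n_markers < 2) stop("n_markers must be >= 2")
  if (n_haps_per_pop < 2) stop("n_haps_per_pop must be >= 2")
  if (n_founders < 2) stop("n_founders must be >= 2")
  Fst <- rep(differentiation, length.out = 3)
  if (any(Fst <= 0) || any(Fst >= 1))
    stop("differentiation parameters must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  bp <- round(seq(1, region_length, length.out = n_markers))
  markers <- data.frame(id = sprintf("m%04d", seq_len(n_markers)), bp = bp,
                        cM = bp / 1e6 * cm_per_mb)
  p_anc <- stats::runif(n_markers, 0.05, 0.95)
  d_morgan <- diff(markers$cM) / 100
  p_switch <- 1 - exp(-switch_rate * d_morgan)
  panels <- vector("list", 3)
  pop_freqs <- matrix(NA_real_, n_markers, 3)
  freqs <- matrix(NA_real_, n_markers, 3)
  for (k in 1:3) {
    a <- p_anc * (1 - Fst[k]) / Fst[k]
    b <- (1 - p_anc) * (1 - Fst[k]) / Fst[k]
    pk <- stats::rbeta(n_markers, a, b)
    pop_freqs[, k] <- pk
    # founder alleles via a latent AR(1) Gaussian copula: marginals are
    # exactly Bernoulli(pk) while alleles correlate along the map, so the
    # panels carry marker-to-marker LD beyond haplotype sharing alone
    rho <- exp(-3 * switch_rate * d_morgan)
    z <- matrix(0, n_founders, n_markers)
    z[, 1] <- stats::rnorm(n_founders)
    for (m in 2:n_markers)
      z[, m] <- rho[m - 1] * z[, m - 1] +
        sqrt(1 - rho[m - 1]^2) * stats::rnorm(n_founders)
    founders <- sweep(z, 2, stats::qnorm(pk), "<") * 1L
    # founder-mosaic: Markov founder index along the map, uniform on switch
    idx <- matrix(0L, n_haps_per_pop, n_markers)
    idx[, 1] <- sample.int(n_founders, n_haps_per_pop, replace = TRUE)
    for (m in 2:n_markers) {
      sw <- stats::runif(n_haps_per_pop) < p_switch[m - 1]
      idx[, m] <- ifelse(sw,
                         sample.int(n_founders, n_haps_per_pop, TRUE),
                         idx[, m - 1])
    }
    H <- matrix(founders[cbind(as.vector(idx),
                               rep(seq_len(n_markers),
                                   each = n_haps_per_pop))],
                n_haps_per_pop, n_markers)
    freqs[, k] <- colMeans(H)
    panels[[k]] <- haplotype_panel(H, markers,
                                   pop = rep(pop_names[k], n_haps_per_pop))
  }
  names(panels) <- pop_names
  colnames(freqs) <- colnames(pop_freqs) <- pop_names
  structure(list(panels = panels, freqs = freqs, pop_freqs = pop_freqs,
                 ancestral_freq = p_anc, differentiation = Fst,
                 n_founders = n_founders, switch_rate = switch_rate,
                 markers = markers, seed = seed),
            class = "source_panels")
}

#' @export
print.source_panels <- function(x, ...) {
  cat(sprintf(
    "source_panels: %s; %d markers, %d haplotypes each, F = %s\n",
    paste(names(x$panels), collapse = "/"), nrow(x$markers),
    nrow(x$panels[[1]]$haplotypes),
    paste(format(x$differentiation), collapse = "/")))
  invisible(x)
}

segment_of <- function(bp, config) {
  b1 <- (config$region_length - config$midsection_length) / 2
  b2 <- (config$region_length + config$midsection_length) / 2
  findInterval(bp, c(b1, b2)) + 1L
}

#' Forward-simulate a three-way admixed cohort under selection
#'
#' Generation 0 draws `n_pool` haplotypes from the three source panels with
#' the configured admixture proportions (after setting aside training
#' haplotypes).  Each later generation repeats `n_pool/2` times: sample two
#' haplotypes with replacement — a haplotype whose mid-section ancestry is
#' the selected one has sampling weight `1+s`, otherwise 1 — apply an
#' independent crossover at each hotspot with its configured probability,
#' and emit both recombinants.  Crossovers occur only at the two segment
#' boundaries, so each haplotype is a triple of founder segments whose
#' ancestry labels propagate exactly.  After the configured number of
#' generations, `2 * n_cohort_diplotypes` haplotypes are sampled without
#' replacement and paired consecutively into diplotypes.
#'
#' @param panels a `source_panels` object (see [generate_source_panels()]).
#' @param config a [sim_config()].
#' @return An object of class `admixed_cohort`: `haplotypes` (a
#'   [haplotype_panel()] of the cohort), `truth_ancestry` (haplotypes x 3
#'   segments, ancestry index per segment), `pairing`, `training` (list of
#'   per-population training [haplotype_panel()]s), `segment` (segment index
#'   per marker), `pool_selected_freq` (per-generation frequency of the
#'   selected ancestry's mid-section in the pool, generations 0..G), and
#'   `config`.
#' @export
simulate_admixture <- function(panels, config) {
  stopifnot(inherits(panels, "source_panels"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  markers <- panels$markers
  seg <- segment_of(markers$bp, config)
  if (length(unique(seg)) < 3)
    stop("marker grid does not cover all three segments")
  sizes <- vapply(panels$panels, function(p) nrow(p$haplotypes), 0L)
  n_train <- config$n_training_haps_per_pop
  if (any(sizes <= n_train))
    stop("source panels too small for the training set-aside")
  training <- vector("list", 3)
  pool_ids <- vector("list", 3)
  for (k in 1:3) {
    tr <- sample.int(sizes[k], n_train)
    training[[k]] <- haplotype_panel(
      panels$panels[[k]]$haplotypes[tr, , drop = FALSE], markers,
      pop = rep(names(panels$panels)[k], n_train))
    pool_ids[[k]] <- setdiff(seq_len(sizes[k]), tr)
  }
  names(training) <- names(panels$panels)
  founderH <- do.call(rbind, lapply(panels$panels, `[[`, "haplotypes"))
  offset <- c(0L, cumsum(sizes))[1:3]
  founder_pop <- rep(1:3, sizes)

  sel <- config$selected_ancestry
  if (is.character(sel)) sel <- match(sel, names(panels$panels))
  s <- config$selection_coefficient
  n_pool <- config$n_pool

  # one founder per segment; ancestry label = founder's population
  pop0 <- sample.int(3, n_pool, replace = TRUE,
                     prob = config$admix_proportions)
  fid <- matrix(0L, n_pool, 3)
  draw <- function(p) pool_ids[[p]][sample.int(length(pool_ids[[p]]),
                                               sum(pop0 == p), TRUE)]
  for (p in 1:3) fid[pop0 == p, ] <- offset[p] + draw(p)
  anc <- matrix(founder_pop[fid], n_pool, 3)

  traj <- numeric(config$generations + 1)
  traj[1] <- mean(anc[, 2] == sel)
  half <- n_pool / 2
  for (g in seq_len(config$generations)) {
    w <- 1 + s * (anc[, 2] == sel)
    i1 <- sample.int(n_pool, half, replace = TRUE, prob = w)
    i2 <- sample.int(n_pool, half, replace = TRUE, prob = w)
    A <- fid[i1, , drop = FALSE]
    B <- fid[i2, , drop = FALSE]
    x1 <- stats::runif(half) < config$hotspot_probs[1]
    tmp <- A[x1, 2:3]; A[x1, 2:3] <- B[x1, 2:3]; B[x1, 2:3] <- tmp
    x2 <- stats::runif(half) < config$hotspot_probs[2]
    tmp <- A[x2, 3]; A[x2, 3] <- B[x2, 3]; B[x2, 3] <- tmp
    fid <- rbind(A, B)
    anc <- matrix(founder_pop[fid], n_pool, 3)
    traj[g + 1] <- mean(anc[, 2] == sel)
  }

  keep <- sample.int(n_pool, 2 * config$n_cohort_diplotypes)
  fid <- fid[keep, , drop = FALSE]
  anc <- anc[keep, , drop = FALSE]
  H <- matrix(0L, nrow(fid), nrow(markers))
  for (kseg in 1:3) {
    cols <- which(seg == kseg)
    H[, cols] <- founderH[fid[, kseg], cols, drop = FALSE]
  }
  rownames(H) <- sprintf("h%04d", seq_len(nrow(H)))
  structure(list(
    haplotypes = haplotype_panel(H, markers),
    truth_ancestry = anc,
    pairing = rep(seq_len(config$n_cohort_diplotypes), each = 2),
    training = training,
    segment = seg,
    pool_selected_freq = traj,
    ancestries = names(panels$panels),
    config = config), class = "admixed_cohort")
}

#' @export
print.admixed_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "admixed_cohort: %d diplotypes x %d markers, %d generations, s = %g\n",
    "selected ancestry '%s' mid-section frequency: %.4f -> %.4f\n"),
    cfg$n_cohort_diplotypes, ncol(x$haplotypes$haplotypes),
    cfg$generations, cfg$selection_coefficient,
    x$ancestries[cfg$selected_ancestry],
    x$pool_selected_freq[1], x$pool_selected_freq[length(x$pool_selected_freq)]))
  invisible(x)
}

#' Ground-truth ancestry dosages of a simulated cohort
#'
#' @param cohort an `admixed_cohort`.
#' @return Array `n_cohort_diplotypes` x markers x 3 ancestries of true
#'   diploid ancestry dosages (entries 0, 1 or 2; rows sum to 2).
#' @export
truth_dosages <- function(cohort) {
  stopifnot(inherits(cohort, "admixed_cohort"))
  anc_m <- cohort$truth_ancestry[, cohort$segment, drop = FALSE]  # hap x M
  n_ind <- length(unique(cohort$pairing))
  M <- ncol(anc_m)
  D <- array(0, dim = c(n_ind, M, 3),
             dimnames = list(sprintf("i%04d", seq_len(n_ind)),
                             cohort$haplotypes$markers$id,
                             cohort$ancestries))
  for (k in 1:3) {
    ind <- (anc_m == k) * 1
    D[, , k] <- rowsum(ind, cohort$pairing)
  }
  D
}

#' Inject phasing switch errors into paired haplotypes
#'
#' Scanning markers left to right within each diplotype, every heterozygous
#' site independently initiates a switch with probability `rate`; a switch
#' exchanges the two haplotypes' suffixes from that site onward (the site
#' included).  Unphased genotypes are unchanged at every site.
#'
#' @param haps haplotype matrix (rows paired), [haplotype_panel()], or
#'   `admixed_cohort` (its cohort haplotypes are modified).
#' @param rate switch initiation probability per heterozygous site, in
#'   \[0, 1\].
#' @param pairing haplotype-to-diplotype assignment; consecutive by default.
#' @param seed optional RNG seed.
#' @return Same class as the input, with attributes `n_switches` and
#'   `n_het` (total switch initiations and heterozygous sites) on the
#'   returned haplotype matrix.
#' @export
inject_switch_errors <- function(haps, rate, pairing = NULL, seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(haps, "admixed_cohort")) {
    haps$haplotypes$haplotypes <- inject_switch_errors(
      haps$haplotypes$haplotypes, rate, haps$pairing)
    return(haps)
  }
  if (inherits(haps, "haplotype_panel")) {
    haps$haplotypes <- inject_switch_errors(haps$haplotypes, rate, pairing)
    return(haps)
  }
  H <- haps
  if (nrow(H) %% 2 != 0) stop("unpaired haplotypes: odd row count")
  if (is.null(pairing)) pairing <- rep(seq_len(nrow(H) / 2), each = 2)
  groups <- split(seq_len(nrow(H)), pairing)
  if (any(lengths(groups) != 2)) stop("each pair needs exactly 2 haplotypes")
  n_sw <- 0L; n_het <- 0L
  for (g in groups) {
    h1 <- H[g[1], ]; h2 <- H[g[2], ]
    het <- which(!is.na(h1) & !is.na(h2) & h1 != h2)
    n_het <- n_het + length(het)
    if (!length(het) || rate == 0) next
    init <- stats::runif(length(het)) < rate
    n_sw <- n_sw + sum(init)
    if (!any(init)) next
    state <- integer(ncol(H))
    state[het[init]] <- 1L
    swapped <- cumsum(state) %% 2L == 1L
    H[g[1], swapped] <- h2[swapped]
    H[g[2], swapped] <- h1[swapped]
  }
  attr(H, "n_switches") <- n_sw
  attr(H, "n_het") <- n_het
  H
}
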