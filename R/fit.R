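#' Fit the two-layer cluster model and infer local ancestry dosages
#'
#' The workhorse estimator.  Training panels (haplotypes of known ancestry)
#' and cohort samples are fitted jointly by EM; training haplotypes are
#' pinned to their ancestry's lower clusters while cohort samples mix over
#' all ancestries with individually estimated admixture proportions.  The
#' cluster allele-frequency update weights training and cohort samples
#' differentially (`w_t`, `w_c`), which permits an absent training panel:
#' that ancestry's clusters are then learned from the cohort alone.  Runs
#' `em_runs` independent restarts from randomized cluster frequencies and
#' averages the ancestry-dosage fields across runs after adjusting for
#' label switching.
#'
#' Modes: `"supervised"` (every ancestry has a training panel),
#' `"partial"` (at least one panel absent), `"structure"` (no panels and no
#' labels: unsupervised haplotype-based structure analysis).  The default
#' `"auto"` picks by the number of panels supplied.
#'
#' @param cohort cohort samples: a [haplotype_panel()] (phased),
#'   [genotype_panel()] (unphased; slower exact product-state chain), or an
#'   `admixed_cohort` from [simulate_admixture()] (its haplotypes and
#'   pairing are used).
#' @param training named list of [haplotype_panel()]s, one per available
#'   ancestry; names label the ancestries.  May be empty.
#' @param n_upper number of ancestral populations S.
#' @param n_lower total lower-layer clusters, divided as evenly as possible
#'   among ancestries.
#' @param generations admixture age in generations.
#' @param em_steps EM iterations per run.
#' @param em_runs independent EM restarts averaged.
#' @param w_t,w_c training and cohort sample weights.  Default `w_t = 1`
#'   and `w_c = min(0.1, n_training_haplotypes / n_cohort_haplotypes)`, so
#'   the cohort never swamps the training panels and anchored cluster
#'   frequencies stay faithful to their panels (`w_c = 1` when there are
#'   no training samples, where the weight cancels).
#' @param lambda lower-layer switch intensity per Morgan.
#' @param theta_floor clamp bound for cluster allele frequencies.
#' @param mode fitting mode, see Details.
#' @param ancestries optional full vector of ancestry names (length
#'   `n_upper`); defaults to the training names padded with `anc<k>`.
#' @param pairing optional haplotype-to-individual pairing for a phased
#'   cohort; when present, dosages are reported per individual on the
#'   diploid \[0, 2\] scale (an `admixed_cohort` supplies its own pairing).
#' @param seed RNG seed for the randomized restarts.
#' @param verbose print per-run progress.
#'
#' @return An object of class `two_layer_fit` with elements `dosages`
#'   (individuals x markers x ancestries, run-averaged and label-aligned),
#'   `admix` (per-individual admixture proportions), `theta`, `beta`,
#'   `cluster_ancestry` (from the best-likelihood run), `loglik`
#'   (weighted observed-data log-likelihood, iterations x runs),
#'   `permutations`, `ploidy`, `ancestries`, `mode`, `weights`, `config`.
#' @seealso [e_step()], [update_theta()], [align_labels()],
#'   [average_dosages()]
#' @export
two_layer_fit <- function(cohort, training = list(),
                          n_upper = 3, n_lower = 15,
                          generations = 20, em_steps = 20, em_runs = 10,
                          w_t = 1, w_c = NULL, lambda = 100,
                          theta_floor = 1e-4,
                          mode = c("auto", "supervised", "partial",
                                   "structure"),
                          ancestries = NULL, pairing = NULL, seed = NULL,
                          verbose = FALSE) {
  mode <- match.arg(mode)
  if (inherits(cohort, "admixed_cohort")) {
    if (is.null(pairing)) pairing <- cohort$pairing
    cohort <- cohort$haplotypes
  }
  diploid <- inherits(cohort, "genotype_panel")
  if (!diploid && !inherits(cohort, "haplotype_panel"))
    cohort <- haplotype_panel(as.matrix(cohort),
                              data.frame(id = sprintf("m%d",
                                           seq_len(ncol(as.matrix(cohort)))),
                                         bp = seq_len(ncol(as.matrix(cohort))),
                                         cM = seq_len(ncol(as.matrix(cohort)))))
  markers <- cohort$markers
  M <- nrow(markers)
  Xc <- if (diploid) cohort$genotypes else cohort$haplotypes
  if (nrow(Xc) == 0) stop("empty cohort")
  S <- n_upper
  if (S < 2) stop("n_upper must be >= 2")
  if (n_lower < S) stop("n_lower must be >= n_upper")
  if (length(training) > S) stop("more training panels than ancestries")

  if (mode == "auto")
    mode <- if (length(training) == 0) "structure"
            else if (length(training) == S) "supervised" else "partial"
  if (mode == "structure" && length(training) > 0)
    stop("structure mode takes no training panels")
  if (mode == "supervised" && length(training) != S)
    stop("supervised mode needs one training panel per ancestry")

  if (length(training)) {
    if (is.null(names(training)) || any(!nzchar(names(training))))
      names(training) <- sprintf("train%d", seq_along(training))
    for (p in training)
      if (!isTRUE(all.equal(p$markers$bp, markers$bp)))
        stop("training and cohort marker grids differ")
  }
  if (is.null(ancestries)) {
    ancestries <- names(training)
    if (length(ancestries) < S)
      ancestries <- c(ancestries,
                      sprintf("anc%d", seq_len(S - length(ancestries))))
  }
  if (length(ancestries) != S) stop("need one ancestry name per upper cluster")
  anchored <- ancestries %in% names(training)

  Xt <- NULL; t_anc <- integer(0)
  if (length(training)) {
    Xt <- do.call(rbind, lapply(training, `[[`, "haplotypes"))
    t_anc <- rep(match(names(training), ancestries),
                 vapply(training, function(p) nrow(p$haplotypes), 0L))
  }
  n_t <- if (is.null(Xt)) 0L else nrow(Xt)
  n_c <- nrow(Xc)
  n_c_haps <- if (diploid) 2L * n_c else n_c
  # the cluster frequencies of anchored ancestries must stay pinned to the
  # training panels, so the cohort contributes at most a tenth of their
  # weight by default; with no training the weight cancels anyway
  if (is.null(w_c)) w_c <- if (n_t > 0) min(0.1, n_t / n_c_haps) else 1
  if (w_t < 0 || w_c < 0 || (w_t == 0 && w_c == 0))
    stop("invalid weights")

  # lower clusters divided as evenly as possible among ancestries
  sizes <- rep(n_lower %/% S, S) + (seq_len(S) <= n_lower %% S)
  anc_of <- rep(seq_len(S), sizes)
  C <- n_lower
  tr <- transition_rates(markers$cM, generations, lambda)

  # per-ancestry training allele frequencies for theta initialization;
  # free ancestries start from the cohort frequencies instead
  f_train <- matrix(NA_real_, M, S)
  for (s in which(anchored))
    f_train[, s] <- colMeans(Xt[t_anc == s, , drop = FALSE], na.rm = TRUE)
  f_cohort <- if (diploid) colMeans(Xc, na.rm = TRUE) / 2
              else colMeans(Xc, na.rm = TRUE)
  f_cohort[is.nan(f_cohort)] <- 0.5

  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, em_runs)

  pin <- function(idx) {  # one-hot admixture rows for pinned training haps
    a <- matrix(0, length(idx), S); a[cbind(seq_along(idx), idx)] <- 1; a
  }
  clamp <- function(x) pmin(pmax(x, theta_floor), 1 - theta_floor)

  X_all <- if (diploid) NULL else rbind(Xt, Xc)
  w_all <- if (diploid) NULL else c(rep(w_t, n_t), rep(w_c, n_c))

  run_dosage <- vector("list", em_runs)
  run_admix <- vector("list", em_runs)
  run_theta <- vector("list", em_runs)
  run_beta <- vector("list", em_runs)
  ll_mat <- matrix(NA_real_, em_steps + 1, em_runs)
  unocc_warned <- FALSE

  for (r in seq_len(em_runs)) {
    set.seed(run_seeds[r])
    # unsupervised ancestries start from a k-means split of the cohort:
    # cluster centers seed their allele frequencies and the (soft) cluster
    # memberships seed the admixture proportions, breaking the label
    # symmetry that a flat start cannot escape
    f_free <- matrix(f_cohort, M, S)
    a_c <- matrix(stats::rexp(n_c * S), n_c, S)
    a_c <- a_c / rowSums(a_c)
    if (!any(anchored) && n_c > S) {
      Ximp <- if (diploid) Xc / 2 else Xc
      if (anyNA(Ximp)) {
        mu <- colMeans(Ximp, na.rm = TRUE)
        idx <- which(is.na(Ximp), arr.ind = TRUE)
        Ximp[idx] <- mu[idx[, 2]]
      }
      km <- tryCatch(stats::kmeans(Ximp, centers = sum(!anchored),
                                   nstart = 2, iter.max = 20),
                     error = function(e) NULL)
      if (!is.null(km)) {
        free_s <- which(!anchored)
        f_free[, free_s] <- t(km$centers)[, seq_along(free_s), drop = FALSE]
        hard <- matrix(0, n_c, S)
        hard[cbind(seq_len(n_c), free_s[km$cluster])] <- 1
        a_c <- 0.7 * hard + 0.3 * a_c
        a_c <- a_c / rowSums(a_c)
      }
    }
    theta <- matrix(0, M, C)
    for (j in seq_len(C)) {
      u <- stats::runif(M, 0.2, 0.8)
      s <- anc_of[j]
      theta[, j] <- if (anchored[s]) {
        clamp(0.7 * f_train[, s] + 0.3 * u)
      } else if (any(anchored)) {
        # partial mode: seed each free cluster from a random cohort
        # haplotype so the learned ancestry starts as sharp and
        # LD-coherent as the training-pinned clusters it competes with
        h <- Xc[sample.int(n_c, 1), ]
        if (diploid) h <- h / 2
        h[is.na(h)] <- f_cohort[is.na(h)]
        clamp(0.7 * h + 0.3 * u)
      } else clamp(0.6 * f_free[, s] + 0.4 * u)
    }
    beta <- rep(1, C)
    a_t <- if (n_t) pin(t_anc) else NULL

    for (it in seq_len(em_steps + 1)) {
      betaN <- beta_normalize(beta, anc_of)
      # --- E-step ---
      if (!diploid) {
        a <- rbind(a_t, a_c)
        es <- fb_haplotypes(X_all, theta, anc_of, betaN, a, tr$ru, tr$rl,
                            w = w_all)
        wll <- sum(w_all * es$loglik)
        thn <- es$thn; thd <- es$thd; occ <- es$occ
        aocc_c <- es$aocc[n_t + seq_len(n_c), , drop = FALSE]
        D_c <- es$D[n_t + seq_len(n_c), , , drop = FALSE]
      } else {
        thn <- matrix(0, M, C); thd <- matrix(0, M, C); occ <- numeric(C)
        wll <- 0
        if (n_t) {
          es_t <- fb_haplotypes(Xt, theta, anc_of, betaN, a_t,
                                tr$ru, tr$rl, w = rep(w_t, n_t))
          wll <- wll + w_t * sum(es_t$loglik)
          thn <- thn + es_t$thn; thd <- thd + es_t$thd
          occ <- occ + es_t$occ
        }
        aocc_c <- matrix(0, n_c, S)
        D_c <- array(0, dim = c(n_c, M, S))
        for (i in seq_len(n_c)) {
          es_i <- fb_diplotype(Xc[i, ], theta, anc_of, betaN, a_c[i, ],
                               tr$ru, tr$rl)
          wll <- wll + w_c * es_i$loglik
          thn <- thn + w_c * es_i$thn
          thd <- thd + w_c * es_i$thd
          occ <- occ + w_c * es_i$occ
          aocc_c[i, ] <- es_i$aocc
          D_c[i, , ] <- es_i$D
        }
      }
      ll_mat[it, r] <- wll
      if (it > em_steps) break
      # --- M-step ---
      t_new <- thn / thd
      bad <- !is.finite(t_new)
      if (any(bad)) {
        if (!unocc_warned) {
          warning("unoccupied cluster-marker cells: previous theta retained")
          unocc_warned <- TRUE
        }
        t_new[bad] <- theta[bad]
      }
      theta <- clamp(t_new)
      beta <- pmax(occ, 1e-6)
      a_c <- aocc_c / rowSums(aocc_c)
      a_c <- pmax(a_c, 1e-8)
      a_c <- a_c / rowSums(a_c)
    }
    run_dosage[[r]] <- D_c
    run_admix[[r]] <- a_c
    run_theta[[r]] <- theta
    run_beta[[r]] <- beta
    if (verbose)
      message(sprintf("run %d/%d: weighted loglik %.2f", r, em_runs,
                      ll_mat[em_steps + 1, r]))
  }

  perms <- align_labels(run_dosage, anchored)
  D_avg <- array(0, dim = dim(run_dosage[[1]]))
  A_avg <- matrix(0, n_c, S)
  for (r in seq_len(em_runs)) {
    D_avg <- D_avg + run_dosage[[r]][, , perms[[r]], drop = FALSE]
    A_avg <- A_avg + run_admix[[r]][, perms[[r]], drop = FALSE]
  }
  D_avg <- D_avg / em_runs
  A_avg <- A_avg / em_runs

  ploidy <- 1L
  if (diploid) ploidy <- 2L
  ind_names <- if (diploid) rownames(Xc) else NULL
  if (!diploid && !is.null(pairing)) {
    if (length(pairing) != n_c) stop("pairing must cover every haplotype")
    D_ind <- array(0, dim = c(length(unique(pairing)), M, S))
    for (s in seq_len(S)) D_ind[, , s] <- rowsum(D_avg[, , s], pairing)
    A_avg <- rowsum(A_avg, pairing) / 2
    D_avg <- D_ind
    ploidy <- 2L
    ind_names <- sprintf("i%04d", seq_len(dim(D_avg)[1]))
  }
  dimnames(D_avg) <- list(
    if (is.null(ind_names)) sprintf("h%04d", seq_len(dim(D_avg)[1]))
    else ind_names,
    markers$id, ancestries)
  rownames(A_avg) <- dimnames(D_avg)[[1]]
  colnames(A_avg) <- ancestries

  best <- which.max(ll_mat[em_steps + 1, ])
  structure(list(
    dosages = D_avg, admix = A_avg,
    theta = run_theta[[best]], beta = run_beta[[best]],
    cluster_ancestry = anc_of, ancestries = ancestries,
    anchored = anchored, mode = mode, ploidy = ploidy,
    loglik = ll_mat, permutations = perms, best_run = best,
    weights = c(w_t = w_t, w_c = w_c),
    markers = markers,
    config = list(n_upper = S, n_lower = n_lower,
                  generations = generations, em_steps = em_steps,
                  em_runs = em_runs, lambda = lambda,
                  theta_floor = theta_floor, seed = seed),
    call = match.call()), class = "two_layer_fit")
}

#' @export
print.two_layer_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "two_layer_fit (%s mode): %d x %d clusters, g = %d\n",
    "%d individuals x %d markers; %d EM runs x %d steps; ",
    "w_t = %g, w_c = %.3g\n"),
    x$mode, cfg$n_upper, cfg$n_lower, cfg$generations,
    dim(x$dosages)[1], dim(x$dosages)[2], cfg$em_runs, cfg$em_steps,
    x$weights["w_t"], x$weights["w_c"]))
  cat("mean admixture proportions:\n")
  print(round(colMeans(x$admix), 4))
  invisible(x)
}

#' @export
summary.two_layer_fit <- function(object, ...) {
  avg <- apply(object$dosages, c(2, 3), mean)
  out <- list(fit = object, mean_admix = colMeans(object$admix),
              avg_dosage_range = apply(avg, 2, range),
              final_loglik = object$loglik[nrow(object$loglik), ])
  class(out) <- "summary.two_layer_fit"
  out
}

#' @export
print.summary.two_layer_fit <- function(x, ...) {
  print(x$fit)
  cat("\naverage-dosage range per ancestry:\n")
  print(round(x$avg_dosage_range, 4))
  cat(sprintf("\nfinal weighted log-likelihood: best %.2f (run %d)\n",
              max(x$final_loglik), which.max(x$final_loglik)))
  invisible(x)
}

#' @describeIn two_layer_fit per-individual admixture proportions.
#' @param object,x a `two_layer_fit`.
#' @param ... unused.
#' @export
coef.two_layer_fit <- function(object, ...) object$admix

#' @describeIn two_layer_fit the run-averaged ancestry-dosage array
#'   (individuals x markers x ancestries).
#' @export
fitted.two_layer_fit <- function(object, ...) object$dosages

#' @export
logLik.two_layer_fit <- function(object, ...) {
  ll <- max(object$loglik[nrow(object$loglik), ])
  attr(ll, "df") <- length(object$theta) + length(object$beta)
  class(ll) <- "logLik"
  ll
}

#' @describeIn two_layer_fit plot per-marker average dosages along the map.
#' @param ancestry ancestries to draw (default all).
#' @export
plot.two_layer_fit <- function(x, ancestry = NULL, ...) {
  avg <- apply(x$dosages, c(2, 3), mean)
  if (is.null(ancestry)) ancestry <- x$ancestries
  cols <- seq_along(ancestry)
  graphics::matplot(x$markers$bp / 1e6, avg[, ancestry, drop = FALSE],
                    type = "l", lty = 1, col = cols,
                    xlab = "position (Mb)",
                    ylab = sprintf("average ancestry dosage [0,%d]",
                                   x$ploidy), ...)
  graphics::legend("topleft", legend = ancestry, col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}
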