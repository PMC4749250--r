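#' Per-marker average ancestry dosages, optionally family-aware
#'
#' Averages a dosage field over individuals.  With a family map, each
#' family's members are averaged first and families then averaged with
#' equal weight regardless of size, so large sibships do not dominate.
#'
#' @param dosages individuals x markers x ancestries array (e.g.
#'   [fitted.two_layer_fit()] or [truth_dosages()]).
#' @param families optional family assignment: vector of family ids, one
#'   per individual (named vectors are matched against the array's row
#'   names).  `NULL` treats every individual as its own unit.
#' @return Markers x ancestries matrix of average dosages.
#' @export
average_dosages <- function(dosages, families = NULL) {
  stopifnot(length(dim(dosages)) == 3)
  n <- dim(dosages)[1]
  if (n == 0) stop("empty cohort")
  if (is.null(families))
    return(apply(dosages, c(2, 3), mean))
  if (!is.null(names(families)) && !is.null(dimnames(dosages)[[1]])) {
    ord <- match(dimnames(dosages)[[1]], names(families))
    if (anyNA(ord)) stop("every individual needs a family assignment")
    families <- families[ord]
  }
  if (length(families) != n)
    stop("every individual needs a family assignment")
  fam <- as.character(families)
  M <- dim(dosages)[2]; S <- dim(dosages)[3]
  out <- matrix(0, M, S, dimnames = dimnames(dosages)[2:3])
  fam_size <- as.vector(table(fam))  # rowsum and table both sort by level
  for (s in seq_len(S)) {
    fam_means <- rowsum(dosages[, , s], fam) / fam_size
    out[, s] <- colMeans(fam_means)
  }
  out
}

#' Standardized genome scan of average ancestry dosages
#'
#' Per ancestry, computes the genome-wide mean and sample standard
#' deviation (ssd, denominator n-1) of the per-marker average dosages, the
#' per-marker deviation `z = (avg - mean) / ssd`, and a descriptive
#' one-sided upper-tail normal p-value.  Large |z| marks loci whose local
#' ancestry departs from the genome-wide background — the hallmark of
#' recent selection in an admixed cohort.
#'
#' @param avgs markers x ancestries matrix from [average_dosages()] (or any
#'   per-marker dosage summary); >= 2 markers.
#' @param markers optional marker data frame carried into the result.
#' @param exclude optional marker indices excluded from the mean/ssd
#'   computation (sensitivity analysis); z is still reported everywhere.
#' @return An object of class `ancestry_scan`: `avg`, `mean`, `ssd`, `z`,
#'   `p` (one-sided descriptive), `markers`, `excluded`.
#' @export
zscan <- function(avgs, markers = NULL, exclude = NULL) {
  avgs <- as.matrix(avgs)
  if (nrow(avgs) < 2) stop("need >= 2 markers")
  use <- setdiff(seq_len(nrow(avgs)), exclude)
  mu <- colMeans(avgs[use, , drop = FALSE])
  ssd <- apply(avgs[use, , drop = FALSE], 2, stats::sd)
  z <- sweep(sweep(avgs, 2, mu), 2, ssd, "/")
  degenerate <- ssd == 0
  if (any(degenerate)) {
    warning("ssd = 0 for some ancestry: z undefined there")
    z[, degenerate] <- NA_real_
  }
  structure(list(avg = avgs, mean = mu, ssd = ssd, z = z,
                 p = stats::pnorm(z, lower.tail = FALSE),
                 markers = markers, excluded = exclude),
            class = "ancestry_scan")
}

#' @export
print.ancestry_scan <- function(x, ...) {
  cat(sprintf("ancestry_scan: %d markers x %d ancestries\n",
              nrow(x$avg), ncol(x$avg)))
  tab <- data.frame(mean = x$mean, ssd = x$ssd,
                    max_z = apply(x$z, 2, max, na.rm = TRUE))
  print(round(tab, 4))
  invisible(x)
}

#' @export
plot.ancestry_scan <- function(x, ancestry = 1, ssd_lines = 4, ...) {
  pos <- if (!is.null(x$markers)) x$markers$bp / 1e6
         else seq_len(nrow(x$avg))
  graphics::plot(pos, x$avg[, ancestry], type = "l",
                 xlab = if (!is.null(x$markers)) "position (Mb)"
                        else "marker",
                 ylab = "average dosage", ...)
  a <- if (is.character(ancestry)) ancestry
       else colnames(x$avg)[ancestry]
  graphics::abline(h = x$mean[ancestry], col = "blue")
  graphics::abline(h = x$mean[ancestry] + c(-1, 1) * ssd_lines *
                     x$ssd[ancestry], col = "gray")
  invisible(x)
}

#' Call the selected region from a scan
#'
#' Marker set A: markers whose average dosage for the chosen ancestry
#' exceeds `dosage_threshold` (diploid \[0, 2\] scale).  Also reports
#' whether A is a single contiguous run of markers.
#'
#' @param scan an [zscan()] result, or a markers x ancestries average
#'   dosage matrix.
#' @param ancestry column index or name of the scanned ancestry.
#' @param dosage_threshold dosage cut-off.
#' @return List with `markers` (indices of A), `contiguous`, `range`
#'   (first/last index, or `NULL` if empty), `threshold`, `ancestry`.
#' @export
call_region <- function(scan, ancestry, dosage_threshold) {
  avg <- if (inherits(scan, "ancestry_scan")) scan$avg else as.matrix(scan)
  v <- avg[, ancestry]
  A <- which(v > dosage_threshold)
  list(markers = A,
       contiguous = length(A) <= 1 || all(diff(A) == 1),
       range = if (length(A)) range(A) else NULL,
       threshold = dosage_threshold, ancestry = ancestry)
}

#' Ancestry-dosage phenotype over a called region
#'
#' Assigns each individual the mean of its ancestry dosage over the
#' markers of a called region (marker set A) — a quantitative phenotype
#' for downstream association testing.
#'
#' @param dosages individuals x markers x ancestries array.
#' @param region marker indices (or a [call_region()] result).
#' @param ancestry ancestry index or name.
#' @return Named numeric vector in \[0, 2\], one value per individual.
#' @export
define_phenotype <- function(dosages, region, ancestry) {
  if (is.list(region)) region <- region$markers
  if (!length(region)) stop("empty marker set A")
  rowMeans(dosages[, region, ancestry, drop = FALSE])
}

#' Difference of two average-dosage tracks
#'
#' Elementwise difference (a - b) of one ancestry's per-marker average
#' dosages between two scans on the same marker grid, e.g. to compare
#' runs with different training panels or seeds.
#'
#' @param scan_a,scan_b [zscan()] results or average-dosage matrices on
#'   identical marker grids.
#' @param ancestry ancestry index or name.
#' @return Numeric vector of per-marker differences.
#' @export
dosage_difference <- function(scan_a, scan_b, ancestry = 1) {
  avg_a <- if (inherits(scan_a, "ancestry_scan")) scan_a$avg
           else as.matrix(scan_a)
  avg_b <- if (inherits(scan_b, "ancestry_scan")) scan_b$avg
           else as.matrix(scan_b)
  if (!all(dim(avg_a) == dim(avg_b)))
    stop("marker grids differ between scans")
  ma <- if (inherits(scan_a, "ancestry_scan")) scan_a$markers else NULL
  mb <- if (inherits(scan_b, "ancestry_scan")) scan_b$markers else NULL
  if (!is.null(ma) && !is.null(mb) && !isTRUE(all.equal(ma$bp, mb$bp)))
    stop("marker grids differ between scans")
  avg_a[, ancestry] - avg_b[, ancestry]
}
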