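#' Haplotype panel
#'
#' The universal exchange object of the package: a binary allele matrix
#' (haplotypes in rows, markers in columns) together with marker metadata
#' and, optionally, a population label per haplotype.
#'
#' @param haplotypes integer/numeric matrix of 0/1 alleles (`NA` allowed),
#'   one row per haplotype, one column per marker.
#' @param markers data frame with columns `id`, `bp` (1-based physical
#'   position) and `cM` (genetic map position); positions must be strictly
#'   increasing.
#' @param pop optional character/factor vector of population labels, one per
#'   haplotype.
#'
#' @return An object of class `haplotype_panel` with elements `haplotypes`,
#'   `markers` and `pop`.
#' @seealso [genotype_panel()], [read_panel()], [write_panel()]
#' @export
haplotype_panel <- function(haplotypes, markers, pop = NULL) {
  haplotypes <- as.matrix(haplotypes)
  markers <- validate_markers(markers, ncol(haplotypes))
  vals <- haplotypes[!is.na(haplotypes)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stop("haplotype alleles must be coded 0/1 (NA for missing)")
  if (!is.null(pop)) {
    if (length(pop) != nrow(haplotypes))
      stop("'pop' must have one label per haplotype")
    pop <- as.character(pop)
  }
  structure(list(haplotypes = haplotypes, markers = markers, pop = pop),
            class = "haplotype_panel")
}

#' Genotype panel
#'
#' Unphased diploid counterpart of [haplotype_panel()]: entries are counts
#' of the "1" allele (0, 1, 2), `NA` for missing.  BIMBAM-style mean
#' genotypes (non-integer values in \[0, 2\]) are accepted and stored as-is.
#'
#' @param genotypes numeric matrix, individuals in rows, markers in columns.
#' @inheritParams haplotype_panel
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(genotypes, markers) {
  genotypes <- as.matrix(genotypes)
  markers <- validate_markers(markers, ncol(genotypes))
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 2))
    stop("genotypes must lie in [0, 2] (counts of the '1' allele)")
  structure(list(genotypes = genotypes, markers = markers),
            class = "genotype_panel")
}

validate_markers <- function(markers, n_expected) {
  if (is.null(markers)) stop("'markers' is required")
  markers <- as.data.frame(markers)
  need <- c("id", "bp", "cM")
  if (!all(need %in% names(markers)))
    stop("'markers' needs columns id, bp, cM")
  if (nrow(markers) != n_expected)
    stop(sprintf("marker count (%d) does not match matrix columns (%d)",
                 nrow(markers), n_expected))
  if (nrow(markers) > 1 && any(diff(markers$bp) <= 0))
    stop("marker bp positions must be strictly increasing")
  markers
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d markers (%.3f-%.3f Mb)\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              min(x$markers$bp) / 1e6, max(x$markers$bp) / 1e6))
  if (!is.null(x$pop)) {
    tab <- table(x$pop)
    cat("populations:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d markers\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$haplotypes)

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

#' Collapse haplotypes to genotypes
#'
#' Pairs consecutive rows (or an explicit pairing) of a haplotype panel and
#' sums alleles into unphased genotypes.
#'
#' @param panel a [haplotype_panel()] with an even number of rows.
#' @param pairing optional integer vector assigning each haplotype to a
#'   diplotype (two rows per value); defaults to consecutive pairing.
#' @return A [genotype_panel()].
#' @export
as_genotypes <- function(panel, pairing = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  H <- panel$haplotypes
  if (nrow(H) %% 2 != 0) stop("odd number of haplotypes cannot be paired")
  if (is.null(pairing)) pairing <- rep(seq_len(nrow(H) / 2), each = 2)
  idx <- split(seq_len(nrow(H)), pairing)
  if (any(lengths(idx) != 2)) stop("each diplotype needs exactly 2 haplotypes")
  G <- t(vapply(idx, function(i) H[i[1], ] + H[i[2], ],
                numeric(ncol(H))))
  genotype_panel(G, panel$markers)
}
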