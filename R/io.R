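#' Read a haplotype or genotype panel from disk
#'
#' Two dialects are supported.  `"tsv-matrix"` is the package's native
#' format: a tab-separated matrix with markers in rows and samples in
#' columns (a header line of sample ids, a leading `id` column of marker
#' ids) plus a companion marker file with columns `id`, `bp`, `cM`.
#' `"bimbam"` is the BIMBAM mean-genotype dialect: one row per SNP of
#' `id, allele1, allele0, g1, g2, ...` with genotypes in \[0, 2\]
#' (comma- or whitespace-separated); marker positions then come from
#' `marker_file`.  Lines starting with `#` are ignored in all files.
#'
#' @param path matrix file.
#' @param marker_file companion marker file (`id`, `bp`, `cM`, tab-separated,
#'   header line).
#' @param dialect `"tsv-matrix"` or `"bimbam"`.
#' @param type `"haplotype"` (alleles 0/1) or `"genotype"` (0/1/2); the
#'   bimbam dialect is always genotype.  Missing values are coded `NA`.
#' @return A [haplotype_panel()] or [genotype_panel()].
#' @export
read_panel <- function(path, marker_file,
                       dialect = c("tsv-matrix", "bimbam"),
                       type = c("haplotype", "genotype")) {
  dialect <- match.arg(dialect)
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  markers <- utils::read.table(marker_file, header = TRUE, sep = "\t",
                               comment.char = "#", stringsAsFactors = FALSE)
  if (dialect == "bimbam") {
    lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[,[:space:]]+")
    nf <- lengths(parts)
    if (length(unique(nf)) != 1)
      stop(sprintf("ragged bimbam file: line %d has %d fields, expected %d",
                   which(nf != nf[1])[1], nf[which(nf != nf[1])[1]], nf[1]))
    ids <- vapply(parts, `[`, "", 1L)
    G <- do.call(rbind, lapply(parts, function(p) {
      g <- suppressWarnings(as.numeric(p[-(1:3)]))
      g
    }))
    bad <- which(!is.na(G) & (G < 0 | G > 2), arr.ind = TRUE)
    if (nrow(bad)) stop(sprintf("bimbam genotype out of [0,2] at line %d",
                                bad[1, 1]))
    ord <- match(markers$id, ids)
    if (anyNA(ord)) stop("marker file lists SNPs absent from bimbam file")
    return(genotype_panel(t(G[ord, , drop = FALSE]), markers))
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- tab[[1]]
  M <- as.matrix(tab[, -1, drop = FALSE])
  ord <- match(markers$id, ids)
  if (anyNA(ord)) stop("marker file lists markers absent from matrix file")
  M <- M[ord, , drop = FALSE]
  X <- t(M)  # samples x markers
  ok <- if (type == "haplotype") c(0, 1) else c(0, 1, 2)
  bad <- which(!is.na(X) & !(X %in% ok))
  if (length(bad)) {
    m <- ceiling(bad[1] / nrow(X))
    stop(sprintf("unknown allele code %s at marker row %d", X[bad[1]], m))
  }
  if (type == "haplotype") haplotype_panel(X, markers)
  else genotype_panel(X, markers)
}

#' Write a panel (and companion marker file) to disk
#'
#' Writes the native markers-by-samples tab-separated matrix.  A `stage`
#' string and configuration hash are recorded in `#` header comments.
#'
#' @param panel a [haplotype_panel()] or [genotype_panel()].
#' @param path matrix file to write.
#' @param marker_file companion marker file to write (optional).
#' @param stage producing stage, recorded in the header comment.
#' @param config_hash configuration hash, recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, marker_file = NULL,
                        stage = "manual", config_hash = "") {
  X <- if (inherits(panel, "haplotype_panel")) panel$haplotypes
       else panel$genotypes
  hdr <- sprintf("# admixsel stage=%s config=%s", stage, config_hash)
  ids <- panel$markers$id
  samples <- if (is.null(rownames(X)))
    sprintf("s%d", seq_len(nrow(X))) else rownames(X)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("id", samples), collapse = "\t"), con)
  utils::write.table(data.frame(id = ids, t(X), check.names = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(marker_file)) {
    mcon <- file(marker_file, "w")
    writeLines(hdr, mcon)
    suppressWarnings(utils::write.table(panel$markers, mcon, sep = "\t",
                                        quote = FALSE, row.names = FALSE))
    close(mcon)
  }
  invisible(path)
}

#' Read a family map
#'
#' Two-column tab-separated file (`individual`, `family`), header line
#' optional; returns a named character vector mapping individual to family.
#'
#' @param path file path.
#' @return Named character vector.
#' @export
read_families <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (identical(tolower(tab[1, 1]), "individual")) tab <- tab[-1, ]
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Write a dosage field as a per-marker TSV
#'
#' Marker rows; one column per individual x ancestry combination
#' (`<individual>.<ancestry>`), preceded by the marker id.
#'
#' @param dosages 3-d array individuals x markers x ancestries (see
#'   [fitted.two_layer_fit()]).
#' @param markers marker data frame.
#' @param path file to write.
#' @inheritParams write_panel
#' @return `path`, invisibly.
#' @export
write_dosages <- function(dosages, markers, path,
                          stage = "infer", config_hash = "") {
  stopifnot(length(dim(dosages)) == 3)
  n <- dim(dosages)[1]; M <- dim(dosages)[2]; S <- dim(dosages)[3]
  anc <- dimnames(dosages)[[3]]
  if (is.null(anc)) anc <- sprintf("anc%d", seq_len(S))
  ind <- dimnames(dosages)[[1]]
  if (is.null(ind)) ind <- sprintf("i%d", seq_len(n))
  flat <- matrix(aperm(dosages, c(2, 1, 3)), nrow = M)
  colnames(flat) <- as.vector(outer(ind, anc, paste, sep = "."))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# admixsel stage=%s config=%s", stage, config_hash), con)
  utils::write.table(data.frame(id = markers$id, round(flat, 5),
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# short checksum used to tag output files with the producing configuration
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  h <- 5381
  for (k in v) h <- (h * 33 + k) %% 2^28
  sprintf("%07x", h)
}
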