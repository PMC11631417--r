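#' SNP genotype container
#'
#' A light container for pseudo-diploid SNP array calls: an individuals x
#' markers dosage matrix with entries in `{0, 1, 2, NA}` (count of the
#' alternate allele) plus a marker map (`marker`, `chrom`, `pos`, `ref`,
#' `alt`). Octoploid array calls collapse to these three genotype classes,
#' which is the level at which all statistics here operate.
#'
#' @param geno numeric/integer matrix, rows = individuals (rownames = IDs),
#'   columns = markers (colnames = marker IDs).
#' @param map optional data.frame with columns `marker`, `chrom`, `pos`,
#'   `ref`, `alt`; a default single-chromosome map is created if omitted.
#' @return an object of class `snp_geno`.
#' @export
snp_geno <- function(geno, map = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("mk", seq_len(ncol(geno)))
  bad <- !(geno %in% c(0, 1, 2) | is.na(geno))
  if (any(bad)) stop("dosage calls must be 0, 1, 2 or NA")
  if (is.null(map)) {
    map <- data.frame(marker = colnames(geno), chrom = "chr1",
                      pos = seq_len(ncol(geno)), ref = "A", alt = "B",
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(map$marker)) stop("marker IDs must be unique")
  if (any(map$pos < 0)) stop("marker positions must be non-negative")
  if (!identical(as.character(map$marker), colnames(geno)))
    stop("map markers must match genotype columns in order")
  structure(list(geno = geno, map = map), class = "snp_geno")
}

#' Extract the dosage matrix
#'
#' Accepts either a [snp_geno] object or a bare dosage matrix, so metric
#' functions can be called on both.
#'
#' @param x a `snp_geno` or matrix.
#' @return individuals x markers numeric matrix.
#' @export
dosage_matrix <- function(x) {
  if (inherits(x, "snp_geno")) return(x$geno)
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(as.matrix(x))
  stop("cannot interpret input as a dosage matrix")
}

marker_map <- function(x) {
  if (inherits(x, "snp_geno")) return(x$map)
  g <- dosage_matrix(x)
  data.frame(marker = colnames(g), chrom = "chr1", pos = seq_len(ncol(g)),
             ref = "A", alt = "B", stringsAsFactors = FALSE)
}

#' @export
print.snp_geno <- function(x, ...) {
  cat("snp_geno:", nrow(x$geno), "individuals x", ncol(x$geno), "markers;",
      sum(is.na(x$geno)), "missing calls\n")
  invisible(x)
}

#' @export
dim.snp_geno <- function(x) dim(x$geno)

#' Subset a snp_geno
#'
#' @param x a `snp_geno`.
#' @param i individual index (rows).
#' @param j marker index (columns).
#' @param ... unused.
#' @return a `snp_geno` restricted to the selected individuals/markers.
#' @export
`[.snp_geno` <- function(x, i, j, ...) {
  g <- x$geno
  m <- x$map
  if (!missing(j)) {
    jj <- seq_len(ncol(g))
    names(jj) <- colnames(g)
    j_idx <- if (is.character(j)) unname(jj[j]) else jj[j]
    g <- g[, j_idx, drop = FALSE]
    m <- m[j_idx, , drop = FALSE]
  }
  if (!missing(i)) g <- g[i, , drop = FALSE]
  snp_geno(g, m)
}

#' Per-marker alternate allele frequency
#'
#' Frequencies computed from nonmissing calls; markers with no calls give NA.
#'
#' @param x genotypes ([snp_geno] or dosage matrix).
#' @return numeric vector of allele frequencies, one per marker.
#' @export
allele_freq <- function(x) {
  g <- dosage_matrix(x)
  colMeans(g, na.rm = TRUE) / 2
}
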