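# Plain-text interchange: CSV dosage matrices, simple biallelic VCF with GT
# calls, pedigree and phenotype CSVs.

#' Write a dosage matrix as CSV
#'
#' Rows are individuals, columns marker IDs, values 0/1/2 with empty cells
#' for missing.
#'
#' @param geno genotypes ([snp_geno] or dosage matrix).
#' @param path output path.
#' @export
write_dosage_csv <- function(geno, path) {
  g <- dosage_matrix(geno)
  df <- data.frame(individual = rownames(g), g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a dosage matrix from CSV
#'
#' @param path CSV written by [write_dosage_csv()] (first column
#'   `individual`).
#' @param map optional marker map.
#' @return a [snp_geno].
#' @export
read_dosage_csv <- function(path, map = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- df[[1]]
  snp_geno(g, map)
}

#' Write genotypes as a biallelic VCF
#'
#' Pseudo-diploid GT field: dosage 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`,
#' missing -> `./.`; positions are 1-based from the marker map.
#'
#' @param geno a [snp_geno].
#' @param path output path (plain text).
#' @export
write_vcf <- function(geno, path) {
  g <- dosage_matrix(geno)
  map <- marker_map(geno)
  gt <- matrix("./.", nrow = ncol(g), ncol = nrow(g))
  codes <- c("0/0", "0/1", "1/1")
  for (k in 0:2) gt[t(g) == k] <- codes[k + 1]
  header <- c("##fileformat=VCFv4.2",
              "##source=hetsim",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  body <- paste(map$chrom, map$pos, map$marker, map$ref, map$alt, ".", "PASS",
                ".", "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a biallelic VCF into a snp_geno
#'
#' Uses vcfR; GT is mapped to alternate-allele dosage, `./.` to missing.
#'
#' @param path VCF path.
#' @return a [snp_geno].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  g <- t(dose)
  rownames(g) <- colnames(gt)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  map <- data.frame(marker = fix$ID, chrom = fix$CHROM,
                    pos = as.numeric(fix$POS), ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  colnames(g) <- map$marker
  snp_geno(g, map)
}

#' Write / read the pedigree-truth table
#'
#' Columns: `id`, `parent1`, `parent2`, `group`.
#'
#' @param pedigree pedigree data.frame.
#' @param path CSV path.
#' @export
write_pedigree_csv <- function(pedigree, path) {
  write.csv(pedigree, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Write / read long-format phenotype records
#'
#' Columns: `individual`, `block`, `year`, `harvest`, `trait`, `value`.
#'
#' @param records phenotype data.frame.
#' @param path CSV path.
#' @export
write_phenotypes_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
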