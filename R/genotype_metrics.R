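# Per-individual and population genotype summaries: QC filters,
# heterozygosity, inbreeding, effective population size, PCA, segregation
# tests.

#' Filter markers and samples
#'
#' Samples below the call-rate threshold are dropped first; then markers
#' failing the minor-allele-frequency or missingness thresholds are dropped.
#'
#' @param geno genotypes ([snp_geno] or dosage matrix).
#' @param maf_min minimum minor allele frequency (markers with MAF strictly
#'   below are removed).
#' @param max_missing maximum marker missing-call fraction.
#' @param min_call_rate minimum per-sample call rate.
#' @return the filtered object with attribute `qc_report` (counts dropped
#'   per rule).
#' @export
filter_markers_and_samples <- function(geno, maf_min = 0.05,
                                       max_missing = 0.10,
                                       min_call_rate = 0.90) {
  for (v in c(maf_min, max_missing, min_call_rate))
    if (v < 0 || v > 1) stop("thresholds must be in [0, 1]")
  g <- dosage_matrix(geno)
  call_rate <- rowMeans(!is.na(g))
  keep_s <- call_rate >= min_call_rate
  g2 <- g[keep_s, , drop = FALSE]
  p <- colMeans(g2, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  miss <- colMeans(is.na(g2))
  fail_maf <- maf < maf_min
  fail_miss <- miss > max_missing
  keep_m <- !(fail_maf | fail_miss)
  if (sum(keep_s) == 0 || sum(keep_m) == 0)
    stop("no samples or markers survive QC filtering")
  report <- data.frame(
    rule = c("sample_call_rate", "marker_maf", "marker_missing"),
    dropped = c(sum(!keep_s), sum(fail_maf), sum(fail_miss & !fail_maf)),
    threshold = c(min_call_rate, maf_min, max_missing))
  out <- if (inherits(geno, "snp_geno")) {
    snp_geno(g2[, keep_m, drop = FALSE], geno$map[keep_m, , drop = FALSE])
  } else {
    g2[, keep_m, drop = FALSE]
  }
  attr(out, "qc_report") <- report
  out
}

#' Observed heterozygosity per individual
#'
#' `Ho_i = n_het_i / n_nonmissing_i`: the fraction of an individual's
#' nonmissing calls that are heterozygous.
#'
#' @param geno genotypes ([snp_geno] or dosage matrix).
#' @return named numeric vector; individuals with no nonmissing calls get
#'   `NA` with a warning.
#' @export
observed_heterozygosity <- function(geno) {
  g <- dosage_matrix(geno)
  n_call <- rowSums(!is.na(g))
  ho <- rowSums(g == 1, na.rm = TRUE) / n_call
  if (any(n_call == 0)) {
    warning("individual(s) with all calls missing: Ho undefined")
    ho[n_call == 0] <- NA_real_
  }
  ho
}

#' Population expected heterozygosity
#'
#' Mean over markers of `2 p q` computed from panel allele frequencies.
#'
#' @param geno genotypes.
#' @return scalar expected heterozygosity.
#' @export
expected_heterozygosity <- function(geno) {
  p <- allele_freq(geno)
  mean(2 * p * (1 - p), na.rm = TRUE)
}

#' Per-individual inbreeding coefficient
#'
#' Two estimators: `one_minus_H` (`F = 1 - Ho`, the direct array-call
#' measure for a clonal hybrid) and `excess_homozygosity`
#' (`F = (O_hom - E_hom) / (m - E_hom)`, the excess of observed homozygous
#' calls over the Hardy-Weinberg expectation `E_hom = sum(1 - 2 p_j q_j)`
#' over that individual's nonmissing markers).
#'
#' @param geno genotypes.
#' @param method "one_minus_H" (default) or "excess_homozygosity".
#' @return named numeric vector of F per individual; individuals with
#'   non-positive denominator are flagged `NA` with a warning.
#' @export
inbreeding_coefficient <- function(geno,
                                   method = c("one_minus_H",
                                              "excess_homozygosity")) {
  method <- match.arg(method)
  g <- dosage_matrix(geno)
  if (method == "one_minus_H")
    return(1 - observed_heterozygosity(geno))
  if (nrow(g) < 2)
    stop("excess_homozygosity requires >= 2 individuals for allele frequencies")
  p <- allele_freq(g)
  e_hom_m <- 1 - 2 * p * (1 - p)   # per-marker expected homozygosity
  nonmiss <- !is.na(g)
  o_hom <- rowSums(g != 1 & nonmiss, na.rm = TRUE)
  e_hom <- as.vector(nonmiss %*% ifelse(is.na(e_hom_m), 0, e_hom_m))
  m_i <- rowSums(nonmiss)
  denom <- m_i - e_hom
  f <- (o_hom - e_hom) / denom
  bad <- denom <= 0
  if (any(bad)) {
    warning("non-positive denominator for some individuals; F set to NA")
    f[bad] <- NA_real_
  }
  f
}

#' Effective population size from heterozygosity decay
#'
#' `Ne = -1 / (2 * ln(H1 / H0))`, inferred from one generation of observed
#' heterozygosity change (parents `H0` to progeny `H1`).
#'
#' @param H0,H1 parent- and progeny-generation heterozygosities (> 0).
#' @return Ne; `Inf` with a warning when `H1 >= H0` (no decay).
#' @export
effective_population_size <- function(H0, H1) {
  if (H0 <= 0 || H1 <= 0) stop("H0 and H1 must be positive")
  if (H1 >= H0) {
    warning("H1 >= H0: no heterozygosity decay, Ne is not finite")
    return(Inf)
  }
  -1 / (2 * log(H1 / H0))
}

#' Diversity summary
#'
#' Bundles the per-individual and population diversity metrics.
#'
#' @param geno genotypes.
#' @return list with `ho` (per-individual observed heterozygosity), `f_1mh`
#'   and `f_excess` (the two inbreeding estimators), and `exp_het`
#'   (population expected heterozygosity).
#' @export
diversity_summary <- function(geno) {
  list(ho = observed_heterozygosity(geno),
       f_1mh = inbreeding_coefficient(geno, "one_minus_H"),
       f_excess = inbreeding_coefficient(geno, "excess_homozygosity"),
       exp_het = expected_heterozygosity(geno))
}

#' PCA of the centered dosage matrix
#'
#' Missing calls are mean-imputed per marker; scores use a deterministic
#' sign convention (the largest-magnitude loading of each component is
#' positive).
#'
#' @param geno genotypes.
#' @param n_components number of principal components to return.
#' @return list with `scores` (individuals x components), `var_explained`
#'   (fractions), and `loadings`.
#' @export
pca_scores <- function(geno, n_components = 2) {
  g <- dosage_matrix(geno)
  if (n_components > nrow(g))
    stop("fewer individuals than requested components")
  g <- impute_marker_means(g)
  pc <- prcomp(g, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sign(load[which.max(abs(load[, j])), j])
    if (s < 0) {
      scores[, j] <- -scores[, j]
      load[, j] <- -load[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, var_explained = ve[seq_len(k)], loadings = load)
}

impute_marker_means <- function(g) {
  if (!anyNA(g)) return(g)
  cm <- colMeans(g, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  nas <- which(is.na(g), arr.ind = TRUE)
  g[nas] <- cm[nas[, 2]]
  g
}

#' Pearson chi-square segregation test
#'
#' Tests observed genotype-class counts against an expected ratio (e.g.
#' `c(3, 1)` or `c(1, 1)` for single-locus F2/backcross segregation).
#'
#' @param observed_counts non-negative counts.
#' @param expected_ratio positive expected ratio of the same length.
#' @return list with `chisq`, `df`, `p_value`.
#' @export
segregation_test <- function(observed_counts, expected_ratio) {
  if (any(observed_counts < 0)) stop("counts must be >= 0")
  if (any(expected_ratio <= 0)) stop("expected ratio must be positive")
  if (length(observed_counts) != length(expected_ratio))
    stop("counts and ratio must have the same length")
  n <- sum(observed_counts)
  if (n == 0) stop("zero total count")
  p <- expected_ratio / sum(expected_ratio)
  expd <- n * p
  chisq <- sum((observed_counts - expd)^2 / expd)
  df <- length(observed_counts) - 1
  list(chisq = chisq, df = df,
       p_value = pchisq(chisq, df, lower.tail = FALSE))
}
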