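# Marker-derived relationship matrices: additive (VanRaden method 1) and
# classical dominance parameterization. Allele frequencies come from the
# analyzed panel itself; missing calls are mean-imputed per marker.

#' Additive genomic relationship matrix
#'
#' VanRaden method 1: dosages centered by `2 p_j`, `K = W W' / (2 sum p_j
#' q_j)` over polymorphic markers.
#'
#' @param geno genotypes ([snp_geno] or dosage matrix).
#' @return symmetric matrix keyed by individual IDs, with attributes
#'   `kind = "additive"` and `scaling` (the denominator used).
#' @export
additive_grm <- function(geno) {
  g <- dosage_matrix(geno)
  if (nrow(g) < 2) stop("need >= 2 individuals")
  g <- impute_marker_means(g)
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic: additive GRM undefined")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  w <- sweep(g, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  k <- tcrossprod(w) / denom
  structure(k, kind = "additive", scaling = denom)
}

#' Dominance relationship matrix
#'
#' Classical parameterization: per-marker dominance covariate `-2 q_j^2`,
#' `2 p_j q_j`, `-2 p_j^2` for dosages 0, 1, 2; `K_D = D D' / sum (2 p_j
#' q_j)^2`.
#'
#' @param geno genotypes.
#' @return symmetric matrix with attributes `kind = "dominance"` and
#'   `scaling`.
#' @export
dominance_grm <- function(geno) {
  g <- dosage_matrix(geno)
  if (nrow(g) < 1) stop("empty panel")
  if (!any(g == 1, na.rm = TRUE))
    stop("fully homozygous panel: no heterozygous calls, dominance GRM undefined")
  g <- impute_marker_means(g)
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  if (!any(poly))
    stop("fully homozygous panel: dominance GRM undefined (zero denominator)")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  q <- 1 - p
  # covariate = het indicator mapped onto {-2q^2, 2pq, -2p^2}
  d0 <- matrix(-2 * q^2, nrow = nrow(g), ncol = length(p), byrow = TRUE)
  d1 <- matrix(2 * p * q, nrow = nrow(g), ncol = length(p), byrow = TRUE)
  d2 <- matrix(-2 * p^2, nrow = nrow(g), ncol = length(p), byrow = TRUE)
  dd <- d0
  # fractional imputed dosages: interpolate between the three states
  het_w <- 1 - abs(g - 1)           # weight on the heterozygous covariate
  hi_w <- pmax(g - 1, 0)            # weight on dosage-2 covariate
  lo_w <- pmax(1 - g, 0)            # weight on dosage-0 covariate
  dd <- lo_w * d0 + het_w * d1 + hi_w * d2
  denom <- sum((2 * p * q)^2)
  k <- tcrossprod(dd) / denom
  dimnames(k) <- list(rownames(g), rownames(g))
  structure(k, kind = "dominance", scaling = denom)
}
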