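# Directional dominance: kernel mixed models with a homozygosity covariate
# (the inbreeding-depression regression), nested degree comparison, and a
# kinship-corrected additive marker scan.

#' Fit the homozygosity-covariate kernel model
#'
#' `y = mu + beta_Ho * Ho (+ beta_Ho2 * Ho^2) + a + d + e` with
#' `a ~ N(0, K_A sigma2_A)`, `d ~ N(0, K_D sigma2_D)`, residual diagonal,
#' fitted by kernel REML. `Ho` is individual homozygosity (1 - observed
#' heterozygosity); it is centered before fitting, so `beta_Ho` is the
#' inbreeding-depression slope at the population mean homozygosity — a
#' negative slope for a trait with directional (favorable-dominant)
#' architecture.
#'
#' @param y named response per individual (trait EMM, BPH, or MPH).
#' @param Ho homozygosity per individual (same order as `y`).
#' @param K_A,K_D additive and dominance kernels keyed by the same IDs as
#'   `y` (when `y` is named) or in the same order.
#' @param degree 1 (linear Ho) or 2 (adds Ho squared).
#' @return object of class `hod_fit`: the [reml_kernels()] fit plus
#'   `degree`, `beta_Ho`, `beta_Ho_se`, `beta_Ho_p`, `Ho_center`.
#' @export
fit_hod_model <- function(y, Ho, K_A, K_D = NULL, degree = 1) {
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2")
  if (length(Ho) != length(y)) stop("y and Ho must align")
  if (!is.null(names(y)) && !is.null(rownames(K_A))) {
    ids <- names(y)
    K_A <- K_A[ids, ids]
    if (!is.null(K_D)) K_D <- K_D[ids, ids]
  }
  ok <- !is.na(y) & !is.na(Ho)
  y <- y[ok]
  Ho <- Ho[ok]
  K_A <- K_A[ok, ok]
  if (!is.null(K_D)) K_D <- K_D[ok, ok]
  const_ho <- sd(Ho) == 0
  if (const_ho) {
    warning("constant homozygosity: covariate dropped")
    X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    hc <- Ho - mean(Ho)
    X <- if (degree == 1) cbind("(Intercept)" = 1, Ho = hc)
         else cbind("(Intercept)" = 1, Ho = hc, Ho2 = hc^2)
  }
  kernels <- list(A = K_A)
  if (!is.null(K_D)) kernels$D <- K_D
  fit <- reml_kernels(y, X, kernels)
  fit$degree <- degree
  fit$Ho_center <- if (const_ho) NA_real_ else mean(Ho)
  if (!const_ho) {
    fit$beta_Ho <- fit$beta[["Ho"]]
    fit$beta_Ho_se <- fit$beta_se[[which(colnames(X) == "Ho")]]
    fit$beta_Ho_p <- 2 * pnorm(-abs(fit$beta_Ho / fit$beta_Ho_se))
  } else {
    fit$beta_Ho <- NA_real_
    fit$beta_Ho_se <- NA_real_
    fit$beta_Ho_p <- NA_real_
  }
  fit$Ho <- Ho
  fit$kernels_store <- kernels
  class(fit) <- c("hod_fit", class(fit))
  fit
}

#' Compare degree-1 and degree-2 homozygosity models
#'
#' Nested fixed-effect comparison: the variance structure is re-fit under
#' maximum likelihood (REML likelihoods are not comparable across fixed
#' effects) and the Ho-squared term is tested by a 1-df likelihood-ratio
#' test. Both ML and REML log-likelihoods are reported.
#'
#' @param fit1,fit2 degree-1 and degree-2 [fit_hod_model()] fits on the
#'   same data.
#' @return list: `lrt`, `df`, `p_value`, `loglik_ml` (both models),
#'   `loglik_reml` (both models).
#' @export
compare_degree <- function(fit1, fit2) {
  if (fit1$degree != 1 || fit2$degree != 2)
    stop("pass the degree-1 fit first and the degree-2 fit second")
  if (length(fit1$y) != length(fit2$y) ||
      any(abs(fit1$y - fit2$y) > 1e-12))
    stop("fits are not on the same data")
  k1 <- fit1$kernels_store
  k2 <- fit2$kernels_store
  if (is.null(k1) || is.null(k2))
    stop("fits must come from fit_hod_model()")
  m1 <- ml_kernels(fit1$y, fit1$X, k1)
  m2 <- ml_kernels(fit2$y, fit2$X, k2)
  lrt <- max(0, 2 * (m2$loglik - m1$loglik))
  list(lrt = lrt, df = 1,
       p_value = pchisq(lrt, 1, lower.tail = FALSE),
       loglik_ml = c(degree1 = m1$loglik, degree2 = m2$loglik),
       loglik_reml = c(degree1 = fit1$loglik, degree2 = fit2$loglik))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kinship-corrected additive marker scan
#'
#' Association scan of per-individual responses (typically EMMs) on marker
#' dosages under a mixed model with the additive kernel. Variance
#' components are estimated once on the null (no-marker) model and reused
#' for every marker (the population-parameters-previously-determined
#' approximation); `exact = TRUE` refits REML per marker. Missing dosages
#' are mean-imputed; monomorphic markers are skipped.
#'
#' @param y named response per individual.
#' @param geno genotypes covering those individuals.
#' @param K_A additive kernel (computed from `geno` if omitted).
#' @param threshold genome-wide significance threshold (default 5e-8).
#' @param exact per-marker REML refits instead of the null-model
#'   approximation.
#' @return data.frame of class `scan_result`: `marker`, `chrom`, `pos`,
#'   `effect`, `se`, `p`, `sig`, with attribute `threshold`.
#' @export
marker_scan <- function(y, geno, K_A = NULL, threshold = 5e-8,
                        exact = FALSE) {
  g <- dosage_matrix(geno)
  map <- marker_map(geno)
  ids <- names(y)
  if (!is.null(ids)) g <- g[ids, , drop = FALSE]
  if (nrow(g) != length(y)) stop("genotypes do not cover the response")
  if (is.null(K_A)) K_A <- additive_grm(g)
  if (!is.null(ids) && !is.null(rownames(K_A))) K_A <- K_A[ids, ids]
  g <- impute_marker_means(g)
  p <- colMeans(g) / 2
  poly <- p > 1e-6 & p < 1 - 1e-6
  n <- length(y)
  null_fit <- reml_kernels(y, kernels = list(A = K_A))
  effect <- se <- pval <- rep(NA_real_, ncol(g))
  if (exact) {
    for (j in which(poly)) {
      X <- cbind(1, g[, j])
      f <- reml_kernels(y, X, kernels = list(A = K_A))
      effect[j] <- f$beta[2]
      se[j] <- f$beta_se[2]
      pval[j] <- 2 * pnorm(-abs(effect[j] / se[j]))
    }
  } else {
    eg <- eigen(K_A, symmetric = TRUE)
    w <- 1 / (null_fit$sigma2[["A"]] * pmax(eg$values, 0) +
                null_fit$sigma2[["residual"]])
    Ut <- t(eg$vectors)
    ys <- drop(Ut %*% y)
    ones <- drop(Ut %*% rep(1, n))
    Gs <- Ut %*% g[, poly, drop = FALSE]
    # GLS with intercept, vectorized over markers: residualize the marker
    # column and the response on the rotated intercept under the weights
    onesc2 <- sum(w * ones * ones)
    a_y <- sum(w * ones * ys) / onesc2
    yr <- ys - a_y * ones
    a_x <- colSums(w * ones * Gs) / onesc2
    Xr <- Gs - outer(ones, a_x)
    sxx <- colSums(w * Xr * Xr)
    sxy <- colSums(w * Xr * yr)
    b <- sxy / sxx
    vb <- 1 / sxx
    effect[poly] <- b
    se[poly] <- sqrt(vb)
    pval[poly] <- 2 * pnorm(-abs(b / sqrt(vb)))
  }
  out <- data.frame(marker = map$marker, chrom = map$chrom, pos = map$pos,
                    effect = effect, se = se, p = pval,
                    sig = !is.na(pval) & pval < threshold,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "null_sigma2") <- null_fit$sigma2
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Compare scan effect magnitudes between two populations
#'
#' Pairs two scans on the same marker panel (intersected with a warning if
#' they differ) and summarizes whether the full scan (e.g. with exotic
#' hybrids included) yields larger absolute additive effects, via a sign
#' test on the per-marker |effect| differences.
#'
#' @param scan_full,scan_subset `scan_result`s (e.g. all hybrids vs the
#'   elite-only subset).
#' @return list: `table` (marker, |effect| in each scan, difference),
#'   `prop_larger` (fraction of markers with larger magnitude in the full
#'   scan), `p_value` (two-sided sign test).
#' @export
effect_comparison <- function(scan_full, scan_subset) {
  common <- intersect(scan_full$marker, scan_subset$marker)
  if (length(common) < max(nrow(scan_full), nrow(scan_subset)))
    warning("marker sets differ; intersecting")
  a <- scan_full[match(common, scan_full$marker), ]
  b <- scan_subset[match(common, scan_subset$marker), ]
  diff <- abs(a$effect) - abs(b$effect)
  ok <- !is.na(diff) & diff != 0
  n_pos <- sum(diff[ok] > 0)
  tab <- data.frame(marker = common, abs_full = abs(a$effect),
                    abs_subset = abs(b$effect), diff = diff,
                    stringsAsFactors = FALSE)
  if (sum(ok) == 0) {
    # identical scans: no informative markers to compare
    return(list(table = tab, prop_larger = NA_real_, p_value = 1))
  }
  test <- binom.test(n_pos, sum(ok))
  list(table = tab, prop_larger = n_pos / sum(ok), p_value = test$p.value)
}
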