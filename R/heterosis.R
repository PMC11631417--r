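# Mid-, best-, and worst-parent heterosis: contrasts on genotype EMMs with
# Wald standard errors, significance classification, and trait-on-
# heterozygosity regressions.

#' Identify best and worst parent
#'
#' For an elite x elite cross the parent with the greater EMM is best; for
#' an elite x exotic cross the elite parent is best by definition (the
#' exotic parent is screened as a donor), regardless of the means. Ties in
#' elite x elite crosses break deterministically by ID order and are
#' flagged.
#'
#' @param emm_p1,emm_p2 parent EMMs (may be `NA`).
#' @param cross_class "elite_x_elite" or "elite_x_exotic".
#' @param id_p1,id_p2 parent IDs (used for tie-breaking and bookkeeping).
#' @param elite_parent for elite x exotic crosses, which of the two parents
#'   is elite ("p1" or "p2").
#' @return list: `best`, `worst` (EMMs, possibly `NA`), `best_id`,
#'   `worst_id`, `tie` flag.
#' @export
best_parent <- function(emm_p1, emm_p2,
                        cross_class = c("elite_x_elite", "elite_x_exotic"),
                        id_p1 = "P1", id_p2 = "P2", elite_parent = "p1") {
  cross_class <- match.arg(cross_class)
  if (cross_class == "elite_x_exotic") {
    if (elite_parent == "p1") {
      if (is.na(emm_p1)) stop("elite parent EMM required for elite x exotic")
      return(list(best = emm_p1, worst = emm_p2, best_id = id_p1,
                  worst_id = id_p2, tie = FALSE))
    }
    if (is.na(emm_p2)) stop("elite parent EMM required for elite x exotic")
    return(list(best = emm_p2, worst = emm_p1, best_id = id_p2,
                worst_id = id_p1, tie = FALSE))
  }
  if (is.na(emm_p1) || is.na(emm_p2))
    stop("both parent EMMs required for elite x elite best-parent rule")
  tie <- emm_p1 == emm_p2
  if (emm_p1 > emm_p2 || (tie && id_p1 <= id_p2)) {
    list(best = emm_p1, worst = emm_p2, best_id = id_p1, worst_id = id_p2,
         tie = tie)
  } else {
    list(best = emm_p2, worst = emm_p1, best_id = id_p2, worst_id = id_p1,
         tie = tie)
  }
}

#' Heterosis contrasts for every hybrid
#'
#' Mid-parent heterosis `MPH = emm_F1 - (emm_P1 + emm_P2)/2` (only when both
#' parent EMMs exist), best-parent heterosis `BPH = emm_F1 - emm_BP`, and
#' the worst-parent contrast `emm_F1 - emm_WP`, with Wald standard errors
#' from the EMM sampling covariance (off-diagonal covariances used when the
#' EMM table carries them; independence otherwise).
#'
#' @param emms an [estimate_emms()] table covering hybrids and parents.
#' @param pedigree data.frame: `hybrid`, `parent1`, `parent2`,
#'   `cross_class` ("elite_x_elite"/"elite_x_exotic"); for elite x exotic
#'   rows `parent1` must be the elite parent.
#' @return data.frame of class `heterosis_table`: one row per hybrid with
#'   contrasts, percent ratios, SEs and p-values (normal Wald tests).
#' @export
heterosis_contrasts <- function(emms, pedigree) {
  V <- attr(emms, "vcov")
  get_emm <- function(id) {
    i <- match(id, emms$individual)
    if (is.na(i)) NA_real_ else emms$emmean[i]
  }
  cvar <- function(w) {
    # variance of sum(w * emm) over the named weight vector w
    ids <- names(w)
    if (!is.null(V) && all(ids %in% rownames(V))) {
      drop(t(w) %*% V[ids, ids] %*% w)
    } else {
      se <- emms$se[match(ids, emms$individual)]
      sum(w^2 * se^2)
    }
  }
  rows <- lapply(seq_len(nrow(pedigree)), function(k) {
    hy <- as.character(pedigree$hybrid[k])
    p1 <- as.character(pedigree$parent1[k])
    p2 <- as.character(pedigree$parent2[k])
    cls <- as.character(pedigree$cross_class[k])
    e_f1 <- get_emm(hy)
    if (is.na(e_f1)) return(NULL)
    e_p1 <- get_emm(p1)
    e_p2 <- get_emm(p2)
    out <- data.frame(hybrid = hy, parent1 = p1, parent2 = p2,
                      cross_class = cls, emm_f1 = e_f1,
                      emm_p1 = e_p1, emm_p2 = e_p2,
                      mph = NA_real_, mph_se = NA_real_, mph_pct = NA_real_,
                      mph_p = NA_real_,
                      bph = NA_real_, bph_se = NA_real_, bph_pct = NA_real_,
                      bph_p = NA_real_, best_id = NA_character_,
                      wph = NA_real_, wph_se = NA_real_, wph_p = NA_real_,
                      worst_id = NA_character_, tie = FALSE,
                      stringsAsFactors = FALSE)
    if (!is.na(e_p1) && !is.na(e_p2)) {
      w <- setNames(c(1, -0.5, -0.5), c(hy, p1, p2))
      mp <- (e_p1 + e_p2) / 2
      out$mph <- e_f1 - mp
      out$mph_se <- sqrt(cvar(w))
      out$mph_pct <- if (mp != 0) 100 * out$mph / mp else NA_real_
      out$mph_p <- 2 * pnorm(-abs(out$mph / out$mph_se))
    }
    bp <- tryCatch(
      best_parent(e_p1, e_p2, cls, id_p1 = p1, id_p2 = p2,
                  elite_parent = "p1"),
      error = function(e) NULL)
    if (!is.null(bp) && !is.na(bp$best)) {
      w <- setNames(c(1, -1), c(hy, bp$best_id))
      out$bph <- e_f1 - bp$best
      out$bph_se <- sqrt(cvar(w))
      out$bph_pct <- if (bp$best != 0) 100 * out$bph / bp$best else NA_real_
      out$bph_p <- 2 * pnorm(-abs(out$bph / out$bph_se))
      out$best_id <- bp$best_id
      out$tie <- bp$tie
      if (!is.na(bp$worst)) {
        w <- setNames(c(1, -1), c(hy, bp$worst_id))
        out$wph <- e_f1 - bp$worst
        out$wph_se <- sqrt(cvar(w))
        out$wph_p <- 2 * pnorm(-abs(out$wph / out$wph_se))
        out$worst_id <- bp$worst_id
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no hybrid in the pedigree has an EMM")
  rownames(out) <- NULL
  class(out) <- c("heterosis_table", "data.frame")
  out
}

#' Classify heterosis contrasts
#'
#' Per cross class: the percentage of hybrids whose MPH (and BPH) contrasts
#' are significantly negative, not significant, or significantly positive at
#' level `alpha` (no multiple-testing correction, matching per-contrast
#' testing practice), plus a worst-parent table (percent of hybrids below
#' the worst parent, and significantly so).
#'
#' @param records a `heterosis_table`.
#' @param alpha per-contrast Type I error threshold.
#' @return list of data.frames: `mph`, `bph` (columns `cross_class`, `n`,
#'   `pct_sig_neg`, `pct_ns`, `pct_sig_pos`) and `worst` (`pct_below_worst`,
#'   `pct_sig_below`).
#' @export
classify_contrasts <- function(records, alpha = 0.05) {
  one <- function(est, p) {
    cls <- ifelse(is.na(est) | is.na(p), NA_character_,
                  ifelse(p >= alpha, "ns",
                         ifelse(est < 0, "sig_neg", "sig_pos")))
    cls
  }
  records$mph_class <- one(records$mph, records$mph_p)
  records$bph_class <- one(records$bph, records$bph_p)
  sumtab <- function(cls_col) {
    out <- lapply(split(records, records$cross_class), function(rr) {
      cl <- rr[[cls_col]]
      cl <- cl[!is.na(cl)]
      n <- length(cl)
      data.frame(cross_class = rr$cross_class[1], n = n,
                 pct_sig_neg = if (n) 100 * mean(cl == "sig_neg") else NA,
                 pct_ns = if (n) 100 * mean(cl == "ns") else NA,
                 pct_sig_pos = if (n) 100 * mean(cl == "sig_pos") else NA,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  }
  worst <- lapply(split(records, records$cross_class), function(rr) {
    ok <- !is.na(rr$wph)
    n <- sum(ok)
    data.frame(cross_class = rr$cross_class[1], n = n,
               pct_below_worst = if (n) 100 * mean(rr$wph[ok] < 0) else NA,
               pct_sig_below = if (n)
                 100 * mean(rr$wph[ok] < 0 & rr$wph_p[ok] < alpha) else NA,
               stringsAsFactors = FALSE)
  })
  list(mph = sumtab("mph_class"), bph = sumtab("bph_class"),
       worst = do.call(rbind, c(worst, list(make.row.names = FALSE))),
       records = records)
}

#' Regress a hybrid response on genome-wide heterozygosity
#'
#' OLS regressions of a per-hybrid response (EMM, MPH, or BPH) on
#' heterozygosity with linear and quadratic terms, and an F-test of whether
#' the quadratic model fits significantly better. When additive/dominance
#' kernels are supplied, the same nested comparison is run in a kernel
#' mixed model (ML likelihood-ratio test) so the trend is tested after
#' accounting for genetic covariance.
#'
#' @param response named numeric vector (per hybrid).
#' @param H heterozygosity per hybrid (same order or named).
#' @param K_A,K_D optional kernels over the same individuals.
#' @return list: `fit1`, `fit2` (lm objects), `quad_p` (nested F-test),
#'   `coefficients`, and when kernels are given `genetic` (list with
#'   degree-1/degree-2 kernel fits and `quad_p`).
#' @export
heterozygosity_regression <- function(response, H, K_A = NULL, K_D = NULL) {
  if (length(unique(H)) < 3)
    stop("need >= 3 distinct heterozygosity values")
  ok <- !is.na(response) & !is.na(H)
  y <- response[ok]
  h <- H[ok]
  if (sd(y) == 0) {
    # constant response: slopes identically zero, no quadratic improvement
    return(list(fit1 = NULL, fit2 = NULL, quad_p = 1,
                coefficients = c("(Intercept)" = unname(y[1]), h = 0,
                                 "I(h^2)" = 0)))
  }
  fit1 <- lm(y ~ h)
  fit2 <- lm(y ~ h + I(h^2))
  an <- anova(fit1, fit2)
  out <- list(fit1 = fit1, fit2 = fit2,
              quad_p = an[["Pr(>F)"]][2],
              coefficients = coef(fit2))
  if (!is.null(K_A)) {
    ids <- names(y)
    if (is.null(ids)) stop("response must be named when kernels are given")
    KA <- K_A[ids, ids]
    kernels <- list(A = KA)
    if (!is.null(K_D)) kernels$D <- K_D[ids, ids]
    hc <- h - mean(h)
    X1 <- cbind(1, hc)
    X2 <- cbind(1, hc, hc^2)
    g1 <- ml_kernels(y, X1, kernels)
    g2 <- ml_kernels(y, X2, kernels)
    lrt <- max(0, 2 * (g2$loglik - g1$loglik))
    out$genetic <- list(fit1 = g1, fit2 = g2, lrt = lrt,
                        quad_p = pchisq(lrt, 1, lower.tail = FALSE))
  }
  out
}
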