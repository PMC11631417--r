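# Clonal trial analysis: REML variance components and estimated marginal
# means from the randomized-complete-block multi-year model, broad- and
# narrow-sense heritability, and additive genetic correlations.

#' Fit the clonal trial linear mixed model
#'
#' Model: `value ~ genotype + (1|block) + (1|year) + (1|genotype:year)` with
#' genotype ("hybrid") either fixed (for EMMs and contrasts) or random (for
#' the among-genotype variance component and clone-mean heritability).
#' Random terms whose factor has fewer than two levels in the data are
#' dropped with a message. Records with a `harvest` column containing more
#' than one harvest should be aggregated with [aggregate_harvests()] first;
#' if duplicates per individual x block x year remain they are averaged with
#' a message.
#'
#' @param records long phenotype data.frame (`individual`, `block`, `year`,
#'   `trait`, `value`; optional `harvest`).
#' @param genotype_as "fixed" or "random".
#' @param trait which trait to analyze (required if several are present).
#' @return object of class `trial_fit`: list with the `lme4` fit, the
#'   modelling data, `genotype_as`, `trait`, and the fitted formula.
#' @export
fit_trial_lmm <- function(records, genotype_as = c("fixed", "random"),
                          trait = NULL) {
  genotype_as <- match.arg(genotype_as)
  traits <- unique(records$trait)
  if (is.null(trait)) {
    if (length(traits) > 1)
      stop("records contain several traits; pass `trait`")
    trait <- traits
  }
  dat <- records[records$trait == trait, , drop = FALSE]
  if (nrow(dat) == 0) stop("no records for trait ", trait)
  if ("harvest" %in% names(dat) && length(unique(dat$harvest)) > 1) {
    message("averaging over harvests; use aggregate_harvests() to control ",
            "totals vs means")
  }
  key <- interaction(dat$individual, dat$block, dat$year, drop = TRUE)
  if (anyDuplicated(key)) {
    dat <- aggregate(value ~ individual + block + year, data = dat,
                     FUN = mean)
  }
  dat$individual <- factor(dat$individual)
  dat$block <- factor(dat$block)
  dat$year <- factor(dat$year)
  terms <- character(0)
  if (nlevels(dat$block) >= 2) terms <- c(terms, "(1 | block)")
  if (nlevels(dat$year) >= 2)
    terms <- c(terms, "(1 | year)", "(1 | individual:year)")
  else
    message("single year: year and genotype:year terms dropped")
  if (nlevels(dat$block) < 2) message("single block: block term dropped")
  fixed <- if (genotype_as == "fixed") "0 + individual" else "1"
  if (genotype_as == "random") terms <- c("(1 | individual)", terms)
  if (length(terms) == 0) stop("no random terms left; need >= 2 levels")
  fml <- as.formula(paste("value ~", fixed, "+", paste(terms, collapse = " + ")))
  fit <- lme4::lmer(fml, data = dat, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  structure(list(fit = fit, data = dat, genotype_as = genotype_as,
                 trait = trait, formula = fml),
            class = "trial_fit")
}

#' @export
print.trial_fit <- function(x, ...) {
  cat("trial_fit:", x$trait, "| genotype", x$genotype_as, "|",
      nrow(x$data), "plot records\n")
  print(variance_components(x))
  invisible(x)
}

#' REML variance components of a trial fit
#'
#' @param fit a `trial_fit`.
#' @return named numeric vector (`sigma2_G` when genotype is random,
#'   `sigma2_GxY`, `sigma2_B`, `sigma2_Y`, `sigma2_E`) with attributes
#'   `loglik` (restricted) and `converged`.
#' @export
variance_components <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit$fit))
  get <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 0) 0 else v
  }
  out <- c(sigma2_G = get("individual"),
           sigma2_GxY = get("individual:year"),
           sigma2_B = get("block"),
           sigma2_Y = get("year"),
           sigma2_E = get("Residual"))
  attr(out, "loglik") <- as.numeric(logLik(fit$fit))
  msgs <- fit$fit@optinfo$conv$lme4$messages
  attr(out, "converged") <- is.null(msgs) || length(msgs) == 0
  out
}

#' Estimated marginal means per genotype
#'
#' Genotype must be fitted as fixed; the EMM of a genotype is its marginal
#' mean averaging over the random trial factors (in a fully balanced design
#' it equals the arithmetic mean of the genotype's plot values). The full
#' sampling covariance of the EMMs is kept for contrast tests.
#'
#' @param fit a `trial_fit` with `genotype_as = "fixed"`.
#' @return data.frame of class `emm_table` (`individual`, `emmean`, `se`)
#'   with attributes `vcov` (EMM sampling covariance), `trait`, and
#'   `reps` (plot count per genotype).
#' @export
estimate_emms <- function(fit) {
  if (fit$genotype_as != "fixed")
    stop("EMMs require genotype fitted as fixed")
  em <- emmeans::emmeans(fit$fit, "individual", lmer.df = "asymptotic")
  ss <- summary(em)
  out <- data.frame(individual = as.character(ss$individual),
                    emmean = ss$emmean, se = ss$SE,
                    stringsAsFactors = FALSE)
  V <- as.matrix(vcov(em))
  dimnames(V) <- list(out$individual, out$individual)
  reps <- table(fit$data$individual)
  attr(out, "vcov") <- V
  attr(out, "trait") <- fit$trait
  attr(out, "reps") <- setNames(as.integer(reps), names(reps))
  class(out) <- c("emm_table", "data.frame")
  out
}

#' Clone-mean broad-sense heritability
#'
#' `H2 = sigma2_G / (sigma2_G + sigma2_GxY / y + sigma2_E / (r y))`, the
#' among-genotype variance over the phenotypic variance of clone means for
#' a trial with `y` years and `r` replications per year.
#'
#' @param vc variance components (from [variance_components()] on a
#'   genotype-random fit, or a named vector with `sigma2_G`, `sigma2_GxY`,
#'   `sigma2_E`).
#' @param y number of years.
#' @param r (harmonic-mean) number of replications per year.
#' @return H2 in `[0, 1]`.
#' @export
broad_sense_heritability <- function(vc, y, r) {
  if (y < 1 || r <= 0) stop("need y >= 1 and r > 0")
  s2g <- vc[["sigma2_G"]]
  denom <- s2g + vc[["sigma2_GxY"]] / y + vc[["sigma2_E"]] / (r * y)
  if (denom <= 0) stop("zero phenotypic variance")
  s2g / denom
}

#' Harmonic mean of realized replication
#'
#' Harmonic mean over genotypes of the number of plots per genotype per
#' year.
#'
#' @param records plot-level phenotype records (single trait).
#' @return scalar harmonic-mean replication.
#' @export
harmonic_mean_reps <- function(records) {
  cnt <- aggregate(value ~ individual + year, data = records, FUN = length)
  1 / mean(1 / cnt$value)
}

#' Narrow-sense heritability from a single-kernel model on EMMs
#'
#' Fits `emm = mu + a + e` with `a ~ N(0, K_A sigma2_A)` by kernel REML and
#' returns `h2 = sigma2_A / (sigma2_A + sigma2_resid)`.
#'
#' @param emms an `emm_table` (or data.frame with `individual`, `emmean`).
#' @param K_A additive relationship matrix covering the phenotyped
#'   individuals.
#' @return list: `h2`, `sigma2`, `fit` (the [reml_kernels()] fit), `blup`
#'   (additive BLUPs).
#' @export
narrow_sense_heritability <- function(emms, K_A) {
  ids <- intersect(emms$individual, rownames(K_A))
  if (length(ids) < 3) stop("too few individuals shared with the kernel")
  y <- emms$emmean[match(ids, emms$individual)]
  K <- K_A[ids, ids]
  fit <- reml_kernels(y, kernels = list(A = K))
  s2 <- fit$sigma2
  list(h2 = s2[["A"]] / (s2[["A"]] + s2[["residual"]]), sigma2 = s2,
       fit = fit, blup = setNames(fit$blup$A, ids))
}

#' Additive genetic correlation between two traits
#'
#' Bivariate kernel REML on mean-centered, unit-scaled EMMs with an
#' unstructured 2x2 additive covariance (so the additive covariance equals
#' the additive correlation) and trait-specific residuals. The p-value is
#' the upper tail of the standard normal at the covariance Z-ratio. On
#' optimization failure a method-of-moments fallback (correlation of
#' single-trait additive BLUPs) is returned with `fallback = TRUE`.
#'
#' @param emms1,emms2 `emm_table`s for the two traits.
#' @param K_A additive relationship matrix.
#' @return list: `r_g`, `se`, `z`, `p_value`, `sigma2` (per-trait additive
#'   and residual components), `fallback`.
#' @export
genetic_correlation <- function(emms1, emms2, K_A) {
  ids <- Reduce(intersect, list(emms1$individual, emms2$individual,
                                rownames(K_A)))
  if (length(ids) < 5) stop("too few common individuals")
  y1 <- scale(emms1$emmean[match(ids, emms1$individual)])[, 1]
  y2 <- scale(emms2$emmean[match(ids, emms2$individual)])[, 1]
  K <- K_A[ids, ids]
  n <- length(ids)
  y <- c(y1, y2)
  X <- rbind(cbind(1, 0), cbind(0, 1))[rep(1:2, each = n), ]
  In <- diag(n)
  # theta: log s2a1, log s2a2, atanh(ra), log s2e1, log s2e2
  build_V <- function(th) {
    sa1 <- exp(th[1]); sa2 <- exp(th[2]); ra <- tanh(th[3])
    se1 <- exp(th[4]); se2 <- exp(th[5])
    c12 <- ra * sqrt(sa1 * sa2)
    rbind(cbind(sa1 * K + se1 * In, c12 * K),
          cbind(c12 * K, sa2 * K + se2 * In))
  }
  negll <- function(th) {
    V <- build_V(th)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    C <- XtVi %*% X
    chC <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(chC)) return(1e10)
    b <- chol2inv(chC) %*% (XtVi %*% y)
    r <- y - X %*% b
    0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chC))) +
             sum(r * (Vi %*% r)))
  }
  th0 <- c(log(0.5), log(0.5), atanh(0.5 * cor(y1, y2)), log(0.5), log(0.5))
  op <- tryCatch(
    optim(th0, negll, method = "L-BFGS-B",
          lower = c(-12, -12, -6, -12, -12), upper = c(6, 6, 6, 6, 6),
          control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(op) || op$convergence != 0 || !is.finite(op$value)) {
    f1 <- narrow_sense_heritability(emms1, K_A)
    f2 <- narrow_sense_heritability(emms2, K_A)
    r_g <- cor(f1$blup[ids], f2$blup[ids])
    return(list(r_g = r_g, se = NA_real_, z = NA_real_, p_value = NA_real_,
                sigma2 = NULL, fallback = TRUE))
  }
  th <- op$par
  H <- tryCatch(optimHess(th, negll), error = function(e) NULL)
  sa1 <- exp(th[1]); sa2 <- exp(th[2]); ra <- tanh(th[3])
  c12 <- ra * sqrt(sa1 * sa2)
  se_c12 <- NA_real_
  if (!is.null(H)) {
    cov_th <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov_th)) {
      # delta method for c12 = tanh(t3) * exp((t1 + t2) / 2)
      g <- c(0.5 * c12, 0.5 * c12,
             (1 - ra^2) * sqrt(sa1 * sa2), 0, 0)
      v <- drop(t(g) %*% cov_th %*% g)
      if (is.finite(v) && v > 0) se_c12 <- sqrt(v)
    }
  }
  z <- c12 / se_c12
  list(r_g = ra, se = se_c12, z = z,
       p_value = pnorm(z, lower.tail = FALSE),
       sigma2 = c(sigma2_A1 = sa1, sigma2_A2 = sa2, cov_A = c12,
                  sigma2_E1 = exp(th[4]), sigma2_E2 = exp(th[5])),
       fallback = FALSE)
}
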