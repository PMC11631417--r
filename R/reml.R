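# Dense multi-kernel REML engine. Model: y = X b + sum_k u_k + e with
# u_k ~ N(0, sigma2_k K_k) and e ~ N(0, sigma2_e I). Average-information
# updates with fixed-point (EM-like) fallback and step halving keep the
# restricted log-likelihood non-decreasing; variance components are kept
# non-negative by projection onto a small positive bound. Intended for the
# kernel models of this package (hundreds of individuals, <= 4 components);
# grouped-factor trial models go through lme4 instead.

#' REML for mixed models with arbitrary covariance kernels
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (defaults to an intercept).
#' @param kernels named list of n x n positive semi-definite covariance
#'   kernels, one per non-residual variance component. A diagonal residual
#'   component is always appended (named "residual").
#' @param init optional initial variance components (length
#'   `length(kernels) + 1`).
#' @param tol relative restricted-log-likelihood convergence tolerance.
#' @param maxit maximum iterations.
#' @param verbose print the iteration trace.
#' @return list of class `reml_fit`: `sigma2` (named, residual last),
#'   `beta`, `beta_se`, `beta_vcov`, `loglik` (restricted), `blup` (list of
#'   kernel-effect BLUPs), `iterations`, `converged`, `boundary` (logical
#'   per component), plus internals (`V_inv`, `Py`) reused by downstream
#'   code.
#' @export
reml_kernels <- function(y, X = NULL, kernels = list(), init = NULL,
                         tol = 1e-8, maxit = 200, verbose = FALSE) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design matrix is rank deficient")
  if (var(y) == 0) stop("response has zero variance")
  kn <- length(kernels)
  if (kn > 0 && is.null(names(kernels)))
    names(kernels) <- paste0("K", seq_len(kn))
  for (k in seq_len(kn)) {
    if (!all(dim(kernels[[k]]) == c(n, n)))
      stop("kernel ", names(kernels)[k], " does not match length(y)")
  }
  Ks <- c(kernels, list(residual = diag(n)))
  nc <- length(Ks)
  vy <- var(y)
  lb <- 1e-8 * vy
  sigma2 <- if (is.null(init)) rep(vy / nc, nc) else pmax(init, lb)
  names(sigma2) <- names(Ks)

  eval_parts <- function(s2) {
    V <- matrix(0, n, n)
    for (k in seq_len(nc)) V <- V + s2[k] * Ks[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    logdetV <- 2 * sum(log(diag(ch)))
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    C <- XtVi %*% X
    chC <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(chC)) return(NULL)
    logdetC <- 2 * sum(log(diag(chC)))
    Ci <- chol2inv(chC)
    P <- Vi - t(XtVi) %*% Ci %*% XtVi
    Py <- P %*% y
    ll <- -0.5 * ((n - ncol(X)) * log(2 * pi) + logdetV + logdetC +
                    sum(y * Py))
    list(V = V, Vi = Vi, Ci = Ci, XtVi = XtVi, P = P, Py = Py, ll = ll)
  }

  parts <- eval_parts(sigma2)
  if (is.null(parts)) {
    sigma2 <- rep(vy / nc, nc)
    names(sigma2) <- names(Ks)
    parts <- eval_parts(sigma2)
    if (is.null(parts)) stop("could not factor the covariance matrix")
  }
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(maxit)) {
    P <- parts$P
    Py <- parts$Py
    KPy <- lapply(Ks, function(K) K %*% Py)
    grad <- numeric(nc)
    quad <- numeric(nc)
    trPK <- numeric(nc)
    for (k in seq_len(nc)) {
      trPK[k] <- sum(P * Ks[[k]])        # tr(P K), both symmetric
      quad[k] <- sum(Py * KPy[[k]])      # y' P K P y
      grad[k] <- -0.5 * (trPK[k] - quad[k])
    }
    at_bound <- sigma2 <= lb & grad < 0
    free <- which(!at_bound)
    if (length(free) == 0) break
    AI <- matrix(0, nc, nc)
    PKPy <- lapply(KPy, function(a) P %*% a)
    for (k in seq_len(nc)) {
      for (l in k:nc) {
        AI[k, l] <- AI[l, k] <- 0.5 * sum(KPy[[k]] * PKPy[[l]])
      }
    }
    delta <- rep(0, nc)
    ok <- TRUE
    d_free <- tryCatch(solve(AI[free, free, drop = FALSE], grad[free]),
                       error = function(e) NULL)
    if (is.null(d_free)) ok <- FALSE else delta[free] <- d_free
    if (!ok) {
      # fixed-point fallback direction
      delta <- sigma2 * (quad / pmax(trPK, 1e-12)) - sigma2
      delta[at_bound] <- 0
    }
    step <- 1
    new_parts <- NULL
    new_sigma2 <- sigma2
    for (h in 1:30) {
      cand <- pmax(sigma2 + step * delta, lb)
      cand[at_bound] <- lb
      cp <- eval_parts(cand)
      if (!is.null(cp) && cp$ll >= parts$ll - 1e-10) {
        new_parts <- cp
        new_sigma2 <- cand
        break
      }
      step <- step / 2
    }
    if (is.null(new_parts)) {
      # AI direction failed; try the fixed-point update directly
      cand <- pmax(sigma2 * (quad / pmax(trPK, 1e-12)), lb)
      cand[at_bound] <- lb
      cp <- eval_parts(cand)
      if (!is.null(cp) && cp$ll >= parts$ll - 1e-10) {
        new_parts <- cp
        new_sigma2 <- cand
      } else break
    }
    dll <- new_parts$ll - parts$ll
    sigma2 <- new_sigma2
    parts <- new_parts
    if (verbose)
      message(sprintf("it %d  ll %.8f  [%s]", iter, parts$ll,
                      paste(signif(sigma2, 4), collapse = ", ")))
    if (abs(dll) < tol * (1 + abs(parts$ll))) {
      converged <- TRUE
      break
    }
  }
  beta_vcov <- parts$Ci
  beta <- drop(beta_vcov %*% (parts$XtVi %*% y))
  names(beta) <- colnames(X)
  blup <- lapply(seq_len(kn), function(k)
    drop(sigma2[k] * (kernels[[k]] %*% parts$Py)))
  names(blup) <- names(kernels)
  structure(list(sigma2 = sigma2, beta = beta,
                 beta_se = sqrt(diag(beta_vcov)),
                 beta_vcov = beta_vcov, loglik = parts$ll, blup = blup,
                 iterations = iter, converged = converged,
                 boundary = sigma2 <= lb * (1 + 1e-6),
                 V_inv = parts$Vi, Py = drop(parts$Py), y = y, X = X,
                 n = n),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("kernel REML fit: n =", x$n, " restricted logLik =",
      format(x$loglik, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("variance components:\n")
  print(signif(x$sigma2, 5))
  cat("fixed effects:\n")
  print(signif(x$beta, 5))
  invisible(x)
}

#' Maximum-likelihood fit for the same kernel model
#'
#' Full (not restricted) likelihood, profiled over the fixed effects and
#' maximized over log variance components with `optim`. Used for nested
#' fixed-effect comparisons where REML likelihoods are not comparable.
#'
#' @inheritParams reml_kernels
#' @return list: `sigma2`, `beta`, `loglik` (ML), `converged`.
#' @export
ml_kernels <- function(y, X = NULL, kernels = list(), init = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  Ks <- c(kernels, list(residual = diag(n)))
  nc <- length(Ks)
  vy <- var(y)
  lb <- log(1e-8 * vy)
  if (is.null(init)) init <- rep(vy / nc, nc)
  negll <- function(ls2) {
    s2 <- exp(ls2)
    V <- matrix(0, n, n)
    for (k in seq_len(nc)) V <- V + s2[k] * Ks[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    C <- XtVi %*% X
    b <- tryCatch(solve(C, XtVi %*% y), error = function(e) NULL)
    if (is.null(b)) return(1e10)
    r <- y - X %*% b
    0.5 * (2 * sum(log(diag(ch))) + sum(r * (Vi %*% r)))
  }
  op <- optim(log(pmax(init, exp(lb))), negll, method = "L-BFGS-B",
              lower = lb, upper = log(1e6 * vy),
              control = list(maxit = 500))
  s2 <- exp(op$par)
  names(s2) <- names(Ks)
  V <- matrix(0, n, n)
  for (k in seq_len(nc)) V <- V + s2[k] * Ks[[k]]
  Vi <- chol2inv(chol(V))
  XtVi <- crossprod(X, Vi)
  beta <- drop(solve(XtVi %*% X, XtVi %*% y))
  names(beta) <- colnames(X)
  list(sigma2 = s2, beta = beta,
       loglik = -op$value - 0.5 * n * log(2 * pi),
       converged = op$convergence == 0)
}
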