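# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, textbook estimator
# formulas, and plain-arithmetic re-derivations.

# Weir & Cockerham (1984) two-population FST, ratio-of-sums over markers,
# computed from raw dosage matrices per group.
wc_fst_oracle <- function(g1, g2) {
  r <- 2
  a_sum <- 0
  abc_sum <- 0
  for (j in seq_len(ncol(g1))) {
    x1 <- g1[, j][!is.na(g1[, j])]
    x2 <- g2[, j][!is.na(g2[, j])]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) next
    p1 <- mean(x1) / 2; p2 <- mean(x2) / 2
    h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (!is.finite(a) || !is.finite(b) || !is.finite(cc)) next
    a_sum <- a_sum + a
    abc_sum <- abc_sum + a + b + cc
  }
  a_sum / abc_sum
}

# Transgression scores straight from the frequency-product definitions
# (AA = dosage 0, BB = dosage 2, AB = dosage 1).
duo_score_oracle <- function(go, gp) {
  f_aa_o <- as.numeric(go == 0); f_bb_o <- as.numeric(go == 2)
  f_aa_p <- as.numeric(gp == 0); f_bb_p <- as.numeric(gp == 2)
  f_aa_o * f_bb_p + f_bb_o * f_aa_p
}

trio_score_oracle <- function(go, g1, g2) {
  f_ab_o <- as.numeric(go == 1)
  f_ab_o * (as.numeric(g1 == 0) * as.numeric(g2 == 0) +
              as.numeric(g1 == 2) * as.numeric(g2 == 2))
}

trio_summand_oracle <- function(go, g1, g2) {
  t_i <- trio_score_oracle(go, g1, g2)
  s1 <- duo_score_oracle(go, g1)
  s2 <- duo_score_oracle(go, g2)
  t_i + s1 + s2 - s1 * s2
}

# Single-locus population mean by enumerating genotype frequencies
# {q^2 + Fpq, 2pq(1-F), p^2 + Fpq} with values {-a, d, +a}.
pop_mean_enum <- function(p, a, d, F = 0) {
  q <- 1 - p
  f0 <- q^2 + F * p * q
  f1 <- 2 * p * q * (1 - F)
  f2 <- p^2 + F * p * q
  f0 * (-a) + f1 * d + f2 * a
}

# F1 mean between two HWE populations by enumerating parental gamete
# frequencies: offspring genotype probs (q1 q2, p1 q2 + p2 q1, p1 p2).
f1_mean_enum <- function(p1, p2, a, d) {
  q1 <- 1 - p1; q2 <- 1 - p2
  (q1 * q2) * (-a) + (p1 * q2 + p2 * q1) * d + (p1 * p2) * a
}

mph_enum <- function(p1, p2, a, d) {
  f1_mean_enum(p1, p2, a, d) -
    (pop_mean_enum(p1, a, d) + pop_mean_enum(p2, a, d)) / 2
}

# Balanced trial records with known genotype means and N(0, sd) noise.
balanced_trial <- function(gmeans, n_blocks = 3, n_years = 2, sd = 1,
                           trait = "y") {
  ids <- names(gmeans)
  idx <- expand.grid(individual = ids, block = paste0("B", seq_len(n_blocks)),
                     year = paste0("Y", seq_len(n_years)),
                     stringsAsFactors = FALSE)
  idx$trait <- trait
  idx$value <- gmeans[idx$individual] + rnorm(nrow(idx), 0, sd)
  idx
}

# Strip non-structural attributes from a matrix for clean comparisons.
bare <- function(m) {
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

# Restricted log-likelihood at fixed variance components (intercept-only
# fixed part), evaluated from first principles.
reml_loglik_at <- function(y, K, s2) {
  n <- length(y)
  X <- matrix(1, n, 1)
  V <- s2[1] * K + s2[2] * diag(n)
  Vi <- solve(V)
  C <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(C) %*% t(X) %*% Vi
  -0.5 * ((n - 1) * log(2 * pi) + determinant(V)$modulus[1] +
            log(C[1, 1]) + drop(t(y) %*% P %*% y))
}

# Quick two-group founder panel without the sim_config machinery.
toy_two_group_panel <- function(n_per_group = 30, m = 500, p1 = NULL,
                                p2 = NULL) {
  if (is.null(p1)) p1 <- runif(m, 0.1, 0.9)
  if (is.null(p2)) p2 <- runif(m, 0.1, 0.9)
  g1 <- sapply(seq_len(m), function(j) rbinom(n_per_group, 2, p1[j]))
  g2 <- sapply(seq_len(m), function(j) rbinom(n_per_group, 2, p2[j]))
  g <- rbind(g1, g2)
  rownames(g) <- c(paste0("a", seq_len(n_per_group)),
                   paste0("b", seq_len(n_per_group)))
  colnames(g) <- paste0("mk", seq_len(m))
  list(geno = g, groups = rep(c("a", "b"), each = n_per_group))
}
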