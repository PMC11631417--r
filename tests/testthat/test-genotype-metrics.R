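test_that("QC filter matches a brute-force oracle on a planted panel", {
  set.seed(31)
  n <- 40; m <- 1000
  g <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(paste0("i", 1:n), paste0("mk", 1:m)))
  g[, 1:30] <- 0L                         # monomorphic
  g[sample(n, 30), 31:60] <- NA           # high missingness markers
  g[1, seq(2, m, by = 2)] <- NA           # low call-rate sample
  out <- filter_markers_and_samples(g, maf_min = 0.05, max_missing = 0.10,
                                    min_call_rate = 0.90)
  # oracle: recompute with explicit loops
  cr <- apply(g, 1, function(x) mean(!is.na(x)))
  keep_s <- names(cr)[cr >= 0.90]
  g2 <- g[keep_s, ]
  keep_m <- character(0)
  for (j in colnames(g2)) {
    x <- g2[, j]
    p <- mean(x, na.rm = TRUE) / 2
    maf <- min(p, 1 - p)
    if (is.nan(maf)) maf <- 0
    if (maf >= 0.05 && mean(is.na(x)) <= 0.10) keep_m <- c(keep_m, j)
  }
  expect_identical(rownames(out), keep_s)
  expect_identical(colnames(out), keep_m)
  rep <- attr(out, "qc_report")
  expect_identical(rep$dropped[rep$rule == "sample_call_rate"], 1L)
  expect_error(filter_markers_and_samples(g, maf_min = 0.6),
               "survive")
})

test_that("observed heterozygosity counts nonmissing heterozygous calls", {
  g <- rbind(i1 = c(1, 1, 1, 1), i2 = c(0, 2, 0, 2), i3 = c(0, 1, 2, NA))
  colnames(g) <- paste0("mk", 1:4)
  ho <- observed_heterozygosity(g)
  expect_equal(unname(ho), c(1, 0, 1 / 3))
  g2 <- rbind(i1 = c(NA, NA))
  expect_warning(h2 <- observed_heterozygosity(g2), "missing")
  expect_true(is.na(h2))
})

test_that("inbreeding coefficients match hand oracles and agree in rank", {
  # 1 - H convention
  g <- matrix(0L, 1, 100, dimnames = list("x", paste0("mk", 1:100)))
  g[1, 1:38] <- 1L
  expect_equal(unname(inbreeding_coefficient(g, "one_minus_H")), 0.62)
  ghom <- matrix(rep(c(0L, 2L), 10), 1, 20,
                 dimnames = list("x", paste0("mk", 1:20)))
  expect_equal(unname(inbreeding_coefficient(ghom, "one_minus_H")), 1)

  # excess-homozygosity on a 3 x 4 toy, fully hand-computed
  toy <- rbind(i1 = c(0, 1, 2, 1), i2 = c(1, 1, 0, 0), i3 = c(2, 1, 0, 2))
  colnames(toy) <- paste0("mk", 1:4)
  p <- colMeans(toy) / 2                       # (0.5, 0.5, 1/3, 0.5)
  e_hom <- 1 - 2 * p * (1 - p)                 # per marker
  o_hom <- rowSums(toy != 1)
  f_hand <- (o_hom - sum(e_hom)) / (4 - sum(e_hom))
  expect_equal(inbreeding_coefficient(toy, "excess_homozygosity"), f_hand)

  # the two estimators rank individuals identically on a simulated panel
  set.seed(32)
  cfg <- sim_config(n_elite_founders = 15, n_exotic_founders = 0,
                    n_markers = 1000, n_elite_hybrids = 40, n_s1 = 25,
                    n_s1_parents = 8, seed = 33)
  pop <- simulate_population(cfg)
  f1 <- inbreeding_coefficient(pop$geno, "one_minus_H")
  f2 <- inbreeding_coefficient(pop$geno, "excess_homozygosity")
  expect_gt(cor(f1, f2, method = "spearman"), 0.95)
})

test_that("effective population size inverts the heterozygosity-decay formula", {
  expect_warning(ne <- effective_population_size(0.4, 0.4), "decay")
  expect_true(!is.finite(ne))
  expect_equal(effective_population_size(0.5, 0.5 * exp(-1 / 2)), 1)
  # published-style inputs: direct evaluation
  expect_equal(effective_population_size(0.355, 0.313), 3.9706,
               tolerance = 1e-4)
  # selfing closed form: H1/H0 = 0.5 => Ne = -1 / (2 ln 0.5)
  expect_equal(effective_population_size(0.4, 0.2), -1 / (2 * log(0.5)))
  # and the estimator applied to a simulated selfing generation
  set.seed(34)
  parent <- setNames(rbinom(2000, 2, 0.5), paste0("mk", 1:2000))
  s1 <- self_cross(parent, 400)
  h0 <- mean(parent == 1)
  h1 <- mean(rowMeans(s1 == 1))
  expect_lt(abs(effective_population_size(h0, h1) - 0.7213), 0.05)
  expect_error(effective_population_size(0, 0.1), "positive")
})

test_that("additive GRM follows the VanRaden formula", {
  g <- matrix(c(0L, 2L), 2, 1, dimnames = list(c("a", "b"), "mk1"))
  K <- additive_grm(g)
  expect_equal(unclass(K)[1:2, 1:2],
               matrix(c(2, -2, -2, 2), 2, dimnames = list(c("a", "b"),
                                                          c("a", "b"))))
  # duplicated individuals: identical rows, off-diagonal equals diagonal
  set.seed(35)
  gg <- matrix(rbinom(600, 2, 0.5), 6, 100,
               dimnames = list(paste0("i", 1:6), paste0("mk", 1:100)))
  gg[2, ] <- gg[1, ]
  K2 <- additive_grm(gg)
  expect_equal(K2[1, ], K2[2, ])
  expect_equal(K2[1, 2], K2[1, 1])
  # non-inbred HWE panel: mean diagonal near 1
  gl <- matrix(rbinom(200 * 3000, 2, rep(runif(3000, 0.1, 0.9), each = 200)),
               200, 3000, dimnames = list(paste0("i", 1:200), NULL))
  colnames(gl) <- paste0("mk", 1:3000)
  K3 <- additive_grm(gl)
  expect_lt(abs(mean(diag(K3)) - 1), 0.05)
  expect_error(additive_grm(matrix(2L, 3, 4)), "monomorphic")
})

test_that("dominance GRM uses the classical parameterization", {
  g <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("a", "b"), "mk1"))
  K <- dominance_grm(g)
  expect_equal(unclass(K)[1:2, 1:2],
               matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  expect_error(dominance_grm(matrix(c(0L, 2L, 0L, 2L), 2, 2)), "homozygous")
  # symmetry and PSD on random panels
  set.seed(36)
  for (rep in 1:3) {
    gg <- matrix(rbinom(50 * 300, 2, 0.4), 50, 300,
                 dimnames = list(paste0("i", 1:50), paste0("mk", 1:300)))
    KD <- dominance_grm(gg)
    expect_equal(bare(KD), t(bare(KD)))
    ev <- eigen(KD, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * sum(diag(KD)))
  }
})

test_that("GRMs are permutation-conjugate", {
  set.seed(37)
  g <- matrix(rbinom(30 * 200, 2, 0.5), 30, 200,
              dimnames = list(paste0("i", 1:30), paste0("mk", 1:200)))
  perm <- sample(30)
  K <- additive_grm(g)
  Kp <- additive_grm(g[perm, ])
  expect_equal(bare(Kp), bare(K)[perm, perm])
})

test_that("PCA separates diverged groups with a deterministic sign", {
  set.seed(38)
  cfg <- sim_config(n_elite_founders = 50, n_exotic_founders = 50,
                    n_markers = 5000, divergence = 0.2, elite_inbreeding = 0,
                    seed = 39)
  f <- simulate_founders(cfg)
  grp <- attr(f, "group")
  pc <- pca_scores(f, 2)
  s1 <- pc$scores[grp == "elite", 1]
  s2 <- pc$scores[grp == "exotic", 1]
  # perfect linear separation on PC1
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  expect_lte(sum(pc$var_explained), 1)
  # identical individuals -> identical scores
  g <- f$geno[1:10, 1:500]
  g[2, ] <- g[1, ]
  pc2 <- pca_scores(g, 2)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ])
  expect_error(pca_scores(g[1:2, ], 5), "fewer individuals")
})

test_that("segregation chi-square matches hand values", {
  r1 <- segregation_test(c(75, 25), c(3, 1))
  expect_equal(r1$chisq, 0)
  expect_equal(r1$p_value, 1)
  r2 <- segregation_test(c(50, 50), c(1, 1))
  expect_equal(r2$chisq, 0)
  r3 <- segregation_test(c(60, 40), c(1, 1))
  expect_equal(r3$chisq, 4)
  expect_equal(r3$p_value, 0.0455, tolerance = 1e-3)
  expect_error(segregation_test(c(0, 0), c(1, 1)), "zero total")
  expect_error(segregation_test(c(-1, 5), c(1, 1)), ">= 0")
})
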