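test_that("balanced-design EMMs equal arithmetic genotype means", {
  set.seed(61)
  gmeans <- setNames(c(10, 12, 15, 9, 11), paste0("g", 1:5))
  rec <- balanced_trial(gmeans, n_blocks = 3, n_years = 2, sd = 1)
  fit <- fit_trial_lmm(rec, "fixed")
  em <- estimate_emms(fit)
  simple <- tapply(rec$value, rec$individual, mean)
  expect_equal(em$emmean[match(names(simple), em$individual)],
               as.numeric(simple), tolerance = 1e-8)
  # duplicated genotype under a new ID gets an identical EMM
  dup <- rec[rec$individual == "g1", ]
  dup$individual <- "g1copy"
  fit2 <- fit_trial_lmm(rbind(rec, dup), "fixed")
  em2 <- estimate_emms(fit2)
  expect_equal(em2$emmean[em2$individual == "g1"],
               em2$emmean[em2$individual == "g1copy"], tolerance = 1e-8)
})

test_that("a genotype seen in one year is estimable with a larger SE", {
  set.seed(62)
  gmeans <- setNames(c(10, 11, 12, 13), paste0("g", 1:4))
  rec <- balanced_trial(gmeans, n_blocks = 2, n_years = 2, sd = 0.5)
  rec <- rec[!(rec$individual == "g4" & rec$year == "Y2"), ]
  fit <- fit_trial_lmm(rec, "fixed")
  em <- estimate_emms(fit)
  expect_true(all(is.finite(em$emmean)))
  se4 <- em$se[em$individual == "g4"]
  expect_gt(se4, max(em$se[em$individual != "g4"]))
})

test_that("EMM contrasts are invariant to a constant year shift", {
  set.seed(63)
  gmeans <- setNames(c(10, 14, 12), paste0("g", 1:3))
  rec <- balanced_trial(gmeans, n_blocks = 3, n_years = 2, sd = 0.8)
  em1 <- estimate_emms(fit_trial_lmm(rec, "fixed"))
  rec2 <- rec
  rec2$value[rec2$year == "Y2"] <- rec2$value[rec2$year == "Y2"] + 50
  em2 <- estimate_emms(fit_trial_lmm(rec2, "fixed"))
  d1 <- diff(em1$emmean)
  d2 <- diff(em2$emmean)
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("variance components recover simulated values", {
  set.seed(64)
  # moderate replicate check; the full-scale recovery is in the acceptance
  # suite
  bias <- matrix(NA_real_, 10, 3)
  for (r in 1:10) {
    ng <- 120
    u <- rnorm(ng, 0, 1)            # sigma2_G = 1
    gy <- matrix(rnorm(ng * 2, 0, sqrt(0.5)), ng)  # sigma2_GxY = 0.5
    idx <- expand.grid(g = 1:ng, b = 1:3, y = 1:2)
    val <- u[idx$g] + gy[cbind(idx$g, idx$y)] +
      rnorm(nrow(idx), 0, sqrt(2))  # sigma2_E = 2
    rec <- data.frame(individual = paste0("g", idx$g),
                      block = paste0("B", idx$b),
                      year = paste0("Y", idx$y), trait = "t", value = val)
    vc <- suppressWarnings(variance_components(fit_trial_lmm(rec, "random")))
    bias[r, ] <- c(vc[["sigma2_G"]], vc[["sigma2_GxY"]], vc[["sigma2_E"]])
  }
  mm <- colMeans(bias)
  expect_lt(abs(mm[1] - 1) / 1, 0.15)
  expect_lt(abs(mm[2] - 0.5) / 0.5, 0.25)
  expect_lt(abs(mm[3] - 2) / 2, 0.10)
})

test_that("broad-sense heritability follows the clone-mean formula", {
  vc <- c(sigma2_G = 1, sigma2_GxY = 0, sigma2_E = 0)
  expect_equal(broad_sense_heritability(vc, 2, 3), 1)
  vc2 <- c(sigma2_G = 1, sigma2_GxY = 1, sigma2_E = 1)
  expect_equal(broad_sense_heritability(vc2, 2, 3), 0.6)
  vc3 <- c(sigma2_G = 0, sigma2_GxY = 1, sigma2_E = 1)
  expect_equal(broad_sense_heritability(vc3, 2, 3), 0)
  expect_error(broad_sense_heritability(vc, 0, 3), "y >= 1")
  expect_error(
    broad_sense_heritability(c(sigma2_G = 0, sigma2_GxY = 0, sigma2_E = 0),
                             2, 3),
    "zero phenotypic variance")
})

test_that("harmonic-mean replication reflects realized plot counts", {
  rec <- data.frame(individual = c("a", "a", "a", "b"),
                    block = c("B1", "B2", "B3", "B1"),
                    year = "Y1", trait = "t", value = 1:4)
  # a has 3 plots/year, b has 1: harmonic mean = 2/(1/3 + 1/1)
  expect_equal(harmonic_mean_reps(rec), 2 / (1 / 3 + 1))
})

test_that("narrow-sense heritability hits its limiting cases", {
  set.seed(65)
  n <- 300; m <- 1200
  g <- matrix(rbinom(n * m, 2, 0.5), n, m,
              dimnames = list(paste0("i", 1:n), paste0("mk", 1:m)))
  KA <- additive_grm(g)
  a <- rnorm(m, 0, 0.1)
  gv <- drop(g %*% a)
  em_pure <- data.frame(individual = rownames(g), emmean = gv)
  class(em_pure) <- c("emm_table", "data.frame")
  h_pure <- narrow_sense_heritability(em_pure, KA)
  expect_gte(h_pure$h2, 0.95)
  em_noise <- data.frame(individual = rownames(g), emmean = rnorm(n))
  class(em_noise) <- c("emm_table", "data.frame")
  h_noise <- narrow_sense_heritability(em_noise, KA)
  expect_lte(h_noise$h2, 0.1)
  # clones share BLUPs
  g2 <- g; g2[2, ] <- g2[1, ]
  KA2 <- additive_grm(g2)
  em2 <- data.frame(individual = rownames(g2), emmean = drop(g2 %*% a))
  class(em2) <- c("emm_table", "data.frame")
  h2f <- narrow_sense_heritability(em2, KA2)
  expect_equal(unname(h2f$blup[1]), unname(h2f$blup[2]), tolerance = 1e-4)
})

test_that("genetic correlation is 1 for a trait against itself or a rescale", {
  set.seed(66)
  n <- 120; m <- 600
  g <- matrix(rbinom(n * m, 2, 0.5), n, m,
              dimnames = list(paste0("i", 1:n), paste0("mk", 1:m)))
  KA <- additive_grm(g)
  y <- drop(g %*% rnorm(m, 0, 0.1)) + rnorm(n, 0, 1)
  e1 <- data.frame(individual = rownames(g), emmean = y)
  class(e1) <- c("emm_table", "data.frame")
  gc1 <- genetic_correlation(e1, e1, KA)
  expect_gt(gc1$r_g, 0.97)
  e2 <- e1; e2$emmean <- 2 * e1$emmean + 7
  gc2 <- genetic_correlation(e1, e2, KA)
  expect_gt(gc2$r_g, 0.97)
})

test_that("genetic correlation recovers a planted value", {
  set.seed(67)
  ests <- numeric(4)
  for (r in 1:4) {
    n <- 200; m <- 700
    g <- matrix(rbinom(n * m, 2, 0.5), n, m,
                dimnames = list(paste0("i", 1:n), paste0("mk", 1:m)))
    KA <- additive_grm(g)
    qi <- sample(m, 80)
    a1 <- rnorm(80)
    a2 <- 0.8 * a1 + sqrt(1 - 0.64) * rnorm(80)
    gv1 <- drop(g[, qi] %*% a1); gv2 <- drop(g[, qi] %*% a2)
    y1 <- gv1 + rnorm(n, 0, sd(gv1) * 0.4)
    y2 <- gv2 + rnorm(n, 0, sd(gv2) * 0.4)
    e1 <- data.frame(individual = rownames(g), emmean = y1)
    e2 <- data.frame(individual = rownames(g), emmean = y2)
    class(e1) <- class(e2) <- c("emm_table", "data.frame")
    ests[r] <- genetic_correlation(e1, e2, KA)$r_g
  }
  expect_lt(abs(mean(ests) - 0.8), 0.12)
})

test_that("single-year data drops year terms with a message", {
  set.seed(68)
  gmeans <- setNames(c(10, 12), c("g1", "g2"))
  rec <- balanced_trial(gmeans, n_blocks = 3, n_years = 1, sd = 0.5)
  expect_message(fit <- fit_trial_lmm(rec, "fixed"), "single year")
  em <- estimate_emms(fit)
  expect_equal(nrow(em), 2)
})
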