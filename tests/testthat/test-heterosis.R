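test_that("best-parent rules follow cross class", {
  b <- best_parent(100, 80, "elite_x_elite", "P1", "P2")
  expect_equal(b$best, 100)
  expect_equal(b$worst, 80)
  # elite x exotic: the elite parent is best even with a lower mean
  b2 <- best_parent(80, 120, "elite_x_exotic", "E", "X", elite_parent = "p1")
  expect_equal(b2$best, 80)
  expect_equal(b2$best_id, "E")
  # elite x elite tie: deterministic by ID, flagged
  b3 <- best_parent(100, 100, "elite_x_elite", "Pb", "Pa")
  expect_true(b3$tie)
  expect_equal(b3$best_id, "Pa")
  expect_error(best_parent(NA, 120, "elite_x_exotic", elite_parent = "p1"),
               "elite parent EMM")
})

make_emm_table <- function(means, ses = NULL, V = NULL) {
  out <- data.frame(individual = names(means), emmean = unname(means),
                    se = if (is.null(ses)) rep(1, length(means)) else ses,
                    stringsAsFactors = FALSE)
  if (is.null(V)) {
    V <- diag(out$se^2)
    dimnames(V) <- list(out$individual, out$individual)
  }
  attr(out, "vcov") <- V
  class(out) <- c("emm_table", "data.frame")
  out
}

test_that("heterosis contrasts evaluate the textbook examples", {
  em <- make_emm_table(c(F1 = 150, P1 = 100, P2 = 100))
  ped <- data.frame(hybrid = "F1", parent1 = "P1", parent2 = "P2",
                    cross_class = "elite_x_elite")
  h <- heterosis_contrasts(em, ped)
  expect_equal(h$mph, 50)
  expect_equal(h$mph_pct, 50)
  expect_equal(h$bph, 50)
  expect_equal(h$mph_se, sqrt(1 + 0.25 + 0.25))
  # F1 equal to best parent: BPH = 0
  em2 <- make_emm_table(c(F1 = 120, P1 = 120, P2 = 100))
  h2 <- heterosis_contrasts(em2, ped)
  expect_equal(h2$bph, 0)
  expect_equal(h2$bph_pct, 0)
  # missing parent EMM: MPH skipped, BPH still defined for elite x exotic
  em3 <- make_emm_table(c(F1 = 110, P1 = 100))
  ped3 <- data.frame(hybrid = "F1", parent1 = "P1", parent2 = "PX",
                     cross_class = "elite_x_exotic")
  h3 <- heterosis_contrasts(em3, ped3)
  expect_true(is.na(h3$mph))
  expect_equal(h3$bph, 10)
  expect_true(is.na(h3$wph))
})

test_that("contrasts match brute-force plot-mean arithmetic on balanced data", {
  set.seed(71)
  gmeans <- setNames(c(110, 100, 95, 104), c("F1", "P1", "P2", "F2"))
  rec <- balanced_trial(gmeans, n_blocks = 3, n_years = 2, sd = 1)
  em <- estimate_emms(fit_trial_lmm(rec, "fixed"))
  ped <- data.frame(hybrid = c("F1", "F2"), parent1 = "P1", parent2 = "P2",
                    cross_class = "elite_x_elite")
  h <- heterosis_contrasts(em, ped)
  pm <- tapply(rec$value, rec$individual, mean)
  expect_equal(h$mph[1], unname(pm["F1"] - (pm["P1"] + pm["P2"]) / 2),
               tolerance = 1e-6)
  expect_equal(h$bph[2], unname(pm["F2"] - max(pm["P1"], pm["P2"])),
               tolerance = 1e-6)
})

test_that("percent heterosis is scale-invariant, contrasts shift-equivariant", {
  em <- make_emm_table(c(F1 = 120, P1 = 100, P2 = 90))
  ped <- data.frame(hybrid = "F1", parent1 = "P1", parent2 = "P2",
                    cross_class = "elite_x_elite")
  h <- heterosis_contrasts(em, ped)
  em_scaled <- make_emm_table(c(F1 = 240, P1 = 200, P2 = 180))
  hs <- heterosis_contrasts(em_scaled, ped)
  expect_equal(hs$mph_pct, h$mph_pct)
  expect_equal(hs$bph_pct, h$bph_pct)
  em_shift <- make_emm_table(c(F1 = 125, P1 = 105, P2 = 95))
  hsh <- heterosis_contrasts(em_shift, ped)
  expect_equal(hsh$mph, h$mph)
  expect_equal(hsh$bph, h$bph)
})

test_that("classification splits records by signed significance", {
  recs <- data.frame(hybrid = paste0("h", 1:4), parent1 = "a", parent2 = "b",
                     cross_class = "elite_x_elite",
                     mph = c(-3, -1, 1, 3), mph_p = 2 * pnorm(-abs(c(-3, -1, 1, 3))),
                     bph = c(-3, -1, 1, 3), bph_p = 2 * pnorm(-abs(c(-3, -1, 1, 3))),
                     wph = c(-3, -1, 1, 3), wph_p = 2 * pnorm(-abs(c(-3, -1, 1, 3))))
  class(recs) <- c("heterosis_table", "data.frame")
  cl <- classify_contrasts(recs, alpha = 0.05)
  expect_equal(cl$mph$pct_sig_neg, 25)
  expect_equal(cl$mph$pct_ns, 50)
  expect_equal(cl$mph$pct_sig_pos, 25)
  expect_equal(cl$worst$pct_below_worst, 50)
  expect_equal(cl$worst$pct_sig_below, 25)
  # all-zero contrasts: everything not significant
  recs0 <- recs
  recs0$mph <- recs0$bph <- recs0$wph <- 0
  recs0$mph_p <- recs0$bph_p <- recs0$wph_p <- 1
  cl0 <- classify_contrasts(recs0)
  expect_equal(cl0$mph$pct_ns, 100)
})

test_that("heterozygosity regression recovers planted trends", {
  set.seed(72)
  n <- 200
  h <- runif(n, 0.2, 0.5)
  y <- 2 + 3 * h + rnorm(n, 0, 0.01)
  names(y) <- paste0("i", 1:n)
  r <- heterozygosity_regression(y, h)
  expect_lt(abs(coef(r$fit1)[["h"]] - 3), 0.05)
  expect_gt(r$quad_p, 0.05)
  # true quadratic trend: nested test rejects
  y2 <- 2 + 3 * h - 8 * h^2 + rnorm(n, 0, 0.05)
  r2 <- heterozygosity_regression(y2, h)
  expect_lt(r2$quad_p, 1e-6)
  # constant response: flat fit, no quadratic improvement
  r3 <- heterozygosity_regression(setNames(rep(5, n), names(y)), h)
  expect_equal(unname(r3$coefficients["h"]), 0)
  expect_equal(r3$quad_p, 1)
  expect_error(heterozygosity_regression(y[1:3], rep(0.3, 3)), "distinct")
})

test_that("kernel-adjusted heterozygosity regression runs the nested test", {
  set.seed(73)
  n <- 120; m <- 500
  g <- matrix(rbinom(n * m, 2, 0.5), n, m,
              dimnames = list(paste0("i", 1:n), paste0("mk", 1:m)))
  KA <- additive_grm(g)
  KD <- dominance_grm(g)
  h <- observed_heterozygosity(g)
  y <- setNames(5 + 4 * h + rnorm(n, 0, 0.3), rownames(g))
  r <- heterozygosity_regression(y, h, K_A = KA, K_D = KD)
  expect_true(!is.null(r$genetic))
  expect_gte(r$genetic$lrt, 0)
  expect_gt(r$genetic$quad_p, 0.001)  # no true quadratic term
})
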