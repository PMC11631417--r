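test_that("founder simulation is seed-deterministic and respects divergence", {
  cfg0 <- sim_config(n_elite_founders = 40, n_exotic_founders = 40,
                     n_markers = 2000, divergence = 0, elite_inbreeding = 0,
                     seed = 42)
  f1 <- simulate_founders(cfg0)
  f2 <- simulate_founders(cfg0)
  expect_identical(f1$geno, f2$geno)

  grp <- attr(f1, "group")
  fst0 <- wc_fst_oracle(f1$geno[grp == "elite", ], f1$geno[grp == "exotic", ])
  expect_lt(abs(fst0), 0.02)

  cfg2 <- sim_config(n_elite_founders = 40, n_exotic_founders = 40,
                     n_markers = 5000, divergence = 0.2, elite_inbreeding = 0,
                     seed = 43)
  f3 <- simulate_founders(cfg2)
  grp3 <- attr(f3, "group")
  fst2 <- wc_fst_oracle(f3$geno[grp3 == "elite", ],
                        f3$geno[grp3 == "exotic", ])
  expect_lt(abs(fst2 - 0.2), 0.05)
})

test_that("founder genotypes pass HWE at nominal rate when non-inbred", {
  cfg <- sim_config(n_elite_founders = 200, n_exotic_founders = 0,
                    n_markers = 400, divergence = 0, elite_inbreeding = 0,
                    seed = 7)
  f <- simulate_founders(cfg)
  g <- f$geno
  pvals <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]
    p <- mean(x) / 2
    if (p <= 0.05 || p >= 0.95) return(NA_real_)
    obs <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    expd <- nrow(g) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    pchisq(sum((obs - expd)^2 / expd), df = 1, lower.tail = FALSE)
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  # rejection rate at 5% should be near nominal
  expect_lt(mean(pvals < 0.05), 0.10)
  expect_gt(mean(pvals < 0.05), 0.005)
})

test_that("cross obeys Mendelian transmission", {
  m <- 50
  aa <- setNames(rep(0L, m), paste0("mk", 1:m))
  bb <- setNames(rep(2L, m), paste0("mk", 1:m))
  off <- cross(aa, bb, 20)
  expect_true(all(off == 1L))

  # AB x AB at a single marker: 1:2:1 over 10,000 offspring
  set.seed(11)
  ab <- setNames(1L, "mk1")
  off2 <- cross(ab, ab, 10000)
  counts <- c(sum(off2 == 0), sum(off2 == 1), sum(off2 == 2))
  gof <- segregation_test(counts, c(1, 2, 1))
  expect_gt(gof$p_value, 0.001)

  # offspring allele frequency equals mid-parent frequency in expectation
  set.seed(12)
  p1 <- rbinom(200, 2, 0.3)
  p2 <- rbinom(200, 2, 0.7)
  names(p1) <- names(p2) <- paste0("mk", 1:200)
  off3 <- cross(p1, p2, 4000)
  expect_lt(max(abs(colMeans(off3) / 2 - (p1 + p2) / 4)), 0.03)

  expect_error(cross(setNames(0L, "a"), setNames(c(0L, 1L), c("a", "b")), 5),
               "same markers")
})

test_that("selfing halves heterozygosity and fixes homozygotes", {
  hom <- setNames(rep(c(0L, 2L), 25), paste0("mk", 1:50))
  s <- self_cross(hom, 10)
  expect_true(all(t(s) == hom))

  set.seed(13)
  m <- 1000
  parent <- setNames(c(rep(1L, 400), rep(0L, 300), rep(2L, 300)),
                     paste0("mk", 1:m))  # H(parent) = 0.40
  s1 <- self_cross(parent, 500)
  h <- rowMeans(s1 == 1)
  se <- sd(h) / sqrt(length(h))
  expect_lt(abs(mean(h) - 0.20), 3 * se)
})

test_that("linked transmission produces associated adjacent markers", {
  set.seed(21)
  map <- data.frame(marker = paste0("mk", 1:100), chrom = "chr1",
                    pos = seq(0, 990, by = 10) * 1e6, ref = "A", alt = "B")
  het <- setNames(rep(1L, 100), map$marker)
  hom <- setNames(rep(0L, 100), map$marker)
  # only the heterozygous parent's gamete varies; phase is randomized, so
  # the association can be in coupling or repulsion — test its magnitude
  off_link <- cross(het, hom, 400, map = map, linkage = TRUE)
  off_free <- cross(het, hom, 400)
  r_link <- abs(cor(off_link[, 1], off_link[, 2]))
  r_free <- abs(cor(off_free[, 1], off_free[, 2]))
  expect_gt(r_link, 0.5)   # 10 cM apart: |1 - 2 rf| ~ 0.82
  expect_lt(r_free, 0.2)
  expect_error(cross(het, hom, 5, linkage = TRUE), "marker map")
})

test_that("phenotype simulation honours its variance structure", {
  cfg <- sim_config(n_elite_founders = 4, n_exotic_founders = 0,
                    n_markers = 50, n_elite_hybrids = 0, n_s1 = 0,
                    sigma2_block = 0, sigma2_year = 0, sigma2_gxy = 0,
                    sigma2_resid = 0,
                    traits = list(y = list(n_qtl = 0,
                                           additive_effect_scale = 1,
                                           delta_mean = 0, delta_sd = 0,
                                           load_fraction = 0, mu = 5)),
                    seed = 3)
  pop <- simulate_population(cfg)
  rec <- simulate_phenotypes(pop$geno, pop$truth, cfg)
  expect_true(all(rec$value == 5))

  # complete dominance: heterozygote equals favorable homozygote
  g <- matrix(c(0L, 1L, 2L), ncol = 1,
              dimnames = list(c("i0", "i1", "i2"), "mk1"))
  qtl <- data.frame(trait = "y", marker = "mk1", a = 1, d = 1)
  gv <- genetic_value(g, qtl)
  expect_equal(gv["i1", "y"], gv["i2", "y"])
  expect_equal(gv["i0", "y"], -1)
})

test_that("harvest splitting aggregates back to the plot value", {
  cfg <- sim_config(n_elite_founders = 3, n_exotic_founders = 0,
                    n_markers = 20, n_elite_hybrids = 0, n_s1 = 0,
                    sigma2_block = 0, sigma2_year = 0, sigma2_gxy = 0,
                    sigma2_resid = 0, n_harvests = 4, harvest_sd = 0,
                    traits = list(y = list(n_qtl = 0,
                                           additive_effect_scale = 1,
                                           delta_mean = 0, delta_sd = 0,
                                           load_fraction = 0, mu = 8)),
                    seed = 4)
  pop <- simulate_population(cfg)
  rec <- simulate_phenotypes(pop$geno, pop$truth, cfg)
  expect_equal(sort(unique(rec$harvest)), 1:4)
  agg <- aggregate_harvests(rec, "sum")
  expect_true(all(abs(agg$value - 8) < 1e-12))
})

test_that("error injection matches its rates and identity at zero", {
  set.seed(5)
  g <- matrix(rbinom(10000, 2, 0.5), 100, 100,
              dimnames = list(paste0("i", 1:100), paste0("mk", 1:100)))
  expect_identical(inject_errors(g, 0, 0), g)

  gm <- inject_errors(g, 0, 0.1, seed = 6)
  expect_lt(abs(mean(is.na(gm)) - 0.1), 0.01)

  ge <- inject_errors(g, 0.05, 0, seed = 7)
  changed <- mean(ge != g)
  expect_lt(abs(changed - 0.05), 0.01)
  expect_true(all(ge[ge != g] != g[ge != g]))  # always a different state
  expect_error(inject_errors(g, 1.5, 0), "rates")
})

test_that("simulated pedigree records exactly two parents per progeny", {
  cfg <- sim_config(n_elite_founders = 6, n_exotic_founders = 2,
                    n_markers = 100, n_elite_hybrids = 10,
                    n_exotic_hybrids = 5, n_s1 = 4, n_s1_parents = 2,
                    seed = 8)
  pop <- simulate_population(cfg)
  ped <- pop$truth$pedigree
  founders <- is.na(ped$parent1)
  expect_true(all(is.na(ped$parent2[founders])))
  expect_true(all(!is.na(ped$parent2[!founders])))
  expect_true(all(ped$parent1[!founders] %in% ped$id))
  expect_identical(nrow(pop$geno$geno), nrow(ped))
})
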