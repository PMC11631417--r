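# Duo and trio genotypic transgression ratios for parentage identification
# and pedigree authentication from pseudo-diploid SNP calls. A duo
# transgression is a pair of opposite homozygotes between candidate parent
# and offspring (Mendelian-impossible for a true parent-offspring pair); a
# trio transgression adds the heterozygous-offspring / same-homozygote-
# parents configuration.

#' Duo transgression score at one marker
#'
#' `S_i = 1` iff the offspring and candidate parent carry opposite
#' homozygotes (0 vs 2); any heterozygote gives 0.
#'
#' @param g_off,g_par nonmissing dosage calls in `{0, 1, 2}`.
#' @return 0 or 1 (vectorized).
#' @export
duo_score_marker <- function(g_off, g_par) {
  if (anyNA(g_off) || anyNA(g_par))
    stop("calls must be nonmissing; missing markers are excluded from m")
  as.integer((g_off == 0 & g_par == 2) | (g_off == 2 & g_par == 0))
}

#' Duo transgression ratio
#'
#' Mean duo transgression score over markers jointly nonmissing in the
#' offspring and candidate parent.
#'
#' @param geno genotypes ([snp_geno] or dosage matrix).
#' @param offspring,candidate_parent individual IDs (or row indices).
#' @return list: `offspring`, `parent`, `m` (markers scored), `dtr`.
#' @export
dtr <- function(geno, offspring, candidate_parent) {
  g <- dosage_matrix(geno)
  go <- g[offspring, ]
  gp <- g[candidate_parent, ]
  ok <- !is.na(go) & !is.na(gp)
  m <- sum(ok)
  if (m == 0) stop("no jointly nonmissing markers for the duo")
  s <- duo_score_marker(go[ok], gp[ok])
  list(offspring = offspring, parent = candidate_parent, m = m,
       dtr = sum(s) / m)
}

#' Trio transgression score at one marker
#'
#' `T_i = 1` iff the offspring is heterozygous while both candidate parents
#' carry the same homozygote.
#'
#' @param g_off,g_p1,g_p2 nonmissing dosage calls in `{0, 1, 2}`.
#' @return 0 or 1 (vectorized).
#' @export
trio_score_marker <- function(g_off, g_p1, g_p2) {
  if (anyNA(g_off) || anyNA(g_p1) || anyNA(g_p2))
    stop("calls must be nonmissing; missing markers are excluded from m")
  as.integer(g_off == 1 &
               ((g_p1 == 0 & g_p2 == 0) | (g_p1 == 2 & g_p2 == 2)))
}

#' Trio transgression ratio
#'
#' `TTR = (1/m) * sum(T_i + S1_i + S2_i - S1_i * S2_i)` over markers
#' nonmissing in all three individuals; the product term prevents double
#' counting a marker where both parent duos transgress.
#'
#' @param geno genotypes.
#' @param offspring,parent1,parent2 individual IDs (or row indices).
#' @return list: IDs, `m`, `ttr`, component sums (`sum_t`, `sum_s1`,
#'   `sum_s2`, `sum_s1s2`) and the two component duo ratios (`dtr1`,
#'   `dtr2`, computed on the same marker set).
#' @export
ttr <- function(geno, offspring, parent1, parent2) {
  g <- dosage_matrix(geno)
  go <- g[offspring, ]
  g1 <- g[parent1, ]
  g2 <- g[parent2, ]
  ok <- !is.na(go) & !is.na(g1) & !is.na(g2)
  m <- sum(ok)
  if (m == 0) stop("no jointly nonmissing markers for the trio")
  go <- go[ok]; g1 <- g1[ok]; g2 <- g2[ok]
  t_i <- trio_score_marker(go, g1, g2)
  s1 <- duo_score_marker(go, g1)
  s2 <- duo_score_marker(go, g2)
  list(offspring = offspring, parent1 = parent1, parent2 = parent2, m = m,
       ttr = sum(t_i + s1 + s2 - s1 * s2) / m,
       sum_t = sum(t_i), sum_s1 = sum(s1), sum_s2 = sum(s2),
       sum_s1s2 = sum(s1 * s2),
       dtr1 = sum(s1) / m, dtr2 = sum(s2) / m)
}

#' Scan claimed pedigrees against all candidate parents
#'
#' For each offspring in the claims table: duo transgression ratios against
#' every candidate parent (all other genotyped individuals by default),
#' sorted ascending, plus the claimed trio's TTR and a pass/fail call
#' against the threshold. Self-duos are excluded.
#'
#' @param geno genotypes.
#' @param claims data.frame with columns `offspring`, `parent1`, `parent2`.
#' @param threshold maximum transgression ratio compatible with a true
#'   relationship (default 0.01, calibrated for ~0.5% genotyping error).
#' @param candidates optional character vector of candidate parent IDs.
#' @return list with `duos` (one row per offspring x candidate: `dtr`, `m`,
#'   `rank`, `pass`) and `trios` (one row per claim: `ttr`, `m`, `pass`;
#'   claims with ungenotyped parents are reported with `NA`, not dropped).
#' @export
scan_parentage <- function(geno, claims, threshold = 0.01,
                           candidates = NULL) {
  g <- dosage_matrix(geno)
  ids <- rownames(g)
  if (is.null(candidates)) candidates <- ids
  duo_rows <- list()
  trio_rows <- list()
  for (k in seq_len(nrow(claims))) {
    off <- as.character(claims$offspring[k])
    p1 <- as.character(claims$parent1[k])
    p2 <- as.character(claims$parent2[k])
    if (!off %in% ids) {
      warning("offspring ", off, " not genotyped; skipped")
      next
    }
    cand <- setdiff(candidates, off)
    dd <- vapply(cand, function(cp) {
      r <- dtr(g, off, cp)
      c(r$dtr, r$m)
    }, numeric(2))
    ord <- order(dd[1, ])
    duo_rows[[off]] <- data.frame(
      offspring = off, candidate = cand[ord], dtr = dd[1, ord],
      m = dd[2, ord], rank = seq_along(cand),
      pass = dd[1, ord] <= threshold, stringsAsFactors = FALSE)
    if (p1 %in% ids && p2 %in% ids) {
      tt <- ttr(g, off, p1, p2)
      trio_rows[[off]] <- data.frame(
        offspring = off, parent1 = p1, parent2 = p2, m = tt$m,
        ttr = tt$ttr, dtr1 = tt$dtr1, dtr2 = tt$dtr2,
        pass = tt$ttr <= threshold, stringsAsFactors = FALSE)
    } else {
      warning("claimed parent(s) of ", off, " not genotyped")
      trio_rows[[off]] <- data.frame(
        offspring = off, parent1 = p1, parent2 = p2, m = NA_integer_,
        ttr = NA_real_, dtr1 = NA_real_, dtr2 = NA_real_, pass = NA,
        stringsAsFactors = FALSE)
    }
  }
  list(duos = do.call(rbind, c(duo_rows, list(make.row.names = FALSE))),
       trios = do.call(rbind, c(trio_rows, list(make.row.names = FALSE))))
}
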