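# Single-locus generation-means theory for heterosis under the dominance
# hypothesis. Genotype value convention: dosages 0, 1, 2 of the favorable
# allele take values -a, d, +a. All quantities are per locus and additive
# across unlinked loci.

#' Single-locus model
#'
#' @param p1,p2 favorable-allele frequencies in populations 1 and 2.
#' @param a additive effect (half the homozygote difference), trait units.
#' @param d dominance deviation, trait units.
#' @return list of class `locus_model`.
#' @export
locus_model <- function(p1, p2 = p1, a = 1, d = 0) {
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1))
    stop("allele frequencies must be in [0, 1]")
  structure(list(p1 = p1, p2 = p2, a = a, d = d), class = "locus_model")
}

#' Hardy-Weinberg population mean at one locus
#'
#' `mean = a (2p - 1) + 2 p (1 - p) d (1 - F)`: the expectation of the
#' genotype values `{-a, d, +a}` over genotype frequencies with inbreeding
#' coefficient `F` (heterozygote frequency `2pq(1-F)`).
#'
#' @param p favorable-allele frequency.
#' @param a,d additive effect and dominance deviation.
#' @param F inbreeding coefficient of the population.
#' @return population mean (vectorized).
#' @export
population_mean <- function(p, a, d, F = 0) {
  a * (2 * p - 1) + 2 * p * (1 - p) * d * (1 - F)
}

#' Panmictic mid-parent heterosis
#'
#' F1 mean between two random-mating populations minus the mid-population
#' mean: `MPH = d (p1 - p2)^2`. Zero when the populations share allele
#' frequencies (the fixation limit) or when there is no dominance.
#'
#' @param model a [locus_model()] (or p1, p2, d given directly).
#' @param p2,d used when `model` is a bare p1.
#' @return MPH in trait units.
#' @export
panmictic_mph <- function(model, p2 = NULL, d = NULL) {
  if (!inherits(model, "locus_model"))
    model <- locus_model(model, p2, d = d)
  model$d * (model$p1 - model$p2)^2
}

#' Inbred-line mid-parent heterosis
#'
#' F1 mean minus the mean of fully inbred (F = 1) parent populations:
#' `d (p1 q2 + p2 q1)`, the expected F1 heterozygosity times the dominance
#' deviation.
#'
#' @param model a [locus_model()].
#' @return inbred-MPH in trait units.
#' @export
inbred_mph <- function(model) {
  p1 <- model$p1; p2 <- model$p2
  model$d * (p1 * (1 - p2) + p2 * (1 - p1))
}

#' Baseline heterosis (inbreeding-depression amount)
#'
#' The population-mean reduction at inbreeding coefficient `F`:
#' `2 p (1 - p) d F` — the heterosis lost as a consequence of inbreeding,
#' vanishing at fixation (`p = 1`) for any `F`.
#'
#' @param p favorable-allele frequency.
#' @param d dominance deviation.
#' @param F inbreeding coefficient in `[0, 1]`.
#' @return trait-unit reduction (vectorized).
#' @export
baseline_heterosis <- function(p, d, F) {
  if (any(F < 0) || any(F > 1)) stop("F must be in [0, 1]")
  2 * p * (1 - p) * d * F
}

#' Heterosis decay curve toward fixation
#'
#' Panmictic MPH along monotone allele-frequency trajectories; as
#' `|p1 - p2|` decreases to 0 (both populations approaching fixation of the
#' favorable allele), MPH decreases monotonically to 0. Multi-locus models
#' sum per-locus curves.
#'
#' @param p1_seq,p2_seq allele-frequency trajectories (equal length;
#'   `p2_seq` is recycled if scalar).
#' @param a,d per-locus effects; vectors give a multi-locus sum.
#' @return data.frame: `step`, `p1`, `p2`, `mph`.
#' @export
heterosis_decay_curve <- function(p1_seq, p2_seq = 1, a = 1, d = 1) {
  p2_seq <- rep_len(p2_seq, length(p1_seq))
  mph <- vapply(seq_along(p1_seq), function(i)
    sum(d * (p1_seq[i] - p2_seq[i])^2), numeric(1))
  data.frame(step = seq_along(p1_seq), p1 = p1_seq, p2 = p2_seq, mph = mph)
}

#' Expected multi-locus MPH for a set of QTLs
#'
#' Bridge between theory and the simulator: with QTL dominance deviations
#' `d_j` and group allele frequencies `p1_j`, `p2_j`, the expected
#' mid-parent heterosis of F1s between the groups is
#' `sum_j d_j (p1_j - p2_j)^2`.
#'
#' @param d per-QTL dominance deviations.
#' @param p1,p2 per-QTL favorable-allele frequencies in the two groups.
#' @return expected MPH in trait units.
#' @export
expected_mph_multilocus <- function(d, p1, p2) {
  sum(d * (p1 - p2)^2)
}
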