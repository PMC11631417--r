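#' Simulation configuration
#'
#' Builds and validates the configuration driving the breeding-population
#' simulator. Defaults emulate a clonal strawberry breeding study: a closed
#' elite pool of 27 moderately inbred founders plus 3 exotic (divergent)
#' founders, 356 elite x elite and 113 elite x exotic F1 hybrids, 31 S1 selfs
#' of 9 elite parents, a genome-wide sample of 5,000 array SNPs on 28
#' chromosomes, and a two-year randomized complete block trial with three
#' blocks.
#'
#' @param n_elite_founders number of elite-group founders.
#' @param n_exotic_founders number of exotic-group founders.
#' @param n_markers number of biallelic SNP markers.
#' @param n_chromosomes number of chromosomes markers are spread over.
#' @param divergence Balding-Nichols allele-frequency divergence (an FST-like
#'   quantity in `[0,1]`) between the elite and exotic groups.
#' @param elite_inbreeding within-group inbreeding coefficient used when
#'   drawing elite founder genotypes (elite breeding pools are partially
#'   inbred; exotic founders are drawn at Hardy-Weinberg).
#' @param ancestral_freq_range range of the uniform ancestral allele
#'   frequency distribution.
#' @param n_elite_hybrids,n_exotic_hybrids number of elite x elite and
#'   elite x exotic F1 individuals produced by [simulate_population()].
#' @param n_s1,n_s1_parents number of S1 (selfed) individuals and the number
#'   of elite parents they descend from.
#' @param traits named list of per-trait genetic architectures; each element
#'   is a list with fields `n_qtl`, `additive_effect_scale` (SD of additive
#'   effects, trait units), `delta_mean`/`delta_sd` (distribution of the
#'   dominance ratio delta = d/|a|; mean > 0 encodes directional dominance),
#'   `load_fraction` (proportion of QTLs carrying partially recessive
#'   deleterious alleles), `mu` (trait intercept), and `type` ("total" for
#'   season-accumulated traits whose plot value is split across harvests,
#'   "mean" for level traits observed at each harvest). See
#'   [default_trait_specs()].
#' @param sigma2_block,sigma2_year,sigma2_gxy,sigma2_resid variance
#'   components (trait units squared) of the trial model: block, year,
#'   genotype x year, and plot residual.
#' @param n_years,n_blocks,n_harvests trial dimensions. Harvest-level records
#'   are generated by splitting the plot-season value across harvests (plus
#'   optional harvest noise `harvest_sd`) and are meant to be aggregated back
#'   to plot level before modelling.
#' @param harvest_sd SD of within-plot harvest noise (trait units).
#' @param genotype_error_rate,missing_rate per-call genotyping error and
#'   missingness probabilities applied by [inject_errors()].
#' @param linkage if `TRUE`, gametes are generated with per-chromosome
#'   linkage under a Haldane map (marker positions read as cM); default
#'   unlinked.
#' @param seed integer seed; identical seeds give bit-identical output.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_elite_founders = 27L,
                       n_exotic_founders = 3L,
                       n_markers = 5000L,
                       n_chromosomes = 28L,
                       divergence = 0.2,
                       elite_inbreeding = 0.1,
                       ancestral_freq_range = c(0.15, 0.85),
                       n_elite_hybrids = 356L,
                       n_exotic_hybrids = 113L,
                       n_s1 = 31L,
                       n_s1_parents = 9L,
                       traits = default_trait_specs(),
                       sigma2_block = 2,
                       sigma2_year = 2,
                       sigma2_gxy = 5,
                       sigma2_resid = 20,
                       n_years = 2L,
                       n_blocks = 3L,
                       n_harvests = 1L,
                       harvest_sd = 0,
                       genotype_error_rate = 0,
                       missing_rate = 0,
                       linkage = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_elite_founders = as.integer(n_elite_founders),
    n_exotic_founders = as.integer(n_exotic_founders),
    n_markers = as.integer(n_markers),
    n_chromosomes = as.integer(n_chromosomes),
    divergence = divergence,
    elite_inbreeding = elite_inbreeding,
    ancestral_freq_range = ancestral_freq_range,
    n_elite_hybrids = as.integer(n_elite_hybrids),
    n_exotic_hybrids = as.integer(n_exotic_hybrids),
    n_s1 = as.integer(n_s1),
    n_s1_parents = as.integer(n_s1_parents),
    traits = traits,
    sigma2_block = sigma2_block,
    sigma2_year = sigma2_year,
    sigma2_gxy = sigma2_gxy,
    sigma2_resid = sigma2_resid,
    n_years = as.integer(n_years),
    n_blocks = as.integer(n_blocks),
    n_harvests = as.integer(n_harvests),
    harvest_sd = harvest_sd,
    genotype_error_rate = genotype_error_rate,
    missing_rate = missing_rate,
    linkage = isTRUE(linkage),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  counts <- c("n_elite_founders", "n_markers", "n_chromosomes",
              "n_years", "n_blocks", "n_harvests")
  for (nm in counts) stop_if(cfg[[nm]] < 1L, paste0(nm, " must be >= 1"))
  stop_if(cfg$n_exotic_founders < 0L, "n_exotic_founders must be >= 0")
  probs <- c("divergence", "elite_inbreeding", "genotype_error_rate",
             "missing_rate")
  for (nm in probs) {
    stop_if(cfg[[nm]] < 0 || cfg[[nm]] > 1,
            paste0(nm, " must be in [0, 1]"))
  }
  vars <- c("sigma2_block", "sigma2_year", "sigma2_gxy", "sigma2_resid",
            "harvest_sd")
  for (nm in vars) stop_if(cfg[[nm]] < 0, paste0(nm, " must be >= 0"))
  stop_if(length(cfg$ancestral_freq_range) != 2L ||
            any(cfg$ancestral_freq_range <= 0) ||
            any(cfg$ancestral_freq_range >= 1) ||
            diff(cfg$ancestral_freq_range) < 0,
          "ancestral_freq_range must be an increasing pair inside (0, 1)")
  stop_if(cfg$n_s1 > 0 && cfg$n_s1_parents > cfg$n_elite_founders,
          "n_s1_parents cannot exceed n_elite_founders")
  stop_if(cfg$n_s1 > 0 && cfg$n_s1_parents < 1,
          "n_s1_parents must be >= 1 when S1s are requested")
  for (tr in names(cfg$traits)) {
    spec <- cfg$traits[[tr]]
    stop_if(spec$n_qtl < 0, paste0("trait ", tr, ": n_qtl must be >= 0"))
    stop_if(spec$n_qtl > cfg$n_markers,
            paste0("trait ", tr, ": n_qtl cannot exceed n_markers"))
    stop_if(spec$additive_effect_scale < 0,
            paste0("trait ", tr, ": additive_effect_scale must be >= 0"))
    stop_if(spec$load_fraction < 0 || spec$load_fraction > 1,
            paste0("trait ", tr, ": load_fraction must be in [0, 1]"))
    stop_if(!is.null(spec$type) && !spec$type %in% c("total", "mean"),
            paste0("trait ", tr, ": type must be 'total' or 'mean'"))
  }
  invisible(cfg)
}

#' Default trait architectures
#'
#' Two contrasting architectures: a "yield"-like trait with strong
#' directional dominance (mean dominance ratio 0.8) and a fifth of its QTLs
#' carrying partially recessive deleterious alleles, and an "anc"-like
#' (anthocyanin-like, unselected) trait with no directional bias. These are
#' the two regimes needed to show inbreeding depression / heterosis for
#' selected traits and neither for an unselected trait.
#'
#' @param yield_delta_mean mean dominance ratio for the yield-like trait.
#' @return named list of trait specifications.
#' @export
default_trait_specs <- function(yield_delta_mean = 0.8) {
  list(
    yield = list(n_qtl = 100L, additive_effect_scale = 1,
                 delta_mean = yield_delta_mean, delta_sd = 0.3,
                 load_fraction = 0.2, mu = 100, type = "total"),
    anc = list(n_qtl = 100L, additive_effect_scale = 1,
               delta_mean = 0, delta_sd = 0.3,
               load_fraction = 0, mu = 100, type = "mean")
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      x$n_elite_founders, "elite +", x$n_exotic_founders, "exotic founders;",
      x$n_markers, "markers on", x$n_chromosomes, "chromosomes;",
      "divergence", x$divergence, "\n")
  cat("  progeny:", x$n_elite_hybrids, "elite x elite,",
      x$n_exotic_hybrids, "elite x exotic,", x$n_s1, "S1\n")
  cat("  trial:", x$n_years, "years x", x$n_blocks, "blocks x",
      x$n_harvests, "harvests; traits:",
      paste(names(x$traits), collapse = ", "), "\n")
  invisible(x)
}
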