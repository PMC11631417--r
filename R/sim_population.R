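# Breeding-population simulator: founders from diverged allele-frequency
# pools, biparental F1s, S1 selfs, QTL effects with directional dominance,
# and multi-year randomized complete block trial phenotypes.

#' Simulate founder genotypes for two diverged groups
#'
#' Ancestral allele frequencies are drawn uniformly on
#' `config$ancestral_freq_range`; elite- and exotic-group frequencies are
#' then drawn from a Balding-Nichols distribution around the ancestral
#' frequency with divergence parameter `config$divergence` (at divergence 0
#' both groups share the ancestral frequencies exactly). Elite founders are
#' drawn with within-group inbreeding `config$elite_inbreeding`; exotic
#' founders at Hardy-Weinberg.
#'
#' @param config a [sim_config()].
#' @return a [snp_geno] with attributes `group` (character vector,
#'   "elite"/"exotic" per individual), `freq_elite`, `freq_exotic`
#'   (per-marker group allele frequencies used for the draws), and
#'   `pedigree` (founders have `NA` parents).
#' @export
simulate_founders <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  m <- config$n_markers
  p0 <- runif(m, config$ancestral_freq_range[1], config$ancestral_freq_range[2])
  fst <- config$divergence
  if (fst == 0) {
    p_elite <- p0
    p_exotic <- p0
  } else if (fst == 1) {
    p_elite <- rbinom(m, 1, p0)
    p_exotic <- rbinom(m, 1, p0)
  } else {
    shape <- (1 - fst) / fst
    p_elite <- stats::rbeta(m, p0 * shape, (1 - p0) * shape)
    p_exotic <- stats::rbeta(m, p0 * shape, (1 - p0) * shape)
  }
  ids_e <- sprintf("E%02d", seq_len(config$n_elite_founders))
  ids_x <- if (config$n_exotic_founders > 0)
    sprintf("X%02d", seq_len(config$n_exotic_founders)) else character(0)
  ge <- draw_genotypes(config$n_elite_founders, p_elite,
                       f = config$elite_inbreeding)
  gx <- draw_genotypes(config$n_exotic_founders, p_exotic, f = 0)
  g <- rbind(ge, gx)
  rownames(g) <- c(ids_e, ids_x)
  map <- founder_map(m, config$n_chromosomes)
  colnames(g) <- map$marker
  out <- snp_geno(g, map)
  attr(out, "group") <- setNames(
    rep(c("elite", "exotic"), c(length(ids_e), length(ids_x))),
    c(ids_e, ids_x))
  attr(out, "freq_elite") <- p_elite
  attr(out, "freq_exotic") <- p_exotic
  attr(out, "pedigree") <- data.frame(
    id = c(ids_e, ids_x), parent1 = NA_character_, parent2 = NA_character_,
    group = rep(c("elite", "exotic"), c(length(ids_e), length(ids_x))),
    stringsAsFactors = FALSE)
  out
}

founder_map <- function(n_markers, n_chromosomes) {
  chrom <- sort(rep_len(seq_len(n_chromosomes), n_markers))
  pos <- unlist(lapply(split(seq_len(n_markers), chrom), seq_along),
                use.names = FALSE)
  data.frame(marker = sprintf("mk%05d", seq_len(n_markers)),
             chrom = paste0("chr", chrom),
             pos = pos * 100000L,  # ~0.1 cM spacing when read as cM/1e6
             ref = "A", alt = "B", stringsAsFactors = FALSE)
}

# genotype draws with inbreeding f: P(0) = q^2 + f p q, P(1) = 2pq(1 - f),
# P(2) = p^2 + f p q, p = alt allele frequency
draw_genotypes <- function(n, p, f = 0) {
  m <- length(p)
  if (n == 0) return(matrix(integer(0), nrow = 0, ncol = m))
  q <- 1 - p
  p0 <- q * q + f * p * q
  p1 <- 2 * p * q * (1 - f)
  u <- matrix(runif(n * m), nrow = n)
  thr0 <- matrix(p0, nrow = n, ncol = m, byrow = TRUE)
  thr1 <- matrix(p0 + p1, nrow = n, ncol = m, byrow = TRUE)
  g <- (u >= thr0) + (u >= thr1)
  storage.mode(g) <- "integer"
  g
}

#' Cross two genotyped parents
#'
#' Each offspring receives one allele per marker from each parent:
#' homozygous parents transmit their allele deterministically, heterozygous
#' parents transmit either allele with probability 1/2. Markers are unlinked
#' by default; with `linkage = TRUE` gametes follow per-chromosome Haldane
#' recombination with marker positions read as centimorgans (`pos / 1e6`),
#' after a one-time random phasing of each parent's heterozygous calls.
#'
#' @param p1,p2 parent dosage vectors (or 1-row matrices) over the same
#'   markers; names/columns must agree.
#' @param n_offspring number of offspring to generate.
#' @param map optional marker map (required for linkage).
#' @param linkage logical; simulate linked transmission.
#' @param ids optional offspring IDs.
#' @return integer dosage matrix, `n_offspring` x markers.
#' @export
cross <- function(p1, p2, n_offspring, map = NULL, linkage = FALSE,
                  ids = NULL) {
  p1 <- as_parent_vector(p1)
  p2 <- as_parent_vector(p2)
  if (length(p1) != length(p2) ||
      (!is.null(names(p1)) && !is.null(names(p2)) &&
       !identical(names(p1), names(p2))))
    stop("parents must be genotyped at the same markers")
  if (any(is.na(p1)) || any(is.na(p2)))
    stop("parent genotypes must be nonmissing; impute or drop markers first")
  m <- length(p1)
  g1 <- gametes(p1, n_offspring, map, linkage)
  g2 <- gametes(p2, n_offspring, map, linkage)
  g <- g1 + g2
  storage.mode(g) <- "integer"
  colnames(g) <- names(p1)
  rownames(g) <- if (is.null(ids)) paste0("off", seq_len(n_offspring)) else ids
  g
}

as_parent_vector <- function(p) {
  if (inherits(p, "snp_geno")) p <- p$geno
  if (is.matrix(p)) {
    if (nrow(p) != 1) stop("parent must be a single individual")
    p <- p[1, ]
  }
  p
}

gametes <- function(g, n, map = NULL, linkage = FALSE) {
  m <- length(g)
  if (!linkage) {
    het <- matrix(g == 1, nrow = n, ncol = m, byrow = TRUE)
    base <- matrix(as.integer(g == 2), nrow = n, ncol = m, byrow = TRUE)
    coin <- matrix(rbinom(n * m, 1, 0.5), nrow = n)
    return(base + het * coin)
  }
  if (is.null(map)) stop("linkage requires a marker map")
  # random one-time phasing of heterozygous calls
  hap1 <- as.integer(g == 2)
  het_idx <- which(g == 1)
  flip <- rbinom(length(het_idx), 1, 0.5)
  hap1[het_idx] <- flip
  hap2 <- as.integer(g) - hap1
  cm <- map$pos / 1e6
  out <- matrix(0L, nrow = n, ncol = m)
  for (chr in unique(map$chrom)) {
    j <- which(map$chrom == chr)
    d <- diff(cm[j])
    rf <- 0.5 * (1 - exp(-2 * d / 100))  # Haldane, d in cM
    state <- matrix(0L, nrow = n, ncol = length(j))
    state[, 1] <- rbinom(n, 1, 0.5)
    if (length(j) > 1) {
      for (k in 2:length(j)) {
        swap <- rbinom(n, 1, rf[k - 1])
        state[, k] <- (state[, k - 1] + swap) %% 2L
      }
    }
    h1 <- matrix(hap1[j], nrow = n, ncol = length(j), byrow = TRUE)
    h2 <- matrix(hap2[j], nrow = n, ncol = length(j), byrow = TRUE)
    out[, j] <- ifelse(state == 0L, h1, h2)
  }
  out
}

#' Self-pollinate a genotyped parent
#'
#' Equivalent to `cross(parent, parent, ...)`: expected offspring
#' heterozygosity is half the parent's at every unlinked marker.
#'
#' @inheritParams cross
#' @param parent parent dosage vector.
#' @return integer dosage matrix of S1 offspring.
#' @export
self_cross <- function(parent, n_offspring, map = NULL, linkage = FALSE,
                       ids = NULL) {
  cross(parent, parent, n_offspring, map = map, linkage = linkage, ids = ids)
}

#' Draw QTL effects for each trait
#'
#' For each trait, `n_qtl` markers are sampled as causal. Additive effects
#' `a ~ N(0, scale^2)`; dominance deviations `d = delta * |a|` with
#' `delta ~ N(delta_mean, delta_sd)`. A `load_fraction` of the QTLs is
#' treated as deleterious-recessive load loci: the favorable allele is forced
#' to be the alternate allele (`a = |a|`) and its dominance ratio is drawn
#' near complete dominance (`delta ~ N(0.9, 0.1)`), so the deleterious allele
#' is partially recessive and hidden in heterozygotes.
#'
#' @param config a [sim_config()].
#' @param map marker map of the simulated genotypes.
#' @return data.frame (one row per QTL x trait): `trait`, `marker`, `a`, `d`.
#' @export
draw_qtl_effects <- function(config, map) {
  out <- list()
  for (tr in names(config$traits)) {
    spec <- config$traits[[tr]]
    if (spec$n_qtl == 0) next
    idx <- sample.int(nrow(map), spec$n_qtl)
    a <- rnorm(spec$n_qtl, 0, spec$additive_effect_scale)
    delta <- rnorm(spec$n_qtl, spec$delta_mean, spec$delta_sd)
    n_load <- round(spec$load_fraction * spec$n_qtl)
    if (n_load > 0) {
      li <- seq_len(n_load)
      a[li] <- abs(a[li])
      delta[li] <- rnorm(n_load, 0.9, 0.1)
    }
    out[[tr]] <- data.frame(trait = tr, marker = map$marker[idx],
                            a = a, d = delta * abs(a),
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(trait = character(0), marker = character(0),
                      a = numeric(0), d = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' True genetic values from QTL effects
#'
#' Genotype effect at each QTL: dosage 0 -> `-a`, 1 -> `d`, 2 -> `+a`.
#' Missing calls contribute the marker-mean effect.
#'
#' @param geno genotypes ([snp_geno] or dosage matrix).
#' @param qtl data.frame as returned by [draw_qtl_effects()].
#' @return matrix of genetic values, individuals x traits.
#' @export
genetic_value <- function(geno, qtl) {
  g <- dosage_matrix(geno)
  traits <- unique(qtl$trait)
  out <- matrix(0, nrow = nrow(g), ncol = length(traits),
                dimnames = list(rownames(g), traits))
  for (tr in traits) {
    qq <- qtl[qtl$trait == tr, , drop = FALSE]
    miss <- setdiff(qq$marker, colnames(g))
    if (length(miss) > 0)
      stop("QTL markers must be a subset of genotyped markers")
    gm <- g[, qq$marker, drop = FALSE]
    # value(dosage) = (dosage - 1) * a for homozygotes, d for heterozygotes
    val <- sweep(gm - 1, 2, qq$a, `*`)
    hz <- !is.na(gm) & gm == 1
    dmat <- matrix(qq$d, nrow = nrow(gm), ncol = nrow(qq), byrow = TRUE)
    val[hz] <- dmat[hz]
    if (anyNA(val)) {
      cm <- colMeans(val, na.rm = TRUE)
      nas <- which(is.na(val), arr.ind = TRUE)
      val[nas] <- cm[nas[, 2]]
    }
    out[, tr] <- rowSums(val)
  }
  out
}

#' Simulate trial phenotypes
#'
#' Plot value = `mu + genetic value + block + year + genotype:year +
#' residual`, each random term Gaussian with the configured variance. When
#' `config$n_harvests > 1`, a "total"-type trait's plot-season value is
#' split evenly across harvests (sum-aggregate to recover it) while a
#' "mean"-type trait is observed at its plot level at every harvest
#' (mean-aggregate); per-harvest noise with SD `config$harvest_sd` is added
#' either way. Aggregate back with [aggregate_harvests()] before modelling.
#'
#' @param geno genotypes of the phenotyped individuals.
#' @param truth list with elements `qtl` (from [draw_qtl_effects()]) and
#'   optionally `genetic_values`; values are computed if absent.
#' @param config a [sim_config()].
#' @return long data.frame: `individual`, `block`, `year`, `harvest`,
#'   `trait`, `value`, with attribute `effects` holding the drawn random
#'   effects (ground truth).
#' @export
simulate_phenotypes <- function(geno, truth, config) {
  g <- dosage_matrix(geno)
  ids <- rownames(g)
  gv <- truth$genetic_values
  if (is.null(gv)) gv <- genetic_value(geno, truth$qtl)
  traits <- colnames(gv)
  n <- length(ids)
  ny <- config$n_years
  nb <- config$n_blocks
  nh <- config$n_harvests
  recs <- vector("list", length(traits))
  effects <- list()
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    mu <- config$traits[[tr]]$mu
    if (is.null(mu)) mu <- 0
    blk <- rnorm(nb, 0, sqrt(config$sigma2_block))
    yr <- rnorm(ny, 0, sqrt(config$sigma2_year))
    gxy <- matrix(rnorm(n * ny, 0, sqrt(config$sigma2_gxy)), nrow = n)
    eps <- array(rnorm(n * nb * ny, 0, sqrt(config$sigma2_resid)),
                 dim = c(n, nb, ny))
    idx <- expand.grid(ind = seq_len(n), block = seq_len(nb),
                       year = seq_len(ny))
    plot_val <- mu + gv[idx$ind, tr] + blk[idx$block] + yr[idx$year] +
      gxy[cbind(idx$ind, idx$year)] + eps[cbind(idx$ind, idx$block, idx$year)]
    if (nh > 1) {
      type <- config$traits[[tr]]$type
      if (is.null(type)) type <- "total"
      hidx <- idx[rep(seq_len(nrow(idx)), each = nh), ]
      harvest <- rep(seq_len(nh), nrow(idx))
      base <- plot_val[rep(seq_len(nrow(idx)), each = nh)]
      # season totals are split across harvests; level traits are observed
      # (with harvest noise) at each harvest
      if (type == "total") base <- base / nh
      val <- base + rnorm(nrow(hidx), 0, config$harvest_sd)
      recs[[ti]] <- data.frame(individual = ids[hidx$ind],
                               block = paste0("B", hidx$block),
                               year = paste0("Y", hidx$year),
                               harvest = harvest, trait = tr, value = val,
                               stringsAsFactors = FALSE)
    } else {
      recs[[ti]] <- data.frame(individual = ids[idx$ind],
                               block = paste0("B", idx$block),
                               year = paste0("Y", idx$year),
                               harvest = 1L, trait = tr, value = plot_val,
                               stringsAsFactors = FALSE)
    }
    effects[[tr]] <- list(block = blk, year = yr, gxy = gxy)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "effects") <- effects
  out
}

#' Aggregate harvest-level records to plot level
#'
#' Totals (`fun = "sum"`) for yield-like traits, means (`fun = "mean"`) for
#' weight/quality traits; one row per individual x block x year x trait.
#'
#' @param records long phenotype data.frame with a `harvest` column.
#' @param fun "sum" or "mean", recycled over traits, or a named vector by
#'   trait.
#' @return aggregated long data.frame with `harvest` dropped.
#' @export
aggregate_harvests <- function(records, fun = "sum") {
  traits <- unique(records$trait)
  if (is.null(names(fun))) fun <- setNames(rep_len(fun, length(traits)), traits)
  out <- lapply(traits, function(tr) {
    rr <- records[records$trait == tr, , drop = FALSE]
    f <- if (fun[[tr]] == "sum") sum else mean
    agg <- aggregate(value ~ individual + block + year, data = rr, FUN = f)
    agg$trait <- tr
    agg
  })
  out <- do.call(rbind, out)
  out[, c("individual", "block", "year", "trait", "value")]
}

#' Inject genotyping errors and missingness
#'
#' Each call is independently set missing with probability `missing_rate`;
#' surviving calls are perturbed to a different dosage state (uniformly over
#' the other two states) with probability `error_rate`.
#'
#' @param geno genotypes ([snp_geno] or dosage matrix).
#' @param error_rate,missing_rate probabilities in `[0, 1]`.
#' @param seed optional seed for reproducibility.
#' @return object of the same type as the input.
#' @export
inject_errors <- function(geno, error_rate = 0, missing_rate = 0,
                          seed = NULL) {
  if (error_rate < 0 || error_rate > 1 || missing_rate < 0 || missing_rate > 1)
    stop("rates must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  g <- dosage_matrix(geno)
  n <- length(g)
  if (missing_rate > 0) g[runif(n) < missing_rate] <- NA
  if (error_rate > 0) {
    hit <- which(!is.na(g) & runif(n) < error_rate)
    if (length(hit) > 0) {
      old <- g[hit]
      shift <- sample(1:2, length(hit), replace = TRUE)
      g[hit] <- (old + shift) %% 3
    }
  }
  storage.mode(g) <- "integer"
  if (inherits(geno, "snp_geno")) snp_geno(g, geno$map) else g
}

#' Simulate a full study population with truth records
#'
#' Founders, an incomplete-factorial set of elite x elite crosses, elite x
#' exotic crosses, S1 selfs of a subset of elite parents, QTL effects, and
#' true genetic values — the population structure every downstream stage is
#' tested against.
#'
#' @param config a [sim_config()].
#' @return list with `geno` ([snp_geno] of founders + progeny), `truth`
#'   (list: `qtl`, `genetic_values`, `pedigree`, `group`), and `config`.
#' @export
simulate_population <- function(config) {
  founders <- simulate_founders(config)
  map <- founders$map
  grp <- attr(founders, "group")
  elite_ids <- names(grp)[grp == "elite"]
  exotic_ids <- names(grp)[grp == "exotic"]
  fg <- founders$geno

  ped <- attr(founders, "pedigree")
  blocks <- list(fg)

  rand_pairs <- function(pool, n) {
    cbind(pool[sample.int(length(pool), n, replace = TRUE)],
          pool[sample.int(length(pool), n, replace = TRUE)])
  }
  # elite x elite families (distinct parents per cross)
  if (config$n_elite_hybrids > 0) {
    pr <- rand_pairs(elite_ids, config$n_elite_hybrids)
    same <- pr[, 1] == pr[, 2]
    while (any(same)) {
      pr[same, 2] <- elite_ids[sample.int(length(elite_ids), sum(same),
                                          replace = TRUE)]
      same <- pr[, 1] == pr[, 2]
    }
    ids <- sprintf("H%04d", seq_len(config$n_elite_hybrids))
    g <- matrix(0L, nrow = length(ids), ncol = ncol(fg))
    for (i in seq_along(ids))
      g[i, ] <- cross(fg[pr[i, 1], ], fg[pr[i, 2], ], 1, map = map,
                      linkage = config$linkage)
    rownames(g) <- ids
    colnames(g) <- colnames(fg)
    blocks <- c(blocks, list(g))
    ped <- rbind(ped, data.frame(id = ids, parent1 = pr[, 1],
                                 parent2 = pr[, 2], group = "elite_x_elite",
                                 stringsAsFactors = FALSE))
  }
  # elite x exotic families
  if (config$n_exotic_hybrids > 0 && length(exotic_ids) > 0) {
    p1 <- elite_ids[sample.int(length(elite_ids), config$n_exotic_hybrids,
                               replace = TRUE)]
    p2 <- exotic_ids[sample.int(length(exotic_ids), config$n_exotic_hybrids,
                                replace = TRUE)]
    ids <- sprintf("W%04d", seq_len(config$n_exotic_hybrids))
    g <- matrix(0L, nrow = length(ids), ncol = ncol(fg))
    for (i in seq_along(ids))
      g[i, ] <- cross(fg[p1[i], ], fg[p2[i], ], 1, map = map,
                      linkage = config$linkage)
    rownames(g) <- ids
    colnames(g) <- colnames(fg)
    blocks <- c(blocks, list(g))
    ped <- rbind(ped, data.frame(id = ids, parent1 = p1, parent2 = p2,
                                 group = "elite_x_exotic",
                                 stringsAsFactors = FALSE))
  }
  # S1 selfs of a subset of elite parents
  if (config$n_s1 > 0) {
    sp <- elite_ids[seq_len(config$n_s1_parents)]
    par <- sp[rep_len(seq_along(sp), config$n_s1)]
    ids <- sprintf("S%04d", seq_len(config$n_s1))
    g <- matrix(0L, nrow = length(ids), ncol = ncol(fg))
    for (i in seq_along(ids))
      g[i, ] <- self_cross(fg[par[i], ], 1, map = map,
                           linkage = config$linkage)
    rownames(g) <- ids
    colnames(g) <- colnames(fg)
    blocks <- c(blocks, list(g))
    ped <- rbind(ped, data.frame(id = ids, parent1 = par, parent2 = par,
                                 group = "s1", stringsAsFactors = FALSE))
  }
  gall <- do.call(rbind, blocks)
  geno <- snp_geno(gall, map)
  qtl <- draw_qtl_effects(config, map)
  gv <- matrix(0, nrow(gall), length(config$traits),
               dimnames = list(rownames(gall), names(config$traits)))
  if (nrow(qtl) > 0) {
    gvq <- genetic_value(geno, qtl)
    gv[, colnames(gvq)] <- gvq
  }
  group <- setNames(ped$group, ped$id)
  group[names(grp)] <- grp
  truth <- list(qtl = qtl, genetic_values = gv, pedigree = ped, group = group)
  list(geno = geno, truth = truth, config = config)
}
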