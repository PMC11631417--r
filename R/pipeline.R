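# End-to-end orchestration on simulated (or supplied) data, plus the report
# arithmetic used for S0-vs-S1 inbreeding-depression tables and
# heterozygous-gene bounds.

#' Run the full analysis pipeline
#'
#' Ordered stages over a simulated population: QC -> diversity/GRM/PCA ->
#' parentage forensics -> trial LMM + EMMs -> heterosis contrasts and
#' classification -> trait-on-heterozygosity regressions -> directional
#' dominance fit -> marker scan -> theory decay curves. Every stage's
#' outputs are returned in a bundle (and written as CSV when `out_dir` is
#' given) together with a run manifest (seed, thresholds, stage timings).
#' Outputs are pure functions of `(config, alpha, qc)`.
#'
#' @param config a [sim_config()]; the population and trial are simulated
#'   from it.
#' @param out_dir optional output directory for CSVs.
#' @param alpha per-contrast significance level.
#' @param qc list of QC thresholds (`maf_min`, `max_missing`,
#'   `min_call_rate`).
#' @param scan_trait trait used for the marker scan and dominance fits.
#' @return a named list (the report bundle).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         alpha = 0.05,
                         qc = list(maf_min = 0.05, max_missing = 0.10,
                                   min_call_rate = 0.90),
                         scan_trait = names(config$traits)[1]) {
  t0 <- Sys.time()
  stage_times <- c()
  tick <- function(nm) {
    stage_times[[nm]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  }
  pop <- simulate_population(config)
  geno <- pop$geno
  ped <- pop$truth$pedigree
  tick("simulate")

  geno_qc <- filter_markers_and_samples(geno, qc$maf_min, qc$max_missing,
                                        qc$min_call_rate)
  qc_report <- attr(geno_qc, "qc_report")
  tick("qc")

  div <- diversity_summary(geno_qc)
  ids <- rownames(geno_qc$geno)
  grp <- pop$truth$group[ids]
  parents <- ids[grp %in% c("elite", "exotic")]
  hybrids <- ids[grp %in% c("elite_x_elite", "elite_x_exotic")]
  ne_all <- if (length(parents) && length(hybrids))
    effective_population_size(mean(div$ho[parents]), mean(div$ho[hybrids]))
  else NA_real_
  K_A <- additive_grm(geno_qc)
  K_D <- dominance_grm(geno_qc)
  pca <- pca_scores(geno_qc, 2)
  tick("diversity")

  claims <- data.frame(offspring = ped$id[!is.na(ped$parent1)],
                       parent1 = ped$parent1[!is.na(ped$parent1)],
                       parent2 = ped$parent2[!is.na(ped$parent1)],
                       stringsAsFactors = FALSE)
  claims <- claims[claims$offspring %in% ids, , drop = FALSE]
  forensics <- scan_parentage(geno_qc, claims,
                              candidates = intersect(parents, ids))
  tick("forensics")

  records <- simulate_phenotypes(geno, pop$truth, config)
  agg_fun <- vapply(config$traits, function(s)
    if (identical(s$type, "mean")) "mean" else "sum", character(1))
  plot_recs <- if (config$n_harvests > 1)
    aggregate_harvests(records, agg_fun) else records
  traits <- names(config$traits)
  emm_list <- list()
  vc_list <- list()
  h2_list <- list()
  for (tr in traits) {
    ff <- fit_trial_lmm(plot_recs, "fixed", trait = tr)
    emm_list[[tr]] <- estimate_emms(ff)
    fr <- fit_trial_lmm(plot_recs, "random", trait = tr)
    vc <- variance_components(fr)
    vc_list[[tr]] <- vc
    rr <- harmonic_mean_reps(plot_recs[plot_recs$trait == tr, ]) /
      config$n_years
    h2_list[[tr]] <- broad_sense_heritability(vc, config$n_years, rr)
  }
  tick("trial_lmm")

  ped_h <- ped[ped$group %in% c("elite_x_elite", "elite_x_exotic"), ]
  names(ped_h)[names(ped_h) == "id"] <- "hybrid"
  ped_h$cross_class <- ped_h$group
  het_list <- list()
  class_list <- list()
  for (tr in traits) {
    het_list[[tr]] <- heterosis_contrasts(emm_list[[tr]], ped_h)
    class_list[[tr]] <- classify_contrasts(het_list[[tr]], alpha)
  }
  tick("heterosis")

  tr <- scan_trait
  emms <- emm_list[[tr]]
  hy_ids <- intersect(emms$individual, ped_h$hybrid)
  hvec <- div$ho[hy_ids]
  resp <- setNames(emms$emmean[match(hy_ids, emms$individual)], hy_ids)
  hreg <- heterozygosity_regression(resp, hvec, K_A = K_A, K_D = K_D)
  tick("h_regression")

  ho_all <- div$ho[emms$individual]
  yv <- setNames(emms$emmean, emms$individual)
  hod1 <- fit_hod_model(yv, 1 - ho_all, K_A, K_D, degree = 1)
  hod2 <- fit_hod_model(yv, 1 - ho_all, K_A, K_D, degree = 2)
  hod_cmp <- compare_degree(hod1, hod2)
  tick("dominance")

  scan <- marker_scan(yv, geno_qc, K_A)
  tick("scan")

  theory <- heterosis_decay_curve(seq(0.5, 1, by = 0.05), 1, d = 1)
  tick("theory")

  bundle <- list(config = config, geno = geno_qc, truth = pop$truth,
                 qc_report = qc_report, diversity = div, ne_all = ne_all,
                 K_A = K_A, K_D = K_D, pca = pca, forensics = forensics,
                 records = plot_recs, emms = emm_list,
                 variance_components = vc_list, H2 = h2_list,
                 heterosis = het_list, classification = class_list,
                 h_regression = hreg, hod = list(degree1 = hod1,
                                                 degree2 = hod2,
                                                 comparison = hod_cmp),
                 scan = scan, theory = theory,
                 manifest = list(seed = config$seed, alpha = alpha, qc = qc,
                                 r_version = as.character(getRversion()),
                                 stage_seconds = stage_times))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  write.csv(bundle$qc_report, fp("qc_report.csv"), row.names = FALSE)
  div <- data.frame(individual = names(bundle$diversity$ho),
                    ho = bundle$diversity$ho,
                    f_1mh = bundle$diversity$f_1mh,
                    f_excess = bundle$diversity$f_excess)
  write.csv(div, fp("diversity.csv"), row.names = FALSE)
  write.csv(data.frame(individual = rownames(bundle$pca$scores),
                       bundle$pca$scores),
            fp("pca_scores.csv"), row.names = FALSE)
  write.csv(bundle$forensics$duos, fp("forensics_duos.csv"),
            row.names = FALSE)
  write.csv(bundle$forensics$trios, fp("forensics_trios.csv"),
            row.names = FALSE)
  for (tr in names(bundle$emms)) {
    write.csv(bundle$emms[[tr]], fp(paste0("emm_", tr, ".csv")),
              row.names = FALSE)
    write.csv(bundle$heterosis[[tr]], fp(paste0("heterosis_", tr, ".csv")),
              row.names = FALSE)
  }
  write.csv(bundle$scan, fp("scan.csv"), row.names = FALSE)
  write.csv(bundle$theory, fp("theory_decay.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' S0-vs-S1 inbreeding-depression contrast table
#'
#' Given generation means for S0 parents and their S1 selfed offspring,
#' returns `contrast = s0 - s1` and `pct_change = 100 * (s1 - s0) / s0`
#' (negative when selfing depresses the trait).
#'
#' @param s0_means,s1_means named numeric vectors (names = traits), aligned.
#' @return data.frame: `trait`, `s0`, `s1`, `contrast`, `pct_change`.
#' @export
inbreeding_contrast_table <- function(s0_means, s1_means) {
  if (length(s0_means) != length(s1_means))
    stop("S0 and S1 means must align")
  traits <- names(s0_means)
  if (is.null(traits)) traits <- paste0("trait", seq_along(s0_means))
  data.frame(trait = traits, s0 = unname(s0_means), s1 = unname(s1_means),
             contrast = unname(s0_means - s1_means),
             pct_change = unname(100 * (s1_means - s0_means) / s0_means),
             stringsAsFactors = FALSE)
}

#' Heterozygous-gene bounds from inbreeding and gene counts
#'
#' For a genome with `genes` annotated genes and inbreeding coefficient
#' `F`, the expected number of heterozygous (segregating) genes is
#' `(1 - F) * genes`. Given ranges for both, returns the bounds: the lower
#' bound pairs the largest `F` with the smallest gene count and vice versa.
#'
#' @param f_range inbreeding-coefficient range `c(min, max)`.
#' @param gene_range annotated gene-count range `c(min, max)`.
#' @return named vector `c(lower, upper)`.
#' @export
heterozygous_gene_bounds <- function(f_range, gene_range) {
  c(lower = (1 - max(f_range)) * min(gene_range),
    upper = (1 - min(f_range)) * max(gene_range))
}

#' Summary report tables from a pipeline bundle
#'
#' Builds the inbreeding-depression (S0 vs S1), heterosis-classification,
#' and worst-parent summary tables from a completed [run_pipeline()]
#' bundle. Missing stages are omitted with a note.
#'
#' @param bundle a [run_pipeline()] result.
#' @return list of data.frames: `inbreeding` (per-trait S0/S1 EMM means,
#'   contrast, percent change), `mph`, `bph`, `worst` (per trait x cross
#'   class), `notes`.
#' @export
make_report <- function(bundle) {
  notes <- character(0)
  inb <- NULL
  if (!is.null(bundle$emms) && !is.null(bundle$truth)) {
    grp <- bundle$truth$group
    s0_ids <- names(grp)[grp == "elite"]
    s1_ids <- names(grp)[grp == "s1"]
    s1_par <- unique(bundle$truth$pedigree$parent1[
      bundle$truth$pedigree$group == "s1"])
    s0_ids <- intersect(s0_ids, s1_par)
    rows <- lapply(names(bundle$emms), function(tr) {
      em <- bundle$emms[[tr]]
      s0 <- mean(em$emmean[em$individual %in% s0_ids])
      s1 <- mean(em$emmean[em$individual %in% s1_ids])
      cbind(trait = tr, inbreeding_contrast_table(setNames(s0, tr),
                                                  setNames(s1, tr))[, -1])
    })
    inb <- do.call(rbind, rows)
    # heterozygosity row: from genotypes, same contrast arithmetic
    ho <- bundle$diversity$ho
    if (length(intersect(names(ho), s1_ids)) > 0) {
      h0 <- mean(ho[intersect(names(ho), s0_ids)])
      h1 <- mean(ho[intersect(names(ho), s1_ids)])
      inb <- rbind(cbind(trait = "heterozygosity",
                         inbreeding_contrast_table(setNames(h0, "h"),
                                                   setNames(h1, "h"))[, -1]),
                   inb)
    }
  } else {
    notes <- c(notes, "EMM stage missing: inbreeding table omitted")
  }
  mph <- bph <- worst <- NULL
  if (!is.null(bundle$classification)) {
    add_tr <- function(which_tab) {
      do.call(rbind, lapply(names(bundle$classification), function(tr)
        cbind(trait = tr, bundle$classification[[tr]][[which_tab]])))
    }
    mph <- add_tr("mph")
    bph <- add_tr("bph")
    worst <- add_tr("worst")
  } else {
    notes <- c(notes, "classification stage missing: heterosis tables omitted")
  }
  list(inbreeding = inb, mph = mph, bph = bph, worst = worst, notes = notes)
}
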