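#!/usr/bin/env Rscript
# Stage 1 — simulate the study population and trial.
# Writes the small truth tables (pedigree, QTL effects) under results/ and
# the bulk data (genotype CSV + VCF, harvest-level phenotypes) under
# scratch/sim/ for the downstream stages.

source("analysis/00_config.R")

pop <- simulate_population(study_config)
records <- simulate_phenotypes(pop$geno, pop$truth, study_config)

write_dosage_csv(pop$geno, file.path(sim_dir, "genotypes.csv"))
write_vcf(pop$geno, file.path(sim_dir, "genotypes.vcf"))
write_pedigree_csv(pop$truth$pedigree, file.path(results_dir, "pedigree.csv"))
write.csv(pop$truth$qtl, file.path(results_dir, "qtl_truth.csv"),
          row.names = FALSE)
write_phenotypes_csv(records, file.path(sim_dir, "phenotypes.csv"))

grp <- pop$truth$group
cat("simulated", nrow(pop$geno$geno), "individuals x",
    ncol(pop$geno$geno), "markers:\n")
print(table(grp))
cat(nrow(records), "harvest-level phenotype records for",
    length(unique(records$trait)), "traits\n")
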