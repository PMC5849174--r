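#!/usr/bin/env Rscript
# Stage 1: generate the two-cohort case-control study.
#
# The preset panel carries 51 candidate SNPs: 5 rare variants (EAF < 0.5%,
# ORs 2.6-4.9), a 4-SNP LD block (r2 ~ 0.85) tagging one causal SNP
# (OR 1.4), 7 independent causal SNPs (ORs 1.15-1.30) and 35 nulls. Cohort 1
# (1294 cases / 885 controls) trains association statistics; cohort 2
# (301 cases / 243 controls) is held out for PRS evaluation. Cases are on
# average ~7.5 years older than controls in both cohorts.

library(prspipe)

seed <- 2026
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
study <- simulate_study(cfg)

write_manifest(study$manifest, file.path(data_dir, "manifest.tsv"))
for (ch in c("cohort1", "cohort2")) {
  write_genotypes(study[[ch]]$gm, file.path(data_dir, paste0(ch, ".tsv")))
  write_phenotypes(study[[ch]]$phen,
                   file.path(data_dir, paste0(ch, "_phenotypes.tsv")))
}
write.table(study$truth$snps, file.path(data_dir, "truth_snps.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

for (ch in c("cohort1", "cohort2")) {
  ph <- study[[ch]]$phen
  cat(sprintf("%s: %d cases / %d controls; mean age %.1f (cases) vs %.1f (controls)\n",
              ch, sum(ph$status == "case"), sum(ph$status == "control"),
              mean(ph$age[ph$status == "case"]),
              mean(ph$age[ph$status == "control"])))
}
cat("seed:", seed, "- wrote genotypes, phenotypes, manifest and truth to",
    data_dir, "\n")
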