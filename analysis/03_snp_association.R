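#!/usr/bin/env Rscript
# Stage 3: per-SNP additive logistic association on the training cohort,
# with and without age adjustment. Each SNP is tested alone (plus age when
# adjusting); odds ratios are per effect allele, with Wald 95% CIs and
# two-sided p-values. Significance means p <= 0.05 with no multiple-testing
# correction (a Bonferroni column is written for transparency only).

library(prspipe)

data_dir <- "results/data"
assoc_dir <- "results/association"
dir.create(assoc_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest(file.path(data_dir, "manifest.tsv"))
gm <- read_genotypes(file.path(data_dir, "cohort1.tsv"), manifest)
ph <- read_phenotypes(file.path(data_dir, "cohort1_phenotypes.tsv"))
joined <- join_cohort(filter_samples_by_call_rate(gm, 0.95)$gm, ph)
keep <- readLines("results/qc/snps_passing.txt")
gm_qc <- subset_genotypes(joined$gm, snps = keep)

for (mode in c("unadjusted", "age_adjusted")) {
  res <- run_association(gm_qc, joined$phen,
                         adjust_age = mode == "age_adjusted")
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  write.table(res, file.path(assoc_dir, paste0("assoc_", mode, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- significant_snps(res, alpha = 0.05)
  cat(sprintf("%s: %d of %d SNPs significant at p <= 0.05: %s\n",
              mode, nrow(sig), nrow(res),
              paste(sig$snp_id, collapse = ", ")))
}
cat("association tables written to", assoc_dir, "\n")
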