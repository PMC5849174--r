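#!/usr/bin/env Rscript
# Stage 2: sample and SNP quality control on the training cohort.
#
# Samples must reach a 95% genotyping call rate. SNPs are filtered on call
# rate (>= 95%), Hardy-Weinberg equilibrium in controls (exact test,
# exclusion below p = 1e-6) and minor allele frequency (>= 1% of the
# combined case-control cohort). The rare variants, though they carry the
# largest simulated effects, fall below the MAF floor and leave the panel —
# rare risk alleles need far larger cohorts than candidate-panel studies
# provide.

library(prspipe)

data_dir <- "results/data"
qc_dir <- "results/qc"
dir.create(qc_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest(file.path(data_dir, "manifest.tsv"))

for (ch in c("cohort1", "cohort2")) {
  gm <- read_genotypes(file.path(data_dir, paste0(ch, ".tsv")), manifest)
  ph <- read_phenotypes(file.path(data_dir, paste0(ch, "_phenotypes.tsv")))
  filt <- filter_samples_by_call_rate(gm, 0.95)
  cat(sprintf("%s: %d of %d samples pass the 95%% call-rate filter\n",
              ch, length(filt$gm$sample_ids), length(gm$sample_ids)))
  joined <- join_cohort(filt$gm, ph)
  if (ch == "cohort1") {
    qc <- apply_snp_filters(joined$gm, joined$phen, qc_config())
    write.table(qc$results, file.path(qc_dir, "snp_qc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    n_fail <- sum(!qc$results$passed)
    cat(sprintf("cohort1 SNP QC: %d of %d SNPs pass; %d excluded (%s)\n",
                sum(qc$results$passed), nrow(qc$results), n_fail,
                paste(qc$results$snp_id[!qc$results$passed], collapse = ", ")))
    writeLines(qc$results$snp_id[qc$results$passed],
               file.path(qc_dir, "snps_passing.txt"))
  }
}
cat("QC tables written to", qc_dir, "\n")
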