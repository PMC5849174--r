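#!/usr/bin/env Rscript
# Stage 4: linkage disequilibrium among the QC-passing SNPs on the training
# cohort. Pairwise r2 is the squared Pearson correlation of dosages; pairs
# with r2 >= 0.5 are in moderate-to-strong LD and define blocks (connected
# components). Within each block only the SNP with the strongest association
# survives pruning — the input to the pruned score model.

library(prspipe)

data_dir <- "results/data"
ld_dir <- "results/ld"
dir.create(ld_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest(file.path(data_dir, "manifest.tsv"))
gm <- read_genotypes(file.path(data_dir, "cohort1.tsv"), manifest)
ph <- read_phenotypes(file.path(data_dir, "cohort1_phenotypes.tsv"))
joined <- join_cohort(filter_samples_by_call_rate(gm, 0.95)$gm, ph)
keep <- readLines("results/qc/snps_passing.txt")
gm_qc <- subset_genotypes(joined$gm, snps = keep)

ld <- ld_matrix(gm_qc)
write.table(cbind(data.frame(snp_id = ld$snp_ids), as.data.frame(ld$r2)),
            file.path(ld_dir, "ld_matrix.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

blocks <- ld_blocks(ld, threshold = 0.5)
multi <- names(blocks)[blocks %in% blocks[duplicated(blocks)]]
cat("SNPs in multi-SNP LD blocks (r2 >= 0.5):",
    if (length(multi)) paste(multi, collapse = ", ") else "none", "\n")

assoc <- read.delim("results/association/assoc_unadjusted.tsv")
sig <- significant_snps(assoc, alpha = 0.05)
pruned <- prune_by_ld(sig, ld, manifest, threshold = 0.5)
write.table(pruned$log, file.path(ld_dir, "prune_log.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("pruning the %d significant SNPs leaves %d (removed: %s)\n",
            nrow(sig), length(pruned$kept),
            if (nrow(pruned$log)) paste(pruned$log$removed_snp,
                                        collapse = ", ") else "none"))
cat("LD matrix and prune log written to", ld_dir, "\n")
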