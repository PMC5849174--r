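#!/usr/bin/env Rscript
# Stage 5: build the six PRS models on training-cohort statistics and score
# the held-out evaluation cohort. Model-1 keeps every QC-passing SNP,
# Model-2 the significant ones (p <= 0.05), Model-3 the significant ones
# after LD pruning; each crossed with unadjusted or age-adjusted log-OR
# weights. A sample's score is the weight-dosage sum; missing genotypes are
# imputed with twice the training-control allele frequency.

library(prspipe)

data_dir <- "results/data"
prs_dir <- "results/prs"
dir.create(prs_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest(file.path(data_dir, "manifest.tsv"))
keep <- readLines("results/qc/snps_passing.txt")

gm1 <- read_genotypes(file.path(data_dir, "cohort1.tsv"), manifest)
ph1 <- read_phenotypes(file.path(data_dir, "cohort1_phenotypes.tsv"))
train <- join_cohort(filter_samples_by_call_rate(gm1, 0.95)$gm, ph1)
gm_train <- subset_genotypes(train$gm, snps = keep)

gm2 <- read_genotypes(file.path(data_dir, "cohort2.tsv"), manifest)
ph2 <- read_phenotypes(file.path(data_dir, "cohort2_phenotypes.tsv"))
eval_ <- join_cohort(filter_samples_by_call_rate(gm2, 0.95)$gm, ph2)
gm_eval <- subset_genotypes(eval_$gm, snps = keep)

assoc_u <- read.delim("results/association/assoc_unadjusted.tsv")
assoc_a <- read.delim("results/association/assoc_age_adjusted.tsv")
ld <- ld_matrix(gm_train)

ctrl <- subset_genotypes(gm_train,
                         samples = which(train$phen$status == "control"))
ctrl_eaf <- with(allele_frequencies(ctrl), setNames(eaf, snp_id))

weights_out <- list(); scores_out <- list()
for (ws in c("unadjusted", "age_adjusted")) {
  for (rule in c("model1", "model2", "model3")) {
    m <- build_prs_model(assoc_u, assoc_a, ld, manifest, rule = rule,
                         weight_source = ws, control_eaf = ctrl_eaf)
    sc <- score_samples(gm_eval, m)
    key <- paste(rule, ws, sep = ".")
    weights_out[[key]] <- data.frame(model = rule, weight_source = ws,
                                     snp_id = m$snp_ids,
                                     weight = unname(m$weights))
    scores_out[[key]] <- data.frame(sample_id = names(sc), model = rule,
                                    weight_source = ws, prs = unname(sc))
    cat(sprintf("%-22s %2d SNPs; evaluation PRS mean %.3f (sd %.3f)\n",
                key, length(m$snp_ids), mean(sc), sd(sc)))
  }
}
write.table(do.call(rbind, weights_out), file.path(prs_dir, "weights.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, scores_out), file.path(prs_dir, "scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("weights and evaluation-cohort scores written to", prs_dir, "\n")
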