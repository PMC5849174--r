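#!/usr/bin/env Rscript
# Stage 6: evaluate every PRS model on the held-out cohort. For each model:
# quartile odds ratios against the lowest quartile (cutpoints from the
# control score distribution), the trend OR per unit of continuous PRS, and
# the ROC AUC with a DeLong 95% CI. Output mirrors the quartile-table layout
# of candidate-SNP PRS reports.

library(prspipe)

eval_dir <- "results/evaluation"
dir.create(eval_dir, recursive = TRUE, showWarnings = FALSE)

ph2 <- read_phenotypes("results/data/cohort2_phenotypes.tsv")
scores <- read.delim("results/prs/scores.tsv")

rows <- list()
for (key in unique(paste(scores$model, scores$weight_source))) {
  sub <- scores[paste(scores$model, scores$weight_source) == key, ]
  sc <- setNames(sub$prs, sub$sample_id)
  phen <- ph2[match(names(sc), ph2$sample_id), ]
  class(phen) <- c("phenotype_table", "data.frame")
  qa <- quartile_analysis(sc, phen, cutpoint_source = "controls")
  tr <- trend_analysis(sc, phen)
  auc <- prs_auc(sc, phen)
  tab <- qa$table
  rows[[key]] <- rbind(
    data.frame(model = sub$model[1], weight_source = sub$weight_source[1],
               row = paste0("q", tab$quartile), n_controls = tab$n_controls,
               n_cases = tab$n_cases, estimate = tab$or_,
               ci_low = tab$ci_low, ci_high = tab$ci_high, p = tab$p),
    data.frame(model = sub$model[1], weight_source = sub$weight_source[1],
               row = "trend", n_controls = auc$n_controls,
               n_cases = auc$n_cases, estimate = tr$or_, ci_low = tr$ci_low,
               ci_high = tr$ci_high, p = tr$p),
    data.frame(model = sub$model[1], weight_source = sub$weight_source[1],
               row = "auc", n_controls = auc$n_controls, n_cases = auc$n_cases,
               estimate = auc$auc, ci_low = auc$ci_low, ci_high = auc$ci_high,
               p = NA_real_))
  cat(sprintf("%-22s q4 OR %.3f (%.3f-%.3f); trend OR %.3f; AUC %.3f\n",
              key, tab$or_[4], tab$ci_low[4], tab$ci_high[4], tr$or_,
              auc$auc))
}
report <- do.call(rbind, rows)
rownames(report) <- NULL
write.table(report, file.path(eval_dir, "evaluation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("evaluation report written to", file.path(eval_dir, "evaluation.tsv"),
    "\n")
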