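# PRS model construction under the three selection rules, and scoring.

#' Build a PRS model specification
#'
#' The three selection rules mirror a two-cohort design in which association
#' statistics estimated on a training cohort define the score evaluated on an
#' independent cohort:
#' \describe{
#'   \item{model1}{every QC-passing SNP in the association table;}
#'   \item{model2}{only SNPs significant at `alpha` (p <= alpha, inclusive)
#'     in the chosen analysis;}
#'   \item{model3}{model2 after LD pruning: within each block of SNPs in
#'     moderate-to-strong LD (r2 >= `ld_threshold`), only the SNP with the
#'     strongest association is retained.}
#' }
#' Weights are the natural-log odds ratios (betas) from the chosen analysis,
#' so model3 is a subset of model2, which is a subset of model1. Weights of
#' non-converged fits never enter a model (model1 drops them with a note).
#'
#' @param assoc_unadj,assoc_adj association tables from [run_association()]
#'   on the training cohort, unadjusted and age-adjusted.
#' @param ld an [ld_matrix()] computed on the training cohort.
#' @param manifest the [snp_manifest()] (for pruning tie-breaks).
#' @param rule `"model1"`, `"model2"` or `"model3"`.
#' @param weight_source `"unadjusted"` or `"age_adjusted"`: which analysis
#'   supplies both the significance screen and the log-OR weights.
#' @param alpha significance level for model2/model3 selection.
#' @param ld_threshold r2 threshold for model3 pruning.
#' @param control_eaf optional named vector of effect-allele frequencies
#'   among training controls, stored for missing-genotype imputation at
#'   scoring time.
#' @return List of class `prs_model`: `name`, `snp_ids`, `weights` (named,
#'   natural-log OR), `weight_source`, `alpha`, `control_eaf`, `prune_log`.
#' @export
build_prs_model <- function(assoc_unadj, assoc_adj = NULL, ld = NULL,
                            manifest = NULL,
                            rule = c("model1", "model2", "model3"),
                            weight_source = c("unadjusted", "age_adjusted"),
                            alpha = 0.05, ld_threshold = 0.5,
                            control_eaf = NULL) {
  rule <- match.arg(rule)
  weight_source <- match.arg(weight_source)
  assoc <- if (weight_source == "unadjusted") assoc_unadj else {
    if (is.null(assoc_adj)) stop("age-adjusted weights requested but no ",
                                 "age-adjusted association table given")
    assoc_adj
  }
  usable <- assoc[!is.na(assoc$beta) & assoc$converged, , drop = FALSE]
  sel <- switch(rule,
    model1 = usable,
    model2 = significant_snps(usable, alpha = alpha),
    model3 = {
      sig <- significant_snps(usable, alpha = alpha)
      if (nrow(sig) == 0) sig else {
        if (is.null(ld) || is.null(manifest)) {
          stop("model3 requires an LD matrix and a manifest")
        }
        pruned <- prune_by_ld(sig, ld, manifest, threshold = ld_threshold)
        attr(sig, "prune_log") <- pruned$log
        sig[sig$snp_id %in% pruned$kept, , drop = FALSE]
      }
    }
  )
  if (rule != "model1" && nrow(sel) == 0) {
    stop("empty model: no SNP significant at alpha = ", alpha)
  }
  weights <- stats::setNames(sel$beta, sel$snp_id)
  if (!is.null(control_eaf)) {
    control_eaf <- control_eaf[sel$snp_id]
  }
  structure(list(name = rule, snp_ids = sel$snp_id, weights = weights,
                 weight_source = weight_source, alpha = alpha,
                 control_eaf = control_eaf,
                 prune_log = attr(sel, "prune_log")),
            class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("prs_model '%s' (%s weights): %d SNPs\n",
              x$name, x$weight_source, length(x$snp_ids)))
  invisible(x)
}

#' Score samples with a PRS model
#'
#' The polygenic risk score of individual i is the sum over model SNPs of the
#' SNP's log-OR weight times the individual's count of effect alleles:
#' PRS_i = sum_j w_j * g_ij. Missing genotypes are handled by policy:
#' \describe{
#'   \item{impute_control_freq}{replace a missing dosage with twice the
#'     effect-allele frequency among training controls (the model's
#'     `control_eaf`, falling back to the scored cohort's overall frequency
#'     if the model carries none). Keeps the score scale
#'     comparable across samples. Default.}
#'   \item{renormalize}{sum observed terms and rescale by
#'     m / m_observed.}
#' }
#'
#' @param gm a [genotype_matrix()] containing every model SNP.
#' @param model a [build_prs_model()] result.
#' @param missing_policy `"impute_control_freq"` or `"renormalize"`.
#' @return Named numeric vector of scores, one per sample.
#' @export
score_samples <- function(gm, model,
                          missing_policy = c("impute_control_freq",
                                             "renormalize")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(model, "prs_model"))
  absent <- setdiff(model$snp_ids, gm$snps$snp_id)
  if (length(absent)) {
    stop("model SNP(s) absent from genotype matrix: ",
         paste(absent, collapse = ", "))
  }
  if (length(model$snp_ids) == 0) {
    return(stats::setNames(rep(0, length(gm$sample_ids)), gm$sample_ids))
  }
  d <- gm$dosage[, model$snp_ids, drop = FALSE]
  storage.mode(d) <- "double"
  w <- model$weights[model$snp_ids]
  if (missing_policy == "impute_control_freq") {
    fill <- model$control_eaf
    if (is.null(fill) || anyNA(fill)) {
      overall <- colMeans(d, na.rm = TRUE) / 2
      if (is.null(fill)) fill <- overall
      fill[is.na(fill)] <- overall[is.na(fill)]
    }
    for (j in seq_len(ncol(d))) {
      miss <- is.na(d[, j])
      if (any(miss)) d[miss, j] <- 2 * fill[j]
    }
    scores <- drop(d %*% w)
  } else {
    obs <- !is.na(d)
    d0 <- d
    d0[!obs] <- 0
    raw <- drop(d0 %*% w)
    m_obs <- rowSums(obs)
    if (any(m_obs == 0)) stop("sample(s) missing every model SNP")
    scores <- raw * (ncol(d) / m_obs)
  }
  stats::setNames(scores, gm$sample_ids)
}
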