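# PRS evaluation: quartile odds ratios, continuous trend, and ROC AUC.

#' Quartile odds ratios from case/control counts
#'
#' Fits a logistic regression of status on a one-hot quartile factor (first
#' quartile as reference). Because the model is saturated, each OR equals the
#' crude cross-product ratio from the corresponding 2x2 table, so published
#' quartile ORs are exactly recomputable from printed counts. Wald 95\%
#' confidence intervals and two-sided p-values accompany each OR.
#'
#' @param n_cases,n_controls length-4 integer vectors of per-quartile counts
#'   (q1 first).
#' @return data.frame with one row per quartile: `quartile`, `n_controls`,
#'   `n_cases`, `or_`, `ci_low`, `ci_high`, `p` (reference row has OR 1 and
#'   `NA` CI/p).
#' @export
quartile_or_from_counts <- function(n_cases, n_controls) {
  stopifnot(length(n_cases) == 4, length(n_controls) == 4,
            all(n_cases >= 0), all(n_controls >= 0))
  out <- data.frame(quartile = 1:4, n_controls = n_controls,
                    n_cases = n_cases, or_ = c(1, NA, NA, NA),
                    ci_low = NA_real_, ci_high = NA_real_, p = NA_real_)
  df <- data.frame(
    q = factor(rep(rep(1:4, 2), times = c(n_cases, n_controls))),
    y = rep(c(1, 0), times = c(sum(n_cases), sum(n_controls)))
  )
  for (k in 2:4) {
    counts <- c(n_cases[k], n_cases[1], n_controls[k], n_controls[1])
    if (any(counts == 0)) next  # OR undefined, left NA and flagged by caller
    sub <- df[df$q %in% c(1, k), , drop = FALSE]
    fit <- fit_logistic(sub$y, cbind(qk = as.numeric(sub$q == k)))
    b <- fit$beta[["qk"]]
    se <- fit$se[["qk"]]
    out$or_[k] <- exp(b)
    out$ci_low[k] <- exp(b - 1.96 * se)
    out$ci_high[k] <- exp(b + 1.96 * se)
    out$p[k] <- 2 * stats::pnorm(-abs(b / se))
  }
  out
}

#' Quartile risk stratification of a PRS
#'
#' Cutpoints are the 25th/50th/75th percentiles of the score distribution in
#' the reference group — by default the controls, the convention that splits
#' the control column of the evaluation cohort into near-equal quarters.
#' Percentiles use quantile type 6 and samples exactly at a cutpoint go to
#' the lower quartile. Per-quartile odds ratios versus the first quartile
#' come from the saturated one-hot logistic fit (see
#' [quartile_or_from_counts()]).
#'
#' @param scores named numeric PRS vector (names = sample ids); finite.
#' @param phen a [phenotype_table()] covering the scored samples.
#' @param cutpoint_source `"controls"` (default) or `"combined"`.
#' @return List of class `quartile_table`: `cutpoints` (3 thresholds),
#'   `table` (per-quartile counts, OR, CI, p), `assignments` (named quartile
#'   per sample), `flags` (quartiles with an undefined OR).
#' @export
quartile_analysis <- function(scores, phen,
                              cutpoint_source = c("controls", "combined")) {
  cutpoint_source <- match.arg(cutpoint_source)
  stopifnot(all(is.finite(scores)), !is.null(names(scores)))
  phen <- phen[match(names(scores), phen$sample_id), , drop = FALSE]
  if (anyNA(phen$sample_id)) stop("scored samples missing from phenotypes")
  is_ctrl <- phen$status == "control"
  if (sum(is_ctrl) < 4) stop("need at least 4 controls for quartiles")
  ref <- if (cutpoint_source == "controls") scores[is_ctrl] else scores
  cut3 <- stats::quantile(ref, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
  if (anyDuplicated(cut3)) {
    stop("degenerate quartile cutpoints: scores have insufficient spread")
  }
  q <- 1L + (scores > cut3[1]) + (scores > cut3[2]) + (scores > cut3[3])
  n_cases <- vapply(1:4, function(k) sum(q == k & !is_ctrl), integer(1))
  n_controls <- vapply(1:4, function(k) sum(q == k & is_ctrl), integer(1))
  tab <- quartile_or_from_counts(n_cases, n_controls)
  flags <- tab$quartile[tab$quartile > 1 & is.na(tab$or_)]
  structure(list(cutpoints = cut3, table = tab,
                 assignments = stats::setNames(q, names(scores)),
                 cutpoint_source = cutpoint_source, flags = flags),
            class = "quartile_table")
}

#' @export
print.quartile_table <- function(x, ...) {
  cat("PRS quartiles (cutpoints from ", x$cutpoint_source, "):\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Trend odds ratio of a continuous PRS
#'
#' Logistic regression of case status on the PRS as a continuous variable,
#' optionally age-adjusted; reports the OR per unit of PRS.
#'
#' @inheritParams quartile_analysis
#' @param adjust_age include age as a covariate (samples with missing age
#'   excluded).
#' @return One-row data.frame: `or_`, `ci_low`, `ci_high`, `p`, `n_used`,
#'   `converged`, `adjusted`.
#' @export
trend_analysis <- function(scores, phen, adjust_age = FALSE) {
  stopifnot(all(is.finite(scores)), !is.null(names(scores)))
  phen <- phen[match(names(scores), phen$sample_id), , drop = FALSE]
  if (anyNA(phen$sample_id)) stop("scored samples missing from phenotypes")
  keep <- if (adjust_age) !is.na(phen$age) else rep(TRUE, nrow(phen))
  y <- as.numeric(phen$status[keep] == "case")
  X <- if (adjust_age) cbind(prs = scores[keep], age = phen$age[keep])
       else cbind(prs = scores[keep])
  fit <- fit_logistic(y, X)
  b <- fit$beta[["prs"]]
  se <- fit$se[["prs"]]
  data.frame(or_ = exp(b), ci_low = exp(b - 1.96 * se),
             ci_high = exp(b + 1.96 * se),
             p = 2 * stats::pnorm(-abs(b / se)), n_used = fit$n,
             converged = fit$converged, adjusted = adjust_age)
}

#' AUC of a score for case/control discrimination
#'
#' Mann-Whitney estimator (the probability that a random case outscores a
#' random control, ties counted one half) with a DeLong 95\% confidence
#' interval.
#'
#' @param scores numeric score vector.
#' @param labels parallel vector with values `"case"`/`"control"` (or a
#'   [phenotype_table()] whose order matches `scores`).
#' @return List: `auc`, `ci_low`, `ci_high`, `n_cases`, `n_controls`.
#' @export
prs_auc <- function(scores, labels) {
  if (inherits(labels, "phenotype_table")) labels <- labels$status
  labels <- as.character(labels)
  stopifnot(length(labels) == length(scores),
            all(labels %in% c("case", "control")))
  if (length(unique(labels)) < 2) {
    stop("AUC undefined: both classes must be present")
  }
  roc <- pROC::roc(response = labels, predictor = as.numeric(scores),
                   levels = c("control", "case"), direction = "<",
                   quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
  list(auc = as.numeric(pROC::auc(roc)),
       ci_low = max(0, ci[1]), ci_high = min(1, ci[3]),
       n_cases = sum(labels == "case"),
       n_controls = sum(labels == "control"))
}

#' Evaluate a PRS model on a cohort
#'
#' Scores the cohort and assembles the full evaluation: quartile table,
#' continuous trend OR (unadjusted, plus age-adjusted when ages are
#' available) and AUC with DeLong CI.
#'
#' @param gm evaluation-cohort [genotype_matrix()].
#' @param phen evaluation-cohort [phenotype_table()], aligned with `gm`.
#' @param model a [build_prs_model()] result (trained on a different cohort).
#' @param missing_policy passed to [score_samples()].
#' @param cutpoint_source passed to [quartile_analysis()].
#' @return List of class `prs_evaluation`: `model_name`, `weight_source`,
#'   `n_snps`, `scores`, `quartiles`, `trend`, `trend_adjusted` (or NULL),
#'   `auc`.
#' @export
evaluate_prs <- function(gm, phen, model,
                         missing_policy = "impute_control_freq",
                         cutpoint_source = "controls") {
  stopifnot(identical(gm$sample_ids, phen$sample_id))
  scores <- score_samples(gm, model, missing_policy = missing_policy)
  quart <- quartile_analysis(scores, phen, cutpoint_source = cutpoint_source)
  trend <- trend_analysis(scores, phen, adjust_age = FALSE)
  trend_adj <- if (any(!is.na(phen$age))) {
    trend_analysis(scores, phen, adjust_age = TRUE)
  }
  auc <- prs_auc(scores, phen)
  structure(list(model_name = model$name, weight_source = model$weight_source,
                 n_snps = length(model$snp_ids), scores = scores,
                 quartiles = quart, trend = trend, trend_adjusted = trend_adj,
                 auc = auc),
            class = "prs_evaluation")
}

#' @export
print.prs_evaluation <- function(x, ...) {
  cat(sprintf("PRS evaluation: %s (%s weights, %d SNPs)\n",
              x$model_name, x$weight_source, x$n_snps))
  print(x$quartiles)
  cat(sprintf("Trend OR per unit PRS: %.3f (%.3f-%.3f), p = %.3g\n",
              x$trend$or_, x$trend$ci_low, x$trend$ci_high, x$trend$p))
  cat(sprintf("AUC: %.3f (%.3f-%.3f)\n", x$auc$auc, x$auc$ci_low,
              x$auc$ci_high))
  invisible(x)
}
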