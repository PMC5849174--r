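# Per-SNP additive logistic association, with and without age adjustment.

#' Fit a logistic regression with diagnostics
#'
#' Maximum-likelihood logistic regression (IRLS, deviance convergence
#' tolerance 1e-10, at most 100 iterations) of a binary outcome on one or more predictor
#' columns, with Wald standard errors from the inverse observed information.
#' Constant predictor columns and rank deficiencies are errors, not silent
#' drops; complete or quasi-complete separation is flagged as non-converged
#' rather than reported as a finite estimate.
#'
#' @param y binary outcome vector (0/1, logical, or two-level factor).
#' @param X numeric matrix (or vector) of predictors, one column per term;
#'   an intercept is always added.
#' @return List with `beta`, `se` (named, intercept first), `converged`
#'   (FALSE under separation or IRLS failure), `separation`, and `n`.
#' @export
fit_logistic <- function(y, X) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2) stop("y has a single class; logistic fit undefined")
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  const <- apply(X, 2, function(v) length(unique(v[!is.na(v)])) <= 1)
  if (any(const)) {
    stop("constant predictor column(s): ",
         paste(colnames(X)[const], collapse = ", "))
  }
  Xi <- cbind(`(Intercept)` = 1, X)
  if (qr(Xi)$rank < ncol(Xi)) {
    stop("rank-deficient design: predictors are collinear")
  }
  fit <- suppressWarnings(
    stats::glm.fit(Xi, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  p <- fit$fitted.values
  separation <- any(p < 1e-10 | p > 1 - 1e-10)
  cov <- chol2inv(fit$qr$qr[seq_len(ncol(Xi)), seq_len(ncol(Xi)), drop = FALSE])
  se <- sqrt(diag(cov))
  names(se) <- colnames(Xi)
  list(beta = stats::coef(fit), se = se,
       converged = fit$converged && !separation,
       separation = separation, n = length(y),
       deviance = fit$deviance)
}

status_binary <- function(phen) as.numeric(phen$status == "case")

empty_assoc_row <- function(snp_id, adjusted, n_used, reason) {
  data.frame(snp_id = snp_id, n_used = n_used, eaf = NA_real_,
             beta = NA_real_, se = NA_real_, or_ = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
             adjusted = adjusted, converged = FALSE, note = reason,
             stringsAsFactors = FALSE)
}

#' Additive association of one SNP with case status
#'
#' Logistic regression of case/control status on the effect-allele dosage
#' (0/1/2, additive coding), optionally adjusting for age as a linear term on
#' the logit scale. Samples missing the genotype — and, when adjusting,
#' missing age — are excluded pairwise for this SNP only.
#'
#' @param gm a [genotype_matrix()] aligned with `phen`.
#' @param phen a [phenotype_table()] in the same sample order.
#' @param snp_id the SNP to test.
#' @param adjust_age include age as a covariate.
#' @return One-row data.frame: `snp_id`, `n_used`, `eaf`, `beta` (log OR per
#'   effect allele), `se`, `or_`, `ci_low`/`ci_high` (Wald 95\%), `p`
#'   (two-sided Wald), `adjusted`, `converged`, `note`.
#' @export
snp_association <- function(gm, phen, snp_id, adjust_age = FALSE) {
  stopifnot(identical(gm$sample_ids, phen$sample_id))
  j <- match(snp_id, gm$snps$snp_id)
  if (is.na(j)) stop("unknown SNP: ", snp_id)
  g <- gm$dosage[, j]
  keep <- !is.na(g)
  if (adjust_age) keep <- keep & !is.na(phen$age)
  g <- as.numeric(g[keep])
  y <- status_binary(phen)[keep]
  n_used <- length(y)
  if (n_used == 0 || length(unique(g)) < 2) {
    return(empty_assoc_row(snp_id, adjust_age, n_used,
                           "monomorphic after exclusions"))
  }
  if (length(unique(y)) < 2) {
    return(empty_assoc_row(snp_id, adjust_age, n_used,
                           "single class after exclusions"))
  }
  X <- if (adjust_age) cbind(dosage = g, age = phen$age[keep])
       else cbind(dosage = g)
  fit <- fit_logistic(y, X)
  b <- fit$beta[["dosage"]]
  se <- fit$se[["dosage"]]
  z <- b / se
  data.frame(
    snp_id = snp_id, n_used = n_used, eaf = mean(g) / 2,
    beta = b, se = se, or_ = exp(b),
    ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z)),
    adjusted = adjust_age, converged = fit$converged,
    note = if (fit$separation) "separation" else "",
    stringsAsFactors = FALSE
  )
}

#' Association scan over every SNP
#'
#' @inheritParams snp_association
#' @return data.frame, one row per SNP (see [snp_association()]).
#' @export
run_association <- function(gm, phen, adjust_age = FALSE) {
  rows <- lapply(gm$snps$snp_id, function(s)
    snp_association(gm, phen, s, adjust_age = adjust_age))
  do.call(rbind, rows)
}

#' Select statistically significant SNPs
#'
#' Inclusive threshold (p <= alpha), no multiple-testing correction: the
#' selection rule for the significant-SNP score models. SNPs with failed or
#' non-converged fits are never selected. A Bonferroni-adjusted column is
#' available in the association table for transparency but plays no role in
#' selection.
#'
#' @param results association table from [run_association()].
#' @param alpha significance level (default 0.05).
#' @return The subset of `results` with `p <= alpha`, original order kept.
#' @export
significant_snps <- function(results, alpha = 0.05) {
  stopifnot(nrow(results) >= 1)
  results[!is.na(results$p) & results$converged & results$p <= alpha, ,
          drop = FALSE]
}
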