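# Sample- and SNP-level quality control: call rates, Hardy-Weinberg testing
# in controls, minor-allele-frequency exclusion.

#' QC configuration
#'
#' @param call_rate_threshold minimum fraction of non-missing calls; samples
#'   and SNPs at or above the threshold pass (a sample at exactly 95\% passes).
#' @param maf_threshold SNPs with minor allele frequency strictly below this
#'   are excluded. The frequency is computed from non-missing calls on the
#'   cohort being analysed, cases and controls combined.
#' @param hwe_p_threshold SNPs with a control-only Hardy-Weinberg p-value
#'   strictly below this are excluded. There is no universal convention; the
#'   filter is explicit here and every exclusion is logged.
#' @param hwe_method `"exact"` (default) or `"chi2"`. The exact test is
#'   preferred because candidate panels include rare variants for which the
#'   1-df chi-square approximation is unreliable.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(call_rate_threshold = 0.95, maf_threshold = 0.01,
                      hwe_p_threshold = 1e-6,
                      hwe_method = c("exact", "chi2")) {
  hwe_method <- match.arg(hwe_method)
  stopifnot(call_rate_threshold >= 0, call_rate_threshold <= 1,
            maf_threshold >= 0, maf_threshold <= 0.5,
            hwe_p_threshold >= 0, hwe_p_threshold <= 1)
  structure(list(call_rate_threshold = call_rate_threshold,
                 maf_threshold = maf_threshold,
                 hwe_p_threshold = hwe_p_threshold,
                 hwe_method = hwe_method),
            class = "qc_config")
}

#' Per-sample genotyping call rates
#'
#' @param gm a [genotype_matrix()] with at least one SNP.
#' @return Named numeric vector, fraction of non-missing calls per sample.
#' @export
sample_call_rates <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"), ncol(gm$dosage) >= 1)
  rowMeans(!is.na(gm$dosage))
}

#' Per-SNP genotyping call rates
#'
#' @param gm a [genotype_matrix()].
#' @return Named numeric vector, fraction of non-missing calls per SNP.
#' @export
snp_call_rates <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"), nrow(gm$dosage) >= 1)
  colMeans(!is.na(gm$dosage))
}

#' Call rate of one SNP
#' @param gm a [genotype_matrix()].
#' @param snp_id the SNP.
#' @return Fraction of non-missing calls.
#' @export
snp_call_rate <- function(gm, snp_id) {
  if (!snp_id %in% gm$snps$snp_id) stop("unknown SNP: ", snp_id)
  unname(snp_call_rates(gm)[snp_id])
}

#' Exclude samples below a call-rate threshold
#'
#' @param gm a [genotype_matrix()].
#' @param threshold minimum call rate; comparison is `>=` so a sample exactly
#'   at the threshold is kept.
#' @return List with the filtered `gm`, the `excluded` sample ids, and the
#'   per-sample `call_rates`.
#' @export
filter_samples_by_call_rate <- function(gm, threshold = 0.95) {
  cr <- sample_call_rates(gm)
  keep <- cr >= threshold
  list(gm = subset_genotypes(gm, samples = which(keep)),
       excluded = gm$sample_ids[!keep], call_rates = cr)
}

#' Effect-allele and minor-allele frequencies
#'
#' Frequencies use non-missing calls only. `eaf` is the frequency of the
#' manifest's effect allele; `maf = min(eaf, 1 - eaf)`.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame with snp_id, n_called, eaf, maf.
#' @export
allele_frequencies <- function(gm) {
  n_called <- colSums(!is.na(gm$dosage))
  eaf <- colMeans(gm$dosage, na.rm = TRUE) / 2
  eaf[n_called == 0] <- NA_real_
  data.frame(snp_id = gm$snps$snp_id, n_called = n_called, eaf = eaf,
             maf = pmin(eaf, 1 - eaf), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Hardy-Weinberg equilibrium test
#'
#' Tests genotype counts against Hardy-Weinberg proportions. The exact method
#' conditions on the observed allele counts and enumerates all attainable
#' heterozygote counts; the two-sided p-value sums the probabilities of every
#' configuration no more probable than the observed one. The chi-square
#' method is the classical 1-df goodness-of-fit statistic. A monomorphic
#' sample (a single attainable configuration) has p = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (non-negative, sum >= 1).
#' @param method `"exact"` or `"chi2"`.
#' @return p-value in (0, 1].
#' @export
hwe_test <- function(n_hom_ref, n_het, n_hom_alt,
                     method = c("exact", "chi2")) {
  method <- match.arg(method)
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("Hardy-Weinberg test undefined for zero genotypes")
  if (method == "exact") hwe_exact_p(counts[1], counts[2], counts[3])
  else hwe_chi2_p(counts[1], counts[2], counts[3])
}

# Conditional exact distribution of the heterozygote count given the minor
# allele count; probabilities built by the standard ratio recurrence from the
# mode, in plain (not log) space after normalisation.
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_minor <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  if (n_minor == 0) return(1.0)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log-probabilities via the ratio recurrence
  # P(h+2)/P(h) = 4 * hom_minor(h) * hom_major(h) / ((h+2)(h+1))
  k <- length(hets)
  logp <- numeric(k)
  for (i in seq_len(k - 1)) {
    h <- hets[i]
    hom_min <- (n_minor - h) / 2
    hom_maj <- (2 * n - n_minor - h) / 2
    logp[i + 1] <- logp[i] + log(4 * hom_min * hom_maj) -
      log((h + 2) * (h + 1))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_ab)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

hwe_chi2_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  pa <- (2 * n_aa + n_ab) / (2 * n)
  if (pa == 0 || pa == 1) return(1.0)
  expected <- n * c(pa^2, 2 * pa * (1 - pa), (1 - pa)^2)
  stat <- sum((c(n_aa, n_ab, n_bb) - expected)^2 / expected)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Hardy-Weinberg p-values for every SNP, in controls
#'
#' @param gm a [genotype_matrix()].
#' @param phen an aligned [phenotype_table()].
#' @param method passed to [hwe_test()].
#' @return Named numeric vector of p-values (`NA` when a SNP has no called
#'   control genotypes).
#' @export
hwe_controls <- function(gm, phen, method = c("exact", "chi2")) {
  method <- match.arg(method)
  stopifnot(identical(gm$sample_ids, phen$sample_id))
  ctrl <- phen$status == "control"
  p <- vapply(seq_len(ncol(gm$dosage)), function(j) {
    g <- gm$dosage[ctrl, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2), method = method)
  }, numeric(1))
  stats::setNames(p, gm$snps$snp_id)
}

#' Apply SNP-level quality filters
#'
#' Applies, in one pass: the per-SNP call-rate filter, the minor-allele
#' frequency exclusion (MAF below the threshold, computed from non-missing
#' calls in cases and controls combined), and the Hardy-Weinberg filter
#' computed in controls only. Every removal is recorded with its reasons.
#'
#' @param gm a [genotype_matrix()] aligned with `phen` (see [join_cohort()]).
#' @param phen a [phenotype_table()] in the same sample order.
#' @param config a [qc_config()].
#' @return List with `gm` (filtered), `results` (one row per SNP: call_rate,
#'   maf, hwe_p_controls, passed, fail_reasons) and `warnings`.
#' @export
apply_snp_filters <- function(gm, phen, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"),
            identical(gm$sample_ids, phen$sample_id))
  warnings <- character()
  cr <- snp_call_rates(gm)
  af <- allele_frequencies(gm)
  if (!any(phen$status == "control")) {
    warnings <- c(warnings, "no controls present; HWE filter skipped")
    hwe_p <- rep(NA_real_, nrow(af))
  } else {
    hwe_p <- hwe_controls(gm, phen, method = config$hwe_method)
  }
  fail <- vapply(seq_len(nrow(af)), function(j) {
    r <- character()
    if (cr[j] < config$call_rate_threshold) r <- c(r, "low_call_rate")
    if (is.na(af$maf[j]) || af$maf[j] < config$maf_threshold) {
      r <- c(r, "low_maf")
    }
    if (!is.na(hwe_p[j]) && hwe_p[j] < config$hwe_p_threshold) {
      r <- c(r, "hwe_violation")
    }
    paste(r, collapse = ",")
  }, character(1))
  results <- data.frame(
    snp_id = af$snp_id, call_rate = unname(cr), maf = af$maf,
    eaf = af$eaf, hwe_p_controls = unname(hwe_p),
    passed = !nzchar(fail), fail_reasons = fail,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(gm = subset_genotypes(gm, snps = which(results$passed)),
       results = results, warnings = warnings)
}
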