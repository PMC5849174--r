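# Independent oracles and small fixture builders used across tests.

# Exact Hardy-Weinberg p-value by direct enumeration of the conditional
# distribution of heterozygote counts given the minor allele count, using the
# closed-form multinomial expression with lfactorial (independent of the
# package's ratio-recurrence implementation).
hwe_enum_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_minor <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  pr <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    exp(lfactorial(n) - lfactorial(hom_min) - lfactorial(h) -
          lfactorial(hom_maj) + h * log(2) +
          lfactorial(n_minor) + lfactorial(2 * n - n_minor) - lfactorial(2 * n))
  }, numeric(1))
  obs <- pr[hets == n_ab]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# AUC by exhaustive enumeration of case-control pairs, ties counted 1/2.
auc_pair_oracle <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Crude odds ratio from a 2x2 table (exposed cases, unexposed cases,
# exposed controls, unexposed controls).
crude_or <- function(a, b, c, d) (a * d) / (b * c)

toy_manifest <- function(m, prefix = "snp") {
  snp_manifest(sprintf("%s%02d", prefix, seq_len(m)),
               chrom = rep("1", m), pos = seq_len(m) * 1000L,
               effect_allele = rep(c("A", "C", "G", "T"), length.out = m),
               other_allele = rep(c("G", "T", "A", "C"), length.out = m))
}

random_gm <- function(n, m, miss = 0.05) {
  d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (miss > 0) d[matrix(runif(n * m) < miss, n, m)] <- NA_integer_
  genotype_matrix(d, sprintf("s%03d", seq_len(n)), toy_manifest(m))
}

# A hand-built ld_matrix object (bypasses genotype data) for block logic.
fake_ld <- function(ids, r2) {
  dimnames(r2) <- list(ids, ids)
  structure(list(snp_ids = ids, r2 = r2,
                 n_pairs_used = matrix(100L, length(ids), length(ids),
                                       dimnames = list(ids, ids))),
            class = "ld_matrix")
}
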