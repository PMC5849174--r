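# Two-cohort case-control simulator: biallelic SNP panels with LD blocks
# (latent-Gaussian threshold copula on haplotypes), an additive logistic
# disease model, class-dependent ages, and sporadic missingness. Every run is
# reproducible bit-exactly from (config, seed).

#' Simulation configuration
#'
#' Defaults emulate a two-cohort candidate-SNP study: a large discovery
#' cohort (1294 cases / 885 controls) whose association statistics train the
#' score, and an independent evaluation cohort (301 cases / 243 controls),
#' with cases on average older than controls.
#'
#' @param seed integer seed; mandatory, every draw flows from it.
#' @param n_cases_1,n_controls_1,n_cases_2,n_controls_2 cohort sizes.
#' @param snp_panel data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf` (effect-allele frequency in
#'   (0,1)), `or_true` (per-allele odds ratio > 0), `block_id` (integer or
#'   NA for unblocked SNPs). See [default_snp_panel()].
#' @param block_r2 target pairwise dosage r2 within each LD block, in [0,1).
#' @param missing_rate probability that any genotype call is missing.
#' @param dropout_snps SNP ids given heavy assay dropout (missingness
#'   `dropout_rate`) so they fail the call-rate filter.
#' @param dropout_rate missingness applied to `dropout_snps`.
#' @param age_model list: `case_mean`, `case_sd`, `control_mean`,
#'   `control_sd` (years), `slope` (log-odds per year; when non-zero, age is
#'   drawn before status from the control distribution and enters the
#'   disease model, so class age differences emerge rather than being set).
#' @param age_model_2 age model for the second cohort (default: first
#'   cohort's model with means 49.9 / 42.0).
#' @param prevalence baseline population prevalence the disease-model
#'   intercept is tuned to; odds ratios are invariant to it, it only sets
#'   the rejection-sampling efficiency.
#' @param min_call_rate cohort members must reach this genotyping call rate;
#'   the cohort sizes describe the samples remaining after sample-level QC,
#'   so quota filling skips the occasional sample that fails it.
#' @param age_range truncation bounds for sampled ages.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_cases_1 = 1294, n_controls_1 = 885,
                       n_cases_2 = 301, n_controls_2 = 243,
                       snp_panel = default_snp_panel(),
                       block_r2 = 0.85,
                       missing_rate = 0.005,
                       dropout_snps = character(),
                       dropout_rate = 0.10,
                       age_model = list(case_mean = 50.2, case_sd = 9,
                                        control_mean = 42.7, control_sd = 9,
                                        slope = 0),
                       age_model_2 = NULL,
                       prevalence = 0.10,
                       min_call_rate = 0.95,
                       age_range = c(20, 90)) {
  if (missing(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  stopifnot(n_cases_1 > 0, n_controls_1 > 0, n_cases_2 > 0, n_controls_2 > 0,
            block_r2 >= 0, block_r2 < 1,
            missing_rate >= 0, missing_rate < 1,
            prevalence > 0, prevalence < 1)
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "or_true", "block_id")
  if (!all(need %in% names(snp_panel))) {
    stop("snp_panel must have columns ", paste(need, collapse = ", "))
  }
  if (any(snp_panel$eaf <= 0 | snp_panel$eaf >= 1)) {
    stop("eaf must lie in the open interval (0, 1)")
  }
  if (any(snp_panel$or_true <= 0)) stop("or_true must be positive")
  if (is.null(age_model_2)) {
    age_model_2 <- age_model
    age_model_2$case_mean <- 49.9
    age_model_2$control_mean <- 42.0
  }
  structure(list(seed = seed,
                 n_cases_1 = n_cases_1, n_controls_1 = n_controls_1,
                 n_cases_2 = n_cases_2, n_controls_2 = n_controls_2,
                 snp_panel = snp_panel, block_r2 = block_r2,
                 missing_rate = missing_rate, dropout_snps = dropout_snps,
                 dropout_rate = dropout_rate,
                 age_model = age_model, age_model_2 = age_model_2,
                 prevalence = prevalence, min_call_rate = min_call_rate,
                 age_range = age_range),
            class = "sim_config")
}

#' Preset SNP panel emulating a literature-selected candidate study
#'
#' 51 biallelic SNPs: 5 rare variants (effect-allele frequency 0.08-0.15\%,
#' per-allele ORs 2.6-4.9) that the 1\% MAF filter removes by construction
#' even after case enrichment; one 4-SNP LD block in which a single causal
#' SNP (OR 1.4) is tagged by three neutral SNPs; 7 further independent
#' causal SNPs with ORs 1.15-1.30; and 35 null SNPs with frequencies
#' spanning 5-50\%.
#'
#' @return data.frame usable as `snp_panel` in [sim_config()].
#' @export
default_snp_panel <- function() {
  alleles <- c("A", "C", "G", "T")
  mk <- function(ids, eaf, or_true, block_id, chrom, pos0) {
    k <- length(ids)
    data.frame(snp_id = ids, chrom = as.character(chrom),
               pos = as.integer(pos0 + seq_len(k) * 10000L),
               effect_allele = rep(alleles, length.out = k),
               other_allele = rep(c("G", "T", "A", "C"), length.out = k),
               eaf = eaf, or_true = or_true, block_id = block_id,
               stringsAsFactors = FALSE)
  }
  # population EAFs are set low enough that even after case enrichment
  # (case-allele frequency ~ eaf * OR in a case-heavy cohort) the realized
  # cohort MAF stays below the 1% filter
  rare <- mk(sprintf("rs_rare%02d", 1:5),
             eaf = c(0.0008, 0.0010, 0.0012, 0.0013, 0.0015),
             or_true = c(2.64, 3.20, 3.75, 4.30, 4.87),
             block_id = NA_integer_, chrom = "11", pos0 = 69e6)
  block <- mk(sprintf("rs_blk%02d", 1:4),
              eaf = rep(0.30, 4),
              or_true = c(1.40, 1.00, 1.00, 1.00),
              block_id = 1L, chrom = "6", pos0 = 151e6)
  causal <- mk(sprintf("rs_causal%02d", 1:7),
               eaf = c(0.20, 0.25, 0.30, 0.35, 0.40, 0.45, 0.25),
               or_true = c(1.30, 1.28, 1.25, 1.22, 1.20, 1.18, 1.15),
               block_id = NA_integer_, chrom = as.character(1:7 + 7),
               pos0 = 50e6)
  nulls <- mk(sprintf("rs_null%02d", 1:35),
              eaf = round(seq(0.05, 0.50, length.out = 35), 3),
              or_true = 1.0, block_id = NA_integer_,
              chrom = as.character(rep(1:22, length.out = 35)), pos0 = 10e6)
  out <- rbind(rare, block, causal, nulls)
  rownames(out) <- NULL
  out
}

# P(Z1 < t1, Z2 < t2) for standard bivariate normal with correlation rho,
# by one-dimensional quadrature.
bvn_cdf <- function(t1, t2, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(t1) * stats::pnorm(t2))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(z) {
    stats::dnorm(z) * stats::pnorm((t2 - rho * z) / s)
  }, lower = -Inf, upper = t1, rel.tol = 1e-10)$value
}

# Correlation between the threshold indicators I(Z1 < t1), I(Z2 < t2).
indicator_cor <- function(p1, p2, rho) {
  t1 <- stats::qnorm(p1); t2 <- stats::qnorm(p2)
  p11 <- bvn_cdf(t1, t2, rho)
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Latent correlation such that the mean pairwise haplotype-allele correlation
# within the block equals sqrt(target_r2); dosage correlation of summed
# independent haplotypes then equals the allele correlation, so realized
# dosage r2 targets target_r2.
calibrate_block_rho <- function(eafs, target_r2) {
  if (target_r2 == 0) return(0)
  target_r <- sqrt(target_r2)
  pairs <- utils::combn(length(eafs), 2)
  mean_cor <- function(rho) {
    mean(apply(pairs, 2, function(ix)
      indicator_cor(eafs[ix[1]], eafs[ix[2]], rho)))
  }
  upper <- 0.99999
  if (mean_cor(upper) < target_r) {
    stop("calibration error: block allele frequencies cannot reach r2 = ",
         target_r2)
  }
  stats::uniroot(function(rho) mean_cor(rho) - target_r,
                 lower = 1e-9, upper = upper, tol = 1e-9)$root
}

block_rhos <- function(config) {
  panel <- config$snp_panel
  ids <- sort(unique(panel$block_id[!is.na(panel$block_id)]))
  out <- stats::setNames(numeric(length(ids)), as.character(ids))
  for (b in ids) {
    eafs <- panel$eaf[!is.na(panel$block_id) & panel$block_id == b]
    if (length(eafs) < 2) { out[as.character(b)] <- 0; next }
    out[as.character(b)] <- calibrate_block_rho(eafs, config$block_r2)
  }
  out
}

# One cohort's worth of population dosages (no missingness). Haplotypes in a
# block share a latent factor: Z_j = sqrt(rho) U + sqrt(1-rho) e_j, allele
# carried when Z_j < qnorm(eaf_j). Unblocked SNPs are independent binomials.
sim_dosages <- function(panel, n, rhos) {
  m <- nrow(panel)
  d <- matrix(0L, n, m)
  blocked <- !is.na(panel$block_id)
  if (any(!blocked)) {
    for (j in which(!blocked)) {
      d[, j] <- stats::rbinom(n, 2L, panel$eaf[j])
    }
  }
  for (b in unique(panel$block_id[blocked])) {
    jj <- which(blocked & panel$block_id == b)
    rho <- rhos[as.character(b)]
    t_j <- stats::qnorm(panel$eaf[jj])
    hap <- matrix(0L, n, length(jj))
    for (h in 1:2) {
      u <- stats::rnorm(n)
      z <- sqrt(rho) * u + sqrt(1 - rho) *
        matrix(stats::rnorm(n * length(jj)), n)
      hap <- hap + (z < matrix(t_j, n, length(jj), byrow = TRUE))
    }
    d[, jj] <- hap
  }
  d
}

panel_manifest <- function(panel) {
  snp_manifest(panel$snp_id, panel$chrom, panel$pos, panel$effect_allele,
               panel$other_allele)
}

#' Simulate a population genotype matrix with truth metadata
#'
#' Draws `n` unascertained individuals from the configured panel: LD blocks
#' via the latent-Gaussian copula, unblocked SNPs independent, missingness
#' applied uniformly at the configured rate (heavier for dropout SNPs).
#'
#' @param config a [sim_config()]; its `seed` is applied before drawing.
#' @param n number of individuals (default 5000).
#' @return List: `gm` (a [genotype_matrix()]), `truth` (list with per-SNP
#'   `snps` table — true OR, EAF, block — and per-sample linear predictor
#'   `lp` on the log-odds scale, before the intercept).
#' @export
simulate_genotypes <- function(config, n = 5000) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rhos <- block_rhos(config)
  panel <- config$snp_panel
  d <- sim_dosages(panel, n, rhos)
  lp <- drop(d %*% log(panel$or_true))
  d <- apply_missingness(d, panel, config)
  gm <- genotype_matrix(d, sprintf("S%05d", seq_len(n)),
                        panel_manifest(panel))
  truth <- list(
    snps = data.frame(snp_id = panel$snp_id, true_or = panel$or_true,
                      true_eaf = panel$eaf, block_id = panel$block_id,
                      stringsAsFactors = FALSE),
    lp = stats::setNames(lp, gm$sample_ids)
  )
  list(gm = gm, truth = truth)
}

apply_missingness <- function(d, panel, config) {
  n <- nrow(d); m <- ncol(d)
  if (config$missing_rate > 0) {
    d[matrix(stats::runif(n * m) < config$missing_rate, n, m)] <- NA_integer_
  }
  if (length(config$dropout_snps)) {
    jj <- match(config$dropout_snps, panel$snp_id)
    if (anyNA(jj)) stop("dropout SNP not in panel")
    for (j in jj) d[stats::runif(n) < config$dropout_rate, j] <- NA_integer_
  }
  d
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

# Intercept such that mean plogis(alpha + eta) = prevalence, by bisection on
# a fixed calibration vector eta.
tune_alpha <- function(eta, prevalence) {
  f <- function(a) mean(stats::plogis(a + eta)) - prevalence
  lo <- -60; hi <- 60
  if (f(lo) > 0 || f(hi) < 0) stop("tuning error: case fraction unattainable")
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-10)$root
}

#' Assign disease status and age to simulated genotypes
#'
#' Disease probability is logistic(alpha + sum_j log(OR_j) g_ij [+ slope *
#' (age - control mean)]), with alpha tuned by bisection so the expected case
#' fraction equals the configured prevalence. With a zero age slope, ages are
#' drawn per class from the configured truncated normals after status
#' assignment; with a non-zero slope, ages are drawn first (from the control
#' distribution) and enter the disease model.
#'
#' @param gm genotype matrix from [simulate_genotypes()].
#' @param truth its truth metadata (uses the per-sample linear predictor).
#' @param config a [sim_config()].
#' @param age_model which age model to use (default `config$age_model`).
#' @return A [phenotype_table()] for every sample in `gm`.
#' @export
simulate_phenotypes <- function(gm, truth, config,
                                age_model = config$age_model) {
  lp <- truth$lp[gm$sample_ids]
  n <- length(lp)
  lo <- config$age_range[1]; hi <- config$age_range[2]
  slope <- if (is.null(age_model$slope)) 0 else age_model$slope
  if (slope != 0) {
    age <- rtruncnorm(n, age_model$control_mean, age_model$control_sd, lo, hi)
    eta <- lp + slope * (age - age_model$control_mean)
  } else {
    age <- rep(NA_real_, n)
    eta <- lp
  }
  alpha <- tune_alpha(eta, config$prevalence)
  y <- stats::rbinom(n, 1L, stats::plogis(alpha + eta))
  if (slope == 0) {
    age[y == 1] <- rtruncnorm(sum(y), age_model$case_mean, age_model$case_sd,
                              lo, hi)
    age[y == 0] <- rtruncnorm(sum(y == 0), age_model$control_mean,
                              age_model$control_sd, lo, hi)
  }
  phenotype_table(gm$sample_ids, ifelse(y == 1, "case", "control"), age)
}

# Fill case/control quotas by oversampling the population and keeping the
# first arrivals of each class (ORs are invariant to this ascertainment).
sim_cohort <- function(config, n_cases, n_controls, age_model, rhos,
                       id_prefix) {
  panel <- config$snp_panel
  got_case <- 0L; got_ctrl <- 0L
  acc_d <- list(); acc_y <- list(); acc_age <- list(); acc_lp <- list()
  alpha <- NULL
  lo <- config$age_range[1]; hi <- config$age_range[2]
  slope <- if (is.null(age_model$slope)) 0 else age_model$slope
  while (got_case < n_cases || got_ctrl < n_controls) {
    need_case <- n_cases - got_case
    need_ctrl <- n_controls - got_ctrl
    batch <- max(2000L,
                 ceiling(1.3 * max(need_case / config$prevalence,
                                   need_ctrl / (1 - config$prevalence))))
    d <- sim_dosages(panel, batch, rhos)
    lp <- drop(d %*% log(panel$or_true))
    d <- apply_missingness(d, panel, config)
    eligible <- rowMeans(!is.na(d)) >= config$min_call_rate
    if (slope != 0) {
      age <- rtruncnorm(batch, age_model$control_mean, age_model$control_sd,
                        lo, hi)
      eta <- lp + slope * (age - age_model$control_mean)
    } else {
      age <- rep(NA_real_, batch)
      eta <- lp
    }
    if (is.null(alpha)) alpha <- tune_alpha(eta, config$prevalence)
    y <- stats::rbinom(batch, 1L, stats::plogis(alpha + eta))
    ok_case <- which(y == 1L & eligible)
    ok_ctrl <- which(y == 0L & eligible)
    take_case <- ok_case[seq_len(min(need_case, length(ok_case)))]
    take_ctrl <- ok_ctrl[seq_len(min(need_ctrl, length(ok_ctrl)))]
    take <- c(take_case, take_ctrl)
    if (length(take)) {
      acc_d[[length(acc_d) + 1]] <- d[take, , drop = FALSE]
      acc_y[[length(acc_y) + 1]] <- y[take]
      acc_age[[length(acc_age) + 1]] <- age[take]
      acc_lp[[length(acc_lp) + 1]] <- lp[take]
    }
    got_case <- got_case + length(take_case)
    got_ctrl <- got_ctrl + length(take_ctrl)
  }
  d <- do.call(rbind, acc_d)
  y <- unlist(acc_y)
  age <- unlist(acc_age)
  lp <- unlist(acc_lp)
  if (slope == 0) {
    age[y == 1] <- rtruncnorm(sum(y == 1), age_model$case_mean,
                              age_model$case_sd, lo, hi)
    age[y == 0] <- rtruncnorm(sum(y == 0), age_model$control_mean,
                              age_model$control_sd, lo, hi)
  }
  ids <- sprintf("%s%05d", id_prefix, seq_along(y))
  gm <- genotype_matrix(d, ids, panel_manifest(panel))
  phen <- phenotype_table(ids, ifelse(y == 1L, "case", "control"), age)
  list(gm = gm, phen = phen, lp = stats::setNames(lp, ids))
}

#' Simulate a complete two-cohort case-control study
#'
#' Generates both cohorts from a single seed: the training cohort (cohort 1)
#' and the independent evaluation cohort (cohort 2), each filled to its
#' case/control quota by rejection sampling from the configured disease
#' model, with truth metadata for parameter-recovery testing.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_study`: `cohort1`, `cohort2` (each `gm`,
#'   `phen`), `truth` (per-SNP table plus per-sample linear predictors
#'   `lp1`, `lp2`), `manifest`, `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rhos <- block_rhos(config)
  c1 <- sim_cohort(config, config$n_cases_1, config$n_controls_1,
                   config$age_model, rhos, "C1_")
  c2 <- sim_cohort(config, config$n_cases_2, config$n_controls_2,
                   config$age_model_2, rhos, "C2_")
  structure(list(
    cohort1 = list(gm = c1$gm, phen = c1$phen),
    cohort2 = list(gm = c2$gm, phen = c2$phen),
    truth = list(snps = data.frame(snp_id = config$snp_panel$snp_id,
                                   true_or = config$snp_panel$or_true,
                                   true_eaf = config$snp_panel$eaf,
                                   block_id = config$snp_panel$block_id,
                                   stringsAsFactors = FALSE),
                 lp1 = c1$lp, lp2 = c2$lp),
    manifest = panel_manifest(config$snp_panel),
    config = config
  ), class = "sim_study")
}
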