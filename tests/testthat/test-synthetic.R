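test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 33, n_cases_1 = 100, n_controls_1 = 100,
                    n_cases_2 = 40, n_controls_2 = 40)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$cohort1$gm$dosage, b$cohort1$gm$dosage)
  expect_identical(a$cohort2$gm$dosage, b$cohort2$gm$dosage)
  expect_identical(a$cohort1$phen, b$cohort1$phen)
  expect_identical(a$truth$lp1, b$truth$lp1)
})

test_that("realized allele frequencies match their targets", {
  panel <- data.frame(snp_id = c("p1", "p2"), chrom = "1",
                      pos = c(100L, 200L), effect_allele = "A",
                      other_allele = "G", eaf = c(0.30, 0.05),
                      or_true = 1, block_id = NA_integer_)
  cfg <- sim_config(seed = 35, snp_panel = panel, missing_rate = 0)
  pop <- simulate_genotypes(cfg, n = 20000)
  af <- allele_frequencies(pop$gm)
  expect_lt(abs(af$eaf[1] - 0.30), 0.01)
  expect_lt(abs(af$eaf[2] - 0.05), 0.01)
})

test_that("block LD calibration hits the target r2 band", {
  panel <- data.frame(snp_id = sprintf("b%d", 1:4), chrom = "1",
                      pos = (1:4) * 100L, effect_allele = "A",
                      other_allele = "G", eaf = 0.3, or_true = 1,
                      block_id = 1L)
  cfg <- sim_config(seed = 37, snp_panel = panel, block_r2 = 0.8,
                    missing_rate = 0)
  pop <- simulate_genotypes(cfg, n = 2000)
  ld <- ld_matrix(pop$gm)
  off <- ld$r2[upper.tri(ld$r2)]
  expect_true(all(off > 0.70 & off < 0.90))
})

test_that("an infeasible frequency/r2 pair is a calibration error", {
  panel <- data.frame(snp_id = c("q1", "q2"), chrom = "1",
                      pos = c(100L, 200L), effect_allele = "A",
                      other_allele = "G", eaf = c(0.01, 0.50),
                      or_true = 1, block_id = 1L)
  cfg <- sim_config(seed = 39, snp_panel = panel, block_r2 = 0.9,
                    missing_rate = 0)
  expect_error(simulate_genotypes(cfg, n = 10), "calibration error")
})

test_that("case and control age distributions match the configured means", {
  cfg <- sim_config(seed = 41, n_cases_1 = 1294, n_controls_1 = 885,
                    n_cases_2 = 301, n_controls_2 = 243)
  st <- simulate_study(cfg)
  m1 <- tapply(st$cohort1$phen$age, st$cohort1$phen$status, mean)
  expect_equal(unname(m1["case"]), 50.2, tolerance = 1)
  expect_equal(unname(m1["control"]), 42.7, tolerance = 1)
  m2 <- tapply(st$cohort2$phen$age, st$cohort2$phen$status, mean)
  expect_equal(unname(m2["case"]), 49.9, tolerance = 2)
  expect_equal(unname(m2["control"]), 42.0, tolerance = 2)
  expect_true(all(st$cohort1$phen$age >= 20 & st$cohort1$phen$age <= 90))
})

test_that("cohorts fill their case/control quotas exactly", {
  cfg <- sim_config(seed = 43, n_cases_1 = 150, n_controls_1 = 90,
                    n_cases_2 = 40, n_controls_2 = 25)
  st <- simulate_study(cfg)
  expect_equal(sum(st$cohort1$phen$status == "case"), 150L)
  expect_equal(sum(st$cohort1$phen$status == "control"), 90L)
  expect_equal(sum(st$cohort2$phen$status == "case"), 40L)
  expect_equal(sum(st$cohort2$phen$status == "control"), 25L)
})

test_that("assay-dropout SNPs fall below the call-rate threshold", {
  cfg <- sim_config(seed = 45, n_cases_1 = 400, n_controls_1 = 300,
                    n_cases_2 = 40, n_controls_2 = 40,
                    dropout_snps = "rs_null01", dropout_rate = 0.10)
  st <- simulate_study(cfg)
  expect_lt(snp_call_rate(st$cohort1$gm, "rs_null01"), 0.95)
  res <- apply_snp_filters(st$cohort1$gm, st$cohort1$phen)$results
  expect_match(res$fail_reasons[res$snp_id == "rs_null01"], "low_call_rate")
})

test_that("the preset panel reproduces the 51-to-46 QC narrative", {
  expect_equal(nrow(default_snp_panel()), 51L)
  cfg <- sim_config(seed = 47)
  st <- simulate_study(cfg)
  out <- apply_snp_filters(st$cohort1$gm, st$cohort1$phen)
  expect_equal(sum(out$results$passed), 46L)
  excluded <- out$results$snp_id[!out$results$passed]
  expect_setequal(excluded, sprintf("rs_rare%02d", 1:5))
  expect_true(all(grepl("low_maf",
                        out$results$fail_reasons[!out$results$passed])))
})

test_that("simulated genotypes respect Hardy-Weinberg in controls", {
  cfg <- sim_config(seed = 49, n_cases_1 = 600, n_controls_1 = 600,
                    n_cases_2 = 40, n_controls_2 = 40)
  st <- simulate_study(cfg)
  p <- hwe_controls(st$cohort1$gm, st$cohort1$phen)
  expect_true(all(p[!is.na(p)] > 1e-4))
})
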