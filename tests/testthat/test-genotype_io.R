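test_that("manifest and genotype matrix invariants are enforced", {
  expect_error(snp_manifest(c("a", "a"), c("1", "1"), c(1, 2), c("A", "A"),
                            c("G", "G")), "duplicate snp_id")
  expect_error(snp_manifest("a", "1", 1, "A", "A"), "equals other_allele")
  man <- toy_manifest(2)
  expect_error(genotype_matrix(matrix(c(0, 3), 1, 2), "s1", man),
               "must be 0, 1 or 2")
  expect_error(genotype_matrix(matrix(0L, 2, 2), c("s1", "s1"), man),
               "duplicate sample ids")
})

test_that("TSV and PLINK round trips are lossless", {
  set.seed(42)
  for (i in 1:5) {
    n <- sample(1:30, 1); m <- sample(1:12, 1)
    gm <- random_gm(n, m, miss = 0.15)
    tsv <- tempfile(fileext = ".tsv")
    write_genotypes(gm, tsv, dialect = "tsv")
    back <- read_genotypes(tsv, gm$snps, dialect = "tsv")
    expect_identical(back$dosage, gm$dosage)
    expect_identical(back$sample_ids, gm$sample_ids)
    px <- tempfile()
    write_genotypes(gm, px, dialect = "plink_text")
    back2 <- read_genotypes(px, gm$snps, dialect = "plink_text")
    expect_identical(back2$dosage, gm$dosage)
  }
})

test_that("simulator output round-trips losslessly at study scale", {
  cfg <- sim_config(seed = 3, n_cases_1 = 300, n_controls_1 = 200,
                    n_cases_2 = 30, n_controls_2 = 30)
  st <- simulate_study(cfg)
  tsv <- tempfile(fileext = ".tsv")
  write_genotypes(st$cohort1$gm, tsv, dialect = "tsv")
  back <- read_genotypes(tsv, st$manifest, dialect = "tsv")
  expect_identical(back$dosage, st$cohort1$gm$dosage)
})

test_that("ped alleles convert to effect-allele counts against the manifest", {
  man <- snp_manifest(c("rs1", "rs2"), c("1", "1"), c(100, 200),
                      c("A", "C"), c("G", "T"))
  px <- tempfile()
  writeLines(c("f1 s1 0 0 0 0 A A C T",
               "f2 s2 0 0 0 0 G A 0 0"), paste0(px, ".ped"))
  writeLines(c("1\trs1\t0\t100", "1\trs2\t0\t200"), paste0(px, ".map"))
  gm <- read_genotypes(px, man, dialect = "plink_text")
  expect_equal(unname(gm$dosage["s1", ]), c(2L, 1L))
  expect_equal(unname(gm$dosage["s2", ]), c(1L, NA_integer_))
})

test_that("an allele outside the manifest pair is an orientation error", {
  man <- snp_manifest("rs1", "1", 100, "A", "G")
  px <- tempfile()
  writeLines("f1 s1 0 0 0 0 A T", paste0(px, ".ped"))
  writeLines("1\trs1\t0\t100", paste0(px, ".map"))
  expect_error(read_genotypes(px, man, dialect = "plink_text"),
               "orientation error at SNP rs1")
})

test_that("malformed ped lines are reported with their line number", {
  man <- snp_manifest("rs1", "1", 100, "A", "G")
  px <- tempfile()
  writeLines(c("f1 s1 0 0 0 0 A A", "f2 s2 0 0 0 0 A"), paste0(px, ".ped"))
  writeLines("1\trs1\t0\t100", paste0(px, ".map"))
  expect_error(read_genotypes(px, man, dialect = "plink_text"), "line 2")
})

test_that("an empty matrix writes and reads as a header-only TSV", {
  man <- toy_manifest(3)
  gm <- genotype_matrix(matrix(integer(), 0, 3), character(), man)
  tsv <- tempfile(fileext = ".tsv")
  write_genotypes(gm, tsv)
  expect_length(readLines(tsv), 1L)
  back <- read_genotypes(tsv, man)
  expect_equal(dim(back), c(0L, 3L))
})

test_that("phenotype status dialects parse and errors are loud", {
  f <- tempfile()
  writeLines(c("sample_id\tstatus\tage", "s1\t1\t50", "s2\t0\t40"), f)
  ph <- read_phenotypes(f, status_dialect = "zero_one")
  expect_equal(ph$status, c("case", "control"))
  writeLines(c("sample_id\tstatus\tage", "s1\t2\t50", "s2\t1\t40"), f)
  ph <- read_phenotypes(f, status_dialect = "plink")
  expect_equal(ph$status, c("case", "control"))
  writeLines(c("sample_id\tstatus\tage", "s1\tCase\tNA", "s2\tcontrol\t40"), f)
  ph <- read_phenotypes(f, status_dialect = "case_control")
  expect_equal(ph$status, c("case", "control"))
  expect_true(is.na(ph$age[1]))
  writeLines(c("sample_id\tstatus\tage", "s1\tmaybe\t50"), f)
  expect_error(read_phenotypes(f), "unparseable status")
  writeLines(c("sample_id\tstatus\tage", "s1\tcase\t50", "s1\tcase\t51"), f)
  expect_error(read_phenotypes(f), "duplicate sample id")
})

test_that("genotype/phenotype join is by id and reports unmatched samples", {
  gm <- random_gm(4, 2, miss = 0)
  # phenotypes deliberately permuted relative to genotype order, plus a
  # sample absent from the genotypes
  ph <- phenotype_table(c("s003", "s001", "s002", "s999"),
                        c("case", "control", "case", "control"),
                        c(50, 40, 45, 60))
  j <- join_cohort(gm, ph)
  expect_identical(j$gm$sample_ids, j$phen$sample_id)
  expect_equal(j$phen$status[j$phen$sample_id == "s003"], "case")
  expect_equal(j$log$phenotype_only, "s999")
  expect_equal(j$log$genotype_only, "s004")
  expect_equal(j$log$n_joined, 3L)
})
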