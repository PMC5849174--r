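test_that("r2 identities: self, anti-correlation, independence", {
  set.seed(5)
  n <- 2000
  ga <- rbinom(n, 2, 0.4)
  gm <- genotype_matrix(cbind(a = ga, b = 2L - ga,
                              c = rbinom(n, 2, 0.25)),
                        sprintf("s%05d", 1:n), toy_manifest(3))
  ld <- ld_matrix(gm)
  expect_equal(unname(diag(ld$r2)), c(1, 1, 1))
  expect_equal(ld$r2["snp01", "snp02"], 1.0)          # g_b = 2 - g_a
  expect_lt(ld$r2["snp01", "snp03"], 0.01)            # independent SNPs
  expect_true(isSymmetric(ld$r2))
  expect_equal(pairwise_r2(gm, "snp01", "snp02"), 1.0)
})

test_that("a monomorphic SNP yields NA r2, not a crash", {
  gm <- genotype_matrix(cbind(a = c(0L, 1L, 2L, 1L), b = rep(1L, 4)),
                        paste0("s", 1:4), toy_manifest(2))
  expect_true(is.na(pairwise_r2(gm, "snp01", "snp02")))
})

test_that("composite r2 equals haplotype r2 when phase is unambiguous", {
  # all-homozygote fixture: each sample carries two identical haplotypes, so
  # haplotype counts are exactly dosage/2 duplicated
  ga <- c(2L, 2L, 0L, 0L, 2L, 0L, 0L, 0L)
  gb <- c(2L, 0L, 0L, 0L, 2L, 2L, 0L, 0L)
  gm <- genotype_matrix(cbind(a = ga, b = gb), paste0("s", 1:8),
                        toy_manifest(2))
  # haplotype 2x2 table from dosage/2, r2 = D^2 / (pA qA pB qB)
  pa <- mean(ga / 2); pb <- mean(gb / 2)
  pab <- mean(ga / 2 * gb / 2)
  hap_r2 <- (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
  expect_equal(pairwise_r2(gm, "snp01", "snp02"), hap_r2, tolerance = 1e-12)
})

test_that("blocks are connected components at the r2 threshold", {
  ids <- c("a", "b", "c", "d")
  r2 <- diag(4)
  bl <- ld_blocks(fake_ld(ids, r2), threshold = 0.5)
  expect_equal(length(unique(bl)), 4L)  # all singletons
  # chain a-b (0.6), b-c (0.6), a-c (0.2): one block by connectivity
  r2 <- diag(4)
  r2[1, 2] <- r2[2, 1] <- 0.6
  r2[2, 3] <- r2[3, 2] <- 0.6
  r2[1, 3] <- r2[3, 1] <- 0.2
  bl <- ld_blocks(fake_ld(ids, r2), threshold = 0.5)
  expect_equal(bl[["a"]], bl[["b"]])
  expect_equal(bl[["b"]], bl[["c"]])
  expect_false(bl[["a"]] == bl[["d"]])
  # clique of 4 at 0.9: one block of 4
  r2 <- matrix(0.9, 4, 4); diag(r2) <- 1
  bl <- ld_blocks(fake_ld(ids, r2), threshold = 0.5)
  expect_equal(length(unique(bl)), 1L)
})

test_that("pruning keeps the most significant SNP per block and is idempotent", {
  ids <- c("a", "b", "c", "d", "e")
  r2 <- diag(5)
  r2[1, 2] <- r2[2, 1] <- 0.8
  r2[2, 3] <- r2[3, 2] <- 0.7
  ld <- fake_ld(ids, r2)
  man <- snp_manifest(ids, rep("1", 5), 1:5 * 100L,
                      rep("A", 5), rep("G", 5))
  cand <- data.frame(snp_id = ids, p = c(1e-3, 1e-6, 1e-2, 0.04, 0.2),
                     beta = c(0.2, 0.4, 0.1, 0.15, 0.05), converged = TRUE)
  pr <- prune_by_ld(cand, ld, man, threshold = 0.5)
  expect_setequal(pr$kept, c("b", "d", "e"))
  expect_equal(nrow(pr$log), 2L)
  expect_true(all(pr$log$kept_snp == "b"))
  # output size equals block count; pruning the pruned set changes nothing
  bl <- ld_blocks(ld, 0.5)
  expect_equal(length(pr$kept), length(unique(bl)))
  cand2 <- cand[cand$snp_id %in% pr$kept, ]
  pr2 <- prune_by_ld(cand2, ld, man, threshold = 0.5)
  expect_identical(pr2$kept, pr$kept)
  expect_equal(nrow(pr2$log), 0L)
})

test_that("prune tie-breaks: equal p goes to larger |beta|, then position", {
  ids <- c("x", "y")
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2)
  ld <- fake_ld(ids, r2)
  man <- snp_manifest(ids, c("1", "1"), c(200L, 100L), c("A", "A"),
                      c("G", "G"))
  cand <- data.frame(snp_id = ids, p = c(0.01, 0.01), beta = c(0.2, 0.5),
                     converged = TRUE)
  expect_equal(prune_by_ld(cand, ld, man)$kept, "y")
  cand$beta <- c(0.3, 0.3)  # full tie: earlier position wins
  expect_equal(prune_by_ld(cand, ld, man)$kept, "y")
})

test_that("all-singleton candidate sets prune to themselves", {
  ids <- letters[1:6]
  ld <- fake_ld(ids, diag(6))
  man <- snp_manifest(ids, rep("2", 6), 1:6 * 10L, rep("C", 6), rep("T", 6))
  cand <- data.frame(snp_id = ids, p = runif(6), beta = rnorm(6),
                     converged = TRUE)
  expect_identical(prune_by_ld(cand, ld, man)$kept, ids)
})
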