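test_that("one-binary-predictor logistic OR equals the 2x2 cross-product", {
  set.seed(17)
  for (i in 1:100) {
    tab <- sample(5:150, 4)  # exposed cases, unexp cases, exp ctrl, unexp ctrl
    y <- rep(c(1, 1, 0, 0), tab)
    x <- rep(c(1, 0, 1, 0), tab)
    fit <- fit_logistic(y, cbind(x = x))
    expect_equal(exp(fit$beta[["x"]]),
                 crude_or(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-7)
  }
})

test_that("reversing case/control labels negates every beta", {
  set.seed(23)
  n <- 500
  g <- rbinom(n, 2, 0.3)
  age <- rnorm(n, 45, 8)
  y <- rbinom(n, 1, plogis(-0.5 + 0.3 * g + 0.02 * age))
  f1 <- fit_logistic(y, cbind(g = g, age = age))
  f2 <- fit_logistic(1 - y, cbind(g = g, age = age))
  expect_equal(unname(f1$beta), -unname(f2$beta), tolerance = 1e-6)
})

test_that("degenerate designs are errors, separation is flagged", {
  y <- rep(c(0, 1), 20)
  expect_error(fit_logistic(y, cbind(x = rep(1, 40))), "constant predictor")
  expect_error(fit_logistic(rep(1, 40), cbind(x = rnorm(40))), "single class")
  x <- rnorm(40)
  expect_error(fit_logistic(y, cbind(a = x, b = 2 * x)), "rank-deficient")
  # complete separation: x perfectly predicts y
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(0, 1), each = 20)
  fit <- fit_logistic(ys, cbind(x = xs))
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("snp_association uses additive dosage and pairwise exclusion", {
  set.seed(31)
  n <- 600
  g <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-1 + log(1.5) * g))
  gm <- genotype_matrix(cbind(g), sprintf("s%04d", 1:n), toy_manifest(1))
  ph <- phenotype_table(gm$sample_ids, ifelse(y == 1, "case", "control"),
                        c(NA, rnorm(n - 1, 45, 5)))
  res <- snp_association(gm, ph, "snp01", adjust_age = FALSE)
  expect_equal(res$n_used, n)
  res_adj <- snp_association(gm, ph, "snp01", adjust_age = TRUE)
  expect_equal(res_adj$n_used, n - 1)  # missing-age sample dropped
  expect_equal(res$ci_low, exp(res$beta - 1.96 * res$se))
  expect_equal(res$ci_high, exp(res$beta + 1.96 * res$se))
  # monomorphic SNP yields an NA-effect row with a reason, not an error
  gm0 <- genotype_matrix(cbind(z = rep(1L, n)), gm$sample_ids,
                         toy_manifest(1))
  res0 <- snp_association(gm0, ph, "snp01")
  expect_true(is.na(res0$beta))
  expect_match(res0$note, "monomorphic")
})

test_that("age adjustment removes confounding when age drives both risk and dosage", {
  set.seed(41)
  n <- 20000
  age <- rnorm(n, 50, 8)
  # genotype frequency drifts with age; the SNP itself has no effect
  g <- rbinom(n, 2, plogis(qlogis(0.3) + 0.05 * (age - 50)))
  y <- rbinom(n, 1, plogis(-2 + 0.08 * (age - 50)))
  gm <- genotype_matrix(cbind(g), sprintf("s%05d", 1:n), toy_manifest(1))
  ph <- phenotype_table(gm$sample_ids, ifelse(y == 1, "case", "control"), age)
  unadj <- snp_association(gm, ph, "snp01", adjust_age = FALSE)
  adj <- snp_association(gm, ph, "snp01", adjust_age = TRUE)
  expect_gt(abs(unadj$beta), abs(adj$beta))  # adjusted is closer to truth (0)
  expect_gt(unadj$beta, 0.1)                 # confounding is material
  expect_lt(abs(adj$beta), 0.1)
})

test_that("unadjusted and adjusted agree when age is independent of both", {
  set.seed(43)
  n <- 5000
  g <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.5 + log(1.4) * g))
  age <- rnorm(n, 45, 8)
  gm <- genotype_matrix(cbind(g), sprintf("s%05d", 1:n), toy_manifest(1))
  ph <- phenotype_table(gm$sample_ids, ifelse(y == 1, "case", "control"), age)
  unadj <- snp_association(gm, ph, "snp01", FALSE)
  adj <- snp_association(gm, ph, "snp01", TRUE)
  expect_equal(adj$beta, unadj$beta, tolerance = 0.05)
})

test_that("significance selection is inclusive at the threshold", {
  res <- data.frame(snp_id = c("a", "b", "c"), p = c(0.5, 0.05, 0.049),
                    converged = TRUE, beta = 0.1)
  expect_equal(significant_snps(res, 0.05)$snp_id, c("b", "c"))
  res$p <- 0.5
  expect_equal(nrow(significant_snps(res, 0.05)), 0L)
})
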