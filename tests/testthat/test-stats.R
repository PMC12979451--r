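test_that("maltreatment classification applies the published cut-offs inclusively", {
  scores <- tibble::tibble(
    EA = c(13, 12, 5), PA = c(5, 9, 5), SA = c(5, 7, 5),
    EN = c(5, 14, 5), PN = c(5, 9, 5)
  )
  out <- classify_ctq(scores)
  expect_equal(as.character(out$maltreatment), c("CM", "nCM", "nCM"))
  expect_error(classify_ctq(scores[, -1]), "missing CTQ subscale")
})

test_that("permutation test is exact on degenerate inputs and deterministic", {
  same <- permutation_test(rep(2, 6), rep(2, 8), n_perm = 500, seed = 1)
  expect_equal(same$p_value, 1)

  sep <- permutation_test(rep(0, 5), rep(10, 5), n_perm = 10000, seed = 2)
  expect_lte(sep$p_value, 0.01)
  expect_gte(sep$p_value, 1 / 10001)

  a <- rnorm(10); b <- rnorm(12)
  expect_identical(permutation_test(a, b, 500, seed = 7),
                   permutation_test(a, b, 500, seed = 7))
  expect_error(permutation_test(numeric(0), b), "nonempty")
})

test_that("permutation p values are bounded below by the add-one estimator", {
  res <- permutation_test(c(0, 0, 0), c(100, 100, 100), n_perm = 19, seed = 1)
  expect_gte(res$p_value, 1 / 20)
  expect_lte(res$p_value, 1)
})

test_that("BH adjustment reproduces worked examples and its defining properties", {
  expect_equal(fdr_correct(0.2), 0.2)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_correct(rep(0.04, 5)), rep(0.04, 5))
  expect_error(fdr_correct(c(0.5, 1.2)), "out of \\[0, 1\\] at position 2")
  for (seed in 1:5) {
    p <- withr::with_seed(seed, runif(20)^2)
    adj <- fdr_correct(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("partial correlation reduces to Pearson without informative covariates", {
  withr::with_seed(3, {
    x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  })
  plain <- cor.test(x, y)
  pc <- partial_correlation(x, y, covariates = cbind(const = rep(2, 40)))
  expect_equal(pc$r, unname(plain$estimate), tolerance = 1e-12)

  # y identical to a covariate leaves no residual correlation
  withr::with_seed(4, { z <- rnorm(40); x2 <- rnorm(40) })
  pc2 <- partial_correlation(x2, z, covariates = cbind(z = z))
  expect_lt(abs(pc2$r), 1e-10)

  expect_error(
    partial_correlation(x, y, covariates = cbind(a = z, b = 2 * z)),
    "collinear column\\(s\\): b"
  )
})

test_that("partial correlation matches the precision-matrix oracle", {
  withr::with_seed(11, {
    n <- 50
    covs <- cbind(age = rnorm(n, 30, 6), sex = rbinom(n, 1, 0.5), edu = rnorm(n, 14, 2))
    x <- 0.3 * covs[, 1] + rnorm(n)
    y <- -0.2 * covs[, 1] + 0.4 * x + rnorm(n)
  })
  pc <- partial_correlation(x, y, covs)
  # first-order partial correlation via the inverse correlation matrix
  prec <- solve(stats::cor(cbind(x, y, covs)))
  oracle_r <- -prec[1, 2] / sqrt(prec[1, 1] * prec[2, 2])
  expect_equal(pc$r, oracle_r, tolerance = 1e-10)
})

test_that("partial correlation is invariant to affine covariate transformations", {
  withr::with_seed(12, {
    n <- 35
    covs <- cbind(a = rnorm(n), b = runif(n))
    x <- rnorm(n); y <- rnorm(n)
  })
  base_r <- partial_correlation(x, y, covs)$r
  shifted <- cbind(a = 3 * covs[, 1] - 7, b = 100 * covs[, 2] + 4)
  expect_equal(partial_correlation(x, y, shifted)$r, base_r, tolerance = 1e-10)
})

test_that("summary-based ANOVA matches a raw-data oracle and degenerate cases", {
  means <- c(10, 12, 15); sds <- c(2, 2.5, 3); ns <- c(20, 25, 30)
  fit <- anova_from_summary(means, sds, ns)
  raw <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(g = factor(i), y = exact_sample(ns[i], means[i], sds[i], seed = i))
  }))
  oracle <- anova(stats::lm(y ~ g, raw))
  expect_equal(fit$f_statistic, oracle$`F value`[1], tolerance = 1e-10)
  expect_equal(fit$p_value, oracle$`Pr(>F)`[1], tolerance = 1e-10)

  flat <- anova_from_summary(c(5, 5, 5), c(1, 1, 1), c(10, 10, 10))
  expect_equal(flat$f_statistic, 0)
  expect_error(anova_from_summary(c(1, 2), c(1, 1), c(1, 5)), "n >= 2")
})

test_that("summary-based ANOVA invariances hold on random instances", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      g <- sample(3:6, 1)
      means <- rnorm(g, 20, 5); sds <- runif(g, 1, 4); ns <- sample(10:40, g)
    })
    f0 <- anova_from_summary(means, sds, ns)$f_statistic
    expect_equal(anova_from_summary(means + 13.7, sds, ns)$f_statistic, f0)
    # scaling means' spread and sds together leaves F unchanged
    c_scale <- 2.5
    grand <- sum(ns * means) / sum(ns)
    expect_equal(
      anova_from_summary(grand + c_scale * (means - grand), c_scale * sds, ns)$f_statistic,
      f0, tolerance = 1e-10
    )
  }
})

test_that("summary-based t test matches pooled Student t and handles zero variance", {
  raw1 <- exact_sample(15, 8, 2, seed = 21)
  raw2 <- exact_sample(18, 9.5, 2.4, seed = 22)
  fit <- two_sample_t_from_summary(8, 2, 15, 9.5, 2.4, 18)
  oracle <- stats::t.test(raw1, raw2, var.equal = TRUE)
  expect_equal(fit$t_statistic, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(fit$p_value, oracle$p.value, tolerance = 1e-10)

  expect_equal(two_sample_t_from_summary(5, 1, 10, 5, 2, 12)$t_statistic, 0)
  degenerate <- two_sample_t_from_summary(3, 0, 5, 7, 0, 5)
  expect_equal(degenerate$t_statistic, -Inf)
})

test_that("chi-squared statistic matches hand expansion and null structure", {
  # expected counts are all 15, so each of the four cells contributes 25/15
  hand <- chi_squared_independence(matrix(c(10, 20, 20, 10), 2))
  expect_equal(hand$chi_squared, 100 / 15, tolerance = 1e-12)
  same_prop <- chi_squared_independence(matrix(c(10, 20, 30, 60), 2))
  expect_equal(same_prop$chi_squared, 0, tolerance = 1e-12)
  expect_error(chi_squared_independence(matrix(c(0, 0, 5, 5), 2)), "zero marginal")
})

test_that("summary-based Tukey HSD matches the raw-data reference", {
  means <- c(10, 10.5, 14); sds <- c(2, 2.2, 2.1); ns <- c(20, 22, 18)
  fit <- tukey_hsd_from_summary(means, sds, ns, group_labels = c("g1", "g2", "g3"))
  raw <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(g = factor(paste0("g", i)), y = exact_sample(ns[i], means[i], sds[i], seed = 30 + i))
  }))
  ref <- stats::TukeyHSD(stats::aov(y ~ g, raw))$g
  expect_equal(fit$p_adj[fit$group_1 == "g1" & fit$group_2 == "g2"],
               ref["g2-g1", "p adj"], tolerance = 1e-8)
  expect_equal(fit$p_adj[fit$group_1 == "g1" & fit$group_2 == "g3"],
               ref["g3-g1", "p adj"], tolerance = 1e-8)

  flat <- tukey_hsd_from_summary(c(5, 5, 5), c(1, 1, 1), c(12, 12, 12))
  expect_true(all(flat$p_adj > 0.999))

  outlier <- tukey_hsd_from_summary(c(5, 5.2, 20), c(1, 1, 1), c(12, 12, 12))
  involving3 <- outlier$p_adj[outlier$group_1 == "group_3" | outlier$group_2 == "group_3"]
  expect_true(max(involving3) < min(outlier$p_adj[outlier$group_1 != "group_3" &
                                                    outlier$group_2 != "group_3"]))
})

test_that("the bundled cohort summary reconstructs into one statistic per variable", {
  out <- reconstruct_summary_statistics(cohort_summary(), cohort_sex_counts())
  expect_equal(nrow(out), 11)   # sex + 10 continuous variables
  expect_setequal(unique(out$test), c("chi_squared", "anova", "t"))
  expect_true(all(is.finite(out$statistic)))
})
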