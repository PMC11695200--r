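test_that("glm group test equals the pooled two-sample t without covariates", {
  set.seed(1)
  y <- rnorm(40)
  g <- rep(c("a", "b"), each = 20)
  res <- glm_group_test(y, g)
  tt <- t.test(y[g == "b"], y[g == "a"], var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$df, unname(tt$parameter))
})

test_that("glm group test agrees with stats::lm under covariates", {
  set.seed(2)
  n <- 80
  g <- rep(0:1, each = n / 2)
  age <- rnorm(n, 60, 6)
  edu <- rnorm(n, 11, 2)
  y <- 0.4 * g + 0.05 * age + rnorm(n)
  res <- glm_group_test(y, g, cbind(age = age, edu = edu))
  ref <- summary(lm(y ~ g + age + edu))$coefficients["g", ]
  expect_equal(res$estimate, unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(res$t, unname(ref["t value"]), tolerance = 1e-10)
  expect_equal(res$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("glm group test recovers a simulated effect and flags degenerate inputs", {
  set.seed(3)
  n <- 200
  g <- rep(0:1, each = n / 2)
  age <- rnorm(n, 60, 6)
  y <- 0.5 * g + 0.1 * age + rnorm(n)
  res <- glm_group_test(y, g, cbind(age = age))
  se <- res$estimate / res$t
  expect_lt(abs(res$estimate - 0.5), 3 * se)

  # constant outcome: zero effect, p = 1 by convention
  resc <- glm_group_test(rep(1, 40), rep(0:1, 20))
  expect_equal(resc$estimate, 0)
  expect_equal(resc$p, 1)

  # collinear design is named
  expect_error(glm_group_test(rnorm(40), rep(0:1, 20),
                              cbind(dup = rep(0:1, 20))),
               "collinear")
})

test_that("BH adjustment matches the step-up rule and handles edge cases", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(res$significant))
  expect_equal(bh_fdr(1)$q, 1)
  expect_false(bh_fdr(1)$significant)
  expect_length(bh_fdr(numeric(0))$q, 0)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  # 1000 random p-vectors against the brute-force step-up definition
  set.seed(4)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- if (runif(1) < 0.5) runif(m) else rbeta(m, 0.3, 4)
    mine <- bh_fdr(p, 0.05)
    oracle <- oracle_bh(p, 0.05)
    expect_equal(mine$q, oracle$q, tolerance = 1e-12)
    expect_identical(mine$significant, oracle$significant)
  }
})

test_that("partial correlation reduces, errors, and is consistent for trivariate normals", {
  set.seed(5)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)

  z <- rnorm(50)
  expect_error(partial_correlation(x, z, cbind(z)), "constant residuals")

  # known partial correlation 0.4 given z
  n <- 1e4
  rho <- 0.4
  z <- rnorm(n)
  e1 <- rnorm(n); e2 <- rho * e1 + sqrt(1 - rho^2) * rnorm(n)
  x <- 0.8 * z + e1
  y <- -0.5 * z + e2
  res <- partial_correlation(x, y, cbind(z = z))
  expect_lt(abs(res$r - rho), 0.03)
  expect_equal(res$df, n - 3)
})

test_that("summary-statistic t tests satisfy algebraic identities", {
  expect_equal(welch_t(5, 1, 10, 5, 2, 12)$t, 0)
  expect_equal(pooled_t(5, 1, 10, 5, 2, 12)$t, 0)
  # doubling both n at fixed means/sds scales Welch t by sqrt(2)
  t1 <- welch_t(1, 1, 20, 0, 1, 30)$t
  t2 <- welch_t(1, 1, 40, 0, 1, 60)$t
  expect_equal(t2 / t1, sqrt(2), tolerance = 1e-12)
  # equal sds and equal n: pooled equals Welch
  expect_equal(pooled_t(1, 1.3, 25, 0.2, 1.3, 25)$t,
               welch_t(1, 1.3, 25, 0.2, 1.3, 25)$t, tolerance = 1e-12)
  expect_error(welch_t(1, 0, 10, 0, 1, 10), "sd > 0")
})

test_that("chi-square matches stats::chisq.test and its symmetries", {
  expect_equal(chi_square_2x2(matrix(c(10, 20, 10, 20), 2))$chisq, 0)
  tab <- matrix(c(31, 32, 35, 22), 2)
  expect_equal(chi_square_2x2(tab)$chisq, chi_square_2x2(t(tab))$chisq)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("cohort summary tests reproduce the printed reference statistics", {
  res <- cohort_summary_tests()
  stat <- function(ch) res$statistic[res$characteristic == ch]
  # chi-square to printed precision
  expect_lt(abs(stat("gender") - 1.799), 0.005)
  # t statistics within rounding of the printed summaries
  printed <- c(age = 1.084, education = 0.218, pta_left = 26.036,
               pta_right = 19.480, pta_mean = 29.837, mmse = -0.628,
               moca = -1.784, tmt_a = 2.410, tmt_b = 2.357, dst = -2.383,
               dsst = 0.176)
  for (ch in names(printed)) {
    expect_lt(abs(stat(ch) - printed[[ch]]), 0.05)
  }
})

test_that("group_glm adjusts across features and respects the FDR flag", {
  set.seed(6)
  ch <- tiny_cohort(n = 15, t_len = 40, seed = 8)
  feats <- tibble::tibble(subject_id = ch$panel$manifest$subject_id,
                          f1 = rnorm(30), f2 = rnorm(30), f3 = rnorm(30))
  res <- group_glm(feats, ch$panel$manifest)
  expect_s3_class(res, "glm_result")
  expect_true(all(res$q >= res$p - 1e-15))
  expect_true(all(res$q <= 1))
  res_nofdr <- group_glm(feats, ch$panel$manifest, fdr = FALSE)
  expect_equal(res_nofdr$q, res_nofdr$p)
  g <- glance(res)
  expect_equal(g$n_features, 3)
})

test_that("the two covariate-adjustment routes agree: GLM t vs partial correlation t", {
  set.seed(7)
  n <- 60
  g <- rep(0:1, each = n / 2)
  age <- rnorm(n, 60, 5)
  y <- 0.3 * g + 0.05 * age + rnorm(n)
  t_glm <- glm_group_test(y, g, cbind(age = age))$t
  t_pc <- partial_correlation(y, g, cbind(age = age))$t
  expect_equal(t_glm, t_pc, tolerance = 1e-10)
})

test_that("subgroup contrasts control FDR under the null and validate splits", {
  set.seed(8)
  n_sig <- 0
  n_feat <- 20
  reps <- 20
  for (r in seq_len(reps)) {
    man <- tibble::tibble(subject_id = sprintf("S%02d", 1:40),
                          group = "arhl",
                          age = rnorm(40, 60, 6),
                          gender = rbinom(40, 1, 0.5),
                          education = rnorm(40, 11, 2),
                          moca = rnorm(40, 26, 2))
    feats <- tibble::tibble(subject_id = man$subject_id)
    for (f in seq_len(n_feat)) feats[[paste0("f", f)]] <- rnorm(40)
    res <- subgroup_contrast(feats, man, "moca", 26, within_group = "arhl")
    n_sig <- n_sig + sum(res$significant)
  }
  expect_lte(n_sig / (reps * n_feat), 0.05)

  man_bad <- tibble::tibble(subject_id = c("a", "b"), group = "arhl",
                            age = c(60, 62), gender = c(0, 1),
                            education = c(10, 12), moca = c(20, 21))
  feats_bad <- tibble::tibble(subject_id = c("a", "b"), f = c(1, 2))
  expect_error(subgroup_contrast(feats_bad, man_bad, "moca", 10,
                                 covariates = character(0)),
               "empty subgroup")
})
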