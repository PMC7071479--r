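test_that("the Shapiro-Wilk gate passes normal draws and rejects bimodal ones", {
  passes <- vapply(1:100, function(s) {
    withr::with_seed(s, shapiro_gate(rnorm(20))$normal)
  }, logical(1))
  expect_gte(mean(passes), 0.9)

  bimodal <- rep(c(0, 1), 20)
  expect_false(shapiro_gate(bimodal)$normal)

  expect_error(shapiro_gate(rep(2, 10)), "identical")
  expect_error(shapiro_gate(c(1, 2)), "at least 3")
})

test_that("pairwise t-tests cover the six design comparisons", {
  cases <- data.frame(
    mean_score = c(2.13, 2.59, 2.92, 1.07, 1.39, 1.70,
                   1.22, 1.52, 1.81, 1.00, 1.28, 1.55),
    group = rep(group_levels(), each = 3))
  tt <- pairwise_ttests(cases)
  expect_equal(nrow(tt), 6)
  expect_equal(tt$group1[1:3], rep("early_MFG", 3))
  expect_true(all(tt$p_value >= 0 & tt$p_value <= 1))
  expect_equal(tt$p_value, tt$p_adjusted)  # no correction by default
  holm <- pairwise_ttests(cases, p_adjust = "holm")
  expect_true(all(holm$p_adjusted >= holm$p_value))
})

test_that("the t statistic matches the pooled-variance closed form", {
  a <- c(2.13, 2.59, 2.92); b <- c(1.00, 1.24, 1.55)
  cases <- data.frame(mean_score = c(a, 2, 2.1, 1.9, 2.0, b),
                      group = rep(group_levels(), c(3, 2, 2, 3)))
  tt <- pairwise_ttests(cases)
  row <- tt[tt$group1 == "early_MFG" & tt$group2 == "late_aHPC", ]
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  expect_equal(row$t, t_oracle, tolerance = 1e-12)
  expect_equal(row$p_value, p_oracle, tolerance = 1e-12)
  expect_lt(row$p_value, 0.05)  # closed form gives p = 0.01003

  # identical (non-constant) groups: t = 0, p = 1
  eq <- data.frame(mean_score = rep(c(1, 2, 3), 4),
                   group = rep(group_levels(), each = 3))
  tteq <- pairwise_ttests(eq)
  expect_true(all(abs(tteq$t) < 1e-12))
  expect_true(all(abs(tteq$p_value - 1) < 1e-12))
})

test_that("undersized or missing groups are refused", {
  cases <- data.frame(mean_score = c(1, 2, 3, 1, 2, 1.5, 2.5),
                      group = c("early_MFG", "early_MFG", "early_aHPC",
                                "early_aHPC", "late_MFG", "late_MFG",
                                "late_aHPC"))
  expect_error(pairwise_ttests(cases), "too small")
  expect_error(pairwise_ttests(cases[1:4, ]), "absent")
})

test_that("t-test type-I error is near nominal under the null", {
  reject <- withr::with_seed(42, {
    vapply(1:2000, function(i) {
      t.test(rnorm(5), rnorm(5), var.equal = TRUE)$p.value < 0.05
    }, logical(1))
  })
  # binomial 3 SE band around 0.05 at 2000 reps
  expect_lt(abs(mean(reject) - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("APOE genotypes map to epsilon-4 allele counts", {
  expect_equal(apoe_e4_count(c("e3/e3", "e3/e4", "e4/e4")), c(0L, 1L, 2L))
  expect_equal(apoe_e4_count("ε3–ε4"), 1L)  # ε3–ε4
  expect_true(is.na(apoe_e4_count("-")))
  expect_true(is.na(apoe_e4_count(NA)))
  expect_error(apoe_e4_count("x/y"), "unparseable")
})

test_that("ANCOVA drops incomplete cases and reports covariate tests", {
  meta <- cohort_metadata()
  # two regions per patient, score driven by stage and region only
  cases <- withr::with_seed(7, do.call(rbind, lapply(c("MFG", "aHPC"),
    function(rg) {
      d <- meta
      d$region <- rg
      d$mean_score <- 2.5 - 0.8 * (d$stage == "late") -
        0.6 * (rg == "aHPC") + rnorm(10, 0, 0.15)
      d$case_id <- paste(d$case_id, rg, sep = "_")
      d
    })))
  expect_message(res <- ancova_covariates(cases), "HT-20-13")
  expect_equal(res$n_used, 18)
  expect_setequal(res$table$term,
                  c("stage", "region", "age", "final_mmse", "apoe_e4"))
  expect_true(all(res$table$p_value >= 0 & res$table$p_value <= 1,
                  na.rm = TRUE))
})

test_that("a planted age effect is detected and constant covariates flagged", {
  cases <- withr::with_seed(11, {
    n <- 24
    d <- data.frame(case_id = sprintf("c%02d", 1:n),
                    stage = rep(c("early", "late"), each = n / 2),
                    region = rep(c("MFG", "aHPC"), times = n / 2),
                    age = round(runif(n, 55, 85)),
                    final_mmse = round(runif(n, 0, 26)),
                    apoe_e4 = sample(0:2, n, TRUE))
    d$mean_score <- 2 - 0.5 * (d$stage == "late") + 0.04 * (d$age - 70) +
      rnorm(n, 0, 0.1)
    d
  })
  res <- ancova_covariates(cases)
  expect_lt(res$table$p_value[res$table$term == "age"], 0.05)

  cases$final_mmse <- 20
  res2 <- ancova_covariates(cases)
  row <- res2$table[res2$table$term == "final_mmse", ]
  expect_match(row$note, "constant")
  expect_true(is.na(row$p_value))
})

test_that("Spearman rho uses midranks and matches independent oracles", {
  # perfect anti-monotone
  expect_equal(spearman_cor(1:10, 10:1)$rho, -1)
  # ties with G = 1 - R: complements stay perfectly anticorrelated
  R <- c(0.2, 0.2, 0.5, 0.9, 0.9, 0.7)
  s <- spearman_cor(R, 1 - R)
  expect_equal(s$rho, -1)
  # brute-force midrank oracle + stats::cor cross-check on tied data
  withr::with_seed(3, {
    for (rep in 1:10) {
      x <- sample(1:5, 12, replace = TRUE)
      y <- sample(1:5, 12, replace = TRUE)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) next
      got <- spearman_cor(x, y)$rho
      expect_equal(got, spearman_oracle(x, y), tolerance = 1e-12)
      expect_equal(got, unname(cor(x, y, method = "spearman")),
                   tolerance = 1e-12)
    }
  })
})

test_that("exact permutation p-values are returned for small n", {
  s <- spearman_cor(1:5, 5:1)
  expect_equal(s$method, "exact")
  expect_equal(s$p_value, 2 / factorial(5))  # only the two extremes

  # symmetric check: monotone increasing gives the same exact p
  expect_equal(spearman_cor(1:5, 1:5)$p_value, 2 / factorial(5))

  # exact p agrees with cor.test's exact method on untied data
  withr::with_seed(8, {
    x <- rnorm(7); y <- rnorm(7)
    ours <- spearman_cor(x, y)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("independent large samples show negligible correlation", {
  withr::with_seed(19, {
    x <- rnorm(1000); y <- rnorm(1000)
    s <- spearman_cor(x, y)
    expect_equal(s$method, "asymptotic")
    expect_lt(abs(s$rho), 0.1)
    expect_gt(s$p_value, 1e-4)
  })
  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_cor(1:2, 2:1), "at least 3")
})
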