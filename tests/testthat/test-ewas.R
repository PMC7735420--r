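test_that("per-site OLS matches the closed form and base lm()", {
  ages <- c(20, 30, 40, 50, 60, 70)
  beta <- c(0.40, 0.43, 0.44, 0.45, 0.48, 0.50)
  f <- fitSiteLm(beta, ages)
  # hand OLS: sum((x-xbar)(y-ybar)) / sum((x-xbar)^2) = 3.30/1750
  expect_equal(f$effect, 3.30 / 1750, tolerance = 1e-12)
  ref <- summary(lm(beta ~ ages))
  expect_equal(f$se, ref$coefficients[2, 2], tolerance = 1e-10)
  expect_equal(f$t_stat, ref$coefficients[2, 3], tolerance = 1e-10)
  expect_equal(f$p, ref$coefficients[2, 4], tolerance = 1e-10)
  expect_equal(f$n_used, 6L)

  # with a covariate and missing values, still agrees with lm()
  set.seed(11)
  n <- 40
  x <- runif(n, 20, 70); z <- rnorm(n); y <- 0.3 + 0.002 * x + 0.05 * z +
    rnorm(n, 0, 0.02)
  y[c(3, 17)] <- NA
  f2 <- fitSiteLm(y, x, covariates = cbind(z = z))
  ref2 <- summary(lm(y ~ x + z))$coefficients
  expect_equal(f2$effect, ref2[2, 1], tolerance = 1e-10)
  expect_equal(f2$p, ref2[2, 4], tolerance = 1e-10)
  expect_equal(f2$n_used, 38L)
})

test_that("degenerate fits are flagged non-estimable, never silent zeros", {
  ages <- c(20, 30, 40, 50, 60, 70)
  f <- fitSiteLm(rep(0.5, 6), ages)          # constant response
  expect_false(f$estimable)
  expect_true(is.na(f$p))
  f2 <- fitSiteLm(runif(6), ages, covariates = cbind(a2 = ages))  # collinear
  expect_false(f2$estimable)
  f3 <- fitSiteLm(c(0.1, 0.2, NA, NA, NA, NA), ages)   # too few cases
  expect_false(f3$estimable)
})

test_that("effects are scale-equivariant; t and p are scale-invariant", {
  set.seed(2)
  ages <- runif(30, 20, 70)
  y <- 0.4 + 0.003 * ages + rnorm(30, 0, 0.03)
  f1 <- fitSiteLm(y, ages)
  f10 <- fitSiteLm(10 * y, ages)
  expect_equal(f10$effect, 10 * f1$effect)
  expect_equal(f10$se, 10 * f1$se)
  expect_equal(f10$t_stat, f1$t_stat)
  expect_equal(f10$p, f1$p)
})

test_that("q-values reduce to Benjamini-Hochberg with pi0 = 1 and stay monotone", {
  # hand-computed BH on the worked 4-value example
  q <- qvalues(c(0.001, 0.01, 0.5, 0.9), pi0 = 1)
  expect_equal(q, c(0.004, 0.02, 2 / 3, 0.9), tolerance = 1e-12)
  expect_equal(qvalues(rep(1, 5)), rep(1, 5))
  set.seed(3)
  for (i in 1:5) {
    p <- runif(sample(50:500, 1))^sample(1:3, 1)
    expect_equal(qvalues(p, pi0 = 1), p.adjust(p, "BH"), tolerance = 1e-12)
    q2 <- qvalues(p)
    expect_false(is.unsorted(q2[order(p)]))
    expect_true(all(q2 >= 0 & q2 <= 1))
  }
  expect_error(qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(qvalues(numeric(0)), "empty")
})

test_that("Storey pi0 adapts to signal-bearing p-value mixtures", {
  set.seed(4)
  p_null <- runif(4000)
  p_mix <- c(rbeta(2000, 0.2, 8), runif(8000))
  # under a pure null, q-values stay close to BH
  expect_equal(qvalues(p_null), p.adjust(p_null, "BH"), tolerance = 0.25)
  # with true signal, estimated pi0 < 1 so q <= BH everywhere
  expect_true(all(qvalues(p_mix) <= p.adjust(p_mix, "BH") + 1e-12))
})

test_that("genomic inflation is ~1 on a uniform grid and tracks chi-square scaling", {
  m <- 10000
  grid <- (seq_len(m) - 0.5) / m
  expect_lt(abs(genomicInflation(grid)$lambda_gc - 1), 0.01)
  set.seed(5)
  x <- rchisq(50000, df = 1) * 1.5
  p <- pchisq(x, df = 1, lower.tail = FALSE)
  expect_equal(genomicInflation(p)$lambda_gc, 1.5, tolerance = 0.05)
  expect_warning(genomicInflation(c(0, runif(20))), "0")
  expect_error(genomicInflation(runif(5)), "10")
})

test_that("DMC classification splits by direction and labels known regions", {
  mk <- function(n_hyper, n_hypo, n_null) {
    data.frame(id = paste0("chr1:", seq_len(n_hyper + n_hypo + n_null)),
               chrom = "chr1", pos = seq_len(n_hyper + n_hypo + n_null),
               effect = c(rep(0.004, n_hyper), rep(-0.004, n_hypo),
                          rep(0.001, n_null)),
               q = c(rep(0.005, n_hyper + n_hypo), rep(0.5, n_null)),
               direction = c(rep("hyper", n_hyper), rep("hypo", n_hypo),
                             rep("hyper", n_null)))
  }
  res <- mk(620, 380, 500)
  s <- classifyDmcs(res)$summary
  expect_equal(s$n_sig, 1000)
  expect_equal(s$pct_hyper, 62)
  expect_equal(s$pct_hypo, 38)

  # empty significant set: counts 0, percentages undefined
  s0 <- classifyDmcs(mk(0, 0, 10))$summary
  expect_equal(s0$n_sig, 0)
  expect_true(is.na(s0$pct_hyper))

  # known-region labelling
  res2 <- mk(3, 2, 1)
  known <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3))  # pos 0..2
  cl <- classifyDmcs(res2, known_regions = known)
  expect_equal(sum(cl$labels$known), 2)   # sig sites at pos 1 and 2
  expect_equal(cl$summary$n_known_regions_hit, 1)
})

test_that("hyper:hypo split of planted DMCs is recovered near the configured fraction", {
  splits <- sapply(1:5, function(s) {
    co <- smallCohort(seed = 300L + s, n_cpgs = 1500L, frac_age_cpgs = 0.25,
                      n_planted_dmrs = 0L, n_modules = 0L)
    fl <- filterSites(co$me)
    res <- runEwas(fl$me, "age", quiet = TRUE)
    s_ <- classifyDmcs(res)$summary
    s_$pct_hyper
  })
  expect_lt(abs(mean(splits) - 62), 5)
})

test_that("null cohorts yield uniform p-values and nominal type-I error", {
  set.seed(6)
  ps <- c()
  for (s in 1:2) {
    co <- smallCohort(seed = 500L + s, n_cpgs = 800L, frac_age_cpgs = 0,
                      n_planted_dmrs = 0L, n_modules = 0L,
                      n_imprinted_paternal = 0L, n_imprinted_maternal = 0L)
    fl <- filterSites(co$me)
    res <- runEwas(fl$me, "age", quiet = TRUE)
    ps <- c(ps, res$p[res$estimable])
  }
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.02)
})

test_that("planted effects are covered by +/- 2 SE at the nominal rate", {
  co <- smallCohort(seed = 700L, n_cpgs = 2000L, frac_age_cpgs = 0.3,
                    n_planted_dmrs = 0L, n_modules = 0L,
                    coverage_mean = 60)
  fl <- filterSites(co$me)
  res <- runEwas(fl$me, "age", quiet = TRUE)
  eff <- co$truth$age_effect[res$id]
  planted <- eff != 0 & res$estimable
  cover <- abs(res$effect[planted] - eff[planted]) <= 2 * res$se[planted]
  expect_gt(mean(cover), 0.90)   # ~95% nominal, sampling slack
})

test_that("runEwas validates inputs and supports the fertility outcome", {
  co <- smallCohort(seed = 33L, n_cpgs = 120L)
  fl <- filterSites(co$me)
  expect_error(runEwas(fl$me, "age", covariates = "nope", quiet = TRUE),
               "covariate")
  res <- runEwas(fl$me, "fertility", covariates = c("smoking", "BMI"),
                 quiet = TRUE)
  expect_true(all(c("effect", "p", "q") %in% colnames(res)))
  expect_equal(nrow(res), nrow(fl$me))
})

test_that("cohort statistics: degenerate identity, perfect correlation, group tests", {
  sheet <- data.frame(sample_id = paste0("s", 1:20),
                      age = rep(c(25, 55), each = 10),
                      age_group = rep(c("young", "old"), each = 10),
                      fertility = rep(c("fertile", "infertile"), 10),
                      marker = rep(c(1.0, 2.0, 3.0, 4.0, 5.0), 4),
                      doubled = NA,
                      smoking = rep(c("never", "past"), 10))
  sheet$doubled <- 2 * sheet$age
  st <- cohortStats(sheet, group_by = "age_group")
  d <- st$descriptives
  # identical marker distributions in both groups: t = 0, p = 1
  row <- d[d$variable == "marker", ]
  expect_equal(row$t, 0)
  expect_equal(row$p, 1)
  # variable equal to 2*age: Pearson r = 1
  corr <- st$age_correlations
  expect_equal(corr$r[corr$variable == "doubled"], 1)
  expect_error(cohortStats(sheet, group_by = "nope"))

  # groups reconstructed from published-style summary moments give the
  # expected Student t (FSH-like: 4.09 +/- 0.29 SEM (48) vs 6.25 +/- 0.40 (45))
  mkgrp <- function(n, mean, sem) {
    x <- scale(seq_len(n))[, 1]
    mean + x * sem * sqrt(n)
  }
  sheet2 <- data.frame(sample_id = paste0("t", 1:93),
                       age = c(rep(29, 48), rep(53, 45)),
                       age_group = rep(c("young", "old"), c(48, 45)),
                       FSH = c(mkgrp(48, 4.09, 0.29), mkgrp(45, 6.25, 0.40)))
  st2 <- cohortStats(sheet2, group_by = "age_group")
  fsh <- st2$descriptives[st2$descriptives$variable == "FSH", ]
  expect_equal(abs(fsh$t), 2.16 / sqrt(0.29^2 + 0.40^2), tolerance = 0.05)
  expect_lt(fsh$p, 1e-3)
  expect_gt(fsh$p, 1e-8)
})
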