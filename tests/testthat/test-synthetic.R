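test_that("identical seeds give bit-identical cohorts; null cohorts carry no age signal", {
  cfg <- cohortConfig(n_cpgs = 300L, frac_age_cpgs = 0, n_planted_dmrs = 0L,
                      seed = 7L)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(methCounts(a$me), methCounts(b$me))
  expect_identical(totalCounts(a$me), totalCounts(b$me))
  expect_identical(a$sheet, b$sheet)
  expect_true(all(a$truth$age_effect == 0))
  expect_length(a$truth$planted_dmrs, 0)
})

test_that("noiseless latent proportions regress on age with exactly the planted slope", {
  co <- smallCohort(seed = 3L, n_cpgs = 300L, frac_age_cpgs = 0.3,
                    n_planted_dmrs = 2L)
  ages <- co$sheet$age
  tb <- co$truth$true_beta
  eff <- co$truth$age_effect
  planted <- names(eff)[eff != 0]
  # restrict to sites where clamping never bit (latent stays inside (0,1))
  unclamped <- planted[apply(tb[planted, , drop = FALSE], 1,
                             function(x) all(x > 0 & x < 1))]
  expect_gt(length(unclamped), 10)
  for (id in unclamped[1:10]) {
    slope <- coef(lm(tb[id, ] ~ ages))[2]
    expect_equal(unname(slope), unname(eff[id]), tolerance = 1e-10)
  }
  # module-free non-age sites are exactly flat across samples
  flat <- names(eff)[eff == 0 & is.na(co$truth$module_assignment) &
                       co$truth$confounder_effect == 0]
  expect_gt(length(flat), 50)
  expect_true(all(apply(tb[flat, , drop = FALSE], 1, sd) == 0))
})

test_that("cohort structure mirrors the study design", {
  co <- smallCohort(seed = 5L, n_cpgs = 200L)
  sh <- co$sheet
  expect_equal(nrow(sh), 94)
  expect_equal(sum(sh$age_group == "young"), 48)
  expect_equal(sum(sh$age_group == "old"), 46)
  expect_true(abs(mean(sh$age[sh$age_group == "young"]) - 29.4) < 2.5)
  expect_true(abs(mean(sh$age[sh$age_group == "old"]) - 53.2) < 2.5)
  expect_true(all(sh$age[sh$age_group == "young"] >= 18 &
                    sh$age[sh$age_group == "young"] <= 38))
  expect_true(all(sh$age[sh$age_group == "old"] >= 46 &
                    sh$age[sh$age_group == "old"] <= 71))
  # planted hyper fraction honours the configured 62:38 split
  co2 <- smallCohort(seed = 6L, n_cpgs = 3000L, frac_age_cpgs = 0.3)
  eff <- co2$truth$age_effect
  expect_equal(mean(eff[eff != 0] > 0), 0.62, tolerance = 0.06)
})

test_that("covariates land near their configured age correlations", {
  targets <- c(FSH = 0.45, testosterone = -0.35)
  rs <- sapply(1:20, function(s) {
    sh <- smallCohort(seed = 100L + s, n_cpgs = 50L, n_planted_dmrs = 0L,
                      n_modules = 0L,
                      covariate_missing_rate = 0)$sheet
    c(cor(sh$age, sh$FSH), cor(sh$age, sh$testosterone))
  })
  expect_lt(abs(mean(rs[1, ]) - targets[["FSH"]]), 0.15)
  expect_lt(abs(mean(rs[2, ]) - targets[["testosterone"]]), 0.15)
  # signs: FSH rises, testosterone falls with age
  expect_gt(mean(rs[1, ]), 0)
  expect_lt(mean(rs[2, ]), 0)
})

test_that("observed methylation converges to the latent truth as coverage grows", {
  errs <- sapply(c(10, 100, 1000), function(cov) {
    co <- smallCohort(seed = 42L, n_cpgs = 200L, coverage_mean = cov,
                      n_modules = 0L)
    b <- betaValues(co$me)
    mean(abs(b - co$truth$true_beta), na.rm = TRUE)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("planted DMRs respect the window geometry and direction purity", {
  co <- smallCohort(seed = 9L, n_cpgs = 1000L, n_planted_dmrs = 5L,
                    dmr_span = 500L, dmr_min_cpgs = 5L)
  dmrs <- co$truth$planted_dmrs
  expect_length(dmrs, 5)
  eff <- co$truth$age_effect
  st <- data.frame(id = names(eff))
  st$chrom <- sub(":.*", "", st$id)
  st$pos <- as.integer(sub(".*:", "", st$id))
  for (i in seq_along(dmrs)) {
    cr <- as.character(GenomicRanges::seqnames(dmrs[i]))
    lo <- GenomicRanges::start(dmrs[i]) - 1L
    hi <- GenomicRanges::end(dmrs[i])
    memb <- st$id[st$chrom == cr & st$pos >= lo & st$pos < hi]
    e <- eff[memb]
    e <- e[e != 0]
    expect_gte(length(e), 5)
    expect_lte(hi - lo, 500)
    expect_true(all(sign(e) == sign(e[1])))
    dir_truth <- dmrs$direction[i]
    expect_identical(unname(ifelse(e[1] > 0, "hyper", "hypo")), dir_truth)
  }
  expect_error(cohortConfig(dmr_span = 8L, dmr_min_cpgs = 5L), "span")
})

test_that("imprinted loci carry sperm-typical methylation and mix toward 0.5 with contamination", {
  pure <- smallCohort(seed = 13L, n_cpgs = 300L)
  ti <- pure$truth$imprinted
  expect_equal(ti$expected_beta[ti$type == "paternal"], c(0.95, 0.95))
  expect_equal(ti$expected_beta[ti$type == "maternal"], c(0.03, 0.03))
  mixed <- smallCohort(seed = 13L, n_cpgs = 300L, somatic_fraction = 0.5)
  tm <- mixed$truth$imprinted
  expect_equal(tm$expected_beta[tm$type == "paternal"],
               c(0.725, 0.725))
  expect_equal(tm$expected_beta[tm$type == "maternal"],
               0.03 * 0.5 + 0.5 * 0.5 + c(0, 0))
})

test_that("fixtures round-trip losslessly and truth BEDs are sorted half-open", {
  co <- simulateCohort(cohortConfig(n_young = 4L, n_old = 4L, n_cpgs = 80L,
                                    n_planted_dmrs = 1L, n_modules = 0L,
                                    seed = 21L))
  d <- withr::local_tempdir()
  paths <- writeFixture(co$me, co$sheet, co$truth, d)
  cl <- lapply(colnames(co$me), function(s)
    readCytosineReport(file.path(d, paste0(s, ".cytosine_report.txt"))))
  names(cl) <- colnames(co$me)
  me2 <- assembleMatrix(cl)
  expect_identical(methCounts(me2), methCounts(co$me))
  expect_identical(totalCounts(me2), totalCounts(co$me))
  expect_identical(siteIds(me2), siteIds(co$me))
  bed <- read.table(paths[["planted_dmrs"]], sep = "\t")
  expect_true(all(bed$V3 > bed$V2))           # half-open, end > start
  expect_true(!is.unsorted(bed$V2[bed$V1 == bed$V1[1]]))
  gr <- co$truth$planted_dmrs
  expect_equal(bed$V2, GenomicRanges::start(gr) - 1L)  # 0-based starts
  expect_equal(bed$V3, GenomicRanges::end(gr))
})

test_that("a 2-sample micro-fixture matches hand-written report lines", {
  meth <- matrix(c(3L, 0L, 7L, 5L), 2,
                 dimnames = list(NULL, c("sA", "sB")))
  total <- matrix(c(10L, 0L, 7L, 9L), 2,
                  dimnames = list(NULL, c("sA", "sB")))
  me <- MethylationExperiment(meth, total, chrom = c("chr1", "chr1"),
                              pos = c(99L, 199L))
  d <- withr::local_tempdir()
  writeFixture(me, data.frame(sample_id = c("sA", "sB"), age = c(30, 50)),
               NULL, d)
  expect_identical(readLines(file.path(d, "sA.cytosine_report.txt")),
                   c("chr1\t100\t+\t3\t7\tCpG",
                     "chr1\t200\t+\t0\t0\tCpG"))
  expect_identical(readLines(file.path(d, "sB.cytosine_report.txt")),
                   c("chr1\t100\t+\t7\t0\tCpG",
                     "chr1\t200\t+\t5\t4\tCpG"))
})
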