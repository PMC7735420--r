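test_that("variable-CpG selection ranks complete sites by variance", {
  me <- tinyMe()  # contains a zero-coverage cell, hence incomplete sites
  beta <- betaValues(me)
  complete <- rownames(beta)[rowSums(is.na(beta)) == 0]
  sel <- selectVariableCpgs(me, k = 10L, min_sites = 1L)
  expect_setequal(sel, complete)

  co <- smallCohort(seed = 51L, n_cpgs = 200L)
  sel2 <- selectVariableCpgs(co$me, k = 30L, min_sites = 2L)
  b <- betaValues(co$me)
  v <- apply(b, 1, var)
  # oracle: independently recompute the variance ranking
  complete2 <- names(v)[rowSums(is.na(b)) == 0]
  want <- names(sort(v[complete2], decreasing = TRUE))[1:30]
  expect_setequal(sel2, want)
  expect_equal(unname(v[sel2[1]]), max(v[complete2]))
  # a constant site never outranks a varying one
  expect_false(any(v[sel2] == 0))
})

test_that("adjacency is the soft-thresholded absolute correlation", {
  x <- matrix(rnorm(40), 2, 20)
  x[2, ] <- x[1, ]
  rownames(x) <- c("a", "b")
  a <- buildAdjacency(x, power = 8)
  expect_equal(a["a", "b"], 1)

  # two sites with known r = 0.5 -> 0.5^8
  s <- sqrt(0.5)
  z1 <- rnorm(5000); z2 <- s * z1 + sqrt(1 - 0.5) * rnorm(5000)
  y <- rbind(z1, z2)
  r <- cor(z1, z2)
  a2 <- buildAdjacency(y, power = 8)
  expect_equal(a2[1, 2], abs(r)^8, tolerance = 1e-12)
  expect_equal(0.5^8, 0.00390625)   # the arithmetic the transform encodes

  # invariance to sample reordering; symmetry; range
  o <- sample(ncol(y))
  expect_equal(buildAdjacency(y[, o], power = 8), a2)
  expect_true(isSymmetric(unname(a2)))
  expect_true(all(a2 >= 0 & a2 <= 1))
  bad <- rbind(rnorm(10), rep(0.5, 10))
  rownames(bad) <- c("ok", "flat")
  expect_error(buildAdjacency(bad), "zero-variance")
})

test_that("topological overlap matches the formula on toys and a triple-loop oracle", {
  # identity adjacency: no shared neighbours, no overlap
  a0 <- diag(4)
  expect_true(all(topologicalOverlap(a0)[upper.tri(a0)] == 0))

  # 3-node toy, all off-diagonal 0.5: TOM_12 = (0.25 + 0.5)/(1 + 1 - 0.5)
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 1
  t3 <- topologicalOverlap(a3)
  expect_equal(t3[1, 2], 0.5)
  expect_equal(t3[1, 3], 0.5)

  # random matrices vs an elementwise triple loop
  set.seed(52)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    r <- matrix(runif(n * n), n)
    a <- (r + t(r)) / 2; diag(a) <- 1
    a <- a^4
    tom <- topologicalOverlap(a)
    oracle <- matrix(1, n, n)
    k <- colSums(a) - 1
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      oracle[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    expect_equal(tom, oracle, tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    # overlap never falls below the direct-adjacency floor
    floor_ <- a / (outer(k, k, pmin) + 1 - a)
    diag(floor_) <- 1
    expect_true(all(tom >= floor_ - 1e-12))
  }
})

test_that("module detection recovers tight planted blocks and ignores noise", {
  set.seed(53)
  x <- gaussianBlocks(94, sizes = c(50, 50), r = 0.95, n_noise = 100)
  tom <- topologicalOverlap(buildAdjacency(x, power = 8))
  asg <- detectModules(tom, min_size = 30, cut_height = 0.4)
  mods <- setdiff(unique(asg), "grey")
  expect_length(mods, 2)
  truth <- setNames(c(rep("A", 50), rep("B", 50), rep(NA, 100)),
                    rownames(x))
  expect_true(all(bestModuleJaccard(asg, truth) >= 0.9))

  # all-independent CpGs: nothing passes the minimum size
  y <- gaussianBlocks(94, sizes = integer(0), r = 0.5, n_noise = 120)
  tom0 <- topologicalOverlap(buildAdjacency(y, power = 8))
  expect_true(all(detectModules(tom0, min_size = 30,
                                cut_height = 0.4) == "grey"))
})

test_that("module eigengenes are unit-variance leading PCs with fixed sign", {
  # identical CpG vectors: eigengene is that standardized vector, varexp 1
  set.seed(54)
  v <- rnorm(30)
  sub <- rbind(a = v, b = v, c = v)
  colnames(sub) <- paste0("s", 1:30)
  eg <- moduleEigengenes(sub, setNames(rep("M1", 3), c("a", "b", "c")))
  expect_equal(eg$varexp[["M1"]], 1)
  zs <- (v - mean(v)) / sd(v)
  expect_equal(unname(eg$eigengenes[, "M1"]), zs, tolerance = 1e-8)

  # 2 uncorrelated CpGs: leading eigenvalue share of a 2x2 identity is 1/2
  u1 <- rnorm(4000); u2 <- rnorm(4000)
  eg2 <- moduleEigengenes(rbind(a = u1, b = u2),
                          setNames(rep("M1", 2), c("a", "b")))
  expect_equal(eg2$varexp[["M1"]], 0.5, tolerance = 0.05)

  # PC optimality: no random unit projection explains more variance
  x <- gaussianBlocks(60, sizes = 8, r = 0.7)
  asg <- setNames(rep("M1", 8), rownames(x))
  eg3 <- moduleEigengenes(x, asg)
  z <- t(scale(t(x)))
  tot <- sum(z^2)
  for (i in 1:100) {
    w <- rnorm(8); w <- w / sqrt(sum(w^2))
    proj <- drop(w %*% z)
    expect_lte(sum(proj^2) / tot, eg3$varexp[["M1"]] + 1e-10)
  }
  # sign convention: positive correlation with mean standardized methylation
  expect_gt(cor(eg3$eigengenes[, "M1"], colMeans(z)), 0)
})

test_that("module-trait correlation handles numeric coding and degenerate traits", {
  set.seed(55)
  n <- 40
  eg <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "M1"))
  sheet <- data.frame(age = eg[, 1] * 10 + 50,
                      fertility = rep(c("fertile", "infertile"), n / 2),
                      smoking = rep(c("never", "past", "current", "never"),
                                    n / 4),
                      flat = 1)
  mt <- moduleTraitCorrelation(eg, sheet, c("age", "fertility", "smoking",
                                            "flat"))
  expect_equal(mt$r[mt$trait == "age"], 1, tolerance = 1e-12)
  expect_lt(mt$p[mt$trait == "age"], 1e-20)
  expect_true(is.na(mt$r[mt$trait == "flat"]))
  expect_error(moduleTraitCorrelation(eg, sheet, "absent"), "trait")
})

test_that("the co-methylation pipeline is deterministic and recovers planted structure", {
  co <- simulateCohort(cohortConfig(n_cpgs = 600L, frac_age_cpgs = 0,
                                    n_planted_dmrs = 0L, n_modules = 2L,
                                    module_size = 40L,
                                    module_age_r = c(0.6, 0),
                                    seed = 56L))
  fl <- filterSites(co$me)
  cm1 <- runComethylation(fl$me, traits = c("age", "fertility"), k = 600L)
  cm2 <- runComethylation(fl$me, traits = c("age", "fertility"), k = 600L)
  expect_identical(cm1$assignments, cm2$assignments)
  expect_equal(cm1$eigengenes, cm2$eigengenes)
  jac <- bestModuleJaccard(cm1$assignments, co$truth$module_assignment)
  expect_true(all(jac >= 0.8))
  # the age-linked module shows up in the trait screen
  age_r <- cm1$module_trait[cm1$module_trait$trait == "age", ]
  expect_gt(max(abs(age_r$r)), 0.3)
  expect_lt(min(age_r$p[which.max(abs(age_r$r))]), 0.005)
})

test_that("configured module-age correlation is recovered within the sampling band", {
  rs <- sapply(1:5, function(s) {
    co <- simulateCohort(cohortConfig(n_cpgs = 300L, frac_age_cpgs = 0,
                                      n_planted_dmrs = 0L, n_modules = 1L,
                                      module_size = 40L, module_age_r = 0.6,
                                      seed = 600L + s))
    fl <- filterSites(co$me)
    cm <- runComethylation(fl$me, traits = "age", k = 300L,
                           min_size = 30L)
    if (is.null(cm$module_trait)) return(NA_real_)
    max(abs(cm$module_trait$r))
  })
  expect_true(all(!is.na(rs)))
  expect_gt(mean(rs), 0.4)
  expect_lt(mean(rs), 0.8)
})
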