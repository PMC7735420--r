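# Synthetic sperm methylome cohort generator.
#
# The generator is first-class, tested code: it encodes the generative model
# the downstream statistics assume (bimodal sperm baselines, additive
# per-year effects on the proportion scale, binomial read sampling on
# negative-binomial coverage, latent co-methylation factors, age-correlated
# clinical covariates, imprinted-locus methylation) so that every pipeline
# stage can be exercised against known truth without controlled-access data.

#' Configuration of a synthetic sperm methylome cohort
#'
#' Defaults mirror the study design this package models: 48 young donors
#' (ages 18-38, mean ~29.4 y) and 46 old donors (ages 46-71, mean ~53.2 y),
#' targeted coverage of 20-30x, a 62:38 hyper:hypo split among
#' age-associated CpGs, planted differentially methylated regions (>= 5
#' CpGs within 500 bp), latent co-methylation modules (two of them
#' age-linked with opposite signs, like the two large age modules seen in
#' sperm), FSH rising and testosterone falling with age.
#'
#' @param n_young,n_old donors per age group.
#' @param age_range_young,age_range_old inclusive age bounds (years).
#' @param age_mean_young,age_sd_young,age_mean_old,age_sd_old moments of
#'   the truncated-normal age draws within each range.
#' @param n_cpgs total CpG sites on the synthetic capture panel.
#' @param n_chromosomes,chrom_length synthetic genome geometry (bp).
#' @param frac_age_cpgs fraction of CpGs given a true age effect (planted
#'   DMR CpGs count toward this budget). `0` gives a null cohort.
#' @param frac_hyper_among_age fraction of age CpGs that gain methylation
#'   with age (positive effect).
#' @param effect_per_year `c(mean, sd)` of the absolute true effect, in
#'   methylation proportion per year.
#' @param n_planted_dmrs number of clustered age-CpG regions.
#' @param dmr_span bp span within which a planted cluster's CpGs fall.
#' @param dmr_min_cpgs minimum same-direction CpGs per planted cluster
#'   (clusters are planted with `dmr_min_cpgs + 2` CpGs so downstream
#'   callers at this threshold see them whole).
#' @param n_modules,module_size latent co-methylation modules and CpGs per
#'   module.
#' @param module_age_r target Pearson correlation of each module's latent
#'   factor with age (recycled/truncated to `n_modules`).
#' @param module_amplitude proportion-scale amplitude of the module
#'   factor. Module CpGs flip between a low and a high epiallele-like
#'   state (`baseline +/- amplitude * loading`) driven by a per-sample
#'   latent factor, emulating tight locus-level co-methylation.
#' @param coverage_mean,coverage_dispersion cell-level negative-binomial
#'   read coverage (baseline mean and size parameter).
#' @param coverage_profile lognormal meanlog/sdlog of the per-site capture
#'   efficiency and sdlog of the per-sample depth factor; the defaults are
#'   calibrated so that ~80% of panel CpGs reach >= 20x in >= 90% of
#'   samples (the assay's reported detection rate) while a usable minority
#'   is covered >= 20x in every sample.
#' @param covariate_age_correlations named numeric vector of target Pearson
#'   correlations between clinical covariates and age.
#' @param covariate_missing_rate completely-at-random missingness rate of
#'   clinical covariates (age and fertility are never missing).
#' @param confounder_name,confounder_frac_cpgs,confounder_effect_sd when
#'   `confounder_frac_cpgs > 0`, that fraction of non-age CpGs receives a
#'   true effect of the (age-correlated) named covariate, with per-CpG
#'   effect sizes N(0, `confounder_effect_sd`) per standardized covariate
#'   unit — a cohort on which an unadjusted age EWAS is inflated.
#' @param n_imprinted_paternal,n_imprinted_maternal imprinted QC loci.
#' @param somatic_fraction somatic-cell contamination fraction; imprinted
#'   methylation mixes linearly toward 0.5.
#' @param seed integer master seed; identical seeds give bit-identical
#'   cohorts.
#' @return a validated `CohortConfig` (a classed list).
#' @seealso [simulateCohort()]
#' @export
cohortConfig <- function(n_young = 48L, n_old = 46L,
                         age_range_young = c(18, 38),
                         age_range_old = c(46, 71),
                         age_mean_young = 29.38, age_sd_young = 6.30,
                         age_mean_old = 53.15, age_sd_old = 6.65,
                         n_cpgs = 20000L,
                         n_chromosomes = 4L, chrom_length = 5e7,
                         frac_age_cpgs = 0.10,
                         frac_hyper_among_age = 0.62,
                         effect_per_year = c(mean = 0.004, sd = 0.0015),
                         n_planted_dmrs = 10L, dmr_span = 500L,
                         dmr_min_cpgs = 5L,
                         n_modules = 4L, module_size = 50L,
                         module_age_r = c(0.6, -0.6, 0, 0),
                         module_amplitude = 0.4,
                         coverage_mean = 30, coverage_dispersion = 30,
                         coverage_profile = c(site_meanlog = 0.25,
                                              site_sdlog = 0.30,
                                              sample_sdlog = 0.15),
                         covariate_age_correlations = c(
                           FSH = 0.45, testosterone = -0.35,
                           bioavailable_T = -0.20, motility = -0.25,
                           BMI = 0.20, sperm_concentration = 0.10,
                           triglycerides = 0.15, HDL = -0.10,
                           chol_HDL_ratio = 0.10, LH = 0.10, TSH = 0.00),
                         covariate_missing_rate = 0.03,
                         confounder_name = "FSH",
                         confounder_frac_cpgs = 0,
                         confounder_effect_sd = 0,
                         n_imprinted_paternal = 2L,
                         n_imprinted_maternal = 2L,
                         somatic_fraction = 0,
                         seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "CohortConfig"
  validateCohortConfig(cfg)
  cfg
}

#' Validate a CohortConfig
#'
#' @param cfg a `CohortConfig` list.
#' @return `cfg` invisibly; stops with a message on the first violation.
#' @export
validateCohortConfig <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid CohortConfig: ",
                                                 msg, call. = FALSE)
  chk(cfg$n_young + cfg$n_old >= 2, "n_young + n_old must be >= 2")
  for (f in c("frac_age_cpgs", "frac_hyper_among_age", "somatic_fraction",
              "covariate_missing_rate", "confounder_frac_cpgs"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, paste(f, "must lie in [0,1]"))
  chk(cfg$coverage_mean > 0, "coverage_mean must be > 0")
  chk(cfg$dmr_min_cpgs >= 2, "dmr_min_cpgs must be >= 2")
  for (f in c("n_cpgs", "n_chromosomes", "chrom_length", "module_size"))
    chk(cfg[[f]] > 0, paste(f, "must be positive"))
  chk(all(cfg$effect_per_year >= 0),
      "effect_per_year mean and sd must be non-negative")
  chk(diff(cfg$age_range_young) > 0 && diff(cfg$age_range_old) > 0,
      "age ranges must be increasing (low, high)")
  n_planted <- cfg$dmr_min_cpgs + 2L
  chk(cfg$dmr_span >= 2L * n_planted,
      sprintf("planted DMRs need %d CpGs within %d bp: span too small",
              n_planted, cfg$dmr_span))
  invisible(cfg)
}

# truncated-normal draw by rejection (ranges are several sd wide; cheap)
.rtnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# correlate x with standardized anchor z at target r, then rescale
.corrVariate <- function(z, r, mean, sd, lo = -Inf) {
  x <- r * z + sqrt(max(0, 1 - r^2)) * rnorm(length(z))
  pmax(mean + sd * x, lo)
}

#' Simulate a synthetic sperm methylome cohort
#'
#' Draws a full study: ages and clinical covariates, CpG positions
#' (including planted DMR clusters and imprinted loci), bimodal baseline
#' methylation, signed per-year age effects, latent co-methylation module
#' factors, negative-binomial coverage and binomial methylated counts.
#' The per-sample true (noiseless) methylation proportion is
#' `clamp(baseline + effect * (age - reference_age) + module term
#' [+ confounder term], [0, 1])`; the reference age is the cohort mean so
#' baselines read as mid-cohort methylation.
#'
#' @param cfg a [cohortConfig()].
#' @return list with elements `me` (a [MethylationExperiment-class] whose
#'   `colData` carries the sample sheet), `sheet` (the sample sheet as a
#'   `data.frame`) and `truth` (a `SyntheticTruth` list: `age_effect` named
#'   per-CpG signed proportion/year, `planted_dmrs` GRanges with a
#'   `direction` column, `module_assignment` named vector, `baseline_beta`,
#'   `true_beta` latent proportion matrix, `imprinted` GRanges with `type`
#'   and `expected_beta`, `reference_age`, `seed`).
#' @examples
#' cohort <- simulateCohort(cohortConfig(n_cpgs = 300L, seed = 7L))
#' cohort$me
#' @export
simulateCohort <- function(cfg = cohortConfig()) {
  validateCohortConfig(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_young + cfg$n_old

  ## --- sample sheet -------------------------------------------------------
  ages <- c(.rtnorm(cfg$n_young, cfg$age_mean_young, cfg$age_sd_young,
                    cfg$age_range_young[1], cfg$age_range_young[2]),
            .rtnorm(cfg$n_old, cfg$age_mean_old, cfg$age_sd_old,
                    cfg$age_range_old[1], cfg$age_range_old[2]))
  ages <- round(ages, 1)
  ids <- sprintf("S%03d", seq_len(n))
  group <- rep(c("young", "old"), c(cfg$n_young, cfg$n_old))
  # fertile/infertile matched within age group (one extra fertile overall)
  fert <- unlist(lapply(c(cfg$n_young, cfg$n_old), function(k) {
    f <- rep(c("fertile", "infertile"), length.out = k)
    sample(f)
  }))
  zage <- as.numeric(scale(ages))
  covmoms <- list(  # pooled cross-sectional moments, adult male ranges
    sperm_concentration = c(131, 110, 1), motility = c(44, 22, 1),
    BMI = c(27.7, 6.3, 15), FSH = c(5.15, 2.4, 0.3), LH = c(4.0, 1.7, 0.3),
    TSH = c(1.95, 1.6, 0.1), testosterone = c(10.6, 3.9, 1),
    bioavailable_T = c(5.7, 2.5, 0.5), total_cholesterol = c(5.1, 1.4, 1.5),
    triglycerides = c(2.35, 1.6, 0.2), HDL = c(2.2, 0.9, 0.4),
    LDL = c(4.3, 2.0, 0.5), chol_HDL_ratio = c(4.0, 1.2, 1))
  sheet <- data.frame(sample_id = ids, age = ages, age_group = group,
                      fertility = fert, stringsAsFactors = FALSE)
  full_cov <- list()
  for (v in names(covmoms)) {
    r <- if (v %in% names(cfg$covariate_age_correlations))
      cfg$covariate_age_correlations[[v]] else 0
    m <- covmoms[[v]]
    full_cov[[v]] <- round(.corrVariate(zage, r, m[1], m[2], m[3]), 2)
  }
  smoking <- sample(c("never", "past", "current"), n, replace = TRUE,
                    prob = c(0.61, 0.27, 0.12))
  sheet <- cbind(sheet, as.data.frame(full_cov), smoking = smoking,
                 stringsAsFactors = FALSE)
  conf_full <- full_cov[[cfg$confounder_name]]  # pre-missingness values
  if (cfg$covariate_missing_rate > 0) {
    for (v in c(names(covmoms), "smoking")) {
      miss <- runif(n) < cfg$covariate_missing_rate
      sheet[[v]][miss] <- NA
    }
  }

  ## --- genome geometry ----------------------------------------------------
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  k_dmr <- cfg$dmr_min_cpgs + 2L
  plant_dmrs <- cfg$frac_age_cpgs > 0 && cfg$n_planted_dmrs > 0
  n_dmr_sites <- if (plant_dmrs) cfg$n_planted_dmrs * k_dmr else 0L
  n_impr <- cfg$n_imprinted_paternal + cfg$n_imprinted_maternal
  n_impr_sites <- n_impr * 5L
  n_scatter <- cfg$n_cpgs - n_dmr_sites - n_impr_sites
  if (n_scatter < cfg$n_modules * cfg$module_size + 10L)
    stop("n_cpgs too small for the requested planted structure")

  pos_l <- list(); chrom_l <- list(); tag_l <- list()
  scatter_per <- diff(round(seq(0, n_scatter, length.out =
                                  cfg$n_chromosomes + 1L)))
  dmr_chrom <- if (plant_dmrs)
    rep(seq_len(cfg$n_chromosomes), length.out = cfg$n_planted_dmrs) else
    integer(0)
  dmr_meta <- list()
  impr_meta <- list()
  for (ci in seq_len(cfg$n_chromosomes)) {
    p <- sort(sample.int(cfg$chrom_length - 1L, scatter_per[ci])) # 0-based
    tg <- rep("scatter", length(p))
    for (d in which(dmr_chrom == ci)) {
      start <- sample.int(cfg$chrom_length - cfg$dmr_span - 10L, 1L)
      offs <- sort(sample.int(cfg$dmr_span, k_dmr) - 1L)
      dp <- start + offs
      p <- c(p, dp); tg <- c(tg, rep(paste0("dmr", d), k_dmr))
      dmr_meta[[d]] <- list(chrom = chroms[ci], start = min(dp),
                            end = max(dp) + 1L)
    }
    if (ci == 1L && n_impr > 0) {
      for (ii in seq_len(n_impr)) {
        start <- sample.int(cfg$chrom_length - 600L, 1L)
        ip <- start + sort(sample.int(400L, 5L) - 1L)
        p <- c(p, ip); tg <- c(tg, rep(paste0("impr", ii), 5L))
        impr_meta[[ii]] <- list(
          chrom = chroms[ci], start = min(ip), end = max(ip) + 1L,
          type = if (ii <= cfg$n_imprinted_paternal) "paternal" else
            "maternal")
      }
    }
    o <- order(p)
    p <- p[o]; tg <- tg[o]
    dup <- duplicated(p)  # collisions are vanishingly rare; nudge them
    while (any(dup)) { p[dup] <- p[dup] + 1L; o <- order(p); p <- p[o]
      tg <- tg[o]; dup <- duplicated(p) }
    pos_l[[ci]] <- p; chrom_l[[ci]] <- rep(chroms[ci], length(p))
    tag_l[[ci]] <- tg
  }
  pos <- unlist(pos_l); chrom <- unlist(chrom_l); tag <- unlist(tag_l)
  site_id <- paste0(chrom, ":", pos)
  m_sites <- length(pos)

  ## --- baselines, effects, modules ---------------------------------------
  baseline <- numeric(m_sites)
  comp <- sample(c("low", "high", "mid"), m_sites, replace = TRUE,
                 prob = c(0.45, 0.45, 0.10))
  baseline[comp == "low"] <- stats::rbeta(sum(comp == "low"), 2, 18)
  baseline[comp == "high"] <- stats::rbeta(sum(comp == "high"), 18, 2)
  baseline[comp == "mid"] <- runif(sum(comp == "mid"), 0.25, 0.75)

  effect <- numeric(m_sites)
  n_age_target <- round(cfg$frac_age_cpgs * cfg$n_cpgs)
  dmr_truth <- NULL
  if (plant_dmrs) {
    dmr_dir <- ifelse(runif(cfg$n_planted_dmrs) < cfg$frac_hyper_among_age,
                      1, -1)
    for (d in seq_len(cfg$n_planted_dmrs)) {
      idx <- which(tag == paste0("dmr", d))
      mag <- abs(rnorm(length(idx), cfg$effect_per_year[1],
                       cfg$effect_per_year[2]))
      effect[idx] <- dmr_dir[d] * pmax(mag, cfg$effect_per_year[1] / 2)
      baseline[idx] <- if (dmr_dir[d] > 0) runif(length(idx), 0.25, 0.60) else
        runif(length(idx), 0.40, 0.75)
    }
    dmr_truth <- GenomicRanges::GRanges(
      vapply(dmr_meta, `[[`, "", "chrom"),
      IRanges::IRanges(start = vapply(dmr_meta, function(x)
        x$start + 1L, 0L),
        end = vapply(dmr_meta, `[[`, 0L, "end")),
      direction = ifelse(dmr_dir > 0, "hyper", "hypo"))
  } else {
    dmr_truth <- GenomicRanges::GRanges()
  }
  n_scatter_age <- max(n_age_target - n_dmr_sites, 0L)
  scatter_idx <- which(tag == "scatter")
  age_idx <- if (n_scatter_age > 0)
    sort(sample(scatter_idx, min(n_scatter_age, length(scatter_idx)))) else
    integer(0)
  if (length(age_idx)) {
    sign_v <- ifelse(runif(length(age_idx)) < cfg$frac_hyper_among_age, 1, -1)
    mag <- abs(rnorm(length(age_idx), cfg$effect_per_year[1],
                     cfg$effect_per_year[2]))
    effect[age_idx] <- sign_v * pmax(mag, cfg$effect_per_year[1] / 4)
    # give planted effects headroom so clamping rarely bites
    baseline[age_idx] <- ifelse(sign_v > 0,
                                runif(length(age_idx), 0.20, 0.60),
                                runif(length(age_idx), 0.40, 0.80))
  }

  module <- rep(NA_character_, m_sites)
  module_r <- rep_len(cfg$module_age_r, cfg$n_modules)
  mod_factor <- matrix(0, nrow = max(cfg$n_modules, 1L), ncol = n)
  loading <- numeric(m_sites)
  free_idx <- setdiff(scatter_idx, age_idx)
  if (cfg$n_modules > 0) {
    for (mdl in seq_len(cfg$n_modules)) {
      if (length(free_idx) < cfg$module_size)
        stop("n_cpgs too small for the requested planted structure ",
             "(module ", mdl, " needs ", cfg$module_size,
             " free CpGs, only ", length(free_idx), " left)")
      pick <- sort(sample(free_idx, cfg$module_size))
      free_idx <- setdiff(free_idx, pick)
      module[pick] <- paste0("M", mdl)
      loading[pick] <- runif(cfg$module_size, 0.8, 1)
      baseline[pick] <- runif(cfg$module_size, 0.45, 0.55)
      r <- module_r[mdl]
      z <- r * zage + sqrt(max(0, 1 - r^2)) * rnorm(n)
      # epiallele-like bimodal module state: tight locus-level
      # co-methylation strong enough to survive read-sampling noise
      mod_factor[mdl, ] <- ifelse(as.numeric(scale(z)) >= 0, 1, -1)
    }
  }

  conf_effect <- numeric(m_sites)
  if (cfg$confounder_frac_cpgs > 0 && cfg$confounder_effect_sd > 0) {
    k <- round(cfg$confounder_frac_cpgs * cfg$n_cpgs)
    pick <- sort(sample(free_idx, min(k, length(free_idx))))
    conf_effect[pick] <- rnorm(length(pick), 0, cfg$confounder_effect_sd)
  }
  zconf <- as.numeric(scale(conf_full))

  ## --- latent proportions and counts -------------------------------------
  ref_age <- mean(ages)
  true_beta <- baseline + outer(effect, ages - ref_age)
  if (cfg$n_modules > 0)
    true_beta <- true_beta +
      cfg$module_amplitude * (loading * ifelse(is.na(module), 0, 1)) *
      mod_factor[ifelse(is.na(module), 1L,
                        as.integer(sub("M", "", module))), , drop = FALSE]
  if (any(conf_effect != 0))
    true_beta <- true_beta + outer(conf_effect, zconf)
  impr_expected <- numeric(0)
  if (n_impr > 0) {
    for (ii in seq_len(n_impr)) {
      idx <- which(tag == paste0("impr", ii))
      pure <- if (impr_meta[[ii]]$type == "paternal") 0.95 else 0.03
      mixed <- pure * (1 - cfg$somatic_fraction) + 0.5 * cfg$somatic_fraction
      true_beta[idx, ] <- mixed
      baseline[idx] <- mixed
      impr_expected[ii] <- mixed
    }
  }
  true_beta <- pmin(pmax(true_beta, 0), 1)

  # capture-style coverage: per-site capture efficiency x per-sample depth,
  # negative-binomial at the cell level
  prof <- cfg$coverage_profile
  site_f <- exp(rnorm(m_sites, prof[["site_meanlog"]],
                      prof[["site_sdlog"]]))
  # planted modules and imprinted QC loci sit in well-captured panel
  # regions (network input and QC targets are uniformly covered by design)
  well <- !is.na(module) | startsWith(tag, "impr")
  if (any(well)) site_f[well] <- exp(rnorm(sum(well), 0.7, 0.1))
  sample_f <- exp(rnorm(n, 0, prof[["sample_sdlog"]]))
  mu <- cfg$coverage_mean * outer(site_f, sample_f)
  total <- matrix(rnbinom(m_sites * n, mu = as.vector(mu),
                          size = cfg$coverage_dispersion),
                  nrow = m_sites, ncol = n, dimnames = list(site_id, ids))
  meth <- matrix(rbinom(m_sites * n, as.vector(total), as.vector(true_beta)),
                 nrow = m_sites, ncol = n, dimnames = list(site_id, ids))

  me <- MethylationExperiment(meth, total, chrom, pos, sampleData = sheet)
  stopifnot(identical(siteIds(me), site_id))  # construction order is sorted
  dimnames(true_beta) <- list(site_id, ids)

  imprinted <- if (n_impr > 0) GenomicRanges::GRanges(
    vapply(impr_meta, `[[`, "", "chrom"),
    IRanges::IRanges(start = vapply(impr_meta, function(x) x$start + 1L, 0L),
                     end = vapply(impr_meta, `[[`, 0L, "end")),
    type = vapply(impr_meta, `[[`, "", "type"),
    expected_beta = impr_expected) else GenomicRanges::GRanges()

  truth <- list(site_factor = setNames(site_f, site_id),
                age_effect = setNames(effect, site_id),
                baseline_beta = setNames(baseline, site_id),
                module_assignment = setNames(module, site_id),
                planted_dmrs = dmr_truth,
                imprinted = imprinted,
                confounder_effect = setNames(conf_effect, site_id),
                true_beta = true_beta,
                reference_age = ref_age,
                seed = cfg$seed,
                config = cfg)
  class(truth) <- "SyntheticTruth"
  list(me = me, sheet = sheet, truth = truth)
}

#' Simulate an independent replication cohort on the same panel
#'
#' Draws new donors from the *same* site-level biology as an existing
#' synthetic cohort — identical baselines, per-year age effects and
#' per-site capture efficiencies, with fresh ages, sample depth factors
#' and read sampling. This is the design of an external replication of an
#' age predictor: same assay and population process, new individuals.
#' Module and confounder structure is not re-planted.
#'
#' @param truth the `SyntheticTruth` of the training cohort.
#' @param n_young,n_old donors per age group.
#' @param seed integer seed.
#' @return list with `me` and `sheet` (sample_id, age, age_group).
#' @export
simulateReplication <- function(truth, n_young = 6L, n_old = 6L,
                                seed = 1L) {
  cfg <- truth$config
  set.seed(seed)
  n <- n_young + n_old
  ages <- c(.rtnorm(n_young, cfg$age_mean_young, cfg$age_sd_young,
                    cfg$age_range_young[1], cfg$age_range_young[2]),
            .rtnorm(n_old, cfg$age_mean_old, cfg$age_sd_old,
                    cfg$age_range_old[1], cfg$age_range_old[2]))
  ages <- round(ages, 1)
  ids <- sprintf("R%03d", seq_len(n))
  site_id <- names(truth$baseline_beta)
  chrom <- sub(":.*", "", site_id)
  pos <- as.integer(sub(".*:", "", site_id))
  tb <- truth$baseline_beta + outer(truth$age_effect,
                                    ages - truth$reference_age)
  tb <- pmin(pmax(tb, 0), 1)
  prof <- cfg$coverage_profile
  sample_f <- exp(rnorm(n, 0, prof[["sample_sdlog"]]))
  mu <- cfg$coverage_mean * outer(truth$site_factor, sample_f)
  total <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                          size = cfg$coverage_dispersion),
                  nrow = length(site_id), ncol = n,
                  dimnames = list(site_id, ids))
  meth <- matrix(rbinom(length(mu), as.vector(total), as.vector(tb)),
                 nrow = length(site_id), ncol = n,
                 dimnames = list(site_id, ids))
  sheet <- data.frame(sample_id = ids, age = ages,
                      age_group = rep(c("young", "old"),
                                      c(n_young, n_old)),
                      stringsAsFactors = FALSE)
  me <- MethylationExperiment(meth, total, chrom, pos, sampleData = sheet)
  list(me = me, sheet = sheet)
}

#' Write a synthetic cohort to disk as a pipeline-ready fixture
#'
#' Emits one cytosine report per sample (tab-delimited: chrom, 1-based
#' position, strand, methylated count, unmethylated count, context), the
#' sample sheet as CSV, sorted 0-based half-open BED files for the planted
#' DMRs and imprinted loci, a per-CpG truth table, and the generating
#' configuration as YAML. Files round-trip losslessly through
#' [readCytosineReport()] / [assembleMatrix()].
#'
#' @param me a [MethylationExperiment-class]
#' @param sheet the sample sheet `data.frame`
#' @param truth a `SyntheticTruth` (may be `NULL` to skip truth files)
#' @param dir output directory (created if absent)
#' @return named character vector of written paths, invisibly.
#' @export
writeFixture <- function(me, sheet, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- siteTable(me)
  meth <- methCounts(me); total <- totalCounts(me)
  paths <- c()
  for (s in colnames(me)) {
    p <- file.path(dir, paste0(s, ".cytosine_report.txt"))
    writeCytosineReport(
      data.frame(chrom = st$chrom, pos = st$pos,
                 meth = meth[, s], total = total[, s]), p)
    paths[paste0("report_", s)] <- p
  }
  p <- file.path(dir, "sample_sheet.csv")
  utils::write.csv(sheet, p, row.names = FALSE)
  paths["sample_sheet"] <- p
  if (!is.null(truth)) {
    p <- file.path(dir, "truth_age_effects.tsv")
    write.table(data.frame(id = st$id, chrom = st$chrom, pos = st$pos,
                           age_effect = unname(truth$age_effect[st$id]),
                           baseline_beta = unname(truth$baseline_beta[st$id]),
                           module = unname(truth$module_assignment[st$id])),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["truth"] <- p
    p <- file.path(dir, "planted_dmrs.bed")
    writeBed(truth$planted_dmrs, p,
             name = if (length(truth$planted_dmrs))
               truth$planted_dmrs$direction else character(0))
    paths["planted_dmrs"] <- p
    p <- file.path(dir, "imprinted_loci.bed")
    writeBed(truth$imprinted, p,
             name = if (length(truth$imprinted))
               truth$imprinted$type else character(0))
    paths["imprinted"] <- p
    p <- file.path(dir, "config.yaml")
    cfgl <- truth$config; class(cfgl) <- NULL
    cfgl$covariate_age_correlations <- as.list(cfgl$covariate_age_correlations)
    yaml::write_yaml(cfgl, p)
    paths["config"] <- p
  }
  invisible(paths)
}
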