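# Per-CpG covariate-adjusted linear-model association of methylation with
# age (or fertility), Storey q-values, genomic-control inflation, DMC
# classification and cohort descriptive statistics.

#' Per-site ordinary least squares fit
#'
#' Regresses one CpG's methylation proportions on `[intercept, x,
#' covariates]` after complete-case restriction, returning the coefficient
#' of `x` (the exposure of interest, e.g. age in years, so the effect is a
#' change in methylation proportion per year), its standard error, t
#' statistic and two-sided p-value on `n_used - rank` degrees of freedom.
#' Degenerate fits (rank-deficient design, constant response, non-positive
#' residual degrees of freedom, fewer than `min_n` usable samples) are
#' flagged non-estimable with missing effect and p — never a silent zero.
#'
#' @param beta per-sample methylation proportions (may contain `NA`).
#' @param x per-sample exposure (age in years, or a 0/1 indicator).
#' @param covariates optional numeric matrix of adjustment columns.
#' @param min_n minimum complete-case sample count.
#' @return list: `effect`, `se`, `t_stat`, `p`, `n_used`, `estimable`.
#' @examples
#' fitSiteLm(c(0.40, 0.43, 0.44, 0.45, 0.48, 0.50),
#'           c(20, 30, 40, 50, 60, 70))$effect  # 3.30/1750
#' @export
fitSiteLm <- function(beta, x, covariates = NULL, min_n = 0L) {
  bad <- list(effect = NA_real_, se = NA_real_, t_stat = NA_real_,
              p = NA_real_, n_used = 0L, estimable = FALSE)
  X <- cbind(1, x, covariates)
  ok <- !is.na(beta) & stats::complete.cases(X)
  n1 <- sum(ok)
  bad$n_used <- n1
  if (n1 < max(min_n, ncol(X) + 1L)) return(bad)
  X1 <- X[ok, , drop = FALSE]; y <- beta[ok]
  if (qr(X1)$rank < ncol(X1)) return(bad)          # rank-deficient design
  XtX <- crossprod(X1)
  L <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(L)) return(bad)
  XtXinv <- chol2inv(L)
  b <- XtXinv %*% crossprod(X1, y)
  res <- y - X1 %*% b
  df <- n1 - ncol(X1)
  sigma2 <- sum(res^2) / df
  if (df <= 0 || sigma2 < 1e-20) return(bad)       # saturated or constant
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  tv <- b[2L] / se
  list(effect = as.numeric(b[2L]), se = as.numeric(se),
       t_stat = as.numeric(tv),
       p = 2 * pt(-abs(tv), df), n_used = n1, estimable = TRUE)
}

# Build the adjustment design columns from a sample sheet. Fertility and
# smoking become indicator columns (never/fertile = reference); continuous
# covariates are untransformed. Missing covariate values are imputed with
# the per-variable median (mode for smoking), with a message per variable.
.buildCovariates <- function(sheet, covariates, quiet = FALSE) {
  if (length(covariates) == 0) return(NULL)
  cols <- list()
  for (v in covariates) {
    if (!v %in% colnames(sheet))
      stop("covariate not present in sample sheet: ", v)
    col <- sheet[[v]]
    if (v == "fertility") {
      cols[["infertile"]] <- as.numeric(col == "infertile")
    } else if (v == "smoking") {
      if (anyNA(col)) {
        tab <- table(col)
        mode_cat <- names(tab)[which.max(tab)]
        if (!quiet) message("imputed ", sum(is.na(col)),
                            " missing 'smoking' values with '", mode_cat, "'")
        col[is.na(col)] <- mode_cat
      }
      cols[["smoking_past"]] <- as.numeric(col == "past")
      cols[["smoking_current"]] <- as.numeric(col == "current")
    } else {
      col <- as.numeric(col)
      if (anyNA(col)) {
        med <- median(col, na.rm = TRUE)
        if (!quiet) message("imputed ", sum(is.na(col)), " missing '", v,
                            "' values with the median (", signif(med, 4), ")")
        col[is.na(col)] <- med
      }
      cols[[v]] <- col
    }
  }
  do.call(cbind, cols)
}

#' Epigenome-wide association of methylation with age or fertility
#'
#' Fits an ordinary least-squares model per retained CpG: methylation
#' proportion on the outcome of interest plus adjustment covariates
#' ([fitSiteLm()]). Complete cases are taken per site on methylation
#' missingness; missing covariates are median-imputed (see
#' `.buildCovariates` notes in the vignette). Storey q-values
#' ([qvalues()]) fill the `q` column. Deterministic given its inputs.
#'
#' @param me a filtered [MethylationExperiment-class]
#' @param outcome `"age"` (effect in proportion/year) or `"fertility"`
#'   (effect of infertile vs fertile).
#' @param covariates character vector of sample-sheet columns to adjust
#'   for (e.g. `c("fertility", "sperm_concentration", "smoking",
#'   "testosterone", "bioavailable_T", "FSH", "HDL", "BMI",
#'   "triglycerides", "chol_HDL_ratio")`).
#' @param sheet optional sample sheet; defaults to `sampleSheet(me)`.
#' @param min_n minimum per-site complete-case count.
#' @param quiet suppress imputation messages.
#' @return `data.frame` with one row per site: `id`, `chrom`, `pos`,
#'   `effect`, `se`, `t_stat`, `p`, `q`, `n_used`, `direction`
#'   (`hyper`/`hypo` by sign of the effect), `estimable`.
#' @export
runEwas <- function(me, outcome = c("age", "fertility"),
                    covariates = character(), sheet = NULL,
                    min_n = 0L, quiet = FALSE) {
  outcome <- match.arg(outcome)
  if (is.null(sheet)) sheet <- sampleSheet(me)
  if (!outcome %in% colnames(sheet))
    stop("outcome column missing from sample sheet: ", outcome)
  x <- if (outcome == "age") as.numeric(sheet$age) else
    as.numeric(sheet$fertility == "infertile")
  covariates <- setdiff(covariates, outcome)
  Z <- .buildCovariates(sheet, covariates, quiet = quiet)
  beta <- betaValues(me)
  st <- siteTable(me)
  m <- nrow(beta)
  eff <- se <- tv <- pv <- rep(NA_real_, m)
  nuse <- integer(m); est <- logical(m)
  for (i in seq_len(m)) {
    f <- fitSiteLm(beta[i, ], x, covariates = Z, min_n = min_n)
    eff[i] <- f$effect; se[i] <- f$se; tv[i] <- f$t_stat; pv[i] <- f$p
    nuse[i] <- f$n_used; est[i] <- f$estimable
  }
  q <- rep(NA_real_, m)
  if (any(est)) q[est] <- qvalues(pv[est])
  data.frame(id = st$id, chrom = st$chrom, pos = st$pos,
             effect = eff, se = se, t_stat = tv, p = pv, q = q,
             n_used = nuse,
             direction = ifelse(is.na(eff), NA_character_,
                                ifelse(eff > 0, "hyper", "hypo")),
             estimable = est, stringsAsFactors = FALSE)
}

#' Storey q-values
#'
#' False discovery proportion q-values: the proportion of true nulls
#' `pi0` is estimated by fitting a natural cubic smoothing spline to
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)` over
#' `lambda = 0.05, ..., 0.95` and evaluating at the largest lambda,
#' falling back to `pi0 = 1` when the estimate leaves `(0, 1]`. Then
#' `q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j)`, capped at 1 —
#' with `pi0` forced to 1 this is exactly Benjamini-Hochberg.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param pi0 optional fixed null proportion (1 gives BH).
#' @param lambda grid for the pi0 smoother.
#' @return q-values, same order as `p`; monotone in `p`.
#' @export
qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, 0.05)) {
  if (length(p) < 1L) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100L) {
      pi0 <- 1  # too few tests for a stable smoother
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      if (is.na(pi0) || pi0 <= 0 || pi0 > 1) pi0 <- 1
    }
  }
  r <- rank(p, ties.method = "max")
  q <- pmin(pi0 * m * p / r, 1)
  o <- order(p, decreasing = TRUE)
  q[o] <- cummin(q[o])
  q
}

#' Genomic-control inflation factor
#'
#' `lambda_GC`: the median of the association test statistics converted to
#' 1-df chi-squared quantiles, divided by the null median (0.4549364).
#' Values near 1 indicate well-calibrated tests; the sperm age EWAS
#' literature reports ~1.7 unadjusted dropping to ~1.44 after covariate
#' adjustment.
#'
#' @param p vector of p-values (length >= 10). Zeros are mapped to the
#'   smallest representable positive double, with a warning.
#' @return list with `lambda_gc` and `n_tests`.
#' @export
genomicInflation <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 10L) stop("need at least 10 p-values")
  if (any(p == 0)) {
    warning("p-values of 0 mapped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  list(lambda_gc = median(chisq) / qchisq(0.5, df = 1),
       n_tests = length(p))
}

#' Classify differentially methylated CpGs
#'
#' Splits significant sites (`q < q_threshold`) by the sign of the age
#' effect into hyper-/hypomethylated classes, and labels each significant
#' site `known` or `novel` against previously reported sperm-age regions.
#'
#' @param results `data.frame` from [runEwas()].
#' @param q_threshold genome-wide significance threshold (default 0.01).
#' @param known_regions,known_cpgs optional `GRanges` or BED paths of
#'   previously reported regions / single-CpG positions.
#' @return list with `summary` (counts and percentages:
#'   `n_sig`, `n_hyper`, `n_hypo`, `pct_hyper`, `pct_hypo`,
#'   `n_sig_in_known_regions`, `n_known_regions_hit`, `q_threshold`) and
#'   `labels` (per significant site: id, direction, known flag).
#' @export
classifyDmcs <- function(results, q_threshold = 0.01,
                         known_regions = NULL, known_cpgs = NULL) {
  sig <- !is.na(results$q) & results$q < q_threshold
  n_hyper <- sum(sig & results$effect > 0)
  n_hypo <- sum(sig & results$effect < 0)
  n_sig <- n_hyper + n_hypo
  pct_hyper <- if (n_sig > 0) 100 * n_hyper / n_sig else NA_real_
  pct_hypo <- if (n_sig > 0) 100 * n_hypo / n_sig else NA_real_
  labels <- data.frame(id = results$id[sig],
                       chrom = results$chrom[sig], pos = results$pos[sig],
                       direction = results$direction[sig],
                       known = rep(FALSE, sum(sig)),
                       stringsAsFactors = FALSE)
  n_in_known <- 0L; n_regions_hit <- 0L
  if (!is.null(known_regions)) {
    gr <- if (is.character(known_regions)) readBedRegions(known_regions) else
      known_regions
    if (nrow(labels) > 0 && length(gr) > 0) {
      sites <- GenomicRanges::GRanges(labels$chrom,
                                      IRanges::IRanges(labels$pos + 1L,
                                                       width = 1L))
      labels$known <- .quietOverlaps(sites, gr)
      n_in_known <- sum(labels$known)
      n_regions_hit <- sum(.quietOverlaps(gr, sites))
    }
  }
  if (!is.null(known_cpgs) && nrow(labels) > 0) {
    gr <- if (is.character(known_cpgs)) readBedRegions(known_cpgs) else
      known_cpgs
    sites <- GenomicRanges::GRanges(labels$chrom,
                                    IRanges::IRanges(labels$pos + 1L,
                                                     width = 1L))
    labels$known_cpg <- .quietOverlaps(sites, gr)
  }
  list(summary = list(n_sig = n_sig, n_hyper = n_hyper, n_hypo = n_hypo,
                      pct_hyper = pct_hyper, pct_hypo = pct_hypo,
                      n_sig_in_known_regions = n_in_known,
                      n_known_regions_hit = n_regions_hit,
                      q_threshold = q_threshold),
       labels = labels)
}

#' Cohort descriptive statistics
#'
#' Per-group mean, SEM and n for every continuous clinical variable with a
#' two-sided Student's t-test (equal variances, the convention of clinical
#' baseline tables), a chi-squared test over smoking categories, and a
#' Pearson correlation table of every continuous variable against age.
#' Degenerate variables (fewer than 2 values or zero variance in a group)
#' are flagged rather than tested.
#'
#' @param sheet a sample sheet `data.frame`.
#' @param group_by grouping column, `"age_group"` or `"fertility"`.
#' @return list: `descriptives` (variable, per-group mean/sem/n, t, p,
#'   flag), `smoking` (chi-squared test or NULL), `age_correlations`
#'   (variable, r, p, n).
#' @export
cohortStats <- function(sheet, group_by = c("age_group", "fertility")) {
  group_by <- match.arg(group_by)
  if (!group_by %in% colnames(sheet))
    stop("grouping column missing from sheet: ", group_by)
  g <- factor(sheet[[group_by]])
  if (nlevels(g) != 2L) stop("grouping must have exactly 2 levels")
  if (min(table(g)) < 2L) stop("each group needs >= 2 samples")
  skip <- c("sample_id", "age_group", "fertility", "smoking")
  vars <- setdiff(colnames(sheet)[vapply(sheet, is.numeric, TRUE)], skip)
  lev <- levels(g)
  rows <- lapply(vars, function(v) {
    x1 <- sheet[[v]][g == lev[1]]; x2 <- sheet[[v]][g == lev[2]]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    sem <- function(x) sd(x) / sqrt(length(x))
    degen <- length(x1) < 2 || length(x2) < 2 ||
      (sd(x1) == 0 && sd(x2) == 0)
    tt <- if (!degen) t.test(x1, x2, var.equal = TRUE) else NULL
    data.frame(variable = v,
               mean_1 = mean(x1), sem_1 = sem(x1), n_1 = length(x1),
               mean_2 = mean(x2), sem_2 = sem(x2), n_2 = length(x2),
               t = if (degen) NA_real_ else unname(tt$statistic),
               p = if (degen) NA_real_ else tt$p.value,
               degenerate = degen, stringsAsFactors = FALSE)
  })
  desc <- do.call(rbind, rows)
  attr(desc, "groups") <- lev
  smoking <- NULL
  if ("smoking" %in% colnames(sheet)) {
    tab <- table(g, sheet$smoking)
    if (all(dim(tab) >= 2))
      smoking <- suppressWarnings(chisq.test(tab))
  }
  corr <- do.call(rbind, lapply(setdiff(vars, "age"), function(v) {
    ok <- !is.na(sheet$age) & !is.na(sheet[[v]])
    if (sum(ok) < 3 || sd(sheet[[v]][ok]) == 0)
      return(data.frame(variable = v, r = NA_real_, p = NA_real_,
                        n = sum(ok)))
    ct <- cor.test(sheet$age[ok], sheet[[v]][ok])
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  }))
  list(descriptives = desc, smoking = smoking, age_correlations = corr)
}
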