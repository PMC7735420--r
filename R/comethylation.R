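# Weighted co-methylation network analysis: variable-CpG selection,
# soft-threshold adjacency, topological overlap, average-linkage module
# detection at a static cut height, module eigengenes and eigengene-trait
# correlation. No randomized step: identical input gives identical
# modules.

#' Select the most variable complete-coverage CpGs
#'
#' Restricts to sites with no missing beta in any sample, ranks by sample
#' variance (descending; ties broken by chromosome and position) and takes
#' the top `k` (default 20,000, the conventional single-block size).
#'
#' @param me a filtered [MethylationExperiment-class].
#' @param k number of sites to keep.
#' @param min_sites error if fewer complete sites than this survive.
#' @return character vector of site ids, most variable first.
#' @export
selectVariableCpgs <- function(me, k = 20000L, min_sites = 2L) {
  beta <- betaValues(me)
  complete <- rowSums(is.na(beta)) == 0
  if (sum(complete) < min_sites)
    stop("fewer than ", min_sites, " CpGs with complete coverage")
  b <- beta[complete, , drop = FALSE]
  v <- apply(b, 1, var)
  st <- siteTable(me)
  st <- st[match(rownames(b), st$id), ]
  o <- order(-v, st$chrom, st$pos)
  rownames(b)[o][seq_len(min(k, nrow(b)))]
}

#' Soft-thresholded co-methylation adjacency
#'
#' Unsigned (the default): `a_ij = |cor(x_i, x_j)|^power`; signed:
#' `((1 + cor)/2)^power`. Diagonal is 1. A soft-thresholding power of 8
#' is the study's choice for an unsigned sperm methylome network.
#'
#' @param beta_subset sites x samples matrix, no missing values.
#' @param power soft-thresholding exponent.
#' @param signed use the signed transform.
#' @return symmetric sites x sites adjacency with entries in `[0, 1]`.
#' @export
buildAdjacency <- function(beta_subset, power = 8, signed = FALSE) {
  stopifnot(is.matrix(beta_subset), nrow(beta_subset) >= 2,
            !anyNA(beta_subset))
  sds <- apply(beta_subset, 1, sd)
  if (any(sds == 0))
    stop("zero-variance site(s): ",
         paste(head(rownames(beta_subset)[sds == 0], 3), collapse = ", "),
         " — exclude upstream")
  r <- cor(t(beta_subset))
  a <- if (signed) ((1 + r) / 2)^power else abs(r)^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, where the sum runs over `u != i, j` and
#' `k_i = sum_(u != i) a_iu` is the connectivity; `TOM_ii = 1`. The
#' dissimilarity used for clustering is `1 - TOM`.
#'
#' @param adjacency output of [buildAdjacency()].
#' @return TOM matrix, same dimensions.
#' @export
topologicalOverlap <- function(adjacency) {
  a <- adjacency
  stopifnot(isSymmetric(unname(a)))
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a            # (A^2)_ij sums over all u != (diag is 0);
                                 # u = i or j contribute 0 since a_ii = 0
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-methylation modules
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a static
#' height (default 0.4); clusters smaller than `min_size` (default 30)
#' fall into the unassigned pool, labelled `"grey"`. Modules are labelled
#' `"M1", "M2", ...` in decreasing size order (ties broken by first
#' member), making labels deterministic.
#'
#' @param tom a TOM matrix from [topologicalOverlap()].
#' @param min_size minimum CpGs per module.
#' @param cut_height static tree-cut height on the dissimilarity scale.
#' @return named character vector: module label per site (`"grey"` =
#'   unassigned).
#' @export
detectModules <- function(tom, min_size = 30L, cut_height = 0.4) {
  d <- stats::as.dist(1 - tom)
  hc <- hclust(d, method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  lab <- rep("grey", length(raw))
  names(lab) <- rownames(tom)
  if (length(keep)) {
    first_member <- vapply(keep, function(k) min(which(raw == k)), 0L)
    keep <- keep[order(-sizes[keep], first_member)]
    for (i in seq_along(keep))
      lab[raw == as.integer(keep[i])] <- paste0("M", i)
  }
  lab
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' per-CpG standardized (zero mean, unit variance) methylation submatrix
#' across samples, scaled to unit variance; the sign is fixed so that the
#' eigengene correlates positively with the module's mean standardized
#' methylation. `varexp` is the leading eigenvalue's share of the module
#' variance.
#'
#' @param beta_subset sites x samples matrix (no missing values).
#' @param assignments named module labels from [detectModules()]
#'   (`"grey"` is skipped).
#' @return list: `eigengenes` (samples x modules matrix), `varexp`
#'   (named fractions).
#' @export
moduleEigengenes <- function(beta_subset, assignments) {
  mods <- setdiff(sort(unique(assignments)), "grey")
  if (!length(mods)) stop("no modules to summarize")
  egs <- list(); vex <- c()
  for (m in mods) {
    ids <- names(assignments)[assignments == m]
    if (length(ids) < 2L) stop("module ", m, " has fewer than 2 CpGs")
    sub <- beta_subset[ids, , drop = FALSE]
    z <- t(scale(t(sub)))              # per-CpG standardization
    if (anyNA(z)) stop("degenerate (zero-variance) CpG in module ", m)
    sv <- svd(z)
    score <- sv$v[, 1L]
    score <- score / sd(score)         # unit variance across samples
    score <- score - mean(score)
    if (cor(score, colMeans(z)) < 0) score <- -score
    egs[[m]] <- score
    vex[m] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  eg <- do.call(cbind, egs)
  rownames(eg) <- colnames(beta_subset)
  list(eigengenes = eg, varexp = vex)
}

#' Module-trait correlation
#'
#' Pearson correlation (with two-sided p) between each module eigengene
#' and each trait, complete-case per trait. Categorical traits are coded
#' numerically: fertility fertile/infertile as 0/1, smoking
#' never/past/current as 0/1/2 (ordinal). Constant traits are flagged
#' with missing correlation.
#'
#' @param eigengenes samples x modules matrix from [moduleEigengenes()].
#' @param sheet sample sheet `data.frame` (rows in sample order).
#' @param traits character vector of sheet columns.
#' @return `data.frame`: `module`, `trait`, `r`, `p`, `n`.
#' @export
moduleTraitCorrelation <- function(eigengenes, sheet, traits) {
  codeTrait <- function(v, name) {
    if (name == "fertility") as.numeric(v == "infertile")
    else if (name == "smoking")
      c(never = 0, past = 1, current = 2)[as.character(v)]
    else as.numeric(v)
  }
  rows <- list()
  for (tr in traits) {
    if (!tr %in% colnames(sheet)) stop("trait not in sheet: ", tr)
    tv <- codeTrait(sheet[[tr]], tr)
    for (m in colnames(eigengenes)) {
      ok <- !is.na(tv)
      if (sum(ok) < 5L || sd(tv[ok]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          module = m, trait = tr, r = NA_real_, p = NA_real_, n = sum(ok))
        next
      }
      ct <- cor.test(eigengenes[ok, m], tv[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, trait = tr, r = unname(ct$estimate), p = ct$p.value,
        n = sum(ok))
    }
  }
  do.call(rbind, rows)
}

#' One-call co-methylation pipeline
#'
#' [selectVariableCpgs()] -> [buildAdjacency()] -> [topologicalOverlap()]
#' -> [detectModules()] -> [moduleEigengenes()] ->
#' [moduleTraitCorrelation()].
#'
#' @param me a filtered [MethylationExperiment-class].
#' @param traits trait columns for the correlation step.
#' @param k,power,signed,min_size,cut_height stage parameters.
#' @param sheet optional sample sheet override.
#' @return list: `cpg_ids`, `assignments`, `eigengenes`, `varexp`,
#'   `module_trait` (NULL when no module was found).
#' @export
runComethylation <- function(me, traits = c("age", "fertility"),
                             k = 20000L, power = 8, signed = FALSE,
                             min_size = 30L, cut_height = 0.4,
                             sheet = NULL) {
  if (is.null(sheet)) sheet <- sampleSheet(me)
  ids <- selectVariableCpgs(me, k = k, min_sites = min_size)
  beta <- betaValues(me)[ids, , drop = FALSE]
  adj <- buildAdjacency(beta, power = power, signed = signed)
  tom <- topologicalOverlap(adj)
  assignments <- detectModules(tom, min_size = min_size,
                               cut_height = cut_height)
  if (all(assignments == "grey"))
    return(list(cpg_ids = ids, assignments = assignments,
                eigengenes = NULL, varexp = NULL, module_trait = NULL))
  eg <- moduleEigengenes(beta, assignments)
  mt <- moduleTraitCorrelation(eg$eigengenes, sheet, traits)
  list(cpg_ids = ids, assignments = assignments,
       eigengenes = eg$eigengenes, varexp = eg$varexp, module_trait = mt)
}
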