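# Shared fixtures, built in code at test time.

# a tiny hand-built experiment: 4 sites x 3 samples
tinyMe <- function() {
  meth <- matrix(c(5L, 0L, 10L, 2L,
                   8L, 1L, 20L, 0L,
                   0L, 3L, 30L, 4L), nrow = 4,
                 dimnames = list(NULL, c("s1", "s2", "s3")))
  total <- matrix(c(10L, 4L, 10L, 8L,
                    10L, 2L, 40L, 0L,
                    5L, 3L, 30L, 8L), nrow = 4,
                  dimnames = list(NULL, c("s1", "s2", "s3")))
  MethylationExperiment(meth, total,
                        chrom = c("chr1", "chr1", "chr2", "chr2"),
                        pos = c(100L, 250L, 50L, 75L))
}

# a small synthetic cohort; planted structure scaled down to stay fast
smallCohort <- function(seed = 1L, n_cpgs = 400L, ...) {
  args <- list(n_cpgs = n_cpgs, seed = seed, ...)
  for (nm in c("n_planted_dmrs", "n_modules", "module_size")) {
    if (is.null(args[[nm]]))
      args[[nm]] <- c(n_planted_dmrs = 2L, n_modules = 1L,
                      module_size = 30L)[[nm]]
  }
  if (is.null(args$module_age_r)) args$module_age_r <- 0.6
  simulateCohort(do.call(cohortConfig, args))
}

# brute-force DMR oracle: enumerate every window anchored at a significant
# CpG, collect members of qualifying windows, and merge windows that share
# a member CpG (connected components). Independent of callDmrs internals.
bruteDmrs <- function(sig, all_sites = NULL, window = 500L, min_cpgs = 5L) {
  out <- list()
  for (dir in c("hyper", "hypo")) {
    sd_ <- sig[sig$direction == dir, , drop = FALSE]
    for (cr in unique(sd_$chrom)) {
      p <- sort(sd_$pos[sd_$chrom == cr])
      n <- length(p)
      members_of <- list()
      for (i in seq_len(n)) {
        inw <- which(p >= p[i] & p < p[i] + window)
        if (length(inw) >= min_cpgs) members_of[[length(members_of) + 1]] <- inw
      }
      if (!length(members_of)) next
      # merge member sets that intersect
      merged <- list()
      for (s in members_of) {
        hit <- which(vapply(merged, function(m) length(intersect(m, s)) > 0,
                            TRUE))
        if (length(hit)) {
          s <- sort(unique(c(s, unlist(merged[hit]))))
          merged <- merged[-hit]
        }
        merged[[length(merged) + 1]] <- s
      }
      # repeat until stable (chained merges)
      repeat {
        changed <- FALSE
        for (i in seq_along(merged)) {
          for (j in seq_along(merged)) {
            if (i < j && length(intersect(merged[[i]], merged[[j]]))) {
              merged[[i]] <- sort(unique(c(merged[[i]], merged[[j]])))
              merged[[j]] <- integer(0)
              changed <- TRUE
            }
          }
        }
        merged <- merged[lengths(merged) > 0]
        if (!changed) break
      }
      for (m in merged) {
        start <- min(p[m]); end <- max(p[m]) + 1L
        tot <- if (is.null(all_sites)) NA_integer_ else
          sum(all_sites$chrom == cr & all_sites$pos >= start &
                all_sites$pos < end)
        out[[length(out) + 1]] <- data.frame(
          chrom = cr, start = start, end = end, direction = dir,
          n_sig_cpgs = length(m), n_total_cpgs = tot,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      n_sig_cpgs = integer(0), n_total_cpgs = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$direction), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# random significant-CpG instance for DMR oracle comparisons
randomDmrInstance <- function(n_max = 300L) {
  n <- sample.int(n_max, 1)
  chrom <- sample(paste0("chr", 1:2), n, replace = TRUE)
  pos <- sample.int(5000L, n, replace = FALSE)[seq_len(n)]
  df <- data.frame(chrom = chrom, pos = pos,
                   direction = sample(c("hyper", "hypo"), n, replace = TRUE),
                   q = runif(n, 0, 0.01), effect = rnorm(n, 0, 0.004))
  df[order(df$chrom, df$pos), , drop = FALSE]
}

# correlated Gaussian block matrix (sites x samples) for network tests
gaussianBlocks <- function(n_samp, sizes, r, n_noise = 0) {
  rows <- list()
  for (b in seq_along(sizes)) {
    z <- rnorm(n_samp)
    for (i in seq_len(sizes[b]))
      rows[[length(rows) + 1]] <- sqrt(r) * z + sqrt(1 - r) * rnorm(n_samp)
  }
  for (i in seq_len(n_noise)) rows[[length(rows) + 1]] <- rnorm(n_samp)
  x <- do.call(rbind, rows)
  rownames(x) <- paste0("cg", seq_len(nrow(x)))
  x
}

jaccard <- function(a, b)
  length(intersect(a, b)) / length(union(a, b))

# best Jaccard match of each truth module among detected modules
bestModuleJaccard <- function(assignments, truth_assign) {
  truths <- sort(unique(truth_assign[!is.na(truth_assign)]))
  dets <- setdiff(unique(assignments), "grey")
  vapply(truths, function(tm) {
    b <- names(truth_assign)[!is.na(truth_assign) & truth_assign == tm]
    if (!length(dets)) return(0)
    max(vapply(dets, function(m)
      jaccard(names(assignments)[assignments == m], b), 0))
  }, 0)
}
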