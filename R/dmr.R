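# Direction-specific DMR calling (>= min_cpgs significant CpGs within a
# window) and genome-wide DMC density tracks.

.checkSortedPerChrom <- function(chrom, pos, what) {
  for (cr in unique(chrom)) {
    p <- pos[chrom == cr]
    if (is.unsorted(p, strictly = FALSE))
      stop(what, " positions must be sorted per chromosome (", cr,
           " is not); refusing to resort silently")
  }
  invisible(TRUE)
}

#' Call differentially methylated regions
#'
#' Hyper- and hypomethylated DMRs are called independently per direction
#' and chromosome: every window `[p, p + window)` anchored at a significant
#' CpG `p` qualifies when it contains at least `min_cpgs` significant CpGs
#' of that direction; overlapping/chained qualifying windows are merged,
#' and each merged group of member CpGs becomes one DMR spanning its first
#' to last member (half-open end). Mixed-direction clusters yield no call.
#' Defaults are the study rule: 5 or more CpGs within 500 bp.
#'
#' @param sig `data.frame` of significant CpGs: `chrom`, `pos` (0-based),
#'   `direction` (`"hyper"`/`"hypo"`), and optionally `q` and `effect`
#'   (used for per-DMR summaries). Must be position-sorted within each
#'   chromosome; unsorted input is an error, not a silent resort.
#' @param all_sites `data.frame` with `chrom`, `pos` of every assayed CpG
#'   (for the `n_total_cpgs` column); may be `NULL`.
#' @param window window width in bp.
#' @param min_cpgs minimum same-direction significant CpGs in a window.
#' @return `data.frame`: `chrom`, `start`, `end` (0-based half-open),
#'   `direction`, `n_sig_cpgs`, `n_total_cpgs`, `min_q`, `mean_effect`.
#' @export
callDmrs <- function(sig, all_sites = NULL, window = 500L, min_cpgs = 5L) {
  if (window <= 0) stop("window must be positive")
  cols <- c("chrom", "pos", "direction")
  if (!all(cols %in% colnames(sig)))
    stop("sig must have columns chrom, pos, direction")
  if (nrow(sig) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      n_sig_cpgs = integer(0), n_total_cpgs = integer(0),
                      min_q = numeric(0), mean_effect = numeric(0)))
  if (!all(sig$direction %in% c("hyper", "hypo")))
    stop("direction must be 'hyper' or 'hypo'")
  .checkSortedPerChrom(sig$chrom, sig$pos, "significant CpG")
  if (!is.null(all_sites))
    .checkSortedPerChrom(all_sites$chrom, all_sites$pos, "assayed CpG")
  out <- list()
  for (dir in c("hyper", "hypo")) {
    sd_ <- sig[sig$direction == dir, , drop = FALSE]
    for (cr in unique(sd_$chrom)) {
      sc <- sd_[sd_$chrom == cr, , drop = FALSE]
      p <- sc$pos
      n <- length(p)
      if (n < min_cpgs) next
      # right pointer of each anchored window [p_i, p_i + window)
      ends <- findInterval(p + window - 1e-9, p)  # last index with pos < p+w
      counts <- ends - seq_len(n) + 1L
      qual <- which(counts >= min_cpgs)
      if (!length(qual)) next
      # merge overlapping qualifying windows
      ws <- p[qual]; we <- p[qual] + window
      grp <- cumsum(c(TRUE, ws[-1] > cummax(we)[-length(we)]))
      for (gi in unique(grp)) {
        in_g <- grp == gi
        lo <- min(ws[in_g])
        hi <- max(we[in_g])
        memb <- which(p >= lo & p < hi)
        start <- min(p[memb]); end <- max(p[memb]) + 1L
        tot <- if (is.null(all_sites)) NA_integer_ else
          sum(all_sites$chrom == cr & all_sites$pos >= start &
                all_sites$pos < end)
        out[[length(out) + 1L]] <- data.frame(
          chrom = cr, start = start, end = end, direction = dir,
          n_sig_cpgs = length(memb), n_total_cpgs = tot,
          min_q = if ("q" %in% colnames(sc)) min(sc$q[memb]) else NA_real_,
          mean_effect = if ("effect" %in% colnames(sc))
            mean(sc$effect[memb]) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      n_sig_cpgs = integer(0), n_total_cpgs = integer(0),
                      min_q = numeric(0), mean_effect = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$direction), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' DMC density over sliding genomic windows
#'
#' The ratio of differentially methylated CpGs over all assayed CpGs within
#' sliding windows (default 1 Mb windows stepped every 100 kb), computed
#' per direction. Windows holding no assayed CpG have missing density.
#'
#' @param all_sites `data.frame` with `chrom`, `pos` of every assayed CpG.
#' @param dmcs `data.frame` with `chrom`, `pos`, `direction` of significant
#'   CpGs.
#' @param window,step window width and step in bp (`window <= 0` is an
#'   error; `window < step` is allowed).
#' @return `data.frame`: `chrom`, `start`, `end`, `direction`, `n_dmcs`,
#'   `n_cpgs`, `density`.
#' @export
dmcDensity <- function(all_sites, dmcs, window = 1e6, step = 1e5) {
  if (window <= 0) stop("window must be positive")
  if (step <= 0) stop("step must be positive")
  .checkSortedPerChrom(all_sites$chrom, all_sites$pos, "assayed CpG")
  out <- list()
  for (cr in unique(all_sites$chrom)) {
    p_all <- all_sites$pos[all_sites$chrom == cr]
    starts <- seq(0, max(p_all), by = step)
    for (dir in c("hyper", "hypo")) {
      p_dmc <- dmcs$pos[dmcs$chrom == cr & dmcs$direction == dir]
      n_all <- findInterval(starts + window - 1e-9, p_all) -
        findInterval(starts - 1e-9, p_all)
      n_dmc <- if (length(p_dmc))
        findInterval(starts + window - 1e-9, sort(p_dmc)) -
          findInterval(starts - 1e-9, sort(p_dmc)) else
        rep(0L, length(starts))
      out[[length(out) + 1L]] <- data.frame(
        chrom = cr, start = starts, end = starts + window, direction = dir,
        n_dmcs = n_dmc, n_cpgs = n_all,
        density = ifelse(n_all > 0, n_dmc / n_all, NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export DMRs as BED6+
#'
#' Name is `direction_chrom_start`; score is `-log10(min_q)` capped at
#' 1000; strand is `.`; a seventh column repeats the direction.
#'
#' @param dmrs output of [callDmrs()]
#' @param path output path
#' @export
writeDmrBed <- function(dmrs, path) {
  if (nrow(dmrs) == 0) { file.create(path); return(invisible(path)) }
  score <- ifelse(is.na(dmrs$min_q), 0,
                  pmin(-log10(pmax(dmrs$min_q, 1e-300)), 1000))
  df <- data.frame(dmrs$chrom, dmrs$start, dmrs$end,
                   paste0(dmrs$direction, "_", dmrs$chrom, "_", dmrs$start),
                   round(score, 3), ".", dmrs$direction)
  df <- df[order(df[[1]], df[[2]]), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Export a density track as bedGraph (one file per direction)
#'
#' @param density output of [dmcDensity()]
#' @param prefix output path prefix; files are `<prefix>_<direction>.bedGraph`
#' @export
writeDensityBedGraph <- function(density, prefix) {
  paths <- c()
  for (dir in unique(density$direction)) {
    d <- density[density$direction == dir & !is.na(density$density), ]
    p <- paste0(prefix, "_", dir, ".bedGraph")
    write.table(d[, c("chrom", "start", "end", "density")], p, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths[dir] <- p
  }
  invisible(paths)
}
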