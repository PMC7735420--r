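# Nearest-TSS annotation, interval-track overlap fractions, GREAT-style
# +/- 1 Mb gene density enrichment, constrained-element overlap and
# per-chromosome representation.

.asSiteDf <- function(x) {
  if (inherits(x, "GRanges"))
    return(data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                      pos = GenomicRanges::start(x) - 1L))
  stopifnot(all(c("chrom", "pos") %in% colnames(x)))
  x[, c("chrom", "pos")]
}

.asTrack <- function(x) if (is.character(x)) readBedRegions(x) else x

#' Annotate CpGs to their nearest transcription start site
#'
#' Minimum absolute distance, with an orientation-aware sign: positive
#' distances are downstream of the TSS with respect to the gene's strand
#' (a CpG 500 bp right of a minus-strand TSS is 500 bp *upstream*, distance
#' -500). Ties are broken by lexicographically smallest gene id. CpGs on
#' chromosomes carrying no gene are returned unannotated (`NA`).
#'
#' @param cpgs `data.frame` with `chrom`, `pos` (0-based) or a `GRanges`.
#' @param genes `data.frame` with `gene_id`, `chrom`, `tss` (0-based bp),
#'   `strand` (`"+"`/`"-"`).
#' @return `data.frame`: `chrom`, `pos`, `gene_id`, `distance` (signed bp).
#' @export
nearestTss <- function(cpgs, genes) {
  cp <- .asSiteDf(cpgs)
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% colnames(genes)))
  gene_id <- rep(NA_character_, nrow(cp))
  distance <- rep(NA_real_, nrow(cp))
  for (cr in unique(cp$chrom)) {
    gi <- which(genes$chrom == cr)
    ci <- which(cp$chrom == cr)
    if (!length(gi)) next
    g <- genes[gi, , drop = FALSE]
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    # first gene at each distinct tss already carries the smallest id
    keep <- !duplicated(g$tss)
    g <- g[keep, , drop = FALSE]
    pos <- cp$pos[ci]
    k <- findInterval(pos, g$tss)
    left <- pmax(k, 1L); right <- pmin(k + 1L, nrow(g))
    dl <- abs(pos - g$tss[left]); dl[k < 1L] <- Inf
    dr <- abs(pos - g$tss[right]); dr[k >= nrow(g)] <- Inf
    use_left <- dl < dr |
      (dl == dr & g$gene_id[left] <= g$gene_id[right])
    pick <- ifelse(use_left, left, right)
    gene_id[ci] <- g$gene_id[pick]
    raw <- pos - g$tss[pick]
    distance[ci] <- ifelse(g$strand[pick] == "-", -raw, raw)
  }
  data.frame(chrom = cp$chrom, pos = cp$pos, gene_id = gene_id,
             distance = distance, stringsAsFactors = FALSE)
}

#' Binned TSS-distance profile
#'
#' Fraction of annotated CpGs per signed distance bin. Default bins are
#' GREAT-style: 0-5 kb, 5-50 kb, 50-500 kb, > 500 kb on each side of the
#' TSS. Fractions sum to 1 over assigned CpGs.
#'
#' @param distances signed distances from [nearestTss()] (`NA` dropped).
#' @param breaks strictly increasing bin edges.
#' @return `data.frame`: `bin`, `count`, `fraction` (empty for empty
#'   input).
#' @export
distanceProfile <- function(distances,
                            breaks = c(-Inf, -5e5, -5e4, -5e3, 0,
                                       5e3, 5e4, 5e5, Inf)) {
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing")
  d <- distances[!is.na(distances)]
  if (!length(d))
    return(data.frame(bin = character(0), count = integer(0),
                      fraction = numeric(0)))
  cuts <- cut(d, breaks, include.lowest = TRUE, right = TRUE)
  tab <- table(cuts)
  data.frame(bin = names(tab), count = as.integer(tab),
             fraction = as.integer(tab) / length(d),
             stringsAsFactors = FALSE)
}

#' Fraction of CpGs overlapping an interval track
#'
#' @param cpgs `data.frame` with `chrom`, `pos` or a `GRanges`.
#' @param track `GRanges` or BED path (0-based half-open on disk).
#' @return list: `fraction`, `n_overlap`, `n_total`.
#' @export
overlapFraction <- function(cpgs, track) {
  cp <- .asSiteDf(cpgs)
  gr <- .asTrack(track)
  if (nrow(cp) == 0) return(list(fraction = NA_real_, n_overlap = 0L,
                                 n_total = 0L))
  if (length(gr) == 0) return(list(fraction = 0, n_overlap = 0L,
                                   n_total = nrow(cp)))
  sites <- GenomicRanges::GRanges(cp$chrom,
                                  IRanges::IRanges(cp$pos + 1L, width = 1L))
  hit <- .quietOverlaps(sites, gr)
  list(fraction = mean(hit), n_overlap = sum(hit), n_total = nrow(cp))
}

#' Fraction of CpGs in evolutionarily constrained elements
#'
#' Consumes a precomputed per-interval score track (e.g. GERP++ element
#' scores as BED with a score column) and reports the fraction of CpGs
#' falling in elements scoring above `threshold` (default 1.7, the
#' conventional cut for constraint comparable to known functional
#' elements).
#'
#' @param cpgs `data.frame` with `chrom`, `pos` or a `GRanges`.
#' @param score_track `GRanges` with a numeric `score` column, or BED path.
#' @param threshold score cut-off.
#' @return list as in [overlapFraction()].
#' @export
constrainedFraction <- function(cpgs, score_track, threshold = 1.7) {
  gr <- .asTrack(score_track)
  if (length(gr) && is.null(gr$score))
    stop("score_track must carry a 'score' column")
  overlapFraction(cpgs, gr[!is.na(gr$score) & gr$score > threshold])
}

#' GREAT-style gene density enrichment of foreground CpGs
#'
#' For each gene, counts foreground (e.g. hypermethylated DMCs) and
#' background (all retained panel) CpGs within `tss +/- flank` and tests
#' foreground over-representation with a one-sided hypergeometric test
#' (population = background CpGs, successes = background CpGs in the
#' window, draws = all foreground CpGs). q-values come from [qvalues()];
#' a gene is enriched at `q < q_threshold`. Genes whose window holds no
#' background CpG are flagged `skipped` and excluded from testing.
#'
#' @param fg,bg foreground and background CpGs (`data.frame` with `chrom`,
#'   `pos`, or `GRanges`); `fg` should be a subset of `bg`.
#' @param genes gene table as in [nearestTss()].
#' @param flank window half-width in bp (default 1 Mb).
#' @param q_threshold enrichment call threshold.
#' @return `data.frame`: `gene_id`, `n_fg_in_window`, `n_bg_in_window`,
#'   `n_fg_total`, `n_bg_total`, `p`, `q`, `enriched`, `skipped`.
#' @export
geneDensityEnrichment <- function(fg, bg, genes, flank = 1e6,
                                  q_threshold = 0.01) {
  fgd <- .asSiteDf(fg); bgd <- .asSiteDf(bg)
  n_fg <- nrow(fgd); n_bg <- nrow(bgd)
  countIn <- function(df, cr, lo, hi) {
    p <- df$pos[df$chrom == cr]
    sum(p >= lo & p <= hi)
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    cr <- genes$chrom[i]; tss <- genes$tss[i]
    lo <- tss - flank; hi <- tss + flank
    K <- countIn(bgd, cr, lo, hi)
    x <- countIn(fgd, cr, lo, hi)
    p <- if (K > 0) phyper(x - 1, K, n_bg - K, n_fg, lower.tail = FALSE)
      else NA_real_
    data.frame(gene_id = genes$gene_id[i], n_fg_in_window = x,
               n_bg_in_window = K, n_fg_total = n_fg, n_bg_total = n_bg,
               p = p, skipped = K == 0, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  ok <- !res$skipped
  if (any(ok)) res$q[ok] <- qvalues(res$p[ok])
  res$enriched <- !is.na(res$q) & res$q < q_threshold
  res
}

#' Per-chromosome DMC representation
#'
#' Compares each chromosome's share of significant CpGs against its share
#' of the assayed panel with a two-sided binomial test, flagging sex
#' chromosomes (commonly depleted of sperm age-associated CpGs) for
#' separate reporting.
#'
#' @param all_sites,dmcs `data.frame`s with `chrom`, `pos`.
#' @return `data.frame`: `chrom`, `n_panel`, `n_dmc`, `panel_fraction`,
#'   `dmc_fraction`, `ratio`, `p`, `is_sex`.
#' @export
chromosomeRepresentation <- function(all_sites, dmcs) {
  n_all <- nrow(all_sites); n_dmc <- nrow(dmcs)
  chroms <- sort(unique(all_sites$chrom))
  rows <- lapply(chroms, function(cr) {
    np <- sum(all_sites$chrom == cr)
    nd <- sum(dmcs$chrom == cr)
    pf <- np / n_all
    p <- if (n_dmc > 0) stats::binom.test(nd, n_dmc, pf)$p.value else
      NA_real_
    data.frame(chrom = cr, n_panel = np, n_dmc = nd, panel_fraction = pf,
               dmc_fraction = if (n_dmc > 0) nd / n_dmc else NA_real_,
               ratio = if (n_dmc > 0) (nd / n_dmc) / pf else NA_real_,
               p = p, is_sex = cr %in% c("chrX", "chrY", "X", "Y"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
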