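# Reading/writing cytosine reports, BED intervals and methylation tables;
# the site filters; imprinted-locus purity QC.

#' Read a genome-wide cytosine report
#'
#' Parses the tab-delimited per-cytosine report emitted by bisulfite
#' aligners (chrom, 1-based position, strand, methylated count,
#' unmethylated count, context). Only CpG-context rows are retained;
#' positions are converted to the package's 0-based internal convention.
#' With `merge_strands` (the default, matching CpG-level reporting), the
#' G-strand record of each dyad is summed into the forward-strand C record
#' one base upstream.
#'
#' @param path path to the report.
#' @param merge_strands collapse CpG dyads onto the forward-strand C.
#' @return `data.frame` with `chrom`, `pos` (0-based), `meth`, `total`
#'   (and `strand` when `merge_strands = FALSE`), sorted by (chrom, pos).
#' @export
readCytosineReport <- function(path, merge_strands = TRUE) {
  if (!file.exists(path)) stop("no such cytosine report: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L))
    stop("malformed cytosine report line ", which(nf != 6L)[1], " in ", path,
         ": expected 6 tab-separated fields, got ", nf[nf != 6L][1])
  m <- do.call(rbind, parts)
  pos1 <- suppressWarnings(as.integer(m[, 2]))
  meth <- suppressWarnings(as.numeric(m[, 4]))
  unmeth <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(pos1) | is.na(meth) | is.na(unmeth))
  if (length(bad))
    stop("malformed cytosine report line ", bad[1], " in ", path,
         ": non-numeric position or counts")
  if (any(meth < 0) || any(unmeth < 0))
    stop("negative counts in cytosine report ", path, " (line ",
         which(meth < 0 | unmeth < 0)[1], ")")
  keep <- m[, 6] %in% c("CpG", "CG", "CpG_context")
  df <- data.frame(chrom = m[keep, 1], pos1 = pos1[keep],
                   strand = m[keep, 3], meth = meth[keep],
                   unmeth = unmeth[keep], stringsAsFactors = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("invalid strand field in ", path)
  if (merge_strands) {
    # forward C at 1-based p -> 0-based p-1; reverse G at p -> dyad C at p-2
    df$pos <- ifelse(df$strand == "+", df$pos1 - 1L, df$pos1 - 2L)
    agg <- stats::aggregate(cbind(meth, unmeth) ~ chrom + pos, df, sum)
    out <- data.frame(chrom = agg$chrom, pos = agg$pos, meth = agg$meth,
                      total = agg$meth + agg$unmeth, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(chrom = df$chrom, pos = df$pos1 - 1L,
                      strand = df$strand, meth = df$meth,
                      total = df$meth + df$unmeth, stringsAsFactors = FALSE)
  }
  out[order(out$chrom, out$pos), , drop = FALSE] |>
    (\(x) { rownames(x) <- NULL; x })()
}

#' Write per-sample CpG counts as a cytosine report
#'
#' Inverse of [readCytosineReport()] for strand-merged data: one `+`-strand
#' CpG-context row per site, 1-based positions.
#'
#' @param counts `data.frame` with `chrom`, `pos` (0-based), `meth`, `total`.
#' @param path output path.
#' @export
writeCytosineReport <- function(counts, path) {
  df <- data.frame(chrom = counts$chrom, pos = counts$pos + 1L,
                   strand = "+", meth = counts$meth,
                   unmeth = counts$total - counts$meth, context = "CpG")
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write cytosine report: ", path)
  invisible(path)
}

#' Assemble per-sample count tables into a MethylationExperiment
#'
#' Takes the union of sites across samples; (site, sample) pairs absent
#' from a sample's table get `total = 0` (missing beta).
#'
#' @param counts_list named list of `data.frame`s as returned by
#'   [readCytosineReport()] (strand-merged); names are sample ids.
#' @param sampleData optional per-sample covariate `data.frame`.
#' @return a [MethylationExperiment-class].
#' @export
assembleMatrix <- function(counts_list, sampleData = NULL) {
  ids <- names(counts_list)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("counts_list must be named by sample id")
  if (anyDuplicated(ids))
    stop("duplicate sample id: ", ids[anyDuplicated(ids)])
  keys <- unique(do.call(rbind, lapply(counts_list, function(d)
    data.frame(chrom = d$chrom, pos = d$pos))))
  key_id <- paste0(keys$chrom, ":", keys$pos)
  meth <- matrix(0L, nrow(keys), length(ids),
                 dimnames = list(key_id, ids))
  total <- meth
  for (s in ids) {
    d <- counts_list[[s]]
    i <- match(paste0(d$chrom, ":", d$pos), key_id)
    meth[i, s] <- as.integer(round(d$meth))
    total[i, s] <- as.integer(round(d$total))
  }
  MethylationExperiment(meth, total, keys$chrom, keys$pos,
                        sampleData = sampleData)
}

#' Read BED intervals as GRanges
#'
#' @param path a BED3+ file (0-based half-open on disk; returned as the
#'   usual 1-based `GRanges`).
#' @return a [GenomicRanges::GRanges]
#' @export
readBedRegions <- function(path) {
  if (!file.exists(path)) stop("cannot read BED file: ", path)
  tryCatch(rtracklayer::import(path, format = "BED"),
           error = function(e)
             stop("cannot read BED file: ", path, " (", conditionMessage(e),
                  ")"))
}

#' Write GRanges as sorted BED (0-based half-open)
#'
#' @param gr a `GRanges`
#' @param path output path
#' @param name,score optional BED name/score columns
#' @export
writeBed <- function(gr, path, name = NULL, score = NULL) {
  if (length(gr) == 0) { file.create(path); return(invisible(path)) }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (!is.null(name)) {
    df$name <- name
    if (!is.null(score)) df$score <- score
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet CSV
#'
#' @param path CSV with at least `sample_id` and `age` columns.
#' @return `data.frame`; stops on duplicate ids or non-positive ages.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("no such sample sheet: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "age") %in% colnames(df)))
    stop("sample sheet must contain 'sample_id' and 'age' columns: ", path)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         df$sample_id[anyDuplicated(df$sample_id)])
  if (any(!is.na(df$age) & df$age <= 0))
    stop("non-positive age in sample sheet: ", path)
  df
}

#' Apply the site filters
#'
#' Three steps, in order: (1) coverage mask — beta is set missing (counts
#' zeroed) for every (site, sample) cell with fewer than `min_coverage`
#' reads; (2) sites overlapping any exclusion interval (SNPs, blacklisted
#' regions) are removed; (3) sites with fewer than `min_samples` samples
#' still carrying data are removed. Defaults are the conventional rules
#' for deep targeted bisulfite data: >= 20x per-cell coverage and data in
#' at least 30 samples.
#'
#' @param me a [MethylationExperiment-class]
#' @param min_coverage minimum reads for a cell to count as observed.
#' @param min_samples minimum observed samples for a site to be retained.
#' @param exclusion_beds list of BED paths and/or `GRanges` to exclude.
#' @return `list(me = filtered MethylationExperiment, report = FilterReport)`
#' @export
filterSites <- function(me, min_coverage = 20L, min_samples = 30L,
                        exclusion_beds = list()) {
  stopifnot(nrow(me) > 0)
  meth <- methCounts(me); total <- totalCounts(me)
  n_input <- nrow(me)
  mask <- total < min_coverage & total > 0
  n_masked <- sum(mask) + sum(total == 0)  # cells without usable data
  meth[total < min_coverage] <- 0L
  total[total < min_coverage] <- 0L

  rr <- SummarizedExperiment::rowRanges(me)
  excluded <- rep(FALSE, n_input)
  if (length(exclusion_beds)) {
    if (inherits(exclusion_beds, "GRanges"))
      exclusion_beds <- list(exclusion_beds)
    for (b in exclusion_beds) {
      gr <- if (is.character(b)) readBedRegions(b) else b
      excluded <- excluded |
        .quietOverlaps(rr, gr)
    }
  }
  n_excl <- sum(excluded)
  keep1 <- !excluded
  n_obs <- rowSums(total[keep1, , drop = FALSE] > 0)
  few <- n_obs < min_samples
  n_few <- sum(few)
  keep_idx <- which(keep1)[!few]

  st <- siteTable(me)
  out <- MethylationExperiment(meth[keep_idx, , drop = FALSE],
                               total[keep_idx, , drop = FALSE],
                               st$chrom[keep_idx], st$pos[keep_idx],
                               sampleData =
                                 as.data.frame(SummarizedExperiment::colData(me)))
  report <- new("FilterReport",
                n_input_sites = as.integer(n_input),
                n_cells_masked_low_coverage = as.integer(sum(mask)),
                n_removed_excluded_regions = as.integer(n_excl),
                n_removed_few_samples = as.integer(n_few),
                n_retained = as.integer(length(keep_idx)),
                min_coverage = as.integer(min_coverage),
                min_samples = as.integer(min_samples))
  list(me = out, report = report)
}

#' Imprinted-locus purity QC
#'
#' Sperm carries parent-of-origin methylation at germline imprinted DMRs:
#' paternally methylated loci (H19, DLK1/GTL2 IG-DMR) are near-fully
#' methylated and maternally methylated loci (MEST, KCNQ1OT1)
#' near-unmethylated; somatic-cell contamination pulls both toward ~0.5.
#' Each locus passes if its mean methylation across all assayed CpGs and
#' samples is `>= hi` (paternal) or `<= lo` (maternal). The default
#' thresholds (0.80 / 0.20) flag roughly >= 30% somatic admixture under a
#' linear mixture model. Loci with no assayed CpG are reported as not
#' assessable and fail the overall verdict rather than passing silently.
#'
#' @param me a [MethylationExperiment-class]
#' @param paternal_loci,maternal_loci `GRanges` or BED paths.
#' @param hi,lo pass thresholds for paternal / maternal mean methylation.
#' @return a [PurityReport-class]
#' @export
qcImprinting <- function(me, paternal_loci, maternal_loci,
                         hi = 0.80, lo = 0.20) {
  asGr <- function(x) if (is.character(x)) readBedRegions(x) else x
  pat <- asGr(paternal_loci); mat <- asGr(maternal_loci)
  beta <- betaValues(me)
  rr <- SummarizedExperiment::rowRanges(me)
  one <- function(gr, i, type) {
    hits <- .quietOverlaps(rr, gr[i])
    n_sites <- sum(hits)
    mb <- if (n_sites > 0)
      mean(beta[hits, , drop = FALSE], na.rm = TRUE) else NA_real_
    assess <- n_sites > 0 && !is.nan(mb) && !is.na(mb)
    pass <- assess && if (type == "paternal") mb >= hi else mb <= lo
    nm <- if (!is.null(names(gr)) && nzchar(names(gr)[i])) names(gr)[i] else
      paste0(type, "_", i)
    data.frame(locus = nm, type = type, n_sites = n_sites,
               mean_beta = mb, assessable = assess, pass = pass)
  }
  rows <- list()
  for (i in seq_along(pat)) rows[[length(rows) + 1L]] <- one(pat, i, "paternal")
  for (i in seq_along(mat)) rows[[length(rows) + 1L]] <- one(mat, i, "maternal")
  loci <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(0), type = character(0),
               n_sites = integer(0), mean_beta = numeric(0),
               assessable = logical(0), pass = logical(0))
  verdict <- if (nrow(loci) > 0 && all(loci$assessable) && all(loci$pass))
    "pass" else "fail"
  new("PurityReport", loci = loci, hi = hi, lo = lo, verdict = verdict)
}

#' Persist a MethylationExperiment as a wide tab-delimited table
#'
#' One row per site (`id`, `chrom`, 0-based `pos`) followed by one
#' `"meth,total"` column per sample. [readMethylationTable()] restores the
#' object exactly.
#'
#' @param me a [MethylationExperiment-class]
#' @param path output path
#' @export
writeMethylationTable <- function(me, path) {
  st <- siteTable(me)
  meth <- methCounts(me); total <- totalCounts(me)
  pairs <- vapply(seq_len(ncol(me)), function(j)
    paste0(meth[, j], ",", total[, j]), character(nrow(me)))
  if (nrow(me) == 1L) pairs <- matrix(pairs, nrow = 1L)
  df <- cbind(st, as.data.frame(pairs))
  colnames(df) <- c("id", "chrom", "pos", colnames(me))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMethylationTable
#' @param sampleData optional covariate table to attach.
#' @export
readMethylationTable <- function(path, sampleData = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  samples <- colnames(df)[-(1:3)]
  split2 <- function(col) {
    sp <- strsplit(col, ",", fixed = TRUE)
    list(m = as.integer(vapply(sp, `[`, "", 1L)),
         t = as.integer(vapply(sp, `[`, "", 2L)))
  }
  meth <- total <- matrix(0L, nrow(df), length(samples),
                          dimnames = list(df$id, samples))
  for (s in samples) {
    v <- split2(df[[s]])
    meth[, s] <- v$m; total[, s] <- v$t
  }
  MethylationExperiment(meth, total, df$chrom, df$pos, sampleData = sampleData)
}
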