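#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges colData
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom stats approx coef cor cor.test cutree dist hclust lm
#'   mad median model.matrix na.omit p.adjust pchisq pf phyper
#'   pnorm predict pt qchisq quantile rbinom rnbinom rnorm runif sd
#'   setNames smooth.spline t.test var chisq.test ks.test complete.cases
#' @importFrom utils read.table write.table head tail
NULL

#' MethylationExperiment: CpG read counts across samples
#'
#' A container for per-CpG bisulfite methylation data, extending
#' [SummarizedExperiment::RangedSummarizedExperiment]. Two integer assays are
#' carried: `meth` (methylated read counts) and `total` (total read counts),
#' both sites x samples. Methylation proportions (beta values,
#' methylated / total) are derived on demand by [betaValues()] and are
#' missing (`NA`) wherever `total == 0`. Row ranges are width-1 [GRanges]
#' giving the position of the CpG cytosine on the forward strand; sites are
#' always sorted by (chromosome, position). The sample sheet (age, fertility
#' status, semen, hormonal and metabolic covariates) lives in `colData`.
#'
#' Site identifiers returned by [siteIds()] are `"chrom:pos"` with a 0-based
#' position, matching the BED-style coordinates used in all on-disk output;
#' the internal `GRanges` use the usual 1-based Bioconductor convention.
#'
#' @seealso [MethylationExperiment()] (constructor), [filterSites()],
#'   [runEwas()]
#' @aliases MethylationExperiment-class
#' @exportClass MethylationExperiment
setClass("MethylationExperiment",
         contains = "RangedSummarizedExperiment")

.validMethylationExperiment <- function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("meth", "total") %in% an))
    msg <- c(msg, "assays 'meth' and 'total' are required")
  else {
    m <- SummarizedExperiment::assay(object, "meth")
    t <- SummarizedExperiment::assay(object, "total")
    if (any(m < 0) || any(t < 0))
      msg <- c(msg, "counts must be non-negative")
    if (any(m > t))
      msg <- c(msg, "meth counts must not exceed total counts")
  }
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr) > 1L) {
    o <- order(as.integer(GenomicRanges::seqnames(rr)),
               GenomicRanges::start(rr))
    if (!identical(o, seq_along(rr)))
      msg <- c(msg, "sites must be sorted by (chrom, pos)")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (is.null(msg)) TRUE else msg
}
setValidity("MethylationExperiment", .validMethylationExperiment)

#' Construct a MethylationExperiment
#'
#' @param meth,total integer matrices (sites x samples) of methylated and
#'   total read counts. Column names are sample ids.
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 0-based CpG cytosine positions.
#' @param sampleData `data.frame` of per-sample covariates (rows matched to
#'   the columns of `meth` by name or order); may be `NULL`.
#' @return A [MethylationExperiment-class] with sites sorted by
#'   (chromosome, position).
#' @examples
#' me <- MethylationExperiment(
#'   meth  = matrix(c(5L, 8L), 2, 1, dimnames = list(NULL, "s1")),
#'   total = matrix(c(10L, 10L), 2, 1, dimnames = list(NULL, "s1")),
#'   chrom = c("chr1", "chr1"), pos = c(100L, 250L))
#' betaValues(me)
#' @export
MethylationExperiment <- function(meth, total, chrom, pos, sampleData = NULL) {
  meth <- as.matrix(meth); total <- as.matrix(total)
  if (max(total, 0) < .Machine$integer.max) {
    storage.mode(meth) <- "integer"
    storage.mode(total) <- "integer"
  }
  stopifnot(identical(dim(meth), dim(total)),
            length(chrom) == nrow(meth), length(pos) == nrow(meth))
  if (is.null(colnames(meth)))
    colnames(meth) <- colnames(total) <- paste0("S", seq_len(ncol(meth)))
  if (anyDuplicated(colnames(meth)))
    stop("duplicate sample id: ",
         paste(unique(colnames(meth)[duplicated(colnames(meth))]),
               collapse = ", "))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(pos) + 1L, width = 1L))
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  o <- order(as.integer(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr))
  gr <- gr[o]
  meth <- meth[o, , drop = FALSE]
  total <- total[o, , drop = FALSE]
  ids <- paste0(as.character(GenomicRanges::seqnames(gr)), ":",
                GenomicRanges::start(gr) - 1L)
  if (anyDuplicated(ids))
    stop("duplicate site id: ", ids[anyDuplicated(ids)])
  names(gr) <- rownames(meth) <- rownames(total) <- ids
  cd <- if (is.null(sampleData)) {
    S4Vectors::DataFrame(row.names = colnames(meth))
  } else {
    sampleData <- as.data.frame(sampleData)
    if (!is.null(colnames(meth)) && !is.null(sampleData$sample_id))
      sampleData <- sampleData[match(colnames(meth), sampleData$sample_id), ,
                               drop = FALSE]
    S4Vectors::DataFrame(sampleData, row.names = colnames(meth))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = meth, total = total), rowRanges = gr, colData = cd)
  new("MethylationExperiment", se)
}

#' FilterReport: accounting of site filtering
#'
#' Records what [filterSites()] did: the per-cell coverage mask and the two
#' site-level removal steps (exclusion-region overlap, then the minimum
#' informative-sample rule). Site counts always satisfy
#' `n_input_sites - n_removed_excluded_regions - n_removed_few_samples
#'  = n_retained`; low coverage masks individual (site, sample) cells and is
#' reported as `n_cells_masked_low_coverage`.
#'
#' @aliases FilterReport-class
#' @exportClass FilterReport
setClass("FilterReport", representation(
  n_input_sites = "integer",
  n_cells_masked_low_coverage = "integer",
  n_removed_excluded_regions = "integer",
  n_removed_few_samples = "integer",
  n_retained = "integer",
  min_coverage = "integer",
  min_samples = "integer"))

setValidity("FilterReport", function(object) {
  ok <- object@n_input_sites - object@n_removed_excluded_regions -
    object@n_removed_few_samples == object@n_retained
  if (ok) TRUE else "site counts do not sum: input - removed != retained"
})

#' PurityReport: imprinted-locus purity QC verdict
#'
#' Per-locus mean methylation at paternally and maternally imprinted
#' germline regions, a pass/fail per locus, and an overall verdict. In pure
#' sperm, paternal loci (e.g. H19, DLK1/GTL2 IG-DMR) are near-fully
#' methylated and maternal loci (e.g. MEST, KCNQ1OT1) near-unmethylated;
#' somatic-cell contamination pulls both toward ~0.5. The verdict is `pass`
#' only if every assessable locus passes; loci with no assayed CpG are
#' flagged not-assessable and never silently passed.
#'
#' @aliases PurityReport-class
#' @exportClass PurityReport
setClass("PurityReport", representation(
  loci = "data.frame",      # locus, type, n_sites, mean_beta, assessable, pass
  hi = "numeric", lo = "numeric",
  verdict = "character"))

#' AgeClockModel: elastic-net methylation age predictor
#'
#' The fitted sperm epigenetic clock: an ordered CpG feature list with one
#' coefficient per feature (years per unit methylation proportion; zeros
#' are retained so the feature set is reproducible), an intercept in years,
#' the elastic-net mixing parameter `alpha`, the penalty `lambda` selected
#' by leave-one-out cross-validation over `lambda_grid`, the number of
#' training samples, and a feature-selection provenance record.
#'
#' @aliases AgeClockModel-class
#' @exportClass AgeClockModel
setClass("AgeClockModel", representation(
  cpg_ids = "character",
  intercept = "numeric",
  coefficients = "numeric",
  alpha = "numeric",
  lambda = "numeric",
  lambda_grid = "numeric",
  training_n = "integer",
  feature_selection = "list"))

# overlap test tolerant of disjoint seqlevel sets (e.g. QC loci on
# chromosomes absent from a filtered panel)
.quietOverlaps <- function(x, y)
  suppressWarnings(IRanges::overlapsAny(x, y, ignore.strand = TRUE))

setValidity("AgeClockModel", function(object) {
  msg <- NULL
  if (length(object@coefficients) != length(object@cpg_ids))
    msg <- c(msg, "one coefficient per CpG id required")
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (is.null(msg)) TRUE else msg
})
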