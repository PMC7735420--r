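# Accessors and show methods for the core containers.

#' @rdname MethylationExperiment
#' @param object,me a [MethylationExperiment-class]
#' @export
setGeneric("methCounts", function(object) standardGeneric("methCounts"))

#' @rdname MethylationExperiment
#' @export
setGeneric("totalCounts", function(object) standardGeneric("totalCounts"))

#' @rdname MethylationExperiment
#' @export
setGeneric("betaValues", function(object) standardGeneric("betaValues"))

#' @rdname MethylationExperiment
#' @export
setGeneric("siteIds", function(object) standardGeneric("siteIds"))

#' @rdname MethylationExperiment
#' @export
setGeneric("sampleSheet", function(object) standardGeneric("sampleSheet"))

#' @describeIn MethylationExperiment methylated read counts (sites x samples).
#' @export
setMethod("methCounts", "MethylationExperiment", function(object)
  SummarizedExperiment::assay(object, "meth"))

#' @describeIn MethylationExperiment total read counts (sites x samples).
#' @export
setMethod("totalCounts", "MethylationExperiment", function(object)
  SummarizedExperiment::assay(object, "total"))

#' @describeIn MethylationExperiment methylation proportions, `NA` where no
#'   reads cover the site in a sample.
#' @export
setMethod("betaValues", "MethylationExperiment", function(object) {
  m <- SummarizedExperiment::assay(object, "meth")
  t <- SummarizedExperiment::assay(object, "total")
  b <- m / t
  b[t == 0] <- NA_real_
  b
})

#' @describeIn MethylationExperiment `"chrom:pos"` site ids (0-based pos).
#' @export
setMethod("siteIds", "MethylationExperiment", function(object)
  rownames(object))

#' @describeIn MethylationExperiment the per-sample covariate table as a
#'   base `data.frame` with a `sample_id` column.
#' @export
setMethod("sampleSheet", "MethylationExperiment", function(object) {
  df <- as.data.frame(SummarizedExperiment::colData(object))
  if (!"sample_id" %in% colnames(df))
    df <- cbind(sample_id = colnames(object), df)
  rownames(df) <- NULL
  df
})

#' Site coordinate table
#'
#' Chromosome and 0-based position of every site, in matrix row order.
#'
#' @param me a [MethylationExperiment-class]
#' @return `data.frame` with columns `id`, `chrom`, `pos`.
#' @export
siteTable <- function(me) {
  rr <- SummarizedExperiment::rowRanges(me)
  data.frame(id = names(rr),
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr) - 1L,
             stringsAsFactors = FALSE)
}

setMethod("show", "MethylationExperiment", function(object) {
  cat("MethylationExperiment:", nrow(object), "CpG sites x",
      ncol(object), "samples\n")
  t <- SummarizedExperiment::assay(object, "total")
  cov <- mean(t[t > 0])
  cat(sprintf("  mean coverage (covered cells): %.1fx; missing cells: %.1f%%\n",
              if (is.nan(cov)) 0 else cov, 100 * mean(t == 0)))
  cat("  chromosomes:",
      paste(GenomeInfoDb::seqlevels(object), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport (min coverage", object@min_coverage,
      "x, min samples", object@min_samples, ")\n")
  cat("  input sites:               ", object@n_input_sites, "\n")
  cat("  cells masked (<min cov):   ", object@n_cells_masked_low_coverage, "\n")
  cat("  removed, excluded regions: ", object@n_removed_excluded_regions, "\n")
  cat("  removed, too few samples:  ", object@n_removed_few_samples, "\n")
  cat("  retained sites:            ", object@n_retained, "\n")
  invisible(object)
})

setMethod("show", "PurityReport", function(object) {
  cat("PurityReport: verdict =", object@verdict, "\n")
  print(object@loci)
  invisible(object)
})

setMethod("show", "AgeClockModel", function(object) {
  nz <- sum(object@coefficients != 0)
  cat("AgeClockModel:", length(object@cpg_ids), "CpG features (",
      nz, "non-zero ), alpha =", object@alpha,
      ", lambda =", signif(object@lambda, 4),
      ", trained on", object@training_n, "samples\n")
  invisible(object)
})

#' @describeIn AgeClockModel-class model coefficients, named by CpG id
#' @param object an `AgeClockModel`
#' @export
setMethod("coef", "AgeClockModel", function(object)
  c("(Intercept)" = object@intercept,
    setNames(object@coefficients, object@cpg_ids)))
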