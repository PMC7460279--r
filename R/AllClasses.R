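#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib rohdiv, .registration = TRUE
NULL

#' GenotypeDataset: SNP-array genotypes with a marker map and sample table
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rows are biallelic SNP
#' markers (a \code{GRanges} with metadata columns \code{id},
#' \code{allele_a}, \code{allele_b}), whose columns are samples (with
#' \code{id}, \code{breed}, \code{sex}), and whose single assay
#' \code{"calls"} holds integer genotype codes: 0 = homozygous for
#' \code{allele_a}, 1 = heterozygous, 2 = homozygous for \code{allele_b},
#' \code{NA} = missing. Markers are kept sorted by (chromosome, position)
#' with strictly increasing positions within each chromosome; chromosomes
#' are autosomes 1--28.
#'
#' @seealso [GenotypeDataset()] for construction,
#'   [readPedMap()] / [readGenotypeTable()] for file input.
#' @export
setClass("GenotypeDataset",
         contains = "RangedSummarizedExperiment")

.validGenotypeDataset <- function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    return("assay 'calls' is required")
  calls <- SummarizedExperiment::assay(object, "calls")
  if (!is.integer(calls))
    msg <- c(msg, "assay 'calls' must be an integer matrix")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    msg <- c(msg, "non-missing genotype codes must be in {0, 1, 2}")
  mm <- SummarizedExperiment::rowRanges(object)
  need <- c("id", "allele_a", "allele_b")
  if (!all(need %in% colnames(S4Vectors::mcols(mm))))
    msg <- c(msg, "rowRanges must carry id, allele_a, allele_b")
  else if (anyDuplicated(S4Vectors::mcols(mm)$id))
    msg <- c(msg, "marker ids must be unique")
  chrom <- suppressWarnings(as.integer(as.character(
    GenomicRanges::seqnames(mm))))
  if (anyNA(chrom) || (length(chrom) && any(chrom < 1L | chrom > 28L)))
    msg <- c(msg, "chromosomes must be autosomes 1..28")
  if (length(mm)) {
    pos <- GenomicRanges::start(mm)
    ok <- tapply(pos, chrom, function(p) all(diff(p) > 0))
    if (!all(unlist(ok)))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
    if (any(order(chrom, pos) != seq_along(pos)))
      msg <- c(msg, "markers must be sorted by (chromosome, position)")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("id", "breed") %in% colnames(cd)))
    msg <- c(msg, "colData must carry id and breed")
  else {
    if (anyDuplicated(cd$id)) msg <- c(msg, "sample ids must be unique")
    if (anyNA(cd$breed) || any(cd$breed == ""))
      msg <- c(msg, "every sample needs a breed label")
  }
  if (length(msg)) msg else TRUE
}

setValidity("GenotypeDataset", .validGenotypeDataset)

#' Construct a GenotypeDataset
#'
#' @param calls integer matrix, markers x samples, codes 0/1/2/NA.
#' @param markers data.frame with columns \code{id}, \code{chrom} (integer
#'   1..28), \code{pos_bp} (1-based), \code{allele_a}, \code{allele_b}.
#'   Markers are re-sorted by (chrom, pos_bp) and \code{calls} rows are
#'   permuted to match.
#' @param samples data.frame with columns \code{id}, \code{breed} and
#'   optionally \code{sex} (one of \code{"M"}, \code{"F"},
#'   \code{"unknown"}).
#' @return A [GenotypeDataset-class] object.
#' @examples
#' ds <- GenotypeDataset(
#'   calls = matrix(c(0L, 1L, 2L, NA), nrow = 2),
#'   markers = data.frame(id = c("s1", "s2"), chrom = 1L,
#'                        pos_bp = c(100L, 200L),
#'                        allele_a = "A", allele_b = "C"),
#'   samples = data.frame(id = c("i1", "i2"), breed = "ANC"))
#' @export
GenotypeDataset <- function(calls, markers, samples) {
  stopifnot(is.matrix(calls))
  storage.mode(calls) <- "integer"
  markers$chrom <- as.integer(markers$chrom)
  markers$pos_bp <- as.integer(markers$pos_bp)
  if (!"sex" %in% names(samples)) samples$sex <- "unknown"
  ord <- order(markers$chrom, markers$pos_bp)
  markers <- markers[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(markers$chrom),
    ranges = IRanges::IRanges(start = markers$pos_bp,
                              width = 1L),
    id = as.character(markers$id),
    allele_a = as.character(markers$allele_a),
    allele_b = as.character(markers$allele_b))
  names(gr) <- as.character(markers$id)
  cd <- S4Vectors::DataFrame(id = as.character(samples$id),
                             breed = as.character(samples$breed),
                             sex = as.character(samples$sex),
                             row.names = as.character(samples$id))
  dimnames(calls) <- list(as.character(markers$id), as.character(samples$id))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), rowRanges = gr, colData = cd)
  methods::new("GenotypeDataset", se)
}

#' QC report for a genotype dataset
#'
#' Records what [applyQC()] removed and why: marker/sample counts before and
#' after, the ids removed by each rule, the thresholds used and the filter
#' order.
#'
#' @seealso [applyQC()], [writeQCReport()]
#' @export
setClass("QCReport", representation(
  nMarkersIn = "integer", nMarkersOut = "integer",
  nSamplesIn = "integer", nSamplesOut = "integer",
  removedMarkersCallrate = "character",
  removedMarkersMaf = "character",
  removedSamples = "character",
  thresholds = "numeric",
  filterOrder = "character"))

setValidity("QCReport", function(object) {
  msg <- character()
  if (object@nSamplesOut !=
      object@nSamplesIn - length(object@removedSamples))
    msg <- c(msg, "sample counts do not balance")
  if (object@nMarkersOut != object@nMarkersIn -
      length(object@removedMarkersCallrate) -
      length(object@removedMarkersMaf))
    msg <- c(msg, "marker counts do not balance")
  if (length(msg)) msg else TRUE
})

#' ROH calling parameters
#'
#' The five run-level constraints plus the calling mode. Defaults are the
#' standard 600K-array settings: runs of at least 100 SNPs and 1 Mb, at most
#' one heterozygous and two missing calls, average density of at least one
#' SNP per 100 kb, and no gap between consecutive SNPs above 1000 kb.
#' \code{mode = "segment"} emits the deterministic longest-first selection
#' of constraint-satisfying windows; \code{mode = "window"} approximates the
#' classic sliding-window heuristic (\code{windowSnps} SNPs per window,
#' a SNP is in-run when at least \code{windowHitThreshold} of its covering
#' windows are homozygous).
#'
#' @param minLengthKb minimum run length, kb.
#' @param minSnps minimum number of SNPs in a run.
#' @param maxHet maximum heterozygous calls allowed in a run.
#' @param maxMissing maximum missing calls allowed in a run.
#' @param minDensityKbPerSnp maximum average spacing, kb per SNP.
#' @param maxGapKb maximum gap between consecutive SNPs in a run, kb.
#' @param mode \code{"segment"} or \code{"window"}.
#' @param windowSnps window size (SNPs) for window mode.
#' @param windowHitThreshold minimum homozygous-window fraction for a SNP
#'   to be in-run (window mode).
#' @return An object of class \code{ROHParams}.
#' @examples
#' rohParams(minSnps = 50, minLengthKb = 500)
#' @export
rohParams <- function(minLengthKb = 1000, minSnps = 100, maxHet = 1,
                      maxMissing = 2, minDensityKbPerSnp = 100,
                      maxGapKb = 1000, mode = c("segment", "window"),
                      windowSnps = 50, windowHitThreshold = 0.05) {
  mode <- match.arg(mode)
  methods::new("ROHParams",
               minLengthKb = as.numeric(minLengthKb),
               minSnps = as.integer(minSnps),
               maxHet = as.integer(maxHet),
               maxMissing = as.integer(maxMissing),
               minDensityKbPerSnp = as.numeric(minDensityKbPerSnp),
               maxGapKb = as.numeric(maxGapKb),
               mode = mode,
               windowSnps = as.integer(windowSnps),
               windowHitThreshold = as.numeric(windowHitThreshold))
}

#' @rdname rohParams
#' @export
setClass("ROHParams", representation(
  minLengthKb = "numeric", minSnps = "integer", maxHet = "integer",
  maxMissing = "integer", minDensityKbPerSnp = "numeric",
  maxGapKb = "numeric", mode = "character", windowSnps = "integer",
  windowHitThreshold = "numeric"))

setValidity("ROHParams", function(object) {
  msg <- character()
  if (object@minLengthKb <= 0 || object@minSnps <= 0 ||
      object@minDensityKbPerSnp <= 0 || object@maxGapKb <= 0 ||
      object@windowSnps <= 0)
    msg <- c(msg, "thresholds must be positive")
  if (object@maxHet < 0 || object@maxMissing < 0)
    msg <- c(msg, "het/missing allowances must be non-negative")
  if (!object@mode %in% c("segment", "window"))
    msg <- c(msg, "mode must be 'segment' or 'window'")
  if (object@windowHitThreshold <= 0 || object@windowHitThreshold > 1)
    msg <- c(msg, "windowHitThreshold must be in (0, 1]")
  if (length(msg)) msg else TRUE
})
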