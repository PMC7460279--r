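# Accessors and methods for GenotypeDataset.

#' Genotype call matrix
#'
#' @param x a [GenotypeDataset-class].
#' @return Integer matrix, markers x samples; codes 0/1/2/NA.
#' @export
genotypeCalls <- function(x) {
  stopifnot(methods::is(x, "GenotypeDataset"))
  SummarizedExperiment::assay(x, "calls")
}

#' Marker map as a data.frame
#'
#' @param x a [GenotypeDataset-class].
#' @return data.frame with id, chrom, pos_bp, allele_a, allele_b, in map
#'   order.
#' @export
markerMap <- function(x) {
  stopifnot(methods::is(x, "GenotypeDataset"))
  gr <- SummarizedExperiment::rowRanges(x)
  data.frame(id = S4Vectors::mcols(gr)$id,
             chrom = as.integer(as.character(GenomicRanges::seqnames(gr))),
             pos_bp = GenomicRanges::start(gr),
             allele_a = S4Vectors::mcols(gr)$allele_a,
             allele_b = S4Vectors::mcols(gr)$allele_b,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sample table as a data.frame
#'
#' @param x a [GenotypeDataset-class].
#' @return data.frame with id, breed, sex.
#' @export
sampleInfo <- function(x) {
  stopifnot(methods::is(x, "GenotypeDataset"))
  cd <- SummarizedExperiment::colData(x)
  data.frame(id = cd$id, breed = cd$breed, sex = cd$sex,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Breed label per sample / number of samples and markers
#'
#' @param x a [GenotypeDataset-class].
#' @return \code{breedLabels}: character vector of per-sample breed labels;
#'   \code{nSamples}/\code{nMarkers}: integer counts.
#' @export
breedLabels <- function(x) sampleInfo(x)$breed

#' @rdname breedLabels
#' @export
nSamples <- function(x) ncol(x)

#' @rdname breedLabels
#' @export
nMarkers <- function(x) nrow(x)

setMethod("show", "GenotypeDataset", function(object) {
  mm <- markerMap(object)
  br <- breedLabels(object)
  cat("GenotypeDataset:", nrow(mm), "markers x", ncol(object), "samples\n")
  cat("  chromosomes:", paste(sort(unique(mm$chrom)), collapse = " "), "\n")
  cat("  breeds (", length(unique(br)), "): ",
      paste(utils::head(sort(unique(br)), 8), collapse = " "),
      if (length(unique(br)) > 8) " ..." else "", "\n", sep = "")
  miss <- mean(is.na(genotypeCalls(object)))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
})

#' Subset a dataset by sample and/or marker ids
#'
#' Order of the retained samples/markers follows the dataset (map order),
#' not the order of the id vectors.
#'
#' @param ds a [GenotypeDataset-class].
#' @param sampleIds,markerIds character vectors of ids to keep; \code{NULL}
#'   keeps all.
#' @param allowEmpty keep going when the subset has zero markers or samples
#'   (default: error).
#' @return The subset [GenotypeDataset-class].
#' @export
subsetGenotypes <- function(ds, sampleIds = NULL, markerIds = NULL,
                            allowEmpty = FALSE) {
  stopifnot(methods::is(ds, "GenotypeDataset"))
  si <- sampleInfo(ds)
  mm <- markerMap(ds)
  keepS <- rep(TRUE, nrow(si))
  keepM <- rep(TRUE, nrow(mm))
  if (!is.null(sampleIds)) {
    unknown <- setdiff(sampleIds, si$id)
    if (length(unknown))
      stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
    keepS <- si$id %in% sampleIds
  }
  if (!is.null(markerIds)) {
    unknown <- setdiff(markerIds, mm$id)
    if (length(unknown))
      stop("unknown marker id(s): ", paste(unknown, collapse = ", "))
    keepM <- mm$id %in% markerIds
  }
  if (!allowEmpty && (!any(keepS) || !any(keepM)))
    stop("subset would be empty; use allowEmpty = TRUE to permit this")
  out <- ds[keepM, keepS]
  methods::new("GenotypeDataset", out)
}

#' Breed subsets
#'
#' @param ds a [GenotypeDataset-class].
#' @param breed a breed label present in the dataset.
#' @return The [GenotypeDataset-class] restricted to that breed.
#' @export
subsetBreed <- function(ds, breed) {
  si <- sampleInfo(ds)
  if (!breed %in% si$breed) stop("breed not present: ", breed)
  subsetGenotypes(ds, sampleIds = si$id[si$breed == breed])
}

# Total map length covered per chromosome, in kb. Used as the F_ROH
# denominator when the map does not span the standard chicken autosomes.
.mapLengthKb <- function(ds) {
  mm <- markerMap(ds)
  spans <- tapply(mm$pos_bp, mm$chrom, function(p) max(p) - min(p))
  sum(spans) / 1000
}
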