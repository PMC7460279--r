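# Marker/sample quality control: call rate, missingness, allele
# frequencies, and the three-rule filter (sample missingness, marker call
# rate, MAF). Items exactly at a threshold are kept: removal uses strict
# inequalities (call rate strictly below, missingness strictly above,
# MAF strictly below).

#' Per-marker call rate
#'
#' @param ds a [GenotypeDataset-class].
#' @return Named numeric vector in \[0, 1\]: non-missing calls divided by
#'   the number of samples, per marker.
#' @export
snpCallRate <- function(ds) {
  calls <- genotypeCalls(ds)
  if (ncol(calls) < 1L) stop("dataset has no samples")
  rowMeans(!is.na(calls))
}

#' Per-sample missingness
#'
#' @param ds a [GenotypeDataset-class].
#' @return Named numeric vector in \[0, 1\]: missing calls divided by the
#'   number of markers, per sample.
#' @export
sampleMissingness <- function(ds) {
  calls <- genotypeCalls(ds)
  if (nrow(calls) < 1L) stop("dataset has no markers")
  colMeans(is.na(calls))
}

#' Per-marker allele-B frequency
#'
#' Frequency of \code{allele_b} (genotype code 2 counts twice, code 1
#' once) over non-missing calls, optionally within one breed. Markers with
#' no non-missing calls are \code{NaN} (undefined).
#'
#' @param ds a [GenotypeDataset-class].
#' @param group optional breed label restricting the cohort.
#' @return Named numeric vector of frequencies in \[0, 1\] (NaN where
#'   undefined).
#' @export
alleleFrequencies <- function(ds, group = NULL) {
  if (!is.null(group)) ds <- subsetBreed(ds, group)
  calls <- genotypeCalls(ds)
  nn <- rowSums(!is.na(calls))
  rowSums(calls, na.rm = TRUE) / (2 * nn)
}

# frequencies + non-missing counts from a raw calls matrix
.freqCounts <- function(calls) {
  nn <- rowSums(!is.na(calls))
  p <- rowSums(calls, na.rm = TRUE) / (2 * nn)
  list(p = p, n = nn)
}

#' Apply the three-rule QC filter
#'
#' Removal order is fixed and recorded in the report: (1) samples with
#' missingness strictly above \code{maxSampleMissing}; (2) markers with
#' call rate strictly below \code{minCallRate}, computed on the surviving
#' samples; (3) markers with minor allele frequency strictly below
#' \code{minMaf}, computed on the surviving samples pooled across breeds.
#' Markers with no non-missing calls are removed by the call-rate rule.
#'
#' @param ds a [GenotypeDataset-class].
#' @param minCallRate minimum marker call rate (default 0.95).
#' @param minMaf minimum pooled minor allele frequency (default 0.05).
#' @param maxSampleMissing maximum per-sample missingness (default 0.10).
#' @return \code{list(dataset = <filtered GenotypeDataset>,
#'   report = <QCReport>)}.
#' @examples
#' fx <- makeStudyFixture(seed = 1, breedSubset = c("ANC", "SIC"),
#'                        snpsPerChrom = 200, nChrom = 2)
#' res <- applyQC(fx$dataset)
#' res$report
#' @export
applyQC <- function(ds, minCallRate = 0.95, minMaf = 0.05,
                    maxSampleMissing = 0.10) {
  stopifnot(minCallRate >= 0, minCallRate <= 1,
            minMaf >= 0, minMaf <= 1,
            maxSampleMissing >= 0, maxSampleMissing <= 1)
  si <- sampleInfo(ds)
  mm <- markerMap(ds)

  miss <- sampleMissingness(ds)
  dropS <- si$id[miss > maxSampleMissing]
  if (length(dropS) == nrow(si)) stop("empty after QC: all samples removed")
  ds1 <- subsetGenotypes(ds, sampleIds = setdiff(si$id, dropS))

  cr <- snpCallRate(ds1)
  mm1 <- markerMap(ds1)
  dropCR <- mm1$id[cr < minCallRate]
  if (length(dropCR) == nrow(mm1))
    stop("empty after QC: all markers removed by call rate")
  ds2 <- subsetGenotypes(ds1, markerIds = setdiff(mm1$id, dropCR))

  p <- alleleFrequencies(ds2)
  maf <- pmin(p, 1 - p)
  mm2 <- markerMap(ds2)
  dropMAF <- mm2$id[!is.nan(maf) & maf < minMaf]
  if (length(dropMAF) == nrow(mm2))
    stop("empty after QC: all markers removed by MAF")
  ds3 <- subsetGenotypes(ds2, markerIds = setdiff(mm2$id, dropMAF))

  report <- methods::new("QCReport",
    nMarkersIn = nrow(mm), nMarkersOut = nMarkers(ds3),
    nSamplesIn = nrow(si), nSamplesOut = nSamples(ds3),
    removedMarkersCallrate = as.character(dropCR),
    removedMarkersMaf = as.character(dropMAF),
    removedSamples = as.character(dropS),
    thresholds = c(min_call_rate = minCallRate, min_maf = minMaf,
                   max_sample_missing = maxSampleMissing),
    filterOrder = c("sample_missingness", "marker_call_rate", "marker_maf"))
  list(dataset = ds3, report = report)
}

setMethod("show", "QCReport", function(object) {
  th <- object@thresholds
  cat("QC report (filter order: ",
      paste(object@filterOrder, collapse = " -> "), ")\n", sep = "")
  cat(sprintf("  samples: %d -> %d (removed %d, missingness > %g)\n",
              object@nSamplesIn, object@nSamplesOut,
              length(object@removedSamples), th["max_sample_missing"]))
  cat(sprintf("  markers: %d -> %d\n", object@nMarkersIn,
              object@nMarkersOut))
  cat(sprintf("    removed by call rate < %g: %d\n", th["min_call_rate"],
              length(object@removedMarkersCallrate)))
  cat(sprintf("    removed by MAF < %g: %d\n", th["min_maf"],
              length(object@removedMarkersMaf)))
})

#' Write a QC report
#'
#' @param report a [QCReport-class].
#' @param path output path.
#' @param format \code{"text"} (human-readable) or \code{"json"}.
#' @return Invisibly, the path.
#' @export
writeQCReport <- function(report, path, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "text") {
    writeLines(utils::capture.output(show(report)), path, sep = "\n")
  } else {
    x <- list(
      n_samples_in = report@nSamplesIn, n_samples_out = report@nSamplesOut,
      n_markers_in = report@nMarkersIn, n_markers_out = report@nMarkersOut,
      removed_samples = report@removedSamples,
      removed_markers_callrate = report@removedMarkersCallrate,
      removed_markers_maf = report@removedMarkersMaf,
      thresholds = as.list(report@thresholds),
      filter_order = report@filterOrder)
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
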