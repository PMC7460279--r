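# Runs-of-homozygosity detection and genomic inbreeding (F_ROH).
#
# Segment mode (default) emits the deterministic longest-first selection of
# non-overlapping windows satisfying all five run constraints; window mode
# approximates the classic sliding-window heuristic. Segment coordinates
# are the positions of the first and last SNP of the run; length_bp is
# end_bp - start_bp. F_ROH divides the summed run length by the array-
# covered autosomal genome length (944,270 kb for the standard chicken
# 600K map).

#' Chicken autosomal genome length covered by the 600K array, in kb
#' @export
CHICKEN_AUTOSOME_KB <- 944270

.ROH_COLS <- c("sample_id", "breed", "chrom", "start_bp", "end_bp",
               "n_snps", "n_het", "n_missing", "length_bp")

.emptyRoh <- function() {
  data.frame(sample_id = character(), breed = character(),
             chrom = integer(), start_bp = integer(), end_bp = integer(),
             n_snps = integer(), n_het = integer(), n_missing = integer(),
             length_bp = integer(), stringsAsFactors = FALSE)
}

#' Call ROH for one individual on one chromosome
#'
#' @param calls integer genotype codes (0/1/2/NA) ordered along the
#'   chromosome.
#' @param positions strictly increasing 1-based bp positions, same length.
#' @param params an \code{ROHParams} object, see [rohParams()].
#' @return data.frame with start_idx, end_idx (1-based SNP indices),
#'   start_bp, end_bp, n_snps, n_het, n_missing, length_bp, sorted by
#'   start.
#' @examples
#' pos <- seq(1e6, 3e6, length.out = 150)
#' callRohIndividual(rep(0L, 150), as.integer(pos),
#'                   rohParams(minSnps = 100))
#' @export
callRohIndividual <- function(calls, positions, params = rohParams()) {
  stopifnot(methods::is(params, "ROHParams"))
  methods::validObject(params)
  positions <- as.integer(positions)
  calls <- as.integer(calls)
  if (length(calls) != length(positions))
    stop("calls and positions differ in length")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (params@mode == "segment") {
    res <- .roh_segment_chrom(calls, positions,
                              params@minSnps, params@minLengthKb * 1000,
                              params@maxHet, params@maxMissing,
                              params@minDensityKbPerSnp * 1000,
                              params@maxGapKb * 1000)
  } else {
    res <- .roh_window_chrom(calls, positions,
                             params@windowSnps, params@windowHitThreshold,
                             params@minSnps, params@minLengthKb * 1000,
                             params@maxHet, params@maxMissing,
                             params@minDensityKbPerSnp * 1000,
                             params@maxGapKb * 1000)
  }
  res$start_bp <- positions[res$start_idx]
  res$end_bp <- positions[res$end_idx]
  res$length_bp <- res$end_bp - res$start_bp
  res[, c("start_idx", "end_idx", "start_bp", "end_bp", "n_snps",
          "n_het", "n_missing", "length_bp")]
}

#' Call ROH across a whole dataset
#'
#' Applies [callRohIndividual()] to every sample and chromosome.
#'
#' @param ds a [GenotypeDataset-class] (typically after [applyQC()]).
#' @param params an \code{ROHParams} object, see [rohParams()].
#' @return data.frame with one row per run: sample_id, breed, chrom,
#'   start_bp, end_bp, n_snps, n_het, n_missing, length_bp; ordered by
#'   (sample, chrom, start).
#' @export
callRoh <- function(ds, params = rohParams()) {
  mm <- markerMap(ds)
  si <- sampleInfo(ds)
  calls <- genotypeCalls(ds)
  chroms <- sort(unique(mm$chrom))
  out <- vector("list", length(chroms) * nrow(si))
  k <- 0L
  byChrom <- split(seq_len(nrow(mm)), mm$chrom)
  for (i in seq_len(nrow(si))) {
    for (ch in chroms) {
      idx <- byChrom[[as.character(ch)]]
      segs <- callRohIndividual(calls[idx, i], mm$pos_bp[idx], params)
      if (nrow(segs)) {
        k <- k + 1L
        out[[k]] <- data.frame(
          sample_id = si$id[i], breed = si$breed[i], chrom = ch,
          start_bp = segs$start_bp, end_bp = segs$end_bp,
          n_snps = segs$n_snps, n_het = segs$n_het,
          n_missing = segs$n_missing, length_bp = segs$length_bp,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(.emptyRoh())
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(match(res$sample_id, si$id), res$chrom, res$start_bp), ]
  rownames(res) <- NULL
  res
}

#' Per-individual genomic inbreeding from ROH (F_ROH)
#'
#' F_ROH = total ROH length (kb) / \code{genomeLengthKb}. Samples without
#' any run get F_ROH = 0. Also returns the Mb summed per run-length class:
#' (1,5], (5,10], (10,15], (15,20], (20,25], (25,30] and >30 Mb.
#'
#' @param segments ROH table from [callRoh()].
#' @param sampleIds character vector defining the sample universe (samples
#'   with no segments are reported with zeroes). Defaults to the samples
#'   present in \code{segments}.
#' @param genomeLengthKb denominator, kb; default the chicken autosomal
#'   array length 944,270 kb. Use [genomeLengthKb()] to derive it from a
#'   non-standard map.
#' @return data.frame: sample_id, froh, sum_roh_kb, n_roh, and class_1 ..
#'   class_7 (Mb per length class).
#' @export
frohRecords <- function(segments, sampleIds = NULL,
                        genomeLengthKb = CHICKEN_AUTOSOME_KB) {
  stopifnot(genomeLengthKb > 0)
  if (is.null(sampleIds)) sampleIds <- unique(segments$sample_id)
  if (nrow(segments) &&
      any(segments$length_bp / 1000 > genomeLengthKb))
    stop("segment longer than the genome length")
  breaks <- c(-Inf, 5, 10, 15, 20, 25, 30, Inf)
  rows <- lapply(sampleIds, function(s) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    mb <- seg$length_bp / 1e6
    cls <- as.integer(cut(mb, breaks = breaks, right = TRUE))
    classSums <- vapply(1:7, function(k) sum(mb[cls == k]), numeric(1))
    sumKb <- sum(seg$length_bp) / 1000
    out <- data.frame(sample_id = s, froh = sumKb / genomeLengthKb,
                      sum_roh_kb = sumKb, n_roh = nrow(seg),
                      stringsAsFactors = FALSE)
    out[paste0("class_", 1:7)] <- as.list(classSums)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' F_ROH denominator from a marker map
#'
#' Returns 944,270 kb when the map covers the standard chicken autosomes
#' 1--28; otherwise the summed per-chromosome span (max - min position)
#' in kb, with a message.
#'
#' @param ds a [GenotypeDataset-class].
#' @return Length in kb.
#' @export
genomeLengthKb <- function(ds) {
  mm <- markerMap(ds)
  if (setequal(unique(mm$chrom), 1:28)) return(CHICKEN_AUTOSOME_KB)
  g <- .mapLengthKb(ds)
  message("map does not cover chicken autosomes 1-28; using summed map ",
          "span ", round(g), " kb as the F_ROH denominator")
  g
}

#' Mean per-breed ROH length-class sums
#'
#' Per breed and length class, the mean over animals of the summed Mb in
#' that class; animals without runs in a class contribute 0.
#'
#' @param segments ROH table from [callRoh()].
#' @param groups named character vector mapping sample_id to breed (e.g.
#'   from [sampleInfo()]); every sample in it is averaged over, including
#'   samples with no runs.
#' @return data.frame: breed, class_1 .. class_7 (mean Mb).
#' @export
lengthClassSums <- function(segments, groups) {
  fr <- frohRecords(segments, sampleIds = names(groups),
                    genomeLengthKb = CHICKEN_AUTOSOME_KB)
  cls <- fr[paste0("class_", 1:7)]
  agg <- stats::aggregate(cls, by = list(breed = groups[fr$sample_id]),
                          FUN = mean)
  agg[order(agg$breed), , drop = FALSE]
}

#' Per-breed ROH summary
#'
#' Breed-level means and SDs of F_ROH and of the per-animal run count,
#' plus the total number of runs per breed.
#'
#' @param froh data.frame from [frohRecords()].
#' @param groups named character vector mapping sample_id to breed; every
#'   sample must be present.
#' @return data.frame: breed, froh_mean, froh_sd, mean_n_roh, sd_n_roh,
#'   total_n_roh.
#' @export
rohBreedSummary <- function(froh, groups) {
  if (!all(froh$sample_id %in% names(groups)))
    stop("every sample must have a breed in 'groups'")
  b <- groups[froh$sample_id]
  res <- do.call(rbind, lapply(sort(unique(b)), function(br) {
    x <- froh[b == br, , drop = FALSE]
    data.frame(breed = br,
               froh_mean = mean(x$froh), froh_sd = stats::sd(x$froh),
               mean_n_roh = mean(x$n_roh), sd_n_roh = stats::sd(x$n_roh),
               total_n_roh = sum(x$n_roh), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Write ROH calls as TSV or BED
#'
#' The BED form converts the closed 1-based SNP span to 0-based half-open
#' coordinates (start-1, end); the name field is the sample id.
#'
#' @param segments ROH table from [callRoh()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeRohTsv <- function(segments, path) {
  utils::write.table(segments[, .ROH_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname writeRohTsv
#' @export
writeRohBed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start_bp - 1L,
                    end = segments$end_bp,
                    name = segments$sample_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
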