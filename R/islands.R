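# Per-SNP ROH incidence and autozygosity-island detection.
#
# Incidence counts, for each mapped SNP, the animals whose ROH cover it
# (closed bp intervals) divided by the number of animals. Islands are runs
# of SNPs whose incidence reaches the empirical upper quantile of the
# track; island coordinates are member-SNP positions and length_bp is
# end - start, matching the ROH convention.

#' Per-SNP ROH incidence track
#'
#' A marker is counted for an animal when one of that animal's runs is on
#' the same chromosome and start_bp <= pos <= end_bp (closed interval);
#' an animal can contribute at most once per marker.
#'
#' @param segments ROH table from [callRoh()].
#' @param markers marker map data.frame (see [markerMap()]).
#' @param nAnimals total number of animals the proportion is computed
#'   over.
#' @return data.frame: id, chrom, pos_bp, count, proportion.
#' @export
snpIncidence <- function(segments, markers, nAnimals) {
  if (nAnimals <= 0) stop("nAnimals must be positive")
  count <- integer(nrow(markers))
  if (nrow(segments)) {
    mgr <- GenomicRanges::GRanges(
      seqnames = as.character(markers$chrom),
      ranges = IRanges::IRanges(start = markers$pos_bp, width = 1L))
    sgr <- GenomicRanges::GRanges(
      seqnames = as.character(segments$chrom),
      ranges = IRanges::IRanges(start = segments$start_bp,
                                end = segments$end_bp))
    hits <- GenomicRanges::findOverlaps(mgr, sgr)
    pair <- unique(data.frame(
      m = S4Vectors::queryHits(hits),
      a = segments$sample_id[S4Vectors::subjectHits(hits)]))
    tab <- table(factor(pair$m, levels = seq_len(nrow(markers))))
    count <- as.integer(tab)
  }
  data.frame(id = markers$id, chrom = markers$chrom,
             pos_bp = markers$pos_bp, count = count,
             proportion = count / nAnimals, stringsAsFactors = FALSE)
}

#' Detect autozygosity islands from an incidence track
#'
#' Selects the SNPs whose incidence reaches the empirical
#' \code{1 - topFraction} quantile of the whole track (all mapped SNPs,
#' zero-incidence ones included) and merges selected SNPs on the same
#' chromosome into islands while consecutive selected SNPs are at most
#' \code{mergeGapKb} apart.
#'
#' @param track incidence track from [snpIncidence()].
#' @param topFraction upper tail fraction defining hotspot SNPs
#'   (default 0.001, i.e. above the 99.9th percentile).
#' @param mergeGapKb maximum bp gap (kb) between consecutive selected
#'   SNPs within one island (default 1000, mirroring the ROH gap rule).
#' @param force proceed even when all proportions are equal (degenerate
#'   track); default FALSE (error).
#' @return data.frame: chrom, start_bp, end_bp, n_snps, length_bp,
#'   marker_ids (comma-separated member SNP ids), plus the selection
#'   threshold as attribute \code{"threshold"}.
#' @export
detectIslands <- function(track, topFraction = 0.001, mergeGapKb = 1000,
                          force = FALSE) {
  stopifnot(topFraction > 0, topFraction < 1)
  if (length(unique(track$proportion)) == 1L && !force)
    stop("degenerate track: all proportions equal; use force = TRUE")
  thr <- stats::quantile(track$proportion, probs = 1 - topFraction,
                         names = FALSE)
  sel <- track[track$proportion >= thr, , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$pos_bp), , drop = FALSE]
  out <- list()
  for (ch in unique(sel$chrom)) {
    s <- sel[sel$chrom == ch, , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(s$pos_bp) > mergeGapKb * 1000)))
    for (g in unique(grp)) {
      sg <- s[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = min(sg$pos_bp), end_bp = max(sg$pos_bp),
        n_snps = nrow(sg), length_bp = max(sg$pos_bp) - min(sg$pos_bp),
        marker_ids = paste(sg$id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = integer(), start_bp = integer(),
               end_bp = integer(), n_snps = integer(),
               length_bp = integer(), marker_ids = character(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "threshold") <- thr
  res
}

#' Read an interval feature file (BED or GFF)
#'
#' BED intervals are converted to 1-based closed coordinates; GFF features
#' use the \code{Name} attribute (falling back to \code{ID}, then type) as
#' the label.
#'
#' @param path path to a .bed, .gff/.gff3/.gtf file.
#' @return data.frame: chrom, start_bp, end_bp, name.
#' @export
readFeatureFile <- function(path) {
  stopifnot(file.exists(path))
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e)
                   stop("malformed feature file '", path, "': ",
                        conditionMessage(e)))
  mc <- S4Vectors::mcols(gr)
  name <- if ("Name" %in% colnames(mc) && !all(is.na(mc$Name)))
    as.character(mc$Name)
  else if ("name" %in% colnames(mc)) as.character(mc$name)
  else if ("ID" %in% colnames(mc)) as.character(mc$ID)
  else if ("type" %in% colnames(mc)) as.character(mc$type)
  else paste0("feature_", seq_along(gr))
  data.frame(chrom = as.integer(as.character(GenomicRanges::seqnames(gr))),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr),
             name = name, stringsAsFactors = FALSE)
}

#' Annotate islands against interval features
#'
#' A feature is reported for an island when their closed bp intervals
#' intersect on the same chromosome (touching endpoints count). Output
#' order follows the island table, features in file order.
#'
#' @param islands island table from [detectIslands()].
#' @param features data.frame with chrom, start_bp, end_bp, name, or a
#'   path accepted by [readFeatureFile()].
#' @return data.frame: island_idx, chrom, start_bp, end_bp, feature
#'   columns for every intersecting feature.
#' @export
overlapIntervals <- function(islands, features) {
  if (is.character(features)) features <- readFeatureFile(features)
  stopifnot(all(c("chrom", "start_bp", "end_bp", "name") %in%
                names(features)))
  if (!nrow(islands) || !nrow(features))
    return(data.frame(island_idx = integer(), chrom = integer(),
                      start_bp = integer(), end_bp = integer(),
                      feature = character(), feature_start = integer(),
                      feature_end = integer(), stringsAsFactors = FALSE))
  igr <- GenomicRanges::GRanges(
    seqnames = as.character(islands$chrom),
    ranges = IRanges::IRanges(start = islands$start_bp,
                              end = islands$end_bp))
  fgr <- GenomicRanges::GRanges(
    seqnames = as.character(features$chrom),
    ranges = IRanges::IRanges(start = features$start_bp,
                              end = features$end_bp))
  hits <- GenomicRanges::findOverlaps(igr, fgr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  res <- data.frame(island_idx = qi,
                    chrom = islands$chrom[qi],
                    start_bp = islands$start_bp[qi],
                    end_bp = islands$end_bp[qi],
                    feature = features$name[si],
                    feature_start = features$start_bp[si],
                    feature_end = features$end_bp[si],
                    stringsAsFactors = FALSE)
  res[order(res$island_idx, si), , drop = FALSE]
}

#' Write islands / incidence track
#'
#' @param islands island table from [detectIslands()].
#' @param track incidence track from [snpIncidence()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeIslandsTsv <- function(islands, path) {
  utils::write.table(islands, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname writeIslandsTsv
#' @export
writeIslandsBed <- function(islands, path) {
  bed <- data.frame(chrom = islands$chrom,
                    start = islands$start_bp - 1L,
                    end = islands$end_bp,
                    name = paste0("island_", seq_len(nrow(islands))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname writeIslandsTsv
#' @export
writeIncidenceTsv <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
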