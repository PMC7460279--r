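# End-to-end orchestration: QC -> diversity -> structure -> ROH ->
# incidence/islands, written as flat TSV stage outputs plus a JSON run
# manifest, so each stage is independently re-runnable and two runs with
# the same config and inputs are byte-identical.

#' Assemble and validate a pipeline configuration
#'
#' @param pedPath,mapPath input PED/MAP paths (alternatively pass a
#'   dataset directly to [runPipeline()]).
#' @param outDir output directory (created if absent).
#' @param minCallRate,minMaf,maxSampleMissing QC thresholds, see
#'   [applyQC()].
#' @param roh an \code{ROHParams} object, see [rohParams()].
#' @param topFraction,mergeGapKb island parameters, see
#'   [detectIslands()].
#' @param genomeLengthKb F_ROH denominator; \code{NULL} derives it from
#'   the map via [genomeLengthKb()].
#' @param featurePath optional BED/GFF file for island annotation.
#' @param mdsComponents components for the MDS coordinate tables.
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic).
#' @return A validated config list of class \code{"rohdiv_config"}.
#' @export
pipelineConfig <- function(pedPath = NULL, mapPath = NULL, outDir,
                           minCallRate = 0.95, minMaf = 0.05,
                           maxSampleMissing = 0.10, roh = rohParams(),
                           topFraction = 0.001, mergeGapKb = 1000,
                           genomeLengthKb = NULL, featurePath = NULL,
                           mdsComponents = 2, seed = 1) {
  stopifnot(methods::is(roh, "ROHParams"))
  methods::validObject(roh)
  stopifnot(minCallRate >= 0, minCallRate <= 1, minMaf >= 0, minMaf <= 1,
            maxSampleMissing >= 0, maxSampleMissing <= 1,
            topFraction > 0, topFraction < 1, mergeGapKb > 0,
            mdsComponents >= 1)
  structure(list(pedPath = pedPath, mapPath = mapPath, outDir = outDir,
                 minCallRate = minCallRate, minMaf = minMaf,
                 maxSampleMissing = maxSampleMissing, roh = roh,
                 topFraction = topFraction, mergeGapKb = mergeGapKb,
                 genomeLengthKb = genomeLengthKb,
                 featurePath = featurePath,
                 mdsComponents = mdsComponents, seed = seed),
            class = "rohdiv_config")
}

# atomic write: produce into a temp file in the same directory, then rename
.atomically <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), pattern = ".partial_")
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move output into ", path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Reads the genotypes (or takes a [GenotypeDataset-class] directly),
#' applies QC, and writes: the QC report (text + JSON), the per-breed
#' diversity table, ROH calls (TSV + BED) with per-individual F_ROH,
#' breed ROH summaries and length-class means, the per-SNP incidence
#' track, islands (TSV + BED, plus feature annotation when configured),
#' IBS and Reynolds distance matrices (TSV + PHYLIP), individual- and
#' breed-level neighbor-joining trees (Newick) and MDS coordinates, and a
#' \code{manifest.json} recording package version, parameters and input
#' checksums. All files are written atomically.
#'
#' @param config from [pipelineConfig()].
#' @param dataset optional [GenotypeDataset-class] overriding the config
#'   input paths.
#' @return Invisibly, the output directory.
#' @export
runPipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "rohdiv_config"))
  outDir <- config$outDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  checksums <- list()
  if (is.null(dataset)) {
    if (is.null(config$pedPath) || is.null(config$mapPath))
      stop("config has no input paths and no dataset was given")
    message("reading PED/MAP: ", config$pedPath)
    dataset <- readPedMap(config$pedPath, config$mapPath)
    checksums <- as.list(tools::md5sum(c(config$pedPath, config$mapPath)))
  }

  message("QC: call rate >= ", config$minCallRate, ", MAF >= ",
          config$minMaf, ", sample missingness <= ",
          config$maxSampleMissing)
  qc <- applyQC(dataset, config$minCallRate, config$minMaf,
                config$maxSampleMissing)
  ds <- qc$dataset
  .atomically(file.path(outDir, "qc_report.txt"),
              function(p) writeQCReport(qc$report, p, "text"))
  .atomically(file.path(outDir, "qc_report.json"),
              function(p) writeQCReport(qc$report, p, "json"))

  message("diversity indices for ", length(unique(breedLabels(ds))),
          " breeds")
  div <- diversityTable(ds)
  .atomically(file.path(outDir, "diversity_table.tsv"), function(p)
    utils::write.table(div, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n"))

  message("identity-by-state distances, MDS, neighbor joining")
  ibs <- ibsDistance(ds)
  .atomically(file.path(outDir, "ibs_distance.tsv"),
              function(p) writeDistanceTsv(ibs, p))
  mds <- classicalMDS(ibs, k = config$mdsComponents)
  si <- sampleInfo(ds)
  coords <- data.frame(id = rownames(mds$coordinates),
                       breed = si$breed[match(rownames(mds$coordinates),
                                              si$id)],
                       mds$coordinates, check.names = FALSE)
  .atomically(file.path(outDir, "mds_individuals.tsv"), function(p)
    utils::write.table(coords, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n"))
  bmds <- breedMds(ibs, stats::setNames(si$breed, si$id),
                   k = config$mdsComponents)
  .atomically(file.path(outDir, "mds_breeds.tsv"), function(p)
    utils::write.table(
      data.frame(breed = rownames(bmds$coordinates), bmds$coordinates,
                 check.names = FALSE),
      p, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n"))
  njInd <- neighborJoining(ibs)
  .atomically(file.path(outDir, "nj_individuals.nwk"),
              function(p) writeNewick(njInd, p))

  rey <- reynoldsDistance(ds)
  .atomically(file.path(outDir, "reynolds_distance.tsv"),
              function(p) writeDistanceTsv(rey, p))
  .atomically(file.path(outDir, "reynolds_distance.phy"),
              function(p) writeDistancePhylip(rey, p))
  if (nrow(rey) >= 3) {
    njBr <- neighborJoining(rey)
    .atomically(file.path(outDir, "nj_breeds.nwk"),
                function(p) writeNewick(njBr, p))
  }

  message("ROH calling (", config$roh@mode, " mode)")
  segs <- callRoh(ds, config$roh)
  .atomically(file.path(outDir, "roh_segments.tsv"),
              function(p) writeRohTsv(segs, p))
  .atomically(file.path(outDir, "roh_segments.bed"),
              function(p) writeRohBed(segs, p))
  gkb <- if (is.null(config$genomeLengthKb)) genomeLengthKb(ds) else
    config$genomeLengthKb
  froh <- frohRecords(segs, sampleIds = si$id, genomeLengthKb = gkb)
  froh$breed <- si$breed[match(froh$sample_id, si$id)]
  .atomically(file.path(outDir, "froh_individuals.tsv"), function(p)
    utils::write.table(froh, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n"))
  groups <- stats::setNames(si$breed, si$id)
  .atomically(file.path(outDir, "roh_breed_summary.tsv"), function(p)
    utils::write.table(rohBreedSummary(froh, groups), p, sep = "\t",
                       quote = FALSE, row.names = FALSE, eol = "\n"))
  .atomically(file.path(outDir, "roh_length_classes.tsv"), function(p)
    utils::write.table(lengthClassSums(segs, groups), p, sep = "\t",
                       quote = FALSE, row.names = FALSE, eol = "\n"))

  message("incidence track and islands (top fraction ",
          config$topFraction, ")")
  track <- snpIncidence(segs, markerMap(ds), nAnimals = nSamples(ds))
  .atomically(file.path(outDir, "incidence_track.tsv"),
              function(p) writeIncidenceTsv(track, p))
  islands <- tryCatch(
    detectIslands(track, config$topFraction, config$mergeGapKb),
    error = function(e) {
      warning("island detection skipped: ", conditionMessage(e))
      NULL
    })
  thr <- NA_real_
  if (!is.null(islands)) {
    thr <- attr(islands, "threshold")
    .atomically(file.path(outDir, "islands.tsv"),
                function(p) writeIslandsTsv(islands, p))
    .atomically(file.path(outDir, "islands.bed"),
                function(p) writeIslandsBed(islands, p))
    if (!is.null(config$featurePath)) {
      ann <- overlapIntervals(islands, config$featurePath)
      .atomically(file.path(outDir, "island_annotation.tsv"), function(p)
        utils::write.table(ann, p, sep = "\t", quote = FALSE,
                           row.names = FALSE, eol = "\n"))
    }
  }

  manifest <- list(
    package = "rohdiv",
    version = as.character(utils::packageVersion("rohdiv")),
    seed = config$seed,
    input_checksums = checksums,
    n_samples_in = nSamples(dataset), n_markers_in = nMarkers(dataset),
    n_samples = nSamples(ds), n_markers = nMarkers(ds),
    qc = list(min_call_rate = config$minCallRate,
              min_maf = config$minMaf,
              max_sample_missing = config$maxSampleMissing),
    roh = list(mode = config$roh@mode,
               min_length_kb = config$roh@minLengthKb,
               min_snps = config$roh@minSnps,
               max_het = config$roh@maxHet,
               max_missing = config$roh@maxMissing,
               min_density_kb_per_snp = config$roh@minDensityKbPerSnp,
               max_gap_kb = config$roh@maxGapKb),
    genome_length_kb = gkb,
    islands = list(top_fraction = config$topFraction,
                   merge_gap_kb = config$mergeGapKb,
                   threshold = thr),
    complete = TRUE)
  .atomically(file.path(outDir, "manifest.json"), function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA))
  invisible(outDir)
}

#' Draw the standard figures from pipeline outputs
#'
#' MDS scatter of individuals colored by breed, per-breed F_ROH boxplot,
#' and a Manhattan-style plot of the per-SNP ROH incidence with a
#' horizontal line at the island selection threshold. Missing input
#' tables skip the affected figure with a warning; plotting never touches
#' the tables.
#'
#' @param outDir a directory produced by [runPipeline()].
#' @param format image format, \code{"pdf"} (default) or \code{"png"}.
#' @return Invisibly, the paths of the figures written.
#' @export
plotOutputs <- function(outDir, format = c("pdf", "png")) {
  format <- match.arg(format)
  written <- character()
  dev <- function(path) {
    if (format == "pdf") grDevices::pdf(path, width = 8, height = 5)
    else grDevices::png(path, width = 960, height = 600)
  }
  fig <- function(name, tablePath, builder) {
    tp <- file.path(outDir, tablePath)
    if (!file.exists(tp)) {
      warning("skipping ", name, ": missing ", tablePath)
      return()
    }
    tab <- utils::read.table(tp, header = TRUE, sep = "\t",
                             check.names = FALSE)
    path <- file.path(outDir, paste0(name, ".", format))
    dev(path)
    on.exit(grDevices::dev.off())
    print(builder(tab))
    written <<- c(written, path)
  }
  fig("mds_plot", "mds_individuals.tsv", function(tab) {
    ggplot2::ggplot(tab, ggplot2::aes(x = C1, y = C2,
                                      color = breed)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::labs(title = "Identity-by-state MDS", x = "C1", y = "C2") +
      ggplot2::theme_minimal()
  })
  fig("froh_boxplot", "froh_individuals.tsv", function(tab) {
    ggplot2::ggplot(tab, ggplot2::aes(x = breed, y = froh)) +
      ggplot2::geom_boxplot(outlier.size = 0.6) +
      ggplot2::labs(title = "Genomic inbreeding (F_ROH) per breed",
                    x = NULL, y = expression(F[ROH])) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x =
                       ggplot2::element_text(angle = 90, vjust = 0.5))
  })
  manifestPath <- file.path(outDir, "manifest.json")
  thr <- if (file.exists(manifestPath))
    jsonlite::read_json(manifestPath)$islands$threshold else NULL
  fig("incidence_manhattan", "incidence_track.tsv", function(tab) {
    g <- ggplot2::ggplot(tab, ggplot2::aes(x = pos_bp / 1e6,
                                           y = proportion)) +
      ggplot2::geom_point(size = 0.4) +
      ggplot2::facet_grid(cols = ggplot2::vars(chrom),
                          scales = "free_x", space = "free_x") +
      ggplot2::labs(title = "Per-SNP ROH incidence", x = "position (Mb)",
                    y = "proportion of animals") +
      ggplot2::theme_minimal()
    if (!is.null(thr) && is.numeric(thr))
      g <- g + ggplot2::geom_hline(yintercept = thr, color = "blue")
    g
  })
  invisible(written)
}
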