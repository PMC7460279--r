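# PED/MAP and genotype-table input/output.
#
# PED: whitespace-delimited, 6 leading columns (family, id, father, mother,
# sex, phenotype) then two allele symbols per marker; the family column
# carries the breed label. MAP: 4 columns (chrom, id, cM, pos). Allele
# symbols are restricted to {A, C, G, T, 0, 1, 2}; "0" is the missing
# allele. allele_a of each marker is the first allele observed scanning
# samples in file order; monomorphic markers keep the "0" placeholder as
# allele_b. Half-calls (exactly one missing allele) become missing with a
# warning. All writers emit Unix line endings.

.VALID_ALLELES <- c("A", "C", "G", "T", "0", "1", "2")

#' Read genotypes from PED/MAP files
#'
#' @param pedPath,mapPath paths to the PED and MAP files.
#' @return A [GenotypeDataset-class]; markers re-sorted by (chrom, pos)
#'   with calls permuted accordingly.
#' @examples
#' ds <- makeStudyFixture(seed = 1, breedSubset = c("ANC", "SIC"),
#'                        snpsPerChrom = 50, nChrom = 2)$dataset
#' ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
#' writePedMap(ds, ped, map)
#' ds2 <- readPedMap(ped, map)
#' identical(genotypeCalls(ds), genotypeCalls(ds2))
#' @export
readPedMap <- function(pedPath, mapPath) {
  stopifnot(file.exists(pedPath), file.exists(mapPath))
  mapLines <- readLines(mapPath)
  mapLines <- mapLines[nzchar(trimws(mapLines))]
  mapF <- strsplit(trimws(mapLines), "[ \t]+")
  if (!length(mapF)) stop("MAP file has no markers")
  if (any(lengths(mapF) != 4L))
    stop("MAP line(s) without exactly 4 columns: line ",
         which(lengths(mapF) != 4L)[1])
  mapM <- do.call(rbind, mapF)
  ids <- mapM[, 2]
  if (anyDuplicated(ids))
    stop("duplicate marker id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chrom <- suppressWarnings(as.integer(mapM[, 1]))
  pos <- suppressWarnings(as.integer(mapM[, 4]))
  if (anyNA(chrom) || anyNA(pos))
    stop("non-numeric chromosome or position in MAP")
  m <- length(ids)

  pedLines <- readLines(pedPath)
  pedLines <- pedLines[nzchar(trimws(pedLines))]
  if (!length(pedLines)) stop("no samples: PED file is empty")
  pedF <- strsplit(trimws(pedLines), "[ \t]+")
  want <- 6L + 2L * m
  bad <- which(lengths(pedF) != want)
  if (length(bad))
    stop("PED line ", bad[1], " has ", lengths(pedF)[bad[1]],
         " fields, expected ", want)
  ped <- do.call(rbind, pedF)
  n <- nrow(ped)

  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  badSym <- matrix(!(a1 %in% .VALID_ALLELES) | !(a2 %in% .VALID_ALLELES),
                   nrow = n)
  if (any(badSym)) {
    w <- which(badSym, arr.ind = TRUE)[1, ]
    stop("invalid allele symbol '",
         c(a1[badSym], a2[badSym])[1],
         "' at PED line ", w[1], ", marker ", ids[w[2]])
  }
  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) {
    warning(sum(half), " half-call(s) treated as missing")
    a1[half] <- "0"
    a2[half] <- "0"
  }
  missing <- a1 == "0"  # both "0" now when either was

  # allele_a: first allele observed per marker in sample-major order
  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  alleleA <- character(m)
  alleleB <- character(m)
  for (j in seq_len(m)) {
    obs <- as.vector(rbind(a1[, j], a2[, j]))
    obs <- obs[obs != "0"]
    al <- unique(obs)
    if (length(al) > 2L)
      stop("marker ", ids[j], " has more than two alleles: ",
           paste(al, collapse = ", "))
    alleleA[j] <- if (length(al) >= 1L) al[1] else "0"
    alleleB[j] <- if (length(al) == 2L) al[2] else "0"
    cj <- (a1[, j] == alleleB[j]) + (a2[, j] == alleleB[j])
    cj[missing[, j]] <- NA_integer_
    calls[, j] <- as.integer(cj)
  }

  samples <- data.frame(id = ped[, 2], breed = ped[, 1],
                        sex = unname(c("1" = "M", "2" = "F")[ped[, 5]]),
                        stringsAsFactors = FALSE)
  samples$sex[is.na(samples$sex)] <- "unknown"
  if (anyDuplicated(samples$id))
    stop("duplicate sample id(s) in PED")
  markers <- data.frame(id = ids, chrom = chrom, pos_bp = pos,
                        allele_a = alleleA, allele_b = alleleB,
                        stringsAsFactors = FALSE)
  GenotypeDataset(t(calls), markers, samples)  # constructor sorts markers
}

#' Write genotypes to PED/MAP files
#'
#' @param ds a [GenotypeDataset-class].
#' @param pedPath,mapPath output paths.
#' @return Invisibly, the two paths.
#' @export
writePedMap <- function(ds, pedPath, mapPath) {
  mm <- markerMap(ds)
  si <- sampleInfo(ds)
  calls <- genotypeCalls(ds)
  mapLines <- paste(mm$chrom, mm$id, 0, mm$pos_bp, sep = "\t")
  sexCode <- c(M = "1", F = "2", unknown = "0")[si$sex]
  sexCode[is.na(sexCode)] <- "0"
  pedLines <- vapply(seq_len(nrow(si)), function(i) {
    g <- calls[, i]
    aa <- ifelse(is.na(g), "0",
          ifelse(g == 0L, mm$allele_a,
          ifelse(g == 1L, mm$allele_a, mm$allele_b)))
    ab <- ifelse(is.na(g), "0",
          ifelse(g == 0L, mm$allele_a, mm$allele_b))
    paste(si$breed[i], si$id[i], 0, 0, sexCode[i], -9,
          paste(as.vector(rbind(aa, ab)), collapse = " "))
  }, character(1))
  writeLines(mapLines, mapPath, sep = "\n")
  writeLines(pedLines, pedPath, sep = "\n")
  invisible(c(ped = pedPath, map = mapPath))
}

#' Read/write the simple genotype-table format
#'
#' A TSV with header \code{sample_id, breed, <marker ids...>} and one row
#' per sample carrying codes 0/1/2/NA. The table does not store marker
#' positions: pass \code{map} (a data.frame as returned by [markerMap()],
#' or a path readable by [readMarkerMap()]) to restore them; without a map,
#' markers are placed on chromosome 1 at 1 kb spacing as positional
#' placeholders.
#'
#' @param path file path.
#' @param map optional marker map (data.frame or path).
#' @return [readGenotypeTable()]: a [GenotypeDataset-class];
#'   [writeGenotypeTable()]: invisibly, the path.
#' @export
readGenotypeTable <- function(path, map = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("no samples: empty genotype table")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3L || header[1] != "sample_id" ||
      header[2] != "breed")
    stop("genotype table header must start with 'sample_id\tbreed'")
  if (length(lines) < 2L) stop("no samples: data section is empty")
  markerIds <- header[-(1:2)]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(header))
  if (length(bad))
    stop("row ", bad[1] + 1L, " has ", lengths(rows)[bad[1]],
         " fields, expected ", length(header))
  tab <- do.call(rbind, rows)
  codes <- tab[, -(1:2), drop = FALSE]
  okNA <- codes == "NA"
  valid <- okNA | codes %in% c("0", "1", "2")
  if (!all(valid)) {
    w <- which(!valid, arr.ind = TRUE)[1, ]
    stop("invalid genotype code '", codes[!valid][1], "' at row ",
         w[1] + 1L, ", column ", markerIds[w[2]])
  }
  calls <- suppressWarnings(matrix(as.integer(codes), nrow = nrow(tab)))
  if (is.null(map)) {
    markers <- data.frame(id = markerIds, chrom = 1L,
                          pos_bp = 1000L * seq_along(markerIds),
                          allele_a = "A", allele_b = "B",
                          stringsAsFactors = FALSE)
  } else {
    if (is.character(map)) map <- readMarkerMap(map)
    idx <- match(markerIds, map$id)
    if (anyNA(idx))
      stop("marker id(s) absent from map: ",
           paste(markerIds[is.na(idx)][1:min(3, sum(is.na(idx)))],
                 collapse = ", "))
    markers <- map[idx, , drop = FALSE]
  }
  samples <- data.frame(id = tab[, 1], breed = tab[, 2],
                        stringsAsFactors = FALSE)
  GenotypeDataset(t(calls), markers, samples)
}

#' @rdname readGenotypeTable
#' @param ds a [GenotypeDataset-class].
#' @export
writeGenotypeTable <- function(ds, path) {
  mm <- markerMap(ds)
  si <- sampleInfo(ds)
  calls <- genotypeCalls(ds)
  header <- paste(c("sample_id", "breed", mm$id), collapse = "\t")
  body <- vapply(seq_len(nrow(si)), function(i) {
    g <- calls[, i]
    paste(c(si$id[i], si$breed[i],
            ifelse(is.na(g), "NA", as.character(g))), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, sep = "\n")
  invisible(path)
}

#' Read/write a marker map TSV
#'
#' Columns: id, chrom, pos_bp, allele_a, allele_b.
#'
#' @param path file path.
#' @return [readMarkerMap()]: the map data.frame; [writeMarkerMap()]:
#'   invisibly, the path.
#' @export
readMarkerMap <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "character"))
  stopifnot(identical(names(df),
                      c("id", "chrom", "pos_bp", "allele_a", "allele_b")))
  df
}

#' @rdname readMarkerMap
#' @param map a marker map data.frame (see [markerMap()]).
#' @export
writeMarkerMap <- function(map, path) {
  utils::write.table(map[, c("id", "chrom", "pos_bp",
                             "allele_a", "allele_b")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
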