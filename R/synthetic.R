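# Seeded synthetic-genotype generation with truth tables.
#
# The generator emulates the statistical structure a multi-breed SNP-array
# survey assumes: an ancestral allele-frequency spectrum, per-breed drift
# (Beta model), Hardy-Weinberg genotypes with optional sitewise inbreeding,
# i.i.d. missingness, and injected autozygous segments at known locations.
# Genotypes are sitewise independent outside injected segments, so the ROH
# signal comes entirely from injection and the truth set is exact.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a marker map
#'
#' Positions are drawn uniformly per chromosome, de-duplicated and sorted,
#' giving strictly increasing positions. Alleles are drawn from {A,C,G,T}
#' per marker.
#'
#' @param nChrom number of chromosomes (1..28).
#' @param snpsPerChrom markers per chromosome (>= 2).
#' @param chromLengthBp chromosome length in bp (scalar or per
#'   chromosome).
#' @param seed integer seed (NULL: use the current RNG stream).
#' @return Marker map data.frame (see [markerMap()]).
#' @export
simulateMap <- function(nChrom = 5, snpsPerChrom = 1600,
                        chromLengthBp = 4e7, seed = 1) {
  stopifnot(snpsPerChrom >= 2, nChrom >= 1, nChrom <= 28)
  chromLengthBp <- rep_len(chromLengthBp, nChrom)
  if (any(chromLengthBp < snpsPerChrom))
    stop("chromosome shorter than the requested marker count")
  .withSeed(seed, {
    maps <- lapply(seq_len(nChrom), function(ch) {
      pos <- sort(sample.int(chromLengthBp[ch], snpsPerChrom))
      base <- c("A", "C", "G", "T")
      a <- sample(base, snpsPerChrom, replace = TRUE)
      b <- vapply(a, function(x) sample(setdiff(base, x), 1), character(1))
      data.frame(id = sprintf("snp_%d_%d", ch, seq_len(snpsPerChrom)),
                 chrom = ch, pos_bp = pos, allele_a = a, allele_b = b,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, maps)
  })
}

#' Simulate breed allele frequencies under a Beta drift model
#'
#' Ancestral frequencies p0 ~ Beta(alpha, beta) per marker; each breed
#' draws p ~ Beta(p0 (1-c)/c, (1-p0) (1-c)/c) with drift parameter c in
#' (0, 1), so E[p] = p0 and E[(p_x - p_y)^2] = 2 c p0 (1 - p0) for two
#' independent breeds; expected Reynolds distance rises with c. c below
#' 1e-9 returns the ancestral frequencies unchanged.
#'
#' @param nMarkers number of markers.
#' @param divergence named numeric vector of per-breed drift parameters c.
#' @param alpha,beta ancestral Beta spectrum shape (default 1.5, 1.5 — a
#'   mildly U-flattened array-like spectrum).
#' @param seed integer seed (NULL: current stream).
#' @return \code{list(ancestral = <numeric>, breed = <markers x breeds
#'   matrix>)}.
#' @export
simulateBreedFrequencies <- function(nMarkers, divergence,
                                     alpha = 1.5, beta = 1.5, seed = 1) {
  stopifnot(all(divergence >= 0), all(divergence < 1),
            alpha > 0, beta > 0, !is.null(names(divergence)))
  .withSeed(seed, {
    p0 <- stats::rbeta(nMarkers, alpha, beta)
    B <- vapply(names(divergence), function(b) {
      c_ <- divergence[[b]]
      if (c_ < 1e-9) return(p0)
      stats::rbeta(nMarkers, p0 * (1 - c_) / c_, (1 - p0) * (1 - c_) / c_)
    }, numeric(nMarkers))
    colnames(B) <- names(divergence)
    list(ancestral = p0, breed = B)
  })
}

#' Simulate genotypes for one breed
#'
#' Per marker with allele-B frequency p and inbreeding F, genotype
#' probabilities are (q^2 + F p q, 2 p q (1 - F), p^2 + F p q) for codes
#' 0/1/2; missing calls are dropped i.i.d. at \code{missingRate}.
#'
#' @param map marker map data.frame.
#' @param freqs per-marker allele-B frequencies (length = markers).
#' @param n number of individuals.
#' @param inbreedingF sitewise inbreeding coefficient in \[0, 1\].
#' @param missingRate i.i.d. missingness probability.
#' @param breed breed label for the samples.
#' @param seed integer seed (NULL: current stream).
#' @return A [GenotypeDataset-class] of one breed.
#' @export
simulateGenotypes <- function(map, freqs, n, inbreedingF = 0,
                              missingRate = 0, breed = "SIM", seed = 1) {
  m <- nrow(map)
  stopifnot(length(freqs) == m, inbreedingF >= 0, inbreedingF <= 1,
            missingRate >= 0, missingRate < 1, n >= 1)
  .withSeed(seed, {
    p <- freqs
    q <- 1 - p
    p0 <- q^2 + inbreedingF * p * q        # P(code 0)
    p1 <- 2 * p * q * (1 - inbreedingF)    # P(code 1)
    u <- matrix(stats::runif(m * n), nrow = m)
    calls <- matrix(2L, nrow = m, ncol = n)
    calls[u < p0 + p1] <- 1L
    calls[u < p0] <- 0L
    if (missingRate > 0)
      calls[matrix(stats::runif(m * n) < missingRate, nrow = m)] <-
        NA_integer_
    samples <- data.frame(id = sprintf("%s_%02d", breed, seq_len(n)),
                          breed = breed, stringsAsFactors = FALSE)
    GenotypeDataset(calls, map, samples)
  })
}

#' Combine per-breed datasets sharing one map
#'
#' @param ... [GenotypeDataset-class] objects with identical marker maps.
#' @return The column-bound [GenotypeDataset-class].
#' @export
combineBreeds <- function(...) {
  dss <- list(...)
  if (length(dss) == 1L && is.list(dss[[1]]) &&
      !methods::is(dss[[1]], "GenotypeDataset"))
    dss <- dss[[1]]
  maps <- lapply(dss, markerMap)
  for (i in seq_along(maps)[-1])
    if (!identical(maps[[1]], maps[[i]]))
      stop("datasets do not share one marker map")
  calls <- do.call(cbind, lapply(dss, genotypeCalls))
  samples <- do.call(rbind, lapply(dss, sampleInfo))
  GenotypeDataset(calls, maps[[1]], samples)
}

#' Inject autozygous segments at known locations
#'
#' Every marker inside a planned span is set to a homozygous code drawn
#' from the marker's allele frequency (code 2 with probability p, else 0),
#' eliminating heterozygous and missing calls inside the span. Overlapping
#' spans of one individual are merged in the returned truth table.
#'
#' @param ds a [GenotypeDataset-class].
#' @param plan data.frame with columns sample_id, chrom, start_bp, end_bp
#'   (closed bp spans). An empty plan returns the dataset unchanged.
#' @param freqs optional per-marker allele-B frequencies used for the
#'   homozygous draw: a numeric vector, or a markers x breeds matrix whose
#'   columns are matched through each sample's breed. Default: realized
#'   within-breed frequencies of \code{ds}.
#' @param seed integer seed (NULL: current stream).
#' @return \code{list(dataset = <GenotypeDataset>, truth = <data.frame
#'   sample_id, chrom, start_bp, end_bp>)}.
#' @export
injectRoh <- function(ds, plan, freqs = NULL, seed = 1) {
  mm <- markerMap(ds)
  si <- sampleInfo(ds)
  need <- c("sample_id", "chrom", "start_bp", "end_bp")
  stopifnot(all(need %in% names(plan)))
  if (nrow(plan)) {
    chromMax <- tapply(mm$pos_bp, mm$chrom, max)
    if (any(plan$end_bp - plan$start_bp >
            chromMax[as.character(plan$chrom)]))
      stop("planned segment longer than its chromosome")
    if (!all(plan$sample_id %in% si$id))
      stop("plan references unknown sample id(s)")
  }
  if (is.null(freqs)) {
    brs <- unique(si$breed)
    freqs <- vapply(brs, function(b) alleleFrequencies(ds, group = b),
                    numeric(nrow(mm)))
  }
  freqOf <- function(sampleId) {
    if (is.matrix(freqs))
      freqs[, si$breed[match(sampleId, si$id)]]
    else freqs
  }
  calls <- genotypeCalls(ds)
  .withSeed(seed, {
    for (r in seq_len(nrow(plan))) {
      idx <- which(mm$chrom == plan$chrom[r] &
                   mm$pos_bp >= plan$start_bp[r] &
                   mm$pos_bp <= plan$end_bp[r])
      if (!length(idx)) next
      p <- freqOf(plan$sample_id[r])[idx]
      p[is.nan(p)] <- 0.5
      col <- match(plan$sample_id[r], si$id)
      calls[idx, col] <- ifelse(stats::runif(length(idx)) < p, 2L, 0L)
    }
    truth <- .mergePlan(plan)
    list(dataset = GenotypeDataset(calls, mm, si), truth = truth)
  })
}

# merge overlapping/touching spans per (sample, chrom)
.mergePlan <- function(plan) {
  if (!nrow(plan))
    return(data.frame(sample_id = character(), chrom = integer(),
                      start_bp = integer(), end_bp = integer(),
                      stringsAsFactors = FALSE))
  out <- lapply(split(plan, list(plan$sample_id, plan$chrom),
                      drop = TRUE), function(x) {
    x <- x[order(x$start_bp), , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = x$start_bp,
                                           end = x$end_bp))
    data.frame(sample_id = x$sample_id[1], chrom = x$chrom[1],
               start_bp = IRanges::start(ir), end_bp = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, res$chrom, res$start_bp), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Plan random autozygous segments to a target genome fraction
#'
#' Draws segments (uniform start, chromosome chosen proportionally to its
#' length) until the merged coverage of each sample reaches
#' \code{targetF} of the map-covered genome; the last draw is bounded so
#' the overshoot stays below the minimum segment length.
#'
#' @param map marker map data.frame.
#' @param sampleIds samples to plan for.
#' @param targetF target autozygous genome fraction in \[0, 1\].
#' @param lengthRangeMb segment length range in Mb, c(min, max).
#' @param seed integer seed (NULL: current stream).
#' @return Plan data.frame for [injectRoh()].
#' @export
planRohCoverage <- function(map, sampleIds, targetF,
                            lengthRangeMb = c(1, 30), seed = 1) {
  stopifnot(targetF >= 0, targetF < 1, lengthRangeMb[1] > 0,
            lengthRangeMb[2] >= lengthRangeMb[1])
  chromLen <- tapply(map$pos_bp, map$chrom, max)
  chroms <- as.integer(names(chromLen))
  G <- sum(chromLen)
  minL <- lengthRangeMb[1] * 1e6
  maxL <- lengthRangeMb[2] * 1e6
  if (maxL > max(chromLen)) stop("segment range exceeds chromosome length")
  .withSeed(seed, {
    rows <- list()
    for (s in sampleIds) {
      if (targetF == 0) next
      covered <- 0
      spans <- data.frame(sample_id = character(), chrom = integer(),
                          start_bp = integer(), end_bp = integer())
      iter <- 0L
      while (covered < targetF * G && iter < 10000L) {
        iter <- iter + 1L
        remaining <- targetF * G - covered
        drawMax <- min(maxL, max(minL, remaining))
        len <- stats::runif(1, minL, drawMax)
        okCh <- chroms[chromLen >= len + 2]
        ch <- if (length(okCh) == 1L) okCh else
          sample(okCh, 1, prob = chromLen[as.character(okCh)])
        start <- floor(stats::runif(1, 1, chromLen[as.character(ch)] - len))
        spans <- rbind(spans, data.frame(
          sample_id = s, chrom = ch, start_bp = as.integer(start),
          end_bp = as.integer(start + len), stringsAsFactors = FALSE))
        merged <- .mergePlan(spans)
        covered <- sum(merged$end_bp - merged$start_bp)
      }
      rows[[s]] <- spans
    }
    if (!length(rows))
      return(data.frame(sample_id = character(), chrom = integer(),
                        start_bp = integer(), end_bp = integer(),
                        stringsAsFactors = FALSE))
    res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    res
  })
}

# Breed design of the emulated 27-breed survey: 23 local breeds and 4
# commercial stocks, per-breed sample sizes and target autozygous genome
# fractions spanning ~0 (commercial) to ~0.6 (Siciliana-like), with
# stronger drift in the local breeds.
.studyBreeds <- function() {
  local <- data.frame(
    label = c("ANC", "BSA", "BPT", "COR", "PER", "PLB", "PLN", "MER",
              "PML", "MOD", "MUG", "PPA", "PPC", "PPD", "PPP", "PPB",
              "PPN", "PRL", "PRM", "ROM", "SIC", "VLD", "VLP"),
    n = c(24L, 24L, 22L, 22L, 23L, 24L, 24L, 24L, 23L, 24L, 24L, 24L,
          24L, 24L, 24L, 24L, 24L, 23L, 24L, 24L, 24L, 24L, 20L),
    f = c(0.201, 0.081, 0.081, 0.507, 0.305, 0.427, 0.296, 0.326,
          0.166, 0.264, 0.225, 0.509, 0.410, 0.230, 0.482, 0.310,
          0.353, 0.353, 0.410, 0.187, 0.607, 0.121, 0.236),
    divergence = 0.15, group = "local", stringsAsFactors = FALSE)
  comm <- data.frame(
    label = c("708", "EUK", "HYL", "ISA"),
    n = c(13L, 9L, 10L, 9L),
    f = c(0.034, 0.033, 0.038, 0.030),
    divergence = 0.05, group = "commercial", stringsAsFactors = FALSE)
  rbind(local, comm)
}

#' Build the full synthetic study fixture
#'
#' A 27-breed dataset (23 local breeds, 20--24 animals each; 4 commercial
#' stocks, 9--13 animals) on \code{nChrom} autosomes, with per-breed drift,
#' per-breed target autozygous fractions spanning ~0 to ~0.6 realised by
#' segment injection on an HWE background (sitewise inbreeding 0), i.i.d.
#' missingness, and one designed high-incidence island region injected in
#' 90% of all animals. Truth tables record every injected span, the breed
#' design and the simulated frequencies.
#'
#' @param seed integer seed.
#' @param nChrom,snpsPerChrom,chromLengthBp map geometry (defaults: 5
#'   autosomes x 40 Mb, 1600 SNPs each).
#' @param missingRate i.i.d. missingness (default 0.005).
#' @param breedSubset optional character vector restricting the breeds
#'   (mainly for quick examples and tests).
#' @param islandChrom,islandStartBp,islandEndBp the designed island span.
#' @param islandCarrierRate fraction of animals carrying the island
#'   (default 0.9).
#' @param segmentRangeMb length range of the random injected segments.
#' @return \code{list(dataset, truth = list(segments, breeds, island,
#'   frequencies))}; \code{segments} is the merged injection truth,
#'   \code{breeds} the design table (label, n, f, divergence, group).
#' @examples
#' fx <- makeStudyFixture(seed = 1, breedSubset = c("SIC", "708"),
#'                        snpsPerChrom = 200, nChrom = 2)
#' fx$dataset
#' @export
makeStudyFixture <- function(seed, nChrom = 5, snpsPerChrom = 1600,
                             chromLengthBp = 4e7, missingRate = 0.005,
                             breedSubset = NULL, islandChrom = 2,
                             islandStartBp = 12e6, islandEndBp = 15e6,
                             islandCarrierRate = 0.9,
                             segmentRangeMb = c(1, 30)) {
  design <- .studyBreeds()
  if (!is.null(breedSubset)) {
    stopifnot(all(breedSubset %in% design$label))
    design <- design[design$label %in% breedSubset, , drop = FALSE]
  }
  if (nChrom < 2) islandChrom <- 1
  .withSeed(seed, {
    map <- simulateMap(nChrom, snpsPerChrom, chromLengthBp, seed = NULL)
    div <- stats::setNames(design$divergence, design$label)
    freqs <- simulateBreedFrequencies(nrow(map), div, seed = NULL)
    dss <- lapply(seq_len(nrow(design)), function(i) {
      simulateGenotypes(map, freqs$breed[, design$label[i]],
                        n = design$n[i], inbreedingF = 0,
                        missingRate = missingRate,
                        breed = design$label[i], seed = NULL)
    })
    ds <- combineBreeds(dss)
    si <- sampleInfo(ds)
    plans <- lapply(seq_len(nrow(design)), function(i) {
      ids <- si$id[si$breed == design$label[i]]
      planRohCoverage(map, ids, targetF = design$f[i],
                      lengthRangeMb = segmentRangeMb, seed = NULL)
    })
    plan <- do.call(rbind, plans)
    carriers <- si$id[stats::runif(nrow(si)) < islandCarrierRate]
    if (length(carriers)) {
      island <- data.frame(sample_id = carriers, chrom = islandChrom,
                           start_bp = as.integer(islandStartBp),
                           end_bp = as.integer(islandEndBp),
                           stringsAsFactors = FALSE)
      plan <- rbind(plan, island)
    }
    inj <- injectRoh(ds, plan, freqs = freqs$breed, seed = NULL)
    list(dataset = inj$dataset,
         truth = list(segments = inj$truth, breeds = design,
                      island = data.frame(chrom = islandChrom,
                                          start_bp = islandStartBp,
                                          end_bp = islandEndBp,
                                          carrier_rate = islandCarrierRate),
                      frequencies = freqs))
  })
}
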