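# Per-breed diversity indices: MAF, observed/expected heterozygosity, and
# the excess-homozygosity inbreeding coefficient F_HOM.
#
# Conventions: MAF/Ho/He means and SDs are taken across markers (population
# SD, divided by the number of markers); F_HOM mean and SD are taken across
# individuals (sample SD). Markers with no non-missing call in the cohort
# are undefined and excluded from the across-marker summaries.

.popSD <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

#' Within-breed minor allele frequency summary
#'
#' @param ds a [GenotypeDataset-class].
#' @param breed breed label.
#' @return \code{list(mean, sd)} of per-marker MAF = min(p, 1-p) computed
#'   within the breed; SD is the population SD across defined markers.
#' @export
breedMafSummary <- function(ds, breed) {
  p <- alleleFrequencies(ds, group = breed)
  maf <- pmin(p, 1 - p)
  maf <- maf[!is.nan(maf)]
  list(mean = mean(maf), sd = .popSD(maf))
}

#' Observed and expected heterozygosity within a breed
#'
#' Per marker, Ho is the heterozygote fraction among non-missing calls and
#' He = 2p(1-p) from the within-breed frequency; means and population SDs
#' are taken across defined markers.
#'
#' @param ds a [GenotypeDataset-class].
#' @param breed breed label.
#' @return \code{list(ho_mean, ho_sd, he_mean, he_sd)}.
#' @export
heterozygosity <- function(ds, breed) {
  sub <- subsetBreed(ds, breed)
  if (nSamples(sub) < 2L) stop("breed ", breed, " has fewer than 2 samples")
  calls <- genotypeCalls(sub)
  nn <- rowSums(!is.na(calls))
  ok <- nn > 0
  ho <- rowSums(calls == 1L, na.rm = TRUE)[ok] / nn[ok]
  p <- (rowSums(calls, na.rm = TRUE) / (2 * nn))[ok]
  he <- 2 * p * (1 - p)
  list(ho_mean = mean(ho), ho_sd = .popSD(ho),
       he_mean = mean(he), he_sd = .popSD(he))
}

#' Excess-homozygosity inbreeding coefficient F_HOM
#'
#' For individual i with O_i observed homozygotes over its L_i non-missing
#' markers, F_i = (O_i - E_i) / (L_i - E_i) where
#' E_i = sum_j (1 - 2 p_j q_j c_j) over those markers, p_j the allele
#' frequency in the scope cohort and c_j = 2 n_j / (2 n_j - 1) the
#' small-sample correction (n_j = non-missing individuals at marker j in
#' the cohort) when \code{correction = TRUE}, else 1. Negative values
#' indicate observed heterozygosity in excess of the cohort expectation.
#' Individuals with L_i = E_i (no informative marker) get \code{NA}.
#'
#' @param ds a [GenotypeDataset-class].
#' @param breed breed label whose individuals are scored.
#' @param freqScope \code{"within_breed"} (default): expectations from the
#'   breed's own frequencies; \code{"global"}: from all samples pooled.
#' @param correction apply the small-sample factor 2n/(2n-1)
#'   (default TRUE).
#' @return \code{list(f = <named per-individual vector>, mean, sd)}; the
#'   SD is the sample SD across individuals.
#' @export
fHom <- function(ds, breed, freqScope = c("within_breed", "global"),
                 correction = TRUE) {
  freqScope <- match.arg(freqScope)
  sub <- subsetBreed(ds, breed)
  scope <- if (freqScope == "within_breed") sub else ds
  if (nSamples(scope) < 2L) stop("frequency cohort has fewer than 2 samples")
  fc <- .freqCounts(genotypeCalls(scope))
  p <- fc$p
  cj <- if (correction) 2 * fc$n / (2 * fc$n - 1) else rep(1, length(p))
  ej <- 1 - 2 * p * (1 - p) * cj          # per-marker expected hom
  ej[fc$n == 0] <- NA                      # undefined in cohort

  calls <- genotypeCalls(sub)
  nonmiss <- !is.na(calls) & !is.na(ej)
  O <- colSums((calls == 0L | calls == 2L) & nonmiss, na.rm = TRUE)
  L <- colSums(nonmiss)
  E <- colSums(nonmiss * ej, na.rm = TRUE)
  denom <- L - E
  f <- ifelse(abs(denom) < 1e-12, NA_real_, (O - E) / denom)
  names(f) <- sampleInfo(sub)$id
  if (anyNA(f))
    warning(sum(is.na(f)), " individual(s) with undefined F_HOM")
  list(f = f, mean = mean(f, na.rm = TRUE), sd = stats::sd(f, na.rm = TRUE))
}

#' Per-breed diversity table
#'
#' One row per breed with sample count, MAF, Ho, He and F_HOM summaries —
#' the standard descriptive table of a multi-breed SNP-array survey.
#'
#' @param ds a [GenotypeDataset-class].
#' @param freqScope,correction passed to [fHom()].
#' @return data.frame with columns breed, n, maf_mean, maf_sd, ho_mean,
#'   ho_sd, he_mean, he_sd, fhom_mean, fhom_sd.
#' @examples
#' fx <- makeStudyFixture(seed = 1, breedSubset = c("ANC", "SIC", "708"),
#'                        snpsPerChrom = 300, nChrom = 2)
#' diversityTable(fx$dataset)
#' @export
diversityTable <- function(ds, freqScope = "within_breed",
                           correction = TRUE) {
  brs <- sort(unique(breedLabels(ds)))
  rows <- lapply(brs, function(b) {
    maf <- breedMafSummary(ds, b)
    het <- heterozygosity(ds, b)
    fh <- suppressWarnings(fHom(ds, b, freqScope, correction))
    data.frame(breed = b, n = sum(breedLabels(ds) == b),
               maf_mean = maf$mean, maf_sd = maf$sd,
               ho_mean = het$ho_mean, ho_sd = het$ho_sd,
               he_mean = het$he_mean, he_sd = het$he_sd,
               fhom_mean = fh$mean, fhom_sd = fh$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
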