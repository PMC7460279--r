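# Shared fixture builders. Everything is generated in code at test time;
# the full-size study fixture is built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

# 582-animal, 27-breed, 8000-marker synthetic survey with truth tables,
# after standard QC; cached together with its ROH calls.
studyFixtureQC <- function() {
  if (!exists("study", envir = .fixtureCache)) {
    fx <- makeStudyFixture(seed = 42)
    qc <- applyQC(fx$dataset)
    segs <- callRoh(qc$dataset)
    assign("study", list(raw = fx, dataset = qc$dataset,
                         report = qc$report, segments = segs),
           envir = .fixtureCache)
  }
  get("study", envir = .fixtureCache)
}

# small hand-checkable dataset: calls given markers x samples
toyDataset <- function(calls, chrom = NULL, pos = NULL,
                       breeds = NULL, prefix = "S") {
  m <- nrow(calls)
  n <- ncol(calls)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(breeds)) breeds <- rep("B1", n)
  GenotypeDataset(
    calls = calls,
    markers = data.frame(id = paste0("m", seq_len(m)), chrom = chrom,
                         pos_bp = pos, allele_a = "A", allele_b = "C",
                         stringsAsFactors = FALSE),
    samples = data.frame(id = paste0(prefix, seq_len(n)), breed = breeds,
                         stringsAsFactors = FALSE))
}

# the QC example fixture: 4 samples x 12 markers, hand-counted so that
# under default thresholds sample S4 (2/12 = 16.7% missing) is removed,
# then marker m2 (call rate 2/3) and monomorphic marker m3 fall; 3
# samples and 10 markers survive
qcToyDataset <- function() {
  calls <- rbind(
    m1  = c(0L, 1L, 2L, 0L),
    m2  = c(NA, 1L, 1L, 0L),
    m3  = c(0L, 0L, 0L, 0L),
    m4  = c(0L, 1L, 1L, 1L),
    m5  = c(2L, 2L, 1L, 2L),
    m6  = c(1L, 0L, 0L, 0L),
    m7  = c(2L, 0L, 1L, 1L),
    m8  = c(1L, 1L, 1L, 1L),
    m9  = c(0L, 2L, 0L, 2L),
    m10 = c(1L, 2L, 0L, 1L),
    m11 = c(0L, 0L, 1L, NA),
    m12 = c(2L, 1L, 0L, NA))
  toyDataset(calls)
}

writeTempPedMap <- function(pedLines, mapLines) {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(pedLines, ped)
  writeLines(mapLines, map)
  list(ped = ped, map = map)
}
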