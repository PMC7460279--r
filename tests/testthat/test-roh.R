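# ROH calling: hand-traced constraint cases, oracle equivalence,
# properties, F_ROH arithmetic, length classes, breed summaries.

test_that("a clean homozygous run is called as exactly one segment", {
  pos <- as.integer(seq(1e6, 3e6, length.out = 150))
  segs <- callRohIndividual(rep(0L, 150), pos, rohParams())
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 150L)
  expect_equal(segs$start_bp, pos[1])
  expect_equal(segs$end_bp, pos[150])
})

test_that("a gap above the limit splits a run below the SNP minimum", {
  # 150 SNPs, 1.5 Mb gap between SNP 70 and 71: each side < 100 SNPs
  pos <- c(seq(1e6, 2e6, length.out = 70),
           seq(3.5e6, 4.7e6, length.out = 80))
  segs <- callRohIndividual(rep(0L, 150), as.integer(round(pos)),
                            rohParams())
  expect_equal(nrow(segs), 0L)
})

test_that("sparse runs violating the density bound are rejected", {
  # 120 homozygous SNPs spanning 13 Mb: 108 kb/SNP > 100 kb/SNP
  pos <- as.integer(round(seq(1e6, 14e6, length.out = 120)))
  segs <- callRohIndividual(rep(2L, 120), pos, rohParams())
  expect_equal(nrow(segs), 0L)
})

test_that("regular heterozygosity denser than the allowance blocks calling", {
  calls <- rep(0L, 400)
  calls[seq(1, 400, by = 50)] <- 1L   # a het every 50 SNPs
  pos <- as.integer(seq(1e6, 9e6, length.out = 400))
  segs <- callRohIndividual(calls, pos, rohParams())
  expect_equal(nrow(segs), 0L)
})

test_that("segment mode equals the brute-force oracle on random chromosomes", {
  withr::with_seed(101, {
    for (r in 1:30) {
      m <- sample(40:250, 1)
      rc <- randomChromosome(m, runif(1, 0.02, 0.35), runif(1, 0, 0.08))
      p <- rohParams(minSnps = sample(c(5, 10, 20), 1),
                     minLengthKb = sample(c(50, 200, 800), 1),
                     maxHet = sample(0:2, 1), maxMissing = sample(0:3, 1),
                     minDensityKbPerSnp = sample(c(40, 100), 1),
                     maxGapKb = sample(c(300, 1000), 1))
      a <- callRohIndividual(rc$calls, rc$positions, p)
      b <- bruteForceRoh(rc$calls, rc$positions, p)
      expect_equal(a[, c("start_idx", "end_idx", "n_snps", "n_het",
                         "n_missing")],
                   b, ignore_attr = TRUE)
    }
  })
})

test_that("window mode approximates the heuristic and respects final constraints", {
  pos <- as.integer(seq(1e6, 3e6, length.out = 150))
  p <- rohParams(mode = "window")
  segs <- callRohIndividual(rep(0L, 150), pos, p)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 150L)
  # heavy heterozygosity yields nothing in window mode either
  calls <- rep(0L, 150); calls[seq(1, 150, 10)] <- 1L
  expect_equal(nrow(callRohIndividual(calls, pos, p)), 0L)
  # every emitted segment honours the run-level constraints
  withr::with_seed(77, {
    rc <- randomChromosome(400, 0.05, 0.02)
    sw <- callRohIndividual(rc$calls, rc$positions, p)
  })
  if (nrow(sw)) {
    expect_true(all(sw$n_het <= p@maxHet))
    expect_true(all(sw$n_missing <= p@maxMissing))
    expect_true(all(sw$n_snps >= p@minSnps))
    expect_true(all(sw$length_bp >= p@minLengthKb * 1000))
  }
})

test_that("raising min_snps or min_length never increases the call count", {
  withr::with_seed(103, {
    for (r in 1:15) {
      rc <- randomChromosome(sample(80:250, 1), runif(1, 0, 0.3),
                             runif(1, 0, 0.05))
      base <- rohParams(minSnps = 10, minLengthKb = 100)
      n0 <- nrow(callRohIndividual(rc$calls, rc$positions, base))
      n1 <- nrow(callRohIndividual(rc$calls, rc$positions,
                                   rohParams(minSnps = 25,
                                             minLengthKb = 100)))
      n2 <- nrow(callRohIndividual(rc$calls, rc$positions,
                                   rohParams(minSnps = 10,
                                             minLengthKb = 500)))
      expect_lte(n1, n0)
      expect_lte(n2, n0)
    }
  })
})

test_that("dataset-level calling concatenates per-individual calls in order", {
  # all-homozygous dataset: one run per sample on each chromosome
  m <- 240
  calls <- matrix(0L, nrow = m, ncol = 3)
  pos <- rep(as.integer(seq(1e6, 3.4e6, length.out = 120)), 2)
  ds <- toyDataset(calls, chrom = rep(1:2, each = 120), pos = pos)
  segs <- callRoh(ds, rohParams())
  expect_equal(nrow(segs), 6L)   # 3 samples x 2 chromosomes
  expect_equal(segs$sample_id, rep(paste0("S", 1:3), each = 2))
  # empty dataset -> empty call set
  none <- toyDataset(matrix(1L, nrow = 200, ncol = 2),
                     pos = as.integer(seq(1e6, 3e6, length.out = 200)))
  expect_equal(nrow(callRoh(none)), 0L)
})

test_that("F_ROH arithmetic uses the autosomal array length", {
  expect_equal(CHICKEN_AUTOSOME_KB, 944270)
  segs <- data.frame(sample_id = "a", breed = "B", chrom = 1,
                     start_bp = 1, end_bp = 944270 * 1000 + 1,
                     n_snps = 1000, n_het = 0, n_missing = 0,
                     length_bp = 944270 * 1000)
  fr <- frohRecords(segs)
  expect_equal(fr$froh, 1.0)
  segs$length_bp <- 94427 * 1000
  segs$end_bp <- segs$start_bp + segs$length_bp
  expect_equal(frohRecords(segs)$froh, 0.1)
  none <- frohRecords(segs[0, ], sampleIds = "a")
  expect_equal(none$froh, 0)
  expect_equal(none$n_roh, 0L)
  segs$length_bp <- 2 * 944270 * 1000
  expect_error(frohRecords(segs), "longer than the genome")
})

test_that("F_ROH is invariant under chromosome relabeling", {
  fx <- makeStudyFixture(seed = 23, breedSubset = "COR",
                         snpsPerChrom = 400, nChrom = 3)
  ds <- fx$dataset
  mm <- markerMap(ds)
  relab <- mm
  relab$chrom <- c(3L, 1L, 2L)[relab$chrom]   # permute labels
  ds2 <- GenotypeDataset(genotypeCalls(ds), relab, sampleInfo(ds))
  f1 <- frohRecords(callRoh(ds), sampleIds = sampleInfo(ds)$id)
  f2 <- frohRecords(callRoh(ds2), sampleIds = sampleInfo(ds)$id)
  expect_equal(f1$froh[order(f1$sample_id)],
               f2$froh[order(f2$sample_id)])
})

test_that("length classes use right-closed bounds and breed means average animals", {
  seg <- function(mb, s = "a") data.frame(
    sample_id = s, breed = "B", chrom = 1, start_bp = 1e6,
    end_bp = 1e6 + mb * 1e6, n_snps = 200, n_het = 0, n_missing = 0,
    length_bp = mb * 1e6)
  one <- frohRecords(seg(4.2))
  expect_equal(one$class_1, 4.2)
  expect_equal(frohRecords(seg(5.0))$class_1, 5.0)   # boundary stays left
  expect_equal(frohRecords(seg(5.0))$class_2, 0)
  expect_equal(frohRecords(seg(31))$class_7, 31)
  cls <- lengthClassSums(seg(10), groups = c(a = "B", b = "B"))
  expect_equal(cls$class_1[1], 0)
  expect_equal(cls$class_2[1], 5)    # {10, 0} Mb -> mean 5
})

test_that("breed summaries aggregate per-animal records", {
  froh <- data.frame(sample_id = c("a", "b"), froh = c(0.2, 0.4),
                     sum_roh_kb = c(1, 2), n_roh = c(2L, 4L))
  s <- rohBreedSummary(froh, groups = c(a = "B", b = "B"))
  expect_equal(s$mean_n_roh, 3)
  expect_equal(s$total_n_roh, 6L)
  expect_equal(s$froh_mean, 0.3)
  expect_error(rohBreedSummary(froh, groups = c(a = "B")), "breed")
})

test_that("class sums are consistent with total ROH length", {
  st <- studyFixtureQC()
  fr <- frohRecords(st$segments,
                    sampleIds = sampleInfo(st$dataset)$id,
                    genomeLengthKb = suppressMessages(
                      genomeLengthKb(st$dataset)))
  clsTotal <- rowSums(fr[paste0("class_", 1:7)])
  expect_equal(clsTotal * 1000, fr$sum_roh_kb, tolerance = 1e-9)
  expect_true(all(fr$froh >= 0 & fr$froh <= 1))
})
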