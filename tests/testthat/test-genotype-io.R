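# PED/MAP and genotype-table parsing, coding conventions, round trips.

test_that("PED/MAP parsing codes genotypes against the first observed allele", {
  f <- writeTempPedMap(
    pedLines = c("ANC i1 0 0 1 -9 A A A C 0 0",
                 "SIC i2 0 0 2 -9 A A C C G G"),
    mapLines = c("1 s1 0 100", "1 s2 0 200", "2 s3 0 50"))
  ds <- readPedMap(f$ped, f$map)
  expect_equal(dim(genotypeCalls(ds)), c(3L, 2L))
  mm <- markerMap(ds)
  # s1: both samples A A -> monomorphic, allele_b placeholder "0"
  expect_equal(mm$allele_a[mm$id == "s1"], "A")
  expect_equal(mm$allele_b[mm$id == "s1"], "0")
  calls <- genotypeCalls(ds)
  expect_equal(unname(calls["s1", ]), c(0L, 0L))
  # s2: A C -> het, C C -> hom allele_b
  expect_equal(unname(calls["s2", ]), c(1L, 2L))
  # s3: "0 0" -> missing for i1
  expect_true(is.na(calls["s3", "i1"]))
  expect_equal(unname(calls["s3", "i2"]), 0L)
  si <- sampleInfo(ds)
  expect_equal(si$breed, c("ANC", "SIC"))
  expect_equal(si$sex, c("M", "F"))
})

test_that("markers listed out of order are re-sorted by (chrom, pos)", {
  f <- writeTempPedMap(
    pedLines = c("B i1 0 0 0 -9 A A C C"),
    mapLines = c("2 sx 0 500", "1 sy 0 900"))
  ds <- readPedMap(f$ped, f$map)
  mm <- markerMap(ds)
  expect_equal(mm$id, c("sy", "sx"))
  expect_equal(mm$chrom, c(1L, 2L))
  expect_equal(mm$pos_bp, c(900L, 500L))
  # calls permuted with the map: sy was C C (code 0 on its own allele)
  expect_equal(unname(genotypeCalls(ds)[, 1]), c(0L, 0L))
})

test_that("PED parse errors name the offending line or symbol", {
  f <- writeTempPedMap(
    pedLines = c("B i1 0 0 0 -9 A A C C",
                 "B i2 0 0 0 -9 A A"),
    mapLines = c("1 s1 0 100", "1 s2 0 200"))
  expect_error(readPedMap(f$ped, f$map), "line 2")
  f2 <- writeTempPedMap(
    pedLines = c("B i1 0 0 0 -9 A X"),
    mapLines = c("1 s1 0 100"))
  expect_error(readPedMap(f2$ped, f2$map), "allele symbol")
  f3 <- writeTempPedMap(
    pedLines = c("B i1 0 0 0 -9 A A C C"),
    mapLines = c("1 dup 0 100", "1 dup 0 200"))
  expect_error(readPedMap(f3$ped, f3$map), "duplicate marker")
})

test_that("half-calls become missing with a warning", {
  f <- writeTempPedMap(
    pedLines = c("B i1 0 0 0 -9 A 0 C C"),
    mapLines = c("1 s1 0 100", "1 s2 0 200"))
  expect_warning(ds <- readPedMap(f$ped, f$map), "half-call")
  expect_true(is.na(genotypeCalls(ds)["s1", 1]))
})

test_that("PED/MAP write-read round trip preserves the genotypes", {
  fx <- makeStudyFixture(seed = 11, breedSubset = c("ANC", "708"),
                         snpsPerChrom = 60, nChrom = 2,
                         missingRate = 0.02)
  ds <- fx$dataset
  ped <- tempfile(); map <- tempfile()
  writePedMap(ds, ped, map)
  ds2 <- readPedMap(ped, map)
  # reading re-anchors allele_a to the first allele observed in the file,
  # so per marker the codes are either identical or complemented together
  # with a swapped allele pair — the genotypes themselves are unchanged
  m1 <- markerMap(ds); m2 <- markerMap(ds2)
  c1 <- genotypeCalls(ds); c2 <- genotypeCalls(ds2)
  for (j in seq_len(nrow(m1))) {
    if (identical(m2$allele_a[j], m1$allele_a[j])) {
      expect_identical(unname(c2[j, ]), unname(c1[j, ]))
    } else {
      expect_identical(m2$allele_a[j], m1$allele_b[j])
      expect_identical(unname(c2[j, ]), unname(2L - c1[j, ]))
    }
  }
  expect_identical(markerMap(ds2)$pos_bp, markerMap(ds)$pos_bp)
  expect_identical(sampleInfo(ds2)$breed, sampleInfo(ds)$breed)
  # from the second generation on the files are byte-stable
  ped2 <- tempfile(); map2 <- tempfile()
  writePedMap(ds2, ped2, map2)
  ds3 <- readPedMap(ped2, map2)
  ped3 <- tempfile(); map3 <- tempfile()
  writePedMap(ds3, ped3, map3)
  expect_identical(readLines(ped3), readLines(ped2))
  expect_identical(readLines(map3), readLines(map2))
  expect_identical(genotypeCalls(ds3), genotypeCalls(ds2))
})

test_that("genotype coding is invariant under allele swap with code complement", {
  f <- writeTempPedMap(
    pedLines = c("B i1 0 0 0 -9 C C", "B i2 0 0 0 -9 A C",
                 "B i3 0 0 0 -9 A A"),
    mapLines = c("1 s1 0 100"))
  ds <- readPedMap(f$ped, f$map)          # allele_a = C (first observed)
  swapped <- GenotypeDataset(
    calls = 2L - genotypeCalls(ds),
    markers = within(markerMap(ds), {
      tmp <- allele_a; allele_a <- allele_b; allele_b <- tmp; rm(tmp)
    }),
    samples = sampleInfo(ds))
  # same heterozygosity and mirrored frequencies
  expect_equal(unname(alleleFrequencies(swapped)),
               1 - unname(alleleFrequencies(ds)))
  expect_equal(pmin(alleleFrequencies(swapped),
                    1 - alleleFrequencies(swapped)),
               pmin(alleleFrequencies(ds), 1 - alleleFrequencies(ds)),
               ignore_attr = TRUE)
})

test_that("genotype table round-trips and flags bad codes", {
  fx <- makeStudyFixture(seed = 3, breedSubset = c("SIC", "ISA"),
                         snpsPerChrom = 40, nChrom = 2,
                         missingRate = 0.05)
  ds <- fx$dataset
  path <- tempfile(fileext = ".tsv")
  writeGenotypeTable(ds, path)
  ds2 <- readGenotypeTable(path, map = markerMap(ds))
  expect_identical(genotypeCalls(ds2), genotypeCalls(ds))
  # write-read-write is byte-stable
  path2 <- tempfile(fileext = ".tsv")
  writeGenotypeTable(ds2, path2)
  expect_identical(readLines(path2), readLines(path))

  one <- toyDataset(matrix(c(0L, NA, 2L, 1L), nrow = 2))
  p1 <- tempfile(); writeGenotypeTable(one, p1)
  back <- readGenotypeTable(p1)
  expect_equal(sum(is.na(genotypeCalls(back))), 1L)

  bad <- tempfile()
  writeLines(c("sample_id\tbreed\tm1", "i1\tB\t7"), bad)
  expect_error(readGenotypeTable(bad), "row.*column|invalid genotype")
  empty <- tempfile()
  writeLines("sample_id\tbreed\tm1", empty)
  expect_error(readGenotypeTable(empty), "no samples")
})

test_that("subsetting preserves order, checks ids, honours allowEmpty", {
  fx <- makeStudyFixture(seed = 9, breedSubset = c("ANC", "SIC", "708"),
                         snpsPerChrom = 30, nChrom = 2)
  ds <- fx$dataset
  all <- subsetGenotypes(ds, sampleInfo(ds)$id, markerMap(ds)$id)
  expect_identical(genotypeCalls(all), genotypeCalls(ds))
  sic <- subsetBreed(ds, "SIC")
  expect_equal(nSamples(sic), 24L)
  expect_true(all(breedLabels(sic) == "SIC"))
  expect_error(subsetGenotypes(ds, sampleIds = c("nope", "nada")),
               "nope")
  expect_error(subsetGenotypes(ds, markerIds = character(0)),
               "empty")
  emp <- subsetGenotypes(ds, markerIds = character(0), allowEmpty = TRUE)
  expect_equal(nMarkers(emp), 0L)
})
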