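# IBS and Reynolds distances, classical MDS, neighbor joining, Newick.

test_that("IBS distance matches hand arithmetic and axioms", {
  ds <- toyDataset(rbind(m1 = c(0L, 2L), m2 = c(1L, 1L)),
                   breeds = c("X", "Y"))
  D <- ibsDistance(ds)
  expect_equal(D[1, 2], 0.5)   # similarities {0, 1}
  same <- toyDataset(cbind(rep(c(0L, 1L, 2L), 5), rep(c(0L, 1L, 2L), 5)))
  expect_equal(ibsDistance(same)[1, 2], 0)
  opp <- toyDataset(cbind(rep(0L, 10), rep(2L, 10)))
  expect_equal(ibsDistance(opp)[1, 2], 1)
})

test_that("IBS equals the naive double loop with pairwise deletion", {
  fx <- makeStudyFixture(seed = 29, breedSubset = c("MOD", "EUK"),
                         snpsPerChrom = 120, nChrom = 2,
                         missingRate = 0.05)
  ds <- subsetGenotypes(fx$dataset,
                        sampleIds = sampleInfo(fx$dataset)$id[1:20])
  D <- ibsDistance(ds)
  expect_equal(unname(D), naiveIbs(genotypeCalls(ds)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(isSymmetric(unname(D)))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
})

test_that("pairs sharing no typed marker error unless allowed", {
  calls <- rbind(m1 = c(0L, NA), m2 = c(NA, 2L))
  ds <- toyDataset(calls)
  expect_error(ibsDistance(ds), "no typed marker")
  D <- ibsDistance(ds, allowMissingPairs = TRUE)
  expect_true(is.na(D[1, 2]))
})

test_that("classical MDS reproduces exact Euclidean configurations", {
  # collinear points at 0, 1, 2
  D <- as.matrix(stats::dist(matrix(c(0, 1, 2), ncol = 1)))
  dimnames(D) <- list(letters[1:3], letters[1:3])
  mds <- classicalMDS(D, k = 1)
  expect_equal(as.matrix(stats::dist(mds$coordinates)), unname(D),
               tolerance = 1e-9, ignore_attr = TRUE)
  # random 5-point configurations embed exactly
  withr::with_seed(211, {
    for (r in 1:10) {
      X <- matrix(rnorm(10), 5, 2)
      D2 <- as.matrix(stats::dist(X))
      dimnames(D2) <- list(paste0("p", 1:5), paste0("p", 1:5))
      m2 <- classicalMDS(D2, k = 2)
      expect_equal(as.matrix(stats::dist(m2$coordinates)), unname(D2),
                   tolerance = 1e-9, ignore_attr = TRUE)
      expect_true(all(diff(m2$eigenvalues) <= 1e-9))
    }
  })
  # all-zero distances: flat embedding at the origin
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(classicalMDS(Z, k = 2)$coordinates == 0))
})

test_that("breed-average MDS places breed centroids between members", {
  fx <- makeStudyFixture(seed = 31, breedSubset = c("SIC", "PPA", "ISA"),
                         snpsPerChrom = 150, nChrom = 2)
  D <- ibsDistance(fx$dataset)
  si <- sampleInfo(fx$dataset)
  bm <- breedMds(D, stats::setNames(si$breed, si$id), k = 2)
  expect_setequal(rownames(bm$coordinates), c("SIC", "PPA", "ISA"))
  full <- classicalMDS(D, k = 2)
  expect_equal(bm$coordinates["SIC", 1],
               mean(full$coordinates[si$breed == "SIC", 1]))
})

test_that("Reynolds distance matches its closed form and is symmetric", {
  # one locus, p_x = 1, p_y = 0 -> theta = 1
  ds <- toyDataset(matrix(c(2L, 2L, 0L, 0L), nrow = 1),
                   breeds = c("X", "X", "Y", "Y"))
  D <- reynoldsDistance(ds)
  expect_equal(D["X", "Y"], 1)
  # identical frequency vectors -> zero
  same <- toyDataset(rbind(m1 = c(0L, 1L, 0L, 1L),
                           m2 = c(2L, 1L, 2L, 1L)),
                     breeds = c("X", "X", "Y", "Y"))
  expect_equal(reynoldsDistance(same)["X", "Y"], 0)
  # random data: symmetry, zero diagonal, linearized >= theta
  fx <- makeStudyFixture(seed = 37, breedSubset = c("ANC", "SIC", "708"),
                         snpsPerChrom = 100, nChrom = 2)
  R <- reynoldsDistance(fx$dataset)
  expect_true(isSymmetric(unname(R)))
  expect_true(all(diag(R) == 0))
  RL <- reynoldsDistance(fx$dataset, linearized = TRUE)
  expect_true(all(RL >= R - 1e-12))
})

test_that("stronger drift increases the expected Reynolds distance", {
  map <- simulateMap(1, 4000, 5e7, seed = 71)
  fr <- simulateBreedFrequencies(
    4000, c(A1 = 0.05, A2 = 0.05, B1 = 0.3, B2 = 0.3), seed = 72)
  mk <- function(b) simulateGenotypes(map, fr$breed[, b], n = 20,
                                      breed = b, seed = 73 + match(
                                        b, colnames(fr$breed)))
  ds <- combineBreeds(lapply(c("A1", "A2", "B1", "B2"), mk))
  R <- reynoldsDistance(ds)
  expect_lt(R["A1", "A2"], R["B1", "B2"])
})

test_that("neighbor joining recovers additive trees exactly", {
  withr::with_seed(311, {
    for (r in 1:20) {
      nt <- sample(5:8, 1)
      tr <- ape::rtree(nt)
      tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
      D <- stats::cophenetic(tr)
      est <- neighborJoining(D)
      expect_equal(stats::cophenetic(est)[rownames(D), colnames(D)], D,
                   tolerance = 1e-9)
    }
  })
})

test_that("three taxa give the closed-form star lengths", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(D)
  len <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                         tr$tip.label)
  expect_equal(len[["A"]], (2 + 3 - 4) / 2)
  expect_equal(len[["B"]], (2 + 4 - 3) / 2)
  expect_equal(len[["C"]], (3 + 4 - 2) / 2)
  expect_error(neighborJoining(D[, c(2, 1, 3)]), "symmetric")
})

test_that("label permutation yields an isomorphic NJ tree", {
  withr::with_seed(317, {
    tr <- ape::rtree(6)
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
    D <- stats::cophenetic(tr)
    perm <- sample(6)
    D2 <- D[perm, perm]
    t1 <- neighborJoining(D)
    t2 <- neighborJoining(D2)
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
  })
})

test_that("Newick output quotes awkward labels and round-trips", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3)
  labs <- c("Hy-line(w)", "B x", "C")
  dimnames(D) <- list(labs, labs)
  tr <- neighborJoining(D)
  txt <- writeNewick(tr)
  expect_match(txt, "'Hy-line(w)'", fixed = TRUE)
  expect_match(txt, "'B x'", fixed = TRUE)
  back <- ape::read.tree(text = txt)
  expect_setequal(gsub("'", "", back$tip.label), labs)
  # plain labels round-trip isomorphically with branch lengths
  withr::with_seed(331, {
    tr2 <- ape::rtree(7)
    tr2$edge.length <- runif(nrow(tr2$edge), 0.1, 1)
  })
  est <- neighborJoining(stats::cophenetic(tr2))
  back2 <- ape::read.tree(text = writeNewick(est, digits = 10))
  expect_equal(stats::cophenetic(back2)[est$tip.label, est$tip.label],
               stats::cophenetic(est), tolerance = 1e-6)
  p <- tempfile(fileext = ".nwk")
  writeNewick(est, p)
  expect_match(readLines(p), "^\\(.*\\);$")
})

test_that("diverged frequency pools separate in MDS as disjoint breed hulls", {
  fx <- makeStudyFixture(seed = 41, breedSubset = c("SIC", "PPA", "ANC"),
                         snpsPerChrom = 300, nChrom = 2)
  D <- ibsDistance(fx$dataset)
  si <- sampleInfo(fx$dataset)
  mds <- classicalMDS(D, k = 2)
  co <- mds$coordinates
  # centroid separation dwarfs within-breed spread on C1/C2
  cent <- apply(co, 2, function(x) tapply(x, si$breed, mean))
  spread <- max(vapply(unique(si$breed), function(b) {
    max(sqrt(rowSums(sweep(co[si$breed == b, , drop = FALSE], 2,
                           cent[b, ])^2)))
  }, numeric(1)))
  dmin <- min(stats::dist(cent))
  expect_gt(dmin, spread)
})
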