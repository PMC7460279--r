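# Population structure: identity-by-state distances between individuals,
# Reynolds distances between breeds, classical MDS (PCoA) and
# neighbor-joining trees with Newick serialization.

#' Identity-by-state (1 - IBS) distance matrix
#'
#' For a pair of individuals, per-marker allele-sharing similarity over
#' markers typed in both is (2 - |g_a - g_b|)/2 with codes 0/1/2; the
#' distance is 1 minus the mean similarity. Missing genotypes are removed
#' pairwise (per-pair marker sets).
#'
#' @param ds a [GenotypeDataset-class] with at least two samples.
#' @param allowMissingPairs return \code{NA} for pairs with no shared
#'   typed marker instead of erroring (default FALSE).
#' @return Symmetric numeric matrix (zero diagonal) with sample-id
#'   dimnames and attribute \code{level = "individual"}.
#' @export
ibsDistance <- function(ds, allowMissingPairs = FALSE) {
  calls <- genotypeCalls(ds)
  if (ncol(calls) < 2L) stop("need at least two samples")
  A0 <- (!is.na(calls)) & calls == 0L
  A1 <- (!is.na(calls)) & calls == 1L
  A2 <- (!is.na(calls)) & calls == 2L
  storage.mode(A0) <- storage.mode(A1) <- storage.mode(A2) <- "double"
  shared <- crossprod(A0 + A1 + A2)
  absdiff <- 2 * (crossprod(A0, A2) + crossprod(A2, A0)) +
    crossprod(A0, A1) + crossprod(A1, A0) +
    crossprod(A1, A2) + crossprod(A2, A1)
  if (any(shared == 0)) {
    if (!allowMissingPairs)
      stop("sample pair(s) share no typed marker; ",
           "set allowMissingPairs = TRUE to return NA")
  }
  d <- (absdiff / 2) / shared   # 1 - mean similarity
  d[shared == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(sampleInfo(ds)$id, sampleInfo(ds)$id)
  attr(d, "level") <- "individual"
  d
}

#' Classical multidimensional scaling (PCoA)
#'
#' Double-centers the squared distance matrix and eigendecomposes it;
#' coordinates are the top eigenvectors scaled by the square root of
#' their (positive) eigenvalues. Axes with non-positive eigenvalues are
#' excluded, reducing \code{k} with a warning when necessary.
#'
#' @param D symmetric distance matrix with dimnames.
#' @param k number of components requested (default 2).
#' @return \code{list(coordinates = <labels x k'>, eigenvalues =
#'   <k' descending>)}.
#' @export
classicalMDS <- function(D, k = 2) {
  stopifnot(k >= 1)
  res <- suppressWarnings(stats::cmdscale(stats::as.dist(D),
                                          k = min(k, nrow(D) - 1),
                                          eig = TRUE))
  ev <- res$eig
  npos <- sum(ev > 1e-12)
  if (npos == 0) {  # degenerate (e.g. all-zero distances): flat embedding
    coords <- matrix(0, nrow(as.matrix(D)), 1,
                     dimnames = list(rownames(as.matrix(D)), "C1"))
    return(list(coordinates = coords, eigenvalues = 0))
  }
  kk <- min(k, npos)
  if (kk < k)
    warning("only ", kk, " positive-eigenvalue axes available; ",
            "k reduced from ", k)
  coords <- res$points[, seq_len(kk), drop = FALSE]
  colnames(coords) <- paste0("C", seq_len(kk))
  list(coordinates = coords, eigenvalues = sort(ev, decreasing = TRUE)[seq_len(kk)])
}

#' Breed-level MDS coordinates
#'
#' The breed picture of an individual-level embedding: either the mean of
#' individual coordinates per breed (default, matching breed-average
#' plotting), or MDS of the breed-averaged distance matrix.
#'
#' @param D individual-level distance matrix.
#' @param breeds named character vector mapping individual label to breed.
#' @param k number of components.
#' @param average \code{"coordinates"} (embed then average) or
#'   \code{"distances"} (average the distance matrix per breed pair, then
#'   embed).
#' @return As [classicalMDS()], with breed labels.
#' @export
breedMds <- function(D, breeds, k = 2,
                     average = c("coordinates", "distances")) {
  average <- match.arg(average)
  stopifnot(all(rownames(D) %in% names(breeds)))
  b <- breeds[rownames(D)]
  if (average == "coordinates") {
    mds <- classicalMDS(D, k)
    coords <- apply(mds$coordinates, 2, function(x) tapply(x, b, mean))
    list(coordinates = coords, eigenvalues = mds$eigenvalues)
  } else {
    brs <- sort(unique(b))
    Db <- matrix(0, length(brs), length(brs), dimnames = list(brs, brs))
    for (i in seq_along(brs)) for (j in seq_len(i - 1)) {
      Db[i, j] <- Db[j, i] <- mean(D[b == brs[i], b == brs[j]])
    }
    classicalMDS(Db, k)
  }
}

#' Reynolds genetic distance between breeds
#'
#' The coancestry-based distance for short-term drift, computed from
#' within-breed allele frequencies at biallelic loci:
#' theta = sum_l 2 (p_x - p_y)^2 / sum_l 2 (1 - p_x p_y - q_x q_y).
#' Loci with an undefined frequency in either breed are skipped for that
#' pair. The large-sample estimator is used (no sample-size correction).
#'
#' @param ds a [GenotypeDataset-class]; every breed needs at least 2
#'   samples.
#' @param linearized report -ln(1 - theta) instead of theta.
#' @return Symmetric breed-level distance matrix with attribute
#'   \code{level = "breed"}.
#' @export
reynoldsDistance <- function(ds, linearized = FALSE) {
  brs <- sort(unique(breedLabels(ds)))
  ns <- table(breedLabels(ds))
  if (any(ns < 2)) stop("breed(s) with fewer than 2 samples: ",
                        paste(names(ns)[ns < 2], collapse = ", "))
  P <- vapply(brs, function(b) alleleFrequencies(ds, group = b),
              numeric(nMarkers(ds)))
  if (is.null(dim(P)))  # single-marker dataset: keep matrix shape
    P <- matrix(P, nrow = 1, dimnames = list(NULL, brs))
  D <- matrix(0, length(brs), length(brs), dimnames = list(brs, brs))
  for (i in seq_along(brs)) for (j in seq_len(i - 1)) {
    px <- P[, i]; py <- P[, j]
    ok <- !is.nan(px) & !is.nan(py)
    if (!any(ok)) stop("breeds ", brs[i], " and ", brs[j],
                       " share no defined locus")
    num <- sum(2 * (px[ok] - py[ok])^2)
    den <- sum(2 * (1 - px[ok] * py[ok] - (1 - px[ok]) * (1 - py[ok])))
    theta <- if (den == 0) 0 else num / den
    D[i, j] <- D[j, i] <- if (linearized) -log(1 - theta) else theta
  }
  attr(D, "level") <- "breed"
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomeration minimizing the Q criterion; exact on additive
#' distances. Negative branch-length estimates are clamped to zero with a
#' warning.
#'
#' @param D symmetric distance matrix (zero diagonal, >= 3 labels).
#' @return An unrooted \code{ape::phylo} tree.
#' @export
neighborJoining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 labels")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  tree <- ape::nj(stats::as.dist(D))
  if (any(tree$edge.length < 0)) {
    warning(sum(tree$edge.length < 0),
            " negative branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

# quote a Newick label when it contains metacharacters; single quotes in
# the label are doubled per the standard
.newickLabel <- function(x) {
  needs <- grepl("[][():;,'\" \t]", x)
  ifelse(needs, paste0("'", gsub("'", "''", x), "'"), x)
}

#' Serialize a tree to Newick text
#'
#' Labels containing Newick metacharacters are single-quoted per the
#' standard; branch lengths use 6 significant digits.
#'
#' @param tree an \code{ape::phylo} tree.
#' @param path optional output path; when given, the text is also written
#'   (with a trailing newline).
#' @param digits significant digits for branch lengths.
#' @return The Newick string, invisibly when \code{path} is given.
#' @export
writeNewick <- function(tree, path = NULL, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  rec <- function(node) {
    if (node <= ntip) return(.newickLabel(tree$tip.label[node]))
    parts <- vapply(kids[[as.character(node)]], function(e) {
      child <- tree$edge[e, 2]
      br <- if (!is.null(tree$edge.length))
        paste0(":", fmt(tree$edge.length[e])) else ""
      paste0(rec(child), br)
    }, character(1))
    lab <- if (!is.null(tree$node.label) &&
               length(tree$node.label) >= node - ntip)
      .newickLabel(tree$node.label[node - ntip]) else ""
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  txt <- paste0(rec(root), ";")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "\n")
    return(invisible(txt))
  }
  txt
}

#' Write a distance matrix as TSV or square PHYLIP
#'
#' @param D symmetric labeled distance matrix.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeDistanceTsv <- function(D, path) {
  df <- data.frame(label = rownames(D), as.data.frame(D),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname writeDistanceTsv
#' @export
writeDistancePhylip <- function(D, path) {
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i) {
               paste0(formatC(rownames(D)[i], width = -10),
                      paste(formatC(D[i, ], digits = 6, format = "f"),
                            collapse = " "))
             }, character(1)))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
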