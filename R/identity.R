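#' Allelic mismatch between two diploid calls
#'
#' `2 - |multiset intersection|` of the two unordered allele pairs: 0 for
#' identical genotypes, 1 when exactly one allele copy is shared (e.g.
#' homozygote vs heterozygote carrying that allele), 2 when nothing is
#' shared.
#'
#' @param call1,call2 character or numeric vectors of length 2 (the two
#'   alleles of each call).
#' @return integer in 0..2.
#' @examples
#' alleleMismatch(c("A", "A"), c("A", "B"))  # 1
#' @export
alleleMismatch <- function(call1, call2) {
  stopifnot(length(call1) == 2L, length(call2) == 2L)
  if (anyNA(call1) || anyNA(call2))
    stop("alleleMismatch requires non-missing calls")
  x <- sort(as.character(call1))
  y <- sort(as.character(call2))
  shared <- 0L
  for (al in x) {
    i <- match(al, y)
    if (!is.na(i)) {
      shared <- shared + 1L
      y <- y[-i]
    }
  }
  2L - shared
}

## Vectorised multiset mismatch over loci for two sorted pairs
## (a1 <= a2, b1 <= b2): intersection size by merge-style case analysis.
pairMismatchVec <- function(a1, a2, b1, b2) {
  eq <- a1 == b1 & a2 == b2
  one <- !eq & ((a1 == b1) | (a1 == b2) | (a2 == b1) | (a2 == b2))
  ifelse(eq, 0L, ifelse(one, 1L, 2L))
}

#' Mismatch-tolerant multilocus identity analysis
#'
#' All unordered accession pairs are compared locus by locus (only loci
#' non-missing in both members count); a pair "matches at threshold t"
#' when its total allelic mismatch is <= t and it shares at least
#' `minSharedLoci` comparable loci. Accessions matching no other accession
#' at t = 0 carry unique multilocus profiles.
#'
#' @param x a [GenotypeMatrix-class] with >= 2 accessions.
#' @param maxMismatch largest mismatch allowance reported (default 5).
#' @param minSharedLoci minimum comparable loci for a pair to be judged at
#'   all (default 10); pairs below it are listed as incomparable, never as
#'   matches.
#' @return list of class `identityReport`: `pairs` (per-pair shared-locus
#'   and mismatch counts), `matchCounts` (named vector, matching pairs at
#'   t = 0..maxMismatch), `nUniqueProfiles`, `incomparablePairs`.
#' @export
identityAnalysis <- function(x, maxMismatch = 5L, minSharedLoci = 10L) {
  n <- nAccessions(x)
  if (n < 2L) stop("identity analysis needs at least two accessions")
  ids <- accessionIds(x)
  A <- x@alleleA
  B <- x@alleleB
  pairs <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !is.na(A[i, ]) & !is.na(A[j, ])
      mm <- if (any(ok))
        sum(pairMismatchVec(A[i, ok], B[i, ok], A[j, ok], B[j, ok]))
      else 0L
      k <- k + 1L
      pairs[[k]] <- data.frame(id1 = ids[i], id2 = ids[j],
                               shared_loci = sum(ok), mismatches = mm,
                               stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)
  comparable <- pairs$shared_loci >= minSharedLoci
  thr <- 0:maxMismatch
  counts <- vapply(thr, function(t)
    sum(comparable & pairs$mismatches <= t), integer(1))
  names(counts) <- paste0("t", thr)
  matched0 <- pairs[comparable & pairs$mismatches == 0L, , drop = FALSE]
  nonUnique <- unique(c(matched0$id1, matched0$id2))
  structure(list(
    pairs = pairs[comparable, , drop = FALSE],
    matchCounts = counts,
    nUniqueProfiles = n - length(nonUnique),
    incomparablePairs = pairs[!comparable, , drop = FALSE]
  ), class = "identityReport")
}

#' @export
print.identityReport <- function(x, ...) {
  cat("Identity analysis:", x$nUniqueProfiles, "unique profiles\n")
  cat("  matching pairs at t =",
      paste(names(x$matchCounts), x$matchCounts, sep = ":",
            collapse = ", "), "\n")
  if (nrow(x$incomparablePairs))
    cat("  incomparable pairs (too few shared loci):",
        nrow(x$incomparablePairs), "\n")
  invisible(x)
}

#' Probability of identity across independent loci
#'
#' Per locus, the probability that two random individuals share a genotype
#' under Hardy-Weinberg expectations,
#' `pID_l = sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2`, multiplied across loci;
#' and the sibling variant
#' `pIDsib_l = 0.25 + 0.5 S2 + 0.5 S2^2 - 0.25 S4` (S2, S4 the second and
#' fourth frequency moments), appropriate when compared individuals may be
#' close relatives, as bred cultivar panels typically are.
#'
#' @param x a [GenotypeMatrix-class] (frequencies computed per locus over
#'   `accessions`), or a list of numeric allele-frequency vectors.
#' @param accessions optional accession subset when `x` is a matrix.
#' @return list: `perLocus` data.frame (`locus`, `pID`, `pIDsib`),
#'   `pID`, `pIDsib` (products across loci).
#' @export
pIdentity <- function(x, accessions = NULL) {
  freqs <- if (is(x, "GenotypeMatrix")) {
    fl <- lapply(lociNames(x), function(loc)
      alleleFrequencies(x, loc, accessions)$freq)
    names(fl) <- lociNames(x)
    fl
  } else if (is.list(x)) x
  else stop("x must be a GenotypeMatrix or a list of frequency vectors")
  if (length(freqs) == 0L) stop("empty locus set")
  per <- do.call(rbind, lapply(seq_along(freqs), function(i) {
    p <- freqs[[i]]
    s2 <- sum(p^2)
    s4 <- sum(p^4)
    data.frame(
      locus = if (is.null(names(freqs))) paste0("L", i) else names(freqs)[i],
      pID = 2 * s2^2 - s4,
      pIDsib = 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4,
      stringsAsFactors = FALSE)
  }))
  list(perLocus = per, pID = prod(per$pID), pIDsib = prod(per$pIDsib))
}
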