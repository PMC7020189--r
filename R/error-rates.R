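#' Genotyping error rates between reference and replicate datasets
#'
#' Per-locus concordance between a reference typing and a replicate typing
#' of the same accessions, following the per-allele / per-locus error-rate
#' convention of Pompanon et al.: with `m_a` allelic mismatches, `m_l`
#' single-locus genotypes carrying at least one mismatch, `n` genotypes
#' compared and `t` replicate typings,
#' `e_a = m_a / (2 n t)` and `e_l = m_l / (n t)`.
#'
#' Accounting per accession and locus: typed in both datasets contributes
#' its allelic mismatch count; typed in exactly one dataset is an
#' amplification failure and counts as a full locus error (`m_l + 1`,
#' `m_a + 2`), since amplification failure is the dominant error source in
#' cross-species replication; missing in both is excluded from `n`.
#' Mean rates are unweighted means over loci.
#'
#' @param reference,replicate [GenotypeMatrix-class] objects sharing
#'   accession ids and loci.
#' @param t number of replicate typings per genotype (default 1).
#' @return list of class `errorReport`: `perLocus` data.frame (`locus`,
#'   `n`, `m_a`, `m_l`, `e_a`, `e_l`), `meanEa`, `meanEl`, `t`.
#' @export
errorRates <- function(reference, replicate, t = 1L) {
  ids <- intersect(accessionIds(reference), accessionIds(replicate))
  if (length(ids) == 0L)
    stop("reference and replicate share no accession ids")
  loci <- intersect(lociNames(reference), lociNames(replicate))
  if (length(loci) == 0L)
    stop("reference and replicate share no loci")
  ref <- reference[ids, loci]
  rep_ <- replicate[ids, loci]
  per <- lapply(loci, function(loc) {
    ra <- ref@alleleA[, loc]; rb <- ref@alleleB[, loc]
    pa <- rep_@alleleA[, loc]; pb <- rep_@alleleB[, loc]
    refMiss <- is.na(ra)
    repMiss <- is.na(pa)
    both <- !refMiss & !repMiss
    oneOnly <- xor(refMiss, repMiss)
    n <- sum(both) + sum(oneOnly)
    mm <- if (any(both))
      pairMismatchVec(ra[both], rb[both], pa[both], pb[both])
    else integer()
    m_a <- sum(mm) + 2L * sum(oneOnly)
    m_l <- sum(mm > 0L) + sum(oneOnly)
    data.frame(locus = loc, n = n, m_a = m_a, m_l = m_l,
               e_a = if (n > 0) m_a / (2 * n * t) else NA_real_,
               e_l = if (n > 0) m_l / (n * t) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(perLocus = per,
                 meanEa = mean(per$e_a, na.rm = TRUE),
                 meanEl = mean(per$e_l, na.rm = TRUE),
                 t = t),
            class = "errorReport")
}

#' @export
print.errorReport <- function(x, ...) {
  cat(sprintf("Error report over %d loci (t = %d):\n",
              nrow(x$perLocus), x$t))
  cat(sprintf("  mean e_a = %.4f%%, mean e_l = %.4f%%\n",
              100 * x$meanEa, 100 * x$meanEl))
  rng <- range(x$perLocus$e_a, na.rm = TRUE)
  cat(sprintf("  per-locus e_a range: %.4f%% - %.4f%%\n",
              100 * rng[1], 100 * rng[2]))
  invisible(x)
}
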