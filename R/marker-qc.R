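#' Marker quality-control screen
#'
#' Applies the three rejection rules used when selecting single-locus,
#' codominant SSR markers for an autogamous crop:
#' \describe{
#'   \item{MULTIPEAK}{any sample produced three or more peaks at the
#'     locus, indicating co-amplification of multiple loci;}
#'   \item{LOW_POLYMORPHISM}{fewer than `minAlleles` alleles within the
#'     focal accession group (default 3);}
#'   \item{IMPLAUSIBLE_HET}{heterozygote fraction above
#'     `maxHetFraction` (default 0.5) in the focal group — for highly
#'     homozygous inbred varieties a locus where all or almost all plants
#'     look heterozygous is far more likely to amplify two loci at once
#'     than to be genuinely heterozygous.}
#' }
#'
#' @param x a [GenotypeMatrix-class].
#' @param peaks optional peak table ([readPeakTable()]) used for the
#'   MULTIPEAK rule; omit when only genotype-level rules are wanted.
#' @param focalAccessions accession ids of the focal group (default: all
#'   accessions).
#' @param minAlleles minimum allele count per marker (default 3).
#' @param maxHetFraction maximum plausible heterozygote fraction
#'   (default 0.5).
#' @return data.frame: `locus`, `k`, `hetFraction`, `pass`, `reasons`
#'   (comma-joined failure codes, empty when passing).
#' @export
markerQC <- function(x, peaks = NULL, focalAccessions = NULL,
                     minAlleles = 3L, maxHetFraction = 0.5) {
  if (is.null(focalAccessions)) focalAccessions <- accessionIds(x)
  if (length(focalAccessions) == 0L) stop("focal group is empty")
  multipeakLoci <- character()
  if (!is.null(peaks)) {
    npk <- vapply(peaks$sizes, length, integer(1))
    multipeakLoci <- unique(peaks$locus[npk >= 3L])
  }
  rows <- lapply(lociNames(x), function(loc) {
    a <- x@alleleA[focalAccessions, loc]
    b <- x@alleleB[focalAccessions, loc]
    keep <- !is.na(a)
    k <- length(unique(c(a[keep], b[keep])))
    het <- if (any(keep)) sum(a[keep] != b[keep]) / sum(keep) else NA_real_
    reasons <- character()
    if (loc %in% multipeakLoci) reasons <- c(reasons, "MULTIPEAK")
    if (k < minAlleles) reasons <- c(reasons, "LOW_POLYMORPHISM")
    if (!is.na(het) && het > maxHetFraction)
      reasons <- c(reasons, "IMPLAUSIBLE_HET")
    data.frame(locus = loc, k = k, hetFraction = het,
               pass = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
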