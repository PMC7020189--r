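## Column layout shared by both encodings: one column per observed
## (locus, allele), named "locus:allele", alleles in numeric-aware order.
alleleColumns <- function(x) {
  lapply(lociNames(x), function(loc) {
    al <- unique(c(x@alleleA[, loc], x@alleleB[, loc]))
    al <- al[!is.na(al)]
    al[order(suppressWarnings(as.numeric(al)), al, na.last = TRUE)]
  })
}

encodeAlleles <- function(x, hetValue) {
  cols <- alleleColumns(x)
  loci <- lociNames(x)
  n <- nAccessions(x)
  blocks <- vector("list", length(loci))
  for (l in seq_along(loci)) {
    al <- cols[[l]]
    M <- matrix(0, n, length(al),
                dimnames = list(accessionIds(x),
                                paste(loci[l], al, sep = ":")))
    a <- x@alleleA[, l]
    b <- x@alleleB[, l]
    for (r in which(!is.na(a))) {
      if (a[r] == b[r]) {
        M[r, match(a[r], al)] <- 1
      } else {
        M[r, match(a[r], al)] <- hetValue
        M[r, match(b[r], al)] <- hetValue
      }
    }
    blocks[[l]] <- M
  }
  out <- do.call(cbind, blocks)
  attr(out, "missing") <- missingCalls(x)
  attr(out, "lociBlocks") <- rep(loci, vapply(cols, length, integer(1)))
  out
}

#' Binary allele presence/absence encoding
#'
#' One column per observed (locus, allele); an accession scores 1 for each
#' allele present in its genotype (so heterozygotes carry two 1s per
#' locus, homozygotes one). Missing loci leave all of that locus's columns
#' 0 and are flagged in the `missing` attribute.
#'
#' @param x a [GenotypeMatrix-class].
#' @return numeric matrix (accessions x allele columns) with attributes
#'   `missing` (logical accessions x loci) and `lociBlocks` (locus of each
#'   column).
#' @export
encodeBinary <- function(x) encodeAlleles(x, hetValue = 1)

#' Trinary allele-frequency encoding
#'
#' Same layout as [encodeBinary()], but each allele column carries the
#' within-genotype allele frequency: 1 for a homozygote's allele, 0.5 for
#' each allele of a heterozygote, so every non-missing locus block sums
#' to 1 per accession. This is the conventional input encoding for PCA of
#' codominant SSR genotypes.
#'
#' @inheritParams encodeBinary
#' @return numeric matrix with the same attributes as [encodeBinary()].
#' @export
encodeTrinary <- function(x) encodeAlleles(x, hetValue = 0.5)
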