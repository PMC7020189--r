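#' GenotypeMatrix: codominant diploid SSR genotypes
#'
#' Accessions-by-loci container of unordered diploid allele pairs, with
#' per-accession metadata (id, species, group). Alleles are locus-scoped
#' character labels (conventionally nominal fragment sizes in bp);
#' homozygotes carry the same label twice; a missing call has `NA` in both
#' allele slots. Pairs are stored sorted (numeric-aware) so that unordered
#' comparison reduces to componentwise comparison.
#'
#' @slot alleleA character matrix (accessions x loci), first allele of each
#'   sorted pair, `NA` = missing.
#' @slot alleleB character matrix, second allele, `NA` pattern identical to
#'   `alleleA`.
#' @slot accessions data.frame with at least columns `id`, `species`,
#'   `group`; one row per accession, ids unique, order matches the matrix
#'   rows.
#' @export
setClass("GenotypeMatrix",
  slots = c(
    alleleA = "matrix",
    alleleB = "matrix",
    accessions = "data.frame"
  )
)

setValidity("GenotypeMatrix", function(object) {
  a <- object@alleleA
  b <- object@alleleB
  acc <- object@accessions
  msg <- character()
  if (!is.character(a) || !is.character(b))
    msg <- c(msg, "allele slots must be character matrices")
  if (!identical(dim(a), dim(b)))
    msg <- c(msg, "alleleA and alleleB dimensions differ")
  need <- c("id", "species", "group")
  if (!all(need %in% names(acc)))
    msg <- c(msg, "accessions must have columns id, species, group")
  else {
    if (anyDuplicated(acc$id))
      msg <- c(msg, "duplicated accession ids")
    if (nrow(acc) != nrow(a))
      msg <- c(msg, "accession table and allele matrices disagree on rows")
  }
  if (length(msg) == 0L && !identical(is.na(a), is.na(b)))
    msg <- c(msg, "half-missing call: one of two alleles is NA")
  if (length(msg)) msg else TRUE
})

#' AllelicLadder: reference allele sizes for one SSR locus
#'
#' Ordered nominal allele sizes (bp) against which observed fragment sizes
#' are binned. `step` is the expected inter-allele spacing (3 bp for
#' trinucleotide repeats); `tolerance` is the maximum |observed - nominal|
#' accepted during binning and must stay below half the step so bins cannot
#' overlap.
#'
#' @slot locus character(1) locus name.
#' @slot sizes numeric, strictly increasing nominal sizes in bp.
#' @slot step numeric(1), expected spacing in bp.
#' @slot tolerance numeric(1), assignment tolerance in bp.
#' @export
setClass("AllelicLadder",
  slots = c(
    locus = "character",
    sizes = "numeric",
    step = "numeric",
    tolerance = "numeric"
  )
)

setValidity("AllelicLadder", function(object) {
  msg <- character()
  if (length(object@sizes) < 1L)
    msg <- c(msg, "ladder needs at least one nominal size")
  if (any(object@sizes <= 0))
    msg <- c(msg, "nominal sizes must be positive")
  if (is.unsorted(object@sizes, strictly = TRUE))
    msg <- c(msg, "nominal sizes must be strictly increasing")
  if (length(object@tolerance) != 1L || object@tolerance <= 0)
    msg <- c(msg, "tolerance must be a single positive number")
  else if (length(object@step) == 1L && object@tolerance >= object@step / 2)
    msg <- c(msg, "tolerance must be < step/2")
  if (length(msg)) msg else TRUE
})

#' TransferabilityMatrix: two-laboratory amplification calls
#'
#' Boolean marker x species x lab array recording whether each marker
#' produced a scorable amplicon in each species in each laboratory. The
#' consensus call used for reporting is the AND over laboratories: a marker
#' counts as transferable to a species only when every lab amplified it.
#'
#' @slot amplified logical 3-d array, dims marker x species x lab with
#'   dimnames.
#' @slot genera named character vector mapping each species to its genus
#'   (used for across-genera summaries); may be empty.
#' @export
setClass("TransferabilityMatrix",
  slots = c(
    amplified = "array",
    genera = "character"
  )
)

setValidity("TransferabilityMatrix", function(object) {
  a <- object@amplified
  msg <- character()
  if (!is.logical(a) || length(dim(a)) != 3L)
    msg <- c(msg, "amplified must be a logical 3-d array (marker x species x lab)")
  else if (is.null(dimnames(a)) || any(vapply(dimnames(a), is.null, logical(1))))
    msg <- c(msg, "amplified needs complete dimnames")
  if (length(object@genera) &&
      !all(dimnames(a)[[2]] %in% names(object@genera)))
    msg <- c(msg, "genera map does not cover all species")
  if (length(msg)) msg else TRUE
})
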