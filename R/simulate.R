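#' Configuration for the synthetic genotype generator
#'
#' Defines the statistical structure the simulator emulates: a panel of
#' trinucleotide SSR loci with fixed per-locus allele counts, allele
#' frequencies drawn from a symmetric Dirichlet, and an accession-level
#' homozygosity model for autogamous cultivar panels — an accession is
#' fully homozygous at every locus with probability `piHomo` (default
#' 0.71, the fraction observed in inbred poppy variety panels), and
#' residual heterozygotes carry heterozygous calls at only one or two loci
#' (probabilities 0.6 / 0.4). Isoline pairs are exact profile copies;
#' error injection and two-lab transferability panels have their own
#' parameters.
#'
#' @param nLoci number of loci (default 17).
#' @param alleleCounts per-locus allele numbers; defaults to the published
#'   all-accessions k column of [opestAlleleCounts()] so simulated
#'   summaries live on the same scale as the real panel.
#' @param alpha symmetric Dirichlet concentration for allele frequencies
#'   (default 1: uniform over the simplex).
#' @param piHomo probability an accession is homozygous at all loci
#'   (default 0.71).
#' @param hetLociProbs probabilities that a residual heterozygote is
#'   heterozygous at 1, 2, ... loci (default c(0.6, 0.4)).
#' @param nIsolinePairs accession pairs duplicated verbatim (default 3,
#'   matching the number of indistinguishable variety pairs a 47-accession
#'   cultivar panel produced).
#' @param epsSub per-allele substitution rate for [injectErrors()].
#' @param epsFail per-genotype amplification-failure rate for
#'   [injectErrors()].
#' @param sizeRange allele size window in bp (default 100-300, the
#'   fragment-analysis design window).
#' @param step allele spacing in bp (3 for trinucleotide repeats).
#' @return list of class `simulationConfig`.
#' @export
simulationConfig <- function(nLoci = 17L,
                             alleleCounts = opestAlleleCounts()$k_all,
                             alpha = 1,
                             piHomo = 0.71,
                             hetLociProbs = c(0.6, 0.4),
                             nIsolinePairs = 3L,
                             epsSub = 0,
                             epsFail = 0,
                             sizeRange = c(100, 300),
                             step = 3) {
  if (length(alleleCounts) == 1L)
    alleleCounts <- rep(alleleCounts, nLoci)
  if (length(alleleCounts) != nLoci)
    stop("alleleCounts length must equal nLoci")
  if (any(alleleCounts < 1L)) stop("allele counts must be >= 1")
  probs <- c(piHomo, epsSub, epsFail)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(hetLociProbs < 0) || abs(sum(hetLociProbs) - 1) > 1e-9)
    stop("hetLociProbs must be a probability vector summing to 1")
  markers <- if (identical(alleleCounts, opestAlleleCounts()$k_all))
    opestAlleleCounts()$marker else sprintf("SSR%02d", seq_len(nLoci))
  structure(list(nLoci = as.integer(nLoci), alleleCounts = alleleCounts,
                 markers = markers, alpha = alpha, piHomo = piHomo,
                 hetLociProbs = hetLociProbs,
                 nIsolinePairs = as.integer(nIsolinePairs),
                 epsSub = epsSub, epsFail = epsFail,
                 sizeRange = sizeRange, step = step),
            class = "simulationConfig")
}

## Safe weighted sampling: never falls into sample()'s scalar-x trap.
sampleFrom <- function(v, n = 1L, prob = NULL, replace = FALSE) {
  v[sample.int(length(v), n, replace = replace, prob = prob)]
}

rdirichlet1 <- function(k, alpha) {
  g <- rgamma(k, shape = alpha)
  while (sum(g) == 0) g <- rgamma(k, shape = alpha)
  g / sum(g)
}

#' Simulate an SSR marker panel
#'
#' For each locus draws k allele labels on a 3-bp ladder inside the
#' configured size window, plus an allele-frequency vector from the
#' symmetric Dirichlet. Pure function of (config, seed).
#'
#' @param config a [simulationConfig()].
#' @param seed integer RNG seed (required).
#' @return list of class `ssrPanel`; one element per locus with fields
#'   `locus`, `sizes` (allele labels in bp) and `freq`.
#' @export
simulatePanel <- function(config, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  loci <- lapply(seq_len(config$nLoci), function(l) {
    k <- config$alleleCounts[l]
    maxBase <- config$sizeRange[2] - config$step * (k - 1)
    if (maxBase < config$sizeRange[1])
      stop("locus ", l, ": ", k, " alleles at ", config$step,
           "-bp spacing exceed the size range")
    base <- sample(seq(config$sizeRange[1], maxBase), 1L)
    list(locus = config$markers[l],
         sizes = base + config$step * (seq_len(k) - 1L),
         freq = rdirichlet1(k, config$alpha))
  })
  names(loci) <- config$markers
  structure(loci, class = "ssrPanel")
}

#' @export
print.ssrPanel <- function(x, ...) {
  cat("ssrPanel:", length(x), "loci, k =",
      paste(vapply(x, function(l) length(l$sizes), integer(1)),
            collapse = ","), "\n")
  invisible(x)
}

#' Shift a panel's allele pools
#'
#' Offsets every allele size by a constant, producing a (partially or
#' fully) disjoint allele pool — the device used to emulate species-level
#' divergence when testing whether multivariate analyses separate species.
#'
#' @param panel an `ssrPanel`.
#' @param offset size shift in bp (use a multiple of the panel step to
#'   stay on-ladder; a large offset makes pools fully disjoint).
#' @return the shifted `ssrPanel`.
#' @export
shiftPanel <- function(panel, offset) {
  out <- lapply(panel, function(l) {
    l$sizes <- l$sizes + offset
    l
  })
  structure(out, class = "ssrPanel")
}

#' Simulate a cultivar genotype panel
#'
#' Each accession is fully homozygous at every locus with probability
#' `piHomo` (each locus one allele drawn from the panel frequencies,
#' doubled); otherwise it is heterozygous at a small number of loci drawn
#' from `hetLociProbs` (two distinct alleles at those loci) and homozygous
#' elsewhere. The last `nIsolinePairs` accessions are verbatim copies of
#' the first `nIsolinePairs` profiles under new ids, emulating isolines /
#' duplicated varieties. Pure function of (panel, config, seed).
#'
#' @param panel an `ssrPanel` from [simulatePanel()].
#' @param config a [simulationConfig()].
#' @param nAccessions panel size (default 47).
#' @param seed integer RNG seed (required).
#' @param species,group metadata labels attached to every accession.
#' @param idPrefix accession id prefix.
#' @return a [GenotypeMatrix-class].
#' @export
simulateGenotypes <- function(panel, config, nAccessions = 47L, seed,
                              species = "P. somniferum",
                              group = "culinary", idPrefix = "ACC") {
  if (missing(seed)) stop("seed is required")
  nIso <- config$nIsolinePairs
  if (2L * nIso > nAccessions)
    stop("isoline pairs require 2 * nIsolinePairs <= nAccessions")
  set.seed(seed)
  nFresh <- nAccessions - nIso
  L <- length(panel)
  hetEligible <- which(vapply(panel, function(l) length(l$sizes) > 1L,
                              logical(1)))
  a <- matrix(NA_character_, nAccessions, L,
              dimnames = list(NULL, names(panel)))
  b <- a
  for (i in seq_len(nFresh)) {
    hom <- vapply(panel, function(l)
      as.character(sampleFrom(l$sizes, 1L, prob = l$freq)), character(1))
    a[i, ] <- hom
    b[i, ] <- hom
    if (runif(1) >= config$piHomo && length(hetEligible)) {
      nHet <- sample.int(length(config$hetLociProbs), 1L,
                         prob = config$hetLociProbs)
      nHet <- min(nHet, length(hetEligible))
      hetLoci <- sampleFrom(hetEligible, nHet)
      for (l in hetLoci) {
        al <- sampleFrom(panel[[l]]$sizes, 2L, prob = panel[[l]]$freq)
        a[i, l] <- as.character(al[1])
        b[i, l] <- as.character(al[2])
      }
    }
  }
  if (nIso > 0L) {
    copyOf <- seq_len(nIso)
    a[nFresh + copyOf, ] <- a[copyOf, , drop = FALSE]
    b[nFresh + copyOf, ] <- b[copyOf, , drop = FALSE]
  }
  ids <- sprintf("%s%03d", idPrefix, seq_len(nAccessions))
  GenotypeMatrix(a, b, data.frame(id = ids, species = species,
                                  group = group, stringsAsFactors = FALSE))
}

#' Inject genotyping errors into a replicate dataset
#'
#' Independently per genotype: with probability `epsFail` the call is set
#' missing (amplification failure); otherwise each allele is substituted,
#' with probability `epsSub`, by a uniformly drawn different allele of the
#' same locus. Allele pools come from `panel` when given, else from the
#' alleles observed in `x`. Pure function of (x, rates, seed).
#'
#' @param x a [GenotypeMatrix-class] (the reference dataset).
#' @param epsSub per-allele substitution probability.
#' @param epsFail per-genotype failure probability.
#' @param seed integer RNG seed (required).
#' @param panel optional `ssrPanel` supplying per-locus allele pools.
#' @return the replicate [GenotypeMatrix-class].
#' @export
injectErrors <- function(x, epsSub, epsFail, seed, panel = NULL) {
  if (epsSub < 0 || epsSub > 1 || epsFail < 0 || epsFail > 1)
    stop("error rates must lie in [0, 1]")
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  a <- x@alleleA
  b <- x@alleleB
  loci <- lociNames(x)
  pools <- if (!is.null(panel))
    lapply(loci, function(loc) as.character(panel[[loc]]$sizes))
  else
    lapply(loci, function(loc) {
      al <- unique(c(a[, loc], b[, loc]))
      al[!is.na(al)]
    })
  names(pools) <- loci
  for (l in seq_along(loci)) {
    typed <- which(!is.na(a[, l]))
    if (length(typed) == 0L) next
    fail <- typed[runif(length(typed)) < epsFail]
    a[fail, l] <- NA_character_
    b[fail, l] <- NA_character_
    live <- setdiff(typed, fail)
    pool <- pools[[l]]
    if (epsSub > 0 && length(pool) > 1L) {
      for (i in live) {
        if (runif(1) < epsSub)
          a[i, l] <- sampleFrom(setdiff(pool, a[i, l]), 1L)
        if (runif(1) < epsSub)
          b[i, l] <- sampleFrom(setdiff(pool, b[i, l]), 1L)
      }
    }
  }
  GenotypeMatrix(a, b, x@accessions)
}

#' Simulate a two-laboratory transferability panel
#'
#' Draws marker x species amplification indicators with per-species
#' probabilities, then derives the second laboratory from the first by
#' flipping each call independently with probability `labDiscordance`,
#' exercising the AND-consensus reporting rule. Pure function of
#' (arguments, seed).
#'
#' @param markers marker names.
#' @param speciesProbs named numeric vector: per-species amplification
#'   probability.
#' @param labDiscordance probability a lab-2 call differs from lab 1
#'   (default 0).
#' @param seed integer RNG seed (required).
#' @param genera optional named character vector species -> genus.
#' @return a [TransferabilityMatrix-class] with labs "lab1", "lab2".
#' @export
simulateTransferability <- function(markers, speciesProbs,
                                    labDiscordance = 0, seed,
                                    genera = character()) {
  if (missing(seed)) stop("seed is required")
  if (labDiscordance < 0 || labDiscordance > 1)
    stop("labDiscordance must lie in [0, 1]")
  set.seed(seed)
  nM <- length(markers)
  sp <- names(speciesProbs)
  lab1 <- vapply(speciesProbs, function(p) runif(nM) < p,
                 logical(nM))
  flip <- matrix(runif(nM * length(sp)) < labDiscordance, nM)
  lab2 <- xor(lab1, flip)
  amp <- array(c(lab1, lab2), dim = c(nM, length(sp), 2L),
               dimnames = list(markers, sp, c("lab1", "lab2")))
  TransferabilityMatrix(amp, genera)
}
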