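#' Construct a TransferabilityMatrix
#'
#' @param amplified logical 3-d array marker x species x lab, with
#'   dimnames.
#' @param genera optional named character vector species -> genus.
#' @return A [TransferabilityMatrix-class].
#' @export
TransferabilityMatrix <- function(amplified, genera = character()) {
  new("TransferabilityMatrix", amplified = amplified, genera = genera)
}

#' @export
setMethod("show", "TransferabilityMatrix", function(object) {
  d <- dim(object@amplified)
  cat("TransferabilityMatrix:", d[1], "markers x", d[2], "species x",
      d[3], "labs\n")
  cons <- consensusAmplification(object)
  cat("  consensus amplifying calls per species:",
      paste(colnames(cons), colSums(cons), sep = ":", collapse = ", "),
      "\n")
})

#' Consensus amplification over laboratories
#'
#' A marker counts as amplifying in a species only when every laboratory
#' scored it as amplifying there (logical AND) — the conservative
#' reporting rule for cross-species transferability.
#'
#' @param tm a [TransferabilityMatrix-class].
#' @return logical marker x species matrix.
#' @export
consensusAmplification <- function(tm) {
  apply(tm@amplified, c(1, 2), all)
}

#' Read a long-format transferability CSV
#'
#' Columns `marker`, `species`, `lab`, `amplified` (0/1 or TRUE/FALSE) and
#' optionally `genus`. Missing marker x species x lab combinations default
#' to non-amplifying.
#'
#' @param path CSV file path.
#' @return A [TransferabilityMatrix-class].
#' @export
readTransferability <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker", "species", "lab", "amplified")
  if (!all(need %in% names(df)))
    stop("transferability file ", path, ": need columns ",
         paste(need, collapse = ", "))
  markers <- unique(df$marker)
  species <- unique(df$species)
  labs <- unique(df$lab)
  amp <- array(FALSE, dim = c(length(markers), length(species), length(labs)),
               dimnames = list(markers, species, labs))
  amp[cbind(match(df$marker, markers), match(df$species, species),
            match(df$lab, labs))] <- as.logical(as.numeric(df$amplified))
  genera <- character()
  if ("genus" %in% names(df)) {
    genera <- vapply(species, function(sp)
      df$genus[match(sp, df$species)], character(1))
  }
  TransferabilityMatrix(amp, genera)
}

#' Summarise cross-species marker transferability
#'
#' From the lab-consensus amplification matrix, reports the per-species
#' amplifying-marker counts and, over a focal species set (conventionally
#' the congeneric species of the source genus), the percentage of markers
#' amplifying in all focal species, in all but one, in at least two, and
#' in at least one; plus the percentage amplifying across genera (at least
#' one consensus call in every genus of the genera map). Percentages are
#' rounded to 2 decimals.
#'
#' @param tm a [TransferabilityMatrix-class].
#' @param focalSpecies character vector of focal species names.
#' @return list: `nMarkers`, `perSpecies` (named counts),
#'   `pctAllFocal`, `pctAllButOneFocal`, `pctAtLeastTwoFocal`,
#'   `pctAtLeastOneFocal`, `pctCrossGenera` (NA when no genera map).
#' @export
transferabilitySummary <- function(tm, focalSpecies) {
  cons <- consensusAmplification(tm)
  if (!all(focalSpecies %in% colnames(cons)))
    stop("unknown focal species: ",
         paste(setdiff(focalSpecies, colnames(cons)), collapse = ", "))
  nM <- nrow(cons)
  nf <- length(focalSpecies)
  hits <- rowSums(cons[, focalSpecies, drop = FALSE])
  pct <- function(count) round(100 * count / nM, 2)
  crossGenera <- NA_real_
  if (length(tm@genera)) {
    genus <- tm@genera[colnames(cons)]
    inEveryGenus <- apply(cons, 1, function(row)
      all(vapply(split(row, genus), any, logical(1))))
    crossGenera <- pct(sum(inEveryGenus))
  }
  list(nMarkers = nM,
       perSpecies = colSums(cons),
       pctAllFocal = pct(sum(hits == nf)),
       pctAllButOneFocal = pct(sum(hits >= nf - 1L)),
       pctAtLeastTwoFocal = pct(sum(hits >= 2L)),
       pctAtLeastOneFocal = pct(sum(hits >= 1L)),
       pctCrossGenera = crossGenera)
}

#' Reference transferability pattern of the 17-marker panel
#'
#' A two-laboratory [TransferabilityMatrix-class] encoding the reported
#' cross-species amplification pattern of the OPEST/OPGSSR panel:
#' per-congener amplifying-marker counts 13 (*P. nudicaule*),
#' 10 (*P. orientale*), 9 (*P. glaucum*), 8 (*P. rhoeas*) and
#' 2 (*A. mexicana*); five markers amplifying in all four *Papaver*
#' congeners (29.41%); two markers crossing the *Papaver*/*Argemone*
#' genus boundary (11.76%); OPEST099 amplifying in every species and
#' OPEST156 strictly specific to *P. somniferum*. The exact marker-by-
#' species assignment of the remaining markers is reconstructed to match
#' those published counts (the full table is not public), so this object
#' is a count-faithful synthetic reconstruction, with both laboratories
#' concordant.
#'
#' @return A [TransferabilityMatrix-class] (17 markers x 6 species x
#'   2 labs).
#' @export
referenceTransferability <- function() {
  markers <- opestAlleleCounts()$marker
  species <- c("P. somniferum", "P. nudicaule", "P. orientale",
               "P. glaucum", "P. rhoeas", "A. mexicana")
  pattern <- rbind(
    OPEST026  = c(1, 1, 1, 1, 0, 0),
    OPEST048c = c(1, 1, 1, 1, 0, 1),
    OPEST051c = c(1, 1, 1, 0, 0, 0),
    OPEST053c = c(1, 1, 1, 1, 1, 0),
    OPEST061  = c(1, 1, 1, 0, 0, 0),
    OPEST081c = c(1, 1, 1, 0, 0, 0),
    OPEST086d = c(1, 1, 0, 0, 1, 0),
    OPEST099  = c(1, 1, 1, 1, 1, 1),
    OPEST102b = c(1, 1, 1, 1, 1, 0),
    OPEST106  = c(1, 1, 0, 0, 1, 0),
    OPEST120b = c(1, 1, 1, 1, 1, 0),
    OPEST126b = c(1, 1, 0, 0, 1, 0),
    OPEST131  = c(1, 1, 1, 1, 1, 0),
    OPEST156  = c(1, 0, 0, 0, 0, 0),
    OPEST169  = c(1, 0, 0, 1, 0, 0),
    OPEST177b = c(1, 0, 0, 1, 0, 0),
    OPGSSR001 = c(1, 0, 0, 0, 0, 0)
  ) == 1
  stopifnot(identical(rownames(pattern), markers))
  colnames(pattern) <- species
  amp <- array(pattern, dim = c(length(markers), length(species), 2L),
               dimnames = list(markers, species, c("DGB", "CRI")))
  genera <- c("Papaver", "Papaver", "Papaver", "Papaver", "Papaver",
              "Argemone")
  names(genera) <- species
  TransferabilityMatrix(amp, genera)
}
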