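#' Read a peak-size table
#'
#' CSV with columns `accession`, `locus`, `lab`, `sizes`, where `sizes` is a
#' semicolon-separated list of called fragment sizes in bp (empty for
#' amplification failure).
#'
#' @param path CSV file path.
#' @return data.frame with a list-column `sizes` of numeric vectors.
#' @export
readPeakTable <- function(path) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 stringsAsFactors = FALSE)
  need <- c("accession", "locus", "lab", "sizes")
  if (!all(need %in% names(df)))
    stop("peak table ", path, ": need columns ",
         paste(need, collapse = ", "))
  df$sizes <- lapply(df$sizes, function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric())
    v <- as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
    if (anyNA(v)) stop("peak table ", path, ": unparseable sizes '", s, "'")
    if (any(v <= 0)) stop("peak table ", path, ": non-positive size in '",
                          s, "'")
    v
  })
  df
}

#' Collapse one peak list into a diploid call
#'
#' Zero peaks is an amplification failure (missing call); one peak is read
#' as a homozygote (null alleles are undetectable by fragment analysis);
#' two peaks a heterozygote; three or more peaks indicate co-amplification
#' of multiple loci and flag the sample for marker QC rather than yielding
#' a genotype.
#'
#' @param sizes numeric vector of called fragment sizes (bp).
#' @return list with `status` ("ok", "missing" or "multipeak") and
#'   `alleles` (numeric length 2, `NA` unless status is "ok").
#' @examples
#' callGenotypeFromPeaks(c(153.2))          # homozygote (153.2, 153.2)
#' callGenotypeFromPeaks(c(150, 153, 156))  # multipeak flag
#' @export
callGenotypeFromPeaks <- function(sizes) {
  n <- length(sizes)
  if (n == 0L) return(list(status = "missing", alleles = c(NA_real_, NA_real_)))
  if (n == 1L) return(list(status = "ok", alleles = c(sizes, sizes)))
  if (n == 2L) return(list(status = "ok", alleles = sort(sizes)))
  list(status = "multipeak", alleles = c(NA_real_, NA_real_))
}

#' Build an allelic ladder from observed fragment sizes
#'
#' Single-linkage 1-D clustering: sorted sizes are split wherever the gap
#' between neighbours exceeds `step/2`; each cluster becomes one ladder
#' rung with nominal size = median of its members (rounded to 0.01 bp).
#' Two rungs closer than `tolerance` indicate irreconcilable calls and
#' raise a ladder-conflict error.
#'
#' @param sizes numeric vector of observed sizes in bp (>= 1 value).
#' @param locus locus name stored in the ladder.
#' @param step expected allele spacing in bp (3 for trinucleotide repeats).
#' @param tolerance binning tolerance in bp; must be < step/2.
#' @return An [AllelicLadder-class].
#' @examples
#' ladder <- buildLadder(c(150.0, 150.2, 153.1, 153.0, 156.2), "L1")
#' ladder@sizes  # 150.1, 153.05, 156.2
#' @export
buildLadder <- function(sizes, locus = "locus", step = 3, tolerance = 1) {
  if (length(sizes) < 1L) stop("need at least one observed size")
  s <- sort(as.numeric(sizes))
  cl <- cumsum(c(1, diff(s) > step / 2))
  nominal <- round(vapply(split(s, cl), median, numeric(1)), 2)
  nominal <- unname(nominal)
  if (any(diff(nominal) < tolerance))
    stop("ladder conflict at locus ", locus, ": rungs ",
         paste(round(nominal[which(diff(nominal) < tolerance)], 2),
               collapse = ", "), " closer than the tolerance")
  new("AllelicLadder", locus = locus, sizes = nominal, step = step,
      tolerance = tolerance)
}

#' Bin an observed fragment size against an allelic ladder
#'
#' Assigns to the nearest nominal size when within the ladder tolerance;
#' a tie at the exact midpoint goes to the lower rung. The returned allele
#' label is the nominal size rounded to an integer. Sizes outside the
#' tolerance of every rung return [OFF_LADDER] — a new or artifact allele
#' is never silently assigned.
#'
#' @param size observed size in bp (vectorised).
#' @param ladder an [AllelicLadder-class].
#' @return character vector of allele labels, with [OFF_LADDER] for
#'   unassignable sizes.
#' @export
binSize <- function(size, ladder) {
  stopifnot(is(ladder, "AllelicLadder"))
  vapply(as.numeric(size), function(x) {
    d <- x - ladder@sizes
    i <- which.min(abs(d))          # which.min takes the first (lower) tie
    if (abs(d[i]) > ladder@tolerance) return(OFF_LADDER)
    as.character(round(ladder@sizes[i]))
  }, character(1))
}

#' Bin a peak table into genotype matrices
#'
#' Collapses peak lists to diploid calls ([callGenotypeFromPeaks()]) and
#' bins allele sizes against per-locus ladders, producing one
#' [GenotypeMatrix-class] per laboratory. Multipeak samples become missing
#' calls and are reported in the `flags` element; off-ladder sizes likewise.
#'
#' @param peaks data.frame from [readPeakTable()].
#' @param ladders named list of [AllelicLadder-class] objects, one per
#'   locus appearing in `peaks`.
#' @param species,group metadata attached to accessions (recycled).
#' @return list with `genotypes` (named list of `GenotypeMatrix` by lab)
#'   and `flags` (data.frame of multipeak / off-ladder events).
#' @export
binPeakTable <- function(peaks, ladders, species = "P. somniferum",
                         group = "unknown") {
  missing_ladders <- setdiff(unique(peaks$locus), names(ladders))
  if (length(missing_ladders))
    stop("no ladder for locus/loci: ",
         paste(missing_ladders, collapse = ", "))
  flags <- list()
  out <- list()
  for (lab in unique(peaks$lab)) {
    sub <- peaks[peaks$lab == lab, , drop = FALSE]
    accs <- unique(sub$accession)
    loci <- sort(unique(peaks$locus))
    a <- matrix(NA_character_, length(accs), length(loci),
                dimnames = list(accs, loci))
    b <- a
    for (r in seq_len(nrow(sub))) {
      call <- callGenotypeFromPeaks(sub$sizes[[r]])
      acc <- sub$accession[r]
      loc <- sub$locus[r]
      if (call$status == "multipeak") {
        flags[[length(flags) + 1L]] <- data.frame(
          lab = lab, accession = acc, locus = loc, flag = "MULTIPEAK",
          detail = paste(sub$sizes[[r]], collapse = ";"),
          stringsAsFactors = FALSE)
        next
      }
      if (call$status == "missing") next
      lab_alleles <- binSize(call$alleles, ladders[[loc]])
      if (any(lab_alleles == OFF_LADDER)) {
        flags[[length(flags) + 1L]] <- data.frame(
          lab = lab, accession = acc, locus = loc, flag = "OFF_LADDER",
          detail = paste(call$alleles[lab_alleles == OFF_LADDER],
                         collapse = ";"),
          stringsAsFactors = FALSE)
        next
      }
      a[acc, loc] <- lab_alleles[1]
      b[acc, loc] <- lab_alleles[2]
    }
    out[[lab]] <- GenotypeMatrix(a, b, data.frame(
      id = accs, species = species, group = group,
      stringsAsFactors = FALSE))
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(lab = character(), accession = character(),
               locus = character(), flag = character(),
               detail = character(), stringsAsFactors = FALSE)
  list(genotypes = out, flags = flags)
}

#' Read per-locus ladder definitions from a YAML file
#'
#' Layout: one entry per locus with fields `sizes` (numeric vector),
#' optional `step` (default 3) and `tolerance` (default 1).
#'
#' @param path YAML file path.
#' @return named list of [AllelicLadder-class] objects.
#' @export
readLadders <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(loc) {
    entry <- cfg[[loc]]
    new("AllelicLadder", locus = loc,
        sizes = sort(as.numeric(entry$sizes)),
        step = if (is.null(entry$step)) 3 else as.numeric(entry$step),
        tolerance = if (is.null(entry$tolerance)) 1 else
          as.numeric(entry$tolerance))
  })
  names(out) <- names(cfg)
  out
}

#' @export
setMethod("show", "AllelicLadder", function(object) {
  cat("AllelicLadder for", object@locus, "-", length(object@sizes),
      "rungs:", paste(object@sizes, collapse = ", "), "\n")
  cat("  step", object@step, "bp, tolerance", object@tolerance, "bp\n")
})
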