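## Numeric-aware sorting of unordered allele pairs: labels that all parse as
## numbers compare numerically (so "99" < "102"), otherwise lexicographically.
sortPairs <- function(a, b) {
  an <- suppressWarnings(as.numeric(a))
  bn <- suppressWarnings(as.numeric(b))
  numeric_ok <- !is.na(an) & !is.na(bn)
  swap <- ifelse(numeric_ok, an > bn, a > b)
  swap[is.na(swap)] <- FALSE
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

#' Construct a GenotypeMatrix
#'
#' @param alleleA,alleleB character matrices (accessions x loci) holding the
#'   two alleles of each call; `NA` in both marks a missing call. Pair order
#'   is normalised internally, so the input order of the two alleles does
#'   not matter.
#' @param accessions data.frame with columns `id`, `species`, `group` (extra
#'   columns are kept).
#' @param loci optional character vector of locus names; defaults to the
#'   column names of `alleleA`.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix(
#'   alleleA = matrix(c("152", "152"), 2, 1, dimnames = list(NULL, "L1")),
#'   alleleB = matrix(c("152", "158"), 2, 1, dimnames = list(NULL, "L1")),
#'   accessions = data.frame(id = c("a1", "a2"),
#'                           species = "P. somniferum", group = "culinary")
#' )
#' nAccessions(gm)
#' @export
GenotypeMatrix <- function(alleleA, alleleB, accessions, loci = colnames(alleleA)) {
  alleleA <- as.matrix(alleleA)
  alleleB <- as.matrix(alleleB)
  storage.mode(alleleA) <- "character"
  storage.mode(alleleB) <- "character"
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(alleleA)))
  s <- sortPairs(as.vector(alleleA), as.vector(alleleB))
  alleleA[] <- s$a
  alleleB[] <- s$b
  dimnames(alleleA) <- dimnames(alleleB) <-
    list(as.character(accessions$id), loci)
  new("GenotypeMatrix", alleleA = alleleA, alleleB = alleleB,
      accessions = as.data.frame(accessions))
}

#' @describeIn GenotypeMatrix Number of accessions.
#' @param x,object a `GenotypeMatrix`.
#' @export
nAccessions <- function(x) nrow(x@alleleA)

#' @describeIn GenotypeMatrix Number of loci.
#' @export
nLoci <- function(x) ncol(x@alleleA)

#' @describeIn GenotypeMatrix Accession identifiers.
#' @export
accessionIds <- function(x) as.character(x@accessions$id)

#' @describeIn GenotypeMatrix Accession metadata table.
#' @export
accessionInfo <- function(x) x@accessions

#' @describeIn GenotypeMatrix Locus names.
#' @export
lociNames <- function(x) colnames(x@alleleA)

#' @describeIn GenotypeMatrix Logical accessions x loci matrix of missing calls.
#' @export
missingCalls <- function(x) is.na(x@alleleA)

#' @describeIn GenotypeMatrix Logical accessions x loci matrix of heterozygous
#'   calls (`NA` where missing).
#' @export
heterozygousCalls <- function(x) {
  out <- x@alleleA != x@alleleB
  out
}

#' Extract one genotype call
#'
#' @param x a [GenotypeMatrix-class].
#' @param accession accession id or row index.
#' @param locus locus name or column index.
#' @return Character vector of the two allele labels, or `NA` pair if
#'   missing.
#' @export
genotypeCall <- function(x, accession, locus) {
  c(x@alleleA[accession, locus], x@alleleB[accession, locus])
}

#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nAccessions(object), "accessions x",
      nLoci(object), "loci\n")
  miss <- mean(missingCalls(object))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  sp <- table(object@accessions$species)
  cat("  species:", paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "),
      "\n")
})

#' @describeIn GenotypeMatrix Subset by accessions (i) and/or loci (j);
#'   indices, names or logical vectors.
#' @param i,j,drop,... subsetting arguments (drop is ignored).
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nAccessions(x))
  if (missing(j)) j <- seq_len(nLoci(x))
  if (is.character(i)) i <- match(i, accessionIds(x))
  acc <- x@accessions[i, , drop = FALSE]
  rownames(acc) <- NULL
  new("GenotypeMatrix",
      alleleA = x@alleleA[i, j, drop = FALSE],
      alleleB = x@alleleB[i, j, drop = FALSE],
      accessions = acc)
})

#' Combine two genotype matrices over the same loci
#'
#' Stacks the accessions of `x` and `y`; loci must match exactly. Used to
#' assemble multi-species panels from separately simulated species.
#'
#' @param x,y [GenotypeMatrix-class] objects with identical loci.
#' @return A combined `GenotypeMatrix`.
#' @export
bindAccessions <- function(x, y) {
  if (!identical(lociNames(x), lociNames(y)))
    stop("cannot bind: loci differ")
  common <- intersect(names(x@accessions), names(y@accessions))
  GenotypeMatrix(rbind(x@alleleA, y@alleleA),
                 rbind(x@alleleB, y@alleleB),
                 rbind(x@accessions[common], y@accessions[common]))
}

#' Read a wide-format genotype CSV
#'
#' Expected layout: column 1 `id`, column 2 `species`, column 3 `group`,
#' then two columns per locus named `LOCUS.1` / `LOCUS.2`. Missing alleles
#' are coded `"0"`; a call must be missing in both columns or neither.
#'
#' @param path CSV file path.
#' @return A [GenotypeMatrix-class].
#' @seealso [writeGenotypes()] for the inverse; the two functions
#'   round-trip canonical files exactly.
#' @export
readGenotypes <- function(path) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (ncol(df) < 5L)
    stop("genotype file ", path, ": need id,species,group + locus columns")
  meta <- df[, 1:3]
  names(meta) <- c("id", "species", "group")
  if (anyDuplicated(meta$id))
    stop("genotype file ", path, ": duplicated accession id '",
         meta$id[duplicated(meta$id)][1], "'")
  gcols <- names(df)[-(1:3)]
  if (length(gcols) %% 2L != 0L)
    stop("genotype file ", path, ": odd number of allele columns")
  odd <- gcols[seq(1, length(gcols), by = 2)]
  even <- gcols[seq(2, length(gcols), by = 2)]
  loci1 <- sub("\\.1$", "", odd)
  loci2 <- sub("\\.2$", "", even)
  if (!all(grepl("\\.1$", odd)) || !all(grepl("\\.2$", even)) ||
      !identical(loci1, loci2))
    stop("genotype file ", path,
         ": allele columns must come in LOCUS.1/LOCUS.2 pairs")
  a <- as.matrix(df[, odd, drop = FALSE])
  b <- as.matrix(df[, even, drop = FALSE])
  halfMissing <- xor(a == "0", b == "0")
  if (any(halfMissing)) {
    w <- which(halfMissing, arr.ind = TRUE)[1, ]
    stop("genotype file ", path, ": half-missing call at row ", w[1],
         ", locus ", loci1[w[2]])
  }
  a[a == "0"] <- NA_character_
  b[b == "0"] <- NA_character_
  GenotypeMatrix(a, b, meta, loci = loci1)
}

#' Write a GenotypeMatrix as canonical wide CSV
#'
#' @param x a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(x, path) {
  a <- x@alleleA
  b <- x@alleleB
  a[is.na(a)] <- "0"
  b[is.na(b)] <- "0"
  L <- lociNames(x)
  out <- data.frame(id = accessionIds(x),
                    species = x@accessions$species,
                    group = x@accessions$group,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (k in seq_along(L)) {
    out[[paste0(L[k], ".1")]] <- a[, k]
    out[[paste0(L[k], ".2")]] <- b[, k]
  }
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
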