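## --- Perfect SSR detection -------------------------------------------------
##
## A trinucleotide SSR locus is a maximal perfect tandem repeat of a 3-bp
## unit. The scanner works for any unit length m: positions i where
## s[i] == s[i+m] define periodic stretches; a run of L such positions is a
## stretch of total length L + m with floor((L+m)/m) complete units.

emptySSRFrame <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             motif = character(), canonical_motif = character(),
             n_repeats = integer(), stringsAsFactors = FALSE)
}

## TRUE when the unit is itself periodic with a shorter period dividing its
## length (e.g. "AAA" is a mononucleotide run, not a trinucleotide unit).
reducibleMotif <- function(motif) {
  m <- nchar(motif)
  for (d in seq_len(m - 1L)) {
    if (m %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), m / d)) return(TRUE)
  }
  FALSE
}

#' Find maximal perfect microsatellites in one sequence
#'
#' Scans a nucleotide sequence for maximal perfect tandem repeats of
#' `motifLength`-bp units with at least `minRepeats` complete copies.
#' Reported loci are non-overlapping (greedy, leftmost-longest); runs are
#' broken at `N` bases; units reducible to a shorter period (homopolymers
#' within the trinucleotide class) are excluded. Coordinates are 0-based
#' half-open, so `end - start == motifLength * n_repeats`.
#'
#' @param sequence character(1) over A/C/G/T/N (case-insensitive).
#' @param motifLength repeat-unit length in bp (default 3, the
#'   trinucleotide class used for EST-SSR marker development).
#' @param minRepeats minimum number of complete units (default 10).
#' @param seqId sequence identifier placed in the `seq_id` column.
#' @return data.frame with columns `seq_id`, `start`, `end`, `motif`,
#'   `canonical_motif`, `n_repeats`.
#' @examples
#' findSSRs(strrep("ATG", 10))
#' @export
findSSRs <- function(sequence, motifLength = 3L, minRepeats = 10L,
                     seqId = "seq") {
  stopifnot(length(sequence) == 1L, motifLength >= 1L, minRepeats >= 2L)
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  if (n == 0L) return(emptySSRFrame())
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% c("A", "C", "G", "T", "N"))
  if (any(bad))
    stop("invalid nucleotide character(s): ",
         paste(unique(chars[bad]), collapse = ", "))
  m <- as.integer(motifLength)
  if (n < m * minRepeats) return(emptySSRFrame())
  idx <- seq_len(n - m)
  eq <- chars[idx] == chars[idx + m]
  isN <- chars == "N"
  eq[isN[idx] | isN[idx + m]] <- FALSE
  r <- rle(eq)
  runEnd <- cumsum(r$lengths)
  runStart <- runEnd - r$lengths + 1L
  rows <- vector("list", sum(r$values))
  nrow_ <- 0L
  lastEnd <- 0L
  for (j in which(r$values)) {
    total <- r$lengths[j] + m          # periodic stretch length in bp
    nrep <- total %/% m
    if (nrep < minRepeats) next
    i <- runStart[j]                   # 1-based stretch start
    motif <- substr(s, i, i + m - 1L)
    if (reducibleMotif(motif)) next
    start0 <- i - 1L
    end0 <- start0 + m * nrep
    if (start0 < lastEnd) next         # earlier (leftmost) locus wins
    nrow_ <- nrow_ + 1L
    rows[[nrow_]] <- data.frame(
      seq_id = seqId, start = start0, end = end0, motif = motif,
      canonical_motif = canonicalMotif(motif), n_repeats = nrep,
      stringsAsFactors = FALSE)
    lastEnd <- end0
  }
  if (nrow_ == 0L) return(emptySSRFrame())
  do.call(rbind, rows[seq_len(nrow_)])
}

#' Canonical motif class of a trinucleotide unit
#'
#' Standardises a repeat unit to the lexicographically smallest string among
#' its 3 cyclic rotations and the 3 rotations of its reverse complement, so
#' that e.g. TGA, GAT, ATG, TCA, CAT and ATC all report the class "ATC".
#'
#' @param motif character vector of 3-bp units over A/C/G/T.
#' @return character vector of canonical classes.
#' @export
canonicalMotif <- function(motif) {
  vapply(motif, function(mo) {
    mo <- toupper(mo)
    if (nchar(mo) != 3L || grepl("[^ACGT]", mo))
      stop("motif must be 3 bp over A/C/G/T, got '", mo, "'")
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(mo, "")[[1]]),
                                       collapse = ""))
    rot <- function(x) vapply(0:2, function(k)
      paste0(substr(x, k + 1L, 3L), substr(x, 1L, k)), character(1))
    min(c(rot(mo), rot(rc)))
  }, character(1), USE.NAMES = FALSE)
}

#' Mark marker candidates with duplicated flanking sequence
#'
#' Candidates whose (left flank, right flank) pair exactly matches an
#' earlier candidate are marked as duplicates of that candidate; order is
#' preserved and unique candidates keep `duplicate_of = NA`. Exact flank
#' identity at `flankLen` bp is the uniqueness criterion.
#'
#' @param candidates data.frame with columns `left_flank`, `right_flank`
#'   and a `candidate_id` column (created by [mineFasta()]).
#' @param flankLen number of flanking bp compared on each side; flanks are
#'   truncated to this length (left flank keeps its rightmost bp, right
#'   flank its leftmost).
#' @return `candidates` with a `duplicate_of` column filled in.
#' @export
dedupeCandidates <- function(candidates, flankLen = 50L) {
  stopifnot(flankLen > 0L)
  lf <- candidates$left_flank
  rf <- candidates$right_flank
  lf <- substr(lf, pmax(1L, nchar(lf) - flankLen + 1L), nchar(lf))
  rf <- substr(rf, 1L, flankLen)
  key <- paste(lf, rf, sep = "|")
  first <- match(key, key)
  dup <- first < seq_along(key)
  candidates$duplicate_of <- ifelse(dup, candidates$candidate_id[first],
                                    NA_character_)
  candidates
}

#' Mine marker candidates from a FASTA file
#'
#' Per-record SSR detection ([findSSRs()]), flank extraction, amplicon
#' feasibility and flank-based deduplication ([dedupeCandidates()]).
#' A candidate is amplicon-feasible when the repeat itself does not exceed
#' `maxProduct` bp and repeat plus available flanking sequence (up to
#' `flankLen` bp a side) can reach `minProduct` bp — the size window within
#' which fragment-analysis markers are designed.
#'
#' @param fastaPath path to a (multi-record) FASTA file; record ids are
#'   taken up to the first whitespace.
#' @param motifLength,minRepeats passed to [findSSRs()].
#' @param flankLen flank length extracted and compared for uniqueness (bp).
#' @param minProduct,maxProduct amplicon size window in bp (default
#'   100-300).
#' @return data.frame of candidates: `candidate_id`, `seq_id`, `start`,
#'   `end`, `motif`, `canonical_motif`, `n_repeats`, `left_flank`,
#'   `right_flank`, `amplicon_feasible`, `duplicate_of`.
#' @export
mineFasta <- function(fastaPath, motifLength = 3L, minRepeats = 10L,
                      flankLen = 50L, minProduct = 100L, maxProduct = 300L) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(fastaPath),
                   error = function(e)
                     stop("cannot read FASTA '", fastaPath, "': ",
                          conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(seqs))
  res <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    sq <- as.character(seqs[[k]])
    loci <- findSSRs(sq, motifLength, minRepeats, seqId = ids[k])
    if (nrow(loci) == 0L) next
    n <- nchar(sq)
    ls <- pmax(1L, loci$start + 1L - flankLen)
    loci$left_flank <- substr(rep(sq, nrow(loci)), ls, loci$start)
    loci$right_flank <- substr(rep(sq, nrow(loci)), loci$end + 1L,
                               pmin(n, loci$end + flankLen))
    repLen <- loci$end - loci$start
    avail <- nchar(loci$left_flank) + nchar(loci$right_flank)
    loci$amplicon_feasible <- repLen <= maxProduct &
      repLen + avail >= minProduct
    res[[k]] <- loci
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    out <- emptySSRFrame()
    out$left_flank <- character()
    out$right_flank <- character()
    out$amplicon_feasible <- logical()
    out$candidate_id <- character()
    out$duplicate_of <- character()
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$candidate_id <- sprintf("%s:%d-%d", out$seq_id, out$start, out$end)
  dedupeCandidates(out, flankLen)
}

#' Write a marker-candidate table as TSV
#'
#' @param candidates data.frame from [mineFasta()].
#' @param path output path.
#' @param headerLines optional comment lines prepended to the file.
#' @return `path`, invisibly.
#' @export
writeCandidates <- function(candidates, path, headerLines = NULL) {
  cols <- c("seq_id", "start", "end", "motif", "canonical_motif",
            "n_repeats", "amplicon_feasible", "duplicate_of")
  writeReportTable(candidates[, cols], path, headerLines)
}
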