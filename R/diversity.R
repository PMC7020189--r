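#' Allele frequencies at one locus
#'
#' Counts both alleles of every non-missing call (homozygotes contribute
#' two copies); missing calls are excluded from the denominator
#' `2 * n_typed`.
#'
#' @param x a [GenotypeMatrix-class].
#' @param locus locus name or index.
#' @param accessions optional accession ids/indices restricting the group.
#' @return data.frame with columns `allele`, `count`, `freq`, plus
#'   attributes `locus` and `n_typed`.
#' @export
alleleFrequencies <- function(x, locus, accessions = NULL) {
  if (is.null(accessions)) accessions <- seq_len(nAccessions(x))
  a <- x@alleleA[accessions, locus]
  b <- x@alleleB[accessions, locus]
  keep <- !is.na(a)
  if (!any(keep))
    stop("locus ", locus, ": no non-missing calls in the requested group")
  tab <- table(c(a[keep], b[keep]))
  ord <- order(suppressWarnings(as.numeric(names(tab))), names(tab),
               na.last = TRUE)
  tab <- tab[ord]
  out <- data.frame(allele = names(tab), count = as.integer(tab),
                    freq = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  attr(out, "locus") <- if (is.character(locus)) locus else
    lociNames(x)[locus]
  attr(out, "n_typed") <- sum(keep)
  out
}

## PIC in the Botstein form used by Cervus:
## PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2
##     = 1 - S2 - (S2^2 - S4), with S2 = sum p^2, S4 = sum p^4.
picFromFreq <- function(p) {
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  1 - s2 - (s2^2 - s4)
}

#' Per-locus diversity summary for one accession group
#'
#' Computes the standard marker-characterisation statistics: number of
#' alleles `k`, observed heterozygosity `Ho` (heterozygous calls /
#' non-missing calls), expected heterozygosity `He = 1 - sum(p_i^2)` and
#' polymorphic information content
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2` (Botstein et al. form).
#' A monomorphic locus (k = 1) has He = PIC = 0, and PIC <= He always.
#'
#' @inheritParams alleleFrequencies
#' @return one-row data.frame: `locus`, `n_typed`, `k`, `Ho`, `He`, `PIC`.
#' @export
locusSummary <- function(x, locus, accessions = NULL) {
  af <- alleleFrequencies(x, locus, accessions)
  if (is.null(accessions)) accessions <- seq_len(nAccessions(x))
  a <- x@alleleA[accessions, locus]
  b <- x@alleleB[accessions, locus]
  keep <- !is.na(a)
  ho <- sum(a[keep] != b[keep]) / sum(keep)
  p <- af$freq
  data.frame(locus = attr(af, "locus"), n_typed = attr(af, "n_typed"),
             k = nrow(af), Ho = ho, He = 1 - sum(p^2), PIC = picFromFreq(p),
             stringsAsFactors = FALSE)
}

#' Summary rows for a locus-by-statistic table
#'
#' Appends the descriptive rows printed under per-locus marker tables:
#' total (sum), mean, median, min and max of every numeric column. The
#' median is the middle order statistic for odd counts.
#'
#' @param df data.frame whose numeric columns are summarised (non-numeric
#'   columns are dropped).
#' @return data.frame with a `statistic` column and one column per numeric
#'   input column.
#' @examples
#' panelSummary(data.frame(k = c(3, 7, 10)))
#' @export
panelSummary <- function(df) {
  num <- df[, vapply(df, is.numeric, logical(1)), drop = FALSE]
  if (ncol(num) == 0L) stop("no numeric columns to summarise")
  stat <- function(f) vapply(num, f, numeric(1))
  out <- rbind(total = stat(sum), mean = stat(mean),
               median = stat(function(v) median(v)),
               min = stat(min), max = stat(max))
  data.frame(statistic = rownames(out), out, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Diversity report per locus and accession group
#'
#' One [locusSummary()] row per locus per group, followed by a per-group
#' summary block ([panelSummary()] over `k`, `Ho`, `He`, `PIC`).
#'
#' @param x a [GenotypeMatrix-class].
#' @param groups named list of accession-id vectors. The default builds
#'   the three conventional groups: all accessions, each species, and each
#'   `group` label within *P. somniferum*.
#' @return list with `perLocus` (data.frame, one row per group x locus)
#'   and `summary` (data.frame of per-group summary statistics).
#' @export
groupReport <- function(x, groups = NULL) {
  if (is.null(groups)) groups <- defaultGroups(x)
  if (length(groups) == 0L) stop("no groups to report")
  per <- list()
  summ <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (length(ids) == 0L) stop("empty group '", g, "'")
    rows <- do.call(rbind, lapply(lociNames(x), function(loc)
      locusSummary(x, loc, ids)))
    rows <- cbind(group = g, rows, stringsAsFactors = FALSE)
    per[[g]] <- rows
    s <- panelSummary(rows[, c("k", "Ho", "He", "PIC")])
    summ[[g]] <- cbind(group = g, s, stringsAsFactors = FALSE)
  }
  list(perLocus = do.call(rbind, c(per, list(make.row.names = FALSE))),
       summary = do.call(rbind, c(summ, list(make.row.names = FALSE))))
}

defaultGroups <- function(x) {
  info <- accessionInfo(x)
  groups <- list(all = as.character(info$id))
  for (sp in unique(info$species))
    groups[[sp]] <- as.character(info$id[info$species == sp])
  som <- info$species == "P. somniferum"
  if (any(som)) {
    for (gl in unique(info$group[som])) {
      if (is.na(gl)) next
      groups[[paste0("P. somniferum-", gl)]] <-
        as.character(info$id[som & info$group == gl])
    }
  }
  groups
}

#' Published allele counts of the OPEST/OPGSSR marker panel
#'
#' Per-locus allele counts (k) reported for the 17-marker opium-poppy
#' EST-SSR panel, for three accession groups: all accessions, all
#' *P. somniferum* accessions, and the culinary *P. somniferum* cultivars.
#' These counts serve as the default per-locus allele numbers of the
#' synthetic-panel generator and as a reference input for summary
#' arithmetic (totals 118 / 88 / 77 alleles).
#'
#' @return data.frame with columns `marker`, `k_all`, `k_somniferum`,
#'   `k_culinary`.
#' @export
opestAlleleCounts <- function() {
  data.frame(
    marker = c("OPEST026", "OPEST048c", "OPEST051c", "OPEST053c",
               "OPEST061", "OPEST081c", "OPEST086d", "OPEST099",
               "OPEST102b", "OPEST106", "OPEST120b", "OPEST126b",
               "OPEST131", "OPEST156", "OPEST169", "OPEST177b",
               "OPGSSR001"),
    k_all        = c(10, 9, 5, 10, 7, 8, 3, 8, 9, 6, 7, 6, 6, 3, 6, 6, 9),
    k_somniferum = c(8, 7, 5, 6, 6, 6, 3, 3, 5, 4, 3, 5, 4, 3, 5, 6, 9),
    k_culinary   = c(7, 6, 5, 6, 6, 5, 2, 3, 4, 4, 3, 3, 4, 3, 2, 5, 9),
    stringsAsFactors = FALSE)
}
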