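#' Principal component analysis of a trinary allele matrix
#'
#' Column-centred, unscaled PCA (eigendecomposition of the covariance
#' matrix) of the trinary encoding from [encodeTrinary()]. The percentage
#' of variance per axis is the eigenvalue over the total variance. Score
#' signs are fixed deterministically: each component is flipped, if
#' necessary, so that its largest-magnitude loading is positive.
#'
#' @param t numeric matrix (accessions x allele columns), typically from
#'   [encodeTrinary()].
#' @param nComponents number of components returned (default 2).
#' @return list: `scores` (accessions x nComponents), `loadings`,
#'   `pctVariance` (all components), `nComponents`.
#' @export
trinaryPCA <- function(t, nComponents = 2L) {
  t <- as.matrix(t)
  if (nrow(t) < 2L || ncol(t) < 2L)
    stop("PCA needs at least 2 accessions and 2 allele columns")
  if (all(apply(t, 2, var) == 0))
    stop("zero-variance matrix: PCA undefined")
  p <- prcomp(t, center = TRUE, scale. = FALSE)
  eig <- p$sdev^2
  pct <- 100 * eig / sum(eig)
  nComponents <- min(nComponents, ncol(p$rotation))
  scores <- p$x[, seq_len(nComponents), drop = FALSE]
  load <- p$rotation[, seq_len(nComponents), drop = FALSE]
  for (k in seq_len(nComponents)) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(scores = scores, loadings = load, pctVariance = pct,
       nComponents = nComponents)
}
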