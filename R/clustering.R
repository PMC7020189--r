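#' Dice distance matrix from a binary allele matrix
#'
#' Pairwise Dice (Sorensen) similarity `s = 2a / (2a + b + c)` — `a` the
#' number of shared presence calls, `b` and `c` those unique to either
#' accession — converted to distance `d = 1 - s`. Two accessions with no
#' presence calls at all have undefined similarity and raise an error
#' naming them.
#'
#' @param b numeric 0/1 matrix from [encodeBinary()] (rows = accessions).
#' @return symmetric distance matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @export
diceDistance <- function(b) {
  if (nrow(b) < 2L) stop("need at least two accessions")
  r <- rowSums(b)
  zero <- which(r == 0)
  if (length(zero) >= 2L)
    stop("Dice similarity undefined between all-absent accessions: ",
         paste(rownames(b)[zero], collapse = ", "))
  a <- tcrossprod(b)
  denom <- outer(r, r, "+")
  d <- 1 - 2 * a / denom
  diag(d) <- 0
  dimnames(d) <- list(rownames(b), rownames(b))
  d
}

linkageMethods <- c(single = "single", complete = "complete",
                    upgma = "average", wpgma = "mcquitty")

#' Agglomerative clustering of accessions
#'
#' Standard agglomerative merge on a distance matrix; node heights are the
#' inter-cluster distance at each merge, so cophenetic distances live on
#' the same scale as the input distances.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param method one of `"upgma"` (unweighted average linkage),
#'   `"wpgma"`, `"single"`, `"complete"`.
#' @return an [stats::hclust] object.
#' @export
clusterAccessions <- function(d, method = "upgma") {
  method <- match.arg(tolower(method), names(linkageMethods))
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8))
      stop("distance matrix is not symmetric")
    d <- as.dist(d)
  }
  hclust(d, method = linkageMethods[[method]])
}

#' Cophenetic correlation and Mather's delta for a dendrogram
#'
#' `CC` is the Pearson correlation between the upper triangles of the
#' input distance matrix and the cophenetic (tree-implied) matrix.
#' `delta_q = sqrt( sum((d^q - c^q)^2) / sum(d^(2q)) )` for q = 0.5 and 1
#' (Mather's goodness-of-fit criterion); smaller is better, 0 for an
#' exact ultrametric fit.
#'
#' @param d distance matrix (or `dist`) the tree was built from.
#' @param hc an `hclust` tree on the same labels.
#' @return one-row data.frame: `method`, `cc`, `delta_05`, `delta_1`.
#' @export
linkageEvaluation <- function(d, hc) {
  if (is.matrix(d)) d <- as.dist(d)
  cm <- cophenetic(hc)
  labs <- attr(d, "Labels")
  if (!is.null(labs) && !setequal(labs, attr(cm, "Labels")))
    stop("label sets of distance matrix and tree differ")
  if (!is.null(labs)) {
    C <- as.matrix(cm)[labs, labs]
    cv <- C[lower.tri(C)]
  } else cv <- as.vector(cm)
  dv <- as.vector(d)
  if (sd(dv) == 0)
    stop("constant distance matrix: cophenetic correlation undefined")
  delta <- function(q) sqrt(sum((dv^q - cv^q)^2) / sum(dv^(2 * q)))
  data.frame(method = hc$method, cc = cor(dv, cv),
             delta_05 = delta(0.5), delta_1 = delta(1),
             stringsAsFactors = FALSE)
}

#' Select the best-fitting linkage method
#'
#' Builds one dendrogram per candidate linkage, scores each by cophenetic
#' correlation (CC) and Mather's delta, and picks the method with the
#' highest CC, breaking ties by the smaller `delta_1`. A residual exact
#' tie (e.g. ultrametric input, which every linkage fits perfectly) goes
#' to average linkage (UPGMA, then WPGMA, complete, single), the
#' conventional default for allele-sharing distances.
#'
#' @param d distance matrix.
#' @param methods candidate linkage names (see [clusterAccessions()]).
#' @return list: `best` (method name), `evaluations` (data.frame, one row
#'   per method), `trees` (named list of `hclust` objects).
#' @export
selectLinkage <- function(d, methods = c("single", "complete", "upgma",
                                         "wpgma")) {
  stopifnot(length(methods) >= 1L)
  trees <- lapply(methods, function(m) clusterAccessions(d, m))
  names(trees) <- methods
  ev <- do.call(rbind, lapply(trees, function(hc) linkageEvaluation(d, hc)))
  ev$method <- methods
  rownames(ev) <- NULL
  pref <- match(ev$method, c("upgma", "wpgma", "complete", "single"))
  ord <- order(-ev$cc, ev$delta_1, pref)
  list(best = ev$method[ord[1]], evaluations = ev, trees = trees)
}

## Leaf-set key of every internal node of an hclust tree, used to compare
## topologies across bootstrap replicates.
cladeKeys <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  keys <- character(n - 1L)
  for (i in seq_len(n - 1L)) {
    members <- unlist(lapply(hc$merge[i, ], function(m)
      if (m < 0) hc$labels[-m] else sets[[m]]))
    sets[[i]] <- members
    keys[i] <- paste(sort(members), collapse = "|")
  }
  keys
}

#' Bootstrap supports for dendrogram clades
#'
#' Resamples loci with replacement (the resampling unit for multilocus
#' marker data, preserving within-locus allele dependence), rebuilds
#' binary encoding, Dice distances and the dendrogram for each replicate,
#' and reports for every internal node of the original tree the percentage
#' of replicates containing the same leaf set. Fully seeded and
#' reproducible.
#'
#' @param x a [GenotypeMatrix-class] with >= 3 loci.
#' @param method linkage passed to [clusterAccessions()].
#' @param nBoot number of bootstrap replicates (default 10000).
#' @param seed integer RNG seed (required).
#' @return list: `tree` (the original `hclust`), `supports` (data.frame
#'   `clade`, `size`, `support` in percent), `nBoot`, `nValid` (replicates
#'   where Dice distances were defined).
#' @export
bootstrapSupports <- function(x, method = "upgma", nBoot = 10000L, seed) {
  if (nLoci(x) < 3L) stop("bootstrap needs at least three loci")
  if (nBoot < 1L) stop("nBoot must be >= 1")
  if (missing(seed)) stop("seed is required")
  full <- encodeBinary(x)
  blockOf <- attr(full, "lociBlocks")
  blocks <- lapply(lociNames(x), function(loc)
    full[, blockOf == loc, drop = FALSE])
  tree <- clusterAccessions(diceDistance(full), method)
  keys <- cladeKeys(tree)
  counts <- setNames(numeric(length(keys)), keys)
  nValid <- 0L
  set.seed(seed)
  for (bb in seq_len(nBoot)) {
    idx <- sample.int(nLoci(x), replace = TRUE)
    Bb <- do.call(cbind, blocks[idx])
    Db <- tryCatch(diceDistance(Bb), error = function(e) NULL)
    if (is.null(Db)) next
    nValid <- nValid + 1L
    repKeys <- cladeKeys(clusterAccessions(Db, method))
    hit <- keys %in% repKeys
    counts[hit] <- counts[hit] + 1
  }
  if (nValid == 0L) stop("no bootstrap replicate yielded defined distances")
  supports <- data.frame(
    clade = keys,
    size = lengths(regmatches(keys, gregexpr("|", keys, fixed = TRUE))) + 1L,
    support = 100 * counts / nValid,
    stringsAsFactors = FALSE, row.names = NULL)
  list(tree = tree, supports = supports, nBoot = nBoot, nValid = nValid)
}

#' Export a dendrogram as Newick, with bootstrap supports as node labels
#'
#' @param hc an `hclust` tree.
#' @param path output file path.
#' @param supports optional `supports` data.frame from
#'   [bootstrapSupports()]; support percentages become internal node
#'   labels.
#' @return `path`, invisibly.
#' @export
writeDendrogram <- function(hc, path, supports = NULL) {
  phy <- ape::as.phylo(hc)
  if (!is.null(supports)) {
    pp <- ape::prop.part(phy)
    labs <- attr(pp, "labels")
    keys <- vapply(pp, function(ix)
      paste(sort(labs[ix]), collapse = "|"), character(1))
    phy$node.label <- round(supports$support[match(keys, supports$clade)], 1)
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}
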