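# Independent oracles and fixture builders. These re-derive expected
# results by brute force / first principles, deliberately sharing no code
# with the implementation paths they check.

# Brute-force SSR scan: test every start position, count unit copies to
# the right, keep left-maximal qualifying repeats, then apply the same
# greedy leftmost non-overlap rule the scanner documents.
bruteForceSSR <- function(s, m = 3L, minRep = 10L) {
  s <- toupper(s)
  n <- nchar(s)
  cand <- list()
  lastStart <- n - m * minRep + 1L
  if (lastStart >= 1L) {
    for (i in seq_len(lastStart)) {
      motif <- substr(s, i, i + m - 1L)
      if (grepl("N", motif, fixed = TRUE)) next
      reducible <- FALSE
      for (d in seq_len(m - 1L)) {
        if (m %% d == 0L && motif == strrep(substr(motif, 1L, d), m / d))
          reducible <- TRUE
      }
      if (reducible) next
      if (i > m && substr(s, i - m, i - 1L) == motif) next  # not left-maximal
      k <- 1L
      pos <- i + m
      while (pos + m - 1L <= n && substr(s, pos, pos + m - 1L) == motif) {
        k <- k + 1L
        pos <- pos + m
      }
      if (k >= minRep)
        cand[[length(cand) + 1L]] <- data.frame(
          start = i - 1L, end = i - 1L + m * k, motif = motif,
          n_repeats = k, stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(start = integer(), end = integer(),
                      motif = character(), n_repeats = integer(),
                      stringsAsFactors = FALSE)
  if (!length(cand)) return(empty)
  df <- do.call(rbind, cand)
  df <- df[order(df$start), , drop = FALSE]
  keep <- integer()
  lastEnd <- 0L
  for (r in seq_len(nrow(df))) {
    if (df$start[r] >= lastEnd) {
      keep <- c(keep, r)
      lastEnd <- df$end[r]
    }
  }
  rownames(df) <- NULL
  df[keep, , drop = FALSE]
}

randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# Deterministic random-looking DNA for file fixtures; restores the RNG
# state so surrounding seeded code is unaffected.
randomDNAFixed <- function(n, seed = n + 1000L) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  randomDNA(n)
}

# Naive O(n^3) UPGMA agglomeration recording cophenetic distances as the
# inter-cluster distance at each merge.
naiveUPGMACophenetic <- function(D) {
  n <- nrow(D)
  C <- matrix(0, n, n, dimnames = dimnames(D))
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  d <- D
  active <- seq_len(n)
  while (length(active) > 1L) {
    bestd <- Inf
    best <- c(NA_integer_, NA_integer_)
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        a <- active[ii]; b <- active[jj]
        if (d[a, b] < bestd) {
          bestd <- d[a, b]
          best <- c(a, b)
        }
      }
    }
    a <- best[1]; b <- best[2]
    C[members[[a]], members[[b]]] <- bestd
    C[members[[b]], members[[a]]] <- bestd
    for (x in setdiff(active, c(a, b))) {
      nd <- (sizes[a] * d[a, x] + sizes[b] * d[b, x]) / (sizes[a] + sizes[b])
      d[a, x] <- d[x, a] <- nd
    }
    members[[a]] <- c(members[[a]], members[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  C
}

# Set-based Dice distance between two binary rows.
diceOracle <- function(x, y) {
  sx <- which(x == 1)
  sy <- which(y == 1)
  a <- length(intersect(sx, sy))
  b <- length(setdiff(sx, sy))
  cc <- length(setdiff(sy, sx))
  1 - 2 * a / (2 * a + b + cc)
}

# Exhaustive probability-of-identity: sum over all unordered genotypes of
# the squared Hardy-Weinberg genotype probability.
pidEnumeration <- function(p) {
  k <- length(p)
  tot <- 0
  for (i in seq_len(k)) {
    for (j in i:k) {
      pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      tot <- tot + pg^2
    }
  }
  tot
}

# PIC by explicit double loop over allele pairs.
picOracle <- function(p) {
  k <- length(p)
  s <- 1 - sum(p^2)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j > i) s <- s - 2 * p[i]^2 * p[j]^2
    }
  }
  s
}

# Small genotype matrix from a list of per-accession call lists; each call
# is c(a, b) or NA for missing.
makeGM <- function(calls, loci, species = "P. somniferum",
                   group = "culinary", ids = NULL) {
  n <- length(calls)
  if (is.null(ids)) ids <- sprintf("A%02d", seq_len(n))
  a <- matrix(NA_character_, n, length(loci),
              dimnames = list(NULL, loci))
  b <- a
  for (i in seq_len(n)) {
    for (l in seq_along(loci)) {
      cl <- calls[[i]][[l]]
      if (length(cl) == 1L && !is.na(cl)) cl <- c(cl, cl)  # homozygote
      if (length(cl) == 2L && !anyNA(cl)) {
        a[i, l] <- as.character(cl[1])
        b[i, l] <- as.character(cl[2])
      }
    }
  }
  GenotypeMatrix(a, b, data.frame(id = ids, species = species,
                                  group = group, stringsAsFactors = FALSE))
}

# Mean silhouette of a 1-D embedding with two groups.
silhouette1D <- function(scores, groups) {
  g <- unique(groups)
  stopifnot(length(g) == 2L)
  s <- vapply(seq_along(scores), function(i) {
    own <- scores[setdiff(which(groups == groups[i]), i)]
    oth <- scores[groups != groups[i]]
    a <- if (length(own)) mean(abs(scores[i] - own)) else 0
    b <- mean(abs(scores[i] - oth))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
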