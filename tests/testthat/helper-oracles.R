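## Independent brute-force oracles used by the tests. These deliberately
## avoid the package's own code paths: the Smith-Waterman here is written
## from the recurrence, components come from iterated transitive closure,
## and canonical rotations from explicit enumeration.

rcOracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

## Smith-Waterman score matrix, linear gap cost (match +1, mismatch -2,
## gap 2 per column), row-wise: the left-gap dependency is resolved with a
## running maximum, exact for linear gap costs.
swMatrix <- function(A, B, match = 1, mismatch = -2, gap = 2) {
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    sub <- ifelse(A[i] == B, match, mismatch)
    prev <- H[i, ]
    cand <- pmax(0, prev[seq_len(m)] + sub, prev[-1L] - gap)
    row <- numeric(m + 1L)
    for (j in seq_len(m))
      row[j + 1L] <- max(cand[j], row[j] - gap)
    H[i + 1L, ] <- row
  }
  H
}

## Traceback from the maximum cell; move preference diag > up > left.
swTraceback <- function(A, B, H, match = 1, mismatch = -2, gap = 2) {
  score <- max(H)
  if (score == 0)
    return(list(score = 0, matches = 0L, columns = 0L,
                a_range = c(0L, 0L), b_range = c(0L, 0L)))
  bestCell <- unname(which(H == score, arr.ind = TRUE)[1L, ])
  i <- bestCell[1L] - 1L
  j <- bestCell[2L] - 1L
  ei <- i
  ej <- j
  matches <- 0L
  columns <- 0L
  while (i > 0L || j > 0L) {
    h <- H[i + 1L, j + 1L]
    if (h == 0) break
    if (i > 0L && j > 0L &&
        h == H[i, j] + (if (A[i] == B[j]) match else mismatch)) {
      matches <- matches + (A[i] == B[j])
      columns <- columns + 1L
      i <- i - 1L
      j <- j - 1L
    } else if (i > 0L && h == H[i, j + 1L] - gap) {
      columns <- columns + 1L
      i <- i - 1L
    } else {
      columns <- columns + 1L
      j <- j - 1L
    }
  }
  list(score = score, matches = matches, columns = columns,
       a_range = c(i + 1L, ei), b_range = c(j + 1L, ej))
}

## Full DP similarity of two reads, both orientations of b (ties prefer
## the forward orientation), mirroring the reported quantities.
swOracle <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  hits <- lapply(c(fwd = b, rev = rcOracle(b)), function(bb) {
    B <- strsplit(bb, "", fixed = TRUE)[[1]]
    H <- swMatrix(A, B)
    swTraceback(A, B, H)
  })
  best <- if (hits[[2]]$score > hits[[1]]$score) 2L else 1L
  h <- hits[[best]]
  lenA <- nchar(a)
  lenB <- nchar(b)
  wA <- h$a_range[2L] - h$a_range[1L] + 1L
  wB <- h$b_range[2L] - h$b_range[1L] + 1L
  list(score = h$score,
       identity_pct = if (h$columns > 0) 100 * h$matches / h$columns
                      else NA_real_,
       columns = h$columns,
       longer_cov_frac = if (lenA >= lenB) wA / lenA else wB / lenB,
       strand = c("same", "opposite")[best])
}

## Exhaustive DP edge evaluation for a read set.
swGraphEdges <- function(seqs, identityCutoff = 90, coverageCutoff = 0.55,
                         minAlnLen = 30L) {
  ids <- names(seqs)
  out <- list()
  for (i in seq_along(seqs)[-length(seqs)]) {
    for (j in (i + 1L):length(seqs)) {
      h <- swOracle(seqs[[i]], seqs[[j]])
      if (h$columns >= minAlnLen && h$identity_pct >= identityCutoff &&
          h$longer_cov_frac >= coverageCutoff)
        out[[length(out) + 1L]] <- data.frame(
          read_i = ids[i], read_j = ids[j],
          identity_pct = h$identity_pct,
          longer_cov_frac = h$longer_cov_frac,
          strand = h$strand, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(read_i = character(0), read_j = character(0)))
  do.call(rbind, out)
}

## Connected components by iterated transitive closure.
closureComponents <- function(nodes, edges) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      a <- comp[edges$read_i[r]]
      b <- comp[edges$read_j[r]]
      if (a != b) {
        comp[comp == b] <- a
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  members <- split(names(comp), comp)
  members <- members[lengths(members) >= 2L]
  unname(lapply(members, sort))
}

## Canonical rotation by explicit enumeration of all 2L rotations.
bruteCanonical <- function(s) {
  rots <- function(x) {
    d <- paste0(x, x)
    vapply(seq_len(nchar(x)), function(i) substr(d, i, i + nchar(x) - 1L),
           character(1))
  }
  min(c(rots(s), rots(rcOracle(s))))
}

## Tandem period by brute-force lag scoring: fraction of positions i with
## seq[i] == seq[i + lag], maximized over lags (ties -> smallest lag).
bruteLagPeriod <- function(s, maxLag = nchar(s) %/% 2) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  frac <- vapply(seq_len(maxLag), function(lag)
    mean(ch[seq_len(n - lag)] == ch[seq_len(n - lag) + lag]), numeric(1))
  ## multiples of the fundamental period score within noise of each other;
  ## the period is the smallest near-maximal lag
  min(which(frac >= max(frac) - 0.02))
}

## All maximal telomere-unit chains (start0, nCopies, strand) with at most
## maxMM mismatches per copy, by explicit window enumeration.
bruteTelomereChains <- function(q, unit, maxMM = 1L, minCopies = 2L) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  u <- nchar(unit)
  n <- length(qc)
  out <- list()
  for (strand in c("+", "-")) {
    uc <- strsplit(if (strand == "+") unit else rcOracle(unit), "",
                   fixed = TRUE)[[1]]
    okCopy <- function(s) {
      if (s < 1L || s + u - 1L > n) return(FALSE)
      sum(qc[s:(s + u - 1L)] != uc) <= maxMM
    }
    for (s in seq_len(n)) {
      if (!okCopy(s) || okCopy(s - u)) next
      len <- 0L
      while (okCopy(s + len * u)) len <- len + 1L
      if (len >= minCopies)
        out[[length(out) + 1L]] <- data.frame(
          q_start = s - 1L, q_end = s - 1L + len * u, strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(q_start = integer(0), q_end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## Deterministic random DNA for fixtures.
randomSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

edgeKey <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(paste(pmin(df$read_i, df$read_j), pmax(df$read_i, df$read_j)))
}

## All k-mers of a sequence, forward strand, independent of the package.
.kmersOfOracle <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), k:n)
}
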