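## Alignment-free reconstruction of tandem monomer consensus sequences from
## cluster reads: k-mer frequency table, greedy high-frequency extension,
## circularization, tandem-period estimation, and positional base logos.

#' Count k-mer occurrences in a read set (both strands)
#'
#' Every k-mer occurrence in every read and in its reverse complement is
#' counted (reads are unstranded); k-mers containing N are skipped.
#'
#' @param reads `DNAStringSet` or character vector of reads.
#' @param k k-mer length, between 11 and 31 (17 and 20 are the values used
#'   for satellite monomer reconstruction).
#' @return A [KmerTable].
#' @examples
#' tab <- kmerFrequencies(strrep("ACGT", 10), k = 11)
#' @export
kmerFrequencies <- function(reads, k) {
  k <- as.integer(k)
  if (k < 11L || k > 31L)
    stop("k must be between 11 and 31", call. = FALSE)
  seqs <- .asSeqChar(reads)
  .checkDNA(seqs, "reads")
  if (!any(nchar(seqs) >= k))
    stop("no read reaches length k", call. = FALSE)
  seqs <- seqs[nchar(seqs) >= k]
  all <- c(seqs, .revcomp(seqs))
  km <- unlist(lapply(all, .kmersOf, k = k), use.names = FALSE)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (!length(km))
    stop("no countable k-mers (all contain N)", call. = FALSE)
  tab <- table(km)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  ## decreasing count, ties lexicographic, for deterministic seeding order
  counts <- counts[order(-counts, names(counts))]
  new("KmerTable", k = k, counts = counts, total = sum(counts))
}

#' Greedy reconstruction of high-frequency fragments
#'
#' Repeatedly seeds at the unused k-mer of highest frequency (at least
#' `seedMinFreq`), then extends right and left through overlapping k-mers:
#' among the four k-mers overlapping the current terminal k-mer by k-1
#' bases, the most frequent is taken; extension stops when its frequency
#' falls below `extensionThreshold` times the current terminal k-mer's
#' frequency, or when it is already part of the fragment (which is how a
#' circular monomer closes on itself). All k-mers of a finished fragment
#' are marked used.
#'
#' @param table A [KmerTable].
#' @param seedMinFreq Minimal seed k-mer frequency (default 0.0001).
#' @param extensionThreshold Extension threshold relative to the current
#'   terminal k-mer's frequency (default 0.10).
#' @return A list of fragments, each a list with `seq` (character) and
#'   `support` (frequency of the k-mer starting at each position;
#'   `length(support) == nchar(seq) - k + 1`), ordered by seed frequency
#'   descending.
#' @export
reconstructFragments <- function(table, seedMinFreq = 0.0001,
                                 extensionThreshold = 0.10) {
  if (seedMinFreq <= 0 || seedMinFreq >= 1 ||
      extensionThreshold <= 0 || extensionThreshold >= 1)
    stop("thresholds must be in (0, 1)", call. = FALSE)
  if (!length(table@counts))
    stop("empty k-mer table", call. = FALSE)
  k <- table@k
  freq <- table@counts / table@total
  used <- logical(length(freq))
  names(used) <- names(freq)
  lookup <- function(kmers) {
    f <- freq[kmers]
    f[is.na(f)] <- 0
    f
  }
  fragments <- list()
  seedable <- freq >= seedMinFreq
  repeat {
    open <- which(seedable & !used)
    if (!length(open)) break
    seed <- names(freq)[open[1L]]  # counts are sorted: highest freq first
    fragKmers <- seed
    inFrag <- new.env(hash = TRUE, parent = emptyenv())
    assign(seed, TRUE, envir = inFrag)
    ## rightward
    cur <- seed
    right <- character(0)
    repeat {
      cand <- paste0(substr(cur, 2L, k), .BASES)
      f <- lookup(cand)
      i <- which.max(f)  # ties: alphabetic (A first)
      if (f[i] == 0 || f[i] < extensionThreshold * unname(freq[cur]) ||
          !is.null(inFrag[[cand[i]]]))
        break
      cur <- cand[i]
      assign(cur, TRUE, envir = inFrag)
      right <- c(right, cur)
    }
    ## leftward
    cur <- seed
    left <- character(0)
    repeat {
      cand <- paste0(.BASES, substr(cur, 1L, k - 1L))
      f <- lookup(cand)
      i <- which.max(f)
      if (f[i] == 0 || f[i] < extensionThreshold * unname(freq[cur]) ||
          !is.null(inFrag[[cand[i]]]))
        break
      cur <- cand[i]
      assign(cur, TRUE, envir = inFrag)
      left <- c(cur, left)
    }
    chain <- c(left, seed, right)
    used[chain] <- TRUE
    ## the table counts both strands, so the mirror-image cycle of every
    ## fragment is present at the same frequencies; consume it too
    rcChain <- .revcomp(chain)
    used[rcChain[rcChain %in% names(used)]] <- TRUE
    seq <- paste0(chain[1L],
                  paste(substr(chain[-1L], k, k), collapse = ""))
    fragments[[length(fragments) + 1L]] <- list(
      seq = seq, support = unname(freq[chain]),
      seed_freq = unname(freq[seed]))
  }
  ord <- order(-vapply(fragments, `[[`, numeric(1), "seed_freq"))
  fragments[ord]
}

## Booth's least-rotation algorithm (O(n)): index (1-based) of the
## lexicographically least rotation of s.
.leastRotationStart <- function(s) {
  n <- nchar(s)
  ch <- strsplit(paste0(s, s), "", fixed = TRUE)[[1]]
  f <- rep(-1L, 2L * n)
  kk <- 0L
  for (j in 2:(2L * n)) {
    sj <- ch[j]
    i <- f[j - kk - 1L]
    while (i != -1L && sj != ch[kk + i + 2L]) {
      if (sj < ch[kk + i + 2L]) kk <- j - i - 2L
      i <- f[i + 1L]
    }
    if (sj != ch[kk + i + 2L]) {
      if (sj < ch[kk + 1L]) kk <- j - 1L
      f[j - kk] <- -1L
    } else {
      f[j - kk] <- i + 1L
    }
  }
  kk + 1L
}

#' Canonical rotation of a circular sequence
#'
#' The unique representative of a circular monomer: the lexicographically
#' smallest string among all rotations of the sequence and of its reverse
#' complement, so the result is invariant to phase and orientation.
#'
#' @param seq Character or `DNAString`.
#' @return Character scalar, the canonical rotation.
#' @examples
#' canonicalRotation("GTACA") == canonicalRotation("ACAGT")  # TRUE
#' @export
canonicalRotation <- function(seq) {
  s <- .asSeqChar(seq)
  .checkDNA(s, "sequence")
  best <- NULL
  for (x in c(s, .revcomp(s))) {
    i <- .leastRotationStart(x)
    rot <- paste0(substr(x, i, nchar(x)), substr(x, 1L, i - 1L))
    if (is.null(best) || rot < best) best <- rot
  }
  best
}

#' Circularize a reconstructed fragment into a monomer consensus
#'
#' A fragment wraps when its terminal (k-1)-mer exactly matches its first
#' (k-1) bases; the monomer is then the fragment with the duplicated
#' overlap removed, reported in canonical rotation, and the monomer length
#' is the cycle length.
#'
#' @param fragment A fragment from [reconstructFragments()] (or a character
#'   sequence).
#' @param k The k-mer length the fragment was built with.
#' @return A [MonomerConsensus] (logo/variants unfilled), or `NULL` for a
#'   non-circular fragment.
#' @examples
#' circularize("ACGTTGAC", k = 3)  # 6-bp monomer
#' @export
circularize <- function(fragment, k) {
  seq <- if (is.list(fragment)) fragment$seq else .asSeqChar(fragment)
  n <- nchar(seq)
  if (n < k)
    stop("fragment shorter than k", call. = FALSE)
  ov <- k - 1L
  if (n <= ov) return(NULL)
  if (substr(seq, 1L, ov) != substr(seq, n - ov + 1L, n))
    return(NULL)
  mono <- substr(seq, 1L, n - ov)
  mono <- canonicalRotation(mono)
  new("MonomerConsensus", monomer = mono, lengthBp = nchar(mono),
      circular = TRUE,
      logo = matrix(numeric(0), nrow = 4, ncol = 0,
                    dimnames = list(.BASES, NULL)),
      variants = data.frame(position = integer(0),
                            prevailing = character(0),
                            variant = character(0),
                            variant_freq = numeric(0),
                            stringsAsFactors = FALSE))
}

#' Estimate the tandem period of a sequence
#'
#' Collects, over all k-mers occurring more than once in `seq`, the
#' distances between successive occurrences, and returns the modal
#' distance - the tandem sub-repeat period estimate.
#'
#' @param seq Character or `DNAString` of length at least `2 * k`.
#' @param k k-mer length (default 10).
#' @return Integer period, or `NA` when fewer than 3 distinct k-mers
#'   repeat.
#' @export
tandemPeriod <- function(seq, k = 10L) {
  s <- .asSeqChar(seq)
  if (nchar(s) < 2L * k)
    stop("sequence must be at least 2k long", call. = FALSE)
  km <- .kmersOf(s, k)
  pos <- split(seq_along(km), km)
  pos <- pos[lengths(pos) > 1L]
  if (length(pos) < 3L) return(NA_integer_)
  d <- unlist(lapply(pos, diff), use.names = FALSE)
  d <- d[d > 0]
  tab <- table(d)
  as.integer(names(tab)[which.max(tab)])  # tie -> smallest distance
}

#' Positional base-frequency logo and variant positions
#'
#' Aligns every read (both orientations) to a 3-copy linearization of the
#' monomer, accumulates per-monomer-position base counts (positions taken
#' modulo the monomer length), and normalizes columns to frequencies.
#' Positions where the second most frequent base reaches `variantMinFreq`
#' are reported as variants.
#'
#' @param reads `DNAStringSet` or character vector.
#' @param monomer A circular [MonomerConsensus].
#' @param variantMinFreq Minimum frequency of the second base to call a
#'   variant (default 0.20).
#' @param minIdentity Identity gate (percent) for using a read (default 70).
#' @return The [MonomerConsensus] with `logo` and `variants` filled.
#' @export
positionalLogo <- function(reads, monomer, variantMinFreq = 0.20,
                           minIdentity = 70) {
  stopifnot(is(monomer, "MonomerConsensus"))
  if (!monomer@circular)
    stop("monomer must be circular", call. = FALSE)
  seqs <- .asSeqChar(reads)
  .checkDNA(seqs, "reads")
  if (!length(seqs))
    stop("no reads", call. = FALSE)
  L <- monomer@lengthBp
  lin <- Biostrings::DNAString(strrep(monomer@monomer, 3L))
  counts <- matrix(0, nrow = 4L, ncol = L, dimnames = list(.BASES, NULL))
  nUsed <- 0L
  for (s in seqs) {
    pats <- Biostrings::DNAStringSet(c(s, .revcomp(s)))
    aln <- Biostrings::pairwiseAlignment(
      pats, lin, type = "local", substitutionMatrix = .alnSubMat,
      gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT)
    best <- which.max(Biostrings::score(aln))
    aln <- aln[best]
    cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
    ## the read must align along most of its length, not just by a short
    ## chance hit, to contribute to the logo
    if (cols == 0 || cols < 0.5 * nchar(s)) next
    if (100 * Biostrings::nmatch(aln) / cols < minIdentity) next
    nUsed <- nUsed + 1L
    pg <- strsplit(as.character(Biostrings::alignedPattern(aln)), "",
                   fixed = TRUE)[[1]]
    sg <- strsplit(as.character(Biostrings::alignedSubject(aln)), "",
                   fixed = TRUE)[[1]]
    refPos <- Biostrings::start(Biostrings::subject(aln))  # 1-based on lin
    for (i in seq_along(pg)) {
      advance <- sg[i] != "-"
      if (advance && pg[i] %in% .BASES) {
        col <- (refPos - 1L) %% L + 1L
        counts[pg[i], col] <- counts[pg[i], col] + 1
      }
      if (advance) refPos <- refPos + 1L
    }
  }
  if (nUsed == 0L)
    stop("no read aligns above ", minIdentity, "% identity", call. = FALSE)
  covered <- colSums(counts) > 0
  if (!all(covered))
    stop("monomer positions without read coverage: ",
         paste(utils::head(which(!covered), 5L), collapse = ", "),
         call. = FALSE)
  logo <- sweep(counts, 2L, colSums(counts), "/")
  cons <- apply(logo, 2L, function(col) .BASES[which.max(col)])
  variants <- do.call(rbind, lapply(seq_len(L), function(p) {
    ord <- order(-logo[, p], .BASES)
    second <- ord[2L]
    if (logo[second, p] >= variantMinFreq)
      data.frame(position = p, prevailing = .BASES[ord[1L]],
                 variant = .BASES[second],
                 variant_freq = logo[second, p],
                 stringsAsFactors = FALSE)
    else NULL
  }))
  if (is.null(variants))
    variants <- data.frame(position = integer(0), prevailing = character(0),
                           variant = character(0), variant_freq = numeric(0),
                           stringsAsFactors = FALSE)
  initialize(monomer, logo = logo, variants = variants)
}

## Collapse a monomer that is an internal multimer: when rotating the
## circular monomer by a divisor p of its length matches >= minIdentity of
## positions, the monomer is p-periodic (the greedy walk traversed the
## cycle more than once through variant branches); the collapsed monomer
## is the per-phase majority consensus over the L/p repeats.
.collapseInternalPeriod <- function(mono, minPeriod = 10L,
                                    minIdentity = 0.95) {
  L <- nchar(mono)
  ch <- strsplit(mono, "", fixed = TRUE)[[1]]
  divs <- seq_len(L %/% 2)
  divs <- divs[L %% divs == 0 & divs >= minPeriod]
  for (p in divs) {
    shifted <- ch[(seq_len(L) - 1L + p) %% L + 1L]
    if (mean(ch == shifted) >= minIdentity) {
      m <- matrix(ch, nrow = p)
      cons <- apply(m, 1L, function(v) names(which.max(table(v))))
      return(canonicalRotation(paste(cons, collapse = "")))
    }
  }
  mono
}

#' Reconstruct the monomer consensus of a read cluster
#'
#' Convenience wrapper for the consensus stage: k-mer table, greedy
#' fragment reconstruction, and circularization of the first (highest
#' seed-frequency) fragment that wraps.
#'
#' @param reads Cluster member reads.
#' @param k k-mer length (17 or 20 for satellite monomers).
#' @param seedMinFreq,extensionThreshold See [reconstructFragments()].
#' @param maxFragments How many leading fragments to try to circularize
#'   (default 5).
#' @param collapsePeriod Collapse monomers that are internal multimers
#'   (the greedy walk can traverse the cycle more than once through
#'   variant branches before closing; default `TRUE`).
#' @return A [MonomerConsensus], or `NULL` when no leading fragment wraps.
#' @export
clusterConsensus <- function(reads, k = 17L, seedMinFreq = 0.0001,
                             extensionThreshold = 0.10, maxFragments = 5L,
                             collapsePeriod = TRUE) {
  tab <- kmerFrequencies(reads, k)
  frags <- reconstructFragments(tab, seedMinFreq, extensionThreshold)
  for (fr in utils::head(frags, maxFragments)) {
    mono <- circularize(fr, k)
    if (!is.null(mono)) {
      if (collapsePeriod) {
        collapsed <- .collapseInternalPeriod(mono@monomer)
        if (nchar(collapsed) != mono@lengthBp)
          mono <- monomerConsensus(collapsed)
      }
      return(mono)
    }
  }
  NULL
}

#' Construct a monomer consensus from a known sequence
#'
#' Wraps a known monomer (e.g. a published satellite consensus) as a
#' circular [MonomerConsensus] in canonical rotation, for use as an
#' alignment reference in junction classification.
#'
#' @param seq Monomer sequence (character or `DNAString`).
#' @param circular Logical (default `TRUE`).
#' @return A [MonomerConsensus] with empty logo and variant slots.
#' @export
monomerConsensus <- function(seq, circular = TRUE) {
  s <- .asSeqChar(seq)
  .checkDNA(s, "monomer")
  if (circular) s <- canonicalRotation(s)
  new("MonomerConsensus", monomer = s, lengthBp = nchar(s),
      circular = circular,
      logo = matrix(numeric(0), nrow = 4, ncol = 0,
                    dimnames = list(.BASES, NULL)),
      variants = data.frame(position = integer(0),
                            prevailing = character(0),
                            variant = character(0),
                            variant_freq = numeric(0),
                            stringsAsFactors = FALSE))
}
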