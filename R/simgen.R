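## Synthetic genomes with subtelomeric tandem arrays and 454-like shotgun
## reads, with full ground-truth records. All coordinates are 0-based
## half-open; strand is "+"/"-".

#' Generate a random monomer sequence
#'
#' @param lengthBp Monomer length in bp (>= 10).
#' @param gcFraction GC content in (0, 1).
#' @param seed Integer seed; the result is deterministic in
#'   (`lengthBp`, `gcFraction`, `seed`).
#' @return A character scalar of exactly `lengthBp` bases.
#' @examples
#' nchar(makeMonomer(182, 0.4, 1))  # 182
#' @export
makeMonomer <- function(lengthBp, gcFraction = 0.5, seed = 1L) {
  if (lengthBp < 10)
    stop("lengthBp must be >= 10", call. = FALSE)
  if (gcFraction <= 0 || gcFraction >= 1)
    stop("gcFraction must be in (0, 1)", call. = FALSE)
  .withSeed(seed, .randomDNA(lengthBp, gcFraction))
}

## Substitute bases at `rate` per position; returns list(chars, n_mut).
.substituteChars <- function(ch, rate) {
  if (rate <= 0) return(list(chars = ch, n_mut = 0L))
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    ch[hit] <- .BASES[(match(ch[hit], .BASES) - 1L + shift) %% 4L + 1L]
  }
  list(chars = ch, n_mut = length(hit))
}

## Substitutions plus (rarely) indels; indelRate split evenly between
## single-base insertions and deletions.
.mutateChars <- function(ch, divergence, indelRate = 0) {
  out <- .substituteChars(ch, divergence)
  ch <- out$chars
  nm <- out$n_mut
  if (indelRate > 0) {
    u <- runif(length(ch))
    del <- u < indelRate / 2
    ins <- u >= indelRate / 2 & u < indelRate
    if (any(del) || any(ins)) {
      pieces <- as.list(ch)
      for (i in which(ins))
        pieces[[i]] <- c(ch[i], sample(.BASES, 1L))
      pieces[del] <- list(character(0))
      ch <- unlist(pieces)
      nm <- nm + sum(ins) + sum(del)
    }
  }
  list(chars = ch, n_mut = nm)
}

#' Build a tandem array from a master monomer
#'
#' Each copy is mutated independently from the master (star phylogeny).
#' With `nSubfamilies > 1`, each subfamily first derives its own master from
#' the array master at the same divergence rate, and copies are mutated from
#' their subfamily master; this reproduces the contrast between
#' well-homogenized and subfamily-structured satellite families.
#'
#' @param monomer Master monomer (character or `DNAString`).
#' @param spec An [ArraySpec]; `monomerLength` must match `nchar(monomer)`.
#' @param seed Integer seed.
#' @return A list with `seq` (the array, character) and `copies`, a truth
#'   `data.frame` with columns `label`, `copy_index`, `start`, `end`
#'   (0-based half-open), `strand`, `n_mutations`, `subfamily`.
#' @examples
#' m <- makeMonomer(50, 0.5, 1)
#' arr <- buildArray(m, ArraySpec("sat", 50, 10), seed = 1)
#' nchar(arr$seq)  # 500
#' @export
buildArray <- function(monomer, spec, seed = 1L) {
  monomer <- .asSeqChar(monomer)
  .checkDNA(monomer, "monomer")
  if (nchar(monomer) != spec@monomerLength)
    stop("monomer length does not match spec@monomerLength", call. = FALSE)
  .withSeed(seed, {
    master <- strsplit(monomer, "", fixed = TRUE)[[1]]
    masters <- list(master)
    if (spec@nSubfamilies > 1L)
      masters <- lapply(seq_len(spec@nSubfamilies), function(i)
        .substituteChars(master, spec@divergenceRate)$chars)
    fam <- sample.int(spec@nSubfamilies, spec@nCopies, replace = TRUE)
    copies <- vector("list", spec@nCopies)
    nmut <- integer(spec@nCopies)
    for (i in seq_len(spec@nCopies)) {
      mut <- .mutateChars(masters[[fam[i]]], spec@divergenceRate,
                          spec@indelRate)
      copies[[i]] <- mut$chars
      nmut[i] <- mut$n_mut
    }
    lens <- lengths(copies)
    ends <- cumsum(lens)
    starts <- ends - lens
    list(
      seq = paste(vapply(copies, paste, character(1), collapse = ""),
                  collapse = ""),
      master = monomer,
      copies = data.frame(
        label = spec@label, copy_index = seq_len(spec@nCopies),
        start = starts, end = ends, strand = "+",
        n_mutations = nmut, subfamily = fam,
        stringsAsFactors = FALSE)
    )
  })
}

#' Assemble a chromosome end: telomere, distal array, junction, proximal array
#'
#' Emits `telomere run | arrayB | junction material | arrayA`, i.e. the
#' distal satellite array (B) between the telomere and the proximal array
#' (A), with one of three junction styles between the arrays:
#' \describe{
#'   \item{`direct`}{truncated terminal monomers join with no extra bases;}
#'   \item{`mixed`}{1--3 sub-monomer fragment pairs of both arrays
#'     interleave at the boundary;}
#'   \item{`insert`}{`insertLen` bp of random non-repeat sequence sits at
#'     the boundary (an `UNKNOWN` truth segment).}
#' }
#'
#' @param config A [SimConfig] (supplies the telomere unit and unit count).
#' @param arrayA,arrayB Results of [buildArray()] for the proximal (A) and
#'   distal (B) arrays.
#' @param junctionStyle `"direct"`, `"mixed"`, or `"insert"`.
#' @param insertLen Insert length in bp (style `"insert"` only).
#' @param seed Integer seed.
#' @return A list with `seq` (character) and `segments`, a truth
#'   `data.frame` (columns `label`, `start`, `end`, `strand`) of
#'   non-overlapping, contiguous segments covering the whole sequence.
#' @export
buildChromosomeEnd <- function(config, arrayA, arrayB,
                               junctionStyle = c("direct", "mixed", "insert"),
                               insertLen = 30L, seed = 1L) {
  junctionStyle <- match.arg(junctionStyle)
  .withSeed(seed, {
    labA <- arrayA$copies$label[1]
    labB <- arrayB$copies$label[1]
    lenA <- arrayA$copies$end[1] - arrayA$copies$start[1]
    lenB <- arrayB$copies$end[1] - arrayB$copies$start[1]
    tel <- strrep(config@telomereUnit, config@nTelomereUnits)
    seqA <- arrayA$seq
    seqB <- arrayB$seq
    ## truncate the facing terminal monomers so the junction falls at a
    ## random phase within each monomer
    trimB <- sample.int(lenB, 1L) - 1L
    trimA <- sample.int(lenA, 1L) - 1L
    seqB <- substr(seqB, 1L, nchar(seqB) - trimB)
    seqA <- substr(seqA, trimA + 1L, nchar(seqA))
    pieces <- c(TEL = tel, stats::setNames(seqB, labB))
    if (junctionStyle == "mixed") {
      nPairs <- sample(1:3, 1L)
      for (p in seq_len(nPairs)) {
        fragA <- .randomArrayFragment(arrayA$seq)
        fragB <- .randomArrayFragment(arrayB$seq)
        pieces <- c(pieces, stats::setNames(fragA, labA),
                    stats::setNames(fragB, labB))
      }
    } else if (junctionStyle == "insert") {
      if (insertLen < 0) stop("insertLen must be >= 0", call. = FALSE)
      if (insertLen > 0)
        pieces <- c(pieces, UNKNOWN = .randomDNA(insertLen))
    }
    pieces <- c(pieces, stats::setNames(seqA, labA))
    lens <- nchar(pieces)
    ends <- cumsum(lens)
    list(
      seq = paste(pieces, collapse = ""),
      segments = data.frame(
        label = names(pieces), start = ends - lens, end = ends,
        strand = "+", stringsAsFactors = FALSE)
    )
  })
}

## A sub-monomer fragment cut at a random internal position of an array.
.randomArrayFragment <- function(arraySeq, minLen = 40L, maxLen = 120L) {
  n <- nchar(arraySeq)
  len <- sample(seq.int(minLen, min(maxLen, n - 1L)), 1L)
  start <- sample.int(n - len + 1L, 1L)
  substr(arraySeq, start, start + len - 1L)
}

#' Embed arrays in a background genome
#'
#' Lays out the configured arrays left to right, separated and flanked by
#' random single-copy background sequence, to the configured genome size.
#'
#' @param config A [SimConfig] with at least one [ArraySpec].
#' @return A list with `seq` (character), `segments` (truth `data.frame`
#'   with `label` = array label or `"BG"`), and `arrays` (the per-array
#'   [buildArray()] results, named by label).
#' @export
buildGenome <- function(config) {
  .withSeed(config@seed, {
    arrays <- lapply(config@arraySpecs, function(spec) {
      m <- .randomDNA(spec@monomerLength, 0.45)
      buildArray(m, spec, seed = sample.int(2^30, 1L))
    })
    names(arrays) <- vapply(config@arraySpecs, function(s) s@label,
                            character(1))
    arrLens <- vapply(arrays, function(a) nchar(a$seq), numeric(1))
    bgTotal <- config@genomeSize - sum(arrLens)
    nGaps <- length(arrays) + 1L
    gapLens <- diff(round(seq(0, bgTotal, length.out = nGaps + 1L)))
    pieces <- character(0)
    for (i in seq_along(arrays)) {
      pieces <- c(pieces, BG = .randomDNA(gapLens[i]),
                  stats::setNames(arrays[[i]]$seq, names(arrays)[i]))
    }
    pieces <- c(pieces, BG = .randomDNA(gapLens[nGaps]))
    pieces <- pieces[nchar(pieces) > 0]
    lens <- nchar(pieces)
    ends <- cumsum(lens)
    list(
      seq = paste(pieces, collapse = ""),
      segments = data.frame(label = names(pieces), start = ends - lens,
                            end = ends, strand = "+",
                            stringsAsFactors = FALSE),
      arrays = arrays
    )
  })
}

#' Simulate 454-like shotgun reads from a genome
#'
#' Read count is Poisson with mean `coverage * genomeLength / readMeanLen`;
#' read lengths follow a normal law truncated below at 50 bp (and at the
#' genome length); start positions and strands are uniform; substitution
#' errors are applied per base at `errorRate`. Truth coordinates (0-based
#' half-open on the forward genome strand) are recorded in `mcols()`.
#'
#' @param genome Genome sequence (character or `DNAString`).
#' @param config A [SimConfig].
#' @param sourceLabel Value recorded in the truth `source` column.
#' @return A named `DNAStringSet`; `mcols()` holds `source`, `start`, `end`,
#'   `strand`, `n_errors`.
#' @export
simulateReads <- function(genome, config, sourceLabel = "genome") {
  genome <- .asSeqChar(genome)
  .checkDNA(genome, "genome")
  G <- nchar(genome)
  if (G < 50)
    stop("genome shorter than the minimum read length (50 bp)",
         call. = FALSE)
  .withSeed(config@seed, {
    n <- rpois(1L, config@coverage * G / config@readMeanLen)
    if (n == 0L)
      return(Biostrings::DNAStringSet())
    lens <- pmin(pmax(50L, as.integer(round(
      rnorm(n, config@readMeanLen, config@readLenSd)))), G)
    starts <- floor(runif(n) * (G - lens + 1L))  # 0-based
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(genome, starts + 1L, starts + lens)
    flip <- strand == "-"
    if (any(flip)) seqs[flip] <- .revcomp(seqs[flip])
    nerr <- integer(n)
    if (config@errorRate > 0) {
      for (i in seq_len(n)) {
        ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        out <- .substituteChars(ch, config@errorRate)
        seqs[i] <- paste(out$chars, collapse = "")
        nerr[i] <- out$n_mut
      }
    }
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- sprintf("r%06d", seq_len(n))
    S4Vectors::mcols(reads) <- S4Vectors::DataFrame(
      source = sourceLabel, start = starts, end = starts + lens,
      strand = strand, n_errors = nerr)
    reads
  })
}
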