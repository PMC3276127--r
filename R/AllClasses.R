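#' @import methods
#' @importFrom stats rnorm rpois runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

## ---------------------------------------------------------------------------
## ArraySpec: description of one planted tandem array
## ---------------------------------------------------------------------------

#' Specification of a tandem satellite array
#'
#' Describes one tandem array to be planted in a synthetic genome: the
#' monomer length, copy number, per-copy divergence from the master monomer
#' (a star phylogeny, i.e. every copy mutated independently from the master),
#' indel rate, and the number of sequence subfamilies (each subfamily derives
#' its own master from the array master, modelling partially homogenized
#' satellite families).
#'
#' @slot label Character label for the array (e.g. `"CL14like"`).
#' @slot monomerLength Integer monomer length in bp (>= 10).
#' @slot nCopies Integer number of monomer copies (>= 1).
#' @slot divergenceRate Substitutions per base per copy, in [0, 0.3].
#' @slot indelRate Indels per base per copy (default 0).
#' @slot nSubfamilies Number of subfamilies (>= 1).
#' @export
setClass("ArraySpec", representation(
  label = "character",
  monomerLength = "integer",
  nCopies = "integer",
  divergenceRate = "numeric",
  indelRate = "numeric",
  nSubfamilies = "integer"
))

setValidity("ArraySpec", function(object) {
  msg <- character(0)
  if (object@monomerLength < 10L)
    msg <- c(msg, "monomerLength must be >= 10")
  if (object@nCopies < 1L)
    msg <- c(msg, "nCopies must be >= 1")
  if (object@divergenceRate < 0 || object@divergenceRate > 0.3)
    msg <- c(msg, "divergenceRate must be in [0, 0.3]")
  if (object@indelRate < 0 || object@indelRate >= 1)
    msg <- c(msg, "indelRate must be in [0, 1)")
  if (object@nSubfamilies < 1L)
    msg <- c(msg, "nSubfamilies must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param label,monomerLength,nCopies,divergenceRate,indelRate,nSubfamilies
#'   See slot documentation.
#' @return An `ArraySpec` object.
#' @rdname ArraySpec-class
#' @examples
#' ArraySpec("CL14like", monomerLength = 182, nCopies = 100,
#'           divergenceRate = 0.02)
#' @export
ArraySpec <- function(label, monomerLength, nCopies,
                      divergenceRate = 0, indelRate = 0, nSubfamilies = 1) {
  new("ArraySpec", label = as.character(label),
      monomerLength = as.integer(monomerLength),
      nCopies = as.integer(nCopies),
      divergenceRate = as.numeric(divergenceRate),
      indelRate = as.numeric(indelRate),
      nSubfamilies = as.integer(nSubfamilies))
}

setMethod("show", "ArraySpec", function(object) {
  cat(sprintf(
    "ArraySpec '%s': %d x %d bp, divergence %.3g, indel %.3g, %d subfamil%s\n",
    object@label, object@nCopies, object@monomerLength,
    object@divergenceRate, object@indelRate, object@nSubfamilies,
    if (object@nSubfamilies == 1L) "y" else "ies"))
})

## ---------------------------------------------------------------------------
## SimConfig: the simulated study conditions
## ---------------------------------------------------------------------------

#' Configuration of a synthetic shotgun-sequencing experiment
#'
#' Holds the study conditions emulated by the generator: genome size, the
#' 454-like read-length law (truncated normal, mean 361 bp by default),
#' sequencing depth (0.53x by default, i.e. sub-1x shotgun coverage), the
#' per-base substitution error rate, the planted arrays, and the chromosome
#' end architecture (telomere unit, number of telomeric units, and the
#' telomere -> distal array -> proximal array order).
#'
#' @slot seed Integer RNG seed; every generator is a pure function of
#'   (inputs, seed).
#' @slot genomeSize Genome length in bp.
#' @slot readMeanLen Mean read length in bp (default 361).
#' @slot readLenSd Read length standard deviation in bp (default 60).
#' @slot coverage Target sequence coverage in genome equivalents (default
#'   0.53).
#' @slot errorRate Per-base substitution error rate in [0, 1).
#' @slot arraySpecs List of [ArraySpec] objects.
#' @slot telomereUnit Telomeric repeat unit (default `"TTTAGGG"`).
#' @slot nTelomereUnits Number of tandem telomere units at a chromosome end.
#' @slot endOrder Labels of chromosome-end blocks from the terminus inward.
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  genomeSize = "integer",
  readMeanLen = "integer",
  readLenSd = "integer",
  coverage = "numeric",
  errorRate = "numeric",
  arraySpecs = "list",
  telomereUnit = "character",
  nTelomereUnits = "integer",
  endOrder = "character"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@coverage <= 0)
    msg <- c(msg, "coverage must be > 0")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must be in [0, 1)")
  arrTotal <- sum(vapply(object@arraySpecs,
                         function(s) s@monomerLength * s@nCopies, numeric(1)))
  if (object@genomeSize < arrTotal)
    msg <- c(msg, "genomeSize smaller than the summed array lengths")
  if (!all(vapply(object@arraySpecs, is, logical(1), "ArraySpec")))
    msg <- c(msg, "arraySpecs must all be ArraySpec objects")
  if (grepl("[^ACGT]", object@telomereUnit))
    msg <- c(msg, "telomereUnit must be over {A,C,G,T}")
  if (length(msg)) msg else TRUE
})

#' @param seed,genomeSize,readMeanLen,readLenSd,coverage,errorRate,arraySpecs,telomereUnit,nTelomereUnits,endOrder
#'   See slot documentation.
#' @return A `SimConfig` object.
#' @rdname SimConfig-class
#' @examples
#' SimConfig(seed = 1, genomeSize = 1e5,
#'           arraySpecs = list(ArraySpec("sat", 182, 100)))
#' @export
SimConfig <- function(seed, genomeSize, readMeanLen = 361, readLenSd = 60,
                      coverage = 0.53, errorRate = 0, arraySpecs = list(),
                      telomereUnit = "TTTAGGG", nTelomereUnits = 30,
                      endOrder = c("TEL", "arrayB", "arrayA")) {
  new("SimConfig", seed = as.integer(seed), genomeSize = as.integer(genomeSize),
      readMeanLen = as.integer(readMeanLen), readLenSd = as.integer(readLenSd),
      coverage = as.numeric(coverage), errorRate = as.numeric(errorRate),
      arraySpecs = arraySpecs, telomereUnit = toupper(telomereUnit),
      nTelomereUnits = as.integer(nTelomereUnits),
      endOrder = as.character(endOrder))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: genome %d bp, %.2fx coverage, reads ~N(%d, %d) bp, error %.3g, %d array(s), seed %d\n",
    object@genomeSize, object@coverage, object@readMeanLen, object@readLenSd,
    object@errorRate, length(object@arraySpecs), object@seed))
})

## ---------------------------------------------------------------------------
## ReadGraph
## ---------------------------------------------------------------------------

#' Read-similarity graph
#'
#' Undirected simple graph whose nodes are read identifiers and whose edges
#' are pairwise similarity hits passing the identity and coverage cutoffs
#' (defaults 90% identity over at least 55% of the longer read).
#'
#' @slot nodes Character vector of read ids.
#' @slot edges `data.frame` with columns `read_i`, `read_j`, `identity_pct`,
#'   `longer_cov_frac`, `strand`.
#' @export
setClass("ReadGraph", representation(
  nodes = "character",
  edges = "data.frame"
))

setValidity("ReadGraph", function(object) {
  e <- object@edges
  msg <- character(0)
  need <- c("read_i", "read_j", "identity_pct", "longer_cov_frac", "strand")
  if (!all(need %in% names(e)))
    msg <- c(msg, "edges must have columns read_i, read_j, identity_pct, longer_cov_frac, strand")
  else {
    if (any(e$read_i == e$read_j))
      msg <- c(msg, "self edges not allowed")
    key <- paste(pmin(e$read_i, e$read_j), pmax(e$read_i, e$read_j))
    if (anyDuplicated(key))
      msg <- c(msg, "graph must be simple (one edge per pair)")
    if (!all(c(e$read_i, e$read_j) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ReadGraph-class Node (read id) vector.
#' @param graph A `ReadGraph`.
#' @export
graphNodes <- function(graph) graph@nodes

#' @describeIn ReadGraph-class Edge table.
#' @export
graphEdges <- function(graph) graph@edges

setMethod("show", "ReadGraph", function(object) {
  cat(sprintf("ReadGraph: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
})

## ---------------------------------------------------------------------------
## KmerTable
## ---------------------------------------------------------------------------

#' Double-stranded k-mer occurrence table
#'
#' Occurrence counts of every k-mer seen in a read set and in the reverse
#' complement of every read (reads are unstranded). k-mers containing N are
#' skipped. Frequencies are counts over the grand total.
#'
#' @slot k k-mer length.
#' @slot counts Named integer vector of occurrence counts, sorted decreasing.
#' @slot total Sum of all counts.
#' @export
setClass("KmerTable", representation(
  k = "integer",
  counts = "integer",
  total = "numeric"
))

setValidity("KmerTable", function(object) {
  msg <- character(0)
  if (object@total <= 0)
    msg <- c(msg, "total must be > 0")
  if (length(object@counts)) {
    if (any(nchar(names(object@counts)) != object@k))
      msg <- c(msg, "all k-mers must have length k")
    if (any(grepl("[^ACGT]", names(object@counts))))
      msg <- c(msg, "k-mers must be over {A,C,G,T}")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "KmerTable", function(object) {
  cat(sprintf("KmerTable: k = %d, %d distinct k-mers, %d occurrences\n",
              object@k, length(object@counts), as.integer(object@total)))
})

#' @describeIn KmerTable-class Frequency of one or more k-mers (0 for absent
#'   k-mers).
#' @param table A `KmerTable`.
#' @param kmer Character vector of k-mers.
#' @export
kmerFrequency <- function(table, kmer) {
  cnt <- table@counts[kmer]
  cnt[is.na(cnt)] <- 0L
  unname(cnt) / table@total
}

## ---------------------------------------------------------------------------
## MonomerConsensus
## ---------------------------------------------------------------------------

#' Circular tandem-repeat monomer consensus
#'
#' A reconstructed satellite monomer in canonical rotation (the
#' lexicographically smallest string among all rotations of the monomer and
#' of its reverse complement, so the representation is phase- and
#' orientation-free), optionally annotated with a positional base-frequency
#' matrix (sequence logo) and major variant positions.
#'
#' @slot monomer Monomer sequence (canonical rotation).
#' @slot lengthBp Monomer length in bp.
#' @slot circular Logical; `TRUE` when the fragment wrapped on itself.
#' @slot logo 4 x length matrix of per-position frequencies of A, C, G, T
#'   (each column sums to 1), or a 0-column matrix when not yet filled.
#' @slot variants `data.frame` with columns `position` (1-based on the
#'   canonical rotation), `prevailing`, `variant`, `variant_freq`.
#' @export
setClass("MonomerConsensus", representation(
  monomer = "character",
  lengthBp = "integer",
  circular = "logical",
  logo = "matrix",
  variants = "data.frame"
))

setValidity("MonomerConsensus", function(object) {
  msg <- character(0)
  if (object@lengthBp != nchar(object@monomer))
    msg <- c(msg, "lengthBp must equal nchar(monomer)")
  if (ncol(object@logo) > 0) {
    if (nrow(object@logo) != 4L || ncol(object@logo) != object@lengthBp)
      msg <- c(msg, "logo must be a 4 x lengthBp matrix")
    else if (any(abs(colSums(object@logo) - 1) > 1e-9))
      msg <- c(msg, "logo columns must sum to 1")
  }
  if (nrow(object@variants) &&
      any(object@variants$variant_freq >= 0.5 + 1e-12))
    msg <- c(msg, "variant frequency must be below the prevailing frequency")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MonomerConsensus", function(object) {
  cat(sprintf("MonomerConsensus: %d bp, %s, %d variant position(s)\n",
              object@lengthBp,
              if (object@circular) "circular" else "linear",
              nrow(object@variants)))
  s <- object@monomer
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" ", s, "\n")
})

#' @describeIn MonomerConsensus-class Monomer sequence (character scalar).
#' @param x A `MonomerConsensus`.
#' @export
monomerSeq <- function(x) x@monomer

#' @describeIn MonomerConsensus-class Monomer length in bp.
#' @export
monomerLength <- function(x) x@lengthBp

#' @describeIn MonomerConsensus-class Positional base-frequency matrix.
#' @export
logoMatrix <- function(x) x@logo

#' @describeIn MonomerConsensus-class Variant table.
#' @export
variantTable <- function(x) x@variants

## ---------------------------------------------------------------------------
## JunctionCall
## ---------------------------------------------------------------------------

#' Segmentation and classification of a junction clone
#'
#' A junction clone segmented into labelled intervals (two monomer labels,
#' `TEL`, or `UNKNOWN`) with a junction-type verdict: `direct` (two repeat
#' blocks abut), `mixed` (three or more alternating repeat blocks),
#' `insert_containing` (an internal unlabelled insert of at least
#' `minInsertLen` bp separates the blocks), `single_repeat` (one block only),
#' or `unresolved` (less than half of the clone could be labelled).
#'
#' @slot queryId Clone identifier.
#' @slot segments `data.frame` with columns `label`, `q_start`, `q_end`
#'   (0-based half-open on the clone), `ref_start`, `ref_end` (1-based on the
#'   circular monomer; NA for TEL/UNKNOWN), `strand`, `identity_pct`.
#' @slot junctionType One of `direct`, `mixed`, `insert_containing`,
#'   `single_repeat`, `unresolved`.
#' @slot insertLen Length in bp of the internal unlabelled insert
#'   (`NA_integer_` unless `insert_containing`).
#' @export
setClass("JunctionCall", representation(
  queryId = "character",
  segments = "data.frame",
  junctionType = "character",
  insertLen = "integer"
))

setValidity("JunctionCall", function(object) {
  msg <- character(0)
  s <- object@segments
  if (nrow(s)) {
    if (any(s$q_start >= s$q_end))
      msg <- c(msg, "segments must have q_start < q_end")
    if (is.unsorted(s$q_start))
      msg <- c(msg, "segments must be ordered by q_start")
    if (nrow(s) > 1 && any(s$q_start[-1] < s$q_end[-nrow(s)]))
      msg <- c(msg, "segments must not overlap")
  }
  ok <- c("direct", "mixed", "insert_containing", "single_repeat",
          "unresolved")
  if (!object@junctionType %in% ok)
    msg <- c(msg, paste("junctionType must be one of:", paste(ok, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "JunctionCall", function(object) {
  cat(sprintf("JunctionCall '%s': %s%s\n", object@queryId, object@junctionType,
              if (!is.na(object@insertLen))
                sprintf(" (insert %d bp)", object@insertLen) else ""))
  s <- object@segments
  if (nrow(s))
    cat(paste0("  ", s$label, ":", s$q_start, "-", s$q_end,
               ifelse(is.na(s$ref_start), "",
                      paste0(" [", s$ref_start, "-", s$ref_end, "]")),
               " ", s$strand, " ", roundHalfUp(s$identity_pct, 1), "%",
               collapse = "\n"), "\n")
})

#' @describeIn JunctionCall-class Junction-type verdict.
#' @param call A `JunctionCall`.
#' @export
junctionType <- function(call) call@junctionType

#' @describeIn JunctionCall-class Segment table.
#' @export
junctionSegments <- function(call) call@segments

#' @describeIn JunctionCall-class Internal insert length
#'   (`NA` unless `insert_containing`).
#' @export
insertLength <- function(call) call@insertLen
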