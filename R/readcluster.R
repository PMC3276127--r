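## All-vs-all read similarity, thresholded graph construction, and
## connected-component clustering (clusters of mutually overlapping reads =
## repeat families).

## Alignment summary statistics without materializing gapped strings.
## columns = matches + mismatches + inserted + deleted columns, i.e. the
## alignment length with gap columns included.
.alnStats <- function(aln) {
  ni <- Biostrings::nindel(aln)
  insW <- Biostrings::insertion(ni)[, "WidthSum"]
  delW <- Biostrings::deletion(ni)[, "WidthSum"]
  matches <- Biostrings::nmatch(aln)
  columns <- matches + Biostrings::nmismatch(aln) + insW + delW
  list(score = Biostrings::score(aln), matches = matches,
       columns = columns,
       widthP = Biostrings::width(Biostrings::pattern(aln)),
       widthS = Biostrings::width(Biostrings::subject(aln)))
}

## Best local alignment of b (both orientations) against a. Scoring: +1
## match, -2 mismatch, linear gap cost 2 per gapped column. Identity is
## matches / alignment columns, gap columns included in the denominator.
## Returns NULL when the optimal alignment has fewer than minAlnLen columns.
.alignPair <- function(a, b, minAlnLen = 30L) {
  pats <- Biostrings::DNAStringSet(c(fwd = b, rev = .revcomp(b)))
  aln <- Biostrings::pairwiseAlignment(
    pats, Biostrings::DNAString(a), type = "local",
    substitutionMatrix = .alnSubMat,
    gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT)
  st <- .alnStats(aln)
  best <- which.max(st$score)  # tie -> forward
  if (st$columns[best] < minAlnLen) return(NULL)
  lenA <- nchar(a)
  lenB <- nchar(b)
  covLonger <- if (lenA >= lenB) st$widthS[best] / lenA
               else st$widthP[best] / lenB
  list(score = st$score[best],
       identity_pct = 100 * st$matches[best] / st$columns[best],
       columns = st$columns[best],
       longer_cov_frac = covLonger,
       strand = if (best == 1L) "same" else "opposite")
}

#' Best local similarity between two reads
#'
#' Aligns `b` in both orientations against `a` and reports the best local
#' alignment. Identity is computed as matches over alignment columns (gap
#' columns count in the denominator); coverage is the aligned fraction of
#' the longer of the two reads.
#'
#' @param a,b Reads (character or `DNAString`).
#' @param minAlnLen Minimum alignment columns to report a hit (default 30).
#' @param idA,idB Read identifiers.
#' @return A one-row `data.frame` with columns `read_i`, `read_j`,
#'   `identity_pct`, `longer_cov_frac`, `strand` (`"same"`/`"opposite"`),
#'   or `NULL` when no alignment of at least `minAlnLen` columns exists.
#' @examples
#' r <- strrep("ACGT", 20)
#' pairwiseSimilarity(r, r)$identity_pct  # 100
#' @export
pairwiseSimilarity <- function(a, b, minAlnLen = 30L,
                               idA = "read_a", idB = "read_b") {
  a <- .asSeqChar(a)
  b <- .asSeqChar(b)
  .checkDNA(c(a, b), "reads")
  if (!nchar(a) || !nchar(b))
    stop("reads must be nonempty", call. = FALSE)
  hit <- .alignPair(a, b, minAlnLen)
  if (is.null(hit)) return(NULL)
  data.frame(read_i = idA, read_j = idB,
             identity_pct = hit$identity_pct,
             longer_cov_frac = hit$longer_cov_frac,
             strand = hit$strand, stringsAsFactors = FALSE,
             row.names = NULL)
}

## Candidate pairs sharing at least one k-mer, with orientation flags.
## fwd: a forward k-mer shared; rev: a k-mer of one read occurs in the
## reverse complement of the other. Built from sparse read-by-kmer
## incidence matrices.
.candidatePairs <- function(seqs, k = 12L) {
  n <- length(seqs)
  kmF <- lapply(seqs, function(s) unique(.kmersOf(s, k)))
  kmR <- lapply(seqs, function(s) unique(.kmersOf(.revcomp(s), k)))
  lev <- unique(c(unlist(kmF, use.names = FALSE),
                  unlist(kmR, use.names = FALSE)))
  Fm <- Matrix::sparseMatrix(
    i = rep(seq_len(n), lengths(kmF)),
    j = match(unlist(kmF, use.names = FALSE), lev), x = 1,
    dims = c(n, length(lev)))
  Rm <- Matrix::sparseMatrix(
    i = rep(seq_len(n), lengths(kmR)),
    j = match(unlist(kmR, use.names = FALSE), lev), x = 1,
    dims = c(n, length(lev)))
  S <- Matrix::tcrossprod(Fm)
  O <- Matrix::tcrossprod(Fm, Rm)
  O <- O + Matrix::t(O)
  up <- function(M) {
    tr <- methods::as(M, "TsparseMatrix")
    keep <- tr@i < tr@j & tr@x > 0
    cbind(i = tr@i[keep] + 1L, j = tr@j[keep] + 1L)
  }
  sameP <- up(S)
  oppP <- up(O)
  key <- function(m) paste(m[, 1], m[, 2])
  allP <- unique(rbind(sameP, oppP))
  data.frame(i = allP[, 1], j = allP[, 2],
             fwd = key(allP) %in% key(sameP),
             rev = key(allP) %in% key(oppP))
}

#' Build the read-similarity graph
#'
#' Performs (possibly k-mer-prefiltered) all-vs-all comparison of the reads
#' and keeps an edge for every pair whose best local alignment reaches both
#' cutoffs: identity of at least `identityCutoff` percent over at least
#' `coverageCutoff` of the longer read. The prefilter only skips
#' pair-orientations that share no exact `prefilterK`-mer and is
#' equivalent to the exhaustive scan whenever true overlaps retain at
#' least one exact `prefilterK`-mer (always the case at the similarity
#' levels the cutoffs accept, unless mismatches are pathologically evenly
#' spaced).
#'
#' @param reads A named `DNAStringSet` (or named character vector) of at
#'   least 2 reads with unique ids.
#' @param identityCutoff Identity threshold in percent (default 90).
#' @param coverageCutoff Minimum aligned fraction of the longer read
#'   (default 0.55).
#' @param minAlnLen Minimum alignment columns for a hit (default 30).
#' @param prefilter Use the shared-k-mer prefilter (default `TRUE`); set
#'   `FALSE` for the exhaustive all-vs-all scan.
#' @param prefilterK k-mer length of the prefilter (default 12).
#' @return A [ReadGraph].
#' @export
buildReadGraph <- function(reads, identityCutoff = 90,
                           coverageCutoff = 0.55, minAlnLen = 30L,
                           prefilter = TRUE, prefilterK = 12L) {
  seqs <- .asSeqChar(reads)
  if (length(seqs) < 2L)
    stop("need at least 2 reads", call. = FALSE)
  ids <- names(reads)
  if (is.null(ids) || anyDuplicated(ids))
    stop("reads must carry unique names", call. = FALSE)
  .checkDNA(seqs, "reads")
  if (prefilter) {
    pairs <- .candidatePairs(seqs, prefilterK)
  } else {
    m <- t(utils::combn(seq_along(seqs), 2L))
    pairs <- data.frame(i = m[, 1], j = m[, 2], fwd = TRUE, rev = TRUE)
  }
  lens <- nchar(seqs)
  rc <- .revcomp(seqs)
  edges <- vector("list", length(seqs))
  for (j in sort(unique(pairs$j))) {
    pj <- pairs[pairs$j == j, ]
    is <- c(pj$i[pj$fwd], pj$i[pj$rev])
    ori <- rep(c("same", "opposite"), c(sum(pj$fwd), sum(pj$rev)))
    pats <- Biostrings::DNAStringSet(
      c(seqs[pj$i[pj$fwd]], rc[pj$i[pj$rev]]))
    aln <- Biostrings::pairwiseAlignment(
      pats, Biostrings::DNAString(seqs[j]), type = "local",
      substitutionMatrix = .alnSubMat,
      gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT)
    st <- .alnStats(aln)
    ## best orientation per pair: higher score, ties -> forward
    ord <- order(st$score[seq_along(is)] -
                   ifelse(ori == "same", 0, 1e-9), decreasing = TRUE)
    first <- ord[!duplicated(is[ord])]
    identity <- 100 * st$matches[first] / st$columns[first]
    cov <- ifelse(lens[is[first]] >= lens[j],
                  st$widthP[first] / lens[is[first]],
                  st$widthS[first] / lens[j])
    keep <- st$columns[first] >= minAlnLen &
      identity >= identityCutoff & cov >= coverageCutoff
    if (any(keep)) {
      edges[[j]] <- data.frame(
        read_i = ids[is[first][keep]], read_j = ids[j],
        identity_pct = identity[keep],
        longer_cov_frac = cov[keep],
        strand = ori[first][keep],
        stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges))
    edges <- data.frame(read_i = character(0), read_j = character(0),
                        identity_pct = numeric(0),
                        longer_cov_frac = numeric(0),
                        strand = character(0), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  new("ReadGraph", nodes = ids, edges = edges)
}

#' Extract read clusters from the similarity graph
#'
#' Clusters are the connected components of the thresholded graph, sorted
#' by size descending (ties broken by the lexicographically smallest member
#' read id) and labelled `CL1`, `CL2`, ... in that order. Singleton nodes
#' are excluded. `proportion_pct` is `100 * n_reads / totalReads`, the
#' read-count genome-proportion estimate of each repeat family.
#'
#' @param graph A [ReadGraph].
#' @param totalReads Total number of reads in the dataset (>= number of
#'   graph nodes).
#' @param method Component extraction method; only `"components"` is
#'   implemented (`"community"` is reserved).
#' @return A `data.frame` with columns `cluster_id`, `n_reads`,
#'   `proportion_pct`, and a list-column `read_ids`.
#' @export
clusterReads <- function(graph, totalReads,
                         method = c("components", "community")) {
  method <- match.arg(method)
  if (method == "community")
    stop("community detection is reserved; use method = 'components'",
         call. = FALSE)
  if (totalReads < length(graph@nodes))
    stop("totalReads must be >= the number of graph nodes", call. = FALSE)
  empty <- data.frame(cluster_id = character(0), n_reads = integer(0),
                      proportion_pct = numeric(0), stringsAsFactors = FALSE)
  empty$read_ids <- list()
  if (!nrow(graph@edges)) return(empty)
  g <- igraph::graph_from_data_frame(
    graph@edges[, c("read_i", "read_j")], directed = FALSE,
    vertices = graph@nodes)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- members[lengths(members) >= 2L]
  if (!length(members)) return(empty)
  members <- lapply(members, sort)
  ord <- order(-lengths(members),
               vapply(members, `[`, character(1), 1L))
  members <- members[ord]
  out <- data.frame(
    cluster_id = paste0("CL", seq_along(members)),
    n_reads = lengths(members),
    proportion_pct = 100 * lengths(members) / totalReads,
    stringsAsFactors = FALSE)
  out$read_ids <- unname(members)
  rownames(out) <- NULL
  out
}
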