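## Segmentation of junction-clone sequences against monomer and telomere
## references, and classification of the junction pattern (direct / mixed /
## insert-containing / single-repeat).

#' Detect telomeric repeat runs
#'
#' Reports maximal runs of at least `minCopies` tandem copies of the
#' telomere unit, on either strand, allowing up to `maxMismatchPerCopy`
#' substitutions per unit copy.
#'
#' @param query Sequence (character or `DNAString`).
#' @param unit Telomere unit (default `"TTTAGGG"`).
#' @param minCopies Minimum tandem copies to report (default 2).
#' @param maxMismatchPerCopy Allowed mismatches per copy (default 1).
#' @return A `data.frame` of segments (`label = "TEL"`, `q_start`, `q_end`
#'   0-based half-open, `strand`, `identity_pct`, `n_copies`); zero rows
#'   when no run is found.
#' @examples
#' scanTelomere(strrep("TTTAGGG", 10))$q_end  # 70
#' @export
scanTelomere <- function(query, unit = "TTTAGGG", minCopies = 2L,
                         maxMismatchPerCopy = 1L) {
  q <- .asSeqChar(query)
  .checkDNA(q, "query")
  if (!nchar(q))
    stop("query must be nonempty", call. = FALSE)
  u <- nchar(unit)
  n <- nchar(q)
  runs <- list()
  if (n >= minCopies * u) {
    qc <- strsplit(q, "", fixed = TRUE)[[1]]
    for (strand in c("+", "-")) {
      uc <- strsplit(if (strand == "+") unit else .revcomp(unit), "",
                     fixed = TRUE)[[1]]
      nw <- n - u + 1L
      mism <- integer(nw)
      for (j in seq_len(u))
        mism <- mism + (qc[seq_len(nw) + j - 1L] != uc[j])
      ok <- mism <= maxMismatchPerCopy
      ## chain windows spaced exactly one unit apart
      for (s in which(ok)) {
        prev <- s - u
        if (prev >= 1L && ok[prev]) next  # not the start of a chain
        len <- 1L
        while (s + len * u <= nw && ok[s + len * u]) len <- len + 1L
        if (len >= minCopies) {
          mm <- sum(mism[s + (seq_len(len) - 1L) * u])
          runs[[length(runs) + 1L]] <- data.frame(
            label = "TEL", q_start = s - 1L, q_end = s - 1L + len * u,
            strand = strand,
            identity_pct = 100 * (1 - mm / (len * u)),
            n_copies = len, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(runs))
    return(data.frame(label = character(0), q_start = integer(0),
                      q_end = integer(0), strand = character(0),
                      identity_pct = numeric(0), n_copies = integer(0),
                      stringsAsFactors = FALSE))
  runs <- do.call(rbind, runs)
  ## keep non-overlapping runs, longest (then highest identity) first
  runs <- runs[order(-(runs$q_end - runs$q_start), -runs$identity_pct), ]
  kept <- runs[0, ]
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    if (!nrow(kept) ||
        all(r$q_end <= kept$q_start | r$q_start >= kept$q_end))
      kept <- rbind(kept, r)
  }
  kept <- kept[order(kept$q_start), ]
  rownames(kept) <- NULL
  kept
}

#' Local alignments of a query against a circular monomer
#'
#' Aligns the query (both strands) against a 3-copy linearization of the
#' monomer, then recursively realigns the unaligned flanks, so several
#' non-overlapping monomer segments per query are recovered. Reference
#' coordinates are reported modulo the monomer length, 1-based on the
#' canonical rotation.
#'
#' @param query Sequence (character or `DNAString`).
#' @param monomer A circular [MonomerConsensus].
#' @param minIdentity Minimum percent identity to keep an alignment
#'   (default 60).
#' @param minLen Minimum alignment columns (default 25).
#' @param label Segment label (default `"MONO"`).
#' @return A `data.frame` of segments (`label`, `q_start`, `q_end` 0-based
#'   half-open, `ref_start`, `ref_end` 1-based circular, `strand`,
#'   `identity_pct`), ordered by `q_start`.
#' @export
alignCircular <- function(query, monomer, minIdentity = 60, minLen = 25L,
                          label = "MONO") {
  stopifnot(is(monomer, "MonomerConsensus"))
  if (!monomer@circular)
    stop("monomer must be circular", call. = FALSE)
  q <- .asSeqChar(query)
  .checkDNA(q, "query")
  L <- monomer@lengthBp
  lin <- Biostrings::DNAString(strrep(monomer@monomer, 3L))
  segs <- list()
  scan <- function(from, to) {   # 1-based inclusive interval on q
    if (to - from + 1L < minLen) return(invisible())
    sub <- substr(q, from, to)
    pats <- Biostrings::DNAStringSet(c(sub, .revcomp(sub)))
    aln <- Biostrings::pairwiseAlignment(
      pats, lin, type = "local", substitutionMatrix = .alnSubMat,
      gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT)
    st <- .alnStats(aln)
    best <- which.max(st$score)
    a <- aln[best]
    cols <- st$columns[best]
    if (cols < minLen) return(invisible())
    ident <- 100 * st$matches[best] / cols
    if (ident < minIdentity) return(invisible())
    ps <- Biostrings::start(Biostrings::pattern(a))
    pe <- Biostrings::end(Biostrings::pattern(a))
    subLen <- nchar(sub)
    if (best == 2L) {  # coordinates were on the reverse complement
      tmp <- subLen - pe + 1L
      pe <- subLen - ps + 1L
      ps <- tmp
    }
    qs <- from + ps - 2L           # 0-based half-open on q
    qe <- from + pe - 1L
    ss <- Biostrings::start(Biostrings::subject(a))
    se <- Biostrings::end(Biostrings::subject(a))
    segs[[length(segs) + 1L]] <<- data.frame(
      label = label, q_start = qs, q_end = qe,
      ref_start = (ss - 1L) %% L + 1L, ref_end = (se - 1L) %% L + 1L,
      strand = if (best == 1L) "+" else "-",
      identity_pct = ident, stringsAsFactors = FALSE)
    scan(from, qs)                 # left flank (q 1-based end = qs)
    scan(qe + 1L, to)
  }
  scan(1L, nchar(q))
  if (!length(segs))
    return(data.frame(label = character(0), q_start = integer(0),
                      q_end = integer(0), ref_start = integer(0),
                      ref_end = integer(0), strand = character(0),
                      identity_pct = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  out <- out[order(out$q_start), ]
  rownames(out) <- NULL
  out
}

## Greedy exact-match boundary extension of a monomer segment along the
## circular reference: walk outward base by base; an isolated mismatch is
## absorbed only when the following 4 bases match (so a boundary into
## non-repeat sequence stops within ~1 bp). Recovers segment ends that the
## anchor intervals clip when a substitution falls near a true boundary.
.refineBoundary <- function(q, r, monomer, lookahead = 4L) {
  if (is.na(r$ref_start)) return(r)
  refc <- strsplit(monomer@monomer, "", fixed = TRUE)[[1]]
  L <- length(refc)
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  wrap <- function(p) (p - 1L) %% L + 1L
  ## qDir: +1 extend right, -1 extend left; returns bases consumed
  walk <- function(qPos0, refPos0, refDir, flip, qDir) {
    consumed <- 0L
    qPos <- qPos0
    refPos <- refPos0
    repeat {
      nq <- qPos + qDir
      if (nq < 1L || nq > length(qc)) break
      rb <- refc[wrap(refPos + refDir)]
      if (flip) rb <- comp[[rb]]
      if (qc[nq] == rb) {
        qPos <- nq
        refPos <- refPos + refDir
        consumed <- consumed + 1L
        next
      }
      ## isolated-substitution bridge
      ok <- TRUE
      for (m in seq_len(lookahead)) {
        qm <- nq + m * qDir
        if (qm < 1L || qm > length(qc)) { ok <- FALSE; break }
        rm <- refc[wrap(refPos + (1L + m) * refDir)]
        if (flip) rm <- comp[[rm]]
        if (qc[qm] != rm) { ok <- FALSE; break }
      }
      if (!ok) break
      qPos <- nq + lookahead * qDir
      refPos <- refPos + (1L + lookahead) * refDir
      consumed <- consumed + 1L + lookahead
    }
    consumed
  }
  plus <- r$strand == "+"
  ## rightward: q position r$q_end (0-based exclusive) = 1-based index q_end
  nR <- walk(r$q_end, if (plus) r$ref_end else r$ref_start,
             if (plus) +1L else -1L, !plus, +1L)
  ## leftward: first q char is 1-based index q_start + 1
  nL <- walk(r$q_start + 1L, if (plus) r$ref_start else r$ref_end,
             if (plus) -1L else +1L, !plus, -1L)
  r$q_end <- r$q_end + nR
  r$q_start <- r$q_start - nL
  if (plus) {
    r$ref_end <- wrap(r$ref_end + nR)
    r$ref_start <- wrap(r$ref_start - nL)
  } else {
    r$ref_start <- wrap(r$ref_start - nR)
    r$ref_end <- wrap(r$ref_end + nL)
  }
  r
}

## Per-base match vector of gap bases against the expected circular
## continuation of a flanking segment (in query order).
.gapMatches <- function(gapChars, monomer, startRef, refDir, flip,
                        fromEnd = FALSE) {
  refc <- strsplit(monomer@monomer, "", fixed = TRUE)[[1]]
  L <- length(refc)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  g <- length(gapChars)
  out <- logical(g)
  pos <- startRef
  idx <- if (fromEnd) rev(seq_len(g)) else seq_len(g)
  for (i in idx) {
    pos <- pos + refDir
    rb <- refc[(pos - 1L) %% L + 1L]
    if (flip) rb <- comp[[rb]]
    out[i] <- gapChars[i] == rb
  }
  out
}

## Trim candidate segment r so it does not overlap interval [s, e); ref
## coordinates are shifted by the trimmed amount (gapless colinearity
## approximation - exact within the boundary-wobble tolerance).
.trimSegment <- function(r, s, e, L) {
  if (r$q_start >= e || r$q_end <= s) return(r)       # no overlap
  leftLen <- s - r$q_start
  rightLen <- r$q_end - e
  if (leftLen >= rightLen) {                           # keep left piece
    cut <- r$q_end - s
    r$q_end <- s
    if (!is.na(r$ref_end)) {
      if (r$strand == "+") r$ref_end <- (r$ref_end - cut - 1L) %% L + 1L
      else r$ref_start <- (r$ref_start + cut - 1L) %% L + 1L
    }
  } else {                                             # keep right piece
    cut <- e - r$q_start
    r$q_start <- e
    if (!is.na(r$ref_start)) {
      if (r$strand == "+") r$ref_start <- (r$ref_start + cut - 1L) %% L + 1L
      else r$ref_end <- (r$ref_end - cut - 1L) %% L + 1L
    }
  }
  r
}

## k-mer anchored intervals of q against a reference's k-mer set (both
## strands): maximal unions of exact-match k-mer placements, nearby runs
## merged, padded so boundary bases lost to a substitution near a segment
## end are recovered by the subsequent alignment. Prevents a local
## alignment from bridging across a foreign block (no exact k-mer there).
.anchorIntervals <- function(q, refKmerSet, k0 = 12L, mergeGap = 24L,
                             pad = 0L, minLen = 25L) {
  n <- nchar(q)
  if (n < k0) return(NULL)
  km <- .kmersOf(q, k0)
  hit <- which(!is.na(match(km, refKmerSet)))
  if (!length(hit)) return(NULL)
  ## union of [i, i + k0) intervals, merging gaps <= mergeGap
  starts <- hit
  ends <- hit + k0 - 1L
  brk <- which(starts[-1] - ends[-length(ends)] - 1L > mergeGap)
  from <- starts[c(1L, brk + 1L)]
  to <- ends[c(brk, length(ends))]
  from <- pmax(1L, from - pad)
  to <- pmin(n, to + pad)
  keep <- to - from + 1L >= minLen
  if (!any(keep)) return(NULL)
  cbind(from = from[keep], to = to[keep])
}

#' Segment and classify a junction clone
#'
#' Tiles the clone greedily with the highest-identity segments drawn from
#' telomere-run detection and circular alignment against both monomers,
#' then assigns the junction type: internal unlabelled gaps of at least
#' `minInsertLen` bp become `UNKNOWN` segments and make the clone
#' `insert_containing`; three or more alternating repeat blocks are
#' `mixed`; exactly two abutting blocks are `direct`; one block is
#' `single_repeat`. Clones with less than half their length labelled are
#' `unresolved`.
#'
#' @param query Clone sequence (character or `DNAString`).
#' @param monomerA,monomerB Circular [MonomerConsensus] references for the
#'   two repeat families.
#' @param unit Telomere unit (default `"TTTAGGG"`).
#' @param labels Labels for `monomerA` and `monomerB` segments.
#' @param queryId Clone identifier.
#' @param minInsertLen Minimum internal gap to call an `UNKNOWN` insert
#'   (default 10 bp); smaller residuals are absorbed as boundary slack.
#' @param minIdentity,minLen Alignment acceptance thresholds (see
#'   [alignCircular()]).
#' @param mergeSlack Adjacent same-label segments separated by at most this
#'   many bases are merged into one block (default 5).
#' @return A [JunctionCall].
#' @export
classifyJunction <- function(query, monomerA, monomerB, unit = "TTTAGGG",
                             labels = c("CL14", "CL34"),
                             queryId = "clone", minInsertLen = 10L,
                             minIdentity = 60, minLen = 25L,
                             mergeSlack = 5L) {
  q <- .asSeqChar(query)
  .checkDNA(q, "query")
  n <- nchar(q)
  if (n < 50L)
    stop("query must be at least 50 bp", call. = FALSE)
  tel <- scanTelomere(q, unit = unit)
  if (nrow(tel)) tel <- tel[, names(tel) != "n_copies"]
  if (nrow(tel)) {
    tel$ref_start <- NA_integer_
    tel$ref_end <- NA_integer_
    tel <- tel[, c("label", "q_start", "q_end", "ref_start", "ref_end",
                   "strand", "identity_pct")]
  }
  ## candidate monomer segments: align only within k-mer anchored
  ## intervals, so short alternating blocks cannot be bridged over
  ## sub-monomer fragments at mixed junctions can have clean (anchorable)
  ## cores shorter than the reporting minimum, so candidates are generated
  ## down to candMinLen columns; boundary refinement then restores their
  ## true extent before the final size filter
  candMinLen <- min(minLen, 15L)
  anchoredSegments <- function(monomer, label) {
    lin2 <- strrep(monomer@monomer, 2L)
    refSet <- unique(c(.kmersOf(lin2, 12L), .kmersOf(.revcomp(lin2), 12L)))
    iv <- .anchorIntervals(q, refSet, minLen = candMinLen)
    if (is.null(iv)) return(NULL)
    out <- lapply(seq_len(nrow(iv)), function(r) {
      seg <- alignCircular(substr(q, iv[r, "from"], iv[r, "to"]),
                           monomer, minIdentity, candMinLen, label = label)
      if (nrow(seg)) {
        seg$q_start <- seg$q_start + iv[r, "from"] - 1L
        seg$q_end <- seg$q_end + iv[r, "from"] - 1L
      }
      seg
    })
    do.call(rbind, out)
  }
  segA <- anchoredSegments(monomerA, labels[1])
  segB <- anchoredSegments(monomerB, labels[2])
  cand <- rbind(if (nrow(tel)) tel, segA, segB)
  accepted <- list()
  if (!is.null(cand) && nrow(cand)) {
    ## telomere runs are exact-model hits; monomer alignments compete by
    ## identity then length
    cand <- cand[order(cand$label != "TEL", -cand$identity_pct,
                       -(cand$q_end - cand$q_start)), ]
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, ]
      for (a in accepted) {
        r <- .trimSegment(r, a$q_start, a$q_end,
                          if (r$label == labels[1]) monomerA@lengthBp
                          else monomerB@lengthBp)
        if (r$q_end - r$q_start < candMinLen) break
      }
      if (r$q_end - r$q_start >= candMinLen)
        accepted[[length(accepted) + 1L]] <- r
    }
  }
  if (!length(accepted)) {
    segs <- data.frame(label = character(0), q_start = integer(0),
                       q_end = integer(0), ref_start = integer(0),
                       ref_end = integer(0), strand = character(0),
                       identity_pct = numeric(0), stringsAsFactors = FALSE)
    return(new("JunctionCall", queryId = queryId, segments = segs,
               junctionType = "unresolved", insertLen = NA_integer_))
  }
  ## refine monomer-segment boundaries, then resolve any small overlaps
  ## the extensions introduced
  accepted <- lapply(accepted, function(r) {
    if (r$label == labels[1]) .refineBoundary(q, r, monomerA)
    else if (r$label == labels[2]) .refineBoundary(q, r, monomerB)
    else r
  })
  segs <- do.call(rbind, accepted)
  segs <- segs[order(segs$q_start), ]
  if (nrow(segs) > 1L) {
    for (i in seq_len(nrow(segs))[-1]) {
      ov <- segs$q_end[i - 1L] - segs$q_start[i]
      if (ov > 0L) {
        segs$q_start[i] <- segs$q_start[i] + ov
        if (!is.na(segs$ref_start[i])) {
          Lr <- if (segs$label[i] == labels[1]) monomerA@lengthBp
                else monomerB@lengthBp
          if (segs$strand[i] == "+")
            segs$ref_start[i] <- (segs$ref_start[i] + ov - 1L) %% Lr + 1L
          else
            segs$ref_end[i] <- (segs$ref_end[i] - ov - 1L) %% Lr + 1L
        }
      }
    }
    segs <- segs[segs$q_end - segs$q_start > 0L, ]
  }

  ## merge adjacent same-label segments into blocks
  merged <- segs[1, ]
  for (i in seq_len(nrow(segs))[-1]) {
    r <- segs[i, ]
    last <- nrow(merged)
    if (r$label == merged$label[last] &&
        r$q_start - merged$q_end[last] <= mergeSlack) {
      cols <- c(merged$q_end[last] - merged$q_start[last],
                r$q_end - r$q_start)
      merged$identity_pct[last] <-
        sum(c(merged$identity_pct[last], r$identity_pct) * cols) / sum(cols)
      merged$q_end[last] <- r$q_end
      if (!is.na(r$ref_end)) merged$ref_end[last] <- r$ref_end
    } else {
      merged <- rbind(merged, r)
    }
  }
  segs <- merged
  ## gap absorption: an internal gap whose bases continue the flanking
  ## repeats (ungapped identity >= 60% at the best split point) is repeat
  ## sequence that boundary clipping left unlabelled, not an insert; a
  ## random insert fails the identity test and stays unlabelled
  monomerOf <- function(lab) if (lab == labels[1]) monomerA else monomerB
  if (nrow(segs) > 1L) {
    qc <- strsplit(q, "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(segs) - 1L)) {
      gLen <- segs$q_start[i + 1L] - segs$q_end[i]
      if (gLen < 1L) next
      gapChars <- qc[(segs$q_end[i] + 1L):segs$q_start[i + 1L]]
      segL <- segs[i, ]
      segR <- segs[i + 1L, ]
      mL <- if (is.na(segL$ref_start)) rep(FALSE, gLen)
            else if (segL$strand == "+")
              .gapMatches(gapChars, monomerOf(segL$label), segL$ref_end,
                          +1L, FALSE)
            else .gapMatches(gapChars, monomerOf(segL$label),
                             segL$ref_start, -1L, TRUE)
      mR <- if (is.na(segR$ref_start)) rep(FALSE, gLen)
            else if (segR$strand == "+")
              .gapMatches(gapChars, monomerOf(segR$label), segR$ref_start,
                          -1L, FALSE, fromEnd = TRUE)
            else .gapMatches(gapChars, monomerOf(segR$label), segR$ref_end,
                             +1L, TRUE, fromEnd = TRUE)
      ## best split t: first t bases to the left block, rest to the right
      cumL <- c(0, cumsum(mL))
      sumRight <- c(rev(cumsum(rev(mR))), 0)
      t <- which.max(cumL + sumRight) - 1L
      if ((cumL[t + 1L] + sumRight[t + 1L]) / gLen < 0.6) next
      if (t > 0L) {
        segs$q_end[i] <- segs$q_end[i] + t
        if (!is.na(segL$ref_start)) {
          Lr <- monomerOf(segL$label)@lengthBp
          if (segL$strand == "+")
            segs$ref_end[i] <- (segL$ref_end + t - 1L) %% Lr + 1L
          else segs$ref_start[i] <- (segL$ref_start - t - 1L) %% Lr + 1L
        }
      }
      if (t < gLen) {
        d <- gLen - t
        segs$q_start[i + 1L] <- segs$q_start[i + 1L] - d
        if (!is.na(segR$ref_start)) {
          Lr <- monomerOf(segR$label)@lengthBp
          if (segR$strand == "+")
            segs$ref_start[i + 1L] <- (segR$ref_start - d - 1L) %% Lr + 1L
          else segs$ref_end[i + 1L] <- (segR$ref_end + d - 1L) %% Lr + 1L
        }
      }
    }
    ## re-merge same-label blocks that absorption made adjacent
    merged <- segs[1, ]
    for (i in seq_len(nrow(segs))[-1]) {
      r <- segs[i, ]
      last <- nrow(merged)
      if (r$label == merged$label[last] &&
          r$q_start - merged$q_end[last] <= mergeSlack) {
        merged$q_end[last] <- max(merged$q_end[last], r$q_end)
        if (!is.na(r$ref_end)) merged$ref_end[last] <- r$ref_end
      } else {
        merged <- rbind(merged, r)
      }
    }
    segs <- merged
  }
  ## internal unlabelled gaps >= minInsertLen become UNKNOWN segments
  insertLen <- NA_integer_
  if (nrow(segs) > 1L) {
    gaps <- segs$q_start[-1] - segs$q_end[-nrow(segs)]
    for (g in which(gaps >= minInsertLen)) {
      unk <- data.frame(label = "UNKNOWN", q_start = segs$q_end[g],
                        q_end = segs$q_start[g + 1L],
                        ref_start = NA_integer_, ref_end = NA_integer_,
                        strand = "+", identity_pct = NA_real_,
                        stringsAsFactors = FALSE)
      segs <- rbind(segs, unk)
      len <- unk$q_end - unk$q_start
      insertLen <- if (is.na(insertLen)) len else max(insertLen, len)
    }
    segs <- segs[order(segs$q_start), ]
  }
  rownames(segs) <- NULL
  labelled <- segs[segs$label != "UNKNOWN", , drop = FALSE]
  coverage <- sum(labelled$q_end - labelled$q_start) / n
  type <-
    if (coverage < 0.5) "unresolved"
    else if (!is.na(insertLen)) "insert_containing"
    else if (nrow(labelled) >= 3L) "mixed"
    else if (nrow(labelled) == 2L) "direct"
    else "single_repeat"
  if (type != "insert_containing") insertLen <- NA_integer_
  new("JunctionCall", queryId = queryId, segments = segs,
      junctionType = type, insertLen = as.integer(insertLen))
}
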