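## clone fixture: chromosome-end window spanning the array-B/array-A
## boundary, with the generating truth
.junctionClone <- function(style, seed, mA, mB, divergence = 0.02,
                           insertLen = 30L) {
  arrA <- buildArray(mA, ArraySpec("CL14", nchar(mA), 12,
                                   divergenceRate = divergence),
                     seed = seed * 3 + 1)
  arrB <- buildArray(mB, ArraySpec("CL34", nchar(mB), 8,
                                   divergenceRate = divergence),
                     seed = seed * 3 + 2)
  cfg <- SimConfig(seed = seed, genomeSize = 1e5, arraySpecs = list())
  ce <- buildChromosomeEnd(cfg, arrA, arrB, style, insertLen = insertLen,
                           seed = seed)
  seg <- ce$segments
  bEnd <- max(seg$end[seg$label == "CL34"])
  aStart <- min(seg$start[seg$label == "CL14"])
  substr(ce$seq, max(0, bEnd - 400) + 1,
         min(nchar(ce$seq), aStart + 400))
}

test_that("scanTelomere finds exact and mismatch-tolerant runs", {
  run <- scanTelomere(strrep("TTTAGGG", 10))
  expect_identical(nrow(run), 1L)
  expect_identical(run$q_start, 0L)
  expect_identical(run$q_end, 70L)
  expect_identical(run$n_copies, 10L)
  ## no unit occurrence
  expect_identical(nrow(scanTelomere(randomSeq(200, seed = 1))), 0L)
  ## one substitution inside one copy still yields a single 35-bp run
  q <- strrep("TTTAGGG", 5)
  substr(q, 17, 17) <- "C"
  run2 <- scanTelomere(q)
  expect_identical(nrow(run2), 1L)
  expect_identical(run2$q_end - run2$q_start, 35L)
  ## reverse-strand runs are reported with strand "-"
  run3 <- scanTelomere(strrep("CCCTAAA", 4))
  expect_identical(run3$strand, "-")
  expect_error(scanTelomere(""), "nonempty")
})

test_that("scanTelomere agrees with the brute-force window oracle", {
  set.seed(12)
  for (i in 1:10) {
    parts <- c(randomSeq(sample(10:40, 1)), strrep("TTTAGGG", sample(2:6, 1)),
               randomSeq(sample(10:40, 1)), strrep("CCCTAAA", sample(2:5, 1)),
               randomSeq(sample(10:30, 1)))
    q <- paste(parts, collapse = "")
    ## sprinkle one substitution
    p <- sample(nchar(q), 1)
    substr(q, p, p) <- sample(c("A", "C", "G", "T"), 1)
    got <- scanTelomere(q)
    want <- bruteTelomereChains(q, "TTTAGGG")
    ## every reported run is a maximal oracle chain
    if (nrow(got)) {
      key <- paste(got$q_start, got$q_end, got$strand)
      wantKey <- paste(want$q_start, want$q_end, want$strand)
      expect_true(all(key %in% wantKey))
    }
    ## the longest oracle chain is always reported
    if (nrow(want)) {
      lens <- want$q_end - want$q_start
      expect_true(max(got$q_end - got$q_start) >= max(lens))
    } else {
      expect_identical(nrow(got), 0L)
    }
  }
})

test_that("alignCircular reports circular phase, strand, and DP decisions", {
  m <- makeMonomer(182, 0.45, 3)
  ref <- monomerConsensus(m)
  canon <- monomerSeq(ref)
  ## query = monomer rotated to internal phase 50 (0-based)
  q <- substr(strrep(canon, 2), 51, 51 + 181)
  hit <- alignCircular(q, ref)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$ref_start, 51L)
  expect_equal(hit$identity_pct, 100)
  expect_identical(hit$strand, "+")
  ## reverse complement: strand flips
  hitRc <- alignCircular(rcOracle(q), ref)
  expect_identical(hitRc$strand, "-")
  expect_identical(hitRc$ref_start, 51L)
  ## hit/no-hit decisions equal a full DP oracle on the linearization
  lin <- strrep(canon, 3)
  set.seed(31)
  for (i in 1:12) {
    q2 <- if (i <= 6) randomSeq(120)
          else {
            ch <- strsplit(substr(strrep(canon, 2), 30, 149), "",
                           fixed = TRUE)[[1]]
            pos <- sample(length(ch), 25)
            ch[pos] <- sample(c("A", "C", "G", "T"), 25, replace = TRUE)
            paste(ch, collapse = "")
          }
    o <- swOracle(lin, q2)
    oHit <- o$columns >= 25 && !is.na(o$identity_pct) && o$identity_pct >= 60
    expect_identical(nrow(alignCircular(q2, ref)) > 0, oHit)
  }
})

test_that("classifyJunction resolves the three junction patterns", {
  mA <- makeMonomer(182, 0.45, 11)
  mB <- makeMonomer(339, 0.45, 12)
  refA <- monomerConsensus(mA)
  refB <- monomerConsensus(mB)
  ## noise-free clone: CL34 fragment | 30-bp insert | CL14 fragment, with
  ## insert ends forced to differ from the flanking repeat continuations
  fragB <- substr(strrep(monomerSeq(refB), 2), 100, 399)
  fragA <- substr(strrep(monomerSeq(refA), 2), 50, 349)
  ins <- strsplit(randomSeq(30, seed = 13), "", fixed = TRUE)[[1]]
  nextB <- substr(strrep(monomerSeq(refB), 2), 400, 400)
  prevA <- substr(strrep(monomerSeq(refA), 2), 49, 49)
  if (ins[1] == nextB) ins[1] <- setdiff(c("A", "C", "G", "T"), nextB)[1]
  if (ins[30] == prevA) ins[30] <- setdiff(c("A", "C", "G", "T"), prevA)[1]
  clone <- paste0(fragB, paste(ins, collapse = ""), fragA)
  call <- classifyJunction(clone, refA, refB)
  expect_identical(junctionType(call), "insert_containing")
  expect_identical(insertLength(call), 30L)
  segs <- junctionSegments(call)
  expect_identical(segs$label, c("CL34", "UNKNOWN", "CL14"))
  ## telomere run directly joined to the distal repeat
  clone2 <- paste0(strrep("TTTAGGG", 10),
                   substr(strrep(monomerSeq(refB), 2), 1, 500))
  call2 <- classifyJunction(clone2, refA, refB)
  expect_identical(junctionType(call2), "direct")
  expect_identical(junctionSegments(call2)$label, c("TEL", "CL34"))
  ## a pure single-repeat fragment
  call3 <- classifyJunction(substr(strrep(monomerSeq(refA), 3), 20, 470),
                            refA, refB)
  expect_identical(junctionType(call3), "single_repeat")
  expect_identical(junctionSegments(call3)$label, "CL14")
  ## unresolvable random sequence
  call4 <- classifyJunction(randomSeq(300, seed = 14), refA, refB)
  expect_identical(junctionType(call4), "unresolved")
  expect_error(classifyJunction(randomSeq(40), refA, refB), "50")
})

test_that("junction tiling is valid and strand-invariant", {
  mA <- makeMonomer(182, 0.45, 21)
  mB <- makeMonomer(339, 0.45, 22)
  refA <- monomerConsensus(mA)
  refB <- monomerConsensus(mB)
  for (style in c("direct", "mixed", "insert")) {
    for (sd in 1:4) {
      clone <- .junctionClone(style, sd, mA, mB)
      call <- classifyJunction(clone, refA, refB)
      segs <- junctionSegments(call)
      ## ordered, non-overlapping tiling
      expect_true(all(segs$q_start < segs$q_end))
      if (nrow(segs) > 1)
        expect_true(all(segs$q_start[-1] >= segs$q_end[-nrow(segs)]))
      ## UNKNOWN segments exactly fill their gaps
      unk <- which(segs$label == "UNKNOWN")
      for (u in unk) {
        expect_gt(u, 1)
        expect_lt(u, nrow(segs))
        expect_identical(segs$q_start[u], segs$q_end[u - 1])
        expect_identical(segs$q_end[u], segs$q_start[u + 1])
      }
      ## reverse complement: same verdict, mirrored coordinates
      rcCall <- classifyJunction(rcOracle(clone), refA, refB)
      expect_identical(junctionType(rcCall), junctionType(call))
      expect_identical(insertLength(rcCall), insertLength(call))
      rcSegs <- junctionSegments(rcCall)
      n <- nchar(clone)
      expect_identical(rev(rcSegs$label), segs$label)
      ## boundary bases at abutting segments can be claimed by either
      ## side; mirrored coordinates agree up to that wobble
      expect_lt(max(abs(n - rev(rcSegs$q_end) - segs$q_start)), 10)
      expect_lt(max(abs(n - rev(rcSegs$q_start) - segs$q_end)), 10)
    }
  }
})
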