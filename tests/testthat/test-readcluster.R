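test_that("pairwiseSimilarity reports self-identity and constructed overlaps", {
  r <- randomSeq(200, seed = 1)
  self <- pairwiseSimilarity(r, r)
  expect_equal(self$identity_pct, 100)
  expect_equal(self$longer_cov_frac, 1.0)
  expect_identical(self$strand, "same")
  ## reverse complement of the central 120 bp: 100% identity over 0.60 of
  ## the longer read, opposite strand
  b <- rcOracle(substr(r, 41, 160))
  hit <- pairwiseSimilarity(r, b)
  expect_equal(hit$identity_pct, 100)
  expect_equal(hit$longer_cov_frac, 120 / 200)
  expect_identical(hit$strand, "opposite")
  expect_error(pairwiseSimilarity("ACGTX", r), "non-ACGTN")
  expect_error(pairwiseSimilarity("", r), "nonempty")
})

test_that("pairwiseSimilarity is symmetric in its two arguments", {
  set.seed(11)
  for (i in 1:8) {
    base <- randomSeq(240)
    a <- substr(base, 1, 150)
    b <- substr(base, sample(30:80, 1), 220)
    if (i %% 2 == 0) b <- rcOracle(b)
    ab <- pairwiseSimilarity(a, b)
    ba <- pairwiseSimilarity(b, a)
    expect_equal(ab$identity_pct, ba$identity_pct)
    expect_equal(ab$longer_cov_frac, ba$longer_cov_frac)
    expect_identical(ab$strand, ba$strand)
  }
})

test_that("alignment scores and decisions equal an independent DP oracle", {
  set.seed(21)
  for (i in 1:25) {
    if (i <= 18) {
      base <- randomSeq(200)
      a <- substr(base, 1, 120)
      bc <- strsplit(substr(base, sample(20:60, 1), 180), "",
                     fixed = TRUE)[[1]]
      nm <- rbinom(1, length(bc), 0.04)
      if (nm > 0) {
        pos <- sample(length(bc), nm)
        bc[pos] <- sample(c("A", "C", "G", "T"), nm, replace = TRUE)
      }
      b <- paste(bc, collapse = "")
      if (i %% 2 == 0) b <- rcOracle(b)
    } else {
      a <- randomSeq(120)
      b <- randomSeq(120)
    }
    o <- swOracle(a, b)
    h <- SatelliteSeeker:::.alignPair(a, b, minAlnLen = 1L)
    ## both are exact DP: optimal scores must agree everywhere
    expect_equal(h$score, o$score)
    ## threshold decisions must agree (identity of co-optimal tracebacks
    ## can differ, the accept/reject outcome cannot in non-tied cases)
    dImpl <- h$columns >= 30 && h$identity_pct >= 90 &&
      h$longer_cov_frac >= 0.55
    dOr <- o$columns >= 30 && !is.na(o$identity_pct) &&
      o$identity_pct >= 90 && o$longer_cov_frac >= 0.55
    expect_identical(dImpl, dOr)
  }
  ## exact ungapped overlaps leave no traceback ambiguity
  base <- randomSeq(260, seed = 3)
  a <- substr(base, 1, 180)
  b <- substr(base, 61, 260)
  o <- swOracle(a, b)
  h <- SatelliteSeeker:::.alignPair(a, b)
  expect_equal(h$identity_pct, 100)
  expect_equal(o$identity_pct, 100)
  expect_equal(h$longer_cov_frac, o$longer_cov_frac)
})

test_that("short spurious alignments are suppressed", {
  expect_null(pairwiseSimilarity(randomSeq(40, seed = 2),
                                 randomSeq(40, seed = 3)))
})

test_that("buildReadGraph applies both cutoffs with >= semantics", {
  reads <- setNames(rep(randomSeq(100, seed = 4), 10),
                    sprintf("r%02d", 1:10))
  g <- buildReadGraph(Biostrings::DNAStringSet(reads))
  expect_identical(nrow(graphEdges(g)), 45L)  # complete graph on 10
  expect_true(all(graphEdges(g)$identity_pct == 100))
  ## a pair just under 90% identity must not get an edge
  a <- randomSeq(300, seed = 6)
  ch <- strsplit(a, "", fixed = TRUE)[[1]]
  pos <- seq(10, 290, length.out = 31)
  ch[pos] <- vapply(ch[pos], function(x)
    setdiff(c("A", "C", "G", "T"), x)[1], character(1))
  b <- paste(ch, collapse = "")
  ident <- pairwiseSimilarity(a, b)$identity_pct
  expect_lt(ident, 90)
  expect_gt(ident, 85)
  ## evenly spaced mismatches leave no shared 12-mer, so the prefilter
  ## would (correctly per its contract) skip this adversarial pair;
  ## evaluate the thresholds on the exhaustive path
  pair <- Biostrings::DNAStringSet(c(x = a, y = b))
  expect_identical(
    nrow(graphEdges(buildReadGraph(pair, prefilter = FALSE))), 0L)
  expect_identical(
    nrow(graphEdges(buildReadGraph(pair, identityCutoff = 85,
                                   prefilter = FALSE))), 1L)
  expect_error(buildReadGraph(pair[1]), "at least 2")
  expect_error(buildReadGraph(unname(pair)), "unique names")
})

## shared fixture: two small planted arrays plus background reads
.clusterFixture <- function(seed = 101) {
  cfg <- SimConfig(
    seed = seed, genomeSize = 60000, coverage = 0.6, errorRate = 0.005,
    arraySpecs = list(
      ArraySpec("satA", 182, 60, divergenceRate = 0.02),
      ArraySpec("satB", 339, 33, divergenceRate = 0.02)))
  genome <- buildGenome(cfg)
  reads <- simulateReads(genome$seq, cfg)
  list(cfg = cfg, genome = genome, reads = reads)
}

test_that("prefiltered graph equals the exhaustive all-vs-all evaluation", {
  fx <- .clusterFixture()
  reads <- fx$reads[1:60]
  gPre <- buildReadGraph(reads, prefilter = TRUE)
  gAll <- buildReadGraph(reads, prefilter = FALSE)
  expect_identical(edgeKey(graphEdges(gPre)), edgeKey(graphEdges(gAll)))
})

test_that("clusterReads performs component arithmetic with stable ordering", {
  mk <- function(n, prefix) sprintf("%s%02d", prefix, seq_len(n))
  cliqueEdges <- function(ids) {
    p <- t(combn(ids, 2))
    data.frame(read_i = p[, 1], read_j = p[, 2], identity_pct = 100,
               longer_cov_frac = 1, strand = "same",
               stringsAsFactors = FALSE)
  }
  nodes <- c(mk(30, "a"), mk(20, "b"), mk(50, "s"))
  g <- new("ReadGraph", nodes = nodes,
           edges = rbind(cliqueEdges(mk(30, "a")), cliqueEdges(mk(20, "b"))))
  cl <- clusterReads(g, totalReads = 100)
  expect_identical(cl$cluster_id, c("CL1", "CL2"))
  expect_identical(cl$n_reads, c(30L, 20L))
  expect_equal(cl$proportion_pct, c(30.0, 20.0))
  ## edgeless graph: no clusters
  g0 <- new("ReadGraph", nodes = nodes,
            edges = graphEdges(g)[0, ])
  expect_identical(nrow(clusterReads(g0, 100)), 0L)
  ## equal-size tie broken by smallest member id
  g2 <- new("ReadGraph", nodes = c(mk(3, "z"), mk(3, "a")),
            edges = rbind(cliqueEdges(mk(3, "z")), cliqueEdges(mk(3, "a"))))
  cl2 <- clusterReads(g2, 6)
  expect_identical(cl2$read_ids[[1]], mk(3, "a"))
  expect_error(clusterReads(g, totalReads = 10), "totalReads")
})

test_that("components equal a transitive-closure oracle on random graphs", {
  set.seed(33)
  for (rep in 1:4) {
    n <- sample(50:120, 1)
    nodes <- sprintf("n%03d", seq_len(n))
    m <- sample(20:80, 1)
    e <- unique(t(replicate(m, sort(sample(n, 2)))))
    edges <- data.frame(read_i = nodes[e[, 1]], read_j = nodes[e[, 2]],
                        identity_pct = 95, longer_cov_frac = 1,
                        strand = "same", stringsAsFactors = FALSE)
    g <- new("ReadGraph", nodes = nodes, edges = edges)
    got <- clusterReads(g, n)$read_ids
    want <- closureComponents(nodes, edges)
    want <- want[order(-lengths(want),
                       vapply(want, `[`, character(1), 1))]
    expect_identical(unname(got), want)
  }
})

test_that("cluster composition is invariant to read input order", {
  fx <- .clusterFixture()
  reads <- fx$reads
  cl1 <- clusterReads(buildReadGraph(reads), length(reads))
  set.seed(7)
  perm <- sample(length(reads))
  cl2 <- clusterReads(buildReadGraph(reads[perm]), length(reads))
  sets1 <- lapply(cl1$read_ids, sort)
  sets2 <- lapply(cl2$read_ids, sort)
  expect_setequal(vapply(sets1, paste, character(1), collapse = ","),
                  vapply(sets2, paste, character(1), collapse = ","))
})

test_that("planted arrays are recovered as pure, near-complete clusters", {
  fx <- .clusterFixture()
  tr <- S4Vectors::mcols(fx$reads)
  seg <- fx$genome$segments
  labelOf <- function(lab) {
    s <- seg[seg$label == lab, ]
    names(fx$reads)[tr$start >= s$start & tr$end <= s$end]
  }
  truthA <- labelOf("satA")
  truthB <- labelOf("satB")
  cl <- clusterReads(buildReadGraph(fx$reads), length(fx$reads))
  top2 <- cl$read_ids[1:2]
  ## match each truth set to the cluster containing most of it
  recA <- top2[[which.max(vapply(top2, function(x)
    sum(truthA %in% x), numeric(1)))]]
  recB <- top2[[which.max(vapply(top2, function(x)
    sum(truthB %in% x), numeric(1)))]]
  expect_gte(mean(truthA %in% recA), 0.95)
  expect_gte(mean(truthB %in% recB), 0.95)
  expect_identical(sum(truthB %in% recA), 0L)
  expect_identical(sum(truthA %in% recB), 0L)
})
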