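## reads sampled error-free from an exact tandem array, as a fixture
.arrayReads <- function(monomer, nCopies = 60, coverage = 2,
                        seed = 5, errorRate = 0, divergence = 0) {
  spec <- ArraySpec("sat", nchar(monomer), nCopies,
                    divergenceRate = divergence)
  arr <- buildArray(monomer, spec, seed = seed)
  cfg <- SimConfig(seed = seed + 1, genomeSize = nchar(arr$seq),
                   coverage = coverage, errorRate = errorRate,
                   arraySpecs = list())
  simulateReads(arr$seq, cfg)
}

test_that("kmerFrequencies counts both strands and skips N", {
  ## a read of length 18 has 8 k-mers of length 11 per strand
  tab <- kmerFrequencies(randomSeq(18, seed = 1), k = 11)
  expect_equal(tab@total, 16)
  expect_identical(tab@k, 11L)
  ## absent k-mers have frequency zero
  expect_equal(kmerFrequency(tab, strrep("A", 11)), 0)
  ## N-containing k-mers are dropped from the count
  tabN <- kmerFrequencies(paste0(randomSeq(11, seed = 2), "N",
                                 randomSeq(11, seed = 3)), k = 11)
  expect_equal(tabN@total, 4)  # 2 clean k-mers per strand
  expect_error(kmerFrequencies("ACGT", k = 11), "length k")
  expect_error(kmerFrequencies("ACGT", k = 5), "between")
})

test_that("monomer-spanning k-mers dominate reads from an exact array", {
  m <- makeMonomer(182, 0.45, 4)
  reads <- .arrayReads(m, coverage = 3)
  tab <- kmerFrequencies(reads, k = 17)
  ## the monomer read circularly contributes |M| spanning k-mers, each at
  ## frequency ~ 1/(2|M|) (both strands counted)
  circ <- .kmersOfOracle(paste0(m, substr(m, 1, 16)), 17)
  freqs <- kmerFrequency(tab, circ)
  expect_equal(length(circ), 182L)
  expect_lt(abs(mean(freqs) - 1 / (2 * 182)), 0.15 / (2 * 182))
  ## together the monomer k-mers and their complements are ~everything
  expect_gt(sum(freqs), 0.45)
})

test_that("greedy reconstruction walks the full monomer cycle and wraps", {
  m <- makeMonomer(182, 0.45, 6)
  reads <- .arrayReads(m)
  tab <- kmerFrequencies(reads, k = 17)
  frags <- reconstructFragments(tab)
  fr <- frags[[1]]
  expect_gte(nchar(fr$seq), 182 + 17 - 1)
  expect_identical(length(fr$support), nchar(fr$seq) - 17L + 1L)
  ## wraps: terminal (k-1)-mer equals the leading (k-1)-mer
  n <- nchar(fr$seq)
  expect_identical(substr(fr$seq, 1, 16), substr(fr$seq, n - 15, n))
})

test_that("unextendable seeds yield single-k-mer fragments", {
  tab <- kmerFrequencies(randomSeq(11, seed = 9), k = 11)
  frags <- reconstructFragments(tab, seedMinFreq = 0.01)
  expect_true(all(vapply(frags, function(f) nchar(f$seq), numeric(1)) == 11))
  expect_error(reconstructFragments(tab, seedMinFreq = 0), "thresholds")
})

test_that("two unrelated planted monomers are both reconstructed", {
  m1 <- makeMonomer(182, 0.45, 7)
  m2 <- makeMonomer(339, 0.45, 8)
  reads <- c(.arrayReads(m1, seed = 11), .arrayReads(m2, nCopies = 35,
                                                     seed = 12))
  tab <- kmerFrequencies(reads, k = 17)
  frags <- reconstructFragments(tab)
  got <- vapply(frags[1:2], function(f) {
    mono <- circularize(f, 17)
    if (is.null(mono)) NA_character_ else monomerSeq(mono)
  }, character(1))
  expect_setequal(got, c(canonicalRotation(m1), canonicalRotation(m2)))
})

test_that("circularize removes the duplicated wrap and canonicalizes", {
  ## toy wrap: "ACGTTGAC" with k = 3 closes on "AC" -> 6-bp monomer
  mono <- circularize("ACGTTGAC", k = 3)
  expect_identical(monomerLength(mono), 6L)
  expect_true(mono@circular)
  expect_identical(monomerSeq(mono), canonicalRotation("ACGTTG"))
  ## a non-wrapping fragment is not a monomer
  expect_null(circularize("ACGTTGAA", k = 3))
  expect_error(circularize("AC", k = 3), "shorter")
})

test_that("canonical rotation equals the all-rotation oracle", {
  set.seed(15)
  for (i in 1:60) {
    s <- randomSeq(sample(2:20, 1))
    expect_identical(canonicalRotation(s), bruteCanonical(s))
  }
  ## orientation- and phase-free by construction
  s <- randomSeq(50, seed = 16)
  expect_identical(canonicalRotation(s),
                   canonicalRotation(rcOracle(s)))
  expect_identical(canonicalRotation(s),
                   canonicalRotation(paste0(substr(s, 11, 50),
                                            substr(s, 1, 10))))
})

test_that("tandemPeriod finds exact and noisy periods", {
  m <- makeMonomer(50, 0.5, 21)
  expect_identical(tandemPeriod(strrep(m, 4), k = 10), 50L)
  expect_true(is.na(tandemPeriod(randomSeq(400, seed = 22), k = 10)))
  ## noisy copies: matches the brute-force lag-scoring oracle
  m2 <- makeMonomer(182, 0.45, 23)
  arr <- buildArray(m2, ArraySpec("s", 182, 10, divergenceRate = 0.03),
                    seed = 24)
  expect_identical(tandemPeriod(arr$seq, k = 10), 182L)
  expect_identical(bruteLagPeriod(arr$seq, maxLag = 400), 182L)
  expect_error(tandemPeriod("ACGTACGTAC", k = 10), "2k")
})

test_that("positionalLogo is exact on noise-free arrays", {
  m <- makeMonomer(120, 0.45, 31)
  reads <- .arrayReads(m, nCopies = 40, coverage = 3, seed = 32)
  mono <- clusterConsensus(reads, k = 17)
  expect_identical(monomerLength(mono), 120L)
  mono <- positionalLogo(reads, mono)
  logo <- logoMatrix(mono)
  expect_equal(unname(colSums(logo)), rep(1, 120))
  expect_true(all(apply(logo, 2, max) == 1))
  expect_identical(nrow(variantTable(mono)), 0L)
  ## the logo consensus spells the monomer itself
  cons <- paste(rownames(logo)[apply(logo, 2, which.max)], collapse = "")
  expect_identical(cons, monomerSeq(mono))
  expect_error(positionalLogo(Biostrings::DNAStringSet(randomSeq(200)),
                              mono), "identity")
})

test_that("a planted biallelic position surfaces as a ~50% variant", {
  m <- makeMonomer(120, 0.45, 41)
  ch <- strsplit(m, "", fixed = TRUE)[[1]]
  alt <- ch
  alt[60] <- setdiff(c("A", "C", "G", "T"), ch[60])[1]
  ## alternate the two subfamily masters 50/50 along the array
  arrSeq <- paste(rep(c(m, paste(alt, collapse = "")), 30), collapse = "")
  cfg <- SimConfig(seed = 42, genomeSize = nchar(arrSeq), coverage = 3,
                   arraySpecs = list())
  reads <- simulateReads(arrSeq, cfg)
  mono <- clusterConsensus(reads, k = 17, collapsePeriod = FALSE)
  expect_identical(monomerLength(mono), 120L)
  mono <- positionalLogo(reads, mono)
  v <- variantTable(mono)
  expect_identical(nrow(v), 1L)
  expect_lt(abs(v$variant_freq - 0.5), 0.15)
  expect_equal(unname(colSums(logoMatrix(mono))), rep(1, 120))
})

test_that("the canonical monomer is invariant to read orientation", {
  m <- makeMonomer(150, 0.45, 51)
  reads <- .arrayReads(m, nCopies = 40, seed = 52)
  fwd <- clusterConsensus(reads, k = 17)
  rc <- clusterConsensus(Biostrings::reverseComplement(reads), k = 17)
  expect_identical(monomerSeq(fwd), monomerSeq(rc))
})

test_that("raising the seed threshold never increases fragment count", {
  m <- makeMonomer(90, 0.45, 61)
  reads <- .arrayReads(m, nCopies = 30, coverage = 1, seed = 62,
                       divergence = 0.03, errorRate = 0.01)
  tab <- kmerFrequencies(reads, k = 17)
  counts <- vapply(c(1e-4, 1e-3, 5e-3, 2e-2),
                   function(f) length(reconstructFragments(tab, f)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})
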