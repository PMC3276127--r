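## End-to-end orchestration: simulate (optional) -> cluster -> consensus ->
## abundance, with all per-stage artifacts written to an output directory
## and a single JSON report.

#' Demonstration configuration: two planted satellite families
#'
#' A small genome carrying two unrelated tandem arrays with monomer
#' lengths 182 bp and 339 bp (the two satellite monomer size classes the
#' package is designed around), sampled at 0.53x with 454-like reads.
#'
#' @param seed Integer seed.
#' @param genomeSize Genome length in bp (default 150000).
#' @return A [SimConfig].
#' @export
demoConfig <- function(seed = 1L, genomeSize = 150000L) {
  SimConfig(
    seed = seed, genomeSize = genomeSize,
    arraySpecs = list(
      ArraySpec("CL14like", monomerLength = 182, nCopies = 120,
                divergenceRate = 0.02),
      ArraySpec("CL34like", monomerLength = 339, nCopies = 80,
                divergenceRate = 0.02)),
    errorRate = 0.005)
}

#' Run the discovery pipeline end to end
#'
#' Simulates reads from the configured genome (or uses `reads` when
#' given), builds the similarity graph (90% identity over 55% of the
#' longer read by default), extracts clusters, reconstructs a circular
#' monomer consensus for each of the leading clusters, and summarizes
#' abundances. Artifacts (reads FASTA, edges/clusters TSV, monomer FASTA,
#' JSON report) are written under `outDir` when it is not `NULL`.
#'
#' @param config A [SimConfig].
#' @param outDir Output directory (`NULL` to skip writing).
#' @param reads Optional `DNAStringSet` to analyse instead of simulating.
#' @param k k-mer length for consensus reconstruction (default 17).
#' @param identityCutoff,coverageCutoff Clustering thresholds (defaults
#'   90 and 0.55).
#' @param seedMinFreq,extensionThreshold Consensus thresholds (defaults
#'   0.0001 and 0.10).
#' @param genomeSizeMb Genome size used for the coverage summary; defaults
#'   to the configured genome size.
#' @param maxClusters How many leading clusters to run consensus on
#'   (default 5).
#' @return A report list (`dataset`, `clusters`, `monomers`), invisibly
#'   when `outDir` is given.
#' @export
runPipeline <- function(config, outDir = NULL, reads = NULL, k = 17L,
                        identityCutoff = 90, coverageCutoff = 0.55,
                        seedMinFreq = 0.0001, extensionThreshold = 0.10,
                        genomeSizeMb = NULL, maxClusters = 5L) {
  validObject(config)
  if (is.null(reads)) {
    genome <- buildGenome(config)
    reads <- simulateReads(genome$seq, config)
  }
  if (!length(reads))
    stop("no reads to analyse", call. = FALSE)
  if (is.null(genomeSizeMb)) genomeSizeMb <- config@genomeSize / 1e6
  dataset <- summarizeDataset(reads = reads, genomeSizeMb = genomeSizeMb)
  graph <- buildReadGraph(reads, identityCutoff = identityCutoff,
                          coverageCutoff = coverageCutoff)
  clusters <- clusterReads(graph, totalReads = length(reads))
  monomers <- list()
  for (i in seq_len(min(nrow(clusters), maxClusters))) {
    cl <- clusters$cluster_id[i]
    member <- reads[clusters$read_ids[[i]]]
    mono <- tryCatch(
      clusterConsensus(member, k = k, seedMinFreq = seedMinFreq,
                       extensionThreshold = extensionThreshold),
      error = function(e) NULL)
    if (!is.null(mono))
      monomers[[cl]] <- mono
  }
  report <- list(
    dataset = as.list(dataset),
    clusters = data.frame(
      cluster_id = clusters$cluster_id, n_reads = clusters$n_reads,
      proportion_pct = roundHalfUp(clusters$proportion_pct, 1),
      stringsAsFactors = FALSE),
    monomers = lapply(monomers, function(m)
      list(length_bp = m@lengthBp, circular = m@circular,
           monomer = m@monomer))
  )
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeSequences(reads, file.path(outDir, "reads.fasta"))
    writeTsv(graphEdges(graph), file.path(outDir, "edges.tsv"))
    writeTsv(clusters, file.path(outDir, "clusters.tsv"))
    if (length(monomers)) {
      fa <- vapply(monomers, function(m) m@monomer, character(1))
      names(fa) <- sprintf("%s length=%d circular=%s", names(monomers),
                           vapply(monomers, function(m) m@lengthBp,
                                  integer(1)),
                           vapply(monomers, function(m) m@circular,
                                  logical(1)))
      writeSequences(fa, file.path(outDir, "monomers.fasta"))
    }
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = 8, pretty = TRUE)
    return(invisible(report))
  }
  report
}

#' Seeded monomer-length recovery experiment
#'
#' One replicate of the end-to-end synthetic benchmark: plant a tandem
#' array of a random monomer of the given length in a background genome,
#' shotgun-sample it at sub-1x coverage with 454-like reads, cluster the
#' reads (90%/55%), and reconstruct the monomer by k-mer consensus from
#' the largest cluster.
#'
#' @param monomerLength Planted monomer length in bp.
#' @param k k-mer length for the consensus stage.
#' @param seed Integer seed for the replicate.
#' @param nCopies Array copy number (default 110).
#' @param divergence Per-copy divergence from the master (default 0.02).
#' @param errorRate Per-base read error rate (default 0.005).
#' @param coverage Sequencing depth (default 0.53).
#' @param backgroundBp Single-copy background added around the array
#'   (default 60000).
#' @return A list with `length_bp` (recovered monomer length, `NA` when
#'   nothing circularized), `monomer` (the recovered [MonomerConsensus] or
#'   `NULL`), `planted` (the planted master monomer), and `identity_pct`
#'   (global identity between recovered and planted monomer in canonical
#'   rotation, `NA` when not recovered).
#' @export
recoverMonomer <- function(monomerLength, k = 17L, seed = 1L,
                           nCopies = 110L, divergence = 0.02,
                           errorRate = 0.005, coverage = 0.53,
                           backgroundBp = 60000L) {
  cfg <- SimConfig(
    seed = seed,
    genomeSize = as.integer(monomerLength * nCopies + backgroundBp),
    coverage = coverage, errorRate = errorRate,
    arraySpecs = list(ArraySpec("sat", monomerLength, nCopies,
                                divergenceRate = divergence)))
  genome <- buildGenome(cfg)
  reads <- simulateReads(genome$seq, cfg)
  graph <- buildReadGraph(reads)
  clusters <- clusterReads(graph, totalReads = length(reads))
  planted <- canonicalRotation(genome$arrays[["sat"]]$master)
  ## largest cluster carries the satellite family
  if (!nrow(clusters))
    return(list(length_bp = NA_integer_, monomer = NULL,
                planted = planted, identity_pct = NA_real_))
  member <- reads[clusters$read_ids[[1]]]
  mono <- tryCatch(clusterConsensus(member, k = k),
                   error = function(e) NULL)
  if (is.null(mono))
    return(list(length_bp = NA_integer_, monomer = NULL,
                planted = planted, identity_pct = NA_real_))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(mono@monomer),
    Biostrings::DNAString(strrep(planted, 2L)),
    type = "local", substitutionMatrix = .alnSubMat,
    gapOpening = .GAP_OPEN, gapExtension = .GAP_EXT)
  st <- .alnStats(aln)
  list(length_bp = mono@lengthBp, monomer = mono, planted = planted,
       identity_pct = 100 * st$matches / st$columns)
}
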