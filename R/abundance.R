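## Dataset coverage and per-repeat genome proportion arithmetic from read
## counts. Reported values use half-up rounding (2 decimals for coverage,
## 1 for percentages), matching how such figures are conventionally printed.

#' Summarize a shotgun dataset and its genome coverage
#'
#' @param nReads Number of reads.
#' @param totalBp Total sequenced bases. Alternatively pass `reads` (a
#'   `DNAStringSet` or character vector) and both are derived.
#' @param genomeSizeMb Haploid genome size in Mb.
#' @param reads Optional read set, used instead of `nReads`/`totalBp`.
#' @return A one-row `data.frame` with `n_reads`, `mean_len_bp`,
#'   `total_mb`, `genome_size_mb`, `coverage_x` (unrounded) and
#'   `coverage_x_reported` (half-up, 2 decimals).
#' @examples
#' summarizeDataset(totalBp = 446.7e6, nReads = 1238463,
#'                  genomeSizeMb = 840)$coverage_x_reported  # 0.53
#' @export
summarizeDataset <- function(nReads = NULL, totalBp = NULL, genomeSizeMb,
                             reads = NULL) {
  if (!is.null(reads)) {
    nReads <- length(reads)
    totalBp <- sum(nchar(.asSeqChar(reads)))
  }
  if (is.null(nReads) || nReads <= 0)
    stop("dataset contains zero reads", call. = FALSE)
  if (genomeSizeMb <= 0)
    stop("genomeSizeMb must be > 0", call. = FALSE)
  totalMb <- totalBp / 1e6
  cov <- totalMb / genomeSizeMb
  data.frame(n_reads = nReads, mean_len_bp = totalBp / nReads,
             total_mb = totalMb, genome_size_mb = genomeSizeMb,
             coverage_x = cov,
             coverage_x_reported = roundHalfUp(cov, 2))
}

#' Genome proportion of a repeat from cluster read counts
#'
#' The proportion of the genome occupied by a repeat family is estimated as
#' the fraction of shotgun reads falling in its cluster (count-based, not
#' base-pair-based). Set `weights` to base-pair totals for the bp-weighted
#' alternative.
#'
#' @param clusterNReads Reads in the cluster (or cluster bp when using
#'   `weights = "bp"` semantics: pass bp in both arguments).
#' @param totalReads Total reads in the dataset.
#' @param rounded Report half-up to 1 decimal (default `TRUE`).
#' @return Percent of the genome.
#' @examples
#' genomeProportion(5313, 1238463)                  # 0.4
#' genomeProportion(5313, 1238463, rounded = FALSE) # 0.4289...
#' @export
genomeProportion <- function(clusterNReads, totalReads, rounded = TRUE) {
  if (any(totalReads == 0))
    stop("totalReads must be > 0", call. = FALSE)
  if (any(clusterNReads <= 0) || any(clusterNReads > totalReads))
    stop("need 0 < clusterNReads <= totalReads", call. = FALSE)
  pct <- 100 * clusterNReads / totalReads
  if (rounded) roundHalfUp(pct, 1) else pct
}
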