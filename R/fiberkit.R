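## Fiber-FISH calibration: micrometer signal lengths to physical DNA
## lengths, locus genome fractions, and one-dimensional size-category
## grouping with mean +/- SE.

#' Convert a stretched-fiber length from micrometers to kilobases
#'
#' Stretched DNA fibers have a near-constant DNA content per unit length;
#' the default stretch factor of 3.0 kb/um lies within the commonly used
#' 2.9-3.3 kb/um range.
#'
#' @param lengthUm Signal length(s) in micrometers (> 0).
#' @param kbPerUm Stretch factor in kb per um (default 3.0).
#' @return Length(s) in kb (unrounded; round half-up to integer kb or Mb
#'   for reports).
#' @examples
#' umToKb(322)   # 966 kb
#' umToKb(1031)  # 3093 kb ~ 3 Mb
#' @export
umToKb <- function(lengthUm, kbPerUm = 3.0) {
  if (any(lengthUm <= 0))
    stop("lengthUm must be > 0", call. = FALSE)
  if (kbPerUm <= 0)
    stop("kbPerUm must be > 0", call. = FALSE)
  lengthUm * kbPerUm
}

#' Fraction of the genome accounted for by a single locus
#'
#' @param lengthKb Locus physical length in kb.
#' @param genomeSizeMb Haploid genome size in Mb (default 840).
#' @param rounded Report half-up to 1 decimal (default `TRUE`).
#' @return Percent of the genome.
#' @examples
#' locusFraction(966)  # 0.1
#' @export
locusFraction <- function(lengthKb, genomeSizeMb = 840, rounded = TRUE) {
  if (any(lengthKb <= 0) || genomeSizeMb <= 0)
    stop("lengths and genome size must be > 0", call. = FALSE)
  pct <- 100 * lengthKb / (1000 * genomeSizeMb)
  if (rounded) roundHalfUp(pct, 1) else pct
}

#' Group fiber measurements into size categories
#'
#' Sorts the lengths ascending and splits at the `nGroups - 1` largest
#' adjacent gaps (ties broken towards the leftmost gap), a deterministic,
#' order-free one-dimensional grouping that is exact on well-separated
#' data. Categories are returned ordered by mean. SE is the sample standard
#' deviation over sqrt(n) (0 when n = 1).
#'
#' @param measurements Numeric lengths in um, or a `data.frame` with
#'   columns `id` and `length_um` (as read by [readFiberMeasurements()]).
#' @param nGroups Number of categories (1 to the number of measurements).
#' @return A `data.frame` with `category`, `n`, `mean_um`, `se_um`, and a
#'   list-column `member_ids`.
#' @examples
#' groupSizes(c(1, 2, 3, 100, 101), nGroups = 2)
#' @export
groupSizes <- function(measurements, nGroups) {
  if (is.data.frame(measurements)) {
    lengths <- measurements$length_um
    ids <- as.character(measurements$id)
  } else {
    lengths <- as.numeric(measurements)
    ids <- as.character(seq_along(lengths))
  }
  n <- length(lengths)
  if (nGroups < 1)
    stop("nGroups must be >= 1", call. = FALSE)
  if (nGroups > n)
    stop("nGroups exceeds the number of measurements", call. = FALSE)
  if (any(lengths <= 0))
    stop("lengths must be > 0", call. = FALSE)
  ord <- order(lengths)
  x <- lengths[ord]
  ids <- ids[ord]
  grp <- rep(1L, n)
  if (nGroups > 1L) {
    gaps <- diff(x)
    ## largest gaps win; ties broken towards the leftmost gap
    cutAfter <- sort(order(-gaps, seq_along(gaps))[seq_len(nGroups - 1L)])
    grp <- findInterval(seq_len(n) - 1L, cutAfter) + 1L
  }
  out <- do.call(rbind, lapply(seq_len(nGroups), function(g) {
    v <- x[grp == g]
    data.frame(category = g, n = length(v), mean_um = mean(v),
               se_um = if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0,
               stringsAsFactors = FALSE)
  }))
  ## splitting sorted data yields groups already ordered by mean
  out$member_ids <- lapply(seq_len(nGroups), function(g) ids[grp == g])
  rownames(out) <- NULL
  out
}
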