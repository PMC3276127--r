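#' Round half away from zero
#'
#' Deterministic half-up rounding as used in all printed reports (base
#' `round()` rounds half to even, which would turn 0.25% into 0.2%).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' roundHalfUp(0.25, 1)  # 0.3, not 0.2
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards so generators are pure in (inputs, seed).
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

.BASES <- c("A", "C", "G", "T")

.asSeqChar <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  x <- toupper(x)
  x <- chartr("U", "T", x)
  x
}

.checkDNA <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop("non-ACGTN characters in ", what, call. = FALSE)
  invisible(x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.randomDNA <- function(n, gcFraction = 0.5) {
  p <- c((1 - gcFraction) / 2, gcFraction / 2, gcFraction / 2,
         (1 - gcFraction) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

## All k-mers of a sequence (character scalar), forward strand only.
.kmersOf <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1), k:n)
}

## Substitution matrix shared by every alignment in the package: +1 match,
## -2 mismatch (N never matches), linear gap cost 2 per gapped column.
.alnSubMat <- local({
  m <- matrix(-2, 5, 5, dimnames = list(c(.BASES, "N"), c(.BASES, "N")))
  diag(m)[1:4] <- 1
  m
})
.GAP_OPEN <- 0
.GAP_EXT <- 2
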