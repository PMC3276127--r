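## Standard-format I/O: FASTA/FASTQ readers and writers, TSV round-trip
## helpers, and fiber-measurement tables.

#' Read sequences from FASTA or FASTQ
#'
#' Sequences are upper-cased and U is converted to T. Duplicate ids and
#' characters outside \{A,C,G,T,N\} are errors. For FASTQ, a record whose
#' quality string length differs from its sequence length is a parse error.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension and content), `"fasta"`, or
#'   `"fastq"`.
#' @return A named `DNAStringSet`.
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    if (!length(first))
      stop("empty sequence file: ", path, call. = FALSE)
    format <- if (startsWith(first, "@")) "fastq"
              else if (startsWith(first, ">")) "fasta"
              else stop("cannot determine format of ", path, call. = FALSE)
  }
  if (format == "fastq") {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
      stop("malformed FASTQ (", path, "): record count not a multiple of 4",
           call. = FALSE)
    ids <- sub("^@", "", sub("\\s.*", "", lines[seq(1, length(lines), 4)]))
    seqs <- lines[seq(2, length(lines), 4)]
    quals <- lines[seq(4, length(lines), 4)]
    bad <- which(nchar(seqs) != nchar(quals))
    if (length(bad))
      stop("malformed FASTQ (", path, "): sequence/quality length mismatch",
           " in record ", bad[1L], " (line ", (bad[1L] - 1L) * 4L + 1L, ")",
           call. = FALSE)
    seqs <- stats::setNames(seqs, ids)
  } else {
    x <- Biostrings::readBStringSet(path, format = "fasta")
    seqs <- stats::setNames(as.character(x),
                            sub("\\s.*", "", names(x)))
  }
  seqs <- chartr("u", "t", seqs)
  seqs <- .asSeqChar(seqs)
  .checkDNA(seqs, paste0("sequences in ", path))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in ", path, call. = FALSE)
  out <- Biostrings::DNAStringSet(seqs)
  out
}

#' Write sequences as 60-column FASTA
#'
#' @param seqs Named `DNAStringSet` or character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeSequences <- function(seqs, path) {
  if (!is(seqs, "XStringSet"))
    seqs <- Biostrings::DNAStringSet(.asSeqChar(seqs))
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a fiber-FISH measurement table
#'
#' Expects a TSV with columns `id`, `length_um`, `probe`, and optionally
#' `end_context` (comma-separated ordered probe list).
#'
#' @param path Input TSV.
#' @return A `data.frame` of measurements.
#' @export
readFiberMeasurements <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "length_um", "probe")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("fiber table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$length_um)) || any(df$length_um <= 0))
    stop("fiber table ", path, ": length_um must be positive",
         call. = FALSE)
  df
}

#' Write a data frame as TSV
#'
#' List-columns (e.g. cluster `read_ids`) are comma-joined.
#'
#' @param df A `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df))
    if (is.list(df[[col]]))
      df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ",")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [writeTsv()]
#'
#' @param path Input file.
#' @return A `data.frame`.
#' @export
readTsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
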