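#' Read and write FASTA / FASTQ files
#'
#' Thin wrappers around Biostrings' readers and writers fixing the on-disk
#' conventions used throughout the package: FASTA wrapped at 60 columns,
#' FASTQ with Sanger PHRED+33 qualities. `read_fastq()` validates record
#' structure first and reports the offending line number for malformed
#' input, which Biostrings' own errors do not.
#'
#' @param path File path.
#' @return `read_fasta()`: a named character vector of sequences.
#'   `read_fastq()`: a list with `reads` (named character vector) and
#'   `qualities` (character vector of PHRED+33 strings, same order).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' write_fasta(c(A1 = "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @param records Named character vector of sequences.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.character(records), !is.null(names(records)))
  set <- Biostrings::DNAStringSet(unname(records))
  names(set) <- names(records)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 60L)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  validate_fastq(path)
  # metadata columns (none are written) are dropped with a warning
  set <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(reads = setNames(as.character(set), names(set)),
       qualities = as.character(Biostrings::quality(set)))
}

#' @rdname read_fastq
#' @param reads Named character vector of read sequences.
#' @param qualities Character vector of PHRED+33 quality strings matching
#'   `reads` in order and length.
#' @export
write_fastq <- function(reads, qualities, path) {
  stopifnot(is.character(reads), !is.null(names(reads)),
            length(reads) == length(qualities),
            all(nchar(reads) == nchar(qualities)))
  set <- Biostrings::DNAStringSet(unname(reads))
  names(set) <- names(reads)
  Biostrings::writeXStringSet(
    set, path, format = "fastq",
    qualities = Biostrings::BStringSet(qualities))
  invisible(path)
}

# Structural scan of a FASTQ file: 4-line records, '@' and '+' markers,
# quality length equal to sequence length. Errors name the first bad line.
validate_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(invisible(TRUE))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: truncated record at line ", length(lines))
  starts <- seq(1L, length(lines), by = 4L)
  for (s in starts) {
    if (!startsWith(lines[s], "@"))
      stop("malformed FASTQ: expected '@' header at line ", s)
    if (!startsWith(lines[s + 2L], "+"))
      stop("malformed FASTQ: expected '+' separator at line ", s + 2L)
    if (nchar(lines[s + 3L]) != nchar(lines[s + 1L]))
      stop("malformed FASTQ: quality length differs from sequence length ",
           "at line ", s + 3L)
  }
  invisible(TRUE)
}
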