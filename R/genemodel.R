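#' Gene model: the UTR/exon/intron partition of a genomic allele
#'
#' Constructs and validates a gene model. Features are stored in 0-based
#' half-open coordinates, must tile the sequence without gaps or overlaps,
#' start with a 5' UTR, end with a 3' UTR, and alternate exons and introns
#' in between. Exons are ranked 1..n in genomic order. All internal
#' coordinates in the package follow this convention; conversion to 1-based
#' inclusive happens only when writing EMBL flat files.
#'
#' @param features A data.frame with columns `kind` (one of `"UTR5"`,
#'   `"exon"`, `"intron"`, `"UTR3"`), `start`, `end` (0-based half-open).
#' @param seq_length Total length the features must tile; defaults to the
#'   end of the last feature.
#' @return A `gene_model`: the validated data.frame with an added `rank`
#'   column (exon rank, `NA` elsewhere).
#' @examples
#' gm <- gene_model(data.frame(
#'   kind = c("UTR5", "exon", "intron", "exon", "UTR3"),
#'   start = c(0, 50, 110, 200, 290),
#'   end   = c(50, 110, 200, 290, 340)))
#' @export
gene_model <- function(features, seq_length = NULL) {
  stopifnot(is.data.frame(features),
            all(c("kind", "start", "end") %in% names(features)))
  f <- features[order(features$start), c("kind", "start", "end")]
  f$kind <- as.character(f$kind)
  f$start <- as.integer(f$start); f$end <- as.integer(f$end)
  n <- nrow(f)
  if (n < 3L) stop("gene model needs at least UTR5, one exon, UTR3")
  if (!all(f$kind %in% c("UTR5", "exon", "intron", "UTR3")))
    stop("unknown feature kind")
  if (any(f$end <= f$start)) stop("empty or inverted feature")
  if (f$start[1L] != 0L) stop("first feature must start at 0")
  if (!is.null(seq_length) && f$end[n] != seq_length)
    stop("features do not span the sequence (", f$end[n], " vs ",
         seq_length, ")")
  if (any(f$start[-1L] != f$end[-n]))
    stop("features must tile without gaps or overlaps")
  if (f$kind[1L] != "UTR5" || f$kind[n] != "UTR3")
    stop("model must begin with UTR5 and end with UTR3")
  inner <- f$kind[-c(1L, n)]
  if (inner[1L] != "exon" || inner[length(inner)] != "exon" ||
      !all(inner == rep_len(c("exon", "intron"), length(inner))))
    stop("exons and introns must alternate, flanked by exons")
  f$rank <- NA_integer_
  f$rank[f$kind == "exon"] <- seq_len(sum(f$kind == "exon"))
  rownames(f) <- NULL
  structure(f, class = c("gene_model", "data.frame"))
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %d features spanning %d bp, %d exons\n",
              nrow(x), max(x$end), sum(x$kind == "exon")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Reference allele: a named full-length sequence plus its gene model
#'
#' @param name Allele designation (unique within a reference set).
#' @param sequence DNA string over `A`,`C`,`G`,`T`.
#' @param model A [gene_model()] spanning exactly `nchar(sequence)`.
#' @return A `reference_allele` object.
#' @export
reference_allele <- function(name, sequence, model) {
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0L,
            is.character(sequence), length(sequence) == 1L,
            inherits(model, "gene_model"))
  if (!grepl("^[ACGT]+$", sequence))
    stop("sequence must be DNA over A, C, G, T")
  if (max(model$end) != nchar(sequence))
    stop("gene model spans ", max(model$end), " bp but sequence has ",
         nchar(sequence))
  structure(list(name = name, sequence = sequence, model = model),
            class = "reference_allele")
}

#' @export
print.reference_allele <- function(x, ...) {
  cat(sprintf("<reference_allele> %s: %d bp, %d exons\n", x$name,
              nchar(x$sequence), sum(x$model$kind == "exon")))
  invisible(x)
}

#' Bundle reference alleles into a reference set
#'
#' @param alleles A list of [reference_allele()] objects with unique names.
#' @return A `reference_set` (named list of alleles).
#' @export
reference_set <- function(alleles) {
  stopifnot(length(alleles) >= 1L,
            all(vapply(alleles, inherits, logical(1L), "reference_allele")))
  nms <- vapply(alleles, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) stop("allele names must be unique")
  structure(setNames(alleles, nms), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d alleles: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Write / read a reference set as FASTA plus a gene-model sidecar
#'
#' The sidecar is tab-separated text with columns `allele`, `feature`,
#' `start`, `end` (0-based half-open), one row per feature.
#'
#' @param refs A [reference_set()].
#' @param fasta_path,sidecar_path Output paths.
#' @return `read_reference_set()` returns a [reference_set()].
#' @export
write_reference_set <- function(refs, fasta_path, sidecar_path) {
  stopifnot(inherits(refs, "reference_set"))
  write_fasta(vapply(refs, `[[`, character(1L), "sequence"), fasta_path)
  rows <- do.call(rbind, lapply(refs, function(a) {
    data.frame(allele = a$name, feature = a$model$kind,
               start = a$model$start, end = a$model$end)
  }))
  utils::write.table(rows, sidecar_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta_path)
}

#' @rdname write_reference_set
#' @export
read_reference_set <- function(fasta_path, sidecar_path) {
  seqs <- read_fasta(fasta_path)
  side <- utils::read.table(sidecar_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  reference_set(lapply(names(seqs), function(nm) {
    feats <- side[side$allele == nm, c("feature", "start", "end")]
    names(feats)[1L] <- "kind"
    reference_allele(nm, seqs[[nm]], gene_model(feats, nchar(seqs[[nm]])))
  }))
}

# Spliced coding sequence: concatenation of the exon substrings.
splice_cds <- function(sequence, model) {
  ex <- model[model$kind == "exon", , drop = FALSE]
  paste(substring(sequence, ex$start + 1L, ex$end), collapse = "")
}

# Translate a CDS with the standard nuclear code; incomplete trailing
# codons (frameshifts) are dropped. Stops appear as "*".
translate_cds <- function(cds) {
  n <- 3L * (nchar(cds) %/% 3L)
  if (n == 0L) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, n)),
    if.fuzzy.codon = "X")))
}
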