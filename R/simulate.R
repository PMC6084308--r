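#' Sequencing error profiles
#'
#' Platform presets for the read simulator. The long-read preset models
#' multi-kilobase single-molecule reads with a total per-base error rate of
#' 13% (1% substitution, 6% insertion, 6% deletion) dominated by indels and
#' doubled inside homopolymer runs of four or more bases, matching the
#' documented behaviour of single-molecule instruments (>10% per-read error,
#' randomly distributed, concentrated in homopolymers). The short-read
#' preset models accurate 251 bp paired sequencing-by-synthesis reads
#' (0.2% substitutions, no indels) from fragments capped at ~1000 bp.
#'
#' @param substitution,insertion,deletion Per-base error rates in `[0,1]`.
#' @param homopolymer_multiplier Factor applied to indel rates inside
#'   homopolymer runs of length >= 4.
#' @param read_length Read length in bp; `NA` means reads span the whole
#'   amplicon (long-read amplicon sequencing).
#' @param fragment_min,fragment_max Fragment length bounds (paired mode).
#' @param paired Whether reads come in mate pairs.
#' @return An `error_profile` object.
#' @export
error_profile <- function(substitution, insertion, deletion,
                          homopolymer_multiplier = 1,
                          read_length = NA_integer_,
                          fragment_min = NA_integer_,
                          fragment_max = NA_integer_,
                          paired = FALSE) {
  rates <- c(substitution, insertion, deletion)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    stop("error rates must lie in [0, 1]")
  if (homopolymer_multiplier < 1)
    stop("homopolymer multiplier must be >= 1")
  structure(list(substitution = substitution, insertion = insertion,
                 deletion = deletion,
                 homopolymer_multiplier = homopolymer_multiplier,
                 read_length = as.integer(read_length),
                 fragment_min = as.integer(fragment_min),
                 fragment_max = as.integer(fragment_max),
                 paired = paired),
            class = "error_profile")
}

#' @rdname error_profile
#' @export
long_error_profile <- function() {
  error_profile(substitution = 0.01, insertion = 0.06, deletion = 0.06,
                homopolymer_multiplier = 2, read_length = NA_integer_,
                paired = FALSE)
}

#' @rdname error_profile
#' @export
short_error_profile <- function() {
  error_profile(substitution = 0.002, insertion = 0, deletion = 0,
                read_length = 251L, fragment_min = 400L,
                fragment_max = 1000L, paired = TRUE)
}

# homopolymer mask: TRUE at positions inside a run of identical bases of
# length >= min_run
homopolymer_mask <- function(chars, min_run = 4L) {
  r <- rle(chars)
  rep(r$lengths >= min_run, r$lengths)
}

#' Locate homopolymer runs on a sequence
#'
#' Runs of identical bases of at least `min_run` — the locus class where
#' long-read indel error concentrates. Used to place simulated
#' homopolymer-length variants and by the consensus callers.
#'
#' @param sequence DNA string.
#' @param min_run Minimal run length reported (default 4, the shortest
#'   run where indel bias matters).
#' @return data.frame with `base`, `start` (0-based), `end` (half-open),
#'   `length`.
#' @export
homopolymer_runs <- function(sequence, min_run = 4L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_run
  data.frame(base = r$values[keep], start = (ends - r$lengths)[keep],
             end = ends[keep], length = r$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Simulate a reference allele set
#'
#' Generates a deterministic locus template (class I: 3404 bp, 8 exons;
#' class II: 8500 bp, 6 exons — roughly 2.5 times longer, matching the
#' genomic organisation of the HLA loci where class II genes are about 2 to
#' 3 times the length of class I genes) and derives `n_alleles` mutually
#' diverged alleles from it. A poly-A stretch of nine bases is planted in
#' intron 2 of every template so homopolymer behaviour is exercised by
#' default. Divergence substitutions never create premature stop codons, so
#' every simulated reference allele encodes an intact protein.
#'
#' @param n_alleles Number of alleles (>= 1).
#' @param locus_template `"classI"` or `"classII"`.
#' @param divergence Expected per-base substitution divergence between
#'   alleles, in `[0, 1)`.
#' @param seed RNG seed (mandatory; outputs are pure functions of it).
#' @return A [reference_set()].
#' @export
make_reference_set <- function(n_alleles,
                               locus_template = c("classI", "classII"),
                               divergence = 0.005, seed) {
  locus_template <- match.arg(locus_template)
  stopifnot(n_alleles >= 1L)
  if (divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)")
  layout <- locus_layout(locus_template)
  with_seed(seed, {
    template <- build_template(layout)
    model <- template$model
    alleles <- vector("list", n_alleles)
    alleles[[1L]] <- reference_allele(allele_name(layout$locus, 1L),
                                      template$sequence, model)
    if (n_alleles > 1L) {
      L <- nchar(template$sequence)
      for (i in 2:n_alleles) {
        seq_i <- template$sequence
        n_mut <- max(1L, round(divergence * L))
        pos <- sample.int(L, n_mut) - 1L   # 0-based
        for (p in pos) seq_i <- substitute_safely(seq_i, model, p)
        alleles[[i]] <- reference_allele(allele_name(layout$locus, i),
                                         seq_i, model)
      }
    }
    reference_set(alleles)
  })
}

allele_name <- function(locus, i) sprintf("%s*%02d:01", locus, i)

locus_layout <- function(template) {
  if (template == "classI") {
    list(locus = "A", utr5 = 150L, utr3 = 184L,
         exons = c(73L, 270L, 276L, 276L, 117L, 33L, 48L, 5L),
         introns = c(130L, 241L, 599L, 102L, 442L, 142L, 316L))
  } else {
    list(locus = "DPB1", utr5 = 150L, utr3 = 184L,
         exons = c(106L, 270L, 282L, 24L, 90L, 5L),
         introns = c(2100L, 2900L, 1300L, 600L, 489L))
  }
}

# CDS as random sense codons: ATG ... TAA, no internal stop
random_cds <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

build_template <- function(layout) {
  cds_len <- sum(layout$exons)
  stopifnot(cds_len %% 3L == 0L)
  cds <- random_cds(cds_len %/% 3L)
  # split CDS across exons
  exon_seqs <- character(length(layout$exons))
  off <- 0L
  for (i in seq_along(layout$exons)) {
    exon_seqs[i] <- substr(cds, off + 1L, off + layout$exons[i])
    off <- off + layout$exons[i]
  }
  intron_seqs <- vapply(layout$introns, random_dna, character(1L))
  # plant a poly-A stretch 50 bp into intron 2 (the homopolymer test bed)
  intron_seqs[2L] <- paste0(substr(intron_seqs[2L], 1L, 50L),
                            strrep("A", 9L),
                            substr(intron_seqs[2L], 60L,
                                   nchar(intron_seqs[2L])))
  pieces <- character(0)
  kinds <- character(0)
  pieces <- c(pieces, random_dna(layout$utr5)); kinds <- c(kinds, "UTR5")
  for (i in seq_along(exon_seqs)) {
    pieces <- c(pieces, exon_seqs[i]); kinds <- c(kinds, "exon")
    if (i <= length(intron_seqs)) {
      pieces <- c(pieces, intron_seqs[i]); kinds <- c(kinds, "intron")
    }
  }
  pieces <- c(pieces, random_dna(layout$utr3)); kinds <- c(kinds, "UTR3")
  lens <- nchar(pieces)
  ends <- cumsum(lens)
  model <- gene_model(data.frame(kind = kinds, start = ends - lens,
                                 end = ends))
  list(sequence = paste(pieces, collapse = ""), model = model)
}

# substitute the base at 0-based position p by a random different base that
# does not create a premature stop codon when p is exonic
substitute_safely <- function(sequence, model, p) {
  ref <- substr(sequence, p + 1L, p + 1L)
  alts <- setdiff(c("A", "C", "G", "T"), ref)
  alts <- sample(alts)  # random preference order
  for (alt in alts) {
    cand <- sequence
    substr(cand, p + 1L, p + 1L) <- alt
    if (!creates_premature_stop(cand, model, p)) return(cand)
  }
  sequence  # all alternatives truncate the protein: leave untouched
}

creates_premature_stop <- function(sequence, model, p) {
  ex <- model[model$kind == "exon", , drop = FALSE]
  hit <- which(p >= ex$start & p < ex$end)
  if (length(hit) == 0L) return(FALSE)
  cds_pos <- sum(pmax(0L, pmin(p, ex$end) - ex$start)[seq_len(hit - 1L)]) +
    (p - ex$start[hit])                      # 0-based CDS coordinate
  cds <- splice_cds(sequence, model)
  codon_i <- cds_pos %/% 3L
  codon <- substr(cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  codon %in% c("TAA", "TAG", "TGA") && codon_i < (nchar(cds) %/% 3L - 1L)
}
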