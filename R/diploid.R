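#' Variant specifications for simulated novel alleles
#'
#' Edits are expressed relative to a chosen reference allele in 0-based
#' coordinates: single-nucleotide variants, insertions, deletions, and
#' homopolymer length changes (the class of difference long reads struggle
#' with). Most real novel alleles differ from their closest reference in
#' one or very few bases, which these specs are meant to emulate.
#'
#' @param pos 0-based position on the reference allele. For `snv()` the
#'   position substituted; for `insertion()` the inserted bases go after
#'   this position (`0` = after the first base); for `deletion()` the first
#'   deleted base; for `homopolymer_delta()` any position inside the run.
#' @param alt Replacement base for `snv()`.
#' @param seq Inserted bases for `insertion()`.
#' @param len Number of deleted bases for `deletion()`.
#' @param delta Signed homopolymer length change (e.g. `-1` shortens a
#'   poly-A stretch by one base).
#' @param ... Edits created by `snv()`, `insertion()`, `deletion()`,
#'   `homopolymer_delta()`.
#' @return `variant_spec()` returns a `variant_spec` (list of edits);
#'   the single-edit constructors return one edit.
#' @examples
#' variant_spec(snv(340, "T"), homopolymer_delta(700, -1))
#' @export
variant_spec <- function(...) {
  edits <- list(...)
  if (length(edits) == 1L && is.list(edits[[1L]]) &&
      is.null(edits[[1L]]$type))
    edits <- edits[[1L]]
  stopifnot(all(vapply(edits, function(e) !is.null(e$type), logical(1L))))
  structure(edits, class = "variant_spec")
}

#' @rdname variant_spec
#' @export
snv <- function(pos, alt) {
  stopifnot(alt %in% c("A", "C", "G", "T"))
  list(type = "snv", pos = as.integer(pos), alt = alt)
}

#' @rdname variant_spec
#' @export
insertion <- function(pos, seq) {
  stopifnot(grepl("^[ACGT]+$", seq))
  list(type = "insertion", pos = as.integer(pos), seq = seq)
}

#' @rdname variant_spec
#' @export
deletion <- function(pos, len) {
  stopifnot(len >= 1L)
  list(type = "deletion", pos = as.integer(pos), len = as.integer(len))
}

#' @rdname variant_spec
#' @export
homopolymer_delta <- function(pos, delta) {
  stopifnot(delta != 0L)
  list(type = "homopolymer_delta", pos = as.integer(pos),
       delta = as.integer(delta))
}

# Apply a variant_spec to a sequence. Edits are validated (in range,
# non-overlapping) and applied from the highest position downward so
# earlier coordinates stay valid. Returns list(sequence, applied) where
# `applied` records each edit with its reference span.
apply_variant_spec <- function(sequence, spec) {
  stopifnot(inherits(spec, "variant_spec") || length(spec) == 0L)
  L <- nchar(sequence)
  if (length(spec) == 0L)
    return(list(sequence = sequence, applied = empty_variant_table()))
  spans <- lapply(spec, function(e) {
    if (e$pos < 0L || e$pos >= L) stop("edit position out of range: ", e$pos)
    switch(e$type,
      snv = c(e$pos, e$pos + 1L),
      insertion = c(e$pos, e$pos + 1L),
      deletion = {
        if (e$pos + e$len > L) stop("deletion runs past sequence end")
        c(e$pos, e$pos + e$len)
      },
      homopolymer_delta = c(e$pos, e$pos + 1L))
  })
  ord <- order(vapply(spans, `[`, numeric(1L), 1L), decreasing = TRUE)
  starts <- vapply(spans, `[`, numeric(1L), 1L)
  ends <- vapply(spans, `[`, numeric(1L), 2L)
  o <- order(starts)
  if (any(starts[o][-1L] < ends[o][-length(o)]))
    stop("variant edits overlap")
  applied <- list()
  for (k in ord) {
    e <- spec[[k]]
    res <- apply_one_edit(sequence, e)
    sequence <- res$sequence
    applied[[length(applied) + 1L]] <- res$row
  }
  tab <- do.call(rbind, rev(applied))
  rownames(tab) <- NULL
  list(sequence = sequence, applied = tab)
}

empty_variant_table <- function() {
  data.frame(type = character(0), pos = integer(0), ref = character(0),
             alt = character(0), stringsAsFactors = FALSE)
}

apply_one_edit <- function(sequence, e) {
  p <- e$pos
  if (e$type == "snv") {
    ref <- substr(sequence, p + 1L, p + 1L)
    if (ref == e$alt) stop("snv at ", p, " does not change the base")
    substr(sequence, p + 1L, p + 1L) <- e$alt
    row <- data.frame(type = "snv", pos = p, ref = ref, alt = e$alt,
                      stringsAsFactors = FALSE)
  } else if (e$type == "insertion") {
    sequence <- paste0(substr(sequence, 1L, p + 1L), e$seq,
                       substr(sequence, p + 2L, nchar(sequence)))
    row <- data.frame(type = "insertion", pos = p, ref = "",
                      alt = e$seq, stringsAsFactors = FALSE)
  } else if (e$type == "deletion") {
    ref <- substr(sequence, p + 1L, p + e$len)
    sequence <- paste0(substr(sequence, 1L, p),
                       substr(sequence, p + e$len + 1L, nchar(sequence)))
    row <- data.frame(type = "deletion", pos = p, ref = ref, alt = "",
                      stringsAsFactors = FALSE)
  } else {  # homopolymer_delta
    base <- substr(sequence, p + 1L, p + 1L)
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    s <- p; while (s > 0L && chars[s] == base) s <- s - 1L
    t <- p + 1L; while (t < length(chars) && chars[t + 1L] == base)
      t <- t + 1L
    run_len <- t - s
    if (e$delta < 0L && run_len + e$delta < 1L)
      stop("homopolymer contraction exceeds run length")
    sequence <- paste0(substr(sequence, 1L, s),
                       strrep(base, run_len + e$delta),
                       substr(sequence, t + 1L, nchar(sequence)))
    row <- data.frame(type = "homopolymer_delta", pos = s,
                      ref = strrep(base, run_len),
                      alt = strrep(base, run_len + e$delta),
                      stringsAsFactors = FALSE)
  }
  list(sequence = sequence, row = row)
}

#' Simulate a heterozygous diploid sample
#'
#' Builds the two haplotype sequences of a simulated sample by applying a
#' variant spec to each of two (possibly identical) source reference
#' alleles, and records the ground truth: the applied edits and the
#' heterozygous positions, projected onto allele 1 coordinates via global
#' alignment of the two haplotypes.
#'
#' @param ref_set A [reference_set()].
#' @param spec1,spec2 [variant_spec()]s (possibly empty) applied to the
#'   source alleles.
#' @param source1,source2 Names of the source alleles in `ref_set`
#'   (default: the first allele for both).
#' @return A `diploid_truth` object with fields `allele1`, `allele2`,
#'   `source1`, `source2`, `variants1`, `variants2`, `het_positions`
#'   (0-based on allele 1) and `model` (the source gene model of allele 1).
#' @export
make_diploid_sample <- function(ref_set, spec1 = variant_spec(),
                                spec2 = variant_spec(),
                                source1 = names(ref_set)[1L],
                                source2 = source1) {
  stopifnot(inherits(ref_set, "reference_set"),
            source1 %in% names(ref_set), source2 %in% names(ref_set))
  r1 <- apply_variant_spec(ref_set[[source1]]$sequence, spec1)
  r2 <- apply_variant_spec(ref_set[[source2]]$sequence, spec2)
  het <- diploid_het_positions(r1$sequence, r2$sequence)
  structure(list(allele1 = r1$sequence, allele2 = r2$sequence,
                 source1 = source1, source2 = source2,
                 variants1 = r1$applied, variants2 = r2$applied,
                 het_positions = het,
                 model = ref_set[[source1]]$model),
            class = "diploid_truth")
}

# 0-based allele-1 positions at which the two haplotypes differ
# (mismatches, and the allele-1 flank of indels)
diploid_het_positions <- function(a1, a2) {
  if (identical(a1, a2)) return(integer(0))
  aln <- align_global(a2, a1)  # target = allele1 so positions are on a1
  ops <- cigar_ops(aln$cigar)
  pos <- integer(0)
  ti <- 0L
  for (r in seq_len(nrow(ops))) {
    op <- ops$op[r]; len <- ops$len[r]
    if (op == "X") pos <- c(pos, ti + seq_len(len) - 1L)
    if (op == "D") pos <- c(pos, ti + seq_len(len) - 1L)
    if (op == "I") pos <- c(pos, max(0L, ti - 1L))
    if (op != "I") ti <- ti + len
  }
  sort(unique(pos))
}

#' @export
print.diploid_truth <- function(x, ...) {
  cat(sprintf(
    "<diploid_truth> %d / %d bp (sources %s, %s), %d het position(s)\n",
    nchar(x$allele1), nchar(x$allele2), x$source1, x$source2,
    length(x$het_positions)))
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# introduce per-base sequencing errors into one sequence
corrupt_sequence <- function(sequence, substitution, ins_rate, del_rate,
                             hp_mult = 1, hp_min_run = 4L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  hp <- homopolymer_mask(chars, hp_min_run)
  mult <- ifelse(hp, hp_mult, 1)
  keep <- runif(n) >= del_rate * mult
  sub_hit <- runif(n) < substitution
  if (any(sub_hit)) {
    alt3 <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                   nrow = 3L,
                   dimnames = list(NULL, c("A","C","G","T")))
    idx <- which(sub_hit)
    pick <- sample.int(3L, length(idx), replace = TRUE)
    chars[idx] <- alt3[cbind(pick, match(chars[idx], colnames(alt3)))]
  }
  ins_hit <- runif(n) < ins_rate * mult
  out <- ifelse(keep, chars, "")
  if (any(ins_hit)) {
    idx <- which(ins_hit)
    # inside a homopolymer the inserted base repeats the run base
    # (stretch-length errors); elsewhere it is uniform
    ins_base <- ifelse(hp[idx], chars[idx],
                       sample(c("A","C","G","T"), length(idx),
                              replace = TRUE))
    out[idx] <- paste0(out[idx], ins_base)
  }
  res <- paste(out, collapse = "")
  # events actually introduced (a substituted-then-deleted base is one
  # deletion); alignment distance may be smaller when adjacent indels
  # partially cancel
  attr(res, "n_events") <- sum(!keep) + sum(sub_hit & keep) + sum(ins_hit)
  res
}

#' Simulate long single-molecule reads
#'
#' Draws `n_reads` full-length amplicon reads from the two haplotypes of a
#' diploid sample (50/50), applying the error profile per base: i.i.d.
#' substitutions, insertions and deletions, with indel rates multiplied
#' inside homopolymer runs of four or more bases. The source haplotype of
#' every read is recorded in a hidden truth table (never written to FASTQ)
#' so downstream clustering can be scored exactly.
#'
#' @param truth A `diploid_truth` from [make_diploid_sample()].
#' @param n_reads Number of reads (> 0).
#' @param profile An [error_profile()]; default [long_error_profile()].
#' @param seed RNG seed.
#' @return A `read_set`: list with `reads`, `qualities`, `truth`
#'   (data.frame read / hap) and `profile`.
#' @export
simulate_long_reads <- function(truth, n_reads,
                                profile = long_error_profile(), seed) {
  stopifnot(inherits(truth, "diploid_truth"))
  if (n_reads <= 0L) stop("n_reads must be positive")
  with_seed(seed, {
    hap <- sample(c(1L, 2L), n_reads, replace = TRUE)
    n_events <- integer(n_reads)
    src_len <- integer(n_reads)
    reads <- vapply(seq_len(n_reads), function(i) {
      src <- if (hap[i] == 1L) truth$allele1 else truth$allele2
      if (!is.na(profile$read_length) &&
          profile$read_length < nchar(src)) {
        start <- sample.int(nchar(src) - profile$read_length + 1L, 1L)
        src <- substr(src, start, start + profile$read_length - 1L)
      }
      src_len[i] <<- nchar(src)
      r <- corrupt_sequence(src, profile$substitution, profile$insertion,
                            profile$deletion,
                            profile$homopolymer_multiplier)
      n_events[i] <<- attr(r, "n_events")
      as.character(r)
    }, character(1L))
    names(reads) <- sprintf("lr%05d", seq_len(n_reads))
    structure(list(
      reads = reads,
      qualities = vapply(nchar(reads), function(n)
        strrep("+", n), character(1L)),
      truth = data.frame(read = names(reads),
                         hap = paste0("allele", hap),
                         n_errors = n_events, source_length = src_len,
                         stringsAsFactors = FALSE),
      profile = profile), class = "read_set")
  })
}

#' Simulate short accurate paired-end reads
#'
#' Shotgun-sequencing emulation: fragments of 400-1000 bp are drawn
#' uniformly along each haplotype (50/50), and each fragment yields a
#' forward read from its 5' end and a reverse-complemented read from its
#' 3' end, 251 bp each, with substitution-only errors. The pair count is
#' `round(coverage * gene_length / (2 * read_length))`. Fragment spans
#' never exceed the profile maximum (~1000 bp), the property that breaks
#' phasing of distant heterozygous positions.
#'
#' @param truth A `diploid_truth`.
#' @param coverage Target mean coverage (x).
#' @param profile An [error_profile()] with `paired = TRUE`.
#' @param seed RNG seed.
#' @return A `paired_read_set`: list with `read1`, `read2`, `qual1`,
#'   `qual2`, hidden `truth` (pair / hap / fragment span) and `profile`.
#' @export
simulate_short_reads <- function(truth, coverage,
                                 profile = short_error_profile(), seed) {
  stopifnot(inherits(truth, "diploid_truth"), isTRUE(profile$paired))
  if (coverage <= 0) stop("coverage must be positive")
  rl <- profile$read_length
  L <- nchar(truth$allele1)
  n_pairs <- round(coverage * L / (2 * rl))
  with_seed(seed, {
    hap <- sample(c(1L, 2L), n_pairs, replace = TRUE)
    src_len <- ifelse(hap == 1L, nchar(truth$allele1),
                      nchar(truth$allele2))
    frag_len <- pmin(src_len, profile$fragment_min +
      floor(runif(n_pairs) *
              (profile$fragment_max - profile$fragment_min + 1L)))
    frag_start <- floor(runif(n_pairs) * (src_len - frag_len + 1L))  # 0-based
    r1 <- character(n_pairs); r2 <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      src <- if (hap[i] == 1L) truth$allele1 else truth$allele2
      frag <- substr(src, frag_start[i] + 1L, frag_start[i] + frag_len[i])
      fwd <- substr(frag, 1L, min(rl, frag_len[i]))
      rev <- revcomp(substr(frag, max(1L, frag_len[i] - rl + 1L),
                            frag_len[i]))
      r1[i] <- corrupt_sequence(fwd, profile$substitution, 0, 0)
      r2[i] <- corrupt_sequence(rev, profile$substitution, 0, 0)
    }
    ids <- sprintf("sr%05d", seq_len(n_pairs))
    structure(list(
      read1 = setNames(r1, paste0(ids, "/1")),
      read2 = setNames(r2, paste0(ids, "/2")),
      qual1 = vapply(nchar(r1), function(n) strrep("I", n), character(1L)),
      qual2 = vapply(nchar(r2), function(n) strrep("I", n), character(1L)),
      truth = data.frame(pair = ids, hap = paste0("allele", hap),
                         frag_start = frag_start, frag_len = frag_len,
                         stringsAsFactors = FALSE),
      profile = profile), class = "paired_read_set")
  })
}

#' Write simulated reads and their truth sidecar to disk
#'
#' Reads go to FASTQ (one file for long reads, two mate files for pairs);
#' the hidden read-to-haplotype truth goes to a separate tab-separated
#' sidecar and never into the FASTQ records themselves.
#'
#' @param rs A `read_set` or `paired_read_set`.
#' @param prefix Output path prefix; files are `<prefix>.fastq` or
#'   `<prefix>_R1.fastq` / `<prefix>_R2.fastq`, plus `<prefix>_truth.tsv`.
#' @return The sidecar path, invisibly.
#' @export
write_read_set <- function(rs, prefix) {
  if (inherits(rs, "paired_read_set")) {
    write_fastq(rs$read1, rs$qual1, paste0(prefix, "_R1.fastq"))
    write_fastq(rs$read2, rs$qual2, paste0(prefix, "_R2.fastq"))
  } else {
    write_fastq(rs$reads, rs$qualities, paste0(prefix, ".fastq"))
  }
  side <- paste0(prefix, "_truth.tsv")
  utils::write.table(rs$truth, side, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(side)
}
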