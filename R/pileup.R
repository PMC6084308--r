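BASES5 <- c("A", "C", "G", "T", "-")

#' Build a pileup of reads against a backbone sequence
#'
#' Places every read on the backbone by pairwise alignment and tallies
#' per-position base and deletion counts plus insertion observations.
#' Short paired reads are placed with a fitting (glocal) alignment, the
#' reverse mate being reverse-complemented first; long reads are aligned
#' end to end with a diagonal band. Reads whose best placement is ambiguous
#' (several equally scoring placements) are dropped and counted, so no read
#' contributes evidence twice.
#'
#' @param reads A `read_set` (long reads) or `paired_read_set` (short
#'   pairs), or a plain named character vector of sequences.
#' @param backbone Backbone DNA string (usually the closest reference
#'   allele, or a preliminary haplotype consensus during polishing).
#' @param min_score_frac Placements scoring below this fraction of the
#'   read's maximum possible score are discarded as unalignable.
#' @return A `pileup`: list with `backbone`, `counts` (5 x L matrix over
#'   A/C/G/T/deletion), `coverage`, `insertions` (data.frame read/pos/seq;
#'   `pos` is the 1-based backbone position after which the bases sit),
#'   `placements` (per read: name, pair, tstart, tend, calls), and
#'   `unaligned` (dropped read names).
#' @export
build_pileup <- function(reads, backbone, min_score_frac = 0.3) {
  stopifnot(is.character(backbone), length(backbone) == 1L,
            nchar(backbone) > 0L)
  if (inherits(reads, "paired_read_set")) {
    seqs <- c(reads$read1, revcomp(reads$read2))
    pair <- c(reads$truth$pair, reads$truth$pair)
    mode <- "glocal"; band <- 0L
  } else if (inherits(reads, "read_set")) {
    seqs <- reads$reads
    pair <- names(seqs)
    mode <- "global"
    band <- max(100L, ceiling(0.05 * nchar(backbone)))
  } else {
    stopifnot(is.character(reads))
    seqs <- reads
    if (is.null(names(seqs))) names(seqs) <- sprintf("r%05d", seq_along(seqs))
    pair <- names(seqs)
    mode <- if (all(nchar(seqs) < 0.8 * nchar(backbone))) "glocal"
            else "global"
    band <- if (mode == "global")
      max(100L, ceiling(0.05 * nchar(backbone))) else 0L
  }
  alns <- align_batch(seqs, backbone, mode = mode, band = band)
  L <- nchar(backbone)
  counts <- matrix(0L, nrow = 5L, ncol = L, dimnames = list(BASES5, NULL))
  placements <- vector("list", length(seqs))
  ins_read <- ins_pos <- ins_seq <- vector("list", length(seqs))
  unaligned <- character(0)
  max_match <- 2  # align_batch default match score
  for (i in seq_along(seqs)) {
    a <- alns[[i]]
    nm <- names(seqs)[i]
    ambiguous <- !is.null(a$nbest) && a$nbest > 1L
    poor <- a$score < min_score_frac * max_match * nchar(seqs[[i]])
    if (ambiguous || poor) { unaligned <- c(unaligned, nm); next }
    a$query <- seqs[[i]]
    pc <- alignment_calls(a)
    pos <- (a$tstart + 1L):a$tend
    counts[cbind(match(pc$calls, BASES5), pos)] <-
      counts[cbind(match(pc$calls, BASES5), pos)] + 1L
    placements[[i]] <- list(name = nm, pair = pair[i],
                            tstart = a$tstart, tend = a$tend,
                            calls = pc$calls)
    if (length(pc$insertions)) {
      ins_read[[i]] <- rep(nm, length(pc$insertions))
      ins_pos[[i]] <- as.integer(names(pc$insertions))
      ins_seq[[i]] <- unname(pc$insertions)
    }
  }
  placements <- placements[!vapply(placements, is.null, logical(1L))]
  names(placements) <- vapply(placements, `[[`, character(1L), "name")
  insertions <- data.frame(read = unlist(ins_read) %||% character(0),
                           pos = unlist(ins_pos) %||% integer(0),
                           seq = unlist(ins_seq) %||% character(0),
                           stringsAsFactors = FALSE)
  structure(list(backbone = backbone, counts = counts,
                 coverage = colSums(counts), insertions = insertions,
                 placements = placements, unaligned = unaligned),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf(
    "<pileup> %d reads on %d bp backbone, mean coverage %.1fx, %d dropped\n",
    length(x$placements), ncol(x$counts), mean(x$coverage),
    length(x$unaligned)))
  invisible(x)
}

# counts matrix restricted to a subset of placements (per-cluster pileups)
subset_counts <- function(pileup, members) {
  L <- ncol(pileup$counts)
  counts <- matrix(0L, nrow = 5L, ncol = L, dimnames = list(BASES5, NULL))
  for (p in pileup$placements[members]) {
    pos <- (p$tstart + 1L):p$tend
    idx <- cbind(match(p$calls, BASES5), pos)
    counts[idx] <- counts[idx] + 1L
  }
  counts
}

# read base at a 1-based backbone position, NA when not covered
placement_call <- function(p, pos) {
  if (pos <= p$tstart || pos > p$tend) return(NA_character_)
  p$calls[pos - p$tstart]
}
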