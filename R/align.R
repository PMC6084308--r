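#' Global or fitting pairwise alignment with affine gap costs
#'
#' Aligns `query` against `target` with the Gotoh affine-gap algorithm and a
#' fixed traceback tie-break (diagonal over deletion over insertion, gap
#' opening over extension), so repeated runs and all downstream consensus
#' calls are deterministic.
#'
#' @param query,target DNA strings over `A`, `C`, `G`, `T` (single character
#'   vectors). Both must be non-empty.
#' @param match Score added per matching column (positive).
#' @param mismatch Score added per mismatching column (negative).
#' @param gap_open Cost charged once when a gap is opened (negative).
#' @param gap_extend Cost charged per gapped base (negative); a gap of length
#'   `k` costs `gap_open + k * gap_extend`.
#' @param mode `"global"` aligns both sequences end to end; `"glocal"` fits
#'   the whole query inside the target with free target overhangs (used for
#'   placing short reads on a long backbone).
#' @param band Optional band half-width around the main diagonal for
#'   `"global"` mode; `0` (default) computes the full matrix. Banding is a
#'   speed device for near-diagonal alignments such as long reads against a
#'   same-length backbone; results are identical to the full matrix whenever
#'   the optimal path stays inside the band.
#'
#' @return An object of class `dna_alignment`: a list with `score`, `cigar`
#'   (run-length encoded over `=`, `X`, `I` query-insertion, `D` deletion),
#'   `tstart`/`tend` (0-based half-open span on the target), the op counts
#'   `nmatch`, `nmismatch`, `nins`, `ndel`, and the two sequences.
#' @examples
#' aln <- align_global("ACGT", "ACCT")
#' aln$nmismatch  # 1
#' @export
align_global <- function(query, target, match = 2, mismatch = -4,
                         gap_open = -4, gap_extend = -2,
                         mode = c("global", "glocal"), band = 0L) {
  mode <- match.arg(mode)
  stopifnot(is.character(query), length(query) == 1L,
            is.character(target), length(target) == 1L)
  if (nchar(query) == 0L || nchar(target) == 0L)
    stop("align_global(): sequences must be non-empty")
  res <- .cpp_align_batch(query, target, mode, match, mismatch,
                          gap_open, gap_extend, as.integer(band), -1L)[[1L]]
  res$query <- query
  res$target <- target
  res$mode <- mode
  structure(res, class = "dna_alignment")
}

# Vectorised backend used by the pileup builders: aligns every read in
# `queries` against one target, reusing DP buffers on the C++ side.
align_batch <- function(queries, target, match = 2, mismatch = -4,
                        gap_open = -4, gap_extend = -2,
                        mode = "global", band = 0L,
                        fast_mismatch = if (mode == "glocal") 3L else -1L) {
  if (length(queries) == 0L) return(list())
  .cpp_align_batch(as.character(queries), target, mode, match, mismatch,
                   gap_open, gap_extend, as.integer(band),
                   as.integer(fast_mismatch))
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment %s> score %.1f, target span [%d, %d)\n",
              x$mode, x$score, x$tstart, x$tend))
  cat(sprintf("  %d match, %d mismatch, %d ins, %d del; cigar %s\n",
              x$nmatch, x$nmismatch, x$nins, x$ndel,
              if (nchar(x$cigar) > 40) paste0(substr(x$cigar, 1, 40), "...")
              else x$cigar))
  invisible(x)
}

# Decode a run-length encoded CIGAR into a data.frame of (op, len).
cigar_ops <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[=XID]", cigar))[[1L]]
  stopifnot(length(lens) == length(ops))
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

# Per-target-position calls for pileups. Returns list(tstart, calls,
# insertions): `calls` is a character vector over target positions
# (tstart+1)..tend in 1-based coordinates, with "-" marking a deleted target
# base; `insertions` is a named character vector, names are the 1-based
# target position AFTER which the inserted bases sit ("0" = before the
# first aligned base).
alignment_calls <- function(aln, query = aln$query) {
  ops <- cigar_ops(aln$cigar)
  qchars <- strsplit(query, "", fixed = TRUE)[[1L]]
  ncol_t <- sum(ops$len[ops$op %in% c("=", "X", "D")])
  calls <- character(ncol_t)
  ins <- character(0)
  qi <- 0L; ti <- 0L  # consumed so far
  for (r in seq_len(nrow(ops))) {
    op <- ops$op[r]; len <- ops$len[r]
    if (op == "=" || op == "X") {
      calls[(ti + 1L):(ti + len)] <- qchars[(qi + 1L):(qi + len)]
      qi <- qi + len; ti <- ti + len
    } else if (op == "D") {
      calls[(ti + 1L):(ti + len)] <- "-"
      ti <- ti + len
    } else {  # I
      key <- as.character(aln$tstart + ti)
      piece <- paste(qchars[(qi + 1L):(qi + len)], collapse = "")
      ins[key] <- paste0(if (is.na(ins[key])) "" else ins[key], piece)
      qi <- qi + len
    }
  }
  list(tstart = aln$tstart, calls = calls, insertions = ins)
}

# Project a 0-based target boundary coordinate through an alignment onto the
# query. Insertions sitting exactly at the boundary are assigned upstream,
# i.e. the projected boundary lies AFTER them (except at coordinate 0, which
# always maps to 0 so the first feature absorbs leading insertions).
project_boundaries <- function(aln, boundaries) {
  ops <- cigar_ops(aln$cigar)
  dq <- ifelse(ops$op == "D", 0L, ops$len)
  dt <- ifelse(ops$op == "I", 0L, ops$len)
  qcum <- cumsum(c(0L, dq))
  tcum <- cumsum(c(0L, dt)) + aln$tstart
  vapply(boundaries, function(s) {
    if (s == 0L) return(0L)
    hit <- which(tcum == s)
    if (length(hit) == 0L) {
      # boundary falls inside a run; interpolate within it
      r <- which(tcum > s)[1L] - 1L
      if (is.na(r) || r < 1L)
        stop("boundary ", s, " outside aligned target span")
      off <- s - tcum[r]
      return(qcum[r] + if (ops$op[r] == "D") 0L else as.integer(off))
    }
    max(qcum[hit])  # after any insertion parked at the boundary
  }, integer(1L))
}

#' Unit-cost edit distance between two sequences
#'
#' Levenshtein distance (substitutions, insertions and deletions each cost
#' one), the metric used to pick the closest reference allele and to count
#' deviations from it.
#'
#' @param a,b Character strings.
#' @return A non-negative integer.
#' @examples
#' edit_distance("ACGT", "ACCT")  # 1
#' @export
edit_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  as.integer(adist(a, b))
}
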