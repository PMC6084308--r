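#' Call a per-position consensus with heterozygote detection
#'
#' Majority calling over a pileup. A position is called heterozygous when
#' the second most frequent call (bases or deletion) reaches the
#' heterozygote band: its frequency must be at least `het_band[1]` and the
#' leading call's frequency at most `het_band[2]` of the position's
#' coverage. Positions under `min_coverage` are flagged instead of called.
#' Accurate short-read data yields an essentially error-free consensus at
#' homozygous positions; heterozygous positions carry both alleles but no
#' phase — phase is the business of [phase_hets()].
#'
#' @param pileup A [build_pileup()] result.
#' @param min_coverage Minimum coverage for a call (default 10).
#' @param het_band Two ascending frequencies in `[0,1]` bounding the
#'   heterozygote band (default `c(0.25, 0.75)`).
#' @return A `consensus_track`: list with `sequence` (majority sequence,
#'   deletions removed), `call1`/`call2` (per-position leading and second
#'   call; `call2` is `NA` at homozygous positions), `status`
#'   (`"hom"`/`"het"`/`"low_coverage"` per position), `het_positions`
#'   (0-based backbone coordinates), `het_alleles`, `coverage`, and
#'   `phase_blocks` (`NULL` until [phase_hets()] is run).
#' @export
call_consensus <- function(pileup, min_coverage = 10,
                           het_band = c(0.25, 0.75)) {
  stopifnot(inherits(pileup, "pileup"))
  if (length(het_band) != 2L || het_band[1L] >= het_band[2L] ||
      het_band[1L] < 0 || het_band[2L] > 1)
    stop("het_band must be ascending frequencies within [0, 1]")
  counts <- pileup$counts
  cov <- pileup$coverage
  L <- ncol(counts)
  ord1 <- apply(counts, 2L, which.max)           # ties: A<C<G<T<- order
  call1 <- BASES5[ord1]
  c1 <- counts[cbind(ord1, seq_len(L))]
  counts2 <- counts
  counts2[cbind(ord1, seq_len(L))] <- -1L
  ord2 <- apply(counts2, 2L, which.max)
  c2 <- counts[cbind(ord2, seq_len(L))]
  call2 <- BASES5[ord2]
  f1 <- ifelse(cov > 0, c1 / cov, 0)
  f2 <- ifelse(cov > 0, c2 / cov, 0)
  status <- rep("hom", L)
  het <- f2 >= het_band[1L] & f1 <= het_band[2L] & c2 > 0L
  status[het] <- "het"
  status[cov < min_coverage] <- "low_coverage"
  call1[cov == 0L] <- NA_character_
  call2[status != "het"] <- NA_character_
  het_pos <- which(status == "het") - 1L   # 0-based
  seq_chars <- call1
  seq_chars[is.na(seq_chars) | seq_chars == "-"] <- ""
  structure(list(sequence = paste(seq_chars, collapse = ""),
                 call1 = call1, call2 = call2, status = status,
                 het_positions = het_pos,
                 het_alleles = lapply(het_pos, function(p)
                   c(call1[p + 1L], call2[p + 1L])),
                 coverage = cov, min_coverage = min_coverage,
                 het_band = het_band, phase_blocks = NULL),
            class = "consensus_track")
}

#' @export
print.consensus_track <- function(x, ...) {
  cat(sprintf(
    "<consensus_track> %d bp backbone: %d het, %d low-coverage position(s)\n",
    length(x$status), sum(x$status == "het"),
    sum(x$status == "low_coverage")))
  if (!is.null(x$phase_blocks))
    cat(sprintf("  %d phase block(s); whole-gene phasing %s\n",
                length(x$phase_blocks),
                if (length(x$phase_blocks) <= 1L) "defined" else "undefined"))
  invisible(x)
}

#' Group heterozygous positions into phase blocks via fragment linkage
#'
#' Two heterozygous positions belong to the same phase block iff they are
#' connected, transitively, by sequenced fragments covering both with
#' consistent allele co-occurrence. Because fragments on current shotgun
#' instruments are capped near 1000 bp, heterozygous positions separated by
#' more than the fragment span can never share a fragment: the track splits
#' into two or more blocks and whole-gene phasing is undefined — the short
#' read approach cannot phase the two alleles across such a gap.
#'
#' @param track A [call_consensus()] result.
#' @param pileup The pileup the track was called from (fragment linkage is
#'   read from its placements; the two placements of a read pair count as
#'   one fragment).
#' @return The track with `phase_blocks` filled in: a list of integer
#'   vectors of 0-based het positions, ordered by leftmost member, plus
#'   `phasing_defined` (`TRUE` iff at most one block).
#' @export
phase_hets <- function(track, pileup) {
  stopifnot(inherits(track, "consensus_track"), inherits(pileup, "pileup"))
  hp <- track$het_positions
  if (length(hp) <= 1L) {
    track$phase_blocks <- if (length(hp)) list(hp) else list()
    track$phasing_defined <- TRUE
    return(track)
  }
  frag <- split(pileup$placements,
                vapply(pileup$placements, `[[`, character(1L), "pair"))
  edges <- matrix(integer(0), ncol = 2L)
  for (pl in frag) {
    seen <- integer(0)
    for (p in pl) {
      calls <- vapply(hp + 1L, function(pos) placement_call(p, pos),
                      character(1L))
      seen <- union(seen, which(!is.na(calls)))
    }
    if (length(seen) >= 2L) {
      seen <- sort(seen)
      edges <- rbind(edges, cbind(seen[-length(seen)], seen[-1L]))
    }
  }
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(hp), seq_along(hp))), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(hp)]
  blocks <- unname(split(hp, comp))
  blocks <- blocks[order(vapply(blocks, min, numeric(1L)))]
  track$phase_blocks <- lapply(blocks, sort)
  track$phasing_defined <- length(blocks) <= 1L
  track
}
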