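#' Find informative (allele-discriminating) positions in a long-read pileup
#'
#' A position is informative when its second most frequent base (among
#' A/C/G/T) has a frequency inside `freq_window` — the signature of a true
#' heterozygous substitution standing out above the random error floor.
#' Deletion evidence is ignored here and candidates inside backbone
#' homopolymer runs (length >= 4) are excluded: indel-dominated long-read
#' error makes run-length differences unreliable, and those loci are
#' handled by run-length calling and short-read polishing downstream.
#'
#' @param pileup A long-read [build_pileup()] result.
#' @param freq_window Ascending frequency pair, default `c(0.30, 0.70)`.
#' @param min_coverage Minimum coverage to consider a position.
#' @return Sorted integer vector of 0-based backbone positions.
#' @export
call_informative_positions <- function(pileup, freq_window = c(0.30, 0.70),
                                       min_coverage = 10) {
  stopifnot(inherits(pileup, "pileup"))
  if (length(freq_window) != 2L || freq_window[1L] > freq_window[2L])
    stop("freq_window must be ascending")
  counts <- pileup$counts[c("A", "C", "G", "T"), , drop = FALSE]
  cov <- pileup$coverage
  L <- ncol(counts)
  ord1 <- apply(counts, 2L, which.max)
  counts2 <- counts
  counts2[cbind(ord1, seq_len(L))] <- -1L
  c2 <- counts[cbind(apply(counts2, 2L, which.max), seq_len(L))]
  f2 <- ifelse(cov > 0, c2 / cov, 0)
  ok <- cov >= min_coverage & f2 >= freq_window[1L] & f2 <= freq_window[2L]
  hp <- homopolymer_runs(pileup$backbone)
  if (nrow(hp))
    for (r in seq_len(nrow(hp)))
      ok[(hp$start[r] + 1L):hp$end[r]] <- FALSE
  which(ok) - 1L
}

#' Cluster long reads by source allele
#'
#' Each read is reduced to its base signature at the informative positions
#' and assigned to one of two clusters by agreement with iteratively
#' refined cluster centroids (column-wise majority signatures). Reads
#' disagreeing with both centroids at more than `max_mismatch` of their
#' comparable positions are left unassigned. With no informative positions
#' the sample is flagged homozygous and all reads form a single cluster.
#' The procedure is deterministic: centroids are seeded from the read with
#' the most complete signature and the read most distant from it.
#'
#' @param pileup The long-read pileup.
#' @param informative_positions From [call_informative_positions()].
#' @param max_mismatch Unassignment threshold (default 0.4).
#' @param max_iter Refinement iteration cap.
#' @return A `cluster_assignment`: `labels` (named vector over reads with
#'   values 1, 2 or `NA`), `homozygous` flag, `centroids`, `consistency`
#'   (mean agreement of assigned reads with their centroid, in `[0,1]`).
#' @export
cluster_long_reads <- function(pileup, informative_positions,
                               max_mismatch = 0.4, max_iter = 20L) {
  stopifnot(inherits(pileup, "pileup"))
  nms <- names(pileup$placements)
  if (length(informative_positions) == 0L) {
    return(structure(list(
      labels = setNames(rep(1L, length(nms)), nms), homozygous = TRUE,
      centroids = NULL, consistency = 1), class = "cluster_assignment"))
  }
  sig <- t(vapply(pileup$placements, function(p)
    vapply(informative_positions + 1L, function(pos)
      placement_call(p, pos), character(1L)),
    character(length(informative_positions))))
  sig[sig == "-"] <- NA_character_
  dimnames(sig) <- list(nms, NULL)
  agree <- function(a, b) {
    cmp <- !is.na(a) & !is.na(b)
    if (!any(cmp)) return(NA_real_)
    mean(a[cmp] == b[cmp])
  }
  # Initial centroids by co-occurrence chaining: at every informative
  # position take the two most frequent bases, then phase them across
  # positions by majority co-occurrence within reads. This is robust at
  # 50/50 allele balance, where seeding from individual (error-carrying)
  # reads can capture both centroids on the same allele.
  P <- ncol(sig)
  top2 <- lapply(seq_len(P), function(p) {
    tab <- sort(table(sig[, p]), decreasing = TRUE)
    c(names(tab), NA_character_, NA_character_)[1:2]
  })
  hapA <- character(P); hapB <- character(P)
  hapA[1L] <- top2[[1L]][1L]; hapB[1L] <- top2[[1L]][2L]
  if (P > 1L) for (p in 2:P) {
    prev_a <- sig[, p - 1L] == hapA[p - 1L]
    votes <- sig[which(prev_a), p]
    votes <- votes[!is.na(votes) & votes %in% top2[[p]]]
    a_base <- if (length(votes)) names(sort(table(votes),
                                            decreasing = TRUE))[1L]
              else top2[[p]][1L]
    hapA[p] <- a_base
    hapB[p] <- if (!is.na(top2[[p]][2L]) && a_base == top2[[p]][1L])
      top2[[p]][2L] else top2[[p]][1L]
  }
  cent <- list(hapA, hapB)
  labels <- rep(NA_integer_, nrow(sig))
  # a read is assigned only when it favours one centroid by a net margin
  # of >= 2 discriminating sites (1 when the sample offers a single
  # informative position): with indel-heavy reads an individual site call
  # is occasionally corrupted by an adjacent indel, so a one-site margin
  # is not trustworthy evidence of allele membership
  min_margin <- min(2L, ncol(sig))
  for (it in seq_len(max_iter)) {
    m1 <- apply(sig, 1L, function(s) sum(s == cent[[1L]], na.rm = TRUE))
    m2 <- apply(sig, 1L, function(s) sum(s == cent[[2L]], na.rm = TRUE))
    a1 <- apply(sig, 1L, agree, cent[[1L]])
    a2 <- apply(sig, 1L, agree, cent[[2L]])
    new_labels <- ifelse(m1 - m2 >= min_margin, 1L,
                  ifelse(m2 - m1 >= min_margin, 2L, NA_integer_))
    low1 <- (1 - (a1 %|NA|% 1)) > max_mismatch
    low2 <- (1 - (a2 %|NA|% 1)) > max_mismatch
    new_labels[low1 & low2] <- NA_integer_
    if (identical(new_labels, labels)) break
    labels <- new_labels
    cent <- lapply(1:2, function(k) {
      sub <- sig[which(labels == k), , drop = FALSE]
      if (nrow(sub) == 0L) return(cent[[k]])
      apply(sub, 2L, function(col) {
        col <- col[!is.na(col)]
        if (!length(col)) return(NA_character_)
        tab <- table(col)
        names(tab)[which.max(tab)]
      })
    })
  }
  # canonical orientation: cluster 1 holds the first assigned read
  first <- which(!is.na(labels))[1L]
  if (!is.na(first) && labels[first] == 2L) {
    labels <- 3L - labels
    cent <- rev(cent)
  }
  a_own <- ifelse(is.na(labels), NA_real_,
                  ifelse(labels == 1L, apply(sig, 1L, agree, cent[[1L]]),
                         apply(sig, 1L, agree, cent[[2L]])))
  structure(list(labels = setNames(labels, nms), homozygous = FALSE,
                 centroids = cent,
                 consistency = mean(a_own, na.rm = TRUE)),
            class = "cluster_assignment")
}

`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

#' @export
print.cluster_assignment <- function(x, ...) {
  if (x$homozygous) {
    cat(sprintf("<cluster_assignment> homozygous: %d reads, one cluster\n",
                length(x$labels)))
  } else {
    cat(sprintf(
      "<cluster_assignment> %d / %d / %d reads (1 / 2 / unassigned), consistency %.3f\n",
      sum(x$labels == 1L, na.rm = TRUE), sum(x$labels == 2L, na.rm = TRUE),
      sum(is.na(x$labels)), x$consistency))
  }
  invisible(x)
}

#' Preliminary per-allele consensus from clustered long reads
#'
#' Majority call per backbone column over one cluster's placements, with
#' insertion consensus (inserted when supported by more than half of the
#' covering reads) and explicit homopolymer run-length calling: for every
#' backbone homopolymer run (>= 4 bases) the run length is re-called as the
#' mode of the per-read observed run lengths, and flagged ambiguous when
#' the mode's support falls below `hp_support` (or ties). An ambiguous flag
#' is the long-read stage saying the run length must not be decided from
#' long reads alone — exactly the poly-A situation that forces short-read
#' polishing.
#'
#' @param pileup The long-read pileup.
#' @param members Read names of the cluster.
#' @param hp_support Minimal mode support for an unambiguous run-length
#'   call (default 0.6).
#' @return An `allele_consensus`: `sequence`, `hp_flags` (data.frame with
#'   backbone run span, called length, support, `ambiguous`, and the run's
#'   0-based half-open span `out_start`/`out_end` on the consensus), and
#'   `n_reads`.
#' @export
build_allele_consensus <- function(pileup, members, hp_support = 0.6) {
  stopifnot(inherits(pileup, "pileup"), length(members) >= 1L,
            all(members %in% names(pileup$placements)))
  counts <- subset_counts(pileup, members)
  L <- ncol(counts)
  cov <- colSums(counts)
  ord1 <- apply(counts, 2L, which.max)
  call1 <- BASES5[ord1]
  call1[cov == 0L] <- "-"   # uncovered columns contribute nothing
  pieces <- ifelse(call1 == "-", "", call1)
  # insertion consensus
  ins <- pileup$insertions[pileup$insertions$read %in% members, ,
                           drop = FALSE]
  ins_after <- setNames(character(0), character(0))
  if (nrow(ins)) {
    for (pos in unique(ins$pos)) {
      n_cov <- if (pos == 0L) length(members)
               else sum(counts[, pos]) # reads covering the flank
      obs <- ins$seq[ins$pos == pos]
      tab <- sort(table(obs), decreasing = TRUE)
      if (tab[1L] > 0.5 * n_cov) ins_after[as.character(pos)] <- names(tab)[1L]
    }
  }
  # homopolymer run-length recall
  hp <- homopolymer_runs(pileup$backbone)
  flags <- NULL
  if (nrow(hp)) {
    flags <- hp
    flags$called_len <- NA_integer_
    flags$support <- NA_real_
    flags$ambiguous <- FALSE
    for (r in seq_len(nrow(hp))) {
      obs <- observed_run_lengths(pileup, members, hp$base[r],
                                  hp$start[r], hp$end[r])
      if (!length(obs)) next
      tab <- sort(table(obs), decreasing = TRUE)
      mode_len <- as.integer(names(tab)[1L])
      support <- tab[[1L]] / length(obs)
      tied <- sum(tab == tab[1L]) > 1L
      if (tied) mode_len <- min(as.integer(names(tab)[tab == tab[1L]]))
      flags$called_len[r] <- mode_len
      flags$support[r] <- support
      flags$ambiguous[r] <- tied || support < hp_support
      # override the run region with the called length
      pieces[(hp$start[r] + 1L):hp$end[r]] <- ""
      pieces[hp$start[r] + 1L] <- strrep(hp$base[r], mode_len)
      drop <- as.character(hp$start[r]:hp$end[r])
      ins_after <- ins_after[setdiff(names(ins_after), drop)]
    }
  }
  # assemble, tracking where each backbone column lands on the consensus
  out_pieces <- character(L + 1L)
  out_pieces[1L] <- ins_after["0"] %|NA|% ""
  for (k in seq_len(L))
    out_pieces[k + 1L] <- paste0(pieces[k], ins_after[as.character(k)] %|NA|% "")
  # offsets[i] = consensus chars emitted before piece i; column k (1-based)
  # is piece k+1, so a run starting at 0-based backbone s begins at
  # offsets[s + 2] on the consensus
  offsets <- cumsum(c(0L, nchar(out_pieces)))
  if (!is.null(flags) && nrow(flags)) {
    flags$out_start <- offsets[flags$start + 2L]
    flags$out_end <- flags$out_start + ifelse(is.na(flags$called_len), 0L,
                                              flags$called_len)
  }
  structure(list(sequence = paste(out_pieces, collapse = ""),
                 hp_flags = flags, n_reads = length(members),
                 backbone = pileup$backbone),
            class = "allele_consensus")
}

# per-read observed length of a homopolymer run [s, e) (0-based) of `base`:
# matching non-deleted calls within the run plus adjacent same-base
# insertions keyed at backbone positions s..e
observed_run_lengths <- function(pileup, members, base, s, e) {
  ins <- pileup$insertions
  obs <- integer(0)
  for (p in pileup$placements[members]) {
    if (p$tstart > s - 1L || p$tend < e + 1L) next  # must span the run
    calls <- p$calls[(s + 1L - p$tstart):(e - p$tstart)]
    n <- sum(calls == base)
    mine <- ins[ins$read == p$name & ins$pos >= s & ins$pos <= e, ,
                drop = FALSE]
    if (nrow(mine)) {
      for (sq in mine$seq) {
        ch <- strsplit(sq, "", fixed = TRUE)[[1L]]
        n <- n + sum(ch == base)
      }
    }
    obs <- c(obs, n)
  }
  obs
}

#' @export
print.allele_consensus <- function(x, ...) {
  namb <- if (is.null(x$hp_flags)) 0L else sum(x$hp_flags$ambiguous)
  cat(sprintf(
    "<allele_consensus> %d bp from %d reads; %d ambiguous homopolymer locus/loci\n",
    nchar(x$sequence), x$n_reads, namb))
  invisible(x)
}
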