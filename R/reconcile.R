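CONFLICT_CATEGORIES <- c("SMRT_only_deviation", "SBS_only_deviation",
                         "concordant_deviation", "homopolymer_indel",
                         "phase_gap")

# classify one position given the three call sets; `hp_indel` marks a
# deviation that is indel-type inside a reference homopolymer run — the
# locus class where platform disagreement reflects long-read indel error,
# not a sample problem, whichever side shows the indel (the poly-A
# situation: short reads see one allele's deletion while long reads are
# inconclusive). The published rules leave one cell open (both platforms
# deviate from the reference AND from each other); outside homopolymers it
# is treated as an SBS deviation so the safest action (repeat) wins.
classify_calls <- function(ref, sbs, smrt, hp_indel = FALSE) {
  sbs <- sort(unique(sbs)); smrt <- sort(unique(smrt))
  sbs_dev <- !identical(sbs, ref); smrt_dev <- !identical(smrt, ref)
  if (!sbs_dev && !smrt_dev) return(NA_character_)
  if (identical(sbs, smrt)) return("concordant_deviation")
  if (hp_indel) return("homopolymer_indel")
  if (!sbs_dev) return("SMRT_only_deviation")
  "SBS_only_deviation"
}

#' Compare short-read and long-read consensus tracks against a reference
#'
#' Projects the long-read haplotype pair onto the reference backbone and
#' classifies every position where the short-read track, the long-read
#' pair, or both deviate from the reference. Categories:
#' `concordant_deviation` (both platforms agree on a non-reference call —
#' a real variant), `SMRT_only_deviation`, `SBS_only_deviation`,
#' `homopolymer_indel` (a long-read-only indel deviation inside a
#' reference homopolymer run, or an ambiguity-flagged run), and
#' `phase_gap` (emitted between consecutive short-read phase blocks when
#' whole-gene phasing is undefined). An empty result means full
#' concordance.
#'
#' @param sbs_track A phased [call_consensus()] track (see
#'   [phase_hets()]) called against the reference backbone.
#' @param smrt_pair List of two [build_allele_consensus()] results (one
#'   per allele; pass the same one twice for homozygous samples).
#' @param reference The closest reference allele sequence (the common
#'   backbone).
#' @return A `conflict_list`: data.frame with `position` (0-based
#'   reference coordinate, `NA` for phase gaps), `category`, `ref`,
#'   `sbs`, `smrt`.
#' @export
compare_tracks <- function(sbs_track, smrt_pair, reference) {
  stopifnot(inherits(sbs_track, "consensus_track"),
            length(smrt_pair) == 2L,
            is.character(reference), length(reference) == 1L)
  L <- nchar(reference)
  ref_chars <- strsplit(reference, "", fixed = TRUE)[[1L]]
  # project each long-read haplotype onto reference coordinates
  proj <- lapply(smrt_pair, function(h) {
    aln <- align_global(h$sequence, reference,
                        band = max(100L, ceiling(0.05 * L)))
    alignment_calls(aln)
  })
  smrt_calls <- vapply(seq_len(L), function(pos) {
    c(proj[[1L]]$calls[pos], proj[[2L]]$calls[pos])
  }, character(2L))
  hp <- homopolymer_runs(reference)
  in_hp <- rep(FALSE, L)
  if (nrow(hp))
    for (r in seq_len(nrow(hp))) in_hp[(hp$start[r] + 1L):hp$end[r]] <- TRUE
  rows <- list()
  for (pos in seq_len(L)) {
    if (sbs_track$status[pos] == "low_coverage") next
    sbs <- if (sbs_track$status[pos] == "het")
      c(sbs_track$call1[pos], sbs_track$call2[pos])
    else sbs_track$call1[pos]
    smrt <- smrt_calls[, pos]
    hp_indel <- in_hp[pos] &&
      ("-" %in% smrt || "-" %in% sbs ||
         any(vapply(proj, function(p)
           any(as.integer(names(p$insertions)) == pos), logical(1L))))
    cat_ <- classify_calls(ref_chars[pos], sbs, smrt, hp_indel)
    if (is.na(cat_)) next
    rows[[length(rows) + 1L]] <- data.frame(
      position = pos - 1L, category = cat_, ref = ref_chars[pos],
      sbs = paste(sort(unique(sbs)), collapse = "/"),
      smrt = paste(sort(unique(smrt)), collapse = "/"),
      stringsAsFactors = FALSE)
  }
  # ambiguity-flagged homopolymer runs are indel conflicts by definition
  for (h in smrt_pair) {
    fl <- h$hp_flags
    if (is.null(fl)) next
    fl <- fl[which(fl$ambiguous), , drop = FALSE]
    for (r in seq_len(nrow(fl))) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = fl$start[r], category = "homopolymer_indel",
        ref = fl$base[r], sbs = "", smrt = "ambiguous_run",
        stringsAsFactors = FALSE)
    }
  }
  # phase gaps between consecutive phase blocks
  blocks <- sbs_track$phase_blocks
  if (!is.null(blocks) && length(blocks) > 1L) {
    for (k in 2:length(blocks)) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = min(blocks[[k]]), category = "phase_gap",
        ref = "", sbs = "", smrt = "", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(0), category = character(0),
               ref = character(0), sbs = character(0), smrt = character(0),
               stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("position", "category")]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("conflict_list", "data.frame")
  out
}

#' Decide the workflow action from a conflict list
#'
#' The rule engine of the dual redundant strategy. With fixed precedence
#' (configurable, safest first):
#' \itemize{
#'   \item rule 2 — any short-read-only deviation: the analysis must be
#'     repeated (`REPEAT_ANALYSIS`); accurate short reads disagreeing with
#'     both reference and long reads signal a sample or library problem.
#'   \item rule 3 — whole-gene short-read phasing undefined and any
#'     homopolymer-indel or phase-gap conflict: run the cluster-and-polish
#'     procedure (`RUN_DR2S`).
#'   \item rule 1 — remaining long-read-only deviations are flagged as
#'     sequencing errors and the short-read consensus is submitted
#'     (`SUBMIT_SBS`).
#'   \item otherwise (no conflicts, or only concordant deviations — true
#'     variants seen by both platforms): `SUBMIT_CONCORDANT`.
#' }
#'
#' @param conflicts A [compare_tracks()] result.
#' @param sbs_phasing_defined Whether the short-read track forms a single
#'   phase block.
#' @param precedence Order in which the three rules are tried.
#' @return A `decision`: `action`, per-conflict `justification` (rule id),
#'   and the inputs. Total and deterministic for every conflict list.
#' @export
decide <- function(conflicts, sbs_phasing_defined,
                   precedence = c("REPEAT_ANALYSIS", "RUN_DR2S",
                                  "SUBMIT_SBS")) {
  stopifnot(is.data.frame(conflicts),
            all(precedence %in% c("REPEAT_ANALYSIS", "RUN_DR2S",
                                  "SUBMIT_SBS")))
  cats <- conflicts$category
  fire <- c(
    REPEAT_ANALYSIS = any(cats == "SBS_only_deviation"),
    RUN_DR2S = !sbs_phasing_defined &&
      any(cats %in% c("homopolymer_indel", "phase_gap")),
    SUBMIT_SBS = any(cats == "SMRT_only_deviation" |
                       cats == "homopolymer_indel"))
  action <- "SUBMIT_CONCORDANT"
  for (a in precedence) if (fire[[a]]) { action <- a; break }
  rule <- c(SMRT_only_deviation = "rule1", homopolymer_indel = "rule1",
            SBS_only_deviation = "rule2", phase_gap = "rule3",
            concordant_deviation = "concordant")[cats]
  rule[cats %in% c("homopolymer_indel", "phase_gap") &
         !sbs_phasing_defined] <- "rule3"
  structure(list(action = action,
                 justification = data.frame(
                   position = conflicts$position, category = cats,
                   rule = unname(rule), stringsAsFactors = FALSE),
                 sbs_phasing_defined = sbs_phasing_defined,
                 precedence = precedence),
            class = "decision")
}

#' @export
print.decision <- function(x, ...) {
  cat(sprintf("<decision> %s (%d conflict(s); SBS phasing %s)\n", x$action,
              nrow(x$justification),
              if (x$sbs_phasing_defined) "defined" else "undefined"))
  if (nrow(x$justification)) print.data.frame(x$justification)
  invisible(x)
}

#' Polish preliminary haplotype consensus sequences with short reads
#'
#' The correction stage of the cluster-and-polish procedure. All short
#' reads are mapped against each preliminary haplotype; in addition, every
#' read pair is assigned to the haplotype it matches better (ties
#' dropped). A preliminary call is then corrected wherever the short-read
#' evidence contradicts it:
#' \itemize{
#'   \item where the full read set is unimodal (majority above
#'     `min_fraction`) the haplotypes agree with each other, every read is
#'     valid evidence, and the majority call overrules the preliminary
#'     call — this is how long-read consensus errors in
#'     haplotype-shared sequence (including miscalled homopolymer runs)
#'     are repaired;
#'   \item where the evidence is bimodal (a true difference between the
#'     two alleles, e.g. the poly-A length difference), only the pairs
#'     assigned to this haplotype vote, so each haplotype receives its own
#'     allele.
#' }
#' Ambiguity-flagged homopolymer loci are always re-called by these rules;
#' unflagged positions the short reads agree with are never touched.
#'
#' @param preliminary_pair List of two [build_allele_consensus()] results.
#' @param short_reads A `paired_read_set`.
#' @param min_coverage Minimum short-read coverage to correct a position.
#' @param min_fraction Majority fraction above which the full read set
#'   overrules the preliminary call (default 0.7); minority evidence above
#'   `1 - min_fraction` marks a position bimodal.
#' @return A `polished_pair`: list with `haplotypes` (two sequences),
#'   `changes` (per-haplotype data.frames of applied corrections) and
#'   `assignment` counts.
#' @export
polish_consensus <- function(preliminary_pair, short_reads,
                             min_coverage = 10, min_fraction = 0.7) {
  stopifnot(length(preliminary_pair) == 2L,
            inherits(short_reads, "paired_read_set"))
  h1 <- preliminary_pair[[1L]]$sequence
  h2 <- preliminary_pair[[2L]]$sequence
  seqs <- c(short_reads$read1, revcomp(short_reads$read2))
  names(seqs) <- sprintf("%s@%d", names(seqs), seq_along(seqs))
  pair_ids <- c(short_reads$truth$pair, short_reads$truth$pair)
  s1 <- vapply(align_batch(seqs, h1, mode = "glocal"), `[[`,
               numeric(1L), "score")
  s2 <- vapply(align_batch(seqs, h2, mode = "glocal"), `[[`,
               numeric(1L), "score")
  t1 <- tapply(s1, pair_ids, sum)
  t2 <- tapply(s2, pair_ids, sum)
  to1 <- names(t1)[t1 > t2]
  to2 <- names(t1)[t2 > t1]   # ties shared via the full pileup, not split
  pu_all <- list(build_pileup(seqs, h1), build_pileup(seqs, h2))
  pu_own <- list(build_pileup(seqs[pair_ids %in% to1], h1),
                 build_pileup(seqs[pair_ids %in% to2], h2))
  # Ambiguity-flagged homopolymer runs are re-called jointly across the
  # pair from the short-read run-length histogram: when both preliminary
  # haplotypes carry the same (possibly wrong) run length, reads cannot be
  # assigned by score at that locus, so per-haplotype evidence alone
  # cannot recover a het run. A bimodal histogram hands one mode to each
  # haplotype (oriented by assigned-read votes when available, else by the
  # preliminary called lengths).
  run_calls <- joint_run_recall(preliminary_pair, pu_all, pu_own,
                                min_coverage, min_fraction)
  r1 <- correct_haplotype(h1, preliminary_pair[[1L]], pu_all[[1L]],
                          pu_own[[1L]], min_coverage, min_fraction,
                          run_calls[[1L]])
  r2 <- correct_haplotype(h2, preliminary_pair[[2L]], pu_all[[2L]],
                          pu_own[[2L]], min_coverage, min_fraction,
                          run_calls[[2L]])
  structure(list(haplotypes = c(r1$sequence, r2$sequence),
                 changes = list(r1$changes, r2$changes),
                 assignment = c(hap1 = length(to1), hap2 = length(to2),
                                unassigned = sum(t1 == t2))),
            class = "polished_pair")
}

# decide the polished length of every ambiguity-flagged run for both
# haplotypes; returns a list of two data.frames (out_start, out_end,
# base, new_len) in preliminary-haplotype coordinates. Run lengths are
# measured per read through the alignment (matching calls plus same-base
# insertions within the run), the same statistic the long-read caller
# uses, which stays consistent when adjacent runs shift.
joint_run_recall <- function(pair, pu_all, pu_own, min_coverage,
                             min_fraction) {
  flags <- lapply(pair, function(h) {
    fl <- h$hp_flags
    if (is.null(fl)) return(fl)
    fl[which(fl$ambiguous & !is.na(fl$out_start)), , drop = FALSE]
  })
  calls <- list(NULL, NULL)
  # index runs by their backbone span so pair members line up
  keys <- unique(unlist(lapply(flags, function(f)
    if (is.null(f) || !nrow(f)) character(0)
    else paste(f$start, f$base))))
  for (key in keys) {
    rows <- lapply(flags, function(f) {
      if (is.null(f)) return(NULL)
      r <- f[paste(f$start, f$base) == key, , drop = FALSE]
      if (nrow(r)) r[1L, ] else NULL
    })
    base <- (rows[[1L]] %||% rows[[2L]])$base
    k0 <- if (is.null(rows[[1L]])) 2L else 1L
    span <- c(rows[[k0]]$out_start, rows[[k0]]$out_end)
    obs_all <- observed_run_lengths(pu_all[[k0]],
                                    names(pu_all[[k0]]$placements),
                                    base, span[1L], span[2L])
    if (length(obs_all) < min_coverage) next
    tab <- sort(table(obs_all), decreasing = TRUE)
    top <- as.integer(names(tab)[1L])
    supp <- tab[[1L]] / length(obs_all)
    if (supp >= min_fraction) {
      new_len <- c(top, top)
    } else if (length(tab) >= 2L &&
               (tab[[1L]] + tab[[2L]]) / length(obs_all) >= min_fraction &&
               tab[[2L]] / length(obs_all) > 1 - min_fraction) {
      modes <- as.integer(names(tab)[1:2])
      # orient by assigned-read votes where possible
      own_mode <- vapply(1:2, function(k) {
        if (is.null(rows[[k]])) return(NA_integer_)
        o <- observed_run_lengths(pu_own[[k]],
                                  names(pu_own[[k]]$placements), base,
                                  rows[[k]]$out_start, rows[[k]]$out_end)
        o <- o[o %in% modes]
        if (length(o) < 3L) return(NA_integer_)
        as.integer(names(sort(table(o), decreasing = TRUE))[1L])
      }, integer(1L))
      if (!anyNA(own_mode) && length(unique(own_mode)) == 2L) {
        new_len <- own_mode
      } else {
        # fall back to the preliminary called lengths' ordering
        prelim <- vapply(1:2, function(k)
          if (is.null(rows[[k]])) NA_integer_
          else rows[[k]]$called_len, integer(1L))
        hi <- max(modes); lo <- min(modes)
        if (!anyNA(prelim) && prelim[1L] != prelim[2L]) {
          new_len <- if (prelim[1L] > prelim[2L]) c(hi, lo) else c(lo, hi)
        } else new_len <- c(hi, lo)
      }
    } else next
    for (k in 1:2) {
      if (is.null(rows[[k]])) next
      calls[[k]] <- rbind(calls[[k]], data.frame(
        out_start = rows[[k]]$out_start, out_end = rows[[k]]$out_end,
        base = base, new_len = new_len[k], stringsAsFactors = FALSE))
    }
  }
  calls
}

# majority call and fraction per column of a counts matrix
column_majority <- function(counts) {
  cov <- colSums(counts)
  ord1 <- apply(counts, 2L, which.max)
  c1 <- counts[cbind(ord1, seq_len(ncol(counts)))]
  list(call = BASES5[ord1], frac = ifelse(cov > 0, c1 / cov, 0),
       cov = cov)
}

# apply short-read corrections to one haplotype (see polish_consensus);
# `run_calls` carries jointly re-called homopolymer run lengths whose
# regions are excluded from per-column correction and overridden at
# assembly time
correct_haplotype <- function(hap, cons, pu_all, pu_own, min_coverage,
                              min_fraction, run_calls = NULL) {
  L <- nchar(hap)
  hap_chars <- strsplit(hap, "", fixed = TRUE)[[1L]]
  in_run <- logical(L)
  if (!is.null(run_calls) && nrow(run_calls)) {
    for (r in seq_len(nrow(run_calls)))
      if (run_calls$out_end[r] > run_calls$out_start[r])
        in_run[(run_calls$out_start[r] + 1L):run_calls$out_end[r]] <- TRUE
  }
  all_m <- column_majority(pu_all$counts)
  own_m <- column_majority(pu_own$counts)
  min_own <- max(3L, ceiling(min_coverage / 2))
  unimodal <- all_m$cov >= min_coverage & all_m$frac >= min_fraction &
    !in_run
  bimodal <- all_m$cov >= min_coverage & all_m$frac < min_fraction &
    !in_run
  call <- hap_chars
  call[unimodal] <- all_m$call[unimodal]
  use_own <- bimodal & own_m$cov >= min_own & own_m$frac > 0.5
  call[use_own] <- own_m$call[use_own]
  edit_pos <- which(call != hap_chars)
  changes <- data.frame(pos = edit_pos - 1L, from = hap_chars[edit_pos],
                        to = call[edit_pos],
                        evidence = ifelse(unimodal[edit_pos], "all_reads",
                                          "assigned_reads"),
                        stringsAsFactors = FALSE)
  # insertion corrections, same unimodal / bimodal logic
  ins_after <- setNames(character(0), character(0))
  ins_all <- pu_all$insertions
  own_reads <- names(pu_own$placements)
  for (pos in unique(ins_all$pos)) {
    if (pos > 0L && in_run[pos]) next
    if (pos < L && in_run[pos + 1L]) next
    n_all <- if (pos == 0L) length(pu_all$placements)
             else sum(pu_all$counts[, pos])
    if (n_all < min_coverage) next
    tab <- sort(table(ins_all$seq[ins_all$pos == pos]), decreasing = TRUE)
    supp <- tab[[1L]] / n_all
    if (supp >= min_fraction) {
      ins_after[as.character(pos)] <- names(tab)[1L]
    } else if (supp > 1 - min_fraction) {  # bimodal: assigned reads vote
      mine <- ins_all[ins_all$pos == pos & ins_all$read %in% own_reads, ,
                      drop = FALSE]
      n_own <- if (pos == 0L) length(pu_own$placements)
               else sum(pu_own$counts[, pos])
      if (n_own >= max(3L, ceiling(min_coverage / 2)) && nrow(mine)) {
        tab_own <- sort(table(mine$seq), decreasing = TRUE)
        if (tab_own[[1L]] > 0.5 * n_own)
          ins_after[as.character(pos)] <- names(tab_own)[1L]
      }
    }
  }
  out <- ifelse(call == "-", "", call)
  for (k in names(ins_after)) {
    ki <- as.integer(k)
    piece <- ins_after[[k]]
    if (ki == 0L) out[1L] <- paste0(piece, out[1L])
    else out[ki] <- paste0(out[ki], piece)
    changes <- rbind(changes, data.frame(pos = ki - 1L, from = "",
                                         to = piece, evidence = "insertion",
                                         stringsAsFactors = FALSE))
  }
  # jointly re-called homopolymer runs override their region wholesale
  if (!is.null(run_calls) && nrow(run_calls)) {
    for (r in seq_len(nrow(run_calls))) {
      s <- run_calls$out_start[r]; e <- run_calls$out_end[r]
      old_len <- e - s
      if (e > s) out[(s + 1L):e] <- ""
      out[s + 1L] <- strrep(run_calls$base[r], run_calls$new_len[r])
      if (run_calls$new_len[r] != old_len)
        changes <- rbind(changes, data.frame(
          pos = s, from = strrep(run_calls$base[r], old_len),
          to = strrep(run_calls$base[r], run_calls$new_len[r]),
          evidence = "run_recall", stringsAsFactors = FALSE))
    }
  }
  list(sequence = paste(out, collapse = ""), changes = changes)
}

#' The masking / artifact position audit
#'
#' For a consensus of length `L` carrying `d` true differences from the
#' closest reference there are exactly `d` positions where a sequencing
#' error could mask a real difference (by reverting it to the reference
#' base) but `L - d` positions where an error would introduce an
#' artificial difference — the asymmetry that motivates requiring a second,
#' independent sequencing technology. The worked class I example: a
#' 3404 bp consensus with 4 true differences has 4 masking and 3400
#' artifact-prone positions.
#'
#' @param consensus_length Consensus length `L` in bp.
#' @param n_true_differences Number of true differences `d`, `0 <= d <= L`.
#' @return Named integer vector `c(masking = d, artifact = L - d)`.
#' @examples
#' audit_positions(3404, 4)  # masking 4, artifact 3400
#' @export
audit_positions <- function(consensus_length, n_true_differences) {
  L <- as.integer(consensus_length); d <- as.integer(n_true_differences)
  if (is.na(L) || is.na(d) || d < 0L || d > L)
    stop("need 0 <= n_true_differences <= consensus_length")
  c(masking = d, artifact = L - d)
}
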