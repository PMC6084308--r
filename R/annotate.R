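#' Find the closest reference allele
#'
#' Minimal unit-cost edit distance over the reference set; ties are broken
#' by the lexicographically smallest allele name so results are stable.
#' The deviations of a consensus from this allele are what define it as
#' novel.
#'
#' @param novel Consensus DNA string.
#' @param ref_set A [reference_set()].
#' @return List with `allele` (a `reference_allele`) and `distance`.
#' @export
find_closest_reference <- function(novel, ref_set) {
  stopifnot(inherits(ref_set, "reference_set"), length(ref_set) >= 1L)
  d <- vapply(ref_set, function(a) edit_distance(novel, a$sequence),
              integer(1L))
  best <- min(d)
  nm <- sort(names(d)[d == best])[1L]
  list(allele = ref_set[[nm]], distance = best)
}

#' Transfer a gene model onto a novel sequence by alignment projection
#'
#' Globally aligns the novel consensus against its closest reference and
#' projects every feature boundary through the alignment. Insertions
#' inside a feature extend it; insertions sitting exactly on a boundary
#' are assigned to the upstream feature. Alignments under 90% identity are
#' refused — projecting a gene model across that much divergence would be
#' meaningless.
#'
#' @param novel Novel consensus DNA string.
#' @param closest A [reference_allele()] (e.g. from
#'   [find_closest_reference()]).
#' @param min_identity Refusal threshold on alignment identity.
#' @return A `gene_annotation`: projected `model`, `cds`, `protein`,
#'   `differences` (one row per aligned mismatch or indel: 0-based
#'   reference position, feature kind, ref/novel bases, type, codon
#'   effect), `closest` name, `distance`, `identity`.
#' @export
transfer_gene_model <- function(novel, closest, min_identity = 0.9) {
  stopifnot(is.character(novel), length(novel) == 1L,
            inherits(closest, "reference_allele"))
  aln <- align_global(novel, closest$sequence,
                      band = max(100L, ceiling(0.05 * nchar(novel))))
  ncols <- aln$nmatch + aln$nmismatch + aln$nins + aln$ndel
  identity <- aln$nmatch / ncols
  if (identity < min_identity)
    stop(sprintf(
      "refusing gene-model transfer: %.1f%% identity to %s is below %.0f%%",
      100 * identity, closest$name, 100 * min_identity))
  ref_model <- closest$model
  bounds <- c(ref_model$start, max(ref_model$end))
  proj <- project_boundaries(aln, bounds)
  n <- nrow(ref_model)
  model <- gene_model(data.frame(kind = ref_model$kind,
                                 start = proj[seq_len(n)],
                                 end = proj[-1L]), nchar(novel))
  cds <- splice_cds(novel, model)
  differences <- enumerate_alignment_differences(aln, closest, novel, model)
  structure(list(model = model, cds = cds, protein = translate_cds(cds),
                 differences = differences, closest = closest$name,
                 distance = aln$nmismatch + aln$nins + aln$ndel,
                 identity = identity,
                 ref_cds = splice_cds(closest$sequence, ref_model)),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf(
    "<gene_annotation> closest %s (%.2f%% identity): %d difference(s)\n",
    x$closest, 100 * x$identity, nrow(x$differences)))
  if (nrow(x$differences)) print.data.frame(x$differences)
  invisible(x)
}

# walk the alignment and list every mismatch / indel with its feature kind
# and, for exonic SNVs, the synonymous / nonsynonymous status
enumerate_alignment_differences <- function(aln, closest, novel, model) {
  ops <- cigar_ops(aln$cigar)
  ref_model <- closest$model
  kind_at <- function(p) {   # 0-based reference position -> feature kind
    ref_model$kind[which(p >= ref_model$start & p < ref_model$end)[1L]]
  }
  rows <- list()
  qi <- 0L; ti <- 0L
  for (r in seq_len(nrow(ops))) {
    op <- ops$op[r]; len <- ops$len[r]
    if (op == "=") { qi <- qi + len; ti <- ti + len }
    else if (op == "X") {
      for (k in seq_len(len)) {
        p <- ti + k - 1L
        rb <- substr(closest$sequence, p + 1L, p + 1L)
        nb <- substr(novel, qi + k, qi + k)
        kind <- kind_at(p)
        eff <- if (kind == "exon")
          snv_codon_effect(closest, p, nb) else NA_character_
        rows[[length(rows) + 1L]] <- data.frame(
          pos = p, feature = kind, type = "snv", ref = rb, novel = nb,
          codon_effect = eff, stringsAsFactors = FALSE)
      }
      qi <- qi + len; ti <- ti + len
    } else if (op == "D") {   # bases present in reference, absent in novel
      p <- ti
      kind <- kind_at(p)
      rows[[length(rows) + 1L]] <- data.frame(
        pos = p, feature = kind, type = "deletion",
        ref = substr(closest$sequence, p + 1L, p + len), novel = "",
        codon_effect = if (kind == "exon") {
          if (len %% 3L == 0L) "inframe_indel" else "frameshift"
        } else NA_character_, stringsAsFactors = FALSE)
      ti <- ti + len
    } else {                  # I: bases inserted in the novel sequence
      p <- max(0L, ti - 1L)
      kind <- kind_at(p)
      rows[[length(rows) + 1L]] <- data.frame(
        pos = p, feature = kind, type = "insertion", ref = "",
        novel = substr(novel, qi + 1L, qi + len),
        codon_effect = if (kind == "exon") {
          if (len %% 3L == 0L) "inframe_indel" else "frameshift"
        } else NA_character_, stringsAsFactors = FALSE)
      qi <- qi + len
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(0), feature = character(0),
               type = character(0), ref = character(0),
               novel = character(0), codon_effect = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# synonymous / nonsynonymous status of a reference-exon SNV
snv_codon_effect <- function(closest, p, novel_base) {
  ex <- closest$model[closest$model$kind == "exon", , drop = FALSE]
  hit <- which(p >= ex$start & p < ex$end)
  if (length(hit) == 0L) return(NA_character_)
  cds_pos <- if (hit > 1L) sum(ex$end[seq_len(hit - 1L)] -
                                 ex$start[seq_len(hit - 1L)]) else 0L
  cds_pos <- cds_pos + (p - ex$start[hit])
  cds <- splice_cds(closest$sequence, closest$model)
  ci <- cds_pos %/% 3L
  codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
  mut <- codon
  substr(mut, cds_pos %% 3L + 1L, cds_pos %% 3L + 1L) <- novel_base
  if (nchar(codon) < 3L) return(NA_character_)
  if (translate_cds(codon) == translate_cds(mut)) "synonymous"
  else "nonsynonymous"
}

#' Classify the expression status of an annotated allele
#'
#' Scans the coding sequence 5' to 3'. A stop codon appearing before the
#' reference stop — directly or through a frameshift — predicts a
#' non-functional null (N) allele. Otherwise, any difference matching the
#' questionable-expression catalog (variants shown in other alleles to
#' affect normal expression) yields Q status; everything else is normal.
#'
#' @param annotation A [transfer_gene_model()] result.
#' @param q_catalog Optional data.frame of known expression-affecting
#'   variants with columns `pos` (0-based reference coordinate), `ref`,
#'   `novel`, `id`; matching is exact on all three.
#' @return An `expression_class`: `class` (`"normal"`, `"N"` or `"Q"`)
#'   and `evidence` (stop codon index or matched catalog id).
#' @export
classify_expression <- function(annotation, q_catalog = NULL) {
  stopifnot(inherits(annotation, "gene_annotation"))
  prot <- annotation$protein
  ref_prot <- translate_cds(annotation$ref_cds)
  stops <- gregexpr("*", prot, fixed = TRUE)[[1L]]
  first_stop <- if (stops[1L] == -1L) Inf else stops[1L]
  ref_stops <- gregexpr("*", ref_prot, fixed = TRUE)[[1L]]
  ref_stop <- if (ref_stops[1L] == -1L) nchar(ref_prot) + 1L else ref_stops[1L]
  if (first_stop < ref_stop) {
    return(structure(list(class = "N",
                          evidence = sprintf("premature stop at codon %d (reference stop at %d)",
                                             first_stop, ref_stop)),
                     class = "expression_class"))
  }
  if (!is.null(q_catalog) && nrow(annotation$differences)) {
    d <- annotation$differences
    for (i in seq_len(nrow(q_catalog))) {
      hit <- d$pos == q_catalog$pos[i] & d$ref == q_catalog$ref[i] &
        d$novel == q_catalog$novel[i]
      if (any(hit)) {
        return(structure(list(class = "Q",
                              evidence = as.character(q_catalog$id[i])),
                         class = "expression_class"))
      }
    }
  }
  structure(list(class = "normal", evidence = NA_character_),
            class = "expression_class")
}

#' @export
print.expression_class <- function(x, ...) {
  cat(sprintf("<expression_class> %s%s\n", x$class,
              if (!is.na(x$evidence)) paste0(" (", x$evidence, ")") else ""))
  invisible(x)
}

#' Per-feature difference table of an annotated allele
#'
#' @param annotation A [transfer_gene_model()] result.
#' @return The difference table: one row per aligned mismatch or indel
#'   with feature kind and, for exonic SNVs, synonymous/nonsynonymous
#'   status. Empty for a confirmatory (identical) sequence.
#' @export
enumerate_differences <- function(annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  annotation$differences
}
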