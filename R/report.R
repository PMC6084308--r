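# half-up decimal rounding (R's round() is banker's); used for all
# printed percentages
round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

#' Assemble a submission record
#'
#' The unit handed to the submission file writer: the final sequence with
#' its annotation, expression class and category. The complete HLA types
#' of the sample for the HLA-A, -B and -DRB1 genes must accompany every
#' submission, so they are mandatory here.
#'
#' @param sample_id Sample identifier.
#' @param locus Locus name (e.g. `"A"`, `"DPB1"`).
#' @param sequence Final consensus DNA string.
#' @param annotation A [transfer_gene_model()] result spanning `sequence`.
#' @param expression A [classify_expression()] result.
#' @param category One of `"novel"`, `"extension"`, `"confirmatory"`.
#' @param companion_typings Named character vector with at least entries
#'   `A`, `B` and `DRB1` (free-form typing strings).
#' @return A `submission_record`.
#' @export
submission_record <- function(sample_id, locus, sequence, annotation,
                              expression, category, companion_typings) {
  stopifnot(category %in% c("novel", "extension", "confirmatory"),
            inherits(annotation, "gene_annotation"),
            inherits(expression, "expression_class"))
  if (!all(c("A", "B", "DRB1") %in% names(companion_typings)))
    stop("companion typings for HLA-A, -B and -DRB1 are required")
  if (max(annotation$model$end) != nchar(sequence))
    stop("annotation does not span the sequence")
  structure(list(sample_id = sample_id, locus = locus,
                 sequence = sequence, annotation = annotation,
                 expression = expression, category = category,
                 companion_typings = companion_typings),
            class = "submission_record")
}

#' @export
print.submission_record <- function(x, ...) {
  cat(sprintf(
    "<submission_record> %s %s: %d bp, %s, expression %s\n",
    x$sample_id, x$locus, nchar(x$sequence), x$category,
    x$expression$class))
  invisible(x)
}

#' Per-locus submission summary table
#'
#' Counts submissions per locus: novel alleles, extended (full-length
#' completion of previously named alleles), their distinct total,
#' confirmatory resubmissions, and the grand total, plus a `Total` row.
#' Row and column sums are internally consistent by construction:
#' `distinct = novel + extended` and `total = distinct + confirmatory`.
#'
#' @param records A list of [submission_record()]s, or a data.frame with
#'   columns `locus` and `category`.
#' @return A data.frame with columns `locus`, `novel`, `extended`,
#'   `distinct`, `confirmatory`, `total`.
#' @export
summarize_submissions <- function(records) {
  tab <- if (is.data.frame(records)) records else
    data.frame(
      locus = vapply(records, `[[`, character(1L), "locus"),
      category = vapply(records, `[[`, character(1L), "category"),
      stringsAsFactors = FALSE)
  loci <- unique(tab$locus)
  rows <- lapply(loci, function(l) {
    sub <- tab[tab$locus == l, , drop = FALSE]
    n <- sum(sub$category == "novel")
    e <- sum(sub$category == "extension")
    cf <- sum(sub$category == "confirmatory")
    data.frame(locus = l, novel = n, extended = e, distinct = n + e,
               confirmatory = cf, total = n + e + cf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    locus = "Total",
    novel = sum(tab$category == "novel"),
    extended = sum(tab$category == "extension"),
    distinct = sum(tab$category %in% c("novel", "extension")),
    confirmatory = sum(tab$category == "confirmatory"),
    total = nrow(tab), stringsAsFactors = FALSE))))
  if (length(rows) == 0L)
    out <- data.frame(locus = "Total", novel = 0L, extended = 0L,
                      distinct = 0L, confirmatory = 0L, total = 0L,
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Share of fully characterised alleles, printed to one decimal
#'
#' `100 * fully_characterised / all_known`, rounded half-up to one
#' decimal and formatted with a percent sign — the convention of the
#' database-effect summaries.
#'
#' @param fully_characterised,all_known Non-negative counts.
#' @return A string like `"10.8%"`.
#' @examples
#' full_characterisation_stats(1697, 15662)  # "10.8%"
#' @export
full_characterisation_stats <- function(fully_characterised, all_known) {
  stopifnot(all_known > 0, fully_characterised >= 0)
  sprintf("%.1f%%",
          round_half_up(100 * fully_characterised / all_known, 1L))
}

#' Combined null and Q allele count with whole-percent share
#'
#' @param n_null,n_q Counts of null (N) and questionable-expression (Q)
#'   alleles.
#' @param n_unique Number of distinct submitted sequences.
#' @return A string like `"45 (5%)"`.
#' @examples
#' null_q_proportions(33, 12, 898)  # "45 (5%)"
#' @export
null_q_proportions <- function(n_null, n_q, n_unique) {
  stopifnot(n_null >= 0, n_q >= 0, n_unique > 0)
  total <- n_null + n_q
  sprintf("%d (%d%%)", total,
          as.integer(round_half_up(100 * total / n_unique, 0L)))
}

#' Population frequency of an allele from registry observations
#'
#' Observations divided by the number of gene copies in the genotyped
#' sample base: `observations / (2 * total_samples)`, two copies per
#' diploid donor. Note that registry reports often print the sample base
#' rounded (e.g. to tenths of a million), so frequencies recomputed from
#' printed tables may differ slightly from the originally published
#' values, which used the unrounded internal totals.
#'
#' @param observations Number of times the allele was observed.
#' @param total_samples Number of genotyped samples (donors).
#' @return The frequency as a plain number.
#' @examples
#' allele_frequency(82, 6e5)  # 6.83e-05
#' @export
allele_frequency <- function(observations, total_samples) {
  stopifnot(observations >= 0, total_samples > 0,
            observations <= 2 * total_samples)
  observations / (2 * total_samples)
}
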