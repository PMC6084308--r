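# EMBL feature-table kinds <-> internal gene-model kinds
EMBL_KIND <- c(UTR5 = "5'UTR", exon = "exon", intron = "intron",
               UTR3 = "3'UTR")

#' Write a submission record as an EMBL-style flat file
#'
#' Emits a minimal EMBL feature-table subset (ID / DE / FT / SQ lines):
#' a `source` feature, a `CDS` with a `join(...)` over the exon ranges,
#' the UTR / exon / intron features in genomic order, a `/translation`
#' qualifier, and the sequence in 60-column lines with a running position.
#' This is the single point where internal 0-based half-open coordinates
#' become the flat file's 1-based inclusive ranges. The output is exactly
#' round-trippable by [read_embl_flatfile()]. Network submission is out of
#' scope — the file is the product.
#'
#' @param record A [submission_record()].
#' @param path Optional output path.
#' @return The flat-file text as a single string (invisibly when `path`
#'   is given).
#' @export
write_embl_flatfile <- function(record, path = NULL) {
  stopifnot(inherits(record, "submission_record"))
  seq <- record$sequence
  L <- nchar(seq)
  model <- record$annotation$model
  id <- sprintf("%s_%s", record$sample_id, record$locus)
  lines <- c(
    sprintf("ID   %s; SV 1; linear; genomic DNA; STD; HUM; %d BP.", id, L),
    "XX",
    sprintf("DE   %s locus allele, category %s, expression %s",
            record$locus, record$category, record$expression$class),
    "XX",
    sprintf("CC   closest reference %s; sample %s; HLA-A %s; HLA-B %s; HLA-DRB1 %s",
            record$annotation$closest, record$sample_id,
            record$companion_typings[["A"]],
            record$companion_typings[["B"]],
            record$companion_typings[["DRB1"]]),
    "XX",
    "FH   Key             Location/Qualifiers",
    "FH")
  ft <- function(key, loc) sprintf("FT   %-15s %s", key, loc)
  ftq <- function(text) paste0("FT                   ", text)
  lines <- c(lines, ft("source", sprintf("1..%d", L)),
             ftq("/organism=\"Homo sapiens\""))
  ex <- model[model$kind == "exon", , drop = FALSE]
  join <- sprintf("join(%s)",
                  paste(sprintf("%d..%d", ex$start + 1L, ex$end),
                        collapse = ","))
  lines <- c(lines, wrap_ft(ft("CDS", join)))
  prot <- sub("\\*$", "", record$annotation$protein)
  lines <- c(lines, wrap_ft(ftq(sprintf("/translation=\"%s\"", prot))))
  for (r in seq_len(nrow(model))) {
    key <- EMBL_KIND[[model$kind[r]]]
    lines <- c(lines, ft(key, sprintf("%d..%d", model$start[r] + 1L,
                                      model$end[r])))
    if (model$kind[r] %in% c("exon", "intron")) {
      num <- if (model$kind[r] == "exon") model$rank[r]
             else sum(model$kind[seq_len(r)] == "intron")
      lines <- c(lines, ftq(sprintf("/number=%d", num)))
    }
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  lines <- c(lines, "XX", sprintf(
    "SQ   Sequence %d BP; %d A; %d C; %d G; %d T; %d other;", L,
    sum(chars == "A"), sum(chars == "C"), sum(chars == "G"),
    sum(chars == "T"), sum(!chars %in% c("A", "C", "G", "T"))))
  for (i in seq_len(ceiling(L / 60))) {
    block <- tolower(substr(seq, (i - 1L) * 60L + 1L, min(L, i * 60L)))
    grouped <- paste(
      substring(block, seq(1L, nchar(block), 10L),
                pmin(nchar(block), seq(10L, nchar(block) + 9L, 10L))),
      collapse = " ")
    body <- sprintf("     %s", grouped)
    lines <- c(lines, sprintf("%s%s%d", body,
                              strrep(" ", max(1L, 70L - nchar(body))),
                              min(L, i * 60L)))
  }
  lines <- c(lines, "//")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(text))
  }
  text
}

# wrap an FT line at 80 columns with FT continuation lines
wrap_ft <- function(line) {
  out <- character(0)
  prefix <- "FT                   "
  while (nchar(line) > 80L) {
    cut <- 80L
    out <- c(out, substr(line, 1L, cut))
    line <- paste0(prefix, substr(line, cut + 1L, nchar(line)))
  }
  c(out, line)
}

#' Read an EMBL-style flat file written by this package
#'
#' The round-trip counterpart of [write_embl_flatfile()]: recovers the
#' record id, sequence length, gene-model features (back in 0-based
#' half-open coordinates), CDS exon ranges, translation and sequence.
#'
#' @param path File path (or a character vector of lines).
#' @return A list with `id`, `length`, `features` (data.frame kind /
#'   start / end), `cds_exons`, `translation`, `sequence`.
#' @export
read_embl_flatfile <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else unlist(strsplit(path, "\n"))
  idl <- grep("^ID   ", lines, value = TRUE)[1L]
  idf <- strsplit(sub("^ID   ", "", idl), ";")[[1L]]
  id <- trimws(idf[1L])
  len <- as.integer(sub(".* (\\d+) BP\\.$", "\\1", idl))
  # stitch FT continuation lines back onto their feature line
  ftl <- grep("^FT   ", lines, value = TRUE)
  items <- list()
  for (l in ftl) {
    key <- trimws(substr(l, 6L, 20L))
    rest <- substr(l, 22L, nchar(l))
    if (nzchar(key)) {
      items[[length(items) + 1L]] <- list(key = key, text = rest)
    } else if (length(items)) {
      it <- items[[length(items)]]
      it$text <- paste0(it$text, rest)
      items[[length(items)]] <- it
    }
  }
  feats <- list(); cds <- NULL; translation <- NA_character_
  kind_back <- setNames(names(EMBL_KIND), unname(EMBL_KIND))
  for (it in items) {
    txt <- it$text
    if (it$key == "CDS") {
      nums <- regmatches(txt, gregexpr("\\d+", txt))[[1L]]
      m <- matrix(as.integer(nums), ncol = 2L, byrow = TRUE)
      cds <- data.frame(start = m[, 1L] - 1L, end = m[, 2L])
      tr <- regmatches(txt, regexpr("/translation=\"[^\"]*\"", txt))
      if (length(tr))
        translation <- sub("/translation=\"(.*)\"", "\\1", tr)
    } else if (it$key %in% names(kind_back)) {
      loc <- regmatches(txt, regexpr("^\\d+\\.\\.\\d+", txt))
      nums <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1L]])
      feats[[length(feats) + 1L]] <- data.frame(
        kind = kind_back[[it$key]], start = nums[1L] - 1L, end = nums[2L],
        stringsAsFactors = FALSE)
    } else if (grepl("^/translation=", txt)) {
      translation <- sub("/translation=\"(.*)\"?", "\\1", txt)
      translation <- gsub("\"", "", translation)
    }
  }
  seq_lines <- lines[grepl("^     [a-z]", lines)]
  sequence <- toupper(paste(gsub("[^acgtn]", "", seq_lines),
                            collapse = ""))
  features <- do.call(rbind, feats)
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  list(id = id, length = len, features = features, cds_exons = cds,
       translation = translation, sequence = sequence)
}
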