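# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: plain-R dynamic programming, textbook
# recursions, breadth-first search, and seqinr-based translation.

# Affine-gap global alignment score by the O(n^3) formulation: every gap
# length is enumerated explicitly instead of using the E/F recurrence.
oracle_affine_score <- function(q, t, match = 2, mismatch = -4,
                                gap_open = -4, gap_extend = -2) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  m <- length(qc); n <- length(tc)
  S <- matrix(-Inf, m + 1, n + 1)
  S[1, 1] <- 0
  for (j in seq_len(n)) S[1, j + 1] <- gap_open + gap_extend * j
  for (i in seq_len(m)) S[i + 1, 1] <- gap_open + gap_extend * i
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      best <- S[i, j] + if (qc[i] == tc[j]) match else mismatch
      for (k in seq_len(i))   # gap in target consuming k query bases
        best <- max(best, S[i - k + 1, j + 1] + gap_open + gap_extend * k)
      for (k in seq_len(j))   # gap in query consuming k target bases
        best <- max(best, S[i + 1, j - k + 1] + gap_open + gap_extend * k)
      S[i + 1, j + 1] <- best
    }
  }
  S[m + 1, n + 1]
}

# Textbook Levenshtein distance (iterative edit-distance recursion)
oracle_levenshtein <- function(a, b) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  prev <- 0:length(bc)
  for (i in seq_along(ac)) {
    cur <- numeric(length(bc) + 1)
    cur[1] <- i
    for (j in seq_along(bc)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (ac[i] != bc[j]))
    }
    prev <- cur
  }
  as.integer(prev[length(bc) + 1])
}

# Connected components of an undirected graph by breadth-first search;
# nodes are 1..n, edges a 2-column matrix. Returns membership vector.
oracle_components <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}

# Independent premature-stop scan: translate with seqinr codon-by-codon
# and report the first stop index (in codons), Inf if none.
oracle_first_stop <- function(cds) {
  n <- 3 * (nchar(cds) %/% 3)
  if (n == 0) return(Inf)
  aa <- seqinr::translate(strsplit(tolower(substr(cds, 1, n)), "")[[1]])
  stops <- which(aa == "*")
  if (length(stops) == 0) Inf else stops[1]
}

# small single-intron toy allele for annotation tests; CDS is built from
# sense codons so the reference protein has no internal stop
make_toy_allele <- function(seed, n_codons = 40, name = "TOY*01:01") {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                             collapse = ""), "TAA")
  cut1 <- 3 * floor(n_codons / 3) + 1   # split CDS off codon boundary
  cut2 <- 3 * floor(2 * n_codons / 3) + 2
  ex <- c(substr(cds, 1, cut1), substr(cds, cut1 + 1, cut2),
          substr(cds, cut2 + 1, nchar(cds)))
  rand_dna <- function(n) paste(sample(bases, n, TRUE), collapse = "")
  utr5 <- rand_dna(30); i1 <- rand_dna(50); i2 <- rand_dna(60)
  utr3 <- rand_dna(40)
  pieces <- c(utr5, ex[1], i1, ex[2], i2, ex[3], utr3)
  kinds <- c("UTR5", "exon", "intron", "exon", "intron", "exon", "UTR3")
  ends <- cumsum(nchar(pieces))
  reference_allele(name, paste(pieces, collapse = ""),
                   gene_model(data.frame(kind = kinds,
                                         start = ends - nchar(pieces),
                                         end = ends)))
}

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a base different from the reference base at 0-based position p
alt_base <- function(sequence, p) {
  ref <- substr(sequence, p + 1, p + 1)
  setdiff(c("A", "C", "G", "T"), ref)[1]
}
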