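test_that("closest reference search honours distance and the name tie-break", {
  refs <- make_reference_set(3, "classI", divergence = 0.005, seed = 81)
  q <- refs[[2]]$sequence
  hit <- find_closest_reference(q, refs)
  expect_equal(hit$allele$name, refs[[2]]$name)
  expect_equal(hit$distance, 0L)
  mut <- q
  substr(mut, 500, 500) <- alt_base(q, 499)
  hit2 <- find_closest_reference(mut, refs)
  expect_equal(hit2$allele$name, refs[[2]]$name)
  expect_equal(hit2$distance, 1L)
  expect_equal(hit2$distance, oracle_levenshtein(mut, q))
  # equidistant duplicates resolve to the smallest name
  twin_a <- reference_allele("Z*01:01", q, refs[[2]]$model)
  twin_b <- reference_allele("B*01:01", q, refs[[2]]$model)
  twins <- reference_set(list(twin_a, twin_b))
  expect_equal(find_closest_reference(mut, twins)$allele$name, "B*01:01")
})

test_that("gene-model transfer is exact for identical sequences", {
  toy <- make_toy_allele(82)
  ann <- transfer_gene_model(toy$sequence, toy)
  expect_identical(as.data.frame(ann$model), as.data.frame(toy$model))
  expect_equal(nrow(ann$differences), 0)
  expect_equal(ann$identity, 1)
  expect_identical(ann$cds, splice_cds(toy$sequence, toy$model))
})

test_that("SNVs leave projected coordinates unchanged", {
  toy <- make_toy_allele(83)
  mut <- toy$sequence
  substr(mut, 100, 100) <- alt_base(mut, 99)
  ann <- transfer_gene_model(mut, toy)
  expect_identical(ann$model$start, toy$model$start)
  expect_identical(ann$model$end, toy$model$end)
})

test_that("an intronic insertion shifts downstream boundaries by its length", {
  toy <- make_toy_allele(84)
  i2 <- toy$model[toy$model$kind == "intron", ][2, ]
  at <- i2$start + 20L   # inside intron 2
  ins_seq <- "GTCATGGTCA"
  novel <- paste0(substr(toy$sequence, 1, at + 1), ins_seq,
                  substr(toy$sequence, at + 2, nchar(toy$sequence)))
  ann <- transfer_gene_model(novel, toy)
  before <- toy$model$start <= at
  expect_identical(ann$model$start[before], toy$model$start[before])
  expect_identical(ann$model$start[!before], toy$model$start[!before] + 10L)
  expect_equal(max(ann$model$end), nchar(novel))
  # the intron grew, the exons did not
  expect_identical(splice_cds(novel, ann$model),
                   splice_cds(toy$sequence, toy$model))
  d <- ann$differences
  expect_equal(nrow(d), 1)
  expect_equal(d$type, "insertion")
  expect_equal(d$feature, "intron")
})

test_that("boundary-adjacent insertions attach to the upstream feature", {
  toy <- make_toy_allele(85)
  ex2 <- toy$model[toy$model$kind == "exon", ][2, ]
  # insert exactly at the exon-2 end boundary: belongs to exon 2
  novel <- paste0(substr(toy$sequence, 1, ex2$end), "ACGTAC",
                  substr(toy$sequence, ex2$end + 1, nchar(toy$sequence)))
  ann <- transfer_gene_model(novel, toy)
  ex2_new <- ann$model[ann$model$kind == "exon", ][2, ]
  expect_equal(ex2_new$end, ex2$end + 6L)
})

test_that("low-identity transfers are refused with a diagnostic", {
  toy <- make_toy_allele(86)
  expect_error(transfer_gene_model(rand_dna(nchar(toy$sequence), 860),
                                   toy),
               "identity")
})

test_that("frameshifting deletion in exon 2 predicts a null allele", {
  toy <- make_toy_allele(87)
  ex2 <- toy$model[toy$model$kind == "exon", ][2, ]
  novel <- paste0(substr(toy$sequence, 1, ex2$start + 10),
                  substr(toy$sequence, ex2$start + 12,
                         nchar(toy$sequence)))
  ann <- transfer_gene_model(novel, toy)
  expect_true(any(ann$differences$codon_effect == "frameshift",
                  na.rm = TRUE))
  cls <- classify_expression(ann)
  expect_equal(cls$class, "N")
  expect_match(cls$evidence, "premature stop")
})

test_that("the unmodified reference classifies as normally expressed", {
  toy <- make_toy_allele(88)
  ann <- transfer_gene_model(toy$sequence, toy)
  expect_equal(classify_expression(ann)$class, "normal")
})

test_that("catalogued variants yield Q status", {
  toy <- make_toy_allele(89)
  i1 <- toy$model[toy$model$kind == "intron", ][1, ]
  p <- i1$start + 5L
  novel <- toy$sequence
  substr(novel, p + 1, p + 1) <- alt_base(novel, p)
  ann <- transfer_gene_model(novel, toy)
  qcat <- data.frame(pos = p, ref = substr(toy$sequence, p + 1, p + 1),
                     novel = substr(novel, p + 1, p + 1),
                     id = "Q-variant-7", stringsAsFactors = FALSE)
  cls <- classify_expression(ann, qcat)
  expect_equal(cls$class, "Q")
  expect_equal(cls$evidence, "Q-variant-7")
  # a premature stop outranks the catalog
  ex2 <- toy$model[toy$model$kind == "exon", ][2, ]
  fs <- paste0(substr(novel, 1, ex2$start + 4),
               substr(novel, ex2$start + 6, nchar(novel)))
  expect_equal(classify_expression(transfer_gene_model(fs, toy),
                                   qcat)$class, "N")
})

test_that("expression classification agrees with an independent codon scan
          on 100 randomized CDS edits", {
  toy <- make_toy_allele(90, n_codons = 60)
  ex <- toy$model[toy$model$kind == "exon", ]
  ref_stop <- oracle_first_stop(splice_cds(toy$sequence, toy$model))
  set.seed(901)
  n_checked <- 0
  while (n_checked < 100) {
    kind <- sample(c("snv", "del", "ins"), 1)
    e <- ex[sample(nrow(ex), 1), ]
    p <- sample(seq(e$start, e$end - 4L), 1)
    novel <- switch(kind,
      snv = { x <- toy$sequence
              substr(x, p + 1, p + 1) <- alt_base(x, p); x },
      del = paste0(substr(toy$sequence, 1, p),
                   substr(toy$sequence, p + 1 + sample(1:3, 1),
                          nchar(toy$sequence))),
      ins = paste0(substr(toy$sequence, 1, p + 1),
                   rand_dna(sample(1:3, 1)),
                   substr(toy$sequence, p + 2, nchar(toy$sequence))))
    ann <- tryCatch(transfer_gene_model(novel, toy),
                    error = function(e) NULL)
    if (is.null(ann)) next
    n_checked <- n_checked + 1
    got <- classify_expression(ann)$class
    want <- if (oracle_first_stop(ann$cds) < ref_stop) "N" else "normal"
    expect_equal(got, want, info = paste(kind, "at", p))
  }
})

test_that("difference enumeration lists each edit once with its feature", {
  toy <- make_toy_allele(91)
  expect_equal(nrow(enumerate_differences(
    transfer_gene_model(toy$sequence, toy))), 0)
  # four intronic/UTR SNVs
  positions <- c(10L,
                 toy$model$start[3] + 5L,   # intron 1
                 toy$model$start[5] + 7L,   # intron 2
                 max(toy$model$end) - 10L)  # UTR3
  novel <- toy$sequence
  for (p in positions) substr(novel, p + 1, p + 1) <- alt_base(novel, p)
  d <- enumerate_differences(transfer_gene_model(novel, toy))
  expect_equal(nrow(d), 4)
  expect_setequal(d$pos, positions)
  expect_equal(d$feature[order(d$pos)],
               c("UTR5", "intron", "intron", "UTR3"))
  expect_true(all(d$type == "snv"))
})

test_that("exonic SNVs carry synonymous / nonsynonymous status", {
  toy <- make_toy_allele(92)
  ex1 <- toy$model[toy$model$kind == "exon", ][1, ]
  # ATG start codon: any change at position 2 of the codon is nonsynonymous
  p <- ex1$start + 1L
  novel <- toy$sequence
  substr(novel, p + 1, p + 1) <- "C"
  d <- enumerate_differences(transfer_gene_model(novel, toy))
  expect_equal(d$codon_effect, "nonsynonymous")
})

test_that("projected feature starts are strictly increasing (property)", {
  set.seed(93)
  for (i in 1:5) {
    toy <- make_toy_allele(930 + i)
    novel <- toy$sequence
    for (k in 1:3) {
      p <- sample(nchar(novel) - 10, 1)
      substr(novel, p, p) <- alt_base(novel, p - 1)
    }
    ann <- transfer_gene_model(novel, toy)
    expect_true(all(diff(ann$model$start) > 0))
    expect_true(all(ann$model$end > ann$model$start))
  }
})
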