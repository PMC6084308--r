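test_that("reference templates have the expected genomic organisation", {
  ci <- make_reference_set(1, "classI", seed = 1)
  cii <- make_reference_set(1, "classII", seed = 1)
  a <- ci[[1]]; b <- cii[[1]]
  expect_equal(sum(a$model$kind == "exon"), 8)
  expect_equal(sum(b$model$kind == "exon"), 6)
  expect_gt(nchar(a$sequence), 3000)
  expect_lt(nchar(a$sequence), 4000)
  ratio <- nchar(b$sequence) / nchar(a$sequence)
  expect_gte(ratio, 2)
  expect_lte(ratio, 3)
  # templates carry the planted poly-A test bed
  expect_true(any(homopolymer_runs(a$sequence)$length >= 9))
  # the spliced CDS encodes an intact protein ending in a stop
  prot <- dualcons:::translate_cds(splice_cds(a$sequence, a$model))
  expect_match(prot, "^M")
  expect_equal(unlist(gregexpr("\\*", prot)), nchar(prot))
})

test_that("reference sets are deterministic and mutually diverged", {
  r1 <- make_reference_set(3, "classI", divergence = 0.01, seed = 5)
  r2 <- make_reference_set(3, "classI", divergence = 0.01, seed = 5)
  expect_identical(
    lapply(r1, `[[`, "sequence"), lapply(r2, `[[`, "sequence"))
  d <- edit_distance(r1[[1]]$sequence, r1[[2]]$sequence)
  expect_gt(d, 0)
  expect_error(make_reference_set(2, "classI", divergence = 1.2, seed = 1),
               "divergence")
  # reference alleles never carry premature stops
  for (a in r1) {
    prot <- dualcons:::translate_cds(splice_cds(a$sequence, a$model))
    expect_equal(unlist(gregexpr("\\*", prot)), nchar(prot))
  }
})

test_that("diploid samples record their edits and het positions", {
  refs <- make_reference_set(2, "classI", seed = 9)
  hom <- make_diploid_sample(refs)
  expect_identical(hom$allele1, hom$allele2)
  expect_length(hom$het_positions, 0)

  spec <- variant_spec(snv(100, alt_base(refs[[1]]$sequence, 100)),
                       snv(600, alt_base(refs[[1]]$sequence, 600)),
                       snv(1500, alt_base(refs[[1]]$sequence, 1500)),
                       snv(2900, alt_base(refs[[1]]$sequence, 2900)))
  het <- make_diploid_sample(refs, spec1 = spec)
  expect_equal(edit_distance(het$allele1, refs[[1]]$sequence), 4L)
  expect_equal(oracle_levenshtein(het$allele1, refs[[1]]$sequence), 4L)
  expect_setequal(het$het_positions, c(100, 600, 1500, 2900))
})

test_that("homopolymer contraction shortens the run by one base", {
  refs <- make_reference_set(1, "classI", seed = 9)
  run <- homopolymer_runs(refs[[1]]$sequence)
  run <- run[run$length >= 9, ][1, ]
  het <- make_diploid_sample(
    refs, spec2 = variant_spec(homopolymer_delta(run$start + 2L, -1L)))
  expect_equal(nchar(het$allele2), nchar(het$allele1) - 1L)
  r2 <- homopolymer_runs(het$allele2)
  hit <- r2[r2$start == run$start & r2$base == run$base, ]
  expect_equal(hit$length, run$length - 1L)
  expect_length(het$het_positions, 1)
})

test_that("overlapping or out-of-range edits are rejected", {
  refs <- make_reference_set(1, "classI", seed = 2)
  expect_error(make_diploid_sample(refs, variant_spec(snv(10^6, "A"))),
               "range")
  expect_error(
    make_diploid_sample(refs, variant_spec(deletion(100, 5),
                                           snv(102, "A"))),
    "overlap")
})

test_that("noiseless long reads reproduce their source alleles", {
  refs <- make_reference_set(1, "classI", seed = 3)
  truth <- make_diploid_sample(refs)
  rs <- simulate_long_reads(truth, 5, error_profile(0, 0, 0), seed = 1)
  expect_true(all(rs$reads == truth$allele1))
  expect_error(simulate_long_reads(truth, 0, seed = 1), "positive")
})

test_that("long-read error preset introduces 13% events per base", {
  # 1/6/6 rates without the homopolymer multiplier: the introduced-event
  # rate is binomial around 0.13; the alignment-visible rate is slightly
  # lower (adjacent indels partially cancel) but stays above the
  # documented >10% per-read error of the platform
  set.seed(11)
  g <- rand_dna(400)
  truth <- structure(list(allele1 = g, allele2 = g, source1 = "x",
                          source2 = "x", het_positions = integer(0)),
                     class = "diploid_truth")
  rs <- simulate_long_reads(truth, 1000,
                            error_profile(0.01, 0.06, 0.06), seed = 42)
  event_rate <- mean(rs$truth$n_errors / rs$truth$source_length)
  expect_lt(abs(event_rate - 0.13), 0.01)
  aln_rate <- mean(vapply(rs$reads, function(r)
    edit_distance(r, g) / 400, numeric(1)))
  expect_gt(aln_rate, 0.10)
  expect_lte(aln_rate, event_rate)
  # the default preset exceeds the >10% platform bound by construction
  p <- long_error_profile()
  expect_gt(p$substitution + p$insertion + p$deletion, 0.10)
})

test_that("long-read sampling is deterministic under the seed", {
  refs <- make_reference_set(1, "classI", seed = 3)
  truth <- make_diploid_sample(refs)
  a <- simulate_long_reads(truth, 100, seed = 8)
  b <- simulate_long_reads(truth, 100, seed = 8)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  expect_identical(table(a$truth$hap), table(b$truth$hap))
})

test_that("short-read pair count follows the coverage contract", {
  refs <- make_reference_set(1, "classI", seed = 3)
  truth <- make_diploid_sample(refs)
  L <- nchar(truth$allele1)
  rs <- simulate_short_reads(truth, 100, seed = 4)
  expect_equal(nrow(rs$truth), round(100 * L / (2 * 251)))
})

test_that("error-free short reads are exact substrings of an allele", {
  refs <- make_reference_set(1, "classI", seed = 3)
  spec <- variant_spec(snv(1000, alt_base(refs[[1]]$sequence, 1000)))
  truth <- make_diploid_sample(refs, spec1 = spec)
  p <- short_error_profile(); p$substitution <- 0
  rs <- simulate_short_reads(truth, 10, p, seed = 4)
  ok <- vapply(seq_len(nrow(rs$truth)), function(i) {
    r1 <- rs$read1[[i]]; r2 <- dualcons:::revcomp(rs$read2[[i]])
    (grepl(r1, truth$allele1, fixed = TRUE) ||
       grepl(r1, truth$allele2, fixed = TRUE)) &&
      (grepl(r2, truth$allele1, fixed = TRUE) ||
         grepl(r2, truth$allele2, fixed = TRUE))
  }, logical(1))
  expect_true(all(ok))
})

test_that("fragment spans never exceed the 1000 bp preset cap", {
  refs <- make_reference_set(1, "classI", seed = 3)
  truth <- make_diploid_sample(refs)
  rs <- simulate_short_reads(truth, 50, seed = 12)
  expect_lte(max(rs$truth$frag_len), 1000)
  expect_gte(min(rs$truth$frag_len), 251)
})

test_that("truth labels stay in the sidecar, never in the FASTQ", {
  refs <- make_reference_set(1, "classI", seed = 3)
  truth <- make_diploid_sample(refs)
  prefix <- file.path(withr::local_tempdir(), "sim")
  lr <- simulate_long_reads(truth, 10, seed = 2)
  write_read_set(lr, prefix)
  fq <- readLines(paste0(prefix, ".fastq"))
  expect_false(any(grepl("allele", fq)))
  side <- utils::read.table(paste0(prefix, "_truth.tsv"), header = TRUE,
                            sep = "\t")
  expect_setequal(side$hap, c("allele1", "allele2"))
  expect_equal(nrow(side), 10)
})
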