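# independent truth-table oracle for the per-position classifier, written
# against the category definitions (not the implementation's control flow)
oracle_classify <- function(ref, sbs, smrt, hp_indel) {
  sbs <- sort(unique(sbs)); smrt <- sort(unique(smrt))
  dev_s <- !identical(sbs, ref)
  dev_m <- !identical(smrt, ref)
  if (!dev_s && !dev_m) return(NA_character_)
  if (identical(sbs, smrt)) return("concordant_deviation")
  if (hp_indel) return("homopolymer_indel")
  if (dev_m && !dev_s) return("SMRT_only_deviation")
  "SBS_only_deviation"
}

test_that("per-position conflict classification matches the case oracle", {
  ref <- "A"
  call_sets <- list("A", "C", "-", c("A", "C"), c("A", "-"), c("C", "G"))
  for (sbs in call_sets) for (smrt in call_sets) for (hp in c(FALSE, TRUE))
    expect_identical(dualcons:::classify_calls(ref, sbs, smrt, hp),
                     oracle_classify(ref, sbs, smrt, hp),
                     info = paste(paste(sbs, collapse = "/"),
                                  paste(smrt, collapse = "/"), hp))
})

# helpers to build toy tracks without sequencing
toy_track <- function(backbone, het = list(), status = NULL) {
  L <- nchar(backbone)
  chars <- strsplit(backbone, "")[[1]]
  track <- structure(list(
    sequence = backbone, call1 = chars,
    call2 = rep(NA_character_, L), status = rep("hom", L),
    het_positions = integer(0), het_alleles = list(),
    coverage = rep(100, L), phase_blocks = NULL,
    phasing_defined = TRUE), class = "consensus_track")
  for (h in het) {   # h: list(pos (0-based), alleles)
    track$status[h$pos + 1] <- "het"
    track$call1[h$pos + 1] <- h$alleles[1]
    track$call2[h$pos + 1] <- h$alleles[2]
    track$het_positions <- c(track$het_positions, h$pos)
  }
  track
}

toy_smrt <- function(seq, flags = NULL) {
  structure(list(sequence = seq, hp_flags = flags, n_reads = 10),
            class = "allele_consensus")
}

test_that("identical inputs produce an empty conflict list", {
  ref <- rand_dna(80, seed = 700)
  conflicts <- compare_tracks(toy_track(ref),
                              list(toy_smrt(ref), toy_smrt(ref)), ref)
  expect_equal(nrow(conflicts), 0)
})

test_that("poly-A deletion seen only by SMRT is a homopolymer indel", {
  set.seed(701)
  ref <- paste0(rand_dna(30), strrep("A", 9), rand_dna(30))
  smrt_del <- paste0(substr(ref, 1, 30), strrep("A", 8),
                     substr(ref, 40, 69))
  conflicts <- compare_tracks(toy_track(ref),
                              list(toy_smrt(ref), toy_smrt(smrt_del)),
                              ref)
  expect_equal(nrow(conflicts), 1)
  expect_equal(conflicts$category, "homopolymer_indel")
  expect_true(conflicts$position >= 30 && conflicts$position < 39)
})

test_that("an SNV seen only by one platform classifies by platform", {
  ref <- rand_dna(60, seed = 702)
  mut <- ref
  substr(mut, 20, 20) <- alt_base(ref, 19)
  smrt_only <- compare_tracks(toy_track(ref),
                              list(toy_smrt(mut), toy_smrt(ref)), ref)
  expect_equal(smrt_only$category, "SMRT_only_deviation")
  sbs_only <- compare_tracks(
    toy_track(ref, het = list(list(pos = 19L,
                                   alleles = c(substr(ref, 20, 20),
                                               substr(mut, 20, 20))))),
    list(toy_smrt(ref), toy_smrt(ref)), ref)
  expect_equal(sbs_only$category, "SBS_only_deviation")
  both <- compare_tracks(
    toy_track(mut), list(toy_smrt(mut), toy_smrt(mut)), ref)
  expect_equal(both$category, "concordant_deviation")
})

test_that("rule decisions match the brute-force enumeration of category subsets", {
  cats <- dualcons:::CONFLICT_CATEGORIES
  oracle_decide <- function(present, phased) {
    # the three published rules plus the no-conflict submission state
    if ("SBS_only_deviation" %in% present) return("REPEAT_ANALYSIS")
    if (!phased && any(c("homopolymer_indel", "phase_gap") %in% present))
      return("RUN_DR2S")
    if (any(c("SMRT_only_deviation", "homopolymer_indel") %in% present))
      return("SUBMIT_SBS")
    "SUBMIT_CONCORDANT"
  }
  for (mask in 0:(2^length(cats) - 1)) {
    present <- cats[bitwAnd(mask, 2^(seq_along(cats) - 1)) > 0]
    conflicts <- data.frame(position = seq_along(present),
                            category = present,
                            stringsAsFactors = FALSE)
    for (phased in c(TRUE, FALSE)) {
      expect_identical(decide(conflicts, phased)$action,
                       oracle_decide(present, phased),
                       info = paste(paste(present, collapse = "+"),
                                    "phased:", phased))
    }
  }
})

test_that("decisions carry per-conflict rule citations", {
  conflicts <- data.frame(
    position = c(5L, 10L, NA),
    category = c("SMRT_only_deviation", "concordant_deviation",
                 "phase_gap"),
    stringsAsFactors = FALSE)
  d <- decide(conflicts, sbs_phasing_defined = FALSE)
  expect_equal(d$action, "RUN_DR2S")
  expect_equal(d$justification$rule,
               c("rule1", "concordant", "rule3"))
  d2 <- decide(conflicts[1, ], sbs_phasing_defined = TRUE)
  expect_equal(d2$action, "SUBMIT_SBS")
})

test_that("the position audit conserves length and matches the worked example", {
  expect_equal(audit_positions(3404, 4),
               c(masking = 4L, artifact = 3400L))
  expect_equal(audit_positions(100, 0), c(masking = 0L, artifact = 100L))
  expect_equal(audit_positions(100, 100), c(masking = 100L, artifact = 0L))
  expect_error(audit_positions(10, 11), "<=")
  set.seed(703)
  for (i in 1:20) {
    L <- sample(1:5000, 1); d <- sample(0:L, 1)
    expect_equal(sum(audit_positions(L, d)), L)
  }
})

# --- polishing ---

polish_fixture <- local({
  refs <- make_reference_set(1, "classI", seed = 71)
  ref <- refs[[1]]
  run <- homopolymer_runs(ref$sequence)
  run <- run[run$length >= 9, ][1, ]
  spec1 <- variant_spec(snv(400, alt_base(ref$sequence, 400)),
                        snv(1900, alt_base(ref$sequence, 1900)))
  spec2 <- variant_spec(homopolymer_delta(run$start + 1L, -1L))
  truth <- make_diploid_sample(refs, spec1, spec2)
  list(refs = refs, ref = ref, truth = truth, run = run)
})

test_that("fully concordant short reads leave the haplotypes untouched", {
  fx <- polish_fixture
  p <- short_error_profile(); p$substitution <- 0
  sr <- simulate_short_reads(fx$truth, 60, p, seed = 72)
  pair <- list(structure(list(sequence = fx$truth$allele1,
                              hp_flags = NULL), class = "allele_consensus"),
               structure(list(sequence = fx$truth$allele2,
                              hp_flags = NULL), class = "allele_consensus"))
  pol <- polish_consensus(pair, sr)
  expect_identical(pol$haplotypes[1], fx$truth$allele1)
  expect_identical(pol$haplotypes[2], fx$truth$allele2)
  expect_equal(nrow(pol$changes[[1]]), 0)
  expect_equal(nrow(pol$changes[[2]]), 0)
})

test_that("ambiguous poly-A lengths are resolved to 9 and 8 by short reads", {
  fx <- polish_fixture
  sr <- simulate_short_reads(fx$truth, 100, seed = 73)
  run <- fx$run
  # both preliminary haplotypes carry the flagged run, one of them with
  # the wrong length (8 where the allele truly has 9)
  wrong1 <- paste0(substr(fx$truth$allele1, 1, run$start),
                   strrep(run$base, run$length - 1),
                   substr(fx$truth$allele1, run$end + 1,
                          nchar(fx$truth$allele1)))
  flags1 <- data.frame(base = run$base, start = run$start, end = run$end,
                       length = run$length, called_len = run$length - 1,
                       support = 0.45, ambiguous = TRUE,
                       out_start = run$start,
                       out_end = run$start + run$length - 1)
  flags2 <- data.frame(base = run$base, start = run$start, end = run$end,
                       length = run$length, called_len = run$length - 1,
                       support = 0.5, ambiguous = TRUE,
                       out_start = run$start,
                       out_end = run$start + run$length - 1)
  pair <- list(structure(list(sequence = wrong1, hp_flags = flags1),
                         class = "allele_consensus"),
               structure(list(sequence = fx$truth$allele2,
                              hp_flags = flags2),
                         class = "allele_consensus"))
  pol <- polish_consensus(pair, sr)
  run_len <- function(seq) {
    r <- homopolymer_runs(seq)
    r$length[r$start >= run$start - 2 & r$start <= run$start + 2 &
               r$base == run$base][1]
  }
  expect_equal(run_len(pol$haplotypes[1]), run$length)      # 9 restored
  expect_equal(run_len(pol$haplotypes[2]), run$length - 1)  # 8 kept
  expect_identical(pol$haplotypes[1], fx$truth$allele1)
  expect_identical(pol$haplotypes[2], fx$truth$allele2)
})

test_that("unflagged concordant positions are never edited (no regression)", {
  fx <- polish_fixture
  sr <- simulate_short_reads(fx$truth, 80, seed = 74)
  # haplotype 1 with one planted consensus error away from any flag
  bad <- fx$truth$allele1
  substr(bad, 1200, 1200) <- alt_base(bad, 1199)
  pair <- list(structure(list(sequence = bad, hp_flags = NULL),
                         class = "allele_consensus"),
               structure(list(sequence = fx$truth$allele2,
                              hp_flags = NULL),
                         class = "allele_consensus"))
  pol <- polish_consensus(pair, sr)
  # the planted error is corrected, nothing else moves
  expect_identical(pol$haplotypes[1], fx$truth$allele1)
  expect_identical(pol$haplotypes[2], fx$truth$allele2)
  ch <- pol$changes[[1]]
  expect_equal(ch$pos, 1199)
})
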