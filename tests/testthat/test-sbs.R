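# shared small fixture: class I reference with a 4-SNV + poly-A het sample
sbs_fixture <- local({
  refs <- make_reference_set(1, "classI", seed = 21)
  ref <- refs[[1]]
  spec1 <- variant_spec(snv(340, alt_base(ref$sequence, 340)),
                        snv(850, alt_base(ref$sequence, 850)),
                        snv(1880, alt_base(ref$sequence, 1880)),
                        snv(3000, alt_base(ref$sequence, 3000)))
  run <- homopolymer_runs(ref$sequence)
  run <- run[run$length >= 9, ][1, ]
  spec2 <- variant_spec(homopolymer_delta(run$start + 1L, -1L))
  truth <- make_diploid_sample(refs, spec1, spec2)
  list(refs = refs, ref = ref, truth = truth, polyA = run)
})

test_that("error-free pileup has no mismatch counts off the het positions", {
  fx <- sbs_fixture
  p <- short_error_profile(); p$substitution <- 0
  rs <- simulate_short_reads(fx$truth, 30, p, seed = 31)
  pu <- build_pileup(rs, fx$ref$sequence)
  ref_chars <- strsplit(fx$ref$sequence, "")[[1]]
  L <- length(ref_chars)
  mism <- vapply(seq_len(L), function(pos) {
    pu$coverage[pos] - pu$counts[ref_chars[pos], pos]
  }, numeric(1))
  off_het <- setdiff(which(mism > 0) - 1L, fx$truth$het_positions)
  # allele-2 reads may place their poly-A gap at a neighbouring run
  # column; everything else must be clean
  run_cols <- seq(fx$polyA$start, fx$polyA$end - 1L)
  expect_length(setdiff(off_het, run_cols), 0)
})

test_that("interior coverage is near the target (Lander-Waterman)", {
  fx <- sbs_fixture
  rs <- simulate_short_reads(fx$truth, 100, seed = 32)
  pu <- build_pileup(rs, fx$ref$sequence)
  interior <- 1000:2400
  # Lander-Waterman-style expectation for this placement model: a pair
  # contributes 2 x 251 read bases, and fragment starts must fit inside
  # the amplicon, so the interior rate is n * 502 / (L - E[flen] + 1)
  # (interior positions are enriched relative to the nominal target
  # because the amplicon edges are reachable by fewer fragments)
  n <- nrow(rs$truth)
  L <- nchar(fx$ref$sequence)
  lambda <- n * 502 / (L - mean(rs$truth$frag_len) + 1)
  expect_lt(abs(mean(pu$coverage[interior]) - lambda) / lambda, 0.05)
  # Poisson fluctuation: ~99% of positions within +/-30% of the rate
  expect_gte(mean(abs(pu$coverage[interior] - lambda) / lambda <= 0.30),
             0.99)
})

test_that("empty read set yields an all-zero pileup", {
  fx <- sbs_fixture
  pu <- build_pileup(character(0), fx$ref$sequence)
  expect_true(all(pu$counts == 0))
  expect_true(all(pu$coverage == 0))
  expect_length(pu$placements, 0)
})

test_that("consensus separates hom, het and low-coverage positions", {
  fx <- sbs_fixture
  rs <- simulate_short_reads(fx$truth, 100, seed = 33)
  pu <- build_pileup(rs, fx$ref$sequence)
  track <- call_consensus(pu)
  # the four SNVs plus the poly-A deletion column are het
  for (p in c(340, 850, 1880, 3000)) {
    expect_equal(track$status[p + 1], "het", info = paste("pos", p))
    expect_setequal(
      c(track$call1[p + 1], track$call2[p + 1]),
      c(substr(fx$ref$sequence, p + 1, p + 1),
        substr(fx$truth$allele1, p + 1, p + 1)))
  }
  hp_cols <- (fx$polyA$start + 1):fx$polyA$end
  het_cols <- hp_cols[track$status[hp_cols] == "het"]
  expect_gte(length(het_cols), 1)
  expect_true(any(c(track$call1[het_cols], track$call2[het_cols]) == "-",
                  na.rm = TRUE))
  # hom positions reproduce the reference exactly
  hom <- track$status == "hom"
  ref_chars <- strsplit(fx$ref$sequence, "")[[1]]
  expect_true(all(track$call1[hom] == ref_chars[hom]))
  expect_error(call_consensus(pu, het_band = c(0.8, 0.2)), "ascending")
})

test_that("a 50/50 site is flagged het at the default band", {
  # direct binomial check of the band: 100x coverage, half the reads carry
  # C and half T at one site of an otherwise identical 30-mer
  backbone <- rand_dna(30, seed = 55)
  allele_c <- backbone
  substr(allele_c, 15, 15) <- "C"
  allele_t <- backbone
  substr(allele_t, 15, 15) <- "T"
  reads <- c(rep(allele_c, 50), rep(allele_t, 50))
  names(reads) <- sprintf("r%03d", seq_along(reads))
  pu <- build_pileup(reads, backbone)
  track <- call_consensus(pu)
  expect_equal(which(track$status == "het"), 15)
  expect_setequal(c(track$call1[15], track$call2[15]), c("C", "T"))
  # binomial: P(minor fraction < 0.25 at 100x, p = 0.5) < 1e-3, so the
  # band flags a balanced het with probability > 0.999
  expect_lt(pbinom(24, 100, 0.5), 1e-3)
})

test_that("low-coverage positions are flagged, not called", {
  reads <- setNames(rep(strrep("A", 20), 3), c("a", "b", "c"))
  pu <- build_pileup(reads, strrep("A", 20))
  track <- call_consensus(pu, min_coverage = 10)
  expect_true(all(track$status == "low_coverage"))
})

test_that("noiseless homozygous input reproduces the allele exactly", {
  fx <- sbs_fixture
  hom <- make_diploid_sample(fx$refs)
  p <- short_error_profile(); p$substitution <- 0
  rs <- simulate_short_reads(hom, 60, p, seed = 35)
  pu <- build_pileup(rs, fx$ref$sequence)
  track <- call_consensus(pu)
  called <- track$status != "low_coverage"
  ref_chars <- strsplit(fx$ref$sequence, "")[[1]]
  expect_true(all(track$call1[called] == ref_chars[called]))
  expect_equal(sum(track$status == "het"), 0)
})

test_that("hets separated by more than the fragment cap split into blocks", {
  fx <- sbs_fixture
  rs <- simulate_short_reads(fx$truth, 100, seed = 36)
  pu <- build_pileup(rs, fx$ref$sequence)
  track <- phase_hets(call_consensus(pu), pu)
  # gaps 850 -> 1880 and 1880 -> 3000 both exceed 1000 bp
  expect_gte(length(track$phase_blocks), 3)
  expect_false(track$phasing_defined)
  b <- track$phase_blocks
  expect_true(all(c(340, 850) %in% b[[1]]))
  expect_true(1880 %in% b[[2]][1])
})

test_that("hets within one fragment span form a single block", {
  refs <- sbs_fixture$refs
  ref <- refs[[1]]
  spec <- variant_spec(snv(1000, alt_base(ref$sequence, 1000)),
                       snv(1300, alt_base(ref$sequence, 1300)))
  truth <- make_diploid_sample(refs, spec1 = spec)
  rs <- simulate_short_reads(truth, 100, seed = 37)
  pu <- build_pileup(rs, ref$sequence)
  track <- phase_hets(call_consensus(pu), pu)
  expect_length(track$phase_blocks, 1)
  expect_true(track$phasing_defined)
})

test_that("phase blocks equal the components of the co-coverage graph", {
  fx <- sbs_fixture
  set.seed(38)
  for (rep in 1:5) {
    npos <- sample(3:6, 1)
    hets <- sort(sample(seq(100, 3300, by = 50), npos))
    spec <- do.call(variant_spec, lapply(hets, function(p)
      snv(p, alt_base(fx$ref$sequence, p))))
    truth <- make_diploid_sample(fx$refs, spec1 = spec)
    rs <- simulate_short_reads(truth, 60, seed = 380 + rep)
    pu <- build_pileup(rs, fx$ref$sequence)
    track <- phase_hets(call_consensus(pu), pu)
    hp <- track$het_positions
    # brute-force oracle over the fragment co-coverage graph
    frags <- split(pu$placements,
                   vapply(pu$placements, `[[`, character(1), "pair"))
    edges <- matrix(integer(0), ncol = 2)
    for (pl in frags) {
      cov <- which(vapply(seq_along(hp), function(k) {
        any(vapply(pl, function(p)
          !is.na(dualcons:::placement_call(p, hp[k] + 1L)), logical(1)))
      }, logical(1)))
      if (length(cov) >= 2)
        edges <- rbind(edges, t(combn(cov, 2)))
    }
    comp <- oracle_components(length(hp), edges)
    got <- integer(length(hp))
    for (b in seq_along(track$phase_blocks))
      got[match(track$phase_blocks[[b]], hp)] <- b
    # same partition (membership up to relabelling)
    expect_equal(length(unique(comp)), length(track$phase_blocks))
    for (cid in unique(comp)) {
      members <- hp[comp == cid]
      expect_length(unique(got[match(members, hp)]), 1)
    }
  }
})

test_that("block structure is invariant under read order permutation", {
  fx <- sbs_fixture
  rs <- simulate_short_reads(fx$truth, 60, seed = 39)
  pu <- build_pileup(rs, fx$ref$sequence)
  track1 <- phase_hets(call_consensus(pu), pu)
  pu2 <- pu
  pu2$placements <- rev(pu$placements)
  track2 <- phase_hets(call_consensus(pu2), pu2)
  expect_identical(track1$phase_blocks, track2$phase_blocks)
})
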