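---
title: "Dual redundant consensus calling for full-length HLA alleles"
author: "dualcons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual redundant consensus calling for full-length HLA alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualcons)
```

## The problem

Registry-scale HLA typing regularly turns up alleles whose full genomic
sequence — 5'UTR through 3'UTR including all introns — is unknown.
Characterising such an allele to reference quality from a single
sequencing technology is unreliable, for two complementary reasons:

* **Short accurate reads cannot phase distant heterozygous positions.**
  Shotgun libraries on current short-read instruments are built from
  fragments of at most roughly 1000 bp. Two heterozygous positions
  separated by more than a fragment length are never observed on the same
  molecule, so the assembly splits into phase blocks and the two allele
  sequences of a heterozygous sample cannot be reconstructed.
* **Long single-molecule reads cannot call homopolymers.** Multi-kilobase
  reads span the whole gene and phase trivially, but carry per-read error
  above 10%, dominated by insertions and deletions that concentrate in
  homopolymer stretches. The length of a poly-A run can remain genuinely
  inconclusive in a long-read consensus.

The dual redundant strategy sequences every sample with both
technologies, compares the two consensus sequences against the closest
reference allele, and resolves disagreements with a small rule engine:

1. a long-read-only deviation is a sequencing error; the short-read
   consensus is submitted (`SUBMIT_SBS`);
2. a short-read-only deviation is suspicious in the accurate technology;
   the analysis is repeated (`REPEAT_ANALYSIS`);
3. if the whole-gene short-read sequence is not phase-defined and the
   long-read data suffers from indel errors, the cluster-and-polish
   procedure is applied (`RUN_DR2S`): long reads are clustered per
   allele, per-allele preliminary consensus sequences are built, and
   short reads correct their residual errors.

A deviation seen identically by both technologies is a real variant
(`SUBMIT_CONCORDANT` when nothing else fires). When rule categories
co-occur the engine applies a fixed precedence, repeat over polish over
submit, on the argument that the repeat state is the safest; the order is
a `pipeline_config()` field.

One cell of the comparison table is not covered by the three rules: both
platforms deviating from the reference *and* from each other. Outside
homopolymers this package classifies it as a short-read deviation so the
safest rule (repeat) wins. Inside a homopolymer run, any indel-type
disagreement — whichever platform shows it — is classified
`homopolymer_indel`: the poly-A situation the strategy exists for is
precisely one where the short reads see a deletion on one allele while
the long reads are inconclusive, and routing it to the repeat rule would
be wrong.

The asymmetry motivating the double check is quantified by
`audit_positions()`: a 3404 bp consensus with 4 true differences from its
closest reference has only 4 positions where an error could mask a real
difference, but 3400 where an error would fabricate one.

## What the simulator emulates

`make_reference_set()` builds deterministic locus templates: class I,
3404 bp with 8 exons; class II, 8500 bp with 6 exons (about 2.5 times
longer, matching the genomic organisation of the HLA loci). The coding
sequence is drawn from sense codons (ATG ... TAA, no internal stop), so
every reference allele encodes an intact protein; divergence
substitutions between alleles are resampled if they would create a
premature stop. A nine-base poly-A stretch is planted in intron 2 of
every template as the homopolymer test bed.

`make_diploid_sample()` applies variant specs (SNVs, indels, homopolymer
length changes) to two source alleles and records the ground truth. The
read simulators then emulate the two platforms:

* `simulate_long_reads()` — full-length amplicon reads, 50/50 per allele,
  i.i.d. per-base errors at the `long_error_profile()` preset: 1%
  substitution, 6% insertion, 6% deletion (13% total, above the >10%
  per-read error documented for the platform), indel rates doubled inside
  homopolymer runs of four or more bases, and in-run insertions repeating
  the run base so the errors manifest as stretch-length noise. Note that
  the *alignment-visible* error rate of such reads is slightly below the
  13% event rate because adjacent insertion and deletion events partially
  cancel under optimal alignment; the hidden truth table therefore
  records the number of introduced events per read.
* `simulate_short_reads()` — `round(coverage * L / (2 * 251))` read pairs
  from fragments of 400-1000 bp placed uniformly inside the amplicon,
  251 bp mates, substitution-only errors at 0.2%
  (`short_error_profile()`). The 1000 bp fragment cap is the parameter
  that breaks phasing. Because fragment starts must fit inside the
  amplicon, interior coverage is enriched relative to the nominal target
  by roughly `L / (L - mean fragment length)` while the terminal ~250 bp
  ramp down — as in real amplicon shotgun data.

Hidden truth labels (read-to-haplotype, introduced error counts) live in
a sidecar table and are never written into the FASTQ records.

What the simulator does **not** emulate: PCR chimeras, barcode hopping,
quality-score/error correlation, strand bias, and context-dependent
error signatures beyond the homopolymer multiplier. Passing the seeded
batteries therefore demonstrates the pipeline's logic under an idealised
random-error model, not performance on any particular instrument's
systematic artifacts.

## Calling, clustering, polishing

**Alignment.** All placements use an affine-gap Gotoh aligner (Rcpp) with
a fixed traceback tie-break — diagonal over deletion over insertion, gap
opening over extension, leftmost end on ties — so every downstream call
is reproducible. Long reads are aligned end-to-end inside a diagonal
band; short reads use a fitting alignment with an exact ungapped fast
path that falls back to the full matrix whenever the best ungapped
placement has more than 3 mismatches (indel-spanning reads always fall
back). Reads with several equally scoring placements are dropped from
pileups rather than double-counted.

**Short-read track.** `call_consensus()` calls the majority base per
position; a position is heterozygous when the second call reaches the
het band (defaults `[0.25, 0.75]` of coverage) and flagged rather than
called below `min_coverage = 10`. `phase_hets()` connects het positions
that share a sequenced fragment and reports the connected components as
phase blocks; more than one block means whole-gene phasing is undefined.

**Long-read stage.** `call_informative_positions()` keeps positions whose
second-most-frequent base falls in `[0.30, 0.70]` of coverage, excluding
candidates inside homopolymer runs (their indel noise is handled by
run-length calling instead). `cluster_long_reads()` reduces each read to
its base signature at those positions and assigns it to one of two
centroids initialised by frequency-and-co-occurrence chaining; a read is
assigned only when it favours one centroid by a net margin of at least
two sites (one when only one informative position exists), because a
single site call is occasionally corrupted by an adjacent indel.
Unassigned reads (typically 5-20%) simply do not contribute to the
preliminary consensus. `build_allele_consensus()` takes the per-column
majority over the cluster and re-calls every homopolymer run as the mode
of the per-read observed run lengths (matching bases plus same-base
insertions inside the run); a mode supported by fewer than 60% of
spanning reads — or tied — is flagged *ambiguous*, the long-read stage's
declaration that it must not decide this locus alone. Under the default
13% indel-heavy profile most runs of four or more bases are flagged,
which is the intended behaviour, not an alarm condition.

**Polishing.** `polish_consensus()` maps all short reads against each
preliminary haplotype and corrects it in three coordinated steps:

* *unimodal columns* (full-read-set majority at or above
  `min_fraction = 0.7`): the haplotypes agree with each other there, so
  every read is valid evidence and the majority overrules the
  preliminary call — this repairs long-read consensus errors in
  haplotype-shared sequence;
* *bimodal columns* (a true difference between the alleles): only the
  read pairs assigned to this haplotype by alignment score vote;
* *flagged homopolymer runs* are re-called jointly across the pair from
  the short-read run-length histogram: a unimodal histogram sets both
  haplotypes, a bimodal one hands one mode to each haplotype, oriented
  by assigned-read votes when available and otherwise by the preliminary
  called lengths. The joint step is essential — when both preliminary
  haplotypes carry the same wrong run length, reads tie at that locus
  and per-haplotype evidence alone could never recover a heterozygous
  run.

An earlier design assigned every read pair to exactly one haplotype and
dropped ties. That starves haplotype-shared regions — most of the gene —
of polishing coverage, and a preliminary consensus error actively repels
its own reads (they score better on the other haplotype), so the error
could never be corrected. The unimodal/bimodal split above is the fix;
ties contribute to shared evidence only, so no allele-discriminating
decision ever double-counts a read.

## Annotation and reporting

`find_closest_reference()` minimises unit-cost edit distance with a
lexicographic name tie-break. `transfer_gene_model()` projects each
feature boundary of the closest reference through the global alignment;
insertions inside a feature extend it and boundary-adjacent insertions
attach to the upstream feature; alignments under 90% identity are
refused, since projecting a gene model across that much divergence would
be meaningless. `classify_expression()` scans the spliced CDS 5' to 3':
a stop codon before the reference stop (direct or via frameshift)
predicts a null (N) allele; otherwise differences are matched against a
user-supplied catalog of variants known to affect expression (Q); the
catalog is configuration because Q status is defined by precedent, not
by an algorithm. `write_embl_flatfile()` is the single point where
0-based half-open coordinates become the flat file's 1-based inclusive
ranges; the minimal EMBL feature-table subset (ID/FT/SQ, CDS as
`join(...)`, 60-column sequence block) was chosen over the full
submission XML because it is bit-exact and round-trippable by the
package's own reader. Printed percentages use half-up rounding: one
decimal for database-share tables, whole percents for null/Q
proportions. `allele_frequency()` divides observations by `2 *
total_samples` (two gene copies per diploid donor); published frequency
tables that print their sample base rounded to tenths of a million are
therefore not exactly recomputable from the printed values, and the
package does not try.

## Study conditions and problem sizes

The default `pipeline_config()` is the package's reference scenario: a
class I heterozygote carrying four substitutions on one haplotype
(spread so that two inter-het gaps exceed the 1000 bp fragment cap) and
a one-base poly-A contraction on the other; 100 full-length long reads
(100x) at the 13% preset and 100x of 251 bp pairs at the 0.2% preset.
Under these conditions short-read phasing is undefined by construction,
the rule engine routes to the cluster-and-polish procedure, and the
polished haplotypes equal the simulated truth exactly in at least 19 of
20 seeded replicates. The documented residual failure mode is a template
whose amplicon terminus itself begins with a long homopolymer: the
terminal ~10 bases receive almost no short-read coverage (fragment ends
ramp), so an ambiguous long-read run call there cannot be repaired —
the same blind spot that primer-defined amplicon ends impose on the wet
assay. Oracle-equivalence tests (alignment scores against an exhaustive
dynamic program, expression calls against an independent codon scan,
phase blocks against a breadth-first-search component oracle) run on
deliberately small inputs — 50-mers, a ~350 bp toy gene, four het sites —
chosen so each oracle stays obviously correct by inspection.

## Known limitations

* Backbone-guided calling only: no de novo assembly, so a novel allele
  must be within reach (>= 90% identity) of some reference.
* The rule engine's precedence when categories co-occur, the het band,
  the informative-position window, the 60% run support and the polish
  thresholds are artifact choices; the published strategy fixes none of
  them. All are exposed in `pipeline_config()`.
* Category assignment for the "both platforms deviate, differently" cell
  is a design decision (see above), not published behaviour.
* Amplicon termini (~10 bp) are effectively unpolishable at the default
  coverage; variants or consensus errors there can survive.
* No network submission: flat files are generated and parsed locally
  only.
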