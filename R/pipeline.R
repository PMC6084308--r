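#' Pipeline configuration
#'
#' All tunables of the end-to-end run in one validated object. The
#' defaults are the package's reference study conditions: a class I locus
#' (3404 bp), a heterozygote carrying four substitutions on one haplotype
#' and a one-base poly-A contraction on the other, 100x long-read coverage
#' at the 13% indel-heavy error preset and 100x short-read coverage at the
#' 0.2% substitution preset. Under these conditions two neighbouring
#' heterozygous positions are separated by more than the 1000 bp fragment
#' cap, so short-read phasing is undefined by construction and the
#' cluster-and-polish route is exercised.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param locus_template,n_ref_alleles,divergence Reference-set
#'   parameters, see [make_reference_set()].
#' @param n_snvs Number of substitutions planted on haplotype 1.
#' @param hp_delta Homopolymer length change planted on haplotype 2 at the
#'   template poly-A locus (`0` disables it).
#' @param coverage_long,coverage_short Coverage targets.
#' @param long_profile,short_profile [error_profile()]s.
#' @param min_coverage,het_band,freq_window,hp_support,min_identity,min_fraction
#'   Calling thresholds, see the stage functions.
#' @param precedence Rule precedence for [decide()].
#' @param q_catalog Optional questionable-expression catalog (data.frame).
#' @param sbs_artifact Optional [snv()] applied to both haplotypes before
#'   short-read simulation only — emulates a PCR artifact private to the
#'   short-read library, the situation that triggers a repeat.
#' @param sample_id,companion_typings Submission metadata.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            locus_template = "classI",
                            n_ref_alleles = 4L,
                            divergence = 0.005,
                            n_snvs = 4L,
                            hp_delta = -1L,
                            coverage_long = 100,
                            coverage_short = 100,
                            long_profile = long_error_profile(),
                            short_profile = short_error_profile(),
                            min_coverage = 10,
                            het_band = c(0.25, 0.75),
                            freq_window = c(0.30, 0.70),
                            hp_support = 0.6,
                            min_identity = 0.9,
                            min_fraction = 0.7,
                            precedence = c("REPEAT_ANALYSIS", "RUN_DR2S",
                                           "SUBMIT_SBS"),
                            q_catalog = NULL,
                            sbs_artifact = NULL,
                            sample_id = "SIM0001",
                            companion_typings = c(
                              A = "A*01:01,A*02:01",
                              B = "B*07:02,B*08:01",
                              DRB1 = "DRB1*03:01,DRB1*15:01")) {
  stopifnot(seed == as.integer(seed),
            locus_template %in% c("classI", "classII"),
            n_ref_alleles >= 1L, n_snvs >= 0L,
            coverage_long > 0, coverage_short > 0,
            min_coverage >= 1, hp_support > 0.5, hp_support <= 1,
            min_identity > 0, min_identity <= 1,
            min_fraction > 0.5, min_fraction <= 1)
  if (het_band[1L] >= het_band[2L] || freq_window[1L] > freq_window[2L])
    stop("het_band / freq_window must be ascending")
  structure(as.list(environment()), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config> seed %d, %s locus, %d SNVs + hp delta %d, %gx long / %gx short\n",
    x$seed, x$locus_template, x$n_snvs, x$hp_delta, x$coverage_long,
    x$coverage_short))
  invisible(x)
}

#' Save / load a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a validated
#'   [pipeline_config()] identical to the saved one.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$long_profile <- unclass(x$long_profile)
  x$short_profile <- unclass(x$short_profile)
  x$companion_typings <- as.list(x$companion_typings)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$long_profile <- do.call(error_profile, x$long_profile[
    setdiff(names(x$long_profile), character(0))])
  x$short_profile <- do.call(error_profile, x$short_profile)
  x$companion_typings <- unlist(x$companion_typings)
  do.call(pipeline_config, x)
}

# default variant specs for the simulated heterozygote: n_snvs transitions
# on haplotype 1, spread so at least one inter-het gap exceeds the
# short-read fragment cap, plus a homopolymer contraction on haplotype 2
# at the template poly-A locus
default_variant_plan <- function(ref, n_snvs, hp_delta) {
  L <- nchar(ref$sequence)
  frac <- c(0.10, 0.25, 0.55, 0.88, 0.40, 0.70, 0.95, 0.05)
  pos <- round(L * frac[seq_len(max(n_snvs, 0L))])
  chars <- strsplit(ref$sequence, "", fixed = TRUE)[[1L]]
  hp_mask <- homopolymer_mask(chars)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  edits1 <- list()
  for (p in pos) {
    while (hp_mask[p + 1L]) p <- p + 7L   # keep SNVs out of homopolymers
    edits1[[length(edits1) + 1L]] <- snv(p, transition[[chars[p + 1L]]])
  }
  spec1 <- do.call(variant_spec, edits1)
  spec2 <- variant_spec()
  if (hp_delta != 0L) {
    # use the planted intron poly-A test bed: an interior run long enough
    # to be genuinely ambiguous for long reads, and far enough from the
    # amplicon edges that short-read fragments span it
    runs <- homopolymer_runs(ref$sequence)
    runs <- runs[runs$length >= 8L & runs$start > 300L &
                   runs$end < L - 300L, , drop = FALSE]
    if (nrow(runs) == 0L) stop("template has no interior run >= 8")
    spec2 <- variant_spec(homopolymer_delta(runs$start[1L], hp_delta))
  }
  list(spec1 = spec1, spec2 = spec2)
}

# reconstruct the two SBS haplotype sequences when phasing is defined:
# heterozygous alleles are oriented along the single phase block by
# majority fragment co-occurrence with the previous het
sbs_haplotypes <- function(track, pileup) {
  hp <- track$het_positions
  base_calls1 <- track$call1
  if (length(hp) == 0L)
    return(c(track$sequence, track$sequence))
  stopifnot(isTRUE(track$phasing_defined))
  al <- track$het_alleles
  hapA <- vapply(al, `[`, character(1L), 1L)
  hapB <- vapply(al, `[`, character(1L), 2L)
  if (length(hp) > 1L) {
    frag <- split(pileup$placements,
                  vapply(pileup$placements, `[[`, character(1L), "pair"))
    for (k in 2:length(hp)) {
      same <- 0L; cross <- 0L
      for (pl in frag) {
        ci <- cj <- NA_character_
        for (p in pl) {
          ci <- ci %|NA|% placement_call(p, hp[k - 1L] + 1L)
          cj <- cj %|NA|% placement_call(p, hp[k] + 1L)
        }
        if (is.na(ci) || is.na(cj)) next
        if ((ci == hapA[k - 1L] && cj == hapA[k]) ||
            (ci == hapB[k - 1L] && cj == hapB[k])) same <- same + 1L
        else if ((ci == hapA[k - 1L] && cj == hapB[k]) ||
                 (ci == hapB[k - 1L] && cj == hapA[k])) cross <- cross + 1L
      }
      if (cross > same) {  # flip orientation of het k
        tmp <- hapA[k]; hapA[k] <- hapB[k]; hapB[k] <- tmp
      }
    }
  }
  build <- function(hets) {
    chars <- base_calls1
    chars[hp + 1L] <- hets
    chars[is.na(chars) | chars == "-"] <- ""
    paste(chars, collapse = "")
  }
  c(build(hapA), build(hapB))
}

#' Run the whole dual redundant characterisation pipeline
#'
#' Executes, deterministically under the configured seed: reference-set
#' and sample simulation, short-read and long-read simulation, short-read
#' consensus calling and phasing, long-read informative-position calling,
#' clustering and per-allele consensus, conflict classification and the
#' rule decision, short-read polishing when the decision demands it,
#' annotation of the final haplotypes against the reference set, and
#' submission-record assembly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, reads (FASTQ + truth
#'   sidecars), the reference set, the decision (JSON) and the submission
#'   flat files are written there.
#' @return A `dual_run` with all stage outputs; see `summary()`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  seed <- as.integer(config$seed)
  refs <- make_reference_set(config$n_ref_alleles, config$locus_template,
                             config$divergence, seed = seed)
  backbone <- refs[[1L]]
  plan <- default_variant_plan(backbone, config$n_snvs, config$hp_delta)
  truth <- make_diploid_sample(refs, plan$spec1, plan$spec2)
  say("simulate: %d reference alleles, %d het position(s)",
      length(refs), length(truth$het_positions))
  L <- nchar(truth$allele1)
  n_long <- round(config$coverage_long * L / L)  # full-length amplicon reads
  long_reads <- simulate_long_reads(truth, n_long, config$long_profile,
                                    seed = seed + 1000L)
  sbs_truth <- truth
  if (!is.null(config$sbs_artifact)) {
    sbs_truth$allele1 <- apply_one_edit(truth$allele1,
                                        config$sbs_artifact)$sequence
    sbs_truth$allele2 <- apply_one_edit(truth$allele2,
                                        config$sbs_artifact)$sequence
    say("simulate: injected PCR artifact into the short-read library")
  }
  short_reads <- simulate_short_reads(sbs_truth, config$coverage_short,
                                      config$short_profile,
                                      seed = seed + 2000L)
  say("simulate: %d long reads, %d short-read pairs",
      length(long_reads$reads), nrow(short_reads$truth))

  sbs_pileup <- build_pileup(short_reads, backbone$sequence)
  sbs_track <- call_consensus(sbs_pileup, config$min_coverage,
                              config$het_band)
  sbs_track <- phase_hets(sbs_track, sbs_pileup)
  say("sbs: %d het position(s) in %d phase block(s); phasing %s",
      length(sbs_track$het_positions), length(sbs_track$phase_blocks),
      if (sbs_track$phasing_defined) "defined" else "undefined")

  smrt_pileup <- build_pileup(long_reads, backbone$sequence)
  informative <- call_informative_positions(smrt_pileup,
                                            config$freq_window,
                                            config$min_coverage)
  clusters <- cluster_long_reads(smrt_pileup, informative)
  say("smrt: %d informative position(s); %s", length(informative),
      if (clusters$homozygous) "homozygous (single cluster)" else
        sprintf("clusters %d / %d (consistency %.3f)",
                sum(clusters$labels == 1L, na.rm = TRUE),
                sum(clusters$labels == 2L, na.rm = TRUE),
                clusters$consistency))
  members <- function(k) {
    if (clusters$homozygous) names(clusters$labels)
    else names(clusters$labels)[which(clusters$labels == k)]
  }
  smrt_pair <- list(
    build_allele_consensus(smrt_pileup, members(1L), config$hp_support),
    build_allele_consensus(smrt_pileup, members(2L), config$hp_support))
  say("smrt: consensus %d / %d bp, %d ambiguous homopolymer locus/loci",
      nchar(smrt_pair[[1L]]$sequence), nchar(smrt_pair[[2L]]$sequence),
      sum(vapply(smrt_pair, function(h)
        sum(h$hp_flags$ambiguous %||% FALSE) + 0, numeric(1L))))

  conflicts <- compare_tracks(sbs_track, smrt_pair, backbone$sequence)
  decision <- decide(conflicts, sbs_track$phasing_defined,
                     config$precedence)
  for (i in seq_len(nrow(decision$justification)))
    say("reconcile: position %s %s -> %s",
        decision$justification$position[i],
        decision$justification$category[i],
        decision$justification$rule[i])
  say("reconcile: %d conflict(s) -> %s", nrow(conflicts), decision$action)

  polished <- NULL
  final <- NULL
  if (decision$action == "RUN_DR2S") {
    polished <- polish_consensus(smrt_pair, short_reads,
                                 config$min_coverage, config$min_fraction)
    final <- polished$haplotypes
    say("dr2s: polished with %d / %d assigned pairs (%d unassigned); %d + %d correction(s)",
        polished$assignment[["hap1"]], polished$assignment[["hap2"]],
        polished$assignment[["unassigned"]],
        nrow(polished$changes[[1L]]), nrow(polished$changes[[2L]]))
  } else if (decision$action %in% c("SUBMIT_SBS", "SUBMIT_CONCORDANT")) {
    final <- sbs_haplotypes(sbs_track, sbs_pileup)
    say("submit: short-read haplotypes taken as final")
  } else {
    say("terminal: analysis must be repeated; no sequence submitted")
  }

  annotations <- NULL
  records <- NULL
  if (!is.null(final)) {
    annotations <- lapply(final, function(h) {
      closest <- find_closest_reference(h, refs)
      transfer_gene_model(h, closest$allele, config$min_identity)
    })
    records <- lapply(seq_along(final), function(i) {
      ann <- annotations[[i]]
      expr <- classify_expression(ann, config$q_catalog)
      submission_record(
        sample_id = sprintf("%s_h%d", config$sample_id, i),
        locus = sub("\\*.*$", "", ann$closest),
        sequence = final[[i]], annotation = ann, expression = expr,
        category = if (ann$distance == 0L) "confirmatory" else "novel",
        companion_typings = config$companion_typings)
    })
    for (r in records)
      say("annotate: %s %s, %d difference(s) vs %s, expression %s",
          r$sample_id, r$category, nrow(r$annotation$differences),
          r$annotation$closest, r$expression$class)
  }

  run <- structure(list(config = config, refs = refs, truth = truth,
                        sbs_track = sbs_track, informative = informative,
                        clusters = clusters, smrt_pair = smrt_pair,
                        conflicts = conflicts, decision = decision,
                        polished = polished, final = final,
                        annotations = annotations, records = records,
                        log = log),
                   class = "dual_run")
  if (!is.null(out_dir)) write_run_outputs(run, long_reads, short_reads,
                                           out_dir)
  run
}

write_run_outputs <- function(run, long_reads, short_reads, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_reference_set(run$refs, file.path(out_dir, "references.fasta"),
                      file.path(out_dir, "references.tsv"))
  write_read_set(long_reads, file.path(out_dir, "long"))
  write_read_set(short_reads, file.path(out_dir, "short"))
  jsonlite::write_json(
    list(action = run$decision$action,
         phasing_defined = run$decision$sbs_phasing_defined,
         justification = run$decision$justification),
    file.path(out_dir, "decision.json"), auto_unbox = TRUE, digits = NA)
  for (r in run$records %||% list())
    write_embl_flatfile(r, file.path(out_dir,
                                     paste0(r$sample_id, ".embl")))
  if (!is.null(run$records))
    utils::write.table(summarize_submissions(run$records),
                       file.path(out_dir, "submissions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.dual_run <- function(x, ...) {
  cat(sprintf("<dual_run> seed %d: %s\n", x$config$seed,
              x$decision$action))
  cat(sprintf("  %d conflict(s); SBS phasing %s; %d het position(s)\n",
              nrow(x$conflicts),
              if (x$sbs_track$phasing_defined) "defined" else "undefined",
              length(x$sbs_track$het_positions)))
  if (!is.null(x$final))
    cat(sprintf("  final haplotypes: %d / %d bp (%s / %s)\n",
                nchar(x$final[[1L]]), nchar(x$final[[2L]]),
                x$records[[1L]]$category, x$records[[2L]]$category))
  invisible(x)
}

#' @export
summary.dual_run <- function(object, ...) {
  cat(paste(object$log, collapse = "\n"), "\n")
  if (!is.null(object$final)) {
    ok1 <- identical(object$final[[1L]], object$truth$allele1) ||
      identical(object$final[[1L]], object$truth$allele2)
    ok2 <- identical(object$final[[2L]], object$truth$allele1) ||
      identical(object$final[[2L]], object$truth$allele2)
    cat(sprintf("haplotype recovery vs simulation truth: %s / %s\n",
                if (ok1) "exact" else "differs",
                if (ok2) "exact" else "differs"))
  }
  invisible(object)
}
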