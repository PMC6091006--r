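#' Run the full profiling pipeline on a simulated study
#'
#' End-to-end orchestration of the analysis stages on synthetic data with
#' known ground truth: locus family simulation, in-silico gag amplicon
#' extraction with difference matrix and diagnostic sites, read simulation and
#' assignment, relative cloning-frequency tables with per-group aggregation
#' and a disease-vs-control comparison, splice-variant inference and protein
#' prediction for the canonical transcript variants, and delta-delta-Ct qPCR
#' quantification with QC. Every stage is a pure function of (config, seed),
#' so re-running with the same config reproduces identical outputs.
#'
#' @param config a [simulation_config()]; its `seed` drives all randomness.
#' @param out_dir optional directory; when given, stage outputs are written as
#'   TSV files plus a `manifest.json`-style TSV snapshot.
#' @return list with elements `family`, `profile`, `samples`, `reads`,
#'   `assignment`, `freq`, `aggregates`, `group_test`, `splice`, `coding`,
#'   `qpcr`, `manifest`.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  family <- simulate_locus_family(config)
  ly <- family$layout

  gag_def <- amplicon_definition(
    "gag",
    primer_set("gag", family$primers$gag$forward, family$primers$gag$reverse,
               max_mismatches = 1L),
    expected_lengths = list("1" = c(600L, 640L), "2" = c(600L, 640L)))
  profile <- extract_amplicons(family$registry, gag_def)
  profile <- diagnostic_sites(profile)   # also fills the difference matrix

  # pseudo-samples mirroring the gag panel: 19 ALS (11 motor cortex, 6
  # occipital, 2 spinal cord) and 9 controls (5 motor, 2 occipital, 2 spinal)
  n_als <- ceiling(config$n_samples * 19 / 28)
  n_ctl <- config$n_samples - n_als
  tissues <- c(rep(c("motor_cortex", "occipital", "spinal_cord"),
                   times = pmax(0, round(n_als * c(11, 6, 2) / 19))),
               rep(c("motor_cortex", "occipital", "spinal_cord"),
                   times = pmax(0, round(n_ctl * c(5, 2, 2) / 9))))
  tissues <- rep_len(tissues, config$n_samples)
  samples <- sample_meta(
    sample_id = sprintf("%d-%s", seq_len(config$n_samples),
                        ifelse(tissues == "motor_cortex", "Mot",
                               ifelse(tissues == "occipital", "Occ", "SC"))),
    tissue = tissues,
    condition = c(rep("ALS", n_als), rep("control", n_ctl)),
    rin = round(pmin(10, pmax(1, stats::rnorm(config$n_samples, 6.3, 2.1))),
                1))

  if (config$reads_total > 0L) {
    sim <- simulate_amplicon_reads(
      profile, family$truth$proportions,
      n_reads = config$reads_total, error_rate = config$read_error_rate,
      revcomp_fraction = config$revcomp_fraction,
      sample_ids = samples$sample_id)
    assignment <- assign_batch(sim$reads, profile)
    assigned <- merge(assignment$assignments,
                      sim$truth[, c("read_id", "sample_id")], by = "read_id")

    freq <- frequency_table(assigned, samples)
    agg_condition <- aggregate_frequencies(freq, samples,
                                           group_by = "condition",
                                           mode = "per_sample_mean")
    agg_pooled <- aggregate_frequencies(
      freq, cbind(samples, all = "all"), group_by = "all", mode = "pooled")

    dominant <- rownames(freq$counts)[which.max(rowSums(freq$counts))]
    dom_freq <- freq$frequency[dominant, ]
    cond <- samples$condition[match(colnames(freq$frequency),
                                    samples$sample_id)]
    group_test <- if (min(table(cond)) >= 3L)
      compare_groups(dom_freq, cond) else NULL
  } else {
    warning("zero reads requested: assignment and frequency stages skipped")
    sim <- list(reads = DNAStringSet(), truth = NULL)
    assignment <- assign_batch(DNAStringSet(), profile)
    freq <- NULL; agg_condition <- NULL; agg_pooled <- NULL
    group_test <- NULL
  }

  # splice variants: one read per canonical variant, classified end-to-end
  type2_id <- names(family$truth$types)[family$truth$types == "2" &
    family$truth$provenance == "reference"][1]
  dominant_t1 <- names(family$truth$types)[family$truth$types == "1" &
    family$truth$provenance == "reference"][1]
  variants <- list(
    list(locus = type2_id, variant = "rec"),
    list(locus = dominant_t1, variant = "np9"),
    list(locus = type2_id, variant = "np9_like_alternative"))
  if (config$mutated_acceptor)
    variants <- c(variants, list(list(locus = "synK-NR1",
                                      variant = "np9_mut_acceptor")))
  if (config$retrocopy)
    variants <- c(variants, list(list(locus = "synK-retro",
                                      variant = "unspliced")))
  splice_rows <- lapply(variants, function(v) {
    sr <- simulate_splice_read(family, v$locus, v$variant)
    locus_seq <- get_locus(family$registry, v$locus)$sequence
    ann <- family$annotations[family$annotations$locus_id == v$locus, ]
    introns <- spliced_align(sr$sequence, locus_seq,
                             prefer_acceptor = ann$sa2)
    call <- classify_transcript(introns, ann,
                                family$truth$types[[v$locus]],
                                read_id = paste0(v$locus, ":", v$variant))
    prot <- if (call$transcript_class != "unknown")
      predict_spliced_protein(locus_seq, call, ann, family$references,
                              introns = introns)
    else data.frame(protein_class = "none", aa_sequence = "", aa_length = 0L,
                    source_transcript_class = "unknown",
                    stop_position = NA_integer_,
                    truncation_note = NA_character_)
    cbind(call, prot[, c("protein_class", "aa_length", "stop_position",
                         "truncation_note")],
          true_variant = v$variant)
  })
  splice <- do.call(rbind, splice_rows)

  # coding: canonical Env ORF + cleavage products on the canonical locus
  canon_seq <- get_locus(family$registry,
                         family$registry$canonical_env_reference)$sequence
  orfs <- scan_env_orfs(canon_seq, family$references$env_cds,
                        provirus_type = "2")
  fl <- orfs[orfs$class == "full_length_env", , drop = FALSE]
  products <- if (nrow(fl)) annotate_domains(fl[1, ]) else NULL

  # qPCR: tissue-level true fold changes relative to the hESC reference
  tissue_fold <- c(motor_cortex = 0.05, occipital = 0.006,
                   spinal_cord = 0.03, cerebellum = 0.21,
                   hippocampus = 0.005, other = 0.02)
  true_folds <- stats::setNames(
    tissue_fold[samples$tissue] * stats::runif(nrow(samples), 0.5, 2),
    samples$sample_id)
  ctt <- simulate_ct_table(true_folds, replicate_sd = 0.2)
  folds <- ddct_fold_change(ctt)
  fold_cond <- samples$condition[match(folds$sample_id, samples$sample_id)]
  qpcr_test <- if (length(unique(stats::na.omit(fold_cond))) == 2L &&
                   min(table(fold_cond)) >= 3L)
    compare_groups(log2(folds$fold_change[!is.na(fold_cond)]),
                   fold_cond[!is.na(fold_cond)])
  else NULL
  rin_ct <- simulate_rin_ct(n = 108L, r2 = 0.38)
  r2 <- qc_correlation(rin_ct$rin, rin_ct$ct)

  manifest <- list(
    tool_version = as.character(utils::packageVersion("hml2profiler")),
    seed = config$seed,
    config = unclass(config),
    rows = c(loci = nrow(family$registry$metadata),
             amplified = length(profile$sequences),
             reads = length(sim$reads),
             assignments = nrow(assignment$assignments),
             freq_categories = if (is.null(freq)) 0L else nrow(freq$counts),
             splice_calls = nrow(splice),
             orfs = nrow(orfs),
             ct_samples = length(unique(ctt$sample_id))))

  res <- list(family = family, profile = profile, samples = samples,
              reads = sim, assignment = assignment, freq = freq,
              aggregates = list(condition_mean = agg_condition,
                                pooled = agg_pooled),
              group_test = group_test, splice = splice,
              coding = list(orfs = orfs, products = products),
              qpcr = list(ct = ctt, folds = folds, test = qpcr_test,
                          rin_ct = rin_ct, r2 = r2),
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Write the main stage outputs as TSV files.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_registry(res$family$registry,
                 file.path(out_dir, "registry.fasta"),
                 file.path(out_dir, "registry_metadata.tsv"))
  if (!is.null(res$freq)) {
    utils::write.table(
      data.frame(category = rownames(res$freq$counts), res$freq$counts,
                 check.names = FALSE),
      file.path(out_dir, "frequency_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    w(res$aggregates$condition_mean, "aggregate_condition_mean.tsv")
    w(res$aggregates$pooled, "aggregate_pooled.tsv")
  }
  w(res$assignment$assignments, "assignments.tsv")
  w(res$assignment$summary, "assignment_summary.tsv")
  w(res$splice, "splice_calls.tsv")
  w(res$coding$orfs, "env_orfs.tsv")
  if (!is.null(res$coding$products)) w(res$coding$products, "env_products.tsv")
  w(res$qpcr$folds, "ddct_folds.tsv")
  manifest <- res$manifest
  w(data.frame(key = c("tool_version", "seed", names(manifest$rows)),
               value = c(manifest$tool_version, manifest$seed,
                         unname(manifest$rows))),
    "manifest.tsv")
  invisible(out_dir)
}
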