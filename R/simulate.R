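#' Layout of the synthetic type-2 provirus
#'
#' All synthetic loci descend from one ancestor with this fixed coordinate
#' layout (1-based on the type-2 sequence). The env CDS is 699 codons; the
#' 292-bp type-1/type-2 segment sits in its 5' region and contains the rec
#' splice donor SD2; the canonical rec/np9 acceptor SA2 lies near the CDS end;
#' an alternative acceptor 260 nt downstream of SA2 inside the 3' LTR is
#' followed by a planted copy of the first 19 exon-3 codons plus a stop, so
#' the alternatively spliced product is exactly the Rec protein lacking its
#' C-terminal 17 aa. Deleting the segment turns the locus into type 1 and
#' shifts all downstream coordinates by -292.
#'
#' @return named list of coordinates.
#' @export
provirus_layout <- function() {
  env_start <- 1401L
  sa2 <- env_start + 1988L         # last intron base (G of AG), type-2 coords
  list(
    length            = 3900L,
    ltr5              = c(1L, 300L),
    gag_fwd           = c(351L, 370L),
    gag_rev_site      = c(951L, 970L),
    gag_amplicon      = c(351L, 970L),
    gag_interior      = c(371L, 950L),
    env_prestop       = c(1398L, 1400L),
    env_start         = env_start,
    env_cds           = c(env_start, env_start + 2096L),
    env_stop          = c(env_start + 2097L, env_start + 2099L),
    np9_sd            = env_start + 150L,    # GT of codon 51
    segment           = c(env_start + 200L, env_start + 491L),  # 292 bp
    sd2               = env_start + 300L,    # GT of codon 101, inside segment
    sa2               = sa2,
    exon3_start       = sa2 + 1L,
    env600_rev_site   = c(env_start + 600L, env_start + 619L),
    ltr3_start        = 3501L,
    alt_acceptor      = sa2 + 260L,          # AG ends here, inside the 3' LTR
    alt_exon          = c(sa2 + 261L, sa2 + 261L + 56L),  # copy of 19 codons
    alt_stop          = c(sa2 + 318L, sa2 + 320L),
    recnp9_rev_site   = c(3750L, 3769L),
    rec_len_aa        = 136L,
    np9_len_aa        = 86L,
    rec_truncated_aa  = 119L)
}

# Random DNA of length n.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# n random sense codons (no stop).
random_codons <- function(n) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

set_range <- function(s, from, to, value) {
  stopifnot(nchar(value) == to - from + 1L)
  substr(s, from, to) <- value
  s
}

#' Build the synthetic type-2 ancestor provirus
#'
#' Uses the current RNG state; wrap in `set.seed()` for reproducibility.
#'
#' @return list with `sequence`, `layout`, `primers` (per amplicon: forward,
#'   reverse, both 5'->3'), and `references` (canonical `env_cds`, `env_aa`,
#'   `rec`, `np9` — the latter three amino-acid strings).
#' @export
simulate_provirus <- function() {
  ly <- provirus_layout()
  s <- random_dna(ly$length)
  # env CDS: random sense codons, then planted feature codons
  cds <- random_codons(699L)
  cds <- set_range(cds, 1L, 3L, "ATG")       # codon 1: Env/Rec/Np9 start
  cds <- set_range(cds, 151L, 153L, "GTA")   # codon 51: np9 splice donor GT
  cds <- set_range(cds, 301L, 303L, "GTC")   # codon 101: rec SD2 GT
  cds <- set_range(cds, 1987L, 1989L, "CAG") # codon 663: SA2 acceptor ..AG
  s <- set_range(s, ly$env_cds[1], ly$env_cds[2], cds)
  s <- set_range(s, ly$env_prestop[1], ly$env_prestop[2], "TAA")
  s <- set_range(s, ly$env_stop[1], ly$env_stop[2], "TAA")
  # alternative acceptor in the 3' LTR + copy of exon-3 codons 664..682 + stop
  s <- set_range(s, ly$alt_acceptor - 1L, ly$alt_acceptor, "AG")
  exon3_copy <- substr(s, ly$exon3_start, ly$exon3_start + 56L)
  s <- set_range(s, ly$alt_exon[1], ly$alt_exon[2], exon3_copy)
  s <- set_range(s, ly$alt_stop[1], ly$alt_stop[2], "TAA")
  # make sure no stray stop sneaked into the CDS via feature planting
  cds_final <- substr(s, ly$env_cds[1], ly$env_cds[2])
  aa <- as.character(Biostrings::translate(DNAString(cds_final)))
  stopifnot(!grepl("*", aa, fixed = TRUE))

  primers <- list(
    gag = list(forward = substr(s, ly$gag_fwd[1], ly$gag_fwd[2]),
               reverse = revcomp_chr(substr(s, ly$gag_rev_site[1],
                                            ly$gag_rev_site[2]))),
    env600nt = list(forward = substr(s, ly$env_start, ly$env_start + 19L),
                    reverse = revcomp_chr(substr(s, ly$env600_rev_site[1],
                                                 ly$env600_rev_site[2]))),
    rec_np9 = list(forward = substr(s, ly$env_start, ly$env_start + 19L),
                   reverse = revcomp_chr(substr(s, ly$recnp9_rev_site[1],
                                                ly$recnp9_rev_site[2]))))
  rec_aa <- paste0(substr(aa, 1L, 100L), substr(aa, 664L, 699L))
  np9_aa <- paste0(substr(aa, 1L, 50L), substr(aa, 664L, 699L))
  list(sequence = s, layout = ly, primers = primers,
       references = list(env_cds = cds_final, env_aa = aa,
                         rec = rec_aa, np9 = np9_aa))
}

#' Derive the type-1 sequence (292-bp segment deleted)
#'
#' @param type2_sequence a type-2 locus sequence laid out per
#'   [provirus_layout()].
#' @return the type-1 sequence (all downstream coordinates shift by -292).
#' @export
make_type1 <- function(type2_sequence) {
  ly <- provirus_layout()
  paste0(substr(type2_sequence, 1L, ly$segment[1] - 1L),
         substr(type2_sequence, ly$segment[2] + 1L,
                nchar(type2_sequence)))
}

# Mutate the canonical acceptor AG -> GG and plant a new AG 7 nt downstream
# (type-1 coordinates), emulating the HERV-K111-style skipped acceptor.
make_mutated_acceptor <- function(type1_sequence) {
  ly <- provirus_layout()
  sa2_t1 <- ly$sa2 - 292L
  s <- set_range(type1_sequence, sa2_t1 - 1L, sa2_t1, "GG")
  set_range(s, sa2_t1 + 6L, sa2_t1 + 7L, "AG")
}

# Retrotransposed rec mRNA: 5' flank (pre-gag), the env-start exon 1 and the
# spliced exon 3 through the 3' LTR — no gag amplicon, a stop at Rec codon 19.
make_retrocopy <- function(type2_sequence) {
  ly <- provirus_layout()
  s <- paste0(substr(type2_sequence, 1L, 300L),
              substr(type2_sequence, 1391L, ly$sd2 - 1L),
              substr(type2_sequence, ly$exon3_start, ly$length))
  env_start_rc <- 300L + (ly$env_start - 1391L) + 1L   # 311
  stop_from <- env_start_rc + 3L * 18L                 # codon 19
  s <- set_range(s, stop_from, stop_from + 2L, "TAA")
  attr(s, "env_start") <- env_start_rc
  s
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: a family of 20 paralogous loci whose
#' ~620-nt gag amplicons differ by 1-40 pairwise substitutions, one
#' indistinguishable pair (0 differences), a retrotransposed spliced-mRNA
#' locus, one non-reference type-1 locus with a mutated canonical acceptor,
#' skewed mixing proportions (dominant locus 53%, next three 12.1/10.4/6.7%),
#' 820 reads over 28 pseudo-samples, 0.2% per-base read error, unstranded
#' reads.
#'
#' @param n_loci family size (>= 4).
#' @param type2_fraction fraction of type-2 proviruses.
#' @param identical_pair plant a pair with identical amplicons.
#' @param retrocopy include the retrotransposed rec-mRNA locus.
#' @param mutated_acceptor include the non-reference skipped-acceptor locus.
#' @param read_error_rate per-base substitution error of simulated reads.
#' @param reads_total total reads across all samples.
#' @param n_samples number of pseudo-samples.
#' @param mixing_proportions per-locus transcript proportions (default
#'   Table-1-like skew); must sum to 1.
#' @param revcomp_fraction fraction of reads reported on the minus strand.
#' @param max_subs maximum planted substitutions per locus amplicon.
#' @param seed RNG seed (fixed seed implies byte-identical outputs).
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_loci = 20L, type2_fraction = 0.4,
                              identical_pair = TRUE, retrocopy = TRUE,
                              mutated_acceptor = TRUE,
                              read_error_rate = 0.002,
                              reads_total = 820L, n_samples = 28L,
                              mixing_proportions = NULL,
                              revcomp_fraction = 0.5,
                              max_subs = 20L, seed = 1L) {
  if (identical_pair && n_loci < 2L)
    stop("identical_pair requires n_loci >= 2")
  stopifnot(n_loci >= 4L, type2_fraction >= 0, type2_fraction <= 1,
            read_error_rate >= 0, read_error_rate <= 1,
            revcomp_fraction >= 0, revcomp_fraction <= 1)
  if (is.null(mixing_proportions))
    mixing_proportions <- table1_like_proportions(n_loci)
  if (abs(sum(mixing_proportions) - 1) > 1e-8)
    stop("mixing_proportions must sum to 1")
  if (length(mixing_proportions) != n_loci)
    stop("mixing_proportions must have one entry per locus")
  structure(list(n_loci = as.integer(n_loci),
                 type2_fraction = type2_fraction,
                 identical_pair = identical_pair, retrocopy = retrocopy,
                 mutated_acceptor = mutated_acceptor,
                 read_error_rate = read_error_rate,
                 reads_total = as.integer(reads_total),
                 n_samples = as.integer(n_samples),
                 mixing_proportions = mixing_proportions,
                 revcomp_fraction = revcomp_fraction,
                 max_subs = as.integer(max_subs), seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Skewed mixing proportions emulating the observed cloning frequencies
#'
#' One dominant locus at 53%, three more at 12.1%, 10.4% and 6.7%, the
#' remaining loci sharing the rest equally — the top four together make up
#' ~80% of all transcripts.
#'
#' @param n_loci number of loci.
#' @return numeric vector summing to 1.
#' @export
table1_like_proportions <- function(n_loci) {
  stopifnot(n_loci >= 4L)
  top <- c(0.53, 0.121, 0.104, 0.067)
  rest <- rep((1 - sum(top)) / (n_loci - 4L), n_loci - 4L)
  c(top, rest)
}

#' Simulate a paralogous locus family
#'
#' All loci descend from one synthetic ancestor provirus; per-locus
#' substitutions are planted uniformly at random inside the gag amplicon
#' interior (never in primer sites, so primer matching cannot silently fail),
#' giving pairwise amplicon differences spread over ~1-40. Type-1 members lack
#' the 292-bp segment; optionally one identical pair, one retrocopy and one
#' non-reference mutated-acceptor locus are added.
#'
#' @param config a [simulation_config()].
#' @return list: `registry` (a `LocusRegistry`), `truth` (planted
#'   substitutions, per-locus type and proportions), `annotations` (per-locus
#'   splice annotations), `primers`, `layout`, `references`, `config`.
#' @export
simulate_locus_family <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  anc <- simulate_provirus()
  ly <- anc$layout
  n <- config$n_loci
  ids <- sprintf("synK-%02d", seq_len(n))

  # provirus types: the dominant locus is type 1, the second type 2 (the
  # rec-competent locus), the rest assigned to meet type2_fraction
  types <- rep("1", n)
  n_type2 <- max(1L, round(config$type2_fraction * n))
  types[2L] <- "2"
  extra2 <- setdiff(seq_len(n), 1:2)[seq_len(max(0L, n_type2 - 1L))]
  types[extra2] <- "2"

  n_subs <- pmin(config$max_subs,
                 sample.int(config$max_subs, n, replace = TRUE))
  n_subs[1L] <- min(8L, config$max_subs)
  interior <- seq(ly$gag_interior[1], ly$gag_interior[2])
  seqs <- character(n)
  truth_subs <- list()
  for (i in seq_len(n)) {
    if (config$identical_pair && i == n) {   # exact copy of its neighbour
      seqs[i] <- seqs[n - 1L]
      types[i] <- types[n - 1L]
      truth_subs[[i]] <- truth_subs[[n - 1L]]
      truth_subs[[i]]$locus_id <- ids[i]
      next
    }
    s <- anc$sequence
    pos <- sort(sample(interior, n_subs[i]))
    old <- vapply(pos, function(p) substr(s, p, p), character(1))
    new <- vapply(old, function(b) sample_one(setdiff(c("A","C","G","T"), b)),
                  character(1))
    for (k in seq_along(pos)) s <- set_range(s, pos[k], pos[k], new[k])
    if (types[i] == "1") s <- make_type1(s)
    seqs[i] <- s
    truth_subs[[i]] <- data.frame(locus_id = ids[i], position = pos,
                                  ref_base = old, alt_base = new,
                                  stringsAsFactors = FALSE)
  }
  provenance <- rep("reference", n)

  extra_ids <- character(0); extra_seqs <- character(0)
  extra_types <- character(0); extra_prov <- character(0)
  if (config$mutated_acceptor) {
    # non-reference type-1 locus with the skipped canonical acceptor
    base <- make_type1(anc$sequence)
    extra_ids <- c(extra_ids, "synK-NR1")
    extra_seqs <- c(extra_seqs, make_mutated_acceptor(base))
    extra_types <- c(extra_types, "1")
    extra_prov <- c(extra_prov, "non_reference")
  }
  retro_env_start <- NA_integer_
  if (config$retrocopy) {
    rc <- make_retrocopy(anc$sequence)
    retro_env_start <- attr(rc, "env_start")
    extra_ids <- c(extra_ids, "synK-retro")
    extra_seqs <- c(extra_seqs, as.character(rc))
    extra_types <- c(extra_types, "2")
    extra_prov <- c(extra_prov, "retrocopy")
  }

  all_ids <- c(ids, extra_ids)
  all_seqs <- c(seqs, extra_seqs)
  all_types <- c(types, extra_types)
  all_prov <- c(provenance, extra_prov)
  meta <- data.frame(
    locus_id = all_ids, assembly = "synthetic-1.0",
    chrom = sprintf("chr%d", seq_along(all_ids)),
    anchor_pos = ly$gag_amplicon[1] + (ly$gag_amplicon[2] -
                                         ly$gag_amplicon[1]) %/% 2L,
    strand = "+", provirus_type = all_types, provenance = all_prov,
    notes = "", stringsAsFactors = FALSE)
  canonical <- all_ids[which(all_types == "2" & all_prov == "reference")[1]]
  registry <- locus_registry(
    stats::setNames(DNAStringSet(all_seqs), all_ids), meta,
    canonical_env_reference = canonical)

  shift <- ifelse(all_types == "1", 292L, 0L)
  annotations <- data.frame(
    locus_id = all_ids,
    sd1 = NA_integer_,
    sd2 = ifelse(all_types == "2", ly$sd2, NA_integer_),
    np9_sd = ifelse(all_types == "1", ly$np9_sd, NA_integer_),
    sa1 = NA_integer_,
    sa2 = ly$sa2 - shift,
    ltr3_start = ly$ltr3_start - shift,
    env_start = ly$env_start,
    stringsAsFactors = FALSE)
  if (config$retrocopy) {
    k <- which(all_ids == "synK-retro")
    annotations[k, c("sd2", "np9_sd", "sa2", "ltr3_start")] <- NA_integer_
    annotations$env_start[k] <- retro_env_start
  }

  list(registry = registry,
       truth = list(substitutions = do.call(rbind, truth_subs),
                    types = stats::setNames(all_types, all_ids),
                    provenance = stats::setNames(all_prov, all_ids),
                    proportions = stats::setNames(config$mixing_proportions,
                                                  ids)),
       annotations = annotations,
       primers = anc$primers, layout = ly, references = anc$references,
       ancestor = anc$sequence, config = config)
}

# Apply per-base substitution errors to one sequence.
add_read_errors <- function(s, error_rate) {
  if (error_rate <= 0) return(list(sequence = s, n_errors = 0L))
  n <- nchar(s)
  k <- stats::rbinom(1L, n, error_rate)
  if (k == 0L) return(list(sequence = s, n_errors = 0L))
  pos <- sample.int(n, k)
  for (p in pos) {
    b <- substr(s, p, p)
    s <- set_range(s, p, p, sample_one(setdiff(c("A","C","G","T"), b)))
  }
  list(sequence = s, n_errors = k)
}

#' Simulate amplicon cDNA reads with known ground truth
#'
#' Reads are drawn multinomially from the mixing proportions over the profile
#' loci, per-base substitution errors applied, and roughly half of them
#' reverse-complemented (the cDNA strategy is unstranded). Reads are spread
#' over samples as evenly as a multinomial allows.
#'
#' @param profile an `AmpliconProfile` (its sequences are the error-free
#'   templates).
#' @param proportions named per-locus proportions (names must match profile
#'   loci); loci missing from the vector get proportion 0.
#' @param n_reads total number of reads.
#' @param error_rate per-base substitution error.
#' @param revcomp_fraction probability a read is reverse-complemented.
#' @param sample_ids sample identifiers to spread reads over.
#' @return list: `reads` (named `DNAStringSet`) and `truth` (data.frame
#'   read_id, sample_id, locus_id, n_errors, orientation).
#' @export
simulate_amplicon_reads <- function(profile, proportions,
                                    n_reads = 820L, error_rate = 0.002,
                                    revcomp_fraction = 0.5,
                                    sample_ids = "S1") {
  stopifnot(inherits(profile, "AmpliconProfile"))
  amps <- as.character(profile$sequences)
  p <- stats::setNames(rep(0, length(amps)), names(amps))
  common <- intersect(names(proportions), names(amps))
  p[common] <- proportions[common]
  p <- p / sum(p)
  loci <- sample(names(amps), n_reads, replace = TRUE, prob = p)
  smp <- sample(rep_len(sample_ids, n_reads))
  out_seq <- character(n_reads); n_err <- integer(n_reads)
  orient <- character(n_reads)
  for (i in seq_len(n_reads)) {
    e <- add_read_errors(amps[loci[i]], error_rate)
    rc <- stats::runif(1) < revcomp_fraction
    out_seq[i] <- if (rc) revcomp_chr(e$sequence) else e$sequence
    n_err[i] <- e$n_errors
    orient[i] <- if (rc) "reverse_complement" else "forward"
  }
  ids <- sprintf("read%05d", seq_len(n_reads))
  list(reads = stats::setNames(DNAStringSet(out_seq), ids),
       truth = data.frame(read_id = ids, sample_id = smp, locus_id = loci,
                          n_errors = n_err, orientation = orient,
                          stringsAsFactors = FALSE))
}

#' Construct a spliced rec/np9 amplicon product from a family locus
#'
#' Builds the RT-PCR product (forward primer at the Env/Rec/Np9 start codon,
#' reverse primer in the 3' LTR) of the requested transcript variant by
#' excising the corresponding intron from the locus sequence.
#'
#' @param family output of [simulate_locus_family()].
#' @param locus_id which locus the transcript originates from.
#' @param variant one of `"rec"` (type-2 SD2 -> SA2), `"np9"` (type-1 np9
#'   donor -> SA2), `"np9_like_alternative"` (SD2 -> SA2+260 in the 3' LTR),
#'   `"np9_mut_acceptor"` (np9 donor -> SA2+7, mutated-acceptor locus),
#'   `"unspliced"`.
#' @param error_rate per-base substitution error applied to the product.
#' @return list: `sequence` (character), `introns` (true donor/acceptor
#'   positions on the locus), `variant`.
#' @export
simulate_splice_read <- function(family, locus_id,
                                 variant = c("rec", "np9",
                                             "np9_like_alternative",
                                             "np9_mut_acceptor",
                                             "unspliced"),
                                 error_rate = 0) {
  variant <- match.arg(variant)
  ly <- family$layout
  s <- get_locus(family$registry, locus_id)$sequence
  type <- family$truth$types[[locus_id]]
  shift <- if (type == "1") 292L else 0L
  env_start <- family$annotations$env_start[
    family$annotations$locus_id == locus_id]
  sa2 <- ly$sa2 - shift
  rev_end <- ly$recnp9_rev_site[2] - shift
  intron <- switch(variant,
    rec = c(ly$sd2, sa2),
    np9 = c(ly$np9_sd, sa2),
    np9_like_alternative = c(ly$sd2, ly$alt_acceptor - shift),
    np9_mut_acceptor = c(ly$np9_sd, sa2 + 7L),
    unspliced = NULL)
  if (variant == "rec" && type != "2")
    stop("rec splicing needs a type-2 locus")
  if (variant %in% c("np9", "np9_mut_acceptor") && type != "1")
    stop("np9 splicing needs a type-1 locus")
  if (is.null(intron)) {
    # pre-spliced (retrocopy) template: straight through to the reverse
    # primer site, which sits a fixed distance from the 3' end
    prod_end <- nchar(s) - (ly$length - ly$recnp9_rev_site[2])
    prod <- substr(s, env_start, prod_end)
  } else {
    prod <- paste0(substr(s, env_start, intron[1] - 1L),
                   substr(s, intron[2] + 1L, rev_end))
  }
  e <- add_read_errors(prod, error_rate)
  list(sequence = e$sequence,
       introns = if (is.null(intron)) NULL else
         data.frame(donor_pos = intron[1], acceptor_pos = intron[2]),
       variant = variant, locus_id = locus_id)
}

#' Simulate a replicate Ct table consistent with the 2^-ddCt model
#'
#' Target Cts are offset from the normalizer by a per-sample delta-Ct chosen so
#' that the fold change relative to the reference sample equals `true_folds`;
#' Normal replicate noise with `replicate_sd` is added to every measurement.
#'
#' @param true_folds named vector of true fold changes (the reference sample
#'   is added with fold 1 if absent).
#' @param replicate_sd replicate noise SD in Ct units.
#' @param n_replicates replicate measurements per sample and target (4 =
#'   duplicates x technical replicate).
#' @param reference_sample_id the fold = 1 reference (default `"H9-hESC"`).
#' @param target,normalizer assay names.
#' @param base_ct mean normalizer Ct.
#' @param reference_delta_ct the reference sample's true delta-Ct.
#' @return a `CtTable`.
#' @export
simulate_ct_table <- function(true_folds, replicate_sd = 0.2,
                              n_replicates = 4L,
                              reference_sample_id = "H9-hESC",
                              target = "HML2_gag", normalizer = "GAPDH",
                              base_ct = 18, reference_delta_ct = 8) {
  stopifnot(all(true_folds > 0))
  if (!reference_sample_id %in% names(true_folds))
    true_folds <- c(stats::setNames(1, reference_sample_id), true_folds)
  samples <- names(true_folds)
  rows <- lapply(samples, function(sm) {
    dct <- reference_delta_ct - log2(true_folds[[sm]])
    data.frame(
      sample_id = sm,
      target = rep(c(target, normalizer), each = n_replicates),
      ct = c(base_ct + dct + stats::rnorm(n_replicates, 0, replicate_sd),
             base_ct + stats::rnorm(n_replicates, 0, replicate_sd)),
      stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  ct_table(d$sample_id, d$target, d$ct,
           reference_sample_id = reference_sample_id,
           normalizer = normalizer)
}

#' Simulate paired RIN / Ct values with a planted population R-squared
#'
#' RNA integrity numbers are drawn around the study's distribution (mean 6.3,
#' SD 2.1, truncated to 1-10); Ct values decline linearly in RIN with Normal
#' noise scaled so the population coefficient of determination equals `r2`.
#'
#' @param n number of samples.
#' @param r2 planted population R-squared.
#' @param mean_rin,sd_rin RIN distribution parameters.
#' @param ct_mean intercept-level mean Ct.
#' @param slope Ct change per RIN unit.
#' @return data.frame with `rin` and `ct`.
#' @export
simulate_rin_ct <- function(n = 108L, r2 = 0.38, mean_rin = 6.3,
                            sd_rin = 2.1, ct_mean = 22, slope = -1) {
  rin <- pmin(10, pmax(1, stats::rnorm(n, mean_rin, sd_rin)))
  sd_e <- sqrt(slope^2 * stats::var(rin) * (1 - r2) / r2)
  ct <- ct_mean + slope * (rin - mean(rin)) + stats::rnorm(n, 0, sd_e)
  data.frame(rin = rin, ct = ct)
}
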