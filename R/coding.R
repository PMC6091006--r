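# Average (not monoisotopic) residue masses in Da; printed "approx." kDa
# values in the literature fold in gel mobility and glycosylation, so masses
# computed here are compared only within generous tolerance bands.
AVERAGE_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.0928, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

#' Predicted protein mass in kDa
#'
#' Sum of average residue masses plus one water, divided by 1000. The empty
#' chain therefore weighs 0.018 kDa.
#'
#' @param aa_sequence one-letter amino-acid string.
#' @return numeric, kDa.
#' @export
protein_mass <- function(aa_sequence) {
  aa <- strsplit(toupper(as.character(aa_sequence)), "", fixed = TRUE)[[1]]
  if (length(aa) == 0L) return(WATER_MASS / 1000)
  unknown <- setdiff(aa, names(AVERAGE_RESIDUE_MASS))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "))
  (sum(AVERAGE_RESIDUE_MASS[aa]) + WATER_MASS) / 1000
}

#' Env domain map on the canonical 699-aa Env
#'
#' The signal peptide spans aa 1-96 (cleaved by signal peptide peptidase); the
#' furin site splits the remainder into the surface/outer-membrane (SU/OM) and
#' transmembrane (TM) domains. The default furin position (aa 463) is derived
#' from the approximate 41/26 kDa SU/TM mass split and can be overridden.
#'
#' @param sp_end_aa last residue of the signal peptide (96).
#' @param furin_site_aa last residue of SU/OM (463).
#' @param tm_cytoplasmic_tail_start_aa first residue of the TM cytoplasmic
#'   tail (658).
#' @param env_length_aa canonical Env length (699).
#' @return list of class `DomainMap`.
#' @export
domain_map <- function(sp_end_aa = 96L, furin_site_aa = 463L,
                       tm_cytoplasmic_tail_start_aa = 658L,
                       env_length_aa = 699L) {
  stopifnot(0L < sp_end_aa, sp_end_aa < furin_site_aa,
            furin_site_aa < env_length_aa)
  structure(list(sp_end_aa = as.integer(sp_end_aa),
                 furin_site_aa = as.integer(furin_site_aa),
                 tm_cytoplasmic_tail_start_aa =
                   as.integer(tm_cytoplasmic_tail_start_aa),
                 env_length_aa = as.integer(env_length_aa)),
            class = "DomainMap")
}

# Maximal stop-to-stop open reading spans >= min_aa codons on the plus strand.
# Reported spans are non-extendable: the codon before the span start is a stop
# or the sequence boundary, likewise after the end.
find_orfs <- function(sequence, min_aa = 50L) {
  s <- as.character(sequence)
  n <- nchar(s)
  out <- list()
  for (f in 0:2) {
    n_codon <- (n - f) %/% 3L
    if (n_codon < min_aa) next
    cds <- substr(s, f + 1L, f + 3L * n_codon)
    aa <- as.character(Biostrings::translate(DNAString(cds),
                                             if.fuzzy.codon = "X"))
    stops <- c(0L, which(strsplit(aa, "", fixed = TRUE)[[1]] == "*"),
               nchar(aa) + 1L)
    for (k in seq_len(length(stops) - 1L)) {
      a0 <- stops[k] + 1L; a1 <- stops[k + 1L] - 1L
      len <- a1 - a0 + 1L
      if (len < min_aa) next
      out[[length(out) + 1L]] <- data.frame(
        frame_offset = f,
        nt_start = f + 3L * (a0 - 1L) + 1L,
        nt_end = f + 3L * a1,
        aa_length = len,
        aa_sequence = substr(aa, a0, a1),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(frame_offset = integer(0), nt_start = integer(0),
                      nt_end = integer(0), aa_length = integer(0),
                      aa_sequence = character(0)))
  res <- do.call(rbind, out)
  res[order(res$nt_start), , drop = FALSE]
}

# Locate the canonical env CDS on a locus and return a locus-position ->
# canonical-CDS-position map (NA where unaligned).
locate_env_region <- function(locus_seq, canonical_env_cds) {
  aln <- Biostrings::pairwiseAlignment(
    DNAString(as.character(canonical_env_cds)),
    DNAString(as.character(locus_seq)),
    type = "global-local",
    substitutionMatrix = diff_count_matrix(),
    gapOpening = 10, gapExtension = 0.2)
  rowp <- as.character(Biostrings::alignedPattern(aln))
  rows <- as.character(Biostrings::alignedSubject(aln))
  sub_start <- IRanges::start(Biostrings::subject(aln))
  cp <- strsplit(rowp, "", fixed = TRUE)[[1]]
  cs <- strsplit(rows, "", fixed = TRUE)[[1]]
  ppos <- cumsum(cp != "-")
  map <- rep(NA_integer_, nchar(as.character(locus_seq)))
  lpos <- sub_start - 1L + cumsum(cs != "-")
  keep <- cs != "-"
  map[lpos[keep]] <- ifelse(cp[keep] == "-", NA_integer_, ppos[keep])
  list(map = map,
       region = c(start = sub_start,
                  end = sub_start - 1L + sum(cs != "-")),
       score = Biostrings::score(aln))
}

#' Scan a locus for env-region open reading frames
#'
#' Finds all maximal ORFs of at least `min_aa` codons that overlap the env
#' gene region (located by aligning the canonical Env CDS to the locus), maps
#' each onto canonical Env amino-acid coordinates and assigns a class:
#' `full_length_env` (spans aa 1-699, type-2 locus), `type1_env` (starts
#' downstream of the 292-bp indel and reaches the TM region, type-1 locus),
#' `pol_env_fusion` (extends well upstream of the env start, e.g. a Pro-Env
#' fusion), the fragment classes `SP_SU_OM_fragment` / `SU_OM_fragment` /
#' `TM_fragment`, or `other`.
#'
#' @param locus_sequence locus nucleotide sequence.
#' @param canonical_env_cds the canonical Env coding sequence (2097 nt, no
#'   stop) used as the coordinate reference.
#' @param provirus_type `"1"`, `"2"` or `"unknown"`.
#' @param dm a `DomainMap`.
#' @param min_aa minimum ORF length (50; excludes micro-ORF noise while
#'   keeping the smallest relevant product class, Np9, at ~74-86 aa).
#' @param indel_end_aa last canonical-Env residue encoded within the 292-bp
#'   indel region (used for the `type1_env` rule; default 164 matches the
#'   packaged synthetic provirus layout).
#' @return data.frame of `OrfAnnotation` rows: frame, nt span, aa length and
#'   sequence, canonical alignment span (`start_aa`, `end_aa`), `class`,
#'   `predicted_mass_kDa`. Zero rows (with a `reason` attribute) if the env
#'   region cannot be located.
#' @export
scan_env_orfs <- function(locus_sequence, canonical_env_cds,
                          provirus_type = "unknown", dm = domain_map(),
                          min_aa = 50L, indel_end_aa = 164L) {
  loc <- locate_env_region(locus_sequence, canonical_env_cds)
  empty <- data.frame(frame_offset = integer(0), nt_start = integer(0),
                      nt_end = integer(0), aa_length = integer(0),
                      aa_sequence = character(0), start_aa = integer(0),
                      end_aa = integer(0), class = character(0),
                      predicted_mass_kDa = numeric(0))
  if (loc$score < 0.3 * nchar(as.character(canonical_env_cds)) * 0.5) {
    attr(empty, "reason") <- "env region absent"
    return(empty)
  }
  orfs <- find_orfs(locus_sequence, min_aa = min_aa)
  if (!nrow(orfs)) return(empty)
  env_start <- loc$region["start"]; env_end <- loc$region["end"]
  orfs <- orfs[orfs$nt_end >= env_start & orfs$nt_start <= env_end, ,
               drop = FALSE]
  if (!nrow(orfs)) return(empty)
  map_aa <- function(p) {
    v <- loc$map[max(1L, p):min(length(loc$map), p)]
    if (is.na(v)) NA_integer_ else as.integer(ceiling(v / 3))
  }
  res <- do.call(rbind, lapply(seq_len(nrow(orfs)), function(i) {
    o <- orfs[i, ]
    nt_in <- seq(max(o$nt_start, env_start), min(o$nt_end, env_end))
    mapped <- loc$map[nt_in]
    mapped <- mapped[!is.na(mapped)]
    if (!length(mapped)) return(NULL)
    start_aa <- as.integer(ceiling(min(mapped) / 3))
    end_aa <- as.integer(ceiling(max(mapped) / 3))
    upstream_nt <- env_start - o$nt_start
    cls <- if (upstream_nt >= 90L) "pol_env_fusion"
    else if (start_aa <= 1L && end_aa >= dm$env_length_aa &&
             identical(provirus_type, "2")) "full_length_env"
    else if (identical(provirus_type, "1") && start_aa >= indel_end_aa &&
             end_aa > dm$furin_site_aa) "type1_env"
    else if (end_aa <= dm$furin_site_aa) {
      sp_cov <- max(0L, min(end_aa, dm$sp_end_aa) - start_aa + 1L)
      if (sp_cov >= 0.5 * dm$sp_end_aa) "SP_SU_OM_fragment"
      else "SU_OM_fragment"
    } else if (start_aa > dm$furin_site_aa) "TM_fragment"
    else "other"
    data.frame(o, start_aa = start_aa, end_aa = end_aa, class = cls,
               predicted_mass_kDa = protein_mass(o$aa_sequence),
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Cleavage products of an env ORF
#'
#' Intersects the ORF's canonical-Env span with the SP / SU-OM / TM domains
#' and reports each resulting product with its predicted mass. An ORF that
#' never reaches a domain yields no product for it.
#'
#' @param orf one row from [scan_env_orfs()].
#' @param dm a `DomainMap`.
#' @return data.frame: `product` (`SP`, `SU_OM`, `TM`), `start_aa`, `end_aa`
#'   (canonical coordinates), `aa_length`, `predicted_mass_kDa`.
#' @export
annotate_domains <- function(orf, dm = domain_map()) {
  stopifnot(nrow(orf) == 1L)
  domains <- data.frame(
    product = c("SP", "SU_OM", "TM"),
    d_start = c(1L, dm$sp_end_aa + 1L, dm$furin_site_aa + 1L),
    d_end = c(dm$sp_end_aa, dm$furin_site_aa, dm$env_length_aa),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(3L), function(k) {
    s <- max(orf$start_aa, domains$d_start[k])
    e <- min(orf$end_aa, domains$d_end[k])
    if (s > e) return(NULL)
    # residues of the ORF's aa_sequence covering canonical positions s..e
    off <- s - orf$start_aa + 1L
    aa <- substr(orf$aa_sequence, off, off + (e - s))
    data.frame(product = domains$product[k], start_aa = s, end_aa = e,
               aa_length = e - s + 1L,
               predicted_mass_kDa = protein_mass(aa),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(product = character(0), start_aa = integer(0),
                      end_aa = integer(0), aa_length = integer(0),
                      predicted_mass_kDa = numeric(0))
  out
}

# Percent identity of two amino-acid sequences by global alignment; gaps
# count against identity (PID1), so a shared prefix alone cannot saturate it.
aa_identity <- function(x, y) {
  if (!nchar(x) || !nchar(y)) return(0)
  aln <- Biostrings::pairwiseAlignment(
    AAString(x), AAString(y), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID1")
}

#' Predict the protein encoded by a spliced transcript
#'
#' Splices the locus in silico according to a splice call, translates from the
#' Env/Rec/Np9 start codon and classifies the product against canonical
#' references: `Rec`, `Rec_truncated` (a strict C-terminally shortened Rec),
#' `Np9`, `chimeric_env_rec_np9` (N- and C-terminal halves matching different
#' references), or `none` when the start codon is absent or a stop occurs
#' within the first 25 codons (the stop position is reported).
#'
#' @param locus_sequence locus nucleotide sequence.
#' @param splice_call one-row data.frame from [classify_transcript()].
#' @param annotation one-row [splice_annotation()] for the locus (supplies
#'   `env_start`).
#' @param references list with elements `rec`, `np9`, `env` (amino-acid
#'   character strings of the canonical proteins).
#' @param introns optional data.frame of introns (from [spliced_align()]); if
#'   omitted, the single intron recorded in `splice_call` is used.
#' @param identity_threshold minimum percent identity (60) over at least
#'   `min_overlap` aa (30) for a chimeric half-match.
#' @return one-row data.frame (`ProteinPrediction`): `protein_class`,
#'   `aa_sequence`, `aa_length`, `source_transcript_class`, `stop_position`,
#'   `truncation_note`.
#' @export
predict_spliced_protein <- function(locus_sequence, splice_call, annotation,
                                    references, introns = NULL,
                                    identity_threshold = 60,
                                    min_overlap = 30L) {
  stopifnot(splice_call$transcript_class[1] != "unknown")
  locus <- as.character(locus_sequence)
  if (is.null(introns)) {
    introns <- if (is.na(splice_call$donor_pos[1]))
      data.frame(donor_pos = integer(0), acceptor_pos = integer(0))
    else data.frame(donor_pos = splice_call$donor_pos,
                    acceptor_pos = splice_call$acceptor_pos)
  }
  result <- function(class, aa = "", stop_pos = NA_integer_,
                     note = NA_character_) {
    data.frame(protein_class = class, aa_sequence = aa,
               aa_length = nchar(aa),
               source_transcript_class = splice_call$transcript_class[1],
               stop_position = stop_pos, truncation_note = note,
               stringsAsFactors = FALSE)
  }
  env_start <- annotation$env_start[1]
  if (is.na(env_start))
    return(result("none", note = "env_start not annotated"))
  # build the mature mRNA downstream of the start codon
  keep <- rep(TRUE, nchar(locus))
  if (nrow(introns))
    for (k in seq_len(nrow(introns)))
      keep[introns$donor_pos[k]:introns$acceptor_pos[k]] <- FALSE
  pos <- which(keep & seq_len(nchar(locus)) >= env_start)
  mrna <- paste(strsplit(locus, "", fixed = TRUE)[[1]][pos], collapse = "")
  if (substr(mrna, 1L, 3L) != "ATG")
    return(result("none", note = "start codon absent"))
  n_codon <- nchar(mrna) %/% 3L
  aa_full <- as.character(Biostrings::translate(
    DNAString(substr(mrna, 1L, 3L * n_codon)), if.fuzzy.codon = "X"))
  stop_at <- regexpr("*", aa_full, fixed = TRUE)
  if (stop_at < 0L)
    return(result("none", note = "no stop codon in frame"))
  aa <- substr(aa_full, 1L, stop_at - 1L)
  if (stop_at <= 25L)
    return(result("none", stop_pos = as.integer(stop_at),
                  note = sprintf("premature stop %d codons in", stop_at)))
  rec <- references$rec; np9 <- references$np9
  env <- if (!is.null(references$env)) references$env else references$env_aa
  stopifnot(is.character(rec), is.character(np9), is.character(env))
  if (identical(aa, rec)) return(result("Rec", aa))
  if (nchar(aa) < nchar(rec) && identical(aa, substr(rec, 1L, nchar(aa))))
    return(result("Rec_truncated", aa,
                  note = sprintf("lacks the C-terminal %d aa of Rec",
                                 nchar(rec) - nchar(aa))))
  if (identical(aa, np9)) return(result("Np9", aa))
  # chimeric: N-terminal half matches a Rec/Np9 prefix, C-terminal half the
  # Env C-terminus, each over a like-for-like window of its own length
  half <- nchar(aa) %/% 2L
  n_half <- substr(aa, 1L, half); c_half <- substr(aa, half + 1L, nchar(aa))
  if (nchar(n_half) >= min_overlap && nchar(c_half) >= min_overlap) {
    n_ok <- max(aa_identity(n_half, substr(rec, 1L, nchar(n_half))),
                aa_identity(n_half, substr(np9, 1L, nchar(n_half)))) >=
      identity_threshold
    env_cterm <- substr(env, max(1L, nchar(env) - nchar(c_half) + 1L),
                        nchar(env))
    c_ok <- aa_identity(c_half, env_cterm) >= identity_threshold
    if (n_ok && c_ok) return(result("chimeric_env_rec_np9", aa))
  }
  if (aa_identity(aa, np9) >= 90) return(result("Np9", aa))
  if (aa_identity(aa, rec) >= 90) return(result("Rec", aa))
  result("none", aa, note = "matches no reference class")
}
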