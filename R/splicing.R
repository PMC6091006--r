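#' Splice annotation for one locus
#'
#' Positions are 1-based on the locus sequence. `sd2` is the canonical rec
#' splice donor (first intron base, the G of GT) inside the 292-bp type-2
#' segment; `np9_sd` the type-1 np9 donor; `sa2` the canonical rec/np9
#' acceptor (last intron base, the G of AG); `ltr3_start` the first base of
#' the 3' LTR; `env_start` the Env/Rec/Np9 translational start (the A of ATG).
#'
#' @param locus_id locus identifier.
#' @param sd1,sa1 optional positions of the env-mRNA splice sites.
#' @param sd2,sa2 canonical rec/np9 intron boundaries.
#' @param np9_sd the type-1 np9 splice donor, if present.
#' @param ltr3_start,env_start landmark positions.
#' @param seq_length locus length, for bounds checking (optional).
#' @return a one-row data.frame of class `SpliceAnnotation`.
#' @export
splice_annotation <- function(locus_id, sd2, sa2, np9_sd = NA_integer_,
                              sd1 = NA_integer_, sa1 = NA_integer_,
                              ltr3_start = NA_integer_,
                              env_start = NA_integer_,
                              seq_length = NULL) {
  pos <- c(sd1 = sd1, sd2 = sd2, np9_sd = np9_sd, sa1 = sa1, sa2 = sa2,
           ltr3_start = ltr3_start, env_start = env_start)
  if (!is.null(seq_length) &&
      any(!is.na(pos) & (pos < 1L | pos > seq_length)))
    stop("splice annotation positions out of sequence bounds")
  if (!is.na(sd2) && !is.na(sa2) && sd2 >= sa2)
    stop("SD2 must lie upstream of SA2")
  out <- data.frame(locus_id = locus_id, sd1 = sd1, sd2 = sd2,
                    np9_sd = np9_sd, sa1 = sa1, sa2 = sa2,
                    ltr3_start = ltr3_start, env_start = env_start,
                    stringsAsFactors = FALSE)
  class(out) <- c("SpliceAnnotation", class(out))
  out
}

#' Read per-locus splice annotations from a TSV file
#'
#' Expects a header with columns `locus_id`, `sd2`, `sa2` and optionally
#' `np9_sd`, `sd1`, `sa1`, `ltr3_start`, `env_start`.
#'
#' @param path annotation file.
#' @return data.frame, one row per locus.
#' @export
read_splice_annotations <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("locus_id", "sd2", "sa2") %in% names(a)))
  for (col in c("np9_sd", "sd1", "sa1", "ltr3_start", "env_start"))
    if (!col %in% names(a)) a[[col]] <- NA_integer_
  a
}

# Can the intron (d, a) slide by s while producing the same mRNA?
# d = first intron base, a = last intron base, 1-based on the locus.
intron_shift_valid <- function(locus, d, a, s) {
  n <- nchar(locus)
  if (s == 0L) return(TRUE)
  if (s > 0L) {
    if (a + s > n) return(FALSE)
    substr(locus, d, d + s - 1L) == substr(locus, a + 1L, a + s)
  } else {
    k <- -s
    if (d - k < 1L) return(FALSE)
    substr(locus, d - k, d - 1L) == substr(locus, a - k + 1L, a)
  }
}

intron_dinucleotides <- function(locus, d, a) {
  c(donor = substr(locus, d, d + 1L), acceptor = substr(locus, a - 1L, a))
}

#' Spliced alignment of a read against its source locus
#'
#' Aligns the read (pattern, end-to-end) to the locus with near-free long
#' gaps, so that excised introns surface as long deletion runs; runs of at
#' least `min_intron` nt are reported as introns. Each boundary is then
#' refined: among the mRNA-equivalent placements within `shift_window` nt of
#' the unrefined boundary, one with GT..AG dinucleotides is preferred
#' (smallest shift wins; with `prefer_acceptor` given, the placement whose
#' acceptor is closest to it wins).
#'
#' @param read character or `DNAString` (already oriented, assigned to the
#'   locus).
#' @param locus_sequence the locus nucleotide sequence.
#' @param min_intron minimum intron length (default 50 nt; the rec intron is
#'   in the kb range, alternative acceptor offsets are hundreds of nt).
#' @param min_exon minimum exon block length (default 20 nt); shorter terminal
#'   blocks are trimmed, shorter internal blocks merged into one intron.
#' @param shift_window boundary refinement window (+/- 10 nt).
#' @param prefer_acceptor optional locus position; among tied GT..AG
#'   placements the acceptor closest to it is chosen.
#' @return data.frame with one row per intron: `donor_pos`, `acceptor_pos`
#'   (1-based first/last intron base on the locus), `donor_dinucleotide`,
#'   `acceptor_dinucleotide`, `length`, `refined`. Zero rows if the read is
#'   contiguous; `NULL` if no collinear chain was found.
#' @export
spliced_align <- function(read, locus_sequence, min_intron = 50L,
                          min_exon = 20L, shift_window = 10L,
                          prefer_acceptor = NULL) {
  r <- as.character(read)
  locus <- as.character(locus_sequence)
  aln <- Biostrings::pairwiseAlignment(
    DNAString(r), DNAString(locus),
    type = "global-local",
    substitutionMatrix = diff_count_matrix(),
    gapOpening = 10, gapExtension = 0.05)
  if (Biostrings::score(aln) < 0.25 * nchar(r)) return(NULL)
  rowp <- as.character(Biostrings::alignedPattern(aln))
  rows <- as.character(Biostrings::alignedSubject(aln))
  sub_start <- IRanges::start(Biostrings::subject(aln))
  cp <- strsplit(rowp, "", fixed = TRUE)[[1]]
  cs <- strsplit(rows, "", fixed = TRUE)[[1]]
  spos <- sub_start - 1L + cumsum(cs != "-")  # locus coordinate per column
  runs <- rle(cp == "-")
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  gaps <- which(runs$values & runs$lengths >= min_intron)
  introns <- lapply(gaps, function(k) {
    c(d = spos[starts[k]], a = spos[ends[k]])
  })
  # exon blocks between introns; enforce the minimum block size
  if (length(introns) >= 1L) {
    bounds <- c(1L, unlist(lapply(gaps, function(k) c(starts[k] - 1L,
                                                      ends[k] + 1L))),
                length(cp))
    block_cols <- matrix(bounds, ncol = 2L, byrow = TRUE)
    block_len <- vapply(seq_len(nrow(block_cols)), function(b) {
      cols <- block_cols[b, 1]:block_cols[b, 2]
      sum(cp[cols] != "-")
    }, integer(1))
    # merge introns flanking an internal block that is too short
    if (length(block_len) > 2L) {
      short_internal <- which(block_len < min_exon)
      short_internal <- short_internal[short_internal > 1L &
                                       short_internal < length(block_len)]
      for (b in rev(short_internal)) {
        introns[[b - 1L]] <- c(d = introns[[b - 1L]]["d"],
                               a = introns[[b]]["a"])
        introns[[b]] <- NULL
      }
    }
  }
  if (!length(introns))
    return(data.frame(donor_pos = integer(0), acceptor_pos = integer(0),
                      donor_dinucleotide = character(0),
                      acceptor_dinucleotide = character(0),
                      length = integer(0), refined = logical(0)))
  out <- do.call(rbind, lapply(introns, function(iv) {
    d <- unname(iv[1]); a <- unname(iv[2])
    shifts <- setdiff(seq(-shift_window, shift_window), 0L)
    shifts <- c(0L, shifts[order(abs(shifts))])
    cands <- Filter(function(s) intron_shift_valid(locus, d, a, s), shifts)
    canonical <- Filter(function(s) {
      dn <- intron_dinucleotides(locus, d + s, a + s)
      dn["donor"] == "GT" && dn["acceptor"] == "AG"
    }, cands)
    if (length(canonical)) {
      s <- if (!is.null(prefer_acceptor)) {
        canonical[[which.min(vapply(canonical, function(x)
          abs(a + x - prefer_acceptor), numeric(1)))]]
      } else canonical[[1L]]
      d <- d + s; a <- a + s; refined <- TRUE
    } else refined <- FALSE
    dn <- intron_dinucleotides(locus, d, a)
    data.frame(donor_pos = d, acceptor_pos = a,
               donor_dinucleotide = unname(dn["donor"]),
               acceptor_dinucleotide = unname(dn["acceptor"]),
               length = a - d + 1L, refined = refined,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Classify a spliced transcript as rec, np9, np9-like or unspliced
#'
#' Junction-based classification against the locus splice annotation: a
#' type-2 transcript using SD2 -> SA2 is `rec`; a type-1 transcript using the
#' np9 donor is `np9` (with `acceptor_offset` recording any shift away from
#' the canonical SA2, e.g. +7 when SA2 itself is mutated); a type-2 transcript
#' from SD2 to a non-canonical acceptor (e.g. +260 into the 3' LTR) is
#' `np9_like_alternative`; no introns is `unspliced`; anything else `unknown`.
#'
#' @param introns data.frame from [spliced_align()] (or `NULL`).
#' @param annotation one-row annotation for the locus (see
#'   [splice_annotation()]).
#' @param provirus_type `"1"`, `"2"` or `"unknown"`.
#' @param read_id,locus_id identifiers carried into the call.
#' @param site_tolerance maximum deviation (nt) for a boundary to count as
#'   matching an annotated site (default 0: exact).
#' @return a one-row data.frame (`SpliceCall`): `read_id`, `locus_id`,
#'   `transcript_class`, `donor_pos`, `acceptor_pos`, `acceptor_offset`,
#'   `n_introns`, `reason`.
#' @export
classify_transcript <- function(introns, annotation, provirus_type,
                                read_id = "read", locus_id = NULL,
                                site_tolerance = 0L) {
  if (is.null(locus_id)) locus_id <- annotation$locus_id[1]
  call_row <- function(class, donor = NA_integer_, acceptor = NA_integer_,
                       offset = NA_integer_, n = 0L, reason = NA_character_) {
    data.frame(read_id = read_id, locus_id = locus_id,
               transcript_class = class, donor_pos = donor,
               acceptor_pos = acceptor, acceptor_offset = offset,
               n_introns = n, reason = reason, stringsAsFactors = FALSE)
  }
  if (is.null(introns))
    return(call_row("unknown", reason = "no collinear chain"))
  if (nrow(introns) == 0L) return(call_row("unspliced"))
  if (is.na(annotation$sa2) ||
      (is.na(annotation$sd2) && is.na(annotation$np9_sd)))
    return(call_row("unknown", n = nrow(introns),
                    reason = "annotation missing required sites"))
  near <- function(x, site) !is.na(site) && !is.na(x) &&
    abs(x - site) <= site_tolerance
  # the classifying intron is the one starting at an annotated donor
  donor_match <- vapply(introns$donor_pos, function(d)
    near(d, annotation$sd2) || near(d, annotation$np9_sd), logical(1))
  if (sum(donor_match) != 1L)
    return(call_row("unknown", n = nrow(introns),
                    reason = "no single intron at an annotated donor"))
  iv <- introns[donor_match, ]
  if (iv$donor_dinucleotide != "GT" || iv$acceptor_dinucleotide != "AG")
    return(call_row("unknown", donor = iv$donor_pos,
                    acceptor = iv$acceptor_pos, n = nrow(introns),
                    reason = "intron violates the GT..AG rule"))
  offset <- as.integer(iv$acceptor_pos - annotation$sa2)
  at_sa2 <- abs(offset) <= site_tolerance
  if (near(iv$donor_pos, annotation$sd2)) {
    if (at_sa2 && identical(provirus_type, "2"))
      return(call_row("rec", iv$donor_pos, iv$acceptor_pos, 0L,
                      nrow(introns)))
    if (!at_sa2)
      return(call_row("np9_like_alternative", iv$donor_pos, iv$acceptor_pos,
                      offset, nrow(introns)))
    return(call_row("unknown", iv$donor_pos, iv$acceptor_pos, offset,
                    nrow(introns), reason = "SD2->SA2 on a non-type-2 locus"))
  }
  if (near(iv$donor_pos, annotation$np9_sd))
    return(call_row("np9", iv$donor_pos, iv$acceptor_pos, offset,
                    nrow(introns)))
  call_row("unknown", iv$donor_pos, iv$acceptor_pos, offset, nrow(introns),
           reason = "donor matches no annotated site")
}

#' Length-based fallback transcript classifier
#'
#' For loci without splice annotations, classifies a rec/np9 amplicon read by
#' its product length alone (rec-typical vs np9-typical ranges). Junction-based
#' classification is always preferred when annotations exist.
#'
#' @param read_length observed product length (nt).
#' @param rec_range,np9_range inclusive length ranges (defaults match the
#'   packaged synthetic provirus layout: rec products ~680 nt, np9-typical
#'   products ~420-530 nt).
#' @return `"rec_typical_length"`, `"np9_typical_length"` or `"unknown"`.
#' @export
classify_by_length <- function(read_length, rec_range = c(650, 710),
                               np9_range = c(400, 560)) {
  if (read_length >= rec_range[1] && read_length <= rec_range[2])
    "rec_typical_length"
  else if (read_length >= np9_range[1] && read_length <= np9_range[2])
    "np9_typical_length"
  else "unknown"
}
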