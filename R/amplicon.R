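#' Primer sets and amplicon definitions
#'
#' The profiling strategy rests on three RT-PCR amplicons (gag, env600nt,
#' rec/np9), each amplified with a degenerate mix of forward and reverse
#' primers so that locus-specific mismatches in primer binding sites do not
#' silently drop loci. A `primer_set` stores the mix with its relative ratios;
#' ratios are sampling metadata (amplification bias in the simulator), never
#' part of sequence matching.
#'
#' @param name primer set name.
#' @param forward,reverse character vectors of primer sequences (5'->3', the
#'   reverse primers as ordered, i.e. they match the minus strand).
#' @param forward_ratio,reverse_ratio positive mix ratios (default equal).
#' @param max_mismatches maximum substitutions tolerated per primer match.
#' @return an object of class `PrimerSet`.
#' @export
primer_set <- function(name, forward, reverse,
                       forward_ratio = rep(1, length(forward)),
                       reverse_ratio = rep(1, length(reverse)),
                       max_mismatches = 1L) {
  stopifnot(length(forward) >= 1L, length(reverse) >= 1L,
            all(forward_ratio > 0), all(reverse_ratio > 0),
            length(forward_ratio) == length(forward),
            length(reverse_ratio) == length(reverse),
            max_mismatches >= 0L)
  forward <- toupper(gsub("[^A-Za-z]", "", forward))
  reverse <- toupper(gsub("[^A-Za-z]", "", reverse))
  structure(list(name = name, forward = forward, reverse = reverse,
                 forward_ratio = forward_ratio, reverse_ratio = reverse_ratio,
                 max_mismatches = as.integer(max_mismatches)),
            class = "PrimerSet")
}

#' The env600nt reverse primer mix
#'
#' The six reverse primers bounding the ~600-bp env 5' region amplicon that
#' spans the 292-bp type-1/type-2 indel, mixed at ratios 5:1:1:1:1:1. The four
#' degenerate forward primers of the gag/env600nt/rec-np9 assays are not part
#' of the published protocol text and must be supplied by the user (the
#' synthetic-data module generates its own).
#'
#' @return a `PrimerSet` with the reverse mix and placeholder-free forward
#'   slot set to `NA` sequences removed; intended as a template to combine
#'   with user-supplied forward primers via [primer_set()].
#' @export
env600nt_reverse_primers <- function() {
  data.frame(
    name = paste0("env600ntR", 1:6),
    sequence = c("ATTTACCCGTGGCCTGAGTG",
                 "ATTTACCCGTGGCCTAAGTG",
                 "ATTTACCTGTGGCCTGAGCG",
                 "ATTTACCTGTGGCCTGAGAG",
                 "ATTTTATCTGTGGCCCGAGTG",
                 "ATTCATTTGTGACCTGAGC"),
    ratio = c(5, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
}

#' @param name one of `"gag"`, `"env600nt"`, `"rec_np9"`.
#' @param primer_set a `PrimerSet`.
#' @param expected_lengths named list of integer length ranges keyed by
#'   provirus type (e.g. `list("1" = c(300, 360), "2" = c(590, 650))`).
#' @rdname primer_set
#' @export
amplicon_definition <- function(name = c("gag", "env600nt", "rec_np9"),
                                primer_set, expected_lengths) {
  name <- match.arg(name)
  stopifnot(inherits(primer_set, "PrimerSet"), length(expected_lengths) >= 1L)
  structure(list(name = name, primer_set = primer_set,
                 expected_lengths = expected_lengths),
            class = "AmpliconDefinition")
}

# All matches of one primer in a sequence with <= max_mismatches
# substitutions (no indels: primers are short, indel tolerance would create
# ambiguous anchors). Returns start positions.
primer_matches <- function(primer, sequence, max_mismatches) {
  m <- Biostrings::matchPattern(primer, DNAString(as.character(sequence)),
                                max.mismatch = max_mismatches,
                                with.indels = FALSE)
  IRanges::start(m)
}

#' Find amplicon intervals bounded by a primer pair
#'
#' Scans both strands of the locus for a forward-primer match with a
#' downstream reverse-primer match (the reverse primer matched as its reverse
#' complement). For each forward match the nearest downstream reverse match is
#' paired, mirroring the dominant (shortest) PCR product. An empty result is a
#' valid outcome, not an error.
#'
#' @param locus_sequence nucleotide sequence (character or `DNAString`).
#' @param primer_set a `PrimerSet`.
#' @return data.frame with columns `start`, `end` (1-based, inclusive, on the
#'   given sequence), `strand`, `forward_primer`, `reverse_primer`, `length`.
#' @export
match_primers <- function(locus_sequence, primer_set) {
  stopifnot(inherits(primer_set, "PrimerSet"))
  seq_chr <- as.character(locus_sequence)
  mm <- primer_set$max_mismatches
  scan_strand <- function(s, strand) {
    n <- nchar(s)
    fwd <- do.call(rbind, lapply(seq_along(primer_set$forward), function(i) {
      p <- primer_set$forward[i]
      st <- primer_matches(p, s, mm)
      if (!length(st)) return(NULL)
      data.frame(fstart = st, flen = nchar(p), fname = i)
    }))
    rev <- do.call(rbind, lapply(seq_along(primer_set$reverse), function(i) {
      p <- revcomp_chr(primer_set$reverse[i])
      st <- primer_matches(p, s, mm)
      if (!length(st)) return(NULL)
      data.frame(rstart = st, rlen = nchar(p), rname = i)
    }))
    if (is.null(fwd) || is.null(rev)) return(NULL)
    out <- do.call(rbind, lapply(seq_len(nrow(fwd)), function(i) {
      f <- fwd[i, ]
      cand <- rev[rev$rstart > f$fstart + f$flen - 1L, , drop = FALSE]
      if (!nrow(cand)) return(NULL)
      r <- cand[which.min(cand$rstart), ]
      start <- f$fstart
      end <- r$rstart + r$rlen - 1L
      if (strand == "-") {  # report on the input sequence's coordinates
        data.frame(start = n - end + 1L, end = n - f$fstart + 1L,
                   strand = strand,
                   forward_primer = f$fname, reverse_primer = r$rname)
      } else {
        data.frame(start = start, end = end, strand = strand,
                   forward_primer = f$fname, reverse_primer = r$rname)
      }
    }))
    out
  }
  res <- rbind(scan_strand(seq_chr, "+"),
               scan_strand(revcomp_chr(seq_chr), "-"))
  if (is.null(res) || !nrow(res))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), forward_primer = integer(0),
                      reverse_primer = integer(0), length = integer(0)))
  res <- unique(res)
  res$length <- res$end - res$start + 1L
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract per-locus in-silico amplicons
#'
#' Runs [match_primers()] on every registry locus and collects the amplified
#' sequences (primers included, plus-strand orientation of the product). Loci
#' without a primer pair are recorded as absent with the failing step as the
#' reason, mirroring loci a wet-lab assay would silently miss.
#'
#' @param registry a `LocusRegistry`.
#' @param amplicon_def an `AmpliconDefinition`.
#' @return an `AmpliconProfile`: list with `amplicon`, `sequences`
#'   (named `DNAStringSet`), `absent` (data.frame locus_id/reason), and slots
#'   for `difference_matrix` / `diagnostic_sites` filled by the corresponding
#'   functions.
#' @export
extract_amplicons <- function(registry, amplicon_def) {
  stopifnot(inherits(registry, "LocusRegistry"),
            inherits(amplicon_def, "AmpliconDefinition"))
  ps <- amplicon_def$primer_set
  ids <- registry$metadata$locus_id
  seqs <- list(); absent <- list()
  for (i in seq_along(ids)) {
    s <- as.character(registry$sequences[[i]])
    iv <- match_primers(s, ps)
    if (!nrow(iv)) {
      has_f <- any(vapply(ps$forward, function(p)
        length(primer_matches(p, s, ps$max_mismatches)) > 0 ||
        length(primer_matches(p, revcomp_chr(s), ps$max_mismatches)) > 0,
        logical(1)))
      reason <- if (!has_f) "no forward primer match" else
        "no reverse primer match downstream of a forward match"
      absent[[ids[i]]] <- reason
      next
    }
    iv1 <- iv[which.min(iv$length), ]
    amp <- substr(s, iv1$start, iv1$end)
    if (iv1$strand == "-") amp <- revcomp_chr(amp)
    seqs[[ids[i]]] <- amp
  }
  sequences <- if (length(seqs)) DNAStringSet(unlist(seqs)) else DNAStringSet()
  absent_df <- data.frame(locus_id = names(absent),
                          reason = unlist(absent, use.names = FALSE),
                          stringsAsFactors = FALSE)
  structure(list(amplicon = amplicon_def, sequences = sequences,
                 absent = absent_df, difference_matrix = NULL,
                 diagnostic_sites = NULL),
            class = "AmpliconProfile")
}

#' @export
print.AmpliconProfile <- function(x, ...) {
  cat("AmpliconProfile '", x$amplicon$name, "': ",
      length(x$sequences), " loci amplified, ",
      nrow(x$absent), " absent\n", sep = "")
  if (!is.null(x$difference_matrix))
    cat("  pairwise differences: ",
        min(x$difference_matrix[upper.tri(x$difference_matrix)]), "-",
        max(x$difference_matrix), "\n", sep = "")
  invisible(x)
}

#' Classify a provirus as type 1 or type 2 via the 292-bp env indel
#'
#' HML-2 type 2 proviruses carry a 292-bp segment in the env gene 5' region
#' that type 1 proviruses lack. The query is globally aligned to a type-2
#' reference of the region; the call is type 2 if the segment is essentially
#' present (fewer than 50 gap positions inside it), type 1 if it is absent as
#' one deletion of 292 +/- `indel_tolerance` nt, and unknown otherwise.
#'
#' @param env_region_sequence query covering the env 5' indel region.
#' @param reference_type2 type-2 reference sequence of the same region. The
#'   segment location is taken from its `indel_segment` attribute
#'   (`c(start, end)`, 1-based inclusive) unless `segment` is given.
#' @param segment optional `c(start, end)` of the 292-bp segment on the
#'   reference.
#' @param indel_length expected segment length (292).
#' @param indel_tolerance permitted deviation of the single deletion (10).
#' @return factor-like character: `"1"`, `"2"` or `"unknown"`.
#' @export
classify_provirus_type <- function(env_region_sequence, reference_type2,
                                   segment = attr(reference_type2,
                                                  "indel_segment"),
                                   indel_length = 292L,
                                   indel_tolerance = 10L) {
  q <- as.character(env_region_sequence)
  if (nchar(q) < 100L) stop("region too short (< 100 nt)")
  r <- as.character(reference_type2)
  if (is.null(segment))
    stop("segment coordinates required (indel_segment attribute or argument)")
  # global alignment with a cheap gap extension: length differences between
  # the query window and the reference surface as long gap runs (terminal or
  # the internal 292-bp deletion) instead of being absorbed as mismatches
  aln <- Biostrings::pairwiseAlignment(
    DNAString(q), DNAString(r), type = "global",
    substitutionMatrix = diff_count_matrix(),
    gapOpening = 5, gapExtension = 0.1)
  cq <- strsplit(as.character(Biostrings::alignedPattern(aln)), "",
                 fixed = TRUE)[[1]]
  cr <- strsplit(as.character(Biostrings::alignedSubject(aln)), "",
                 fixed = TRUE)[[1]]
  rpos <- cumsum(cr != "-")          # reference coordinate per column
  in_seg <- cr != "-" & rpos >= segment[1] & rpos <= segment[2]
  gap_in_seg <- sum(cq[in_seg] == "-")
  if (gap_in_seg < 50L) return("2")
  # deletion runs in the query overlapping the segment
  runs <- rle(cq == "-")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  del <- which(runs$values)
  overlapping <- del[vapply(del, function(k) {
    cols <- starts[k]:ends[k]
    any(in_seg[cols])
  }, logical(1))]
  if (length(overlapping) == 1L) {
    w <- runs$lengths[overlapping]
    if (abs(w - indel_length) <= indel_tolerance) return("1")
  }
  "unknown"
}

#' Pairwise difference matrix of an amplicon profile
#'
#' For every pair of per-locus amplicons counts substitutions plus indel
#' events (a contiguous gap is one event) from a global affine-gap alignment,
#' the same counting used for locus-specific difference figures.
#'
#' @param profile an `AmpliconProfile` with at least 2 sequences.
#' @return the profile with `$difference_matrix` set (symmetric integer
#'   matrix, zero diagonal, locus order preserved).
#' @export
difference_matrix <- function(profile) {
  stopifnot(inherits(profile, "AmpliconProfile"))
  seqs <- as.character(profile$sequences)
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 amplicon sequences")
  m <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- count_differences(seqs[i], seqs[j])
      m[i, j] <- d; m[j, i] <- d
    }
  }
  profile$difference_matrix <- m
  profile
}

#' Groups of loci with identical amplicons
#'
#' Connected components of the zero-difference relation; reads from any
#' member can never be assigned uniquely within the amplicon.
#'
#' @param profile an `AmpliconProfile` with a difference matrix.
#' @return list of character vectors (each of length >= 2), possibly empty.
#' @export
indistinguishable_groups <- function(profile) {
  m <- profile$difference_matrix
  if (is.null(m)) stop("run difference_matrix() first")
  ids <- rownames(m)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(m) - 1L)) for (j in seq(i + 1L, nrow(m)))
    if (m[i, j] == 0L) parent[find(j)] <- find(i)
  comp <- vapply(seq_along(ids), find, integer(1))
  out <- split(ids, comp)
  out[vapply(out, length, integer(1)) >= 2L]
}

#' Diagnostic sites of an amplicon profile
#'
#' Builds an implied multiple alignment by aligning every amplicon to the
#' longest one (the anchor) and reports anchor columns at which at least one
#' locus differs from at least one other — the diagnostic nucleotide
#' differences that read assignment exploits. A column where a single locus
#' carries a base no other locus has is flagged `private`.
#'
#' @param profile an `AmpliconProfile` (difference matrix not required but
#'   computed if absent, to report indistinguishable groups).
#' @return the profile with `$diagnostic_sites` set: a list with `anchor`,
#'   `columns` (data.frame column/private), `base_matrix` (locus x column),
#'   and `indistinguishable` (list of locus groups no column separates).
#' @export
diagnostic_sites <- function(profile) {
  stopifnot(inherits(profile, "AmpliconProfile"))
  if (is.null(profile$difference_matrix)) profile <- difference_matrix(profile)
  seqs <- as.character(profile$sequences)
  anchor_i <- which.max(nchar(seqs))
  anchor <- seqs[anchor_i]
  n_col <- nchar(anchor)
  bm <- matrix("-", length(seqs), n_col,
               dimnames = list(names(seqs), NULL))
  bm[anchor_i, ] <- strsplit(anchor, "", fixed = TRUE)[[1]]
  for (i in seq_along(seqs)) {
    if (i == anchor_i) next
    rows <- align_global(seqs[i], anchor)
    cq <- strsplit(rows$pattern, "", fixed = TRUE)[[1]]
    ca <- strsplit(rows$subject, "", fixed = TRUE)[[1]]
    keep <- ca != "-"                      # project onto anchor columns
    bm[i, ] <- cq[keep]
  }
  variable <- vapply(seq_len(n_col), function(j) {
    b <- bm[, j]
    length(unique(b)) > 1L
  }, logical(1))
  cols <- which(variable)
  private <- vapply(cols, function(j) {
    tab <- table(bm[, j])
    sum(tab == 1L) == 1L && length(tab) == 2L
  }, logical(1))
  profile$diagnostic_sites <- list(
    anchor = names(seqs)[anchor_i],
    columns = data.frame(column = cols, private = private),
    base_matrix = bm[, cols, drop = FALSE],
    indistinguishable = indistinguishable_groups(profile))
  profile
}
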