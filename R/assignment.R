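#' Orient an unstranded read against an amplicon profile
#'
#' The cDNA generation strategy is unstranded, so roughly half of all reads
#' arrive reverse-complemented. The orientation minimising the fit distance to
#' any profile amplicon is chosen; ties break toward forward.
#'
#' @param read character or `DNAString` read sequence.
#' @param profile an `AmpliconProfile`.
#' @return list with `sequence` (oriented, character) and `orientation`
#'   (`"forward"` or `"reverse_complement"`).
#' @export
orient_read <- function(read, profile) {
  stopifnot(inherits(profile, "AmpliconProfile"),
            length(profile$sequences) > 0L)
  r <- as.character(read)
  rc <- revcomp_chr(r)
  d_f <- min(vapply(as.character(profile$sequences),
                    function(a) fit_distance(DNAStringSet(r), a),
                    integer(1)))
  d_r <- min(vapply(as.character(profile$sequences),
                    function(a) fit_distance(DNAStringSet(rc), a),
                    integer(1)))
  if (d_r < d_f) list(sequence = rc, orientation = "reverse_complement")
  else list(sequence = r, orientation = "forward")
}

# Distance matrices (reads x loci) for both orientations; shared by
# assign_read and assign_batch. Vectorised over reads per locus.
distance_matrices <- function(reads, profile) {
  amps <- as.character(profile$sequences)
  rset <- as(reads, "DNAStringSet")
  rcset <- Biostrings::reverseComplement(rset)
  d_f <- vapply(amps, function(a) fit_distance(rset, a),
                integer(length(rset)))
  d_r <- vapply(amps, function(a) fit_distance(rcset, a),
                integer(length(rset)))
  if (length(rset) == 1L) {
    d_f <- matrix(d_f, nrow = 1L, dimnames = list(NULL, names(amps)))
    d_r <- matrix(d_r, nrow = 1L, dimnames = list(NULL, names(amps)))
  }
  list(forward = d_f, reverse = d_r)
}

# Core per-read decision given its two distance vectors.
decide_assignment <- function(dv_f, dv_r, read_len, amp_lens,
                              margin, max_distance) {
  loci <- names(dv_f)
  # length window: 0.5x - 1.5x of the amplicon length range
  if (read_len < 0.5 * min(amp_lens) || read_len > 1.5 * max(amp_lens)) {
    return(list(orientation = "forward", best_loci = character(0),
                distance = NA_integer_, second_distance = NA_integer_,
                status = "unassigned", reason = "length"))
  }
  use_rev <- min(dv_r) < min(dv_f)      # ties break toward forward
  dv <- if (use_rev) dv_r else dv_f
  o <- order(dv)
  best <- dv[o[1]]
  best_loci <- loci[dv <= best + margin]
  second <- if (length(dv) > 1L) sort(dv)[2] else NA_integer_
  ceiling_d <- max_distance * amp_lens[o[1]]
  if (best > ceiling_d) {
    status <- "unassigned"; reason <- "distance"; best_loci <- character(0)
  } else if (length(best_loci) == 1L) {
    status <- "unique"; reason <- NA_character_
  } else {
    status <- "ambiguous"; reason <- NA_character_
  }
  list(orientation = if (use_rev) "reverse_complement" else "forward",
       best_loci = best_loci, distance = as.integer(best),
       second_distance = as.integer(second), status = status,
       reason = reason)
}

#' Assign one cDNA read to its most likely source locus
#'
#' The read (in its better orientation) is compared to every per-locus
#' amplicon by fit edit distance. All loci within `margin` of the minimum form
#' the best set: a single member is a unique call, several members an
#' ambiguous call (reported as a composite category), and a minimum above
#' `max_distance` x amplicon length is unassigned. Reads outside 0.5-1.5x of
#' the amplicon length range are unassigned with reason `"length"`.
#'
#' @param read character or `DNAString`.
#' @param profile an `AmpliconProfile`.
#' @param margin distance slack defining the ambiguity set (default 0,
#'   i.e. strict ties only).
#' @param max_distance ceiling as a fraction of the best amplicon's length
#'   (default 0.05, absorbing Sanger/PCR error).
#' @param read_id identifier carried into the result.
#' @return a one-row data.frame: `read_id`, `orientation`, `status`
#'   (`unique`/`ambiguous`/`unassigned`), `loci` (composite `"a|b"` for
#'   ambiguous calls), `distance`, `second_distance`, `reason`.
#' @export
assign_read <- function(read, profile, margin = 0L, max_distance = 0.05,
                        read_id = "read") {
  stopifnot(inherits(profile, "AmpliconProfile"),
            length(profile$sequences) > 0L)
  dm <- distance_matrices(DNAStringSet(as.character(read)), profile)
  amp_lens <- Biostrings::width(profile$sequences)
  names(amp_lens) <- names(profile$sequences)
  dec <- decide_assignment(dm$forward[1, ], dm$reverse[1, ],
                           nchar(as.character(read)), amp_lens,
                           margin, max_distance)
  data.frame(read_id = read_id,
             orientation = dec$orientation,
             status = dec$status,
             loci = if (length(dec$best_loci))
               paste(sort(dec$best_loci), collapse = "|") else "unassigned",
             distance = dec$distance,
             second_distance = dec$second_distance,
             reason = dec$reason,
             stringsAsFactors = FALSE)
}

#' Assign a batch of reads and summarise counts
#'
#' Vectorised application of the [assign_read()] decision rule to a read set,
#' with per-category summary counts (unique loci, composite ambiguous groups,
#' unassigned).
#'
#' @param reads named `DNAStringSet` (or character vector) of reads.
#' @param profile an `AmpliconProfile`.
#' @inheritParams assign_read
#' @return list with `assignments` (one row per read, as in [assign_read()])
#'   and `summary` (data.frame `category`, `n`).
#' @export
assign_batch <- function(reads, profile, margin = 0L, max_distance = 0.05) {
  stopifnot(inherits(profile, "AmpliconProfile"))
  reads <- as(reads, "DNAStringSet")
  if (length(reads) == 0L)
    return(list(assignments = data.frame(read_id = character(0),
                                         orientation = character(0),
                                         status = character(0),
                                         loci = character(0),
                                         distance = integer(0),
                                         second_distance = integer(0),
                                         reason = character(0)),
                summary = data.frame(category = character(0), n = integer(0))))
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%05d", seq_along(reads))
  dm <- distance_matrices(reads, profile)
  amp_lens <- Biostrings::width(profile$sequences)
  names(amp_lens) <- names(profile$sequences)
  read_lens <- Biostrings::width(reads)
  rows <- lapply(seq_along(reads), function(i) {
    dec <- decide_assignment(dm$forward[i, ], dm$reverse[i, ],
                             read_lens[i], amp_lens, margin, max_distance)
    data.frame(read_id = names(reads)[i],
               orientation = dec$orientation,
               status = dec$status,
               loci = if (length(dec$best_loci))
                 paste(sort(dec$best_loci), collapse = "|") else "unassigned",
               distance = dec$distance,
               second_distance = dec$second_distance,
               reason = dec$reason,
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  tab <- table(assignments$loci)
  summary <- data.frame(category = names(tab), n = as.integer(tab),
                        stringsAsFactors = FALSE)
  summary <- summary[order(-summary$n), , drop = FALSE]
  rownames(summary) <- NULL
  list(assignments = assignments, summary = summary)
}

#' Write read assignments to a TSV file
#'
#' @param assignments data.frame from [assign_batch()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
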