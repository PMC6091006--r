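#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   readDNAStringSet writeXStringSet reverseComplement pairwiseAlignment
#'   alignedPattern alignedSubject score subject pattern translate subseq
#'   matchPattern vcountPattern nucleotideSubstitutionMatrix pid
#' @importFrom IRanges IRanges start end width
#' @importFrom stats lm p.adjust rmultinom rnorm runif sd setNames shapiro.test
#'   t.test var wilcox.test
#' @importFrom utils head read.delim write.table packageVersion
NULL

# Unit-cost substitution matrix over the ACGTN alphabet: match 0, mismatch -1.
# With gapOpening = 0 and gapExtension = 1 the negated pairwiseAlignment score
# is an edit distance. N is treated as a mismatch against everything
# (including N): an undetermined base never supplies evidence for a locus.
unit_cost_matrix <- function() {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(-1L, 5L, 5L, dimnames = list(ab, ab))
  diag(m) <- 0L
  m["N", "N"] <- -1L
  m
}

# Scoring used for difference counting and feature location: match +1,
# mismatch -1, affine gaps (open -5, extend -1) so a long indel stays one run.
diff_count_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

#' Fit-alignment distance of reads against one amplicon
#'
#' Semi-global ("fit") edit distance: the read is aligned end-to-end while the
#' amplicon may overhang freely on either side, so a truncated Sanger read is
#' not penalised for the amplicon portion it never covered. Unit costs
#' (substitution 1, gap position 1).
#'
#' @param reads a `DNAStringSet` (or coercible) of reads, all in the
#'   orientation to be scored.
#' @param amplicon a single `DNAString`/character amplicon sequence.
#' @return integer vector of distances, one per read.
#' @keywords internal
fit_distance <- function(reads, amplicon) {
  reads <- as(reads, "DNAStringSet")
  aln <- Biostrings::pairwiseAlignment(
    reads, DNAString(as.character(amplicon)),
    type = "global-local",
    substitutionMatrix = unit_cost_matrix(),
    gapOpening = 0, gapExtension = 1,
    scoreOnly = TRUE)
  as.integer(round(-aln))
}

# Global affine alignment of two sequences; returns the two gapped rows.
align_global <- function(x, y, gap_opening = 5, gap_extension = 1) {
  aln <- Biostrings::pairwiseAlignment(
    DNAString(as.character(x)), DNAString(as.character(y)),
    type = "global",
    substitutionMatrix = diff_count_matrix(),
    gapOpening = gap_opening, gapExtension = gap_extension)
  list(pattern = as.character(Biostrings::alignedPattern(aln)),
       subject = as.character(Biostrings::alignedSubject(aln)),
       aln = aln)
}

# Count substitutions and indel events from two gapped alignment rows.
# A contiguous gap run (in either row, terminal runs included) counts as ONE
# event, so the 292-bp type-1/type-2 indel contributes a single difference.
alignment_events <- function(row_x, row_y) {
  cx <- strsplit(row_x, "", fixed = TRUE)[[1]]
  cy <- strsplit(row_y, "", fixed = TRUE)[[1]]
  gap_x <- cx == "-"
  gap_y <- cy == "-"
  n_sub <- sum(!gap_x & !gap_y & cx != cy)
  run_count <- function(g) {
    r <- rle(g)
    sum(r$values)
  }
  n_indel <- run_count(gap_x) + run_count(gap_y)
  list(n_sub = n_sub, n_indel = n_indel, total = n_sub + n_indel)
}

#' Count nucleotide differences between two sequences
#'
#' Substitutions plus indel events (one event per contiguous gap run) in a
#' global pairwise alignment with affine gap costs.
#'
#' @param x,y nucleotide sequences (character or `DNAString`).
#' @return integer difference count.
#' @export
count_differences <- function(x, y) {
  if (as.character(x) == as.character(y)) return(0L)
  rows <- align_global(x, y)
  as.integer(alignment_events(rows$pattern, rows$subject)$total)
}

# Reverse-complement a character sequence.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(DNAString(x)))
}

# Map positions between a gapped alignment's two rows: returns, for every
# ungapped position of row_y (the subject), the ungapped position in row_x
# (the pattern) aligned to it, or NA at pattern gaps.
subject_to_pattern_map <- function(row_x, row_y) {
  cx <- strsplit(row_x, "", fixed = TRUE)[[1]]
  cy <- strsplit(row_y, "", fixed = TRUE)[[1]]
  px <- cumsum(cx != "-")
  keep <- cy != "-"
  out <- ifelse(cx[keep] == "-", NA_integer_, px[keep])
  as.integer(out)
}

# Draw one element; unlike sample(), never treats a length-1 vector as 1:n.
sample_one <- function(x) x[sample.int(length(x), 1L)]
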