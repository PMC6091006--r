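#' Locus registry: the catalogue of HML-2 proviral loci
#'
#' A `LocusRegistry` bundles the nucleotide sequences of reference and
#' non-reference HERV-K(HML-2) loci with their metadata (chromosomal anchor,
#' provirus type, provenance). All downstream stages — in-silico amplicon
#' extraction, read assignment, splice inference, coding prediction — resolve
#' loci through the registry, so every locus id appearing in any output table
#' is guaranteed to map back to a sequence.
#'
#' @param sequences named `DNAStringSet` of locus sequences.
#' @param metadata data.frame with columns `locus_id`, `assembly`, `chrom`,
#'   `anchor_pos`, `strand`, `provirus_type`, `provenance` and optionally
#'   `notes`.
#' @param canonical_env_reference locus id of the full-length Env donor.
#' @return an object of class `LocusRegistry`.
#' @export
locus_registry <- function(sequences, metadata,
                           canonical_env_reference = NULL) {
  stopifnot(is.data.frame(metadata))
  sequences <- as(sequences, "DNAStringSet")
  if (length(sequences) == 0L) stop("no records: registry must contain at least one locus")
  req <- c("locus_id", "assembly", "chrom", "anchor_pos", "strand",
           "provirus_type", "provenance")
  missing_cols <- setdiff(req, names(metadata))
  if (length(missing_cols))
    stop("metadata is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"notes" %in% names(metadata)) metadata$notes <- ""
  metadata$notes[is.na(metadata$notes)] <- ""

  ids_seq <- names(sequences)
  if (is.null(ids_seq) || anyNA(ids_seq) || any(ids_seq == ""))
    stop("every sequence must carry a locus identifier")
  no_meta <- setdiff(ids_seq, metadata$locus_id)
  if (length(no_meta))
    stop("no metadata row for sequence identifier(s): ",
         paste(no_meta, collapse = ", "))
  no_seq <- setdiff(metadata$locus_id, ids_seq)
  if (length(no_seq))
    stop("no sequence for metadata locus_id(s): ",
         paste(no_seq, collapse = ", "))
  if (anyDuplicated(ids_seq))
    stop("duplicate locus_id in registry: ",
         paste(unique(ids_seq[duplicated(ids_seq)]), collapse = ", "))

  bad <- vapply(as.character(sequences),
                function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad))
    stop("invalid alphabet (only A/C/G/T/N allowed) in: ",
         paste(ids_seq[bad], collapse = ", "))
  if (any(Biostrings::width(sequences) == 0L))
    stop("zero-length sequence in registry")

  metadata <- metadata[match(ids_seq, metadata$locus_id), , drop = FALSE]
  rownames(metadata) <- NULL
  metadata$anchor_pos <- as.integer(metadata$anchor_pos)
  if (any(!is.na(metadata$anchor_pos) & metadata$anchor_pos < 1L))
    stop("anchor_pos must be >= 1 (1-based anchor coordinate)")
  metadata$strand <- as.character(metadata$strand)
  if (!all(metadata$strand %in% c("+", "-", "unknown")))
    stop("strand must be one of '+', '-', 'unknown'")
  metadata$provirus_type <- as.character(metadata$provirus_type)
  if (!all(metadata$provirus_type %in% c("1", "2", "unknown")))
    stop("provirus_type must be one of '1', '2', 'unknown'")
  if (!all(metadata$provenance %in% c("reference", "non_reference", "retrocopy")))
    stop("provenance must be reference, non_reference or retrocopy")

  if (!is.null(canonical_env_reference) &&
      !canonical_env_reference %in% ids_seq)
    stop("canonical_env_reference '", canonical_env_reference,
         "' does not resolve in the registry")

  structure(list(sequences = sequences,
                 metadata = metadata,
                 canonical_env_reference = canonical_env_reference),
            class = "LocusRegistry")
}

#' Load a locus registry from FASTA + metadata files
#'
#' @param sequence_file path to a multi-FASTA of locus sequences; record ids
#'   (first whitespace-delimited token) are the locus ids.
#' @param metadata_file path to a tab-separated metadata table with a header
#'   line (`locus_id`, `assembly`, `chrom`, `anchor_pos`, `strand`,
#'   `provirus_type`, `provenance`, optional `notes`). CRLF line endings and
#'   trailing whitespace are tolerated.
#' @param canonical_env_reference locus id of the canonical full-length Env
#'   donor, if present in the registry.
#' @return a `LocusRegistry`.
#' @export
load_registry <- function(sequence_file, metadata_file,
                          canonical_env_reference = NULL) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(sequence_file),
                   error = function(e) stop("could not read FASTA '",
                                            sequence_file, "': ",
                                            conditionMessage(e)))
  if (length(seqs) == 0L) stop("no records in FASTA '", sequence_file, "'")
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  lines <- readLines(metadata_file, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  lines <- lines[nzchar(lines)]
  meta <- utils::read.delim(text = paste(lines, collapse = "\n"),
                            stringsAsFactors = FALSE)
  locus_registry(seqs, meta,
                 canonical_env_reference = canonical_env_reference)
}

#' Write a locus registry back to FASTA + metadata files
#'
#' Round-trips byte-identically with [load_registry()]: sequences are written
#' unwrapped so re-reading reproduces them exactly.
#'
#' @param registry a `LocusRegistry`.
#' @param sequence_file,metadata_file output paths.
#' @return invisibly, the registry.
#' @export
write_registry <- function(registry, sequence_file, metadata_file) {
  stopifnot(inherits(registry, "LocusRegistry"))
  Biostrings::writeXStringSet(registry$sequences, sequence_file,
                              width = 20000L)
  utils::write.table(registry$metadata, metadata_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(registry)
}

#' Retrieve one locus record
#'
#' Lookup is exact (case-sensitive); an unknown id raises an error listing
#' near matches to help catch typos in hand-edited tables.
#'
#' @param registry a `LocusRegistry`.
#' @param locus_id exact locus identifier.
#' @return a list with the metadata fields plus `sequence` (character).
#' @export
get_locus <- function(registry, locus_id) {
  stopifnot(inherits(registry, "LocusRegistry"))
  i <- match(locus_id, registry$metadata$locus_id)
  if (is.na(i)) {
    near <- agrep(locus_id, registry$metadata$locus_id,
                  max.distance = 0.3, ignore.case = TRUE, value = TRUE)
    stop("unknown locus_id '", locus_id, "'",
         if (length(near)) paste0("; did you mean: ",
                                  paste(utils::head(near, 5), collapse = ", "))
         else "")
  }
  rec <- as.list(registry$metadata[i, , drop = FALSE])
  rec$sequence <- as.character(registry$sequences[[i]])
  rec
}

#' @export
print.LocusRegistry <- function(x, ...) {
  tab <- table(x$metadata$provenance)
  cat("LocusRegistry with", nrow(x$metadata), "loci (",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n")
  cat("  provirus types:",
      paste(sprintf("type %s: %d", names(table(x$metadata$provirus_type)),
                    as.integer(table(x$metadata$provirus_type))),
            collapse = ", "), "\n")
  if (!is.null(x$canonical_env_reference))
    cat("  canonical Env reference:", x$canonical_env_reference, "\n")
  invisible(x)
}

#' Cross-check stored provirus types against sequence-derived calls
#'
#' For every locus whose amplicon covers the env 5' indel region, re-derives
#' the type with [classify_provirus_type()] and warns on disagreement with the
#' stored `provirus_type`.
#'
#' @param registry a `LocusRegistry`.
#' @param reference_type2 a type-2 env 5' region reference sequence carrying
#'   an `indel_segment` attribute (see [classify_provirus_type()]).
#' @param region optional function mapping a locus sequence to its env 5'
#'   region (defaults to the whole sequence).
#' @return data.frame of locus_id, stored and derived type, consistent flag.
#' @export
check_provirus_types <- function(registry, reference_type2,
                                 region = identity) {
  stopifnot(inherits(registry, "LocusRegistry"))
  ids <- registry$metadata$locus_id
  derived <- vapply(seq_along(ids), function(i) {
    seq_i <- region(as.character(registry$sequences[[i]]))
    tryCatch(as.character(classify_provirus_type(seq_i, reference_type2)),
             error = function(e) "unknown")
  }, character(1))
  out <- data.frame(locus_id = ids,
                    stored = registry$metadata$provirus_type,
                    derived = derived,
                    stringsAsFactors = FALSE)
  out$consistent <- out$stored == out$derived |
    out$stored == "unknown" | out$derived == "unknown"
  if (any(!out$consistent))
    warning("provirus_type disagrees with sequence-derived call for: ",
            paste(out$locus_id[!out$consistent], collapse = ", "))
  out
}
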