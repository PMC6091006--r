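test_that("contiguous reads yield no introns; excised introns are recovered", {
  fam <- small_family()
  t2 <- names(fam$truth$types)[fam$truth$types == "2" &
    fam$truth$provenance == "reference"][1]
  locus <- get_locus(fam$registry, t2)$sequence
  ly <- fam$layout
  # contiguous substring -> zero introns
  r0 <- substr(locus, ly$env_start, ly$env_start + 500L)
  iv0 <- spliced_align(r0, locus)
  expect_equal(nrow(iv0), 0L)
  # construction inverse: excising the rec intron recovers it exactly
  sr <- simulate_splice_read(fam, t2, "rec")
  iv <- spliced_align(sr$sequence, locus)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$donor_pos, ly$sd2)
  expect_equal(iv$acceptor_pos, ly$sa2)
  expect_identical(iv$donor_dinucleotide, "GT")
  expect_identical(iv$acceptor_dinucleotide, "AG")
})

test_that("boundary refinement lands on GT..AG among shift-equivalent placements", {
  fam <- small_family()
  t2 <- names(fam$truth$types)[fam$truth$types == "2" &
    fam$truth$provenance == "reference"][1]
  locus <- get_locus(fam$registry, t2)$sequence
  ly <- fam$layout
  sr <- simulate_splice_read(fam, t2, "rec")
  iv <- spliced_align(sr$sequence, locus, prefer_acceptor = ly$sa2)
  # exhaustive boundary search: enumerate every mRNA-equivalent placement in
  # the +/-10 window; the reported one must be the GT..AG solution
  d <- iv$donor_pos; a <- iv$acceptor_pos
  equivalents <- Filter(function(s) {
    if (s == 0) return(TRUE)
    if (s > 0) substr(locus, d, d + s - 1) == substr(locus, a + 1, a + s)
    else substr(locus, d + s, d - 1) == substr(locus, a + s + 1, a)
  }, -10:10)
  canonical <- Filter(function(s) {
    substr(locus, d + s, d + s + 1) == "GT" &&
      substr(locus, a + s - 1, a + s) == "AG"
  }, equivalents)
  expect_true(0 %in% canonical)   # the reported placement is canonical
  expect_true(iv$refined)
})

test_that("transcript classification matches every planted variant", {
  fam <- small_family()
  t2 <- names(fam$truth$types)[fam$truth$types == "2" &
    fam$truth$provenance == "reference"][1]
  t1 <- names(fam$truth$types)[fam$truth$types == "1" &
    fam$truth$provenance == "reference"][1]
  cases <- list(
    list(locus = t2, variant = "rec", class = "rec", offset = 0L),
    list(locus = t1, variant = "np9", class = "np9", offset = 0L),
    list(locus = t2, variant = "np9_like_alternative",
         class = "np9_like_alternative", offset = 260L),
    list(locus = "synK-NR1", variant = "np9_mut_acceptor",
         class = "np9", offset = 7L),
    list(locus = "synK-retro", variant = "unspliced",
         class = "unspliced", offset = NA_integer_))
  for (cs in cases) {
    sr <- simulate_splice_read(fam, cs$locus, cs$variant)
    locus <- get_locus(fam$registry, cs$locus)$sequence
    ann <- fam$annotations[fam$annotations$locus_id == cs$locus, ]
    iv <- spliced_align(sr$sequence, locus, prefer_acceptor = ann$sa2)
    call <- classify_transcript(iv, ann, fam$truth$types[[cs$locus]])
    expect_identical(call$transcript_class, cs$class)
    expect_equal(call$acceptor_offset, cs$offset)
    # every intron of a classified transcript obeys the GT..AG rule
    if (!is.null(iv) && nrow(iv) && call$transcript_class != "unknown") {
      expect_true(all(iv$donor_dinucleotide == "GT"))
      expect_true(all(iv$acceptor_dinucleotide == "AG"))
    }
    # canonical acceptor <=> zero offset
    if (!is.na(call$acceptor_offset))
      expect_identical(call$acceptor_offset == 0L,
                       call$acceptor_pos == ann$sa2)
  }
})

test_that("classification is deterministic and annotation-gated", {
  fam <- small_family()
  t2 <- names(fam$truth$types)[fam$truth$types == "2" &
    fam$truth$provenance == "reference"][1]
  sr <- simulate_splice_read(fam, t2, "rec")
  locus <- get_locus(fam$registry, t2)$sequence
  ann <- fam$annotations[fam$annotations$locus_id == t2, ]
  iv <- spliced_align(sr$sequence, locus)
  c1 <- classify_transcript(iv, ann, "2")
  c2 <- classify_transcript(iv, ann, "2")
  expect_identical(c1, c2)
  # missing required sites -> unknown with reason
  ann_na <- ann; ann_na$sa2 <- NA_integer_
  u <- classify_transcript(iv, ann_na, "2")
  expect_identical(u$transcript_class, "unknown")
  expect_match(u$reason, "missing")
  # SD2 -> SA2 on a non-type-2 locus cannot be rec
  expect_identical(classify_transcript(iv, ann, "1")$transcript_class,
                   "unknown")
})

test_that("splice annotations round-trip through the TSV interface", {
  fam <- small_family()
  path <- tempfile(fileext = ".tsv")
  write.table(fam$annotations, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_splice_annotations(path)
  expect_equal(back$sa2, fam$annotations$sa2)
  expect_equal(back$locus_id, fam$annotations$locus_id)
})

test_that("length-based fallback separates rec- from np9-typical products", {
  fam <- small_family()
  t2 <- names(fam$truth$types)[fam$truth$types == "2" &
    fam$truth$provenance == "reference"][1]
  t1 <- names(fam$truth$types)[fam$truth$types == "1" &
    fam$truth$provenance == "reference"][1]
  rec_len <- nchar(simulate_splice_read(fam, t2, "rec")$sequence)
  np9_len <- nchar(simulate_splice_read(fam, t1, "np9")$sequence)
  expect_identical(classify_by_length(rec_len), "rec_typical_length")
  expect_identical(classify_by_length(np9_len), "np9_typical_length")
})
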