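test_that("match_primers finds planted sites and honours the mismatch budget", {
  set.seed(5)
  fwd <- "ACGTACGTACGTACGTACGT"
  rev <- "TGCATGCATGCATGCATGCA"   # primer 5'->3'; site = its revcomp
  site <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  mid <- paste(sample(c("A","C","G","T"), 600, replace = TRUE), collapse = "")
  locus <- paste0(strrep("C", 50), fwd, mid, site, strrep("A", 50))
  ps <- primer_set("toy", fwd, rev, max_mismatches = 0L)
  iv <- match_primers(locus, ps)
  plus <- iv[iv$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$length, 600L + 2L * 20L)
  expect_equal(plus$start, 51L)

  # one mismatch in the forward site: found at max_mismatches 1, not at 0
  locus1 <- locus
  substr(locus1, 55, 55) <- if (substr(locus1, 55, 55) == "A") "C" else "A"
  expect_equal(nrow(match_primers(locus1, ps)[
    match_primers(locus1, ps)$strand == "+", ]), 0L)
  ps1 <- primer_set("toy", fwd, rev, max_mismatches = 1L)
  iv1 <- match_primers(locus1, ps1)
  expect_equal(nrow(iv1[iv1$strand == "+", ]), 1L)
})

test_that("match_primers equals the brute-force sliding-window oracle", {
  set.seed(99)
  fwd <- c("GATTACAGATTACAGATT", "CCGGAACCGGTTAACCGG")
  rev <- c("TTAACCGGTTAACCGGTT", "ACACACGTGTGTACACGT")
  ps <- primer_set("mix", fwd, rev, max_mismatches = 1L)
  for (rep in 1:12) {
    s <- paste(sample(c("A","C","G","T"), 2000, replace = TRUE),
               collapse = "")
    # plant a pair on a random strand in half the cases
    if (rep %% 2 == 0) {
      f <- sample(fwd, 1)
      rsite <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(sample(rev, 1))))
      pos <- sample(200:800, 1)
      substr(s, pos, pos + nchar(f) - 1) <- f
      substr(s, pos + 900, pos + 900 + nchar(rsite) - 1) <- rsite
    }
    got <- match_primers(s, ps)[, c("start", "end", "strand")]
    want <- oracle_match_primers(s, ps)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("extract_amplicons covers all intact loci and reports absences", {
  fam <- small_family()
  prof <- small_profile()
  amplified <- names(prof$sequences)
  with_gag <- setdiff(fam$registry$metadata$locus_id, "synK-retro")
  expect_setequal(amplified, with_gag)
  expect_true("synK-retro" %in% prof$absent$locus_id)
  expect_match(prof$absent$reason[prof$absent$locus_id == "synK-retro"],
               "no forward primer match")

  # deleting the planted forward site drops the locus with that reason
  reg2 <- fam$registry
  ly <- fam$layout
  s <- as.character(reg2$sequences[["synK-01"]])
  s <- paste0(substr(s, 1, ly$gag_fwd[1] - 1L),
              substr(s, ly$gag_fwd[2] + 1L, nchar(s)))
  reg2$sequences[["synK-01"]] <- Biostrings::DNAString(s)
  prof2 <- extract_amplicons(reg2, gag_definition(fam))
  expect_true("synK-01" %in% prof2$absent$locus_id)
})

test_that("type-1 and type-2 env600nt products differ by the 292-bp indel", {
  fam <- small_family()
  env_def <- amplicon_definition(
    "env600nt",
    primer_set("env600nt", fam$primers$env600nt$forward,
               fam$primers$env600nt$reverse, max_mismatches = 1L),
    expected_lengths = list("1" = c(300L, 360L), "2" = c(590L, 650L)))
  prof <- extract_amplicons(fam$registry, env_def)
  w <- Biostrings::width(prof$sequences)
  names(w) <- names(prof$sequences)
  types <- fam$truth$types[names(w)]
  expect_equal(unique(w[types == "2" & names(w) != "synK-retro"]) -
                 unique(w[types == "1"]), 292L)
})

test_that("classify_provirus_type distinguishes the 292-bp indel", {
  fam <- small_family()
  ref <- env_region_reference(fam)
  seg <- attr(ref, "indel_segment")
  expect_identical(classify_provirus_type(ref, ref), "2")
  cut <- function(s, from, to)
    paste0(substr(s, 1, from - 1), substr(s, to + 1, nchar(s)))
  q1 <- cut(ref, seg[1], seg[2])
  expect_identical(classify_provirus_type(q1, ref), "1")
  # 300-nt deletion (8 nt of extra flank) is still type 1; 320 nt is unknown
  q300 <- cut(ref, seg[1] - 8, seg[2])
  expect_identical(classify_provirus_type(q300, ref), "1")
  q320 <- cut(ref, seg[1] - 28, seg[2])
  expect_identical(classify_provirus_type(q320, ref), "unknown")
  expect_error(classify_provirus_type(substr(ref, 1, 80), ref), "too short")
  # reinserting the segment flips the call back
  q2 <- paste0(substr(q1, 1, seg[1] - 1),
               substr(ref, seg[1], seg[2]),
               substr(q1, seg[1], nchar(q1)))
  expect_identical(classify_provirus_type(q2, ref), "2")
})

test_that("difference counting: substitutions plus one event per gap run", {
  set.seed(7)
  x <- paste(sample(c("A","C","G","T"), 600, replace = TRUE), collapse = "")
  expect_equal(count_differences(x, x), 0L)
  # plant 3 substitutions and one 292-nt deletion -> 4 differences
  y <- x
  for (p in c(50L, 150L, 250L))
    substr(y, p, p) <- setdiff(c("A","C","G","T"), substr(y, p, p))[1]
  y <- paste0(substr(y, 1, 299), substr(y, 592, nchar(y)))
  expect_equal(count_differences(x, y), 4L)
  # planted-substitution oracle on random pairs
  for (k in c(1L, 5L, 17L)) {
    z <- x
    pos <- sample(10:590, k)
    for (p in pos)
      substr(z, p, p) <- setdiff(c("A","C","G","T"), substr(z, p, p))[1]
    expect_equal(count_differences(x, z), k)
    expect_equal(count_differences(z, x), k)  # symmetry
  }
})

test_that("difference matrix is symmetric, zero-diagonal, zero iff identical", {
  prof <- small_profile()
  m <- prof$difference_matrix
  expect_true(all(m == t(m)))
  expect_true(all(diag(m) == 0L))
  seqs <- as.character(prof$sequences)
  for (i in seq_len(nrow(m) - 1L)) for (j in seq(i + 1L, nrow(m)))
    expect_identical(unname(m[i, j] == 0L),
                     unname(seqs[i] == seqs[j]))
  # matrix entries equal planted substitution counts for same-type pairs
  fam <- small_family()
  tr <- fam$truth$substitutions
  ids <- sprintf("synK-%02d", 1:4)
  for (a in ids) for (b in ids) {
    if (a >= b) next
    if (fam$truth$types[[a]] != fam$truth$types[[b]]) next
    pa <- tr[tr$locus_id == a, ]; pb <- tr[tr$locus_id == b, ]
    shared <- intersect(pa$position, pb$position)
    # differences = positions where the two amplicons disagree
    want <- length(setdiff(pa$position, pb$position)) +
      length(setdiff(pb$position, pa$position)) +
      sum(pa$alt_base[match(shared, pa$position)] !=
            pb$alt_base[match(shared, pb$position)])
    expect_equal(m[a, b], want)
  }
})

test_that("diagnostic sites flag private bases and indistinguishable pairs", {
  # 3 loci with one private substitution each -> 3 private columns
  set.seed(11)
  base <- paste(sample(c("A","C","G","T"), 200, replace = TRUE), collapse = "")
  mk <- function(p) {
    s <- base
    substr(s, p, p) <- setdiff(c("A","C","G","T"), substr(s, p, p))[1]
    s
  }
  seqs <- Biostrings::DNAStringSet(c(a = mk(20), b = mk(100), c = mk(180)))
  prof <- structure(list(amplicon = NULL, sequences = seqs,
                         absent = data.frame(), difference_matrix = NULL,
                         diagnostic_sites = NULL),
                    class = "AmpliconProfile")
  prof <- diagnostic_sites(prof)
  ds <- prof$diagnostic_sites
  expect_equal(ds$columns$column, c(20L, 100L, 180L))
  expect_true(all(ds$columns$private))
  # brute-force column scan agrees (all sequences same length, ungapped)
  bm <- sapply(as.character(seqs), function(s) strsplit(s, "")[[1]])
  brute <- which(apply(bm, 1, function(r) length(unique(r)) > 1))
  expect_equal(ds$columns$column, brute)

  # the identical pair in the family profile is reported as indistinguishable
  prof2 <- small_profile()
  groups <- prof2$diagnostic_sites$indistinguishable
  expect_equal(length(groups), 1L)
  expect_setequal(groups[[1]], c("synK-05", "synK-06"))
})
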