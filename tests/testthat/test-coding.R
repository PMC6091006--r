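test_that("protein_mass matches an independent average-mass calculation", {
  # water only
  expect_equal(protein_mass(""), 0.0180153, tolerance = 1e-4)
  # glycine + water
  expect_equal(protein_mass("G"), 0.0750667, tolerance = 1e-4)
  # 20-residue panel, frozen from an independent residue-mass summation
  expect_equal(protein_mass("ACDEFGHIKLMNPQRSTVWY"), 2.3957174,
               tolerance = 1e-4)
  expect_error(protein_mass("GBZ"), "unknown residue")
  # strictly increasing in length for fixed composition
  expect_lt(protein_mass("GGG"), protein_mass("GGGG"))
})

test_that("canonical type-2 locus yields one 699-aa full-length Env ORF", {
  fam <- small_family()
  canon <- get_locus(fam$registry,
                     fam$registry$canonical_env_reference)$sequence
  orfs <- scan_env_orfs(canon, fam$references$env_cds, provirus_type = "2")
  fl <- orfs[orfs$class == "full_length_env", ]
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$aa_length, 699L)
  expect_equal(fl$start_aa, 1L)
  expect_equal(fl$end_aa, 699L)
  # translation oracle: reported aa equals re-translation of the nt span
  nt <- substr(canon, fl$nt_start, fl$nt_end)
  expect_identical(
    as.character(Biostrings::translate(Biostrings::DNAString(nt))),
    fl$aa_sequence)
  # non-extendable: codon before the start is a stop (or boundary)
  pre <- substr(canon, fl$nt_start - 3L, fl$nt_start - 1L)
  expect_true(pre %in% c("TAA", "TAG", "TGA"))
  post <- substr(canon, fl$nt_end + 1L, fl$nt_end + 3L)
  expect_true(post %in% c("TAA", "TAG", "TGA"))
})

test_that("a premature stop at Env codon 264 leaves a 263-aa SU/OM-class fragment", {
  fam <- small_family()
  ly <- fam$layout
  canon <- get_locus(fam$registry,
                     fam$registry$canonical_env_reference)$sequence
  from <- ly$env_start + 3L * 263L
  substr(canon, from, from + 2L) <- "TAA"
  orfs <- scan_env_orfs(canon, fam$references$env_cds, provirus_type = "2")
  frag <- orfs[orfs$nt_start == ly$env_start, ]
  expect_equal(frag$aa_length, 263L)
  expect_false(frag$class == "full_length_env")
  expect_true(grepl("SU_OM", frag$class))
})

test_that("an upstream in-frame extension is reported as a Pro-Env fusion", {
  fam <- small_family()
  ly <- fam$layout
  canon <- get_locus(fam$registry,
                     fam$registry$canonical_env_reference)$sequence
  # open the frame upstream: replace the pre-env stop and the 267 upstream
  # codons with sense codons, in frame with the env CDS
  up_start <- ly$env_start - 3L * 270L
  set.seed(1)
  sense <- paste(rep("GCA", 270), collapse = "")
  substr(canon, up_start, ly$env_start - 1L) <- sense
  orfs <- scan_env_orfs(canon, fam$references$env_cds, provirus_type = "2")
  fusion <- orfs[orfs$class == "pol_env_fusion", ]
  expect_gte(nrow(fusion), 1L)
  expect_gte(max(fusion$aa_length), 699L + 200L)
})

test_that("full_length_env is reported only for type-2 loci", {
  fam <- small_family()
  canon <- get_locus(fam$registry,
                     fam$registry$canonical_env_reference)$sequence
  orfs1 <- scan_env_orfs(canon, fam$references$env_cds, provirus_type = "1")
  expect_false(any(orfs1$class == "full_length_env"))
  t1 <- names(fam$truth$types)[fam$truth$types == "1" &
    fam$truth$provenance == "reference"][1]
  s1 <- get_locus(fam$registry, t1)$sequence
  orfs_t1 <- scan_env_orfs(s1, fam$references$env_cds, provirus_type = "1")
  expect_false(any(orfs_t1$class == "full_length_env"))
})

test_that("domain annotation yields SP/SU/TM products with plausible masses", {
  fam <- small_family()
  canon <- get_locus(fam$registry,
                     fam$registry$canonical_env_reference)$sequence
  orfs <- scan_env_orfs(canon, fam$references$env_cds, provirus_type = "2")
  fl <- orfs[orfs$class == "full_length_env", ][1, ]
  pr <- annotate_domains(fl)
  expect_equal(pr$product, c("SP", "SU_OM", "TM"))
  expect_equal(pr$end_aa[pr$product == "SP"], 96L)
  # TM of a full-length Env is approx. 26 kDa (15% band)
  tm <- pr$predicted_mass_kDa[pr$product == "TM"]
  expect_lt(abs(tm - 26) / 26, 0.15)
  # an ORF spanning aa 120-436 gives a single SU/OM-overlap product, no SP
  mid <- fl
  mid$start_aa <- 120L; mid$end_aa <- 436L
  mid$aa_sequence <- substr(fl$aa_sequence, 120L, 436L)
  pr2 <- annotate_domains(mid)
  expect_equal(pr2$product, "SU_OM")
})

test_that("spliced-protein prediction recovers Rec, Np9, truncations and stops", {
  fam <- small_family()
  t2 <- names(fam$truth$types)[fam$truth$types == "2" &
    fam$truth$provenance == "reference"][1]
  t1 <- names(fam$truth$types)[fam$truth$types == "1" &
    fam$truth$provenance == "reference"][1]
  run <- function(locus, variant) {
    sr <- simulate_splice_read(fam, locus, variant)
    seq <- get_locus(fam$registry, locus)$sequence
    ann <- fam$annotations[fam$annotations$locus_id == locus, ]
    iv <- spliced_align(sr$sequence, seq, prefer_acceptor = ann$sa2)
    call <- classify_transcript(iv, ann, fam$truth$types[[locus]])
    predict_spliced_protein(seq, call, ann, fam$references, introns = iv)
  }
  rec <- run(t2, "rec")
  expect_identical(rec$protein_class, "Rec")
  expect_identical(rec$aa_sequence, fam$references$rec)
  np9 <- run(t1, "np9")
  expect_identical(np9$protein_class, "Np9")
  # alternative acceptor +260 -> Rec shortened by exactly 17 aa, a strict
  # prefix of canonical Rec
  tr <- run(t2, "np9_like_alternative")
  expect_identical(tr$protein_class, "Rec_truncated")
  expect_equal(nchar(fam$references$rec) - tr$aa_length, 17L)
  expect_identical(tr$aa_sequence,
                   substr(fam$references$rec, 1, tr$aa_length))
  # retrocopy: stop codon 19 aa into the Rec region -> no protein
  retro <- run("synK-retro", "unspliced")
  expect_identical(retro$protein_class, "none")
  expect_equal(retro$stop_position, 19L)
})

test_that("chimeric products are recognised from half-matches to references", {
  fam <- small_family()
  refs <- fam$references
  # construct a toy locus whose spliced product is Rec N-half + Env C-tail
  rec_half <- substr(refs$rec, 1, 60)
  env_tail <- substr(refs$env_aa, nchar(refs$env_aa) - 59, nchar(refs$env_aa))
  rt <- function(aa) {  # reverse-translate with fixed codons
    codons <- c(A="GCT",R="CGT",N="AAT",D="GAT",C="TGT",E="GAA",Q="CAA",
                G="GGT",H="CAT",I="ATT",L="CTT",K="AAA",M="ATG",F="TTT",
                P="CCT",S="TCT",T="ACT",W="TGG",Y="TAT",V="GTT")
    paste(codons[strsplit(aa, "")[[1]]], collapse = "")
  }
  set.seed(8)
  intron <- paste0("GT", paste(sample(c("A","C","G","T"), 96, replace = TRUE),
                               collapse = ""), "AG")
  locus <- paste0("TAA", rt(rec_half), intron, rt(env_tail), "TAA",
                  paste(sample(c("A","C","G","T"), 40, replace = TRUE),
                        collapse = ""))
  env_start <- 4L
  d <- 4L + 180L              # first intron base
  a <- d + 99L                # last intron base
  ann <- splice_annotation("toy", sd2 = d, sa2 = a, env_start = env_start)
  call <- data.frame(read_id = "r", locus_id = "toy",
                     transcript_class = "rec", donor_pos = d,
                     acceptor_pos = a, acceptor_offset = 0L, n_introns = 1L,
                     reason = NA_character_)
  pred <- predict_spliced_protein(locus, call, ann, refs)
  expect_identical(pred$protein_class, "chimeric_env_rec_np9")
})
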