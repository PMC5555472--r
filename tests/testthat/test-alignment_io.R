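test_that("sample sheets read, validate and case-fold species names", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("id,species,population,individual",
               "L1,Lyrata,pop1,i1",
               "L2,lyrata,pop1,i1",
               "H1,HALLERI,pop2,i2",
               "T1,thaliana,out,i3"), p)
  sh <- read_sample_sheet(p)
  expect_s3_class(sh, "sample_sheet")
  expect_equal(nrow(sh), 4L)
  expect_equal(sh$species, c("lyrata", "lyrata", "halleri", "thaliana"))

  # tab-separated variant
  pt <- tempfile(fileext = ".tsv")
  writeLines(c("id\tspecies\tpopulation\tindividual",
               "L1\tlyrata\tpop1\ti1"), pt)
  expect_equal(read_sample_sheet(pt)$id, "L1")

  pd <- tempfile(fileext = ".csv")
  writeLines(c("id,species,population,individual",
               "L1,lyrata,pop1,i1", "L1,lyrata,pop1,i2"), pd)
  expect_error(read_sample_sheet(pd), "duplicate id L1")

  pu <- tempfile(fileext = ".csv")
  writeLines(c("id,species,population,individual",
               "X1,petraea,pop1,i1"), pu)
  expect_error(read_sample_sheet(pu), "unknown species")

  expect_error(sample_sheet("a", "lyrata", "p", ""), "non-empty")
})

test_that("FASTA loci read with normalization and validation", {
  sh <- sample_sheet(c("a", "b", "c"), rep("lyrata", 3), rep("p", 3),
                     c("i1", "i1", "i2"))
  p <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgtAN", ">b", "ACGU-N", ">c", "ACGTAC"), p)
  aln <- read_locus_alignment(p, sheet = sh)
  expect_equal(aln$length, 6L)
  expect_equal(paste(aln$mat["a", ], collapse = ""), "ACGTAN")
  expect_equal(paste(aln$mat["b", ], collapse = ""), "ACGT-N")

  pr <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTAA", ">b", "ACG"), pr)
  expect_error(read_locus_alignment(pr), "ragged")

  px <- tempfile(fileext = ".fasta")
  writeLines(c(">zz", "ACGTAA"), px)
  expect_error(read_locus_alignment(px, sheet = sh), "absent from sample sheet")

  pb <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTXZ"), pb)
  expect_error(read_locus_alignment(pb), "invalid residue")

  pe <- tempfile(fileext = ".fasta")
  writeLines(character(), pe)
  expect_error(read_locus_alignment(pe))
})

test_that("write/read round-trips alignments and rejects empty ones", {
  aln <- make_aln(c(x1 = "ACG-TA", x2 = "ACGNTA", x3 = "TCGATA"))
  p1 <- tempfile(fileext = ".fasta")
  write_locus_alignment(aln, p1)
  back <- read_locus_alignment(p1)
  expect_identical(back$mat, aln$mat)
  p2 <- tempfile(fileext = ".fasta")
  write_locus_alignment(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  empty <- aln
  empty$mat <- aln$mat[0, , drop = FALSE]
  expect_error(write_locus_alignment(empty, tempfile()), "no sequences")
})

test_that("species partitioning groups indices and flags unknown ids", {
  sh <- sample_sheet(c("L1", "L2", "L3", "H1", "H2", "T1"),
                     c("lyrata", "lyrata", "lyrata", "halleri", "halleri",
                       "thaliana"),
                     rep("p", 6), paste0("i", 1:6))
  aln <- make_aln(setNames(rep("ACG", 5), c("L1", "L2", "L3", "H1", "H2")))
  part <- partition_by_species(aln, sh)
  expect_equal(lengths(part[c("lyrata_idx", "halleri_idx", "outgroup_idx")]),
               c(lyrata_idx = 3L, halleri_idx = 2L, outgroup_idx = 0L))

  aln2 <- make_aln(setNames(rep("ACG", 2), c("L1", "T1")))
  expect_equal(length(partition_by_species(aln2, sh)$outgroup_idx), 1L)

  aln3 <- make_aln(setNames(rep("ACG", 2), c("L1", "X9")))
  expect_error(partition_by_species(aln3, sh), "unassigned sequence X9")
})

test_that("coding masks convert from 1-based ranges and gate the frame", {
  mask <- coding_mask_from_ranges(10, list(c(1, 6), c(9, 10)))
  expect_equal(which(mask), c(1:6, 9:10))
  expect_error(coding_mask_from_ranges(10, list(c(0, 5))), "invalid coding range")
  # 8 coding sites: not divisible by 3 at offset 0, fine at offset 2
  seqs <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  expect_error(make_aln(seqs, coding_mask = mask), "divisible by 3")
  expect_silent(make_aln(seqs, coding_mask = mask, frame_offset = 2L))
})

test_that("singleton individuals are duplicated as homozygotes on request", {
  sh <- sample_sheet(c("L1a", "L1b", "L2a"), rep("lyrata", 3), rep("p", 3),
                     c("i1", "i1", "i2"))
  aln <- make_aln(setNames(c("ACG", "ACT", "AGG"), c("L1a", "L1b", "L2a")))
  res <- duplicate_singleton_individuals(aln, sh)
  expect_equal(nrow(res$alignment$mat), 4L)
  expect_true("L2a_hom2" %in% rownames(res$alignment$mat))
  expect_identical(res$alignment$mat["L2a_hom2", ],
                   res$alignment$mat["L2a", ])
  expect_true("L2a_hom2" %in% res$sheet$id)

  # opt-out locus untouched
  aln2 <- aln; aln2$locus_name <- "At3g46710"
  res2 <- duplicate_singleton_individuals(aln2, sh,
                                          opt_out_loci = "At3g46710")
  expect_equal(nrow(res2$alignment$mat), 3L)
  # disabled flag untouched
  res3 <- duplicate_singleton_individuals(aln, sh, assume_homozygous = FALSE)
  expect_equal(nrow(res3$alignment$mat), 3L)
})
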