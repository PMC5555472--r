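tiny_spec <- function(...) {
  defaults <- list(n_introgressed = 1L, n_balanced = 1L,
                   T_split_years = 50000, N = 2000, mu = 1e-6, rec = 0,
                   n_loci_reference = 3L, n_loci_resistance = 3L,
                   L_reference = 90L, L_resistance = 91L,
                   n_A = 8L, n_B = 6L)
  do.call(synth_spec, utils::modifyList(defaults, list(...)))
}

test_that("mu = 0 datasets are monomorphic with identical pairs everywhere", {
  ds <- generate_dataset(tiny_spec(mu = 0, n_introgressed = 0L,
                                   n_balanced = 0L, outgroup = FALSE),
                         seed = 1)
  for (aln in ds$alignments) {
    part <- partition_by_species(aln, ds$sheet)
    expect_equal(segregating_sites(aln), 0L)
    expect_true(has_identical_interspecific_pair(part))
  }
})

test_that("realization preserves the simulated identity structure", {
  set.seed(2)
  p <- im_params(N_current = 2000, T_split_years = 20000, L = 120,
                 mu = 1e-6, n_sample_A = 6L, n_sample_B = 6L)
  s <- simulate_locus(p)
  aln <- realize_locus_nucleotides(s)
  gkey <- apply(s$genotypes, 1L, paste, collapse = "")
  akey <- apply(aln$mat, 1L, paste, collapse = "")
  expect_identical(outer(gkey, gkey, "=="), outer(akey, akey, "=="))
})

test_that("generated coding sequences carry no internal stop codons", {
  ds <- generate_dataset(tiny_spec(), seed = 3)
  for (aln in ds$alignments) {
    fo <- aln$frame_offset
    n_cod <- (aln$length - fo) %/% 3L
    for (r in seq_len(nrow(aln$mat))) {
      cods <- vapply(seq_len(n_cod - 1L), function(k)
        paste(aln$mat[r, fo + (3 * k - 2):(3 * k)], collapse = ""),
        character(1))
      expect_false(any(cods %in% c("TAA", "TAG", "TGA")),
                   label = paste(aln$locus_name, rownames(aln$mat)[r]))
    }
  }
})

test_that("planted events create the signals the truth table promises", {
  ds <- generate_dataset(tiny_spec(), seed = 4)
  tr <- ds$truth
  for (i in which(tr$planted_introgression)) {
    part <- partition_by_species(ds$alignments[[tr$locus[i]]], ds$sheet)
    expect_true(has_identical_interspecific_pair(part), label = tr$locus[i])
  }
  for (i in which(tr$planted_balanced)) {
    aln <- ds$alignments[[tr$locus[i]]]
    part <- partition_by_species(aln, ds$sheet)
    tree <- neighbor_joining(jc_distance_matrix(aln))
    expect_true(classify_trans_specific(tree, part)$is_trans_specific,
                label = tr$locus[i])
    # balanced planting must not fake identical pairs
    expect_false(has_identical_interspecific_pair(part), label = tr$locus[i])
  }
})

test_that("introgression planting respects recency and bookkeeping modes", {
  set.seed(5)
  p <- im_params(N_current = 2000, T_split_years = 200000, L = 300,
                 mu = 1e-7, n_sample_A = 6L, n_sample_B = 6L)
  s <- simulate_locus(p)
  aln <- realize_locus_nucleotides(s)
  sp <- s$species

  res0 <- plant_introgressed_haplotype(aln, sp, recency_generations = 0)
  part0 <- structure(list(aln = res0$alignment,
                          lyrata_idx = which(res0$species == "lyrata"),
                          halleri_idx = which(res0$species == "halleri"),
                          outgroup_idx = integer()),
                     class = "species_partition")
  expect_true(has_identical_interspecific_pair(part0))
  expect_equal(nrow(res0$alignment$mat), nrow(aln$mat))  # replace mode

  resA <- plant_introgressed_haplotype(aln, sp, mode = "add")
  expect_equal(nrow(resA$alignment$mat), nrow(aln$mat) + 1L)
  expect_equal(length(resA$species), length(sp) + 1L)

  # huge recency: the copied haplotype drifts away from the donor
  resH <- plant_introgressed_haplotype(aln, sp, recency_generations = 5e7,
                                       mu_per_gen = 1e-8)
  partH <- structure(list(aln = resH$alignment,
                          lyrata_idx = which(resH$species == "lyrata"),
                          halleri_idx = which(resH$species == "halleri"),
                          outgroup_idx = integer()),
                     class = "species_partition")
  expect_false(has_identical_interspecific_pair(partH))
  expect_error(plant_introgressed_haplotype(aln, sp,
                                            recency_generations = -1),
               ">= 0")
})

test_that("datasets write to disk and the truth table lines up", {
  dir <- file.path(tempdir(), "synthds")
  ds <- generate_dataset(tiny_spec(), seed = 6, dir = dir)
  expect_equal(nrow(ds$truth), 6L)
  expect_true(file.exists(file.path(dir, "sample_sheet.csv")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  expect_equal(sort(list.files(dir, pattern = "fasta$")),
               sort(paste0(ds$truth$locus, ".fasta")))
  # round-trip one locus through the io layer
  sh <- read_sample_sheet(file.path(dir, "sample_sheet.csv"))
  aln <- read_locus_alignment(file.path(dir, "reference_01.fasta"),
                              sheet = sh)
  expect_identical(aln$mat, ds$alignments$reference_01$mat)
})

test_that("worked fixtures are complete and byte-stable", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  f1 <- make_worked_fixtures(d1)
  f2 <- make_worked_fixtures(d2)
  expect_gte(length(f1), 6L)
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  toy <- read_locus_alignment(file.path(d1, "toy_S2.fasta"))
  expect_equal(segregating_sites(toy), 2L)
})
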