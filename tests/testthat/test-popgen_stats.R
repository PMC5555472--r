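test_that("Jukes-Cantor correction matches the closed form and its domain", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.05), 0.0517447, tolerance = 1e-6)
  expect_error(jukes_cantor(0.75), "saturation")
  # strictly increasing and >= identity on its domain
  p <- seq(0, 0.74, by = 0.01)
  d <- jukes_cantor(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("segregating sites and haplotype counts follow the missing-data rules", {
  expect_equal(segregating_sites(c("ACGT", "ACGT", "ACGT")), 0L)
  expect_equal(segregating_sites(c("AAT", "AAA", "ACA")), 2L)
  # missing residue removes the only second allele at site 2
  expect_equal(segregating_sites(c("A-T", "AAT")), 0L)
  expect_error(segregating_sites("ACGT"), "at least 2")

  expect_equal(count_haplotypes(c("AAT", "AAT", "AAT")), 1L)
  expect_equal(count_haplotypes(c("AAT", "AAA", "ACA")), 3L)
  expect_equal(count_haplotypes(c("AAT", "AAT", "ACA")), 2L)
})

test_that("pairwise total diversity equals JC of the mismatch proportion", {
  L <- 300
  base <- paste(rep("ACG", L / 3), collapse = "")
  mutant <- base
  substr(mutant, 7, 7) <- "T"
  aln <- make_aln(c(a = base, b = mutant))
  expect_equal(pairwise_diversity(aln, "all"), jukes_cantor(1 / L))
  expect_equal(pairwise_diversity(make_aln(c(a = base, b = base)), "all"), 0)

  # property: for two sequences pi_total == jc(raw mismatch proportion)
  set.seed(401)
  for (i in 1:8) {
    a <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
    b <- a
    mut <- runif(60) < 0.12
    b[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    a[runif(60) < 0.05] <- "-"
    b[runif(60) < 0.05] <- "-"
    both <- a != "-" & b != "-"
    p_raw <- mean(a[both] != b[both])
    seqs <- c(s1 = paste(a, collapse = ""), s2 = paste(b, collapse = ""))
    expect_equal(pairwise_diversity(make_aln(seqs), "all"),
                 jukes_cantor(p_raw))
  }
})

test_that("synonymous/nonsynonymous diversity uses conventional labels", {
  # one synonymous Phe change (TTT -> TTC) among 100 codons:
  # pi_s > 0 and pi_a = 0 under the conventional definition
  s1 <- paste(rep("TTT", 100), collapse = "")
  s2 <- paste(c("TTC", rep("TTT", 99)), collapse = "")
  aln <- make_aln(c(a = s1, b = s2))
  expect_gt(pairwise_diversity(aln, "synonymous"), 0)
  expect_equal(pairwise_diversity(aln, "nonsynonymous"), 0)
  # identical sequences: all selectors 0
  aln0 <- make_aln(c(a = s1, b = s1))
  for (sel in c("all", "synonymous", "nonsynonymous"))
    expect_equal(pairwise_diversity(aln0, sel), 0)
})

test_that("Nei-Gojobori site and difference counting matches enumeration", {
  ng <- nei_gojobori_pair("ATG", "ATG")
  expect_equal(ng$syn_sites, 0)
  expect_equal(ng$nonsyn_sites, 3)
  expect_equal(ng$syn_diffs + ng$nonsyn_diffs, 0)

  ng2 <- nei_gojobori_pair("TTT", "TTC")
  expect_equal(ng2$syn_sites, 1 / 3)
  expect_equal(ng2$nonsyn_sites, 8 / 3)
  expect_equal(ng2$syn_diffs, 1)
  expect_equal(ng2$nonsyn_diffs, 0)

  # two-position codon: averaged over the two stop-free orderings
  ng3 <- nei_gojobori_pair("TTT", "GTA")
  oracle3 <- oracle_ng_diffs("TTT", "GTA")
  expect_equal(c(ng3$syn_diffs, ng3$nonsyn_diffs), unname(oracle3))
  expect_equal(ng3$syn_sites, (1 / 3 + 1) / 2)

  expect_error(nei_gojobori_pair(c("TAA", "ATG"), c("TAA", "ATG")),
               "stop codon at codon index 1")
  # missing-data codons skipped
  ngm <- nei_gojobori_pair(c("TT-", "ATG"), c("TTC", "ATG"))
  expect_equal(ngm$n_codons_compared, 1L)
})

test_that("Nei-Gojobori obeys site conservation and the pathway oracle", {
  set.seed(402)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  for (i in 1:40) {
    c1 <- sample(sense, 1)
    c2 <- sample(sense, 1)
    ng <- nei_gojobori_pair(c1, c2)
    # conservation: syn + nonsyn sites = 3 x codons compared
    expect_equal(ng$syn_sites + ng$nonsyn_sites, 3)
    # diffs sum to the minimal Hamming substitution count
    hd <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    expect_equal(ng$syn_diffs + ng$nonsyn_diffs, hd)
    # pathway-averaged split matches the independent enumeration
    orc <- oracle_ng_diffs(c1, c2)
    expect_equal(c(ng$syn_diffs, ng$nonsyn_diffs), unname(orc),
                 tolerance = 1e-12)
  }
})

test_that("Rm reproduces examples and the exhaustive interval-cover oracle", {
  expect_equal(min_recombination_events(c("AAT", "AAA", "ACA")), 0L)
  expect_equal(min_recombination_events(c("AA", "AT", "TA", "TT")), 1L)
  # sites with missing data are excluded from the four-gamete test
  expect_equal(min_recombination_events(c("AA", "AT", "TA", "T-")), 0L)

  set.seed(403)
  for (i in 1:25) {
    seqs <- random_seqs(8, 8, alphabet = c("A", "T"))
    rm_pkg <- min_recombination_events(seqs)
    expect_identical(rm_pkg, as.integer(oracle_rm(seqs)),
                     label = paste("case", i, paste(seqs, collapse = "/")))
  }
})

test_that("polymorphism classification is exclusive and matches examples", {
  part <- make_partition(c(L1 = "A", L2 = "A", H1 = "T", H2 = "T"),
                         coding_mask = rep(FALSE, 1))
  expect_equal(classify_polymorphisms(part)$n_fixed, 1L)
  part2 <- make_partition(c(L1 = "A", L2 = "T", H1 = "A", H2 = "T"),
                          coding_mask = rep(FALSE, 1))
  expect_equal(classify_polymorphisms(part2)$n_shared, 1L)
  part3 <- make_partition(c(L1 = "A", L2 = "T", H1 = "A", H2 = "A"),
                          coding_mask = rep(FALSE, 1))
  expect_equal(classify_polymorphisms(part3)$n_private_lyrata, 1L)
  # a site entirely missing in one species leaves n_analyzed
  part4 <- make_partition(c(L1 = "AA", L2 = "TA", H1 = "-A", H2 = "-C"),
                          coding_mask = rep(FALSE, 2))
  expect_equal(classify_polymorphisms(part4)$n_analyzed, 1L)

  set.seed(404)
  for (i in 1:10) {
    seqs <- random_seqs(8, 30, p_gap = 0.1)
    names(seqs) <- c(paste0("L", 1:4), paste0("H", 1:4))
    pp <- classify_polymorphisms(make_partition(seqs,
                                                coding_mask = rep(FALSE, 30)))
    expect_lte(pp$n_fixed + pp$n_shared + pp$n_private_lyrata +
                 pp$n_private_halleri, pp$n_analyzed)
  }
})

test_that("divergence extremes match brute-force pair enumeration", {
  # six fourfold-degenerate CCT background codons keep p_s well below
  # saturation for every pair
  bg <- paste(rep("CCT", 6), collapse = "")
  cod <- function(...) paste(c(bg, ...), collapse = "")
  seqs <- c(L1 = cod("TTT", "ATG", "GAA"),
            L2 = cod("TTC", "ATG", "GAA"),
            L3 = cod("TTT", "ATG", "GAC"),
            H1 = cod("TTT", "ATG", "GAA"),
            H2 = cod("CTT", "ACG", "GTA"))
  part <- make_partition(seqs)
  dx <- divergence_extremes(part)
  # brute force over the 6 interspecific pairs
  starts <- seq(1, 27, by = 3)
  ks <- kn <- matrix(NA, 3, 2)
  for (a in 1:3) for (b in 1:2) {
    v1 <- substring(seqs[[a]], starts, starts + 2)
    v2 <- substring(seqs[[3 + b]], starts, starts + 2)
    ng <- nei_gojobori_pair(v1, v2)
    ks[a, b] <- jukes_cantor(ng$syn_diffs / ng$syn_sites)
    kn[a, b] <- jukes_cantor(ng$nonsyn_diffs / ng$nonsyn_sites)
  }
  expect_equal(dx$Ks_L, min(ks))
  expect_equal(dx$Ks_H, max(ks))
  expect_equal(dx$Kn_L, min(kn))
  expect_equal(dx$Kn_H, max(kn))
  expect_true(dx$Ks_L <= dx$Ks_H && dx$Kn_L <= dx$Kn_H)

  # identical sequences across species: all extremes zero
  same <- make_partition(c(L1 = cod("TTT", "ATG"), H1 = cod("TTT", "ATG")))
  dx0 <- divergence_extremes(same)
  expect_equal(unlist(dx0[c("Ks_L", "Ks_H", "Kn_L", "Kn_H")]),
               c(Ks_L = 0, Ks_H = 0, Kn_L = 0, Kn_H = 0))
})

test_that("gene-class summaries bootstrap reproducibly", {
  s <- summarize_gene_class(rep(0.02, 8), n_boot = 200, seed = 7)
  expect_equal(s$mean, 0.02)
  expect_equal(c(s$ci_lower, s$ci_upper), c(0.02, 0.02))
  expect_equal(summarize_gene_class(c(0.01, 0.03), n_boot = 50,
                                    seed = 1)$mean, 0.02)
  v <- runif(10)
  s1 <- summarize_gene_class(v, n_boot = 300, seed = 42)
  s2 <- summarize_gene_class(v, n_boot = 300, seed = 42)
  expect_identical(s1, s2)
  expect_false(summarize_gene_class(0.5)$ci_defined)
})
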