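test_that("JC distance matrices agree with ape and the closed form", {
  base <- paste(rep("ACGT", 25), collapse = "")
  mut <- base
  for (i in 1:5) substr(mut, 4 * i, 4 * i) <- "A"  # 5 of 100 sites changed
  third <- base
  substr(third, 1, 1) <- "G"
  dm <- jc_distance_matrix(make_aln(c(a = base, b = mut, c = third)))
  expect_equal(dm$d["a", "b"], 0.0517447, tolerance = 1e-6)
  expect_equal(dm$d, t(dm$d))
  expect_equal(unname(diag(dm$d)), rep(0, 3))
  expect_equal(unname(dm$n_compared[1, 2]), 100)

  # cross-check against ape::dist.dna with pairwise deletion on gapped data
  set.seed(501)
  anc <- sample(c("A", "C", "G", "T"), 120, replace = TRUE)
  seqs <- vapply(1:5, function(i) {
    x <- anc
    mut <- runif(120) < 0.1
    x[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    x[runif(120) < 0.05] <- "-"
    paste(x, collapse = "")
  }, character(1))
  names(seqs) <- paste0("t", 1:5)
  aln <- make_aln(seqs)
  dm2 <- jc_distance_matrix(aln)
  bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "JC69",
                                 pairwise.deletion = TRUE))
  expect_equal(dm2$d, ref[rownames(dm2$d), colnames(dm2$d)],
               tolerance = 1e-12)

  # saturated pairs are reported by name
  sat <- c(a = paste(rep("A", 40), collapse = ""),
           b = paste(rep("C", 40), collapse = ""),
           c = paste(rep("A", 40), collapse = ""))
  expect_error(jc_distance_matrix(make_aln(sat)), "a vs b")
})

test_that("neighbor joining recovers additive trees and closed forms", {
  # 4-taxon additive case from tree ((A:1,B:2):1,(C:1,D:1))
  d <- matrix(c(0, 3, 3, 3,
                3, 0, 4, 4,
                3, 4, 0, 2,
                3, 4, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:1,D:1):0);")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(ref))), 0)
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], d)

  # 3-taxon closed form: a=(dAB+dAC-dBC)/2 etc.
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbor_joining(d3)
  expect_equal(ape::cophenetic.phylo(tr3)[c("A", "B", "C"), c("A", "B", "C")],
               d3)

  # all-ties matrix: deterministic output across reruns
  dt <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(dt) <- 0
  expect_equal(ape::write.tree(neighbor_joining(dt)),
               ape::write.tree(neighbor_joining(dt)))

  dbad <- d; dbad[1, 2] <- NaN
  expect_error(neighbor_joining(dbad), "non-finite")
})

test_that("NJ reconstructs random additive 5-8 taxon trees exactly", {
  set.seed(502)
  for (i in 1:12) {
    n <- sample(5:8, 1)
    ra <- random_additive_tree(n)
    tr <- neighbor_joining(ra$d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(ra$tree))), 0,
                 label = paste("additive case", i))
  }
})

test_that("bootstrap supports are deterministic and saturate on clean signal", {
  # two deep clades, long alignment: every internal edge fully supported
  block <- function(ch, n) paste(rep(ch, n), collapse = "")
  shared <- block("A", 100)
  clade_marker <- block("T", 20)  # 20/130 diverged: far from saturation
  seqs <- c(a1 = paste0(shared, block("A", 20), block("C", 10)),
            a2 = paste0(shared, block("A", 20), block("G", 10)),
            b1 = paste0(shared, clade_marker, block("C", 10)),
            b2 = paste0(shared, clade_marker, block("G", 10)))
  tr <- bootstrap_support(make_aln(seqs), n_boot = 100, seed = 9)
  sup <- tr$node.label[!is.na(tr$node.label)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(any(sup == 100))
  tr2 <- bootstrap_support(make_aln(seqs), n_boot = 100, seed = 9)
  expect_identical(tr$node.label, tr2$node.label)
  tr3 <- bootstrap_support(make_aln(seqs), n_boot = 100, seed = 10)
  expect_s3_class(tr3, "phylo")
})

test_that("trans-specificity calls follow rooted monophyly of both species", {
  seqs <- setNames(rep("ACGT", 5), c("L1", "L2", "H1", "H2", "OUT"))
  part <- make_partition(seqs)

  t1 <- ape::read.tree(text = "(((L1,H1),(L2,H2)),OUT);")
  c1 <- classify_trans_specific(t1, part)
  expect_true(c1$is_trans_specific)

  t2 <- ape::read.tree(text = "(((L1,L2),(H1,H2)),OUT);")
  c2 <- classify_trans_specific(t2, part)
  expect_false(c2$is_trans_specific)
  expect_true(c2$lyrata_monophyletic && c2$halleri_monophyletic)

  # singleton species counts as monophyletic
  part3 <- make_partition(setNames(rep("ACGT", 4), c("L1", "L2", "H1", "OUT")))
  t3 <- ape::read.tree(text = "(((L1,L2),H1),OUT);")
  c3 <- classify_trans_specific(t3, part3)
  expect_false(c3$is_trans_specific)
  expect_true(c3$halleri_monophyletic)

  # invariance to leaf order and branch-length scaling
  t1b <- ape::read.tree(text = "(OUT,((H2,L2),(H1,L1)));")
  expect_equal(classify_trans_specific(t1b, part)$is_trans_specific, TRUE)
  t2b <- ape::read.tree(text = "(((L1:5,L2:5):9,(H1:2,H2:1):3):2,OUT:9);")
  expect_false(classify_trans_specific(t2b, part)$is_trans_specific)

  # midpoint rooting path (no outgroup in tree or partition)
  part4 <- make_partition(setNames(rep("ACGT", 4), c("L1", "L2", "H1", "H2")))
  t4 <- ape::read.tree(text = "((L1:1,L2:1):4,(H1:1,H2:1):4);")
  expect_false(classify_trans_specific(t4, part4)$is_trans_specific)
  expect_equal(classify_trans_specific(t4, part4)$rooting_used, "midpoint")
})

test_that("identical interspecific pairs respect the overlap rule", {
  p1 <- make_partition(c(L1 = "ACGTACGTAC", L2 = "TTTTACGTAC",
                         H1 = "ACGTACGTAC"))
  expect_true(has_identical_interspecific_pair(p1))
  p2 <- make_partition(c(L1 = "ACGTACGTAC", H1 = "ACGTACGTAT"))
  expect_false(has_identical_interspecific_pair(p2))
  # equality only over a 60% overlap fails the default min_overlap = 0.9
  p3 <- make_partition(c(L1 = "----ACGTAC", H1 = "TTTTACGTAC"))
  expect_false(has_identical_interspecific_pair(p3))
  expect_true(has_identical_interspecific_pair(p3, min_overlap = 0.5))
})
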