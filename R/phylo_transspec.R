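#' Jukes-Cantor distance matrix with pairwise deletion
#'
#' `d[i,j] = jukes_cantor(p_ij)` where `p_ij` is the mismatch proportion
#' over sites non-missing in both sequences.
#'
#' @param aln a `locus_alignment` with >= 3 sequences.
#' @return a `jc_dist` list: `labels`, symmetric matrix `d`, `n_compared`.
#' @export
jc_distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (nrow(aln$mat) < 3L) stop("need at least 3 sequences")
  pm <- pairwise_p_matrix(aln$mat)
  sat <- which(pm$p >= 0.75 & upper.tri(pm$p), arr.ind = TRUE)
  if (nrow(sat) > 0L) {
    pairs <- apply(sat, 1L, function(ij)
      paste(rownames(aln$mat)[ij], collapse = " vs "))
    stop("saturated pair(s): ", paste(pairs, collapse = "; "))
  }
  if (anyNA(pm$p)) stop("pair(s) with no comparable sites")
  d <- jukes_cantor(pm$p)
  dimnames(d) <- list(rownames(aln$mat), rownames(aln$mat))
  structure(list(labels = rownames(aln$mat), d = d,
                 n_compared = pm$n_compared), class = "jc_dist")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \code{ape::nj}); negative branch
#' lengths are clamped to zero by default (topology unaffected).
#'
#' @param dm a `jc_dist` or a symmetric numeric matrix with dimnames.
#' @param clamp_negative clamp negative branch lengths to 0.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm, clamp_negative = TRUE) {
  d <- if (inherits(dm, "jc_dist")) dm$d else as.matrix(dm)
  if (any(!is.finite(d))) stop("non-finite distance entries")
  tree <- ape::nj(d)
  if (clamp_negative) tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining tree with site-bootstrap node support
#'
#' Resamples alignment columns with replacement, recomputes the NJ tree,
#' and reports for each internal edge of the original tree the percentage
#' of replicates containing the same bipartition (stored in
#' `tree$node.label`).
#'
#' @param aln a `locus_alignment`.
#' @param n_boot number of bootstrap replicates.
#' @param seed optional integer seed.
#' @return a `phylo` tree with `node.label` support values in `[0, 100]`
#'   (`NA` where undefined).
#' @export
bootstrap_support <- function(aln, n_boot = 1000L, seed = NULL) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (!is.null(seed)) set.seed(seed)
  base_tree <- neighbor_joining(jc_distance_matrix(aln))
  if (n_boot < 1L) return(base_tree)
  boot_trees <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(aln$length, aln$length, replace = TRUE)
    baln <- aln
    baln$mat <- aln$mat[, cols, drop = FALSE]
    baln$length <- length(cols)
    baln$coding_mask <- aln$coding_mask[cols]
    boot_trees[[b]] <- tryCatch(
      neighbor_joining(jc_distance_matrix(baln)),
      error = function(e) NULL)
  }
  boot_trees <- Filter(Negate(is.null), boot_trees)
  if (!length(boot_trees)) {
    base_tree$node.label <- rep(NA_real_, base_tree$Nnode)
    return(base_tree)
  }
  counts <- ape::prop.clades(base_tree, boot_trees, rooted = FALSE)
  base_tree$node.label <- 100 * counts / length(boot_trees)
  base_tree
}

#' Classify a locus as trans-specific from its tree
#'
#' The tree is rooted on the outgroup when outgroup leaves are present,
#' otherwise midpoint-rooted. A species is monophyletic when the smallest
#' rooted clade containing all its leaves contains no other leaves
#' (singletons count as monophyletic). The locus is trans-specific when
#' neither species is monophyletic. Topology only; bootstrap support is not
#' thresholded.
#'
#' @param tree a `phylo` tree covering both species.
#' @param partition a `species_partition` whose alignment ids match the
#'   tree's tip labels.
#' @return a `trans_specific_call` list.
#' @export
classify_trans_specific <- function(tree, partition) {
  stopifnot(inherits(partition, "species_partition"))
  ids <- rownames(partition$aln$mat)
  lyr <- ids[partition$lyrata_idx]
  hal <- ids[partition$halleri_idx]
  out <- ids[partition$outgroup_idx]
  lyr <- intersect(lyr, tree$tip.label)
  hal <- intersect(hal, tree$tip.label)
  out <- intersect(out, tree$tip.label)
  if (!length(lyr) || !length(hal))
    stop("tree must contain leaves of both species")
  if (length(out)) {
    rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
    rooting <- paste(out, collapse = ",")
  } else {
    rooted <- phangorn::midpoint(tree)
    rooting <- "midpoint"
  }
  mono <- function(tips) {
    if (length(tips) <= 1L) return(TRUE)
    ape::is.monophyletic(rooted, tips)
  }
  lm <- mono(lyr)
  hm <- mono(hal)
  structure(list(locus = partition$aln$locus_name,
                 is_trans_specific = !lm && !hm,
                 lyrata_monophyletic = lm,
                 halleri_monophyletic = hm,
                 rooting_used = rooting),
            class = "trans_specific_call")
}

#' @export
print.trans_specific_call <- function(x, ...) {
  cat("<trans_specific_call> ", x$locus, ": ",
      if (x$is_trans_specific) "TRANS-SPECIFIC" else "not trans-specific",
      " (lyrata monophyletic: ", x$lyrata_monophyletic,
      ", halleri monophyletic: ", x$halleri_monophyletic,
      ", rooting: ", x$rooting_used, ")\n", sep = "")
  invisible(x)
}

#' Does a locus carry an identical interspecific sequence pair?
#'
#' TRUE when some lyrata sequence equals some halleri sequence at every site
#' where both are non-missing, and the pair shares at least
#' `min_overlap * length` comparable sites (guards against trivial identity
#' driven by missing data).
#'
#' @param partition a `species_partition`.
#' @param min_overlap minimum shared-site fraction of the locus length.
#' @return logical.
#' @export
has_identical_interspecific_pair <- function(partition, min_overlap = 0.9) {
  stopifnot(inherits(partition, "species_partition"))
  aln <- partition$aln
  li <- partition$lyrata_idx
  hi <- partition$halleri_idx
  if (!length(li) || !length(hi)) stop("both species must be non-empty")
  cm <- code_matrix(aln$mat)
  A <- cm[li, , drop = FALSE]
  B <- cm[hi, , drop = FALSE]
  uA <- unique(A)
  uB <- unique(B)
  need <- min_overlap * aln$length
  for (a in seq_len(nrow(uA))) {
    for (b in seq_len(nrow(uB))) {
      both <- uA[a, ] != 0L & uB[b, ] != 0L
      if (sum(both) < need) next
      if (all(uA[a, both] == uB[b, both])) return(TRUE)
    }
  }
  FALSE
}
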