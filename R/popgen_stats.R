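#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`, correcting a raw mismatch proportion
#' for multiple hits under equal substitution rates.
#'
#' @param p_raw raw proportion of mismatching sites, in `[0, 0.75)`.
#' @return corrected distance(s), same length as `p_raw`.
#' @export
jukes_cantor <- function(p_raw) {
  if (any(p_raw < 0)) stop("p_raw must be >= 0")
  if (any(p_raw >= 0.75))
    stop("saturation: p_raw >= 0.75, Jukes-Cantor distance undefined")
  -0.75 * log(1 - (4 / 3) * p_raw)
}

# --- internal helpers on residue matrices -----------------------------------

as_residue_matrix <- function(x, indices = NULL) {
  mat <- if (inherits(x, "locus_alignment")) x$mat
         else if (inherits(x, "species_partition")) x$aln$mat
         else if (is.matrix(x)) x
         else do.call(rbind, strsplit(toupper(as.character(x)), "", fixed = TRUE))
  if (!is.null(indices)) mat <- mat[indices, , drop = FALSE]
  mat
}

# integer coding: 0 = missing, 1..4 = A,C,G,T
code_matrix <- function(mat) {
  m <- match(mat, DNA_RESIDUES, nomatch = 0L)
  dim(m) <- dim(mat)
  rownames(m) <- rownames(mat)
  m
}

# pairwise raw mismatch proportions and compared-site counts for all row
# pairs, with pairwise deletion of missing data; returns list(p, n_compared)
pairwise_p_matrix <- function(mat) {
  cm <- code_matrix(mat)
  obs <- (cm != 0L) * 1
  n_comp <- obs %*% t(obs)
  match_ct <- matrix(0, nrow(cm), nrow(cm))
  for (b in 1:4) {
    ib <- (cm == b) * 1
    match_ct <- match_ct + ib %*% t(ib)
  }
  p <- (n_comp - match_ct) / n_comp
  p[n_comp == 0] <- NA_real_
  diag(p) <- 0
  list(p = p, n_compared = n_comp)
}

#' Count segregating sites
#'
#' A site segregates when at least two distinct non-missing residues are
#' present; `-` and `N` are ignored.
#'
#' @param x a `locus_alignment`, residue matrix, or character vector of
#'   equal-length sequences.
#' @param indices optional row subset.
#' @return integer count.
#' @export
segregating_sites <- function(x, indices = NULL) {
  mat <- as_residue_matrix(x, indices)
  if (nrow(mat) < 2L) stop("need at least 2 sequences")
  cm <- code_matrix(mat)
  seg <- apply(cm, 2L, function(col) {
    v <- unique(col[col != 0L])
    length(v) >= 2L
  })
  sum(seg)
}

#' Count distinct haplotypes
#'
#' Sequences are compared verbatim (missing residues included), so two
#' sequences differing only in missing-data placement count as distinct.
#'
#' @inheritParams segregating_sites
#' @return integer count.
#' @export
count_haplotypes <- function(x, indices = NULL) {
  mat <- as_residue_matrix(x, indices)
  if (nrow(mat) < 1L) stop("need at least 1 sequence")
  length(unique(apply(mat, 1L, paste, collapse = "")))
}

# --- Nei-Gojobori machinery --------------------------------------------------

.ng_env <- new.env(parent = emptyenv())

ng_tables <- function() {
  if (!is.null(.ng_env$syn_sites)) return(.ng_env)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  # fractional synonymous sites: at each position, the fraction of the 3
  # possible single-base changes that preserve the amino acid; changes to
  # stop codons count as nonsynonymous
  syn_sites <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (gc[[cd]] == "*") { syn_sites[[cd]] <- NA_real_; next }
    s <- 0
    ch <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(DNA_RESIDUES, ch[pos])) {
        alt <- ch; alt[pos] <- b
        alt <- paste(alt, collapse = "")
        if (gc[[alt]] != "*" && gc[[alt]] == gc[[cd]]) s <- s + 1 / 3
      }
    }
    syn_sites[[cd]] <- s
  }
  .ng_env$gc <- gc
  .ng_env$syn_sites <- syn_sites
  .ng_env$stops <- codons[gc == "*"]
  .ng_env$perm2 <- list(c(1L, 2L), c(2L, 1L))
  .ng_env$perm3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                        c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  .ng_env$pair_memo <- new.env(parent = emptyenv())
  .ng_env
}

# pathway-averaged synonymous/nonsynonymous substitution counts between two
# sense codons; equal weight over minimal substitution orderings, excluding
# pathways whose intermediate codons are stops (falling back to all
# orderings in the rare case every pathway is blocked)
ng_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  tb <- ng_tables()
  key <- paste0(c1, c2)
  hit <- tb$pair_memo[[key]]
  if (!is.null(hit)) return(hit)
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diff_pos <- which(a != b)
  k <- length(diff_pos)
  perms <- if (k == 1L) list(1L) else if (k == 2L) tb$perm2 else tb$perm3
  path_counts <- list()
  blocked <- list()
  for (pm in perms) {
    cur <- a
    sd <- 0; nd <- 0; ok <- TRUE
    for (step in seq_len(k)) {
      pos <- diff_pos[pm[step]]
      nxt <- cur; nxt[pos] <- b[pos]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (step < k && tb$gc[[to]] == "*") ok <- FALSE
      if (tb$gc[[from]] != "*" && tb$gc[[to]] != "*" &&
          tb$gc[[from]] == tb$gc[[to]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) path_counts[[length(path_counts) + 1L]] <- c(sd, nd)
    blocked[[length(blocked) + 1L]] <- c(sd, nd)
  }
  use <- if (length(path_counts)) path_counts else blocked
  res <- Reduce(`+`, use) / length(use)
  tb$pair_memo[[key]] <- res
  res
}

#' Nei-Gojobori synonymous/nonsynonymous site and difference counts
#'
#' Fractional site counts follow the mutational-opportunity definition under
#' the standard genetic code (changes to stop codons are nonsynonymous) and
#' are averaged over the two sequences. Codons differing at several positions
#' are resolved by equal-weight averaging over all minimal substitution
#' pathways, excluding pathways through stop codons. Codon pairs containing
#' missing residues (`-`/`N`) are skipped.
#'
#' @param codons1,codons2 equal-length character vectors of in-frame codons.
#' @return list with `syn_sites`, `nonsyn_sites`, `syn_diffs`,
#'   `nonsyn_diffs`, `n_codons_compared`.
#' @export
nei_gojobori_pair <- function(codons1, codons2) {
  if (length(codons1) != length(codons2))
    stop("codon vectors must have equal length")
  tb <- ng_tables()
  for (v in list(codons1, codons2)) {
    st <- which(v %in% tb$stops)
    st <- st[st < length(v)]  # terminal stop tolerated
    if (length(st))
      stop("internal stop codon at codon index ", st[[1]])
  }
  ok <- !grepl("[^ACGT]", codons1) & !grepl("[^ACGT]", codons2) &
    !(codons1 %in% tb$stops) & !(codons2 %in% tb$stops)
  c1 <- codons1[ok]; c2 <- codons2[ok]
  syn_sites <- (sum(tb$syn_sites[c1]) + sum(tb$syn_sites[c2])) / 2
  total_sites <- 3 * length(c1)
  sd <- 0; nd <- 0
  for (i in which(c1 != c2)) {
    d <- ng_pair_diffs(c1[[i]], c2[[i]])
    sd <- sd + d[[1]]; nd <- nd + d[[2]]
  }
  list(syn_sites = syn_sites, nonsyn_sites = total_sites - syn_sites,
       syn_diffs = sd, nonsyn_diffs = nd, n_codons_compared = length(c1))
}

# codon strings for one alignment row: coding sites, frame offset applied
codon_strings <- function(aln, row) {
  chars <- aln$mat[row, aln$coding_mask]
  if (aln$frame_offset > 0L) chars <- chars[-seq_len(aln$frame_offset)]
  n <- length(chars) %/% 3L
  if (n == 0L) return(character())
  vapply(seq_len(n), function(i)
    paste(chars[(3L * i - 2L):(3L * i)], collapse = ""), character(1))
}

#' Per-site nucleotide diversity (Jukes-Cantor corrected)
#'
#' Unweighted mean over all unordered sequence pairs of the JC-corrected
#' per-site distance, restricted to a site class. `"all"` uses every site
#' (coding and non-coding) with pairwise deletion; `"synonymous"` and
#' `"nonsynonymous"` use Nei-Gojobori per-pair site counting on coding
#' codons. Saturated pairs (p >= 0.75) are excluded with a warning.
#'
#' @param aln a `locus_alignment`.
#' @param site_selector one of `"all"`, `"synonymous"`, `"nonsynonymous"`.
#' @param indices optional row subset (e.g. one species).
#' @return per-site diversity (dimensionless).
#' @export
pairwise_diversity <- function(aln,
                               site_selector = c("all", "synonymous",
                                                 "nonsynonymous"),
                               indices = NULL) {
  site_selector <- match.arg(site_selector)
  stopifnot(inherits(aln, "locus_alignment"))
  mat <- as_residue_matrix(aln, indices)
  n <- nrow(mat)
  if (n < 2L) stop("need at least 2 sequences")

  # collapse to unique haplotypes with multiplicities (exact optimization:
  # identical strings contribute identical pairwise terms)
  haps <- apply(mat, 1L, paste, collapse = "")
  uh <- unique(haps)
  cnt <- as.numeric(table(factor(haps, levels = uh)))
  rep_row <- match(uh, haps)
  k <- length(uh)

  dist_fun <- if (site_selector == "all") {
    pm <- pairwise_p_matrix(mat[rep_row, , drop = FALSE])
    function(i, j) pm$p[i, j]
  } else {
    orig_rows <- if (is.null(indices)) rep_row else {
      if (is.logical(indices)) which(indices)[rep_row] else indices[rep_row]
    }
    cods <- lapply(orig_rows, function(r) codon_strings(aln, r))
    if (length(cods[[1]]) == 0L) stop("no coding codons available")
    function(i, j) {
      ng <- nei_gojobori_pair(cods[[i]], cods[[j]])
      if (site_selector == "synonymous") {
        if (ng$syn_sites <= 0) return(NA_real_)
        ng$syn_diffs / ng$syn_sites
      } else {
        if (ng$nonsyn_sites <= 0) return(NA_real_)
        ng$nonsyn_diffs / ng$nonsyn_sites
      }
    }
  }

  num <- 0; denom <- 0; n_saturated <- 0
  for (i in seq_len(k)) {
    # identical-haplotype pairs contribute distance 0
    denom <- denom + cnt[i] * (cnt[i] - 1) / 2
    if (i < k) for (j in (i + 1L):k) {
      w <- cnt[i] * cnt[j]
      p <- dist_fun(i, j)
      if (is.na(p)) next
      if (p >= 0.75) { n_saturated <- n_saturated + w; next }
      num <- num + w * jukes_cantor(p)
      denom <- denom + w
    }
  }
  if (n_saturated > 0)
    warning(n_saturated, " saturated pair(s) excluded from diversity at ",
            aln$locus_name)
  if (denom == 0) return(NA_real_)
  num / denom
}

#' Hudson-Kaplan minimum number of recombination events (Rm)
#'
#' Four-gamete bound: only biallelic sites with no missing data enter the
#' test; each four-gamete-incompatible site pair delimits an open interval
#' that must contain a recombination point, and Rm is the minimum number of
#' points stabbing all such intervals (greedy left-to-right scan).
#'
#' @inheritParams segregating_sites
#' @return integer `Rm >= 0`.
#' @export
min_recombination_events <- function(x, indices = NULL) {
  mat <- as_residue_matrix(x, indices)
  if (nrow(mat) < 2L) stop("need at least 2 sequences")
  cm <- code_matrix(mat)
  use <- which(apply(cm, 2L, function(col) {
    all(col != 0L) && length(unique(col)) == 2L
  }))
  if (length(use) < 2L) return(0L)
  X <- apply(cm[, use, drop = FALSE], 2L, function(col) {
    as.integer(col == col[[1L]])
  })
  n11 <- crossprod(X)
  n00 <- crossprod(1 - X)
  n10 <- crossprod(X, 1 - X)
  n01 <- t(n10)
  incomp <- n11 > 0 & n00 > 0 & n10 > 0 & n01 > 0
  idx <- which(incomp & upper.tri(incomp), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  ivl <- cbind(l = use[idx[, 1L]], r = use[idx[, 2L]])
  ivl <- ivl[order(ivl[, "r"], ivl[, "l"]), , drop = FALSE]
  rm_ <- 0L
  last_r <- -Inf
  for (i in seq_len(nrow(ivl))) {
    if (ivl[i, "l"] >= last_r) {
      rm_ <- rm_ + 1L
      last_r <- ivl[i, "r"]
    }
  }
  rm_
}

#' Partition sites into fixed, shared and private polymorphisms
#'
#' Per site (excluding sites with all residues missing in either species):
#' fixed when each species is monomorphic for a different allele; shared when
#' both species segregate and share at least two alleles; private when
#' exactly one species segregates. Categories are mutually exclusive; sites
#' polymorphic in both species but sharing fewer than two alleles fall in no
#' category.
#'
#' @param partition a `species_partition`.
#' @return a `polymorphism_partition` list: counts `n_fixed`, `n_shared`,
#'   `n_private_lyrata`, `n_private_halleri`, `n_analyzed`, and the matching
#'   `proportions`.
#' @export
classify_polymorphisms <- function(partition) {
  stopifnot(inherits(partition, "species_partition"))
  if (!length(partition$lyrata_idx) || !length(partition$halleri_idx))
    stop("both species must be non-empty")
  mat <- partition$aln$mat
  A <- mat[partition$lyrata_idx, , drop = FALSE]
  B <- mat[partition$halleri_idx, , drop = FALSE]
  n_fixed <- n_shared <- n_privA <- n_privB <- n_analyzed <- 0L
  for (s in seq_len(ncol(mat))) {
    ra <- unique(A[, s]); ra <- ra[!ra %in% MISSING_RESIDUES]
    rb <- unique(B[, s]); rb <- rb[!rb %in% MISSING_RESIDUES]
    if (!length(ra) || !length(rb)) next
    n_analyzed <- n_analyzed + 1L
    polyA <- length(ra) >= 2L
    polyB <- length(rb) >= 2L
    if (!polyA && !polyB) {
      if (ra != rb) n_fixed <- n_fixed + 1L
    } else if (polyA && polyB) {
      if (length(intersect(ra, rb)) >= 2L) n_shared <- n_shared + 1L
    } else if (polyA) {
      n_privA <- n_privA + 1L
    } else {
      n_privB <- n_privB + 1L
    }
  }
  counts <- c(n_fixed = n_fixed, n_shared = n_shared,
              n_private_lyrata = n_privA, n_private_halleri = n_privB)
  structure(list(n_fixed = n_fixed, n_shared = n_shared,
                 n_private_lyrata = n_privA, n_private_halleri = n_privB,
                 n_analyzed = n_analyzed,
                 proportions = if (n_analyzed > 0) counts / n_analyzed
                               else counts * NA_real_),
            class = "polymorphism_partition")
}

#' Lowest and highest interspecific Ks and Kn at a locus
#'
#' Every (lyrata, halleri) sequence pair is scored with
#' [nei_gojobori_pair()] and Jukes-Cantor corrected; the extremes Ks(L),
#' Ks(H), Kn(L), Kn(H) are returned with the achieving pairs' ids.
#' Saturated pairs are excluded; an error is raised if all pairs saturate.
#'
#' @param partition a `species_partition`.
#' @return a `divergence_extremes` list.
#' @export
divergence_extremes <- function(partition) {
  stopifnot(inherits(partition, "species_partition"))
  aln <- partition$aln
  li <- partition$lyrata_idx
  hi <- partition$halleri_idx
  if (!length(li) || !length(hi))
    stop("both species must be non-empty")
  ids <- rownames(aln$mat)
  cods <- lapply(seq_len(nrow(aln$mat)), function(r) codon_strings(aln, r))
  ks <- kn <- matrix(NA_real_, length(li), length(hi))
  memo <- new.env(parent = emptyenv())
  for (a in seq_along(li)) for (b in seq_along(hi)) {
    key <- paste(paste(cods[[li[a]]], collapse = ""),
                 paste(cods[[hi[b]]], collapse = ""), sep = "|")
    hit <- memo[[key]]
    if (is.null(hit)) {
      ng <- nei_gojobori_pair(cods[[li[a]]], cods[[hi[b]]])
      ps <- if (ng$syn_sites > 0) ng$syn_diffs / ng$syn_sites else NA_real_
      pn <- if (ng$nonsyn_sites > 0) ng$nonsyn_diffs / ng$nonsyn_sites
            else NA_real_
      hit <- c(if (!is.na(ps) && ps < 0.75) jukes_cantor(ps) else NA_real_,
               if (!is.na(pn) && pn < 0.75) jukes_cantor(pn) else NA_real_)
      memo[[key]] <- hit
    }
    ks[a, b] <- hit[[1]]
    kn[a, b] <- hit[[2]]
  }
  if (all(is.na(ks)) && all(is.na(kn)))
    stop("all interspecific pairs saturated or unscorable")
  pick <- function(m, f) {
    v <- f(m, na.rm = TRUE)
    w <- which(m == v, arr.ind = TRUE)[1L, ]
    list(value = v, pair = c(ids[li[w[[1]]]], ids[hi[w[[2]]]]))
  }
  ksL <- pick(ks, min); ksH <- pick(ks, max)
  knL <- pick(kn, min); knH <- pick(kn, max)
  structure(list(Ks_L = ksL$value, Ks_H = ksH$value,
                 Kn_L = knL$value, Kn_H = knH$value,
                 Ks_L_pair = ksL$pair, Ks_H_pair = ksH$pair,
                 Kn_L_pair = knL$pair, Kn_H_pair = knH$pair),
            class = "divergence_extremes")
}

#' Mean of a per-locus statistic with a bootstrap confidence interval
#'
#' Unweighted mean across loci; the CI is a seeded nonparametric percentile
#' bootstrap over loci. With a single locus the mean is returned and the CI
#' flagged undefined.
#'
#' @param values numeric vector, one value per locus (`NA`s dropped).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed optional integer seed.
#' @return list with `mean`, `ci_lower`, `ci_upper`, `n_loci`,
#'   `ci_defined`.
#' @export
summarize_gene_class <- function(values, n_boot = 1000L, conf = 0.95,
                                 seed = NULL) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("no values to summarize")
  m <- mean(values)
  if (n < 2L)
    return(list(mean = m, ci_lower = NA_real_, ci_upper = NA_real_,
                n_loci = n, ci_defined = FALSE))
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i)
    mean(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
  list(mean = m, ci_lower = ci[[1]], ci_upper = ci[[2]],
       n_loci = n, ci_defined = TRUE)
}

#' Per-species diversity summary for one locus
#'
#' @param aln a `locus_alignment`.
#' @param indices rows belonging to the species being summarized.
#' @param n_boot unused here; present for API symmetry.
#' @return a `diversity_summary` list: `S`, `n_haplotypes`, `pi_s`, `pi_a`,
#'   `pi_total`, `Rm`, `Rm_per_site`, `n_analyzed_sites`.
#' @export
diversity_summary <- function(aln, indices, n_boot = NULL) {
  stopifnot(inherits(aln, "locus_alignment"))
  mat <- aln$mat[indices, , drop = FALSE]
  cm <- code_matrix(mat)
  analyzed <- sum(apply(cm, 2L, function(col) sum(col != 0L) >= 2L))
  S <- segregating_sites(mat)
  rm_ <- min_recombination_events(mat)
  structure(list(
    S = S,
    n_haplotypes = count_haplotypes(mat),
    pi_s = pairwise_diversity(aln, "synonymous", indices),
    pi_a = pairwise_diversity(aln, "nonsynonymous", indices),
    pi_total = pairwise_diversity(aln, "all", indices),
    Rm = rm_,
    Rm_per_site = if (analyzed > 0) rm_ / analyzed else NA_real_,
    n_analyzed_sites = analyzed), class = "diversity_summary")
}
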