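# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the package's own code paths.

# quick locus_alignment from a named character vector of strings
make_aln <- function(seqs, name = "toy", coding_mask = NULL,
                     frame_offset = 0L) {
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("s%d", seq_along(seqs))
  L <- nchar(seqs[[1]])
  if (is.null(coding_mask) && (L - frame_offset) %% 3L != 0L)
    coding_mask <- rep(FALSE, L)  # treat off-frame fixtures as non-coding
  locus_alignment(seqs, locus_name = name, coding_mask = coding_mask,
                  frame_offset = frame_offset)
}

# partition without a sheet: species from id prefixes L/H/OUT
make_partition <- function(seqs, name = "toy", frame_offset = 0L,
                           coding_mask = NULL) {
  aln <- make_aln(seqs, name, coding_mask, frame_offset)
  ids <- rownames(aln$mat)
  structure(list(aln = aln,
                 lyrata_idx = which(startsWith(ids, "L")),
                 halleri_idx = which(startsWith(ids, "H")),
                 outgroup_idx = which(startsWith(ids, "OUT"))),
            class = "species_partition")
}

# random ACGT alignment as named string vector
random_seqs <- function(n, L, p_gap = 0, alphabet = c("A", "C", "G", "T")) {
  seqs <- vapply(seq_len(n), function(i) {
    ch <- sample(alphabet, L, replace = TRUE)
    if (p_gap > 0) ch[runif(L) < p_gap] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%d", seq_len(n))
  seqs
}

# ---- Rm oracle: minimum number of gap positions stabbing every
# four-gamete-incompatible open interval, by exhaustive subset search ----
oracle_rm <- function(seq_strings) {
  mat <- do.call(rbind, strsplit(seq_strings, "", fixed = TRUE))
  L <- ncol(mat)
  usable <- which(vapply(seq_len(L), function(s) {
    col <- mat[, s]
    !any(col %in% c("-", "N")) && length(unique(col)) == 2L
  }, logical(1)))
  if (length(usable) < 2L) return(0L)
  ivl <- list()
  for (a in seq_along(usable)) for (b in seq_along(usable)) {
    if (b <= a) next
    i <- usable[a]; j <- usable[b]
    gam <- unique(paste0(mat[, i], mat[, j]))
    if (length(gam) == 4L) ivl[[length(ivl) + 1L]] <- c(i, j)
  }
  if (!length(ivl)) return(0L)
  gaps <- seq_len(L - 1L)  # gap g sits between sites g and g+1
  covers <- function(g, iv) iv[1] <= g && g < iv[2]
  for (k in 0:length(gaps)) {
    if (k == 0L) next
    for (sub in utils::combn(gaps, k, simplify = FALSE)) {
      if (all(vapply(ivl, function(iv)
        any(vapply(sub, covers, logical(1), iv = iv)), logical(1))))
        return(k)
    }
  }
  length(gaps)
}

# ---- Nei-Gojobori pathway oracle: recursive enumeration of substitution
# orderings using Biostrings::translate, skipping stop intermediates ----
oracle_ng_diffs <- function(c1, c2) {
  aa <- function(cod)
    as.character(Biostrings::translate(Biostrings::DNAString(cod),
                                       no.init.codon = TRUE))
  recurse <- function(cur, target, syn, nonsyn, last) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(pos)) return(list(c(syn, nonsyn)))
    out <- list()
    for (p in pos) {
      ch <- strsplit(cur, "")[[1]]
      ch[p] <- strsplit(target, "")[[1]][p]
      nxt <- paste(ch, collapse = "")
      more <- length(pos) > 1L
      if (more && aa(nxt) == "*") next
      step_syn <- aa(cur) != "*" && aa(nxt) != "*" && aa(cur) == aa(nxt)
      out <- c(out, recurse(nxt, target,
                            syn + as.integer(step_syn),
                            nonsyn + as.integer(!step_syn), p))
    }
    out
  }
  paths <- recurse(c1, c2, 0L, 0L, 0L)
  if (!length(paths)) {
    # all pathways blocked by stops: fall back to including them
    aa2 <- function(cur, nxt) aa(cur) != "*" && aa(nxt) != "*" &&
      aa(cur) == aa(nxt)
    recurse_all <- function(cur, target, syn, nonsyn) {
      pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
      if (!length(pos)) return(list(c(syn, nonsyn)))
      out <- list()
      for (p in pos) {
        ch <- strsplit(cur, "")[[1]]
        ch[p] <- strsplit(target, "")[[1]][p]
        nxt <- paste(ch, collapse = "")
        out <- c(out, recurse_all(nxt, target,
                                  syn + as.integer(aa2(cur, nxt)),
                                  nonsyn + as.integer(!aa2(cur, nxt))))
      }
      out
    }
    paths <- recurse_all(c1, c2, 0L, 0L)
  }
  Reduce(`+`, paths) / length(paths)
}

# ---- Fisher oracle: exhaustive enumeration over tables with fixed margins,
# probabilities from choose() ----
oracle_fisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  prob <- function(x) choose(m, x) * choose(n, k - x) / choose(m + n, k)
  xs <- max(0, k - n):min(k, m)
  p_obs <- prob(tab[1, 1])
  sum(vapply(xs, prob, numeric(1))[vapply(xs, prob, numeric(1)) <=
                                     p_obs * (1 + 1e-7)])
}

# random additive tree + its patristic distance matrix
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.2, 1.5)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
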