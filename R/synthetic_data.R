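# Synthetic study-shaped datasets with known planted ground truth.
#
# Infinite-sites simulated haplotypes are realized as codon-valid nucleotide
# sequences: the ancestral sequence is drawn uniformly over sense codons,
# mutations are mapped to distinct integer sites with a random non-identical
# derived base, and any realization creating an internal stop codon is
# redrawn. This preserves the identity/difference structure of the
# coalescent exactly while giving valid codon statistics.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# which codon (1-based, in the coding frame) covers site `site` (1-based)?
site_codon_index <- function(site, frame_offset) {
  if (site <= frame_offset) return(0L)  # frame prefix, unconstrained
  ((site - frame_offset - 1L) %/% 3L) + 1L
}

codon_at <- function(chars, codon_idx, frame_offset) {
  a <- frame_offset + 3L * (codon_idx - 1L) + 1L
  paste(chars[a:(a + 2L)], collapse = "")
}

# rows x codon scan for internal stops; returns first (row, codon) or NULL
first_internal_stop <- function(mat, frame_offset) {
  L <- ncol(mat)
  n_cod <- (L - frame_offset) %/% 3L
  if (n_cod < 2L) return(NULL)
  k <- n_cod - 1L  # terminal codon exempt
  i1 <- frame_offset + 3L * (seq_len(k) - 1L) + 1L
  cods <- matrix(paste0(mat[, i1], mat[, i1 + 1L], mat[, i1 + 2L]),
                 nrow = nrow(mat))
  hit <- which(matrix(cods %in% STOP_CODONS, nrow = nrow(mat)),
               arr.ind = TRUE)
  if (nrow(hit) == 0L) return(NULL)
  c(row = unname(hit[1L, 1L]), codon = unname(hit[1L, 2L]))
}

random_sense_codons <- function(n) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  sample(sense, n, replace = TRUE)
}

#' Realize an infinite-sites simulated locus as nucleotide sequences
#'
#' @param sim a `sim_locus` from [simulate_locus()].
#' @param frame_offset coding-frame offset (sites before the first codon).
#' @param max_redraws cap on stop-codon redraws.
#' @return a `locus_alignment` whose rows are the simulated haplotypes
#'   (all-coding mask), with attribute `n_redraws`.
#' @export
realize_locus_nucleotides <- function(sim, frame_offset = 0L,
                                      max_redraws = 200L) {
  stopifnot(inherits(sim, "sim_locus"))
  L <- sim$L
  n_cod <- (L - frame_offset) %/% 3L
  anc <- character(L)
  if (frame_offset > 0L)
    anc[seq_len(frame_offset)] <- sample(DNA_RESIDUES, frame_offset,
                                         replace = TRUE)
  anc[(frame_offset + 1L):(frame_offset + 3L * n_cod)] <-
    unlist(strsplit(random_sense_codons(n_cod), "", fixed = TRUE))
  if (frame_offset + 3L * n_cod < L)
    anc[(frame_offset + 3L * n_cod + 1L):L] <-
      sample(DNA_RESIDUES, L - frame_offset - 3L * n_cod, replace = TRUE)

  S <- length(sim$positions)
  if (S > L) stop("more mutations than sites; locus too short for ",
                  "infinite-sites realization")
  sites <- if (S > 0L) sort(sample.int(L, S)) else integer()
  derived <- vapply(sites, function(s)
    sample(setdiff(DNA_RESIDUES, anc[s]), 1L), character(1))

  n <- nrow(sim$genotypes)
  build <- function() {
    mat <- matrix(rep(anc, each = n), nrow = n)
    for (k in seq_len(S)) {
      carriers <- sim$genotypes[, k]
      mat[carriers, sites[k]] <- derived[k]
    }
    mat
  }
  mat <- build()
  redraws <- 0L
  repeat {
    bad <- first_internal_stop(mat, frame_offset)
    if (is.null(bad)) break
    redraws <- redraws + 1L
    if (redraws > max_redraws)
      stop("stop-codon redraw cap exceeded during nucleotide realization")
    cod_sites <- frame_offset + 3L * (bad[["codon"]] - 1L) + 1:3
    k <- which(sites %in% cod_sites & sim$genotypes[bad[["row"]], ])
    if (length(k)) {
      k <- k[[1L]]
      alt <- setdiff(DNA_RESIDUES, c(anc[sites[k]], derived[k]))
      if (length(alt)) {
        derived[k] <- sample(alt, 1L)
      } else {
        free <- setdiff(seq_len(L), sites)
        sites[k] <- sample(free, 1L)
        derived[k] <- sample(setdiff(DNA_RESIDUES, anc[sites[k]]), 1L)
      }
    } else {
      # stop present in the ancestral-only context (possible when a
      # mutation reverts part of a codon): redraw the ancestral codon
      anc[cod_sites] <- strsplit(random_sense_codons(1L), "")[[1L]]
    }
    mat <- build()
  }
  rownames(mat) <- rownames(sim$genotypes)
  seqs <- apply(mat, 1L, paste, collapse = "")
  names(seqs) <- rownames(mat)
  out <- locus_alignment(seqs, locus_name = "sim_locus",
                         frame_offset = frame_offset)
  attr(out, "n_redraws") <- redraws
  out
}

# add `n_mut` codon-safe random mutations to a single sequence (character
# vector); derived base always differs from the current one
mutate_sequence_codon_safe <- function(chars, n_mut, frame_offset,
                                       max_tries = 500L) {
  L <- length(chars)
  done <- 0L; tries <- 0L
  used <- integer()
  while (done < n_mut) {
    if ((tries <- tries + 1L) > max_tries + n_mut)
      stop("could not place codon-safe mutations")
    s <- sample.int(L, 1L)
    if (s %in% used) next
    old <- chars[s]
    cand <- sample(setdiff(DNA_RESIDUES, old))
    placed <- FALSE
    for (b in cand) {
      trial <- chars
      trial[s] <- b
      ci <- site_codon_index(s, frame_offset)
      n_cod <- (L - frame_offset) %/% 3L
      ok <- ci == 0L || ci >= n_cod ||
        !(codon_at(trial, ci, frame_offset) %in% STOP_CODONS)
      if (ok) { chars <- trial; placed <- TRUE; break }
    }
    if (placed) { done <- done + 1L; used <- c(used, s) }
  }
  chars
}

#' Plant an introgressed haplotype into the recipient species
#'
#' Copies one random donor haplotype into the recipient sample, optionally
#' adding `Poisson(mu_per_gen * L * recency)` codon-safe private mutations
#' to emulate post-introgression drift. In `"replace"` mode a random
#' recipient row is overwritten (sample size unchanged); in `"add"` mode a
#' new row is appended.
#'
#' @param aln a `locus_alignment`.
#' @param species character vector of species per row (aligned with
#'   `rownames(aln$mat)`).
#' @param donor_species `"halleri"` or `"lyrata"`.
#' @param recency_generations generations since the introgression event.
#' @param mu_per_gen mutation rate per site per generation.
#' @param mode `"replace"` or `"add"`.
#' @return list `alignment` (modified), `species`, `introgressed_id`.
#' @export
plant_introgressed_haplotype <- function(aln, species,
                                         donor_species = "halleri",
                                         recency_generations = 0,
                                         mu_per_gen = 4e-9,
                                         mode = c("replace", "add")) {
  mode <- match.arg(mode)
  stopifnot(inherits(aln, "locus_alignment"))
  if (recency_generations < 0) stop("recency must be >= 0")
  recipient_species <- setdiff(c("lyrata", "halleri"), donor_species)
  don <- which(species == donor_species)
  rec <- which(species == recipient_species)
  if (!length(don)) stop("donor has no haplotypes")
  hap <- aln$mat[sample(don, 1L), ]
  n_priv <- rpois(1L, mu_per_gen * aln$length * recency_generations)
  if (n_priv > 0L)
    hap <- mutate_sequence_codon_safe(hap, n_priv, aln$frame_offset)
  mat <- aln$mat
  if (mode == "replace") {
    if (!length(rec)) stop("recipient has no haplotypes to replace")
    tgt <- sample(rec, 1L)
    mat[tgt, ] <- hap
    new_id <- rownames(mat)[tgt]
  } else {
    new_id <- paste0(substr(recipient_species, 1, 3), "_intro")
    mat <- rbind(mat, hap)
    rownames(mat)[nrow(mat)] <- new_id
    species <- c(species, recipient_species)
  }
  seqs <- apply(mat, 1L, paste, collapse = "")
  names(seqs) <- rownames(mat)
  list(alignment = locus_alignment(seqs, aln$locus_name, aln$coding_mask,
                                   aln$frame_offset),
       species = species, introgressed_id = new_id)
}

#' Plant a deep balanced (trans-specific) allelic dimorphism
#'
#' Builds a divergent allele B from the locus consensus (`divergence`
#' fraction of sites mutated, codon-safe), derives species-specific B
#' variants (`species_divergence` additional fraction each, so the planted
#' allele never creates identical interspecific pairs), and assigns them to
#' a fraction `freq` of each species' rows. The resulting tree has two deep
#' allelic clades each containing both species, so neither species is
#' monophyletic.
#'
#' @param aln a `locus_alignment`.
#' @param species species per row.
#' @param freq fraction of each species' rows carrying allele B.
#' @param divergence fraction of sites separating alleles A and B.
#' @param species_divergence extra per-species fraction on allele B.
#' @return list `alignment`, `species`, `carrier_ids`.
#' @export
plant_balanced_polymorphism <- function(aln, species, freq = 0.4,
                                        divergence = 0.06,
                                        species_divergence = 0.01) {
  stopifnot(inherits(aln, "locus_alignment"), freq > 0, freq < 1)
  mat <- aln$mat
  L <- aln$length
  consensus <- apply(mat, 2L, function(col) {
    col <- col[!col %in% MISSING_RESIDUES]
    names(sort(table(col), decreasing = TRUE))[[1L]]
  })
  alleleB <- mutate_sequence_codon_safe(consensus, round(divergence * L),
                                        aln$frame_offset)
  carriers <- character()
  for (sp in c("lyrata", "halleri")) {
    rows <- which(species == sp)
    if (!length(rows)) next
    hapB_sp <- mutate_sequence_codon_safe(
      alleleB, max(1L, round(species_divergence * L)), aln$frame_offset)
    take <- sample(rows, max(1L, round(freq * length(rows))))
    for (r in take) mat[r, ] <- hapB_sp
    carriers <- c(carriers, rownames(mat)[take])
  }
  seqs <- apply(mat, 1L, paste, collapse = "")
  names(seqs) <- rownames(mat)
  list(alignment = locus_alignment(seqs, aln$locus_name, aln$coding_mask,
                                   aln$frame_offset),
       species = species, carrier_ids = carriers)
}

#' Default synthetic study specification (paper-shape preset)
#'
#' Geometry mirrors the study: 10 resistance-like loci of 730 bp (coding
#' frame offset 1) and 37 reference-like loci of 513 bp, with 48 lyrata and
#' 23 halleri haplotypes per locus plus one outgroup sequence. The preset's
#' split is deep (2 MY per branch, N = 150,000, so T/2N about 6.7) so that
#' incomplete lineage sorting and chance identical pairs are negligible and
#' planted events are the only expected positives; mutation and
#' recombination rates are the study's (4e-9 per site per year, 4.3e-9 per
#' site per generation).
#'
#' @param n_introgressed number of resistance-like loci given a planted
#'   introgressed haplotype.
#' @param n_balanced number of resistance-like loci given a planted deep
#'   balanced polymorphism.
#' @param T_split_years split depth per branch.
#' @param N diploid effective size.
#' @param mu mutation rate per site per year.
#' @param rec recombination rate per site per generation.
#' @param n_loci_reference,n_loci_resistance loci per class.
#' @param L_reference,L_resistance locus lengths (bp).
#' @param n_A,n_B haploid sample sizes per species.
#' @param outgroup include a divergent outgroup sequence per locus.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_introgressed = 3L, n_balanced = 3L,
                       T_split_years = 2e6, N = 150000,
                       mu = 4e-9, rec = 4.3e-9,
                       n_loci_reference = 37L, n_loci_resistance = 10L,
                       L_reference = 513L, L_resistance = 730L,
                       n_A = 48L, n_B = 23L, outgroup = TRUE) {
  mk <- function(L, n_loci) {
    im_params(N_current = N, T_split_years = T_split_years, L = L,
              mu = mu, rec = rec, m_intro = 0,
              n_sample_A = n_A, n_sample_B = n_B, n_loci = n_loci)
  }
  classes <- list(
    reference = list(params = mk(L_reference, n_loci_reference),
                     frame_offset = (L_reference %% 3L)),
    resistance = list(params = mk(L_resistance, n_loci_resistance),
                      frame_offset = (L_resistance %% 3L)))
  if (n_introgressed + n_balanced > classes$resistance$params$n_loci)
    stop("more planted events than resistance loci")
  planted <- data.frame(
    class = rep("resistance", n_introgressed + n_balanced),
    locus = seq_len(n_introgressed + n_balanced),
    type = rep(c("introgressed_haplotype", "balanced_trans_specific"),
               c(n_introgressed, n_balanced)),
    stringsAsFactors = FALSE)
  structure(list(classes = classes, planted = planted,
                 outgroup = isTRUE(outgroup), outgroup_T_years = 5e6),
            class = "synth_spec")
}

#' Generate a synthetic dataset with a ground-truth table
#'
#' Simulates every locus under its class's isolation-with-migration
#' parameters, realizes codon-valid nucleotide alignments, applies the
#' planted events, optionally appends a divergent outgroup sequence, and
#' returns alignments, a sample sheet and a truth table. When `dir` is
#' given, FASTA files, `sample_sheet.csv` and `truth.tsv` are written.
#'
#' @param spec a [synth_spec()].
#' @param seed integer seed.
#' @param dir optional output directory.
#' @return list `alignments` (named list of `locus_alignment`), `sheet`,
#'   `truth` (data.frame), `n_redraws`.
#' @export
generate_dataset <- function(spec, seed = 1L, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(seed)
  nA_max <- max(vapply(spec$classes, function(cl) cl$params$n_sample_A, 1L))
  nB_max <- max(vapply(spec$classes, function(cl) cl$params$n_sample_B, 1L))
  sheet_ids <- c(sprintf("lyr_%03d", seq_len(nA_max)),
                 sprintf("hal_%03d", seq_len(nB_max)))
  alignments <- list()
  truth_rows <- list()
  total_redraws <- 0L
  any_outgroup <- FALSE
  for (cl_name in names(spec$classes)) {
    cl <- spec$classes[[cl_name]]
    p <- cl$params
    for (i in seq_len(p$n_loci)) {
      locus_name <- sprintf("%s_%02d", cl_name, i)
      sim <- simulate_locus(p)
      aln <- realize_locus_nucleotides(sim, frame_offset = cl$frame_offset)
      total_redraws <- total_redraws + attr(aln, "n_redraws")
      aln$locus_name <- locus_name
      species <- sim$species
      ev <- spec$planted[spec$planted$class == cl_name &
                           spec$planted$locus == i, , drop = FALSE]
      planted_intro <- FALSE; planted_bal <- FALSE
      for (j in seq_len(nrow(ev))) {
        if (ev$type[j] == "introgressed_haplotype") {
          res <- plant_introgressed_haplotype(aln, species,
                                              donor_species = "halleri",
                                              recency_generations = 0)
          aln <- res$alignment; species <- res$species
          planted_intro <- TRUE
        } else if (ev$type[j] == "balanced_trans_specific") {
          res <- plant_balanced_polymorphism(aln, species)
          aln <- res$alignment; species <- res$species
          planted_bal <- TRUE
        } else stop("unknown planted event type: ", ev$type[j])
      }
      if (isTRUE(spec$outgroup)) {
        any_outgroup <- TRUE
        n_out_mut <- rpois(1L, 2 * p$mu * spec$outgroup_T_years * p$L)
        anc_proxy <- aln$mat[1L, ]
        outg <- mutate_sequence_codon_safe(anc_proxy,
                                           min(n_out_mut, p$L %/% 2L),
                                           aln$frame_offset)
        seqs <- apply(aln$mat, 1L, paste, collapse = "")
        names(seqs) <- rownames(aln$mat)
        seqs <- c(seqs, tha_001 = paste(outg, collapse = ""))
        aln <- locus_alignment(seqs, locus_name, aln$coding_mask,
                               aln$frame_offset)
      }
      alignments[[locus_name]] <- aln
      truth_rows[[locus_name]] <- data.frame(
        locus = locus_name, class = cl_name, index = i,
        planted_introgression = planted_intro,
        planted_balanced = planted_bal,
        expected_identical_pair = planted_intro,
        expected_trans_specific = planted_intro || planted_bal,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  ids <- sheet_ids
  species <- c(rep("lyrata", sum(startsWith(ids, "lyr"))),
               rep("halleri", sum(startsWith(ids, "hal"))))
  indiv <- c(sprintf("L%02d", ceiling(seq_len(sum(species == "lyrata")) / 2)),
             sprintf("H%02d", ceiling(seq_len(sum(species == "halleri")) / 2)))
  pop <- rep("synth", length(ids))
  if (any_outgroup) {
    ids <- c(ids, "tha_001", "hal_intro", "lyr_intro")
    species <- c(species, "thaliana", "halleri", "lyrata")
    indiv <- c(indiv, "T01", "Hx", "Lx")
    pop <- c(pop, "outgroup", "synth", "synth")
  }
  sheet <- sample_sheet(ids, species, pop, indiv)
  out <- list(alignments = alignments, sheet = sheet, truth = truth,
              n_redraws = total_redraws, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(alignments))
      write_locus_alignment(alignments[[nm]], file.path(dir, paste0(nm, ".fasta")))
    utils::write.table(sheet, file.path(dir, "sample_sheet.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

#' Write the small worked-example fixtures
#'
#' Deterministic toy inputs used across examples and tests: the
#' segregating-sites toy, the four-gamete toy, Nei-Gojobori codon pairs,
#' a four-taxon additive distance matrix, the Fisher contrast tables,
#' example rooted topologies, and a toy sample sheet.
#'
#' @param dir output directory.
#' @return character vector of file paths (the manifest), invisibly.
#' @export
make_worked_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  w <- function(name, lines) {
    p <- file.path(dir, name)
    writeLines(lines, p)
    paths[[length(paths) + 1L]] <<- p
    p
  }
  w("toy_S2.fasta", c(">s1", "AAT", ">s2", "AAA", ">s3", "ACA"))
  w("toy_fourgamete.fasta",
    c(">h00", "AA", ">h01", "AT", ">h10", "TA", ">h11", "TT"))
  w("ng_codon_pairs.csv",
    c("codon1,codon2,note",
      "ATG,ATG,identical",
      "TTT,TTC,synonymous third position",
      "TTT,GTA,two-position pathway averaging"))
  w("nj_additive_distances.csv",
    c("taxon,A,B,C,D",
      "A,0,3,3,3",
      "B,3,0,4,4",
      "C,3,4,0,2",
      "D,3,4,2,0"))
  w("fisher_tables.csv",
    c("name,a,b,c,d",
      "trans_specific,7,3,8,29",
      "identical_pairs,4,6,3,34",
      "balanced,5,5,5,5"))
  w("transspec_trees.nwk",
    c("(((L1,H1),(L2,H2)),OUT);",
      "(((L1,L2),(H1,H2)),OUT);",
      "(((L1,L2),H1),OUT);"))
  w("toy_sample_sheet.csv",
    c("id,species,population,individual",
      "L1,lyrata,pop1,i1", "L2,lyrata,pop1,i1",
      "H1,halleri,pop2,i2", "H2,halleri,pop2,i2",
      "OUT,thaliana,out,i3"))
  invisible(unlist(paths))
}
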