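#' Read a sample sheet mapping sequence ids to species and populations
#'
#' The sheet is a comma- or tab-separated file with header columns
#' `id`, `species`, `population`, `individual`. Species names are matched
#' case-insensitively against `lyrata`, `halleri` and `thaliana` (the
#' outgroup).
#'
#' @param path path to a CSV/TSV file.
#' @return a `sample_sheet`: a data.frame with columns `id`, `species`,
#'   `population`, `individual`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          comment.char = "")
  names(df) <- tolower(names(df))
  need <- c("id", "species", "population", "individual")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  sample_sheet(df$id, df$species, df$population, df$individual)
}

#' Construct and validate a sample sheet
#'
#' @param id,species,population,individual character vectors of equal length.
#' @return a `sample_sheet` data.frame.
#' @export
sample_sheet <- function(id, species, population, individual) {
  id <- as.character(id)
  species <- tolower(trimws(as.character(species)))
  population <- as.character(population)
  individual <- as.character(individual)
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate id ", paste(dup, collapse = ", "))
  }
  known <- c("lyrata", "halleri", "thaliana")
  bad <- setdiff(unique(species), known)
  if (length(bad))
    stop("unknown species token(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(known, collapse = ", "), ")")
  if (length(species) == 0L) stop("sample sheet has no records")
  if (any(!nzchar(individual))) stop("individual_id must be non-empty")
  out <- data.frame(id = id, species = species, population = population,
                    individual = individual, stringsAsFactors = FALSE)
  class(out) <- c("sample_sheet", "data.frame")
  out
}

#' Build a per-site coding mask from 1-based inclusive ranges
#'
#' Human-facing configs give coding regions as 1-based inclusive
#' `[start, end]` ranges; internally the mask is a logical per-site vector.
#'
#' @param length alignment length in sites.
#' @param ranges list of `c(start, end)` 1-based inclusive pairs, or `NULL`
#'   for an all-coding mask.
#' @return logical vector of `length` sites, `TRUE` = coding.
#' @export
coding_mask_from_ranges <- function(length, ranges = NULL) {
  mask <- rep(is.null(ranges), length)
  if (!is.null(ranges)) {
    for (rg in ranges) {
      if (length(rg) != 2L || rg[1] < 1 || rg[2] > length || rg[1] > rg[2])
        stop("invalid coding range: [", paste(rg, collapse = ", "), "]")
      mask[rg[1]:rg[2]] <- TRUE
    }
  }
  mask
}

#' Construct a locus alignment
#'
#' @param seqs named character vector of equal-length residue strings over
#'   `A,C,G,T,-,N` (lower case and `U` accepted and normalized).
#' @param locus_name locus identifier.
#' @param coding_mask logical per-site vector (`TRUE` = coding); default
#'   all-coding.
#' @param frame_offset number of coding sites (0, 1 or 2) to skip before the
#'   first complete codon.
#' @return a `locus_alignment` object.
#' @export
locus_alignment <- function(seqs, locus_name = "locus",
                            coding_mask = NULL, frame_offset = 0L) {
  if (length(seqs) == 0L) stop("alignment has no sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  len <- lens[[1]]
  if (len < 1L) stop("alignment length must be >= 1")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  bad <- setdiff(unique(as.vector(mat)), c(DNA_RESIDUES, MISSING_RESIDUES))
  if (length(bad))
    stop("invalid residue(s): ", paste(bad, collapse = ", "))
  if (is.null(coding_mask)) coding_mask <- rep(TRUE, len)
  if (length(coding_mask) != len)
    stop("coding_mask length (", length(coding_mask),
         ") does not match alignment length (", len, ")")
  frame_offset <- as.integer(frame_offset)
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  n_coding <- sum(coding_mask)
  if (n_coding > 0L && (n_coding - frame_offset) %% 3L != 0L)
    stop("number of coding sites after frame_offset (", n_coding - frame_offset,
         ") is not divisible by 3")
  structure(list(locus_name = locus_name, mat = mat, length = len,
                 coding_mask = coding_mask, frame_offset = frame_offset),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus_name, ": ", nrow(x$mat), " sequences x ",
      x$length, " sites (", sum(x$coding_mask), " coding, frame offset ",
      x$frame_offset, ")\n", sep = "")
  invisible(x)
}

#' Read a per-locus FASTA alignment
#'
#' Residues are upper-cased, `U` is mapped to `T`, and anything outside
#' `A,C,G,T,-,N` is rejected. All records must have equal length.
#'
#' @param path FASTA file with >= 1 record.
#' @param sheet optional [sample_sheet()]; when given, every record id must
#'   appear in it.
#' @param coding_ranges optional list of 1-based inclusive coding ranges
#'   (see [coding_mask_from_ranges()]); default all-coding.
#' @param frame_offset coding-frame offset in `0:2`.
#' @param locus_name defaults to the file name without extension.
#' @return a `locus_alignment`.
#' @export
read_locus_alignment <- function(path, sheet = NULL, coding_ranges = NULL,
                                 frame_offset = 0L, locus_name = NULL) {
  if (is.null(locus_name))
    locus_name <- sub("\\.[^.]*$", "", basename(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (!is.null(sheet)) {
    unknown <- setdiff(names(seqs), sheet$id)
    if (length(unknown))
      stop("sequence id(s) absent from sample sheet: ",
           paste(unknown, collapse = ", "))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged lengths in ", path, ": ", paste(unique(lens), collapse = ", "))
  mask <- coding_mask_from_ranges(lens[[1]], coding_ranges)
  locus_alignment(seqs, locus_name = locus_name, coding_mask = mask,
                  frame_offset = frame_offset)
}

#' Write a locus alignment to FASTA
#'
#' Round-trips through [read_locus_alignment()]: `read(write(aln))`
#' reproduces the alignment (coding mask and frame offset travel in the
#' config, not the FASTA).
#'
#' @param aln a `locus_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (nrow(aln$mat) == 0L) stop("alignment has no sequences")
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- rownames(aln$mat)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Partition an alignment's sequences by species
#'
#' @param aln a `locus_alignment`.
#' @param sheet a `sample_sheet` covering every aligned id.
#' @return a `species_partition`: the alignment plus row-index vectors
#'   `lyrata_idx`, `halleri_idx`, `outgroup_idx`.
#' @export
partition_by_species <- function(aln, sheet) {
  stopifnot(inherits(aln, "locus_alignment"))
  ids <- rownames(aln$mat)
  hit <- match(ids, sheet$id)
  if (anyNA(hit))
    stop("unassigned sequence ", paste(ids[is.na(hit)], collapse = ", "))
  sp <- sheet$species[hit]
  structure(list(aln = aln,
                 lyrata_idx = which(sp == "lyrata"),
                 halleri_idx = which(sp == "halleri"),
                 outgroup_idx = which(sp == "thaliana")),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat("<species_partition> ", x$aln$locus_name, ": ",
      length(x$lyrata_idx), " lyrata, ", length(x$halleri_idx), " halleri, ",
      length(x$outgroup_idx), " outgroup\n", sep = "")
  invisible(x)
}

#' Duplicate singleton individuals into two identical haplotypes
#'
#' Alleles were cloned, so each FASTA record is one haplotype; an individual
#' represented by a single sequence is assumed homozygous and its sequence
#' duplicated (id suffix `"_hom2"`), unless the locus is listed in
#' `opt_out_loci` (loci known not to be exhaustively sampled).
#'
#' @param aln a `locus_alignment`.
#' @param sheet a `sample_sheet`.
#' @param assume_homozygous flag; `FALSE` returns the inputs unchanged.
#' @param opt_out_loci character vector of locus names exempt from the rule.
#' @return `list(alignment=, sheet=)` with duplicate rows added to both.
#' @export
duplicate_singleton_individuals <- function(aln, sheet,
                                            assume_homozygous = TRUE,
                                            opt_out_loci = character()) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (!assume_homozygous || aln$locus_name %in% opt_out_loci)
    return(list(alignment = aln, sheet = sheet))
  ids <- rownames(aln$mat)
  hit <- match(ids, sheet$id)
  if (anyNA(hit))
    stop("unassigned sequence ", paste(ids[is.na(hit)], collapse = ", "))
  indiv <- sheet$individual[hit]
  tab <- table(indiv)
  singletons <- names(tab)[tab == 1L]
  if (!length(singletons)) return(list(alignment = aln, sheet = sheet))
  take <- indiv %in% singletons
  add <- aln$mat[take, , drop = FALSE]
  rownames(add) <- paste0(rownames(add), "_hom2")
  mat <- rbind(aln$mat, add)
  seqs <- apply(mat, 1L, paste, collapse = "")
  names(seqs) <- rownames(mat)
  extra <- sheet[hit[take], , drop = FALSE]
  extra$id <- paste0(extra$id, "_hom2")
  new_sheet <- sheet
  for (i in seq_len(nrow(extra))) {
    if (!extra$id[i] %in% new_sheet$id)
      new_sheet <- rbind(new_sheet, extra[i, , drop = FALSE])
  }
  class(new_sheet) <- c("sample_sheet", "data.frame")
  list(alignment = locus_alignment(seqs, aln$locus_name, aln$coding_mask,
                                   aln$frame_offset),
       sheet = new_sheet)
}
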