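# End-to-end orchestration: stats -> phylogenetics/trans-specificity ->
# simulation null -> verdicts, with JSON config, per-stage child seeds and
# TSV/JSON outputs. The exported functions are the pipeline's interface;
# each maps onto one stage and is independently reproducible.

# small deterministic hash for embedding a config fingerprint in reports
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# one master seed -> named per-stage child seeds (documented scheme: the
# master seeds R's RNG once and four integers are drawn in fixed order)
stage_seeds <- function(seed) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, 4L),
           c("stats", "phylo", "simulation", "tests"))
}

#' Read a pipeline run configuration from JSON
#'
#' Expected fields: `loci` (list of `{locus, fasta, class, frame_offset,
#'   coding_ranges}`), `sample_sheet` (path), optional `grid`, `observed`,
#'   `seed`, `options` (`assume_homozygous`, `homozygous_opt_out_loci`,
#'   `min_overlap`, `n_boot`).
#'
#' @param path JSON file.
#' @return the parsed config list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(cfg$loci) || is.null(cfg$sample_sheet))
    stop("config must define 'loci' and 'sample_sheet'")
  cfg
}

#' Load a dataset (alignments + sheet + class map) from a run config
#'
#' @param cfg config list from [read_run_config()]; relative paths resolve
#'   against `base_dir`.
#' @param base_dir directory paths are relative to.
#' @return list `alignments`, `sheet`, `classes` (named vector
#'   locus -> class).
#' @export
load_dataset <- function(cfg, base_dir = ".") {
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  sheet <- read_sample_sheet(resolve(cfg$sample_sheet))
  opts <- cfg$options
  alignments <- list()
  classes <- character()
  for (lc in cfg$loci) {
    aln <- read_locus_alignment(
      resolve(lc$fasta), sheet = sheet,
      coding_ranges = lc$coding_ranges,
      frame_offset = if (is.null(lc$frame_offset)) 0L else lc$frame_offset,
      locus_name = lc$locus)
    if (isTRUE(opts$assume_homozygous)) {
      dup <- duplicate_singleton_individuals(
        aln, sheet, assume_homozygous = TRUE,
        opt_out_loci = unlist(opts$homozygous_opt_out_loci))
      aln <- dup$alignment
      sheet <- dup$sheet
    }
    alignments[[lc$locus]] <- aln
    classes[[lc$locus]] <- lc$class
  }
  list(alignments = alignments, sheet = sheet, classes = classes)
}

dataset_classes <- function(dataset) {
  if (!is.null(dataset$classes)) return(dataset$classes)
  if (!is.null(dataset$truth))
    return(setNames(dataset$truth$class, dataset$truth$locus))
  stop("dataset carries no class assignment")
}

#' Per-locus and per-class summary statistics
#'
#' For every locus: per-species S, haplotype count, pi_s/pi_a/pi_total, Rm
#' and Rm per analyzed site; fixed/shared/private polymorphism counts; the
#' interspecific identical-pair indicator; Ks/Kn extremes. Class summaries
#' are unweighted means over loci with seeded bootstrap CIs. Failing loci
#' are recorded and skipped.
#'
#' @param dataset list with `alignments`, `sheet` and a class assignment
#'   (`classes` or a `truth` table), e.g. from [generate_dataset()] or
#'   [load_dataset()].
#' @param n_boot bootstrap resamples for class CIs.
#' @param seed integer seed (stats-stage child seed derived from it).
#' @param out_dir optional directory for `per_locus.tsv` and
#'   `class_summary.tsv`.
#' @param compute_divergence also compute Ks/Kn extremes (the slowest step).
#' @return list `per_locus` (data.frame), `class_summary` (data.frame),
#'   `failures` (named character), `seed`.
#' @export
run_stats <- function(dataset, n_boot = 1000L, seed = 1L, out_dir = NULL,
                      compute_divergence = TRUE) {
  classes <- dataset_classes(dataset)
  seeds <- stage_seeds(seed)
  rows <- list()
  failures <- character()
  for (nm in names(dataset$alignments)) {
    res <- tryCatch({
      aln <- dataset$alignments[[nm]]
      part <- partition_by_species(aln, dataset$sheet)
      poly <- classify_polymorphisms(part)
      row <- data.frame(locus = nm, class = classes[[nm]],
                        n_lyrata = length(part$lyrata_idx),
                        n_halleri = length(part$halleri_idx))
      for (sp in c("lyrata", "halleri")) {
        idx <- part[[paste0(sp, "_idx")]]
        ds <- suppressWarnings(diversity_summary(aln, idx))
        add <- data.frame(ds$S, ds$n_haplotypes, ds$pi_s, ds$pi_a,
                          ds$pi_total, ds$Rm, ds$Rm_per_site)
        names(add) <- paste0(c("S_", "haplotypes_", "pi_s_", "pi_a_",
                               "pi_total_", "Rm_", "Rm_per_site_"), sp)
        row <- cbind(row, add)
      }
      row$n_fixed <- poly$n_fixed
      row$n_shared <- poly$n_shared
      row$n_private_lyrata <- poly$n_private_lyrata
      row$n_private_halleri <- poly$n_private_halleri
      row$n_analyzed <- poly$n_analyzed
      row$prop_fixed <- unname(poly$proportions[["n_fixed"]])
      row$prop_shared <- unname(poly$proportions[["n_shared"]])
      row$identical_pair <- has_identical_interspecific_pair(part)
      if (compute_divergence) {
        dx <- suppressWarnings(divergence_extremes(part))
        row$Ks_L <- dx$Ks_L; row$Ks_H <- dx$Ks_H
        row$Kn_L <- dx$Kn_L; row$Kn_H <- dx$Kn_H
      }
      row
    }, error = function(e) e)
    if (inherits(res, "error")) failures[[nm]] <- conditionMessage(res)
    else rows[[nm]] <- res
  }
  if (!length(rows)) stop("all loci failed: ",
                          paste(failures, collapse = "; "))
  per_locus <- do.call(rbind, rows)
  rownames(per_locus) <- NULL

  stats_cols <- c("pi_s", "pi_a", "pi_total", "Rm_per_site")
  summ <- list()
  k <- 0L
  for (cl in unique(per_locus$class)) for (sp in c("lyrata", "halleri"))
    for (st in stats_cols) {
      v <- per_locus[per_locus$class == cl, paste0(st, "_", sp)]
      s <- summarize_gene_class(v, n_boot = n_boot,
                                seed = seeds[["stats"]] %% 1000000L + k)
      k <- k + 1L
      summ[[length(summ) + 1L]] <- data.frame(
        class = cl, species = sp, statistic = st, mean = s$mean,
        ci_lower = s$ci_lower, ci_upper = s$ci_upper, n_loci = s$n_loci)
    }
  class_summary <- do.call(rbind, summ)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(per_locus, file.path(out_dir, "per_locus.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(class_summary, file.path(out_dir, "class_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(per_locus = per_locus, class_summary = class_summary,
       failures = failures, seed = seed)
}

#' Trees, trans-specificity calls and the class contrast
#'
#' Builds a neighbor-joining tree per locus (optionally with site-bootstrap
#' supports), classifies each locus as trans-specific, flags identical
#' interspecific pairs, and contrasts the two gene classes with Fisher's
#' exact test on both indicators. Loci with fewer than 3 sequences are
#' skipped with a warning.
#'
#' @param dataset as in [run_stats()].
#' @param n_boot bootstrap replicates per locus (0 skips supports; the
#'   study's choice is 1000).
#' @param seed integer seed.
#' @param out_dir optional directory for Newick trees and `calls.tsv`.
#' @return list `calls` (data.frame), `trees` (named list of `phylo`),
#'   `fisher_trans_specific`, `fisher_identical` (`htest` or NULL),
#'   `skipped`, `seed`.
#' @export
run_phylo <- function(dataset, n_boot = 0L, seed = 1L, out_dir = NULL) {
  classes <- dataset_classes(dataset)
  seeds <- stage_seeds(seed)
  set.seed(seeds[["phylo"]])
  calls <- list()
  trees <- list()
  skipped <- character()
  for (nm in names(dataset$alignments)) {
    aln <- dataset$alignments[[nm]]
    if (nrow(aln$mat) < 3L) {
      warning("locus ", nm, " has < 3 sequences; skipped")
      skipped <- c(skipped, nm)
      next
    }
    part <- partition_by_species(aln, dataset$sheet)
    tree <- if (n_boot > 0L) bootstrap_support(aln, n_boot = n_boot)
            else neighbor_joining(jc_distance_matrix(aln))
    call <- classify_trans_specific(tree, part)
    trees[[nm]] <- tree
    calls[[nm]] <- data.frame(
      locus = nm, class = classes[[nm]],
      is_trans_specific = call$is_trans_specific,
      lyrata_monophyletic = call$lyrata_monophyletic,
      halleri_monophyletic = call$halleri_monophyletic,
      rooting_used = call$rooting_used,
      identical_pair = has_identical_interspecific_pair(part))
  }
  if (!length(calls)) stop("no locus had >= 3 sequences")
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL

  contrast <- function(flag) {
    cls <- sort(unique(calls$class))
    if (length(cls) != 2L) return(NULL)
    tab <- t(vapply(cls, function(cl) {
      v <- calls[[flag]][calls$class == cl]
      c(sum(v), sum(!v))
    }, numeric(2)))
    tryCatch(fisher_exact_2x2(tab), error = function(e) NULL)
  }
  ft <- contrast("is_trans_specific")
  fi <- contrast("identical_pair")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(trees))
      ape::write.tree(trees[[nm]], file.path(out_dir, paste0(nm, ".nwk")))
    utils::write.table(calls, file.path(out_dir, "calls.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(calls = calls, trees = trees, fisher_trans_specific = ft,
       fisher_identical = fi, skipped = skipped, seed = seed)
}

#' Simulation grid plus the observed-versus-null verdict report
#'
#' @param observed_ref,observed_res observed identical-locus counts for the
#'   reference and resistance classes.
#' @param grid grid spec (see [default_sim_grid()]).
#' @param classes gene-class geometry (see [default_gene_classes()]).
#' @param n_replicates replicates per combination.
#' @param seed integer seed.
#' @param out_dir optional directory for `grid.tsv` (long format, one row
#'   per replicate) and `verdicts.tsv`.
#' @return list `grid` (`sim_grid`), `comparison` (`grid_comparison`),
#'   `seed`.
#' @export
run_simulation <- function(observed_ref, observed_res,
                           grid = default_sim_grid(),
                           classes = default_gene_classes(),
                           n_replicates = 100L, seed = 1L, out_dir = NULL) {
  seeds <- stage_seeds(seed)
  g <- run_grid(grid = grid, classes = classes,
                n_replicates = n_replicates, seed = seeds[["simulation"]])
  cmp <- compare_observed_to_grid(observed_ref, observed_res, g)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    long <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      data.frame(g[i, c("class", "m_intro", "T_split_years", "N", "rec")],
                 replicate = seq_along(g$counts[[i]]),
                 count = g$counts[[i]], row.names = NULL)
    }))
    utils::write.table(long, file.path(out_dir, "grid.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cmp$table, file.path(out_dir, "verdicts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(grid = g, comparison = cmp, seed = seed)
}

#' Run the full pipeline and consolidate a report
#'
#' stats -> phylogenetics -> simulation -> tests. The observed
#' identical-locus counts feeding the simulation comparison are taken from
#' the data; permutation tests contrast fixed and shared site proportions
#' between classes. The report embeds the seed and a config fingerprint.
#'
#' @param dataset as in [run_stats()].
#' @param grid,classes,n_replicates simulation settings.
#' @param n_perm permutations for the mean-proportion contrasts.
#' @param n_boot bootstrap resamples for class CIs.
#' @param seed master seed (expanded to per-stage child seeds).
#' @param out_dir optional directory; writes all stage outputs plus
#'   `report.json`.
#' @return a `pipeline_report` list.
#' @export
run_all <- function(dataset, grid = default_sim_grid(),
                    classes = default_gene_classes(),
                    n_replicates = 100L, n_perm = 10000L, n_boot = 1000L,
                    seed = 1L, out_dir = NULL) {
  t0 <- Sys.time()
  seeds <- stage_seeds(seed)
  stats <- run_stats(dataset, n_boot = n_boot, seed = seed,
                     out_dir = out_dir)
  phylo <- run_phylo(dataset, seed = seed, out_dir = out_dir)
  tab <- phylo$calls
  obs <- vapply(c("reference", "resistance"), function(cl)
    sum(tab$identical_pair[tab$class == cl]), numeric(1))
  sim <- run_simulation(observed_ref = obs[["reference"]],
                        observed_res = obs[["resistance"]],
                        grid = grid, classes = classes,
                        n_replicates = n_replicates, seed = seed,
                        out_dir = out_dir)
  pl <- stats$per_locus
  perm <- list()
  for (st in c("prop_fixed", "prop_shared")) {
    v1 <- pl[[st]][pl$class == "resistance"]
    v2 <- pl[[st]][pl$class == "reference"]
    perm[[st]] <- permutation_mean_diff_test(
      v1, v2, n_perm = n_perm, seed = seeds[["tests"]])
  }
  report <- list(
    seed = seed,
    config_hash = config_hash(list(grid = grid, classes = classes,
                                   n_replicates = n_replicates,
                                   n_perm = n_perm, n_boot = n_boot)),
    runtime_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    observed_identical = as.list(obs),
    fisher = list(
      trans_specific_p = if (!is.null(phylo$fisher_trans_specific))
        phylo$fisher_trans_specific$p.value else NA,
      identical_p = if (!is.null(phylo$fisher_identical))
        phylo$fisher_identical$p.value else NA),
    permutation = lapply(perm, function(x)
      list(observed = x$observed, p = x$p_value, decision = x$decision)),
    envelope_summary = sim$comparison$summary,
    class_summary = stats$class_summary,
    n_loci = nrow(stats$per_locus),
    failures = as.list(stats$failures))
  out <- structure(list(stats = stats, phylo = phylo, simulation = sim,
                        permutation = perm, report = report),
                   class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat("<pipeline_report> seed ", r$seed, ", config ", r$config_hash,
      ", ", r$n_loci, " loci, ", sprintf("%.1f", r$runtime_seconds),
      " s\n", sep = "")
  cat("  observed identical-pair loci: reference ",
      r$observed_identical$reference, ", resistance ",
      r$observed_identical$resistance, "\n", sep = "")
  cat("  Fisher p (trans-specific): ", signif(r$fisher$trans_specific_p, 3),
      "; Fisher p (identical): ", signif(r$fisher$identical_p, 3), "\n",
      sep = "")
  for (nm in names(x$permutation))
    cat("  permutation ", nm, ": p = ",
        signif(x$permutation[[nm]]$p_value, 3), " (",
        x$permutation[[nm]]$decision, ")\n", sep = "")
  for (cl in unique(r$envelope_summary$class)) {
    req <- unique(r$envelope_summary$introgression_required[
      r$envelope_summary$class == cl])
    cat("  envelope (", cl, "): introgression ",
        if (isTRUE(req)) "REQUIRED" else "not required", " at m = 0\n",
        sep = "")
  }
  invisible(x)
}
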