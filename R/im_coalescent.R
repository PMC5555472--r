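#' Parameters of the two-population isolation-with-migration model
#'
#' Two species of diploid effective size `N_current` diverge from an
#' ancestor of size `N_ancestral` at `T_split_years` per branch, exchanging
#' lineages at a per-sequence, per-generation probability `m_intro`
#' (symmetric by default). Mutation is infinite-sites at `mu` per site per
#' year; recombination at `rec` per site per generation.
#'
#' @param N_current diploid effective size per species.
#' @param T_split_years years on each branch since the split (>= 0).
#' @param L locus length in bp.
#' @param N_ancestral diploid ancestral size (default `N_current`).
#' @param generation_time_years years per generation (default 1).
#' @param mu mutation rate per site per year (default 4e-9).
#' @param rec recombination rate per site per generation (default 0).
#' @param m_intro per-sequence probability of moving species per generation.
#' @param m_intro_BA optional asymmetric reverse rate (default `m_intro`).
#' @param n_sample_A,n_sample_B haploid sample sizes (defaults 48 and 23).
#' @param n_loci number of independent loci for class-level simulation.
#' @return an `im_params` list.
#' @export
im_params <- function(N_current, T_split_years, L,
                      N_ancestral = N_current,
                      generation_time_years = 1,
                      mu = 4e-9, rec = 0, m_intro = 0,
                      m_intro_BA = m_intro,
                      n_sample_A = 48L, n_sample_B = 23L,
                      n_loci = 1L) {
  stopifnot(N_current > 0, N_ancestral > 0, T_split_years >= 0,
            generation_time_years > 0, mu >= 0, rec >= 0,
            m_intro >= 0, m_intro <= 1, m_intro_BA >= 0, m_intro_BA <= 1,
            L >= 1, n_sample_A >= 1, n_sample_B >= 0, n_loci >= 1)
  structure(list(N_current = N_current, N_ancestral = N_ancestral,
                 T_split_years = T_split_years,
                 generation_time_years = generation_time_years,
                 mu = mu, rec = rec,
                 m_intro = m_intro, m_intro_BA = m_intro_BA,
                 L = L, n_sample_A = as.integer(n_sample_A),
                 n_sample_B = as.integer(n_sample_B),
                 n_loci = as.integer(n_loci)),
            class = "im_params")
}

#' @export
print.im_params <- function(x, ...) {
  cat("<im_params> N=", x$N_current, " (anc ", x$N_ancestral, "), T=",
      x$T_split_years, " yr/branch, mu=", x$mu, "/site/yr, r=", x$rec,
      ", m=", x$m_intro, ", L=", x$L, " bp, samples ", x$n_sample_A, "+",
      x$n_sample_B, ", loci ", x$n_loci, "\n", sep = "")
  invisible(x)
}

#' Simulate one locus under the isolation-with-migration model
#'
#' Structured coalescent with recombination, simulated backwards in time
#' with exponential waiting times (continuous time, never per-generation
#' stepping); infinite-sites mutations are dropped along the ancestral
#' recombination graph. Samples `n_sample_A` haplotypes from species A
#' (lyrata) and `n_sample_B` from species B (halleri).
#'
#' @param params an [im_params()] object.
#' @param seed optional integer seed (uses and advances R's RNG otherwise).
#' @return a `sim_locus`: segregating-mutation positions (bp), a logical
#'   genotype matrix (rows = haplotypes, columns = mutations), species
#'   assignment, and event diagnostics.
#' @export
simulate_locus <- function(params, seed = NULL) {
  stopifnot(inherits(params, "im_params"))
  if (!is.null(seed)) set.seed(seed)
  gt <- params$generation_time_years
  res <- sim_im_locus_cpp(
    n_A = params$n_sample_A, n_B = params$n_sample_B,
    hapN1 = 2 * params$N_current, hapN2 = 2 * params$N_current,
    hapNanc = 2 * params$N_ancestral,
    t_split_gen = params$T_split_years / gt,
    m12 = params$m_intro, m21 = params$m_intro_BA,
    mu_sg = params$mu * gt, rec_sg = params$rec, L = params$L,
    max_events = 2000000L)
  n <- params$n_sample_A + params$n_sample_B
  rownames(res$genotypes) <- c(
    sprintf("lyr_%03d", seq_len(params$n_sample_A)),
    if (params$n_sample_B > 0) sprintf("hal_%03d", seq_len(params$n_sample_B)))
  structure(list(positions = res$positions,
                 genotypes = res$genotypes,
                 species = rep(c("lyrata", "halleri"),
                               c(params$n_sample_A, params$n_sample_B)),
                 L = params$L,
                 n_recombination_events = res$n_recombination_events,
                 n_migration_events = res$n_migration_events,
                 tree_material = res$tree_material,
                 t_gmrca = res$t_gmrca),
            class = "sim_locus")
}

#' @export
print.sim_locus <- function(x, ...) {
  cat("<sim_locus> ", nrow(x$genotypes), " haplotypes, ",
      length(x$positions), " segregating mutations over ", x$L, " bp (",
      x$n_recombination_events, " recombinations, ",
      x$n_migration_events, " migrations)\n", sep = "")
  invisible(x)
}

#' Is some interspecific haplotype pair identical?
#'
#' Under infinite sites, TRUE iff some species-A haplotype and some
#' species-B haplotype are separated by zero differentiating mutations.
#'
#' @param locus a `sim_locus`.
#' @return logical.
#' @export
identical_interspecific_indicator <- function(locus) {
  stopifnot(inherits(locus, "sim_locus"))
  a <- locus$species == "lyrata"
  b <- locus$species == "halleri"
  if (!any(a) || !any(b)) stop("both samples must be non-empty")
  if (length(locus$positions) == 0L) return(TRUE)
  key <- apply(locus$genotypes, 1L, paste, collapse = "")
  any(key[a] %in% key[b])
}

#' Replicate distribution of the identical-locus count for one gene class
#'
#' Per replicate, simulates `params$n_loci` independent loci and counts how
#' many carry at least one identical interspecific haplotype pair.
#'
#' @param params an [im_params()] object (with `n_loci` set).
#' @param n_replicates number of replicates (default 100).
#' @param seed optional integer seed.
#' @return a `sim_class_result`: replicate counts plus 2.5/50/97.5
#'   percent quantiles.
#' @export
simulate_gene_class <- function(params, n_replicates = 100L, seed = NULL) {
  stopifnot(inherits(params, "im_params"))
  if (!is.null(seed)) set.seed(seed)
  counts <- vapply(seq_len(n_replicates), function(r) {
    sum(vapply(seq_len(params$n_loci), function(l)
      identical_interspecific_indicator(simulate_locus(params)),
      logical(1)))
  }, numeric(1))
  q <- quantile(counts, c(0.025, 0.5, 0.975), type = 7)
  structure(list(counts = counts,
                 q025 = unname(q[[1]]), q50 = unname(q[[2]]),
                 q975 = unname(q[[3]]),
                 n_loci = params$n_loci, n_replicates = n_replicates,
                 params = params),
            class = "sim_class_result")
}

#' Default gene-class geometry mirroring the study design
#'
#' Reference-like: 37 loci x 513 bp; resistance-like: 10 loci x 730 bp;
#' 48 + 23 haploid samples in both classes (reference-class per-locus sample
#' sizes are not published in the main text; the documented default reuses
#' 48/23).
#'
#' @return named list of class specs (`n_loci`, `L`, `n_A`, `n_B`).
#' @export
default_gene_classes <- function() {
  list(reference = list(n_loci = 37L, L = 513L, n_A = 48L, n_B = 23L),
       resistance = list(n_loci = 10L, L = 730L, n_A = 48L, n_B = 23L))
}

#' Default simulation parameter grid
#'
#' The six distinct printed introgression rates, both split times (0.56 and
#' 0.75 MY per branch), both population sizes (150,000 and 600,000, also
#' used as ancestral sizes) and both recombination rates (0 and 4.3e-9);
#' mutation rate 4e-9 per site per year, generation time 1 year.
#'
#' `N_unit = "gene_copies"`: the study ran fastsimcoal2, whose population
#' sizes are specified in numbers of gene copies (haploid counts), so the
#' printed sizes are taken as haploid 2N; only this reading reproduces the
#' study's envelope result (see the methods vignette). Set
#' `N_unit = "diploids"` to read the same numbers as diploid individuals.
#'
#' @return list of grid vectors and scalars.
#' @export
default_sim_grid <- function() {
  list(m_intro = c(0, 2e-8, 4e-8, 8e-8, 1e-7, 1.5e-7),
       T_split_years = c(560000, 750000),
       N = c(150000, 600000),
       rec = c(0, 4.3e-9),
       mu = 4e-9,
       generation_time_years = 1,
       N_unit = "gene_copies")
}

#' Run the full simulation grid for both gene classes
#'
#' Full factorial over introgression rate, split time, population size and
#' recombination rate, for each gene class. A master seed is expanded into
#' one child seed per (combination, class) row, so any row is independently
#' reproducible.
#'
#' @param grid list as returned by [default_sim_grid()] (vectors `m_intro`,
#'   `T_split_years`, `N`, `rec`; scalars `mu`, `generation_time_years`;
#'   optional `N_unit`, `"diploids"` when absent).
#' @param classes list as returned by [default_gene_classes()].
#' @param n_replicates replicates per combination (default 100).
#' @param seed master integer seed.
#' @return a `sim_grid` data.frame with one row per combination x class:
#'   grid values, quantiles `q025`, `q50`, `q975`, and a `counts`
#'   list-column of replicate counts.
#' @export
run_grid <- function(grid = default_sim_grid(),
                     classes = default_gene_classes(),
                     n_replicates = 100L, seed = 1L) {
  combos <- expand.grid(m_intro = grid$m_intro,
                        T_split_years = grid$T_split_years,
                        N = grid$N, rec = grid$rec,
                        class = names(classes),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(combos) == 0L) stop("empty grid")
  n_unit <- if (is.null(grid$N_unit)) "diploids" else
    match.arg(grid$N_unit, c("diploids", "gene_copies"))
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cl <- classes[[combos$class[i]]]
    p <- im_params(N_current = if (n_unit == "gene_copies") combos$N[i] / 2
                               else combos$N[i],
                   T_split_years = combos$T_split_years[i],
                   L = cl$L, mu = grid$mu,
                   generation_time_years = grid$generation_time_years,
                   rec = combos$rec[i], m_intro = combos$m_intro[i],
                   n_sample_A = cl$n_A, n_sample_B = cl$n_B,
                   n_loci = cl$n_loci)
    res <- simulate_gene_class(p, n_replicates = n_replicates,
                               seed = child_seeds[i])
    rows[[i]] <- data.frame(combos[i, , drop = FALSE],
                            q025 = res$q025, q50 = res$q50, q975 = res$q975,
                            mean_count = mean(res$counts),
                            seed = child_seeds[i])
    rows[[i]]$counts <- I(list(res$counts))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_replicates") <- n_replicates
  attr(out, "master_seed") <- seed
  class(out) <- c("sim_grid", "data.frame")
  out
}

#' @export
print.sim_grid <- function(x, ...) {
  nrep <- attr(x, "n_replicates")
  ms <- attr(x, "master_seed")
  cat("<sim_grid> ", nrow(x), " rows",
      if (!is.null(nrep)) paste0(" (", nrep, " replicates each, master seed ",
                                 ms, ")"),
      "\n", sep = "")
  print.data.frame(x[, setdiff(names(x), "counts")], ...)
  invisible(x)
}

#' Cross-validate the simulator against msprime
#'
#' Runs matched single-population and isolation-with-migration scenarios in
#' this package and in msprime (via the bundled python oracle script) and
#' reports z-scores on mean segregating sites, mean pairwise diversity and
#' the interspecific identity probability. msprime is an oracle only; it is
#' never used for the package's own simulations.
#'
#' @param n_replicates replicates per scenario and engine.
#' @param seed integer seed.
#' @param python python executable to try.
#' @return a `cross_validation` list with `status` (`"ok"` or
#'   `"oracle unavailable"`) and a data.frame of per-scenario z-scores.
#' @export
cross_validate_simulator <- function(n_replicates = 2000L, seed = 1L,
                                     python = "python") {
  script <- system.file("oracle", "msprime_oracle.py", package = "adintro")
  probe <- tryCatch(
    suppressWarnings(system2(python, c("-c", shQuote("import msprime")),
                             stdout = TRUE, stderr = TRUE)),
    error = function(e) "FAIL", warning = function(w) "FAIL")
  if (!identical(attr(probe, "status"), NULL) || identical(probe, "FAIL"))
    return(structure(list(status = "oracle unavailable", table = NULL),
                     class = "cross_validation"))

  scen <- list(
    single_pop = list(mode = "single_pop", n = 10, hapN = 2000, mu = 5e-6,
                      L = 500, rec = 0, t_split = 0, m = 0),
    im_identity = list(mode = "im", n_A = 4, n_B = 4, hapN = 1000,
                       hapNanc = 1000, mu = 2e-6, L = 500, rec = 0,
                       t_split = 800, m = 5e-4),
    recombination = list(mode = "single_pop", n = 8, hapN = 2000, mu = 5e-6,
                         L = 500, rec = 2e-5, t_split = 0, m = 0))

  set.seed(seed)
  ours <- lapply(scen, function(sc) {
    S <- numeric(n_replicates); pi <- numeric(n_replicates)
    ident <- logical(n_replicates)
    for (r in seq_len(n_replicates)) {
      if (sc$mode == "single_pop") {
        p <- im_params(N_current = sc$hapN / 2, T_split_years = 0, L = sc$L,
                       mu = sc$mu, rec = sc$rec, n_sample_A = sc$n,
                       n_sample_B = 0L)
      } else {
        p <- im_params(N_current = sc$hapN / 2,
                       N_ancestral = sc$hapNanc / 2,
                       T_split_years = sc$t_split, L = sc$L, mu = sc$mu,
                       rec = sc$rec, m_intro = sc$m,
                       n_sample_A = sc$n_A, n_sample_B = sc$n_B)
      }
      sim <- simulate_locus(p)
      S[r] <- length(sim$positions)
      g <- sim$genotypes
      pi[r] <- if (ncol(g) == 0L) 0 else {
        f <- colMeans(g)
        n <- nrow(g)
        sum(2 * f * (1 - f) * n / (n - 1)) / sc$L
      }
      ident[r] <- if (sc$mode == "im")
        identical_interspecific_indicator(sim) else NA
    }
    list(S = S, pi = pi, ident = ident)
  })

  args <- list(seed = seed, n_replicates = n_replicates, scenarios = scen)
  inp <- tempfile(fileext = ".json")
  jsonlite::write_json(args, inp, auto_unbox = TRUE, digits = NA)
  out <- tryCatch(system2(python, c(shQuote(script), shQuote(inp)),
                          stdout = TRUE, stderr = ""),
                  error = function(e) NULL)
  if (is.null(out) || !length(out))
    return(structure(list(status = "oracle unavailable", table = NULL),
                     class = "cross_validation"))
  oracle <- jsonlite::fromJSON(paste(out, collapse = ""))

  zrow <- function(name, x, y_mean, y_se) {
    se <- sqrt(sd(x)^2 / length(x) + y_se^2)
    data.frame(scenario = name[[1]], statistic = name[[2]],
               ours = mean(x), oracle = y_mean,
               z = (mean(x) - y_mean) / se)
  }
  tab <- rbind(
    zrow(c("single_pop", "mean_S"), ours$single_pop$S,
         oracle$single_pop$mean_S, oracle$single_pop$se_S),
    zrow(c("im_identity", "identity_prob"),
         as.numeric(ours$im_identity$ident),
         oracle$im_identity$identity_prob, oracle$im_identity$se_identity),
    zrow(c("recombination", "mean_pi"), ours$recombination$pi,
         oracle$recombination$mean_pi, oracle$recombination$se_pi))
  structure(list(status = "ok", table = tab), class = "cross_validation")
}

#' @export
print.cross_validation <- function(x, ...) {
  cat("<cross_validation> status:", x$status, "\n")
  if (!is.null(x$table)) print(x$table, ...)
  invisible(x)
}
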