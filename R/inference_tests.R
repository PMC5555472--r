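#' Simulation-envelope test against a replicate null distribution
#'
#' The observed count is compared with the central `1 - 2*tail` envelope of
#' the replicate distribution (empirical quantiles, type-7 interpolation).
#' Decision: `"excess"` if the observation lies strictly above the upper
#' quantile, `"deficit"` if strictly below the lower one, else
#' `"consistent"`; ties at a quantile count as consistent (conservative).
#'
#' @param observed observed count.
#' @param replicate_counts numeric vector of simulated counts (>= 20).
#' @param tail tail mass on each side (default 0.025).
#' @return a `test_verdict` list.
#' @export
envelope_test <- function(observed, replicate_counts, tail = 0.025) {
  if (length(replicate_counts) == 0L) stop("empty replicate vector")
  if (length(replicate_counts) < 20L)
    warning("fewer than 20 replicates; envelope quantiles are unstable")
  q <- quantile(replicate_counts, c(tail, 1 - tail), type = 7)
  decision <- if (observed > q[[2]]) "excess"
              else if (observed < q[[1]]) "deficit"
              else "consistent"
  structure(list(test_name = "simulation envelope",
                 observed = observed,
                 null_summary = c(q_lo = unname(q[[1]]),
                                  q_median = unname(quantile(replicate_counts,
                                                             0.5, type = 7)),
                                  q_hi = unname(q[[2]])),
                 tail = tail,
                 decision = decision,
                 n_resamples = length(replicate_counts)),
            class = "test_verdict")
}

#' @export
print.test_verdict <- function(x, ...) {
  cat("<test_verdict> ", x$test_name, ": observed ", x$observed, sep = "")
  if (!is.null(x$null_summary))
    cat(" vs null [", paste(signif(x$null_summary, 4), collapse = ", "),
        "]", sep = "")
  if (!is.null(x$p_value)) cat(", p = ", signif(x$p_value, 4), sep = "")
  cat(" -> ", x$decision, "\n", sep = "")
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value by the point-probability rule:
#' the sum of probabilities of all tables (with the observed margins) whose
#' probability does not exceed the observed table's. Computed log-stably
#' via `dhyper`.
#'
#' @param table 2x2 matrix (or something coercible) of non-negative integer
#'   counts with positive margins.
#' @return an object of class `htest` with the two-sided `p.value`.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  m <- sum(tab[1, ])              # row-1 total
  n <- sum(tab[2, ])              # row-2 total
  k <- sum(tab[, 1])              # column-1 total
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  structure(list(statistic = NULL, p.value = p,
                 estimate = c(`odds ratio (sample)` =
                                unname((tab[1, 1] * tab[2, 2]) /
                                         (tab[1, 2] * tab[2, 1]))),
                 alternative = "two.sided",
                 method = "Fisher's exact test (2x2, point-probability rule)",
                 data.name = deparse(substitute(table))),
            class = "htest")
}

#' Permutation test for a difference in class means
#'
#' Statistic: absolute difference of unweighted class means (each locus one
#' observation). The null is built by shuffling class labels over the pooled
#' loci; `p = (1 + #{perm >= obs}) / (1 + n_perm)` (two-sided by
#' construction).
#'
#' @param values_class1,values_class2 numeric per-locus values.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @return a `test_verdict` list with `p_value` and `decision`
#'   (`"significant"` at 0.05 or `"not_significant"`).
#' @export
permutation_mean_diff_test <- function(values_class1, values_class2,
                                       n_perm = 10000L, seed = NULL) {
  if (!length(values_class1) || !length(values_class2))
    stop("both classes must be non-empty")
  if (n_perm < 100L) warning("n_perm < 100: permutation p is coarse")
  if (!is.null(seed)) set.seed(seed)
  x <- c(values_class1, values_class2)
  n1 <- length(values_class1)
  obs <- abs(mean(values_class1) - mean(values_class2))
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(x), n1)
    abs(mean(x[idx]) - mean(x[-idx]))
  }, numeric(1))
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  structure(list(test_name = "permutation test on class means",
                 observed = obs,
                 null_summary = quantile(perm, c(0.5, 0.95, 0.99), type = 7),
                 p_value = p,
                 decision = if (p < 0.05) "significant" else "not_significant",
                 n_resamples = n_perm),
            class = "test_verdict")
}

#' Compare observed identical-locus counts with a simulation grid
#'
#' Applies [envelope_test()] per grid row against the observed count for
#' that row's gene class, and summarizes, per parameter combination, the
#' minimal introgression rate whose envelope contains the observation.
#'
#' @param observed_ref observed count for the reference class.
#' @param observed_res observed count for the resistance class.
#' @param grid a `sim_grid` from [run_grid()].
#' @param tail envelope tail mass (default 0.025).
#' @return a `grid_comparison`: per-row verdict table plus a per-class
#'   summary with an `introgression_required` flag (TRUE when the
#'   observation is outside every m = 0 envelope).
#' @export
compare_observed_to_grid <- function(observed_ref, observed_res, grid,
                                     tail = 0.025) {
  stopifnot(inherits(grid, "sim_grid"))
  obs_of <- c(reference = observed_ref, resistance = observed_res)
  if (!all(grid$class %in% names(obs_of)))
    stop("grid classes must be 'reference' and 'resistance'")
  verdicts <- character(nrow(grid))
  qlo <- qhi <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    v <- envelope_test(obs_of[[grid$class[i]]], grid$counts[[i]], tail = tail)
    verdicts[i] <- v$decision
    qlo[i] <- v$null_summary[["q_lo"]]
    qhi[i] <- v$null_summary[["q_hi"]]
  }
  tab <- data.frame(grid[, c("class", "m_intro", "T_split_years", "N", "rec")],
                    observed = obs_of[grid$class],
                    q025 = qlo, q975 = qhi, decision = verdicts,
                    row.names = NULL)

  combo_key <- interaction(tab$T_split_years, tab$N, tab$rec, drop = TRUE)
  summ <- do.call(rbind, lapply(names(obs_of), function(cl) {
    sel <- tab$class == cl
    per_combo <- tapply(seq_len(nrow(tab))[sel], combo_key[sel], function(ii) {
      ok <- tab$m_intro[ii][tab$decision[ii] == "consistent"]
      if (length(ok)) min(ok) else NA_real_
    })
    m0 <- tab$class == cl & tab$m_intro == 0
    data.frame(class = cl,
               combo = names(per_combo),
               min_consistent_m = as.numeric(per_combo),
               introgression_required = all(tab$decision[m0] != "consistent"),
               row.names = NULL)
  }))
  structure(list(table = tab, summary = summ, tail = tail),
            class = "grid_comparison")
}

#' @export
print.grid_comparison <- function(x, ...) {
  cat("<grid_comparison> envelope tail ", x$tail, "\n", sep = "")
  for (cl in unique(x$summary$class)) {
    req <- unique(x$summary$introgression_required[x$summary$class == cl])
    cat("  ", cl, ": introgression ",
        if (isTRUE(req)) "REQUIRED" else "not required",
        " to explain the observation at m = 0\n", sep = "")
  }
  print(x$table, ...)
  invisible(x)
}
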