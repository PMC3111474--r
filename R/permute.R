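#' Permuted-motif null distribution of the rewiring rate
#'
#' For each replicate, the PSSM's positions (rows) and base identities
#' (columns) are independently shuffled once each ([permute_pssm()]), the
#' stored promoter windows are rescanned with the shuffled matrix, the
#' model is refitted, states are decoded, and the rewiring rate is
#' recomputed. The observed (unpermuted) rate is produced by the identical
#' rescan-refit path with the original matrix, so the identity permutation
#' reproduces it exactly. The mode of the null is taken from a histogram
#' with bin width `bin_width` (default 0.05).
#'
#' @param data a `tn_data` holding window sequences.
#' @param tree a [tn_tree()].
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed; the replicate permutations derive from it.
#' @param weight expression weight used in every fit.
#' @param denominator passed to [rewiring_rate()].
#' @param bin_width histogram bin width for the mode.
#' @param max_iter,tol EM controls passed to [tn_fit()].
#' @return An object of class `tn_permnull`: `rates` (length `n_perm`),
#'   `observed`, `mode`, `quantiles` (2.5/25/50/75/97.5%), `seed`.
#' @export
permutation_null <- function(data, tree, n_perm = 50L, seed = 1L, weight = 1,
                             denominator = "all_groups", bin_width = 0.05,
                             max_iter = 50L, tol = 1e-5) {
  stopifnot(inherits(data, "tn_data"))
  if (n_perm < 1L) stop_tn("'n_perm' must be >= 1")
  if (data$pssm$width < 2L) stop_tn("PSSM must have >= 2 positions to permute")
  tree <- tn_tree(tree)

  rate_for_pssm <- function(pssm) {
    d <- tn_data_from_windows(data$windows, data$labels, pssm,
                              data$seq_params, K = data$K,
                              groups = data$groups)
    fit <- tn_fit(d, tree, weight = weight, max_iter = max_iter, tol = tol)
    rewiring_rate(predict(fit), denominator = denominator)$rate
  }

  observed <- rate_for_pssm(data$pssm)
  rates <- vapply(seq_len(n_perm), function(b)
    rate_for_pssm(permute_pssm(data$pssm, derive_seed(seed, paste0("perm", b)))),
    0)

  breaks <- seq(0, 1 + bin_width, by = bin_width)
  h <- graphics::hist(rates, breaks = breaks, plot = FALSE)
  structure(list(rates = rates, observed = observed,
                 mode = h$mids[which.max(h$counts)],
                 quantiles = stats::quantile(rates, c(.025, .25, .5, .75, .975)),
                 bin_width = bin_width, n_perm = n_perm, seed = seed),
            class = "tn_permnull")
}

#' @export
print.tn_permnull <- function(x, ...) {
  cat(sprintf("permutation null (%d replicates): observed rate %.3f, null mode %.3f\n",
              x$n_perm, x$observed, x$mode))
  print(round(x$quantiles, 3))
  invisible(x)
}

#' Write a permutation-null distribution as TSV
#' @param null a `tn_permnull`.
#' @param path output path.
#' @export
write_null_tsv <- function(null, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#observed\t%.10g", null$observed), con)
  writeLines("#replicate\trate", con)
  utils::write.table(data.frame(seq_along(null$rates), null$rates), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
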