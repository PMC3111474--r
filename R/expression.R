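#' Filter ortholog groups by coefficient of variation of expression
#'
#' A group is retained iff at least one member gene shows a clear change of
#' expression across conditions: coefficient of variation (sd / mean over
#' conditions) above `threshold` in at least one species. Genes with zero
#' mean get CV 0 with a warning.
#'
#' @param expr_list named list (by species) of numeric matrices, rows =
#'   genes (rownames required), columns = conditions/stages.
#' @param ortholog_map data frame with column `group` plus one gene-id
#'   column per species (named by species).
#' @param threshold CV cutoff; default 1.26.
#' @return Character vector of retained group ids.
#' @export
filter_by_cv <- function(expr_list, ortholog_map, threshold = 1.26) {
  stopifnot(is.list(expr_list), is.data.frame(ortholog_map),
            "group" %in% names(ortholog_map))
  species <- setdiff(names(ortholog_map), "group")
  if (!all(species %in% names(expr_list)))
    stop_tn("every species column of the ortholog map needs an expression matrix")
  cv_of <- function(mat) {
    if (ncol(mat) < 2L) stop_tn("need >= 2 conditions to compute CV")
    mu <- rowMeans(mat)
    s <- apply(mat, 1L, stats::sd)
    cv <- ifelse(mu == 0, 0, s / mu)
    if (any(mu == 0))
      warning("zero-mean expression profile(s): CV set to 0", call. = FALSE)
    cv
  }
  cvs <- lapply(expr_list[species], cv_of)
  keep <- vapply(seq_len(nrow(ortholog_map)), function(i) {
    any(vapply(species, function(sp) {
      g <- as.character(ortholog_map[[sp]][i])
      !is.na(cvs[[sp]][g]) && cvs[[sp]][g] > threshold
    }, TRUE))
  }, TRUE)
  as.character(ortholog_map$group[keep])
}

#' Cluster one species' expression profiles with k-means
#'
#' Profiles are standardized per gene (z-score across conditions) before
#' clustering, so clusters capture profile shape rather than absolute
#' level. Clustering is per species and deterministic given `seed`.
#' Genes in singleton clusters are flagged; model fitting drops them.
#'
#' @param expr numeric matrix, rows = genes (rownames required), columns =
#'   conditions.
#' @param k number of centers (>= 1, <= number of genes).
#' @param seed integer seed.
#' @param n_restarts `nstart` for [stats::kmeans()].
#' @param standardize z-score rows first (default TRUE).
#' @return An object of class `tn_clustering`: `labels` (named integer
#'   vector in 1..K), `K`, `singleton` (logical per gene), `sizes`.
#' @export
kmeans_cluster <- function(expr, k, seed = 1L, n_restarts = 10L,
                           standardize = TRUE) {
  stopifnot(is.matrix(expr) || is.data.frame(expr))
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop_tn("expression matrix needs gene rownames")
  if (k < 1L) stop_tn("'k' must be >= 1")
  if (k > nrow(expr)) stop_tn("'k' cannot exceed the number of genes")
  x <- expr
  if (standardize) {
    s <- apply(x, 1L, stats::sd)
    s[s == 0] <- 1
    x <- (x - rowMeans(x)) / s
  }
  set.seed(as.integer(seed))
  km <- if (k == 1L) list(cluster = rep(1L, nrow(x)))
        else stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 100L)
  labels <- stats::setNames(as.integer(km$cluster), rownames(expr))
  sizes <- tabulate(labels, nbins = k)
  structure(list(labels = labels, K = as.integer(k),
                 singleton = stats::setNames(sizes[labels] == 1L, names(labels)),
                 sizes = sizes),
            class = "tn_clustering")
}

#' @export
print.tn_clustering <- function(x, ...) {
  cat(sprintf("tn_clustering: %d genes in %d clusters (%d singletons)\n",
              length(x$labels), x$K, sum(x$singleton)))
  invisible(x)
}

#' Weighted multinomial estimate over cluster indices
#'
#' The M-step sufficient statistic for the expression multinomials:
#' `theta[c]` proportional to `smoothing + sum of weights of genes with
#' label c`. With unit weights this is the smoothed empirical frequency.
#'
#' @param labels integer cluster labels in 1..K.
#' @param weights per-gene weights in `[0, 1]`; default 1.
#' @param K number of clusters (default `max(labels)`).
#' @param smoothing pseudocount per cluster; default 0.5, which keeps every
#'   entry positive (no log(0) for empty clusters).
#' @return Probability vector of length K.
#' @export
estimate_multinomial <- function(labels, weights = 1, K = max(labels),
                                 smoothing = 0.5) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > K))
    stop_tn("labels must be integers in 1..K")
  weights <- rep_len(weights, length(labels))
  if (any(weights < 0) || any(weights > 1))
    stop_tn("weights must be in [0, 1]")
  counts <- vapply(seq_len(K), function(c) sum(weights[labels == c]), 0)
  if (all(counts == 0) && smoothing == 0) {
    warning("all-zero weights: returning the uniform distribution", call. = FALSE)
    return(rep(1 / K, K))
  }
  th <- counts + smoothing
  if (all(counts == 0))
    warning("all-zero weights: estimate driven by smoothing alone", call. = FALSE)
  th / sum(th)
}

#' Per-species target/background expression multinomials
#'
#' @param theta0 named list (by species) of background multinomials over
#'   that species' clusters.
#' @param theta1 named list (by species) of target multinomials; same
#'   lengths as `theta0`.
#' @return An object of class `tn_expr_params`. Cluster counts K may
#'   differ across species.
#' @export
tn_expr_params <- function(theta0, theta1) {
  stopifnot(is.list(theta0), is.list(theta1),
            setequal(names(theta0), names(theta1)))
  for (sp in names(theta0)) {
    t0 <- theta0[[sp]]; t1 <- theta1[[sp]]
    if (length(t0) != length(t1))
      stop_tn(sprintf("theta0/theta1 length mismatch for species '%s'", sp))
    if (any(t0 <= 0) || any(t1 <= 0) ||
        abs(sum(t0) - 1) > 1e-9 || abs(sum(t1) - 1) > 1e-9)
      stop_tn(sprintf("theta vectors for '%s' must be positive and sum to 1", sp))
  }
  structure(list(theta0 = theta0, theta1 = theta1,
                 K = vapply(theta0, length, 0L)),
            class = "tn_expr_params")
}

#' Conditional log-likelihood of a cluster label given the regulatory state
#'
#' `z = 0`: `log theta0[label]` (background multinomial); `z = 1`:
#' `log theta1[label]` (target multinomial). Targets of the same TF tend to
#' concentrate in a subset of clusters, which is what separates theta1
#' from theta0.
#'
#' @param label cluster index in 1..K of `species`.
#' @param z 0 or 1.
#' @param params a [tn_expr_params()].
#' @param species species id.
#' @return Log-probability.
#' @export
expr_loglik <- function(label, z, params, species) {
  stopifnot(inherits(params, "tn_expr_params"))
  if (!species %in% names(params$theta0)) stop_tn("unknown species")
  K <- params$K[[species]]
  label <- as.integer(label)
  if (is.na(label) || label < 1L || label > K)
    stop_tn(sprintf("label must be in 1..%d for species '%s'", K, species))
  if (!z %in% c(0, 1)) stop_tn("'z' must be 0 or 1")
  if (z == 0) log(params$theta0[[species]][label])
  else log(params$theta1[[species]][label])
}
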