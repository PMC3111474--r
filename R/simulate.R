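#' Default three-species study phylogeny
#'
#' A rooted three-taxon tree with divergence times on the scale of the
#' rate parameters' inverse; used by the simulation scenarios.
#' @return A [tn_tree()].
#' @export
default_tree <- function() {
  tn_tree("((sp1:0.25,sp2:0.25):0.15,sp3:0.40);")
}

# sharp-or-flat motif around an octamer consensus
scenario_pssm <- function(consensus = "ATGCAAAT", match_prob = 0.85) {
  w <- nchar(consensus)
  m <- matrix((1 - match_prob) / 3, w, 4L, dimnames = list(NULL, BASES))
  idx <- match(strsplit(consensus, "")[[1L]], BASES)
  m[cbind(seq_len(w), idx)] <- match_prob
  build_pssm(m)
}

# theta1 diverging from uniform theta0 by a given total-variation distance
scenario_thetas <- function(K, tv, species) {
  theta0 <- rep(1 / K, K)
  theta1 <- c(theta0[1L] + tv, rep((1 - theta0[1L] - tv) / (K - 1L), K - 1L))
  tn_expr_params(
    theta0 = stats::setNames(rep(list(theta0), length(species)), species),
    theta1 = stats::setNames(rep(list(theta1), length(species)), species))
}

#' Define a synthetic-data scenario
#'
#' The six canonical scenarios are the cross of two sequence-signal levels
#' and three expression-signal levels. Sequence signal controls the
#' information in planted motifs: `strong` uses a sharp PSSM (consensus
#' probability 0.85) and motif rate `q_true = 0.012`; `weak` a flatter
#' PSSM (0.75) and `q_true = 0.008`. Expression signal sets the
#' total-variation distance between the target and background cluster
#' multinomials: 0.6 (`strong`), 0.3 (`medium`), 0.1 (`weak`), over K = 6
#' clusters. States evolve on [default_tree()] with gain = loss = 0.5 and
#' root prior 0.5. Every knob can be overridden.
#'
#' @param seq_signal `"strong"` or `"weak"`.
#' @param expr_signal `"strong"`, `"medium"` or `"weak"`.
#' @param M number of ortholog groups.
#' @param window_length window length in bp (>= motif width).
#' @param seed scenario seed; all randomness derives from it.
#' @param tree,rates,K,q_true,match_prob,theta_tv,background overrides of
#'   the scenario defaults.
#' @return An object of class `tn_scenario`.
#' @export
tn_scenario <- function(seq_signal = c("strong", "weak"),
                        expr_signal = c("strong", "medium", "weak"),
                        M = 500L, window_length = 500L, seed = 1L,
                        tree = default_tree(), rates = tn_rates(0.5, 0.5, 0.5),
                        K = 6L, q_true = NULL, match_prob = NULL,
                        theta_tv = NULL, background = rep(0.25, 4)) {
  seq_signal <- match.arg(seq_signal)
  expr_signal <- match.arg(expr_signal)
  if (is.null(q_true)) q_true <- c(strong = 0.012, weak = 0.008)[[seq_signal]]
  if (is.null(match_prob)) match_prob <- c(strong = 0.85, weak = 0.75)[[seq_signal]]
  if (is.null(theta_tv))
    theta_tv <- c(strong = 0.6, medium = 0.3, weak = 0.1)[[expr_signal]]
  tree <- tn_tree(tree)
  if (M < 1L) stop_tn("'M' must be >= 1")
  pssm <- scenario_pssm(match_prob = match_prob)
  if (window_length < pssm$width)
    stop_tn("'window_length' must fit at least one motif")
  structure(list(seq_signal = seq_signal, expr_signal = expr_signal,
                 M = as.integer(M), window_length = as.integer(window_length),
                 seed = as.integer(seed), tree = tree, rates = rates,
                 K = as.integer(K), q_true = q_true, match_prob = match_prob,
                 theta_tv = theta_tv, background = background / sum(background),
                 pssm = pssm,
                 expr_params = scenario_thetas(K, theta_tv, tree$species)),
            class = "tn_scenario")
}

#' @export
print.tn_scenario <- function(x, ...) {
  cat(sprintf("tn_scenario: seq %s (q = %.3g, match %.2f), expr %s (TV %.2f), M = %d, seed = %d\n",
              x$seq_signal, x$q_true, x$match_prob, x$expr_signal, x$theta_tv,
              x$M, x$seed))
  invisible(x)
}

#' The six canonical simulation scenarios
#' @param M groups per scenario.
#' @param seed base seed (each scenario derives its own).
#' @param ... passed to [tn_scenario()].
#' @return Named list of six `tn_scenario` objects.
#' @export
six_scenarios <- function(M = 500L, seed = 1L, ...) {
  grid <- expand.grid(seq_signal = c("strong", "weak"),
                      expr_signal = c("strong", "medium", "weak"),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i)
    tn_scenario(grid$seq_signal[i], grid$expr_signal[i], M = M,
                seed = derive_seed(seed, paste0("scn", i)), ...))
  names(out) <- paste(grid$seq_signal, grid$expr_signal, sep = "/")
  out
}

#' Draw leaf regulatory-state configurations from the phylogenetic chain
#'
#' The root state is Bernoulli(`pi_root`); each branch applies
#' [transition_matrix()] for its length, parent before child.
#'
#' @param tree a [tn_tree()].
#' @param rates a [tn_rates()].
#' @param M number of independent draws (ortholog groups).
#' @param seed integer seed.
#' @return M x N 0/1 matrix over the (sorted) leaf species, with the full
#'   node-state matrix in `attr(, "node_states")`.
#' @export
simulate_states <- function(tree, rates, M, seed = 1L) {
  tree <- tn_tree(tree)
  stopifnot(inherits(rates, "tn_rates"), M >= 1L)
  set.seed(as.integer(seed))
  st <- matrix(0L, M, tree$n_nodes)
  st[, tree$root] <- stats::rbinom(M, 1L, rates$pi_root)
  edges <- ape::reorder.phylo(tree$phylo, "postorder")$edge
  for (e in rev(seq_len(nrow(edges)))) {  # preorder: parent before child
    par <- edges[e, 1L]; ch <- edges[e, 2L]
    P <- transition_matrix(rates, tree$blen[ch])
    st[, ch] <- stats::rbinom(M, 1L, P[st[, par] + 1L, 2L])
  }
  leaf <- st[, tree$tip_index[tree$species], drop = FALSE]
  colnames(leaf) <- tree$species
  attr(leaf, "node_states") <- st
  leaf
}

# plant one motif instance drawn from the PSSM (random strand)
draw_motif <- function(pssm) {
  inst <- vapply(seq_len(pssm$width), function(k)
    sample(BASES, 1L, prob = pssm$probs[k, ]), "")
  if (stats::runif(1) < 0.5) inst <- rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
  paste(inst, collapse = "")
}

#' Simulate promoter windows given regulatory states
#'
#' Non-targets (`z = 0`) are i.i.d. background. Targets (`z = 1`) are
#' background with motif instances planted: every position opens a motif
#' with probability `q_true` (overlapping candidates dropped left to
#' right), and each instance is drawn from the PSSM on a random strand.
#'
#' @param configs M x N 0/1 matrix (from [simulate_states()]).
#' @param pssm a `tn_pssm` (the true motif).
#' @param q_true motif rate for targets.
#' @param window_length window length in bp.
#' @param background base frequencies.
#' @param seed integer seed.
#' @return M x N character matrix of window sequences.
#' @export
simulate_sequences <- function(configs, pssm, q_true, window_length = 500L,
                               background = rep(0.25, 4), seed = 1L) {
  stopifnot(inherits(pssm, "tn_pssm"))
  if (window_length < pssm$width)
    stop_tn("window too short to hold one motif instance")
  set.seed(as.integer(seed))
  M <- nrow(configs); N <- ncol(configs)
  w <- pssm$width
  out <- matrix("", M, N, dimnames = dimnames(configs))
  for (j in seq_len(N)) for (i in seq_len(M)) {
    bases <- sample(BASES, window_length, replace = TRUE, prob = background)
    if (configs[i, j] == 1L) {
      cand <- which(stats::runif(window_length) < q_true)
      cand <- cand[cand <= window_length - w + 1L]
      last_end <- 0L
      for (s in cand) {
        if (s > last_end) {
          bases[s:(s + w - 1L)] <- strsplit(draw_motif(pssm), "")[[1L]]
          last_end <- s + w - 1L
        }
      }
    }
    out[i, j] <- paste(bases, collapse = "")
  }
  out
}

#' Simulate expression-cluster labels given regulatory states
#'
#' Labels are drawn from the target multinomial `theta1` when `z = 1` and
#' the background multinomial `theta0` otherwise, independently per
#' species.
#'
#' @param configs M x N 0/1 matrix.
#' @param expr_params a [tn_expr_params()] over the same species.
#' @param seed integer seed.
#' @return M x N integer matrix of cluster labels.
#' @export
simulate_expression <- function(configs, expr_params, seed = 1L) {
  stopifnot(inherits(expr_params, "tn_expr_params"))
  set.seed(as.integer(seed))
  M <- nrow(configs)
  out <- matrix(0L, M, ncol(configs), dimnames = dimnames(configs))
  for (j in seq_len(ncol(configs))) {
    sp <- colnames(configs)[j]
    K <- expr_params$K[[sp]]
    z1 <- configs[, j] == 1L
    out[z1, j] <- sample.int(K, sum(z1), replace = TRUE,
                             prob = expr_params$theta1[[sp]])
    out[!z1, j] <- sample.int(K, sum(!z1), replace = TRUE,
                              prob = expr_params$theta0[[sp]])
  }
  out
}

#' Simulate a complete synthetic dataset from a scenario
#'
#' Composes [simulate_states()], [simulate_sequences()] and
#' [simulate_expression()] under the scenario's seed hierarchy; the hidden
#' truth and the generating parameters are recorded. Regenerating with the
#' same scenario (including seed) is bit-identical.
#'
#' @param scenario a [tn_scenario()].
#' @return An object of class `tn_sim`: `data` (a `tn_data` scanned with
#'   the scenario PSSM), `truth` (M x N 0/1 matrix), `params_true` (a
#'   [tn_params()]), and `scenario`.
#' @export
simulate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "tn_scenario"))
  truth <- simulate_states(scenario$tree, scenario$rates, scenario$M,
                           derive_seed(scenario$seed, "states"))
  windows <- simulate_sequences(truth, scenario$pssm, scenario$q_true,
                                scenario$window_length, scenario$background,
                                derive_seed(scenario$seed, "sequences"))
  labels <- simulate_expression(truth, scenario$expr_params,
                                derive_seed(scenario$seed, "expression"))
  rownames(windows) <- rownames(labels) <- rownames(truth) <-
    paste0("grp", seq_len(scenario$M))
  data <- tn_data_from_windows(windows, labels, scenario$pssm,
                               tn_seq_params(q = scenario$q_true),
                               K = stats::setNames(rep(scenario$K,
                                                       ncol(windows)),
                                                   colnames(windows)))
  structure(list(data = data,
                 truth = truth[, data$species, drop = FALSE],
                 params_true = tn_params(scenario$rates,
                                         tn_seq_params(q = scenario$q_true),
                                         scenario$expr_params, weight = 1),
                 scenario = scenario),
            class = "tn_sim")
}

#' @export
print.tn_sim <- function(x, ...) {
  print(x$scenario)
  print(x$data)
  invisible(x)
}

# generative draw under arbitrary fitted parameters (used by simulate.tn_fit)
simulate_from_params <- function(tree, params, M, pssm, window_length,
                                 seed = 1L) {
  tree <- tn_tree(tree)
  truth <- simulate_states(tree, params$rates, M, derive_seed(seed, "states"))
  windows <- simulate_sequences(truth, pssm, params$seq$q, window_length,
                                pssm$background, derive_seed(seed, "sequences"))
  labels <- simulate_expression(truth, params$expr, derive_seed(seed, "expression"))
  rownames(windows) <- rownames(labels) <- rownames(truth) <- paste0("grp", seq_len(M))
  data <- tn_data_from_windows(windows, labels, pssm, params$seq,
                               K = params$expr$K[colnames(windows)])
  structure(list(data = data, truth = truth[, data$species, drop = FALSE],
                 params_true = params, scenario = NULL),
            class = "tn_sim")
}

#' K-fold cross-validation over the expression-weight grid
#'
#' Groups are partitioned into seeded folds; for every weight in the grid
#' the model is fitted on the training folds and regulatory states are
#' decoded on both the training and the held-out fold and scored against
#' the simulation truth with [prediction_accuracy()].
#'
#' @param sim a [simulate_dataset()] result (truth is required).
#' @param k_folds number of folds (default 5); `k_folds = M` gives
#'   leave-one-out.
#' @param weight_grid numeric vector of expression weights.
#' @param seed seed for the fold assignment.
#' @param tree phylogeny; default the scenario's tree.
#' @param max_iter,tol EM controls passed to [tn_fit()].
#' @return An object of class `tn_cv`: `results` (weight, fold, train and
#'   test accuracy) and `summary` (per-weight means and the train-test
#'   gap).
#' @export
crossvalidate <- function(sim, k_folds = 5L, weight_grid = c(0, 0.5, 1, 2, 5),
                          seed = 1L, tree = NULL, max_iter = 50L, tol = 1e-5) {
  stopifnot(inherits(sim, "tn_sim"))
  M <- n_groups(sim$data)
  if (M < k_folds) stop_tn("'k_folds' cannot exceed the number of groups")
  set.seed(derive_seed(seed, "folds"))
  fold <- sample(rep_len(seq_len(k_folds), M))
  tree <- tn_tree(tree %||% sim$scenario$tree)
  rows <- list()
  for (w in weight_grid) {
    for (f in seq_len(k_folds)) {
      tr_idx <- fold != f
      fit <- tn_fit(sim$data[tr_idx], tree, weight = w,
                    max_iter = max_iter, tol = tol)
      acc_tr <- prediction_accuracy(predict(fit),
                                    sim$truth[tr_idx, , drop = FALSE])
      acc_te <- prediction_accuracy(predict(fit, sim$data[!tr_idx]),
                                    sim$truth[!tr_idx, , drop = FALSE])
      rows[[length(rows) + 1L]] <-
        data.frame(weight = w, fold = f, train_accuracy = acc_tr,
                   test_accuracy = acc_te)
    }
  }
  results <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(results, results$weight), function(d)
    data.frame(weight = d$weight[1L],
               train_accuracy = mean(d$train_accuracy),
               test_accuracy = mean(d$test_accuracy),
               gap = abs(mean(d$train_accuracy) - mean(d$test_accuracy)))))
  rownames(agg) <- NULL
  structure(list(results = results, summary = agg, k_folds = k_folds,
                 seed = seed), class = "tn_cv")
}

#' @export
print.tn_cv <- function(x, ...) {
  cat(sprintf("tn_cv: %d folds\n", x$k_folds))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
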