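#' Gain/loss rates of the regulatory-state Markov chain
#'
#' A gene's regulatory state (1 = target of the focal TF, 0 = non-target)
#' evolves along the phylogeny as a two-state continuous-time Markov chain
#' with gain rate `lam` (0 to 1) and loss rate `mu` (1 to 0) per unit
#' divergence time. `pi_root` is the probability that the root is a target;
#' it may be tied to the stationary distribution lam/(lam+mu) or left free.
#'
#' @param lam gain rate, > 0.
#' @param mu loss rate, > 0.
#' @param pi_root root probability of state 1, in `[0, 1]`, or the string
#'   `"stationary"` to tie it to `lam / (lam + mu)`.
#' @return An object of class `tn_rates`.
#' @examples
#' tn_rates(1, 2, pi_root = "stationary")
#' @export
tn_rates <- function(lam, mu, pi_root = "stationary") {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam <= 0)
    stop_tn("'lam' must be a single positive number")
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0)
    stop_tn("'mu' must be a single positive number")
  tied <- identical(pi_root, "stationary")
  if (tied) pi_root <- lam / (lam + mu) else check_prob(pi_root, "pi_root")
  structure(list(lam = lam, mu = mu, pi_root = pi_root, tied_root = tied),
            class = "tn_rates")
}

#' @export
print.tn_rates <- function(x, ...) {
  cat(sprintf("tn_rates: lam = %.6g, mu = %.6g, pi_root = %.6g%s\n",
              x$lam, x$mu, x$pi_root,
              if (isTRUE(x$tied_root)) " (stationary)" else ""))
  invisible(x)
}

#' Transition probabilities of the regulatory state over time t
#'
#' Closed-form solution of the two-state chain with generator
#' `[[-lam, lam], [mu, -mu]]`:
#' `P(0 -> 1, t) = (lam / (lam + mu)) * (1 - exp(-(lam + mu) t))` and
#' `P(1 -> 1, t) = lam/(lam+mu) + (mu/(lam+mu)) * exp(-(lam + mu) t)`.
#'
#' @param rates a [tn_rates()].
#' @param t nonnegative divergence time.
#' @return A 2x2 row-stochastic matrix with dimnames `c("0", "1")`;
#'   entry `[x, y]` is the probability of state `y` after time `t` given
#'   state `x`.
#' @examples
#' transition_matrix(tn_rates(1, 2), 0.5)
#' @export
transition_matrix <- function(rates, t) {
  stopifnot(inherits(rates, "tn_rates"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop_tn("'t' must be a single nonnegative time")
  s <- rates$lam + rates$mu
  e <- exp(-s * t)
  p1 <- rates$lam / s  # stationary probability of state 1
  p0 <- rates$mu / s
  m <- matrix(c(p0 + p1 * e, p1 * (1 - e),
                p0 * (1 - e), p1 + p0 * e),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("0", "1"), c("0", "1")))
  m
}

#' Stationary distribution of the regulatory-state chain
#'
#' @param rates a [tn_rates()].
#' @return Numeric pair `(P(0), P(1)) = (mu, lam) / (lam + mu)`, a left
#'   fixed point of [transition_matrix()] for every `t`.
#' @export
stationary_distribution <- function(rates) {
  stopifnot(inherits(rates, "tn_rates"))
  s <- rates$lam + rates$mu
  stats::setNames(c(rates$mu / s, rates$lam / s), c("0", "1"))
}

#' Enumerate all leaf-state configurations
#'
#' Configurations are returned in binary-counting order with species sorted
#' lexicographically: the first species is the most significant bit, so the
#' all-zero configuration comes first and the ordering is total and stable
#' across calls (it is also the lexicographic order of the 0/1 rows).
#'
#' @param species character vector of species (leaf) names, or a single
#'   count `n` in which case species are `sp1..spn`.
#' @return An integer matrix with `2^n` rows and one column per species
#'   (sorted), each row a 0/1 configuration.
#' @examples
#' enumerate_leaf_configs(c("human", "mouse", "cow"))
#' @export
enumerate_leaf_configs <- function(species) {
  if (is.numeric(species) && length(species) == 1L) {
    species <- paste0("sp", seq_len(species))
  }
  n <- length(species)
  if (n < 1L || n > 20L) stop_tn("number of leaves must be between 1 and 20")
  species <- sort(species)
  idx <- 0:(2^n - 1L)
  cfg <- matrix(0L, nrow = 2^n, ncol = n, dimnames = list(NULL, species))
  for (j in seq_len(n)) {
    cfg[, j] <- as.integer(idx %/% 2^(n - j) %% 2L)
  }
  cfg
}

# Conditional leaf-config likelihoods by pruning, for all 2^n configs at
# once. Returns list(configs, cond = 2^n x 2 matrix of P(config | root
# state), prior = 2^n vector P(config)). Recursion is over the tree in
# postorder; per node a 2^n x 2 partial-likelihood matrix
# L[cfg, s] = P(observed leaf states under the node in cfg | node state s).
config_prior_table <- function(tree, rates) {
  tree <- tn_tree(tree)
  stopifnot(inherits(rates, "tn_rates"))
  cfg <- enumerate_leaf_configs(tree$phylo$tip.label)
  nc <- nrow(cfg)
  L <- vector("list", tree$n_nodes)
  for (tip in seq_len(tree$n_tips)) {
    P <- transition_matrix(rates, tree$blen[tip])
    obs <- cfg[, tree$phylo$tip.label[tip]] + 1L
    L[[tip]] <- cbind(P[1L, obs], P[2L, obs])
  }
  for (v in tree$postorder_internal) {
    acc <- matrix(1, nrow = nc, ncol = 2L)
    for (ch in tree$children[[v]]) {
      if (ch <= tree$n_tips) {
        # tip partials already include the tip branch
        acc <- acc * L[[ch]]
      } else {
        P <- transition_matrix(rates, tree$blen[ch])
        acc <- acc * (L[[ch]] %*% t(P))
      }
    }
    L[[v]] <- acc
  }
  cond <- L[[tree$root]]
  pi_vec <- c(1 - rates$pi_root, rates$pi_root)
  list(configs = cfg, cond = cond, prior = as.vector(cond %*% pi_vec))
}

# coerce a user-supplied config (named vector / unnamed in species order)
as_leaf_config <- function(config, species) {
  if (!is.null(names(config))) {
    if (!setequal(names(config), species))
      stop_tn("config names must match the tree's leaf species exactly")
    config <- config[species]
  } else if (length(config) != length(species)) {
    stop_tn("config length must equal the number of leaves")
  }
  config <- as.integer(config)
  if (any(is.na(config)) || any(!config %in% c(0L, 1L)))
    stop_tn("config entries must be 0 or 1")
  stats::setNames(config, species)
}

#' Probability of a leaf regulatory-state configuration
#'
#' Marginal probability, under the two-state chain on the phylogeny, of
#' observing a given 0/1 state per leaf species: the root state is drawn
#' from `(1 - pi_root, pi_root)` and ancestral (internal) states are summed
#' out along the shared branches (Felsenstein pruning). On a star tree this
#' reduces to a root-weighted product of per-path transition probabilities.
#'
#' @param tree a [tn_tree()] (or anything it accepts).
#' @param rates a [tn_rates()].
#' @param config 0/1 vector, named by species or given in lexicographic
#'   species order.
#' @return The probability, a number in `[0, 1]`. Summing over
#'   [enumerate_leaf_configs()] gives 1.
#' @examples
#' tr <- tn_tree("((A:0.3,B:0.3):0.2,C:0.5);")
#' leaf_config_probability(tr, tn_rates(1, 1), c(A = 1, B = 1, C = 0))
#' @export
leaf_config_probability <- function(tree, rates, config) {
  tree <- tn_tree(tree)
  config <- as_leaf_config(config, tree$species)
  tab <- config_prior_table(tree, rates)
  i <- which(colSums(abs(t(tab$configs) - config)) == 0L)
  tab$prior[i]
}

#' Exhaustive-enumeration oracle for leaf-configuration probabilities
#'
#' Same contract as [leaf_config_probability()], computed by brute force:
#' every assignment of 0/1 states to every node (internal and leaf) is
#' enumerated, scored as root prior times the product of per-branch
#' transition probabilities, and summed over assignments consistent with
#' the leaf configuration. Intended as a test oracle; refuses trees with
#' more than 12 nodes.
#'
#' @inheritParams leaf_config_probability
#' @return The probability.
#' @export
leaf_config_probability_bruteforce <- function(tree, rates, config) {
  tree <- tn_tree(tree)
  stopifnot(inherits(rates, "tn_rates"))
  if (tree$n_nodes > 12L) stop_tn("brute-force oracle limited to trees with <= 12 nodes")
  config <- as_leaf_config(config, tree$species)
  leaf_states <- config[tree$phylo$tip.label]  # in tip-index order
  internal <- setdiff(seq_len(tree$n_nodes), seq_len(tree$n_tips))
  n_int <- length(internal)
  total <- 0
  pi_vec <- c(1 - rates$pi_root, rates$pi_root)
  Pcache <- lapply(seq_len(tree$n_nodes), function(v)
    if (is.na(tree$blen[v])) NULL else transition_matrix(rates, tree$blen[v]))
  for (a in 0:(2^n_int - 1L)) {
    st <- integer(tree$n_nodes)
    st[seq_len(tree$n_tips)] <- leaf_states
    if (n_int > 0L)
      st[internal] <- as.integer(a %/% 2^(seq_len(n_int) - 1L) %% 2L)
    p <- pi_vec[st[tree$root] + 1L]
    for (v in seq_len(tree$n_nodes)) {
      if (v == tree$root) next
      p <- p * Pcache[[v]][st[tree$parent[v]] + 1L, st[v] + 1L]
    }
    total <- total + p
  }
  total
}
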