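# Shared fixtures and independent oracles.

toy_tree3 <- function() tn_tree("((A:0.3,B:0.3):0.2,C:0.5);")

# sharp toy motif over an 8-mer consensus
toy_pssm <- function(match = 0.9, consensus = "ACGTACGT") {
  w <- nchar(consensus)
  m <- matrix((1 - match) / 3, w, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_len(w), match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T")))] <- match
  build_pssm(m)
}

random_dna <- function(n, seed = NULL, prob = rep(0.25, 4)) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# random rooted tree with positive branch lengths
random_tree <- function(n_leaves) {
  phy <- ape::rtree(n_leaves, rooted = TRUE,
                    br = function(k) stats::runif(k, 0.05, 1))
  phy$tip.label <- paste0("t", seq_len(n_leaves))
  tn_tree(phy)
}

# Independent matrix-exponential oracle: scaling-and-squaring Taylor series
# on the generator, no use of the package's closed form.
expm_oracle <- function(Q, t) {
  A <- Q * t
  s <- max(0L, ceiling(log2(max(1, max(abs(A))))))
  B <- A / 2^s
  term <- diag(2)
  out <- diag(2)
  for (n in 1:30) {
    term <- term %*% B / n
    out <- out + term
  }
  for (i in seq_len(s)) out <- out %*% out
  out
}

ctmc_generator <- function(rates) {
  matrix(c(-rates$lam, rates$lam, rates$mu, -rates$mu), 2, byrow = TRUE)
}

# Direct summation oracle for the joint group likelihood: loop over all
# 2^N configs, brute-force phylogenetic prior, hand-built emissions.
group_loglik_oracle <- function(data, tree, params, mode = "both") {
  cfgs <- enumerate_leaf_configs(data$species)
  q <- params$seq$q
  w <- params$weight
  vapply(seq_along(data$groups), function(i) {
    total <- 0
    for (r in seq_len(nrow(cfgs))) {
      pr <- leaf_config_probability_bruteforce(tree, params$rates, cfgs[r, ])
      emis <- 0
      for (j in seq_along(data$species)) {
        sp <- data$species[j]
        z <- cfgs[r, sp]
        if (mode != "expr") {
          emis <- emis + data$log_bgp[i, j]
          if (z == 1)
            emis <- emis + data$n_background[i, j] * log(1 - q) +
              data$n_motifs[i, j] * log(q) + data$log_r[i, j]
        }
        if (mode != "seq" && w > 0) {
          th <- if (z == 1) params$expr$theta1[[sp]] else params$expr$theta0[[sp]]
          emis <- emis + w * log(th[data$labels[i, j]])
        }
      }
      total <- total + pr * exp(emis)
    }
    log(total)
  }, 0)
}

# small random dataset over the 3-species toy tree with short windows
random_toy_data <- function(M, seed = 1, window = 60L, K = 4L,
                            pssm = toy_pssm()) {
  set.seed(seed)
  windows <- matrix(vapply(seq_len(M * 3), function(i) random_dna(window), ""),
                    M, 3, dimnames = list(paste0("g", seq_len(M)),
                                          c("A", "B", "C")))
  # plant a motif in a random subset so scan statistics vary
  hot <- which(matrix(stats::runif(M * 3) < 0.4, M, 3))
  cons <- paste(c("A", "C", "G", "T")[apply(pssm$probs, 1, which.max)],
                collapse = "")
  for (idx in hot) {
    s <- sample.int(window - nchar(cons) + 1L, 1L)
    substr(windows[idx], s, s + nchar(cons) - 1L) <- cons
  }
  labels <- matrix(sample.int(K, M * 3, replace = TRUE), M, 3,
                   dimnames = dimnames(windows))
  tn_data_from_windows(windows, labels, pssm, tn_seq_params(q = 0.01),
                       K = c(A = K, B = K, C = K))
}

random_toy_params <- function(data, seed = 1, weight = 1) {
  set.seed(seed)
  K <- data$K
  theta0 <- lapply(K, function(k) { v <- stats::rgamma(k, 2); v / sum(v) })
  theta1 <- lapply(K, function(k) { v <- stats::rgamma(k, 2); v / sum(v) })
  tn_params(tn_rates(stats::runif(1, 0.3, 2), stats::runif(1, 0.3, 2),
                     stats::runif(1, 0.1, 0.9)),
            tn_seq_params(q = stats::runif(1, 0.002, 0.05)),
            tn_expr_params(theta0, theta1), weight = weight)
}
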