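test_that("transition matrix matches the closed form and its limits", {
  expect_equal(transition_matrix(tn_rates(0.5, 0.5), 0),
               diag(2), ignore_attr = TRUE)
  P <- transition_matrix(tn_rates(1, 1), 100)
  expect_equal(unname(P), matrix(0.5, 2, 2), tolerance = 1e-12)
  # independent matrix-exponential oracle
  r <- tn_rates(1, 2)
  Pt <- transition_matrix(r, 0.5)
  expect_equal(unname(Pt), expm_oracle(ctmc_generator(r), 0.5),
               tolerance = 1e-12)
  # frozen from the matrix-exponential oracle: (1/3) * (1 - exp(-1.5))
  expect_equal(Pt["0", "1"], 0.2589566, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("transition matrices are stochastic and satisfy Chapman-Kolmogorov", {
  set.seed(42)
  for (i in 1:25) {
    r <- tn_rates(runif(1, 0.05, 5), runif(1, 0.05, 5))
    t1 <- runif(1, 0, 3); t2 <- runif(1, 0, 3)
    P1 <- transition_matrix(r, t1)
    expect_equal(unname(rowSums(P1)), c(1, 1), tolerance = 1e-12)
    expect_true(all(P1 >= 0))
    expect_equal(P1 %*% transition_matrix(r, t2),
                 transition_matrix(r, t1 + t2), tolerance = 1e-10)
    # rows converge to the stationary distribution
    Pinf <- transition_matrix(r, 500 / (r$lam + r$mu))
    expect_equal(unname(Pinf[1, ]), unname(stationary_distribution(r)),
                 tolerance = 1e-10)
  }
})

test_that("stationary distribution is the closed form and a fixed point", {
  expect_equal(unname(stationary_distribution(tn_rates(1, 1))), c(0.5, 0.5))
  expect_equal(unname(stationary_distribution(tn_rates(1, 3))), c(0.75, 0.25))
  set.seed(7)
  for (i in 1:10) {
    r <- tn_rates(runif(1, 0.1, 4), runif(1, 0.1, 4))
    s <- stationary_distribution(r)
    expect_equal(unname(s %*% transition_matrix(r, runif(1, 0, 5))),
                 matrix(unname(s), 1), tolerance = 1e-12)
  }
})

test_that("invalid rates and times are rejected", {
  expect_error(tn_rates(-1, 1), "positive")
  expect_error(tn_rates(1, 0), "positive")
  expect_error(tn_rates(1, 1, 1.5), "probability")
  expect_error(transition_matrix(tn_rates(1, 1), -0.1), "nonnegative")
})

test_that("leaf-config enumeration is complete, ordered, and stable", {
  expect_equal(enumerate_leaf_configs(1), matrix(0:1, 2, 1,
               dimnames = list(NULL, "sp1")))
  cfg <- enumerate_leaf_configs(c("c", "a", "b"))
  expect_equal(nrow(cfg), 8)
  expect_equal(colnames(cfg), c("a", "b", "c"))
  expect_equal(anyDuplicated(cfg), 0)
  expect_identical(cfg, enumerate_leaf_configs(c("b", "a", "c")))
  # binary counting: first row all zeros, last all ones, first species MSB
  expect_equal(unname(cfg[1, ]), c(0, 0, 0))
  expect_equal(unname(cfg[8, ]), c(1, 1, 1))
  expect_equal(unname(cfg[5, ]), c(1, 0, 0))
  expect_error(enumerate_leaf_configs(21), "between 1 and 20")
})

test_that("single-leaf and two-leaf star trees have hand-computable probabilities", {
  t1 <- tn_tree("(A:0);")
  expect_equal(leaf_config_probability(t1, tn_rates(1, 1, 0.3), c(A = 1)), 0.3)
  expect_equal(leaf_config_probability_bruteforce(t1, tn_rates(1, 1, 0.3),
                                                  c(A = 0)), 0.7)
  # star of 2 leaves: sum_r pi_r P[r, z1](t1) P[r, z2](t2)
  st <- tn_tree("(A:0.4,B:0.9);")
  r <- tn_rates(0.7, 1.3, 0.35)
  P1 <- transition_matrix(r, 0.4); P2 <- transition_matrix(r, 0.9)
  hand <- 0.65 * P1[1, 2] * P2[1, 1] + 0.35 * P1[2, 2] * P2[2, 1]
  expect_equal(leaf_config_probability(st, r, c(A = 1, B = 0)), hand,
               tolerance = 1e-12)
  expect_equal(leaf_config_probability_bruteforce(st, r, c(A = 1, B = 0)),
               hand, tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration on random small trees", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(2:4, 1)
    tr <- random_tree(n)
    r <- tn_rates(runif(1, 0.1, 3), runif(1, 0.1, 3), runif(1))
    cfg <- enumerate_leaf_configs(tr$species)
    row <- cfg[sample.int(nrow(cfg), 1), ]
    a <- leaf_config_probability(tr, r, row)
    b <- leaf_config_probability_bruteforce(tr, r, row)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("leaf-config probabilities sum to one over all configurations", {
  set.seed(23)
  for (i in 1:10) {
    tr <- random_tree(sample(2:6, 1))
    r <- tn_rates(runif(1, 0.1, 3), runif(1, 0.1, 3), runif(1))
    cfg <- enumerate_leaf_configs(tr$species)
    pr <- vapply(seq_len(nrow(cfg)), function(k)
      leaf_config_probability(tr, r, cfg[k, ]), 0)
    expect_equal(sum(pr), 1, tolerance = 1e-10)
    expect_true(all(pr >= 0))
  }
})

test_that("config/leaf mismatches and oversized brute-force trees are refused", {
  tr <- toy_tree3()
  r <- tn_rates(1, 1)
  expect_error(leaf_config_probability(tr, r, c(A = 1, B = 0)), "length|match")
  expect_error(leaf_config_probability(tr, r, c(A = 1, B = 0, D = 1)), "match")
  expect_error(leaf_config_probability(tr, r, c(A = 2, B = 0, C = 0)), "0 or 1")
  big <- random_tree(8)
  expect_error(leaf_config_probability_bruteforce(big, r,
               setNames(rep(0, 8), big$species)), "12 nodes")
})

test_that("trees are validated and round-trip through Newick", {
  expect_error(tn_tree("(A:0.1,B:-0.2);"), "nonnegative")
  expect_error(tn_tree("(A:0.1,A:0.2);"), "unique")
  tr <- toy_tree3()
  tmp <- tempfile(fileext = ".nwk")
  write_tree_file(tr, tmp)
  tr2 <- tn_tree(tmp)
  expect_equal(tr2$species, tr$species)
  expect_equal(sort(tr2$blen), sort(tr$blen))
})
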