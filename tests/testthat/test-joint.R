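test_that("group likelihood equals the direct 8-term summation oracle", {
  tree <- toy_tree3()
  for (seed in 1:4) {
    data <- random_toy_data(25, seed = seed)
    params <- random_toy_params(data, seed = seed + 100,
                                weight = sample(c(0.5, 1, 2), 1))
    ll <- group_loglik(data, tree, params)
    oracle <- group_loglik_oracle(data, tree, params)
    expect_equal(unname(ll), oracle, tolerance = 1e-10)
    # sequence-only and expression-only modes agree with the oracle too
    expect_equal(unname(group_loglik(data, tree, params, mode = "seq")),
                 group_loglik_oracle(data, tree, params, mode = "seq"),
                 tolerance = 1e-10)
    expect_equal(unname(group_loglik(data, tree, params, mode = "expr")),
                 group_loglik_oracle(data, tree, params, mode = "expr"),
                 tolerance = 1e-10)
  }
})

test_that("posteriors normalize, reduce to the prior, and decode by argmax", {
  tree <- toy_tree3()
  data <- random_toy_data(30, seed = 2)
  params <- random_toy_params(data, seed = 5)
  gp <- group_posterior(data, tree, params)
  expect_equal(unname(rowSums(gp$posterior)), rep(1, 30), tolerance = 1e-9)
  # MAP equals exhaustive argmax over the 8 configurations
  for (i in seq_len(30)) {
    expect_equal(unname(gp$map[i, ]),
                 unname(gp$configs[which.max(gp$posterior[i, ]), ]))
  }
  # flat emissions: posterior equals the phylogenetic prior
  flat <- params
  flat$expr <- tn_expr_params(theta0 = flat$expr$theta0,
                              theta1 = flat$expr$theta0)
  d0 <- data
  d0$n_motifs[] <- 0; d0$log_r[] <- 0
  d0$n_background[] <- 0  # removes the (1-q)^Nb tilt as well
  gp0 <- group_posterior(d0, tree, flat)
  prior <- config_prior_table(tree, params$rates)$prior
  expect_equal(unname(gp0$posterior[1, ]), prior, tolerance = 1e-9)
})

test_that("strong consistent evidence decodes to the all-target configuration", {
  tree <- toy_tree3()
  pssm <- toy_pssm(0.9)
  cons <- "ACGTACGT"
  set.seed(13)
  win <- random_dna(120)
  hot <- paste0(substr(win, 1, 40), cons, substr(win, 49, 80), cons,
                substr(win, 89, 120))
  windows <- matrix(hot, 8, 3, dimnames = list(paste0("g", 1:8), c("A", "B", "C")))
  labels <- matrix(1L, 8, 3, dimnames = dimnames(windows))
  data <- tn_data_from_windows(windows, labels, pssm, tn_seq_params(q = 0.02),
                               K = c(A = 3, B = 3, C = 3))
  params <- tn_params(tn_rates(0.5, 0.5, 0.5), tn_seq_params(q = 0.02),
                      tn_expr_params(
                        theta0 = list(A = c(.1, .45, .45), B = c(.1, .45, .45),
                                      C = c(.1, .45, .45)),
                        theta1 = list(A = c(.8, .1, .1), B = c(.8, .1, .1),
                                      C = c(.8, .1, .1))))
  st <- infer_states(data, tree, params)
  expect_true(all(st$map == 1))
  expect_true(all(st$category == "conserved_all"))
  expect_true(all(st$marginal > 0.9))
})

test_that("raising one species' expression evidence only raises its own marginal", {
  tree <- toy_tree3()
  data <- random_toy_data(10, seed = 3)
  params <- random_toy_params(data, seed = 9)
  # make cluster 1 theta1-heavy for species A
  params$expr$theta1$A <- c(0.85, 0.05, 0.05, 0.05)
  params$expr$theta0$A <- c(0.05, 0.317, 0.317, 0.316)
  base <- data
  base$labels[1, "A"] <- 2L
  flip <- data
  flip$labels[1, "A"] <- 1L
  g0 <- group_posterior(base, tree, params)
  g1 <- group_posterior(flip, tree, params)
  expect_gt(g1$marginal[1, "A"], g0$marginal[1, "A"])
})

test_that("conservation categories cover the 3-species cases", {
  expect_equal(classify_conservation(c(A = 1, B = 1, C = 1)), "conserved_all")
  expect_equal(classify_conservation(c(A = 1, B = 0, C = 0)),
               "species_specific:A")
  expect_equal(classify_conservation(c(A = 0, B = 0, C = 0)), "non_target")
  expect_equal(classify_conservation(c(A = 1, B = 0, C = 1)),
               "conserved_partial:missing_B")
  m <- rbind(c(1, 1, 1), c(0, 1, 0))
  colnames(m) <- c("x", "y", "z")
  expect_equal(classify_conservation(m),
               c("conserved_all", "species_specific:y"))
})

test_that("rewiring rate follows the stated denominator conventions", {
  cats <- c(rep("conserved_all", 2), rep("species_specific:A", 2))
  expect_equal(rewiring_rate(cats, "all_groups")$rate, 0.5)
  expect_equal(rewiring_rate(cats, "groups_with_any_link")$rate, 0.5)
  cats2 <- c(cats, rep("non_target", 4))
  expect_equal(rewiring_rate(cats2, "all_groups")$rate, 1 - 2 / 8)
  expect_equal(rewiring_rate(cats2, "groups_with_any_link")$rate, 0.5)
  expect_equal(rewiring_rate(rep("conserved_all", 10))$rate, 0)
  # adding one species-specific group strictly increases the rate
  expect_gt(rewiring_rate(c(rep("conserved_all", 10), "species_specific:B"))$rate,
            0)
  expect_error(rewiring_rate(character(0)), "no groups")
  expect_error(rewiring_rate(rep("non_target", 3), "groups_with_any_link"),
               "denominator")
})

test_that("prediction accuracy counts matching (species, gene) pairs", {
  pred <- rbind(c(1, 0, 1), c(0, 0, 1))
  colnames(pred) <- c("A", "B", "C")
  truth <- pred
  expect_equal(prediction_accuracy(pred, truth), 1)
  truth[2, 1] <- 1
  expect_equal(prediction_accuracy(pred, truth), 5 / 6)
  # invariant to gene ordering
  expect_equal(prediction_accuracy(pred[2:1, ], truth[2:1, ]), 5 / 6)
  truth[1, 1] <- NA
  expect_error(prediction_accuracy(pred, truth), "missing")
  expect_error(prediction_accuracy(pred, truth[, 1:2]), "cover")
})

test_that("affinity differences by category match hand-computed pairwise means", {
  tree <- toy_tree3()
  pssm <- toy_pssm(0.9)
  params <- tn_params(tn_rates(1, 1, 0.5), tn_seq_params(q = 0.01),
                      tn_expr_params(theta0 = list(A = c(.5, .5), B = c(.5, .5),
                                                   C = c(.5, .5)),
                                     theta1 = list(A = c(.5, .5), B = c(.5, .5),
                                                   C = c(.5, .5))))
  set.seed(21)
  base <- random_dna(80)
  hot <- paste0(substr(base, 1, 30), "ACGTACGT", substr(base, 39, 80))
  windows <- rbind(g1 = c(base, base, base), g2 = c(hot, base, base))
  colnames(windows) <- c("A", "B", "C")
  labels <- matrix(1L, 2, 3, dimnames = dimnames(windows))
  data <- tn_data_from_windows(windows, labels, pssm, params$seq,
                               K = c(A = 2, B = 2, C = 2))
  states <- infer_states(data, tree, params)
  res <- affinity_by_conservation(data, states, params)
  # identical sequences in all species: zero difference for g1's category
  aff <- vapply(c(base, hot), function(s)
    binding_affinity(s, pssm, params$seq), 0, USE.NAMES = FALSE)
  d_hot <- abs(aff[2] - aff[1])
  expect_true(all(res$n >= 1))
  g1cat <- sub(":.*$", "", states$category[1])
  g2cat <- sub(":.*$", "", states$category[2])
  expect_equal(res$mean[res$category == g1cat][1], 0, tolerance = 1e-12)
  if (g2cat != g1cat)
    expect_equal(res$mean[res$category == g2cat][1], 2 * d_hot / 3,
                 tolerance = 1e-10)
})
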