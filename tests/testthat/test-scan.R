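test_that("build_pssm normalizes counts, applies pseudocounts, passes probabilities", {
  u <- build_pssm(matrix(1, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T"))),
                  pseudocount = 0)
  expect_equal(unname(u$probs), matrix(0.25, 4, 4))
  p <- build_pssm(matrix(c(9, 1, 0, 0), 1, dimnames = list(NULL, c("A", "C", "G", "T"))),
                  pseudocount = 1)
  expect_equal(unname(p$probs[1, ]), c(10, 2, 1, 1) / 14)
  # probability input is idempotent up to renormalization
  m <- matrix(c(0.7, 0.1, 0.1, 0.1, 0.25, 0.25, 0.25, 0.25), 2, 4, byrow = TRUE,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_equal(unname(build_pssm(m)$probs), unname(m))
  expect_error(build_pssm(matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 2, 4, byrow = TRUE),
                          pseudocount = 0), "zero")
  expect_error(build_pssm(matrix(1, 2, 3)), "four bases")
})

test_that("score_segment is the summed per-position log likelihood ratio", {
  u <- build_pssm(matrix(1, 4, 4, dimnames = list(NULL, c("A", "C", "G", "T"))),
                  pseudocount = 0)
  expect_equal(score_segment("ACGT", u), 0)
  # toy 2-mer: probs (0.8 A)(0.8 C), uniform background, segment AC
  m2 <- matrix(c(0.8, 0.2 / 3, 0.2 / 3, 0.2 / 3,
                 0.2 / 3, 0.8, 0.2 / 3, 0.2 / 3), 2, 4, byrow = TRUE,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  p2 <- build_pssm(m2)
  expect_equal(score_segment("AC", p2), 2 * log(3.2))
  # consensus attains the maximal score
  sharp <- toy_pssm(0.9)
  expect_equal(score_segment("ACGTACGT", sharp),
               sum(apply(sharp$log_ratio, 1, max)))
  # N bases contribute zero
  expect_equal(score_segment("NC", p2), log(3.2))
  expect_error(score_segment("ACG", p2), "length")
})

test_that("scan_window counts planted motifs and keeps the N_b/N_m partition", {
  pssm <- toy_pssm(0.9)
  params <- tn_seq_params(q = 0.01)
  set.seed(1)
  bg <- random_dna(200)
  sc0 <- scan_window(bg, pssm, tn_seq_params(q = 0.01, threshold = 1e6))
  expect_equal(sc0$n_motifs, 0)
  expect_equal(sc0$log_r, 0)
  expect_equal(sc0$n_background, 200)

  one <- paste0(substr(bg, 1, 96), "ACGTACGT", substr(bg, 105, 200))
  sc1 <- scan_window(one, pssm, params)
  expect_equal(sc1$n_motifs, 1)
  expect_equal(sc1$n_background, 200 - 8)
  expect_equal(sc1$hits$position, 97)

  two <- paste0(substr(bg, 1, 40), "ACGTACGT", substr(bg, 49, 140),
                "ACGTACGT", substr(bg, 149, 200))
  sc2 <- scan_window(two, pssm, params)
  expect_equal(sc2$n_motifs, 2)
  expect_equal(sc2$log_r, sum(sc2$hits$score))
  expect_equal(sc2$log_r, 2 * score_segment("ACGTACGT", pssm))
  expect_equal(sc2$n_background + sc2$n_motifs * pssm$width, nchar(two))
})

test_that("scanning is reverse-complement invariant", {
  pssm <- toy_pssm(0.85, "ATGCAAAT")
  params <- tn_seq_params(q = 0.01)
  set.seed(9)
  for (i in 1:5) {
    s <- random_dna(300)
    substr(s, 101, 108) <- "ATGCAAAT"
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    a <- scan_window(s, pssm, params)
    b <- scan_window(rc, pssm, params)
    expect_equal(a$n_motifs, b$n_motifs)
    expect_equal(a$n_background, b$n_background)
    expect_equal(a$log_r, b$log_r, tolerance = 1e-12)
  }
})

test_that("raising the calling threshold never increases the motif count", {
  pssm <- toy_pssm(0.8)
  set.seed(4)
  s <- random_dna(800)
  for (i in 1:3) {
    p <- sample.int(793, 1)
    substr(s, p, p + 7) <- "ACGTACGT"
  }
  thr <- seq(0.2, 1, by = 0.1) * sum(apply(pssm$log_ratio, 1, max))
  nm <- vapply(thr, function(th)
    scan_window(s, pssm, tn_seq_params(q = 0.01, threshold = th))$n_motifs, 0)
  expect_true(all(diff(nm) <= 0))
})

test_that("seq_loglik follows the scan statistics and normalizes at z=0", {
  pssm <- toy_pssm(0.9)
  params <- tn_seq_params(q = 0.01)
  set.seed(2)
  s <- random_dna(108)
  substr(s, 50, 57) <- "ACGTACGT"
  sc <- scan_window(s, pssm, params)
  expect_equal(sc$n_motifs, 1)
  d <- seq_loglik(sc, 1, params) - seq_loglik(sc, 0, params)
  expect_equal(d, sc$n_background * log(0.99) + log(0.01) + sc$log_r)
  # difference increases in log_r at fixed N_b, N_m
  sc2 <- sc; sc2$log_r <- sc$log_r + 1
  expect_gt(seq_loglik(sc2, 1, params) - seq_loglik(sc2, 0, params), d)
  # z=0 likelihood is a proper distribution: exhaustive over length-2 windows
  total <- sum(vapply(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T")), 1, paste,
          collapse = ""),
    function(w) exp(seq_loglik(scan_window(w, pssm,
      tn_seq_params(q = 0.01, threshold = 1e6)), 0, params)), 0))
  expect_equal(total, 1, tolerance = 1e-12)
  # hit-free window with q -> 0 makes the sequence uninformative
  bg <- scan_window(random_dna(50), pssm, tn_seq_params(q = 0.5, threshold = 1e6))
  tiny <- tn_seq_params(q = 1e-12)
  expect_equal(seq_loglik(bg, 1, tiny) - seq_loglik(bg, 0, tiny), 0,
               tolerance = 1e-9)
})

test_that("select_best_window finds the planted window and honors ties", {
  pssm <- toy_pssm(0.9)
  params <- tn_seq_params(q = 0.01)
  set.seed(3)
  long <- random_dna(4000)
  substr(long, 1701, 1708) <- "ACGTACGT"  # inside window starting at 1501/1751
  best <- select_best_window(long, pssm, params, window_size = 500, step = 250)
  expect_gte(1701, best$window$start)
  expect_lte(1708, best$window$end)
  expect_gte(best$n_motifs, 1)
  # motif-free sequence: leftmost window wins the tie
  set.seed(5)
  flat <- random_dna(2000)
  b2 <- select_best_window(flat, pssm, tn_seq_params(q = 0.01, threshold = 1e6),
                           window_size = 500, step = 250)
  expect_equal(b2$window$start, 1)
  # degenerate: window covering the whole sequence equals a direct scan
  whole <- select_best_window(flat, pssm, params, window_size = 2000)
  direct <- scan_window(flat, pssm, params)
  expect_equal(whole$n_motifs, direct$n_motifs)
  expect_equal(whole$log_r, direct$log_r)
  expect_warning(select_best_window(random_dna(100), pssm, params,
                                    window_size = 500), "shorter")
})

test_that("binding affinity is strand-symmetric and motif-sensitive", {
  pssm <- toy_pssm(0.9)
  params <- tn_seq_params(q = 0.01)
  set.seed(6)
  s <- random_dna(2000)
  expect_equal(binding_affinity(s, pssm, params),
               binding_affinity(as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(s))), pssm, params),
               tolerance = 1e-10)
  # identical orthologs: zero interspecies difference
  expect_equal(abs(binding_affinity(s, pssm, params) -
                   binding_affinity(s, pssm, params)), 0)
  # adding a hit raises the affinity
  s2 <- s
  substr(s2, 901, 908) <- "ACGTACGT"
  expect_gt(binding_affinity(s2, pssm, params), binding_affinity(s, pssm, params))
})

test_that("PSSM readers parse TSV and MEME-minimal formats and round-trip", {
  pssm <- toy_pssm(0.8)
  tmp <- tempfile(fileext = ".tsv")
  write_pssm(pssm, tmp)
  back <- read_pssm(tmp)
  expect_equal(back$probs, pssm$probs, tolerance = 1e-9)

  meme <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               "A 0.3 C 0.2 G 0.2 T 0.3", "",
               "MOTIF toy", "letter-probability matrix: alength= 4 w= 2",
               "0.970000 0.010000 0.010000 0.010000",
               "0.010000 0.970000 0.010000 0.010000"), meme)
  mp <- read_pssm(meme)
  expect_equal(mp$width, 2)
  expect_equal(unname(mp$background), c(0.3, 0.2, 0.2, 0.3))
  expect_equal(unname(mp$probs[1, 1]), 0.97)
})

test_that("permuted PSSMs are seeded permutations of rows and columns", {
  pssm <- toy_pssm(0.8)
  p1 <- permute_pssm(pssm, 42)
  p2 <- permute_pssm(pssm, 42)
  expect_equal(p1$probs, p2$probs)
  expect_equal(sort(as.vector(p1$probs)), sort(as.vector(pssm$probs)))
  expect_error(permute_pssm(build_pssm(matrix(c(1, 2, 3, 4), 1, 4,
    dimnames = list(NULL, c("A", "C", "G", "T")))), 1), ">= 2 positions")
})

test_that("pooled scans from several motifs keep the partition identity", {
  pssm1 <- toy_pssm(0.9, "ACGTACGT")
  pssm2 <- toy_pssm(0.9, "TTTTCCCC")
  params <- tn_seq_params(q = 0.01)
  set.seed(8)
  s <- random_dna(300)
  substr(s, 21, 28) <- "ACGTACGT"
  substr(s, 201, 208) <- "TTTTCCCC"
  pooled <- pool_scans(list(scan_window(s, pssm1, params),
                            scan_window(s, pssm2, params)))
  expect_equal(pooled$n_motifs, 2)
  expect_equal(pooled$n_background, 300 - 16)
  expect_equal(pooled$log_r,
               score_segment("ACGTACGT", pssm1) + score_segment("TTTTCCCC", pssm2))
})
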