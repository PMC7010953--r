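test_that("discretize applies the mean +/- t*sd three-state rule", {
  m <- expression_matrix(matrix(c(0, 0, 0, 0,
                                  -10, 0, 0, 10), nrow = 2, byrow = TRUE,
                                dimnames = list(c("flat", "spread"),
                                                paste0("s", 1:4))))
  st <- discretize(m, threshold_sigma = 0.5)
  expect_identical(unname(st["flat", ]), rep(1L, 4))  # zero variance
  # mean 0, sd = sqrt(200/3) ~ 8.16, thresholds +/- 4.08
  expect_identical(unname(st["spread", ]), c(0L, 1L, 1L, 2L))
  expect_error(discretize(m, threshold_sigma = 0), "positive")
  expect_error(discretize(m, threshold_sigma = -1), "positive")
})

test_that("discretization is invariant to positive affine transforms", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rnorm(30))
    m <- expression_matrix(rbind(x), gene_ids = "g",
                           sample_ids = paste0("s", 1:30))
    m2 <- expression_matrix(rbind(3.7 * x + 12), gene_ids = "g",
                            sample_ids = paste0("s", 1:30))
    expect_identical(discretize(m), discretize(m2))
  }
})

test_that("mutual information matches closed forms and the joint-count oracle", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)  # H(X)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  x <- c(0, 0, 1, 1, 2, 2); y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(mutual_information(x, y), oracle_mi(x, y), tolerance = 1e-12)
  expect_error(mutual_information(1:3, 1:4), "length")
})

test_that("MI is symmetric, non-negative, bounded by min entropy", {
  entropy <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  for (seed in 1:20) {
    f <- random_states_fixture(2, 25, seed)
    x <- f$states[1, ]; y <- f$states[2, ]
    mi <- mutual_information(x, y)
    expect_equal(mi, mutual_information(y, x))
    expect_gte(mi, 0)
    expect_lte(mi, min(entropy(x), entropy(y)) + 1e-12)
  }
})

test_that("relevance_all equals per-gene MI against the labels", {
  f <- random_states_fixture(5, 30, seed = 3)
  labs <- label_vector(f$labels, colnames(f$states))
  D <- relevance_all(f$states, labs)
  for (g in rownames(f$states))
    expect_equal(unname(D[g]), oracle_mi(f$states[g, ], f$labels),
                 tolerance = 1e-12)
  # a gene identical to the label attains the label entropy
  st <- rbind(g1 = f$labels, g2 = rep(1L, 30))
  colnames(st) <- colnames(f$states)
  D2 <- relevance_all(st, labs)
  p <- mean(f$labels)
  expect_equal(unname(D2["g1"]), -p * log2(p) - (1 - p) * log2(1 - p))
  expect_equal(unname(D2["g2"]), 0)  # constant gene
})

test_that("two independent genes rank by relevance alone", {
  # g1 matches labels exactly (high D); g2 is the label of other samples
  labs <- rep(c(0L, 1L), each = 8)
  st <- rbind(g1 = labs,
              g2 = c(0L, 1L)[1 + (seq_along(labs) %% 2)])
  colnames(st) <- sprintf("s%02d", seq_along(labs))
  r <- mrmr_rank(st, label_vector(labs, colnames(st)), top_n = 2)
  expect_identical(r$gene_id, c("g1", "g2"))
  expect_equal(r$redundancy[1], 0)
  expect_equal(r$relevance[1], 1)
})

test_that("an exact duplicate is demoted below an equally relevant gene", {
  # g1 and g1dup are identical noisy label copies; g3 is an equally relevant
  # copy whose errors fall on different samples. At step 2 the duplicate's
  # score is D - H(g1) while g3 pays only I(g3, g1) < H(g1), so g3 outranks
  # the duplicate even though their solo relevances are equal.
  labs <- rep(c(0L, 1L), each = 10)
  g1 <- labs; g1[1:2] <- 1L     # two errors among negatives
  g3 <- labs; g3[11:12] <- 0L   # two errors among positives (same D)
  st <- rbind(g1 = g1, g1dup = g1, g3 = g3)
  colnames(st) <- sprintf("s%02d", seq_along(labs))
  labv <- label_vector(labs, colnames(st))
  D <- relevance_all(st, labv)
  expect_equal(unname(D["g1"]), unname(D["g3"]), tolerance = 1e-12)
  r <- mrmr_rank(st, labv, top_n = 3)
  orc <- oracle_mrmr(st, labs)
  expect_identical(r$gene_id, rownames(st)[orc$order])
  expect_identical(r$gene_id, c("g1", "g3", "g1dup"))
})

test_that("greedy ranking matches the brute-force oracle on random fixtures", {
  for (seed in 1:12) {
    f <- random_states_fixture(6, 30, seed)
    labs <- label_vector(f$labels, colnames(f$states))
    r <- mrmr_rank(f$states, labs, top_n = 6)
    orc <- oracle_mrmr(f$states, f$labels)
    expect_identical(r$gene_id, rownames(f$states)[orc$order])
    # rank-1 gene maximizes relevance, with zero redundancy
    expect_equal(r$relevance[1], max(orc$relevance), tolerance = 1e-12)
    expect_equal(r$redundancy[1], 0)
    # greedy trace: the winner's score at each step dominates all candidates
    for (step in seq_along(orc$step_scores)) {
      sc <- orc$step_scores[[step]]
      expect_equal(r$score[step], max(sc), tolerance = 1e-12)
      expect_gte(r$score[step] + 1e-12, max(sc))
    }
  }
})

test_that("ranking is invariant to sample permutation and affine transforms", {
  withr::with_seed(21, {
    n <- 40
    X <- matrix(rnorm(5 * n), 5, dimnames = list(paste0("g", 1:5),
                                                 sprintf("s%02d", 1:n)))
    y <- sample(c(0L, 1L), n, replace = TRUE)
    X[1, y == 1] <- X[1, y == 1] + 2
    perm <- sample(n)
  })
  labs <- label_vector(y, colnames(X))
  base_rank <- mrmr_rank(discretize(expression_matrix(X)), labs, top_n = 5)
  Xp <- X[, perm]
  rp <- mrmr_rank(discretize(expression_matrix(Xp)),
                  align_labels(Xp, labs), top_n = 5)
  expect_identical(rp$gene_id, base_rank$gene_id)
  ra <- mrmr_rank(discretize(expression_matrix(2.5 * X - 3)), labs, top_n = 5)
  expect_identical(ra$gene_id, base_rank$gene_id)
  expect_equal(ra$score, base_rank$score, tolerance = 1e-12)
})

test_that("ranked lists survive the TSV round trip", {
  f <- random_states_fixture(6, 20, seed = 5)
  r <- mrmr_rank(f$states, label_vector(f$labels, colnames(f$states)))
  expect_equal(nrow(r), 6L)  # top_n capped at gene count
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_list(r, path)
  r2 <- read_ranked_list(path)
  expect_identical(r2$gene_id, r$gene_id)
  expect_equal(r2$score, r$score, tolerance = 1e-12)
  expect_error(mrmr_rank(f$states, label_vector(f$labels,
                                                colnames(f$states)),
                         top_n = 0), "positive")
})
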