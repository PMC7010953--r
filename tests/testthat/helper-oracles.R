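# Independent brute-force oracles, deliberately naive: exhaustive sums over
# joint count tables and step-by-step re-evaluation of the greedy criterion.
# They share no code with the package internals they check.

# Plug-in mutual information by explicit double loop over all value pairs.
oracle_mi <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      pab <- sum(x == a & y == b) / n
      if (pab > 0) {
        pa <- sum(x == a) / n
        pb <- sum(y == b) / n
        mi <- mi + pab * log2(pab / (pa * pb))
      }
    }
  }
  mi
}

# Greedy mRMR by full re-evaluation of relevance minus mean redundancy for
# every candidate at every step; lowest-index tie-break among scores within
# 1e-9 of the step maximum (exact criterion ties can land apart by a few
# ulps under different summation orders).
oracle_mrmr <- function(states, labels, top_n = nrow(states)) {
  N <- nrow(states)
  D <- vapply(seq_len(N), function(g) oracle_mi(states[g, ], labels),
              numeric(1))
  selected <- integer(0)
  scores <- list()
  for (step in seq_len(min(top_n, N))) {
    cand <- setdiff(seq_len(N), selected)
    sc <- vapply(cand, function(g) {
      red <- if (length(selected) == 0) 0 else
        mean(vapply(selected, function(s)
          oracle_mi(states[g, ], states[s, ]), numeric(1)))
      D[g] - red
    }, numeric(1))
    win <- cand[which(sc >= max(sc) - 1e-9)[1]]
    scores[[step]] <- stats::setNames(sc, cand)
    selected <- c(selected, win)
  }
  list(order = selected, step_scores = scores, relevance = D)
}

# Random discrete fixture: ng genes x ns samples with 3 states, plus labels.
random_states_fixture <- function(ng, ns, seed) {
  withr::with_seed(seed, list(
    states = matrix(sample(0:2, ng * ns, replace = TRUE), ng, ns,
                    dimnames = list(sprintf("g%02d", seq_len(ng)),
                                    sprintf("s%02d", seq_len(ns)))),
    labels = sample(c(0L, 1L), ns, replace = TRUE)))
}

# Two well-separated Gaussian clouds with a held-out set from the same clouds.
separated_clouds <- function(n_per_class = 20, n_test = 10, n_feat = 3,
                             sep = 4, seed = 1) {
  withr::with_seed(seed, {
    tr <- rbind(matrix(rnorm(n_per_class * n_feat), n_per_class),
                matrix(rnorm(n_per_class * n_feat, mean = sep), n_per_class))
    te <- rbind(matrix(rnorm(n_test * n_feat), n_test),
                matrix(rnorm(n_test * n_feat, mean = sep), n_test))
    list(train_X = tr, train_y = rep(c(0L, 1L), each = n_per_class),
         test_X = te, test_y = rep(c(0L, 1L), each = n_test))
  })
}

# Small continuous labelled fixture (samples x features) for LOOCV checks:
# the first two features carry class signal, the rest are noise.
continuous_fixture <- function(n = 50, n_feat = 5, effect = 2, prop_pos = 0.4,
                               seed = 11) {
  withr::with_seed(seed, {
    y <- sample(as.integer(seq_len(n) <= round(n * prop_pos)))
    X <- matrix(rnorm(n * n_feat), n)
    X[y == 1L, 1:2] <- X[y == 1L, 1:2] + effect
    list(X = X, y = y)
  })
}
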