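# Build a small labelled expression dataset plus its mRMR ranking.
ifs_fixture <- function(n = 30, n_genes = 8, effect = 3, seed = 17) {
  withr::with_seed(seed, {
    y <- sample(rep(c(0L, 1L), c(n - n %/% 3, n %/% 3)))
    X <- matrix(rnorm(n_genes * n), n_genes, n,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n))))
    X[1, y == 1L] <- X[1, y == 1L] + effect
    X[2, y == 1L] <- X[2, y == 1L] + effect / 2
  })
  labs <- label_vector(y, colnames(X))
  list(X = expression_matrix(X), y = labs,
       ranked = mrmr_rank(discretize(X), labs, top_n = n_genes))
}

test_that("build_curve covers every (family, k) cell exactly once", {
  fx <- ifs_fixture()
  cv <- build_curve(fx$ranked, fx$X, fx$y, families = c("1NN", "3NN"),
                    max_k = 5)
  expect_equal(nrow(cv), 10L)
  expect_equal(sort(unique(cv$k)), 1:5)
  for (fam in c("1NN", "3NN"))
    expect_equal(cv$k[cv$family == fam], 1:5)  # 1..max_k, no gaps
  one <- build_curve(fx$ranked, fx$X, fx$y, families = "1NN", max_k = 1)
  expect_equal(nrow(one), 1L)
})

test_that("a perfectly separating top gene yields MCC 1 at k = 1", {
  fx <- ifs_fixture(effect = 10)
  expect_identical(fx$ranked$gene_id[1], "g01")
  cv <- build_curve(fx$ranked, fx$X, fx$y, families = "1NN", max_k = 3)
  expect_equal(cv$MCC[cv$k == 1], 1)
})

test_that("curve records agree with independent loocv calls on each prefix", {
  fx <- ifs_fixture(seed = 23)
  fams <- c("1NN", "5NN", "DecisionTree")
  cv <- build_curve(fx$ranked, fx$X, fx$y, families = fams, max_k = 4)
  for (fam in fams) {
    spec <- classifier_spec(fam)
    for (k in 1:4) {
      sub <- t(fx$X[fx$ranked$gene_id[1:k], , drop = FALSE])
      cm <- loocv(spec, sub, as.integer(fx$y))
      row <- cv[cv$family == fam & cv$k == k, ]
      expect_equal(unlist(row[c("TP", "FN", "FP", "TN")], use.names = FALSE),
                   c(cm$TP, cm$FN, cm$FP, cm$TN),
                   label = paste(fam, k))
    }
  }
})

test_that("incremental kNN curve equals naive per-prefix retraining", {
  fx <- ifs_fixture(n = 24, seed = 31)
  fams <- c("1NN", "3NN", "5NN")
  fast <- build_curve(fx$ranked, fx$X, fx$y, families = fams, max_k = 6,
                      fast = TRUE)
  naive <- build_curve(fx$ranked, fx$X, fx$y, families = fams, max_k = 6,
                       fast = FALSE)
  expect_identical(fast[c("family", "k", "TP", "FN", "FP", "TN")],
                   naive[c("family", "k", "TP", "FN", "FP", "TN")])
})

test_that("find_peak takes the argmax and breaks ties toward smaller k", {
  mk_curve <- function(mcc, fam = "3NN") {
    df <- data.frame(family = fam, k = seq_along(mcc), TP = 1L, FN = 1L,
                     FP = 1L, TN = 1L, Sn = 0.5, Sp = 0.5, ACC = 0.5,
                     MCC = mcc, stringsAsFactors = FALSE)
    attr(df, "gene_order") <- sprintf("g%03d", seq_along(mcc))
    class(df) <- c("ifs_curve", "data.frame")
    df
  }
  up <- find_peak(mk_curve(c(0.1, 0.2, 0.3, 0.4)), "3NN")
  expect_equal(up$k_star, 4L)           # monotone increasing -> max_k
  tie <- find_peak(mk_curve(c(0.5, 0.9, 0.9, 0.7)), "3NN")
  expect_equal(tie$k_star, 2L)
  expect_equal(tie$mcc_star, 0.9)
  expect_identical(tie$gene_ids, c("g001", "g002"))
  for (seed in 1:10) {                  # random curve vs exhaustive scan
    mcc <- withr::with_seed(seed, round(runif(200), 3))
    pk <- find_peak(mk_curve(mcc), "3NN")
    expect_equal(pk$mcc_star, max(mcc))
    expect_equal(pk$k_star, which.max(mcc))
    expect_true(all(pk$mcc_star >= mcc))  # peak optimality
  }
  expect_error(find_peak(mk_curve(0.5), "SVM"), "no records")
})

test_that("select_best picks the highest peak across families", {
  two <- data.frame(
    family = rep(c("SVM", "3NN"), each = 3), k = rep(1:3, 2),
    TP = 1L, FN = 1L, FP = 1L, TN = 1L, Sn = 0.5, Sp = 0.5, ACC = 0.5,
    MCC = c(0.60, 0.858, 0.52, 0.61, 0.879, 0.55),
    stringsAsFactors = FALSE)
  attr(two, "gene_order") <- paste0("g", 1:3)
  class(two) <- c("ifs_curve", "data.frame")
  best <- select_best(two)
  expect_equal(best$family, "3NN")
  expect_equal(best$mcc_star, 0.879)
  # equals the max over per-family peaks
  peaks <- lapply(c("SVM", "3NN"), function(f) find_peak(two, f))
  expect_equal(best$mcc_star,
               max(vapply(peaks, function(p) p$mcc_star, numeric(1))))
  solo <- two[two$family == "SVM", ]
  attr(solo, "gene_order") <- paste0("g", 1:3)
  class(solo) <- c("ifs_curve", "data.frame")
  expect_equal(select_best(solo)$family, "SVM")
})

test_that("unknown ranked genes and bad bounds are rejected", {
  fx <- ifs_fixture()
  bad <- fx$ranked
  bad$gene_id[1] <- "ghost"
  expect_error(build_curve(bad, fx$X, fx$y, families = "1NN"),
               "missing from matrix.*ghost")
  expect_error(build_curve(fx$ranked, fx$X, fx$y, families = "1NN",
                           max_k = 0), "max_k")
})

test_that("IFS curves survive the TSV round trip with gene order intact", {
  fx <- ifs_fixture()
  cv <- build_curve(fx$ranked, fx$X, fx$y, families = "3NN", max_k = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ifs_curve(cv, path)
  cv2 <- read_ifs_curve(path)
  expect_equal(cv2$MCC, cv$MCC, tolerance = 1e-12)
  expect_identical(attr(cv2, "gene_order"), attr(cv, "gene_order"))
  expect_s3_class(plot_ifs_curve(cv), "ggplot")
})
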