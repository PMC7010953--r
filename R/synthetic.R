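#' Configuration for the synthetic expression generator
#'
#' Defaults emulate the scale and structure of an L1000 landmark-gene
#' cell-line screen with a rare positive phenotype: 978 genes, 156 positive
#' and 3,582 negative samples (about 4% prevalence, 24:1 imbalance), a small
#' set of class-informative genes whose means shift between classes, and
#' redundant genes correlated with informative ones to exercise the
#' redundancy term of mRMR. All sizes scale down freely for desk-scale runs.
#'
#' @param n_genes total gene count.
#' @param n_pos,n_neg positive / negative sample counts.
#' @param n_informative number of class-informative genes.
#' @param effect_size between-class mean shift of informative genes, in
#'   units of `noise_sd`.
#' @param n_redundant_blocks number of redundant genes; block b is tied to
#'   informative gene `(b - 1) %% n_informative + 1`.
#' @param block_correlation target Pearson correlation in `[0, 1)` between a
#'   redundant gene and its parent.
#' @param noise_sd within-class standard deviation of every gene.
#' @param seed integer RNG seed; fully determines the output.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 978L, n_pos = 156L, n_neg = 3582L,
                             n_informative = 10L, effect_size = 1.5,
                             n_redundant_blocks = 5L,
                             block_correlation = 0.8, noise_sd = 1,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_pos = as.integer(n_pos),
              n_neg = as.integer(n_neg),
              n_informative = as.integer(n_informative),
              effect_size = as.numeric(effect_size),
              n_redundant_blocks = as.integer(n_redundant_blocks),
              block_correlation = as.numeric(block_correlation),
              noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  if (cfg$n_genes < 1L || cfg$n_pos < 1L || cfg$n_neg < 1L)
    stop("gene and per-class sample counts must be positive")
  if (cfg$n_informative < 0L || cfg$n_redundant_blocks < 0L)
    stop("gene role counts must be non-negative")
  if (cfg$n_informative + cfg$n_redundant_blocks > cfg$n_genes)
    stop("infeasible gene budget: informative + redundant exceeds n_genes")
  if (cfg$n_redundant_blocks > 0L && cfg$n_informative == 0L)
    stop("redundant blocks need at least one informative gene")
  if (cfg$block_correlation < 0 || cfg$block_correlation >= 1)
    stop("block_correlation must be in [0, 1)")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Every gene is Gaussian with standard deviation `noise_sd`. Informative
#' genes have mean 0 in negatives and `effect_size * noise_sd` in positives;
#' the remaining genes are class-independent noise. Each redundant gene is
#' its parent informative gene's realized values plus Gaussian noise whose
#' variance is calibrated (against the parent's empirical spread) so the
#' empirical parent-child correlation matches `block_correlation`; redundant
#' genes therefore also carry class signal, but signal that is redundant
#' given the parent — exactly the case mRMR's redundancy penalty targets.
#' Gene roles and class labels are assigned to random positions, and the
#' whole dataset is a deterministic function of the config (including seed).
#'
#' @param cfg a [synthetic_config()].
#' @return list with `expression` (genes x samples matrix), `labels` (named
#'   0/1 vector) and `truth`, a list with `informative` (gene ids) and
#'   `redundant` (named character vector: redundant gene id -> parent id).
#' @export
generate_expression_data <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_pos + cfg$n_neg
    labels <- sample(c(rep(1L, cfg$n_pos), rep(0L, cfg$n_neg)))
    wid_s <- max(4L, nchar(n))
    wid_g <- max(4L, nchar(cfg$n_genes))
    sample_ids <- sprintf("s%0*d", wid_s, seq_len(n))
    gene_ids <- sprintf("g%0*d", wid_g, seq_len(cfg$n_genes))
    roles <- sample(cfg$n_genes)
    inf_idx <- roles[seq_len(cfg$n_informative)]
    red_idx <- roles[cfg$n_informative + seq_len(cfg$n_redundant_blocks)]
    M <- matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$noise_sd),
                cfg$n_genes, n)
    if (cfg$n_informative > 0L)
      M[inf_idx, labels == 1L] <- M[inf_idx, labels == 1L] +
        cfg$effect_size * cfg$noise_sd
    parent_of <- character(0L)
    if (cfg$n_redundant_blocks > 0L) {
      r <- cfg$block_correlation
      for (b in seq_len(cfg$n_redundant_blocks)) {
        p <- inf_idx[(b - 1L) %% cfg$n_informative + 1L]
        x <- M[p, ]
        M[red_idx[b], ] <- if (r > 0)
          x + stats::rnorm(n, 0, stats::sd(x) * sqrt(1 / r^2 - 1))
        else stats::rnorm(n, 0, cfg$noise_sd)
      }
      parent_of <- stats::setNames(gene_ids[inf_idx[(seq_len(
        cfg$n_redundant_blocks) - 1L) %% cfg$n_informative + 1L]],
        gene_ids[red_idx])
    }
    dimnames(M) <- list(gene_ids, sample_ids)
    list(expression = expression_matrix(M),
         labels = label_vector(labels, sample_ids),
         truth = list(informative = gene_ids[inf_idx],
                      redundant = parent_of))
  })
}

#' Write a synthetic dataset to disk in the formats the loaders read
#'
#' Emits the expression matrix (delimited), the label TSV and a
#' ground-truth sidecar TSV (gene id, role, parent) for tests.
#'
#' @param data result of [generate_expression_data()].
#' @param dir output directory, created if needed.
#' @return named character vector of the three file paths.
#' @export
write_synthetic <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "ground_truth.tsv"))
  write_expression(data$expression, paths[["expression"]])
  write_labels(data$labels, paths[["labels"]])
  tr <- data$truth
  df <- rbind(
    data.frame(gene_id = tr$informative, role = "informative",
               parent = NA_character_, stringsAsFactors = FALSE),
    if (length(tr$redundant))
      data.frame(gene_id = names(tr$redundant), role = "redundant",
                 parent = unname(tr$redundant), stringsAsFactors = FALSE))
  utils::write.table(df, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
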