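#' Discretize expression into three per-gene states
#'
#' Mutual information is computed on discrete states, so continuous
#' expression is first reduced, gene by gene, to low/medium/high
#' (0/1/2) relative to that gene's own distribution: values below
#' `mean - threshold_sigma * sd` become 0, values above
#' `mean + threshold_sigma * sd` become 2, everything else 1. This is the
#' mean +/- t*sd scheme of the classical C/C++ mRMR software, default
#' t = 0.5. A zero-variance gene maps entirely to the middle state. The
#' mapping is invariant to positive affine transforms of a gene's values.
#'
#' @param m expression matrix (genes x samples).
#' @param threshold_sigma positive threshold in units of per-gene standard
#'   deviations; default 0.5.
#' @return integer matrix of states in `{0, 1, 2}`, same dimnames as `m`.
#' @export
discretize <- function(m, threshold_sigma = 0.5) {
  if (!is.numeric(threshold_sigma) || length(threshold_sigma) != 1L ||
      !is.finite(threshold_sigma) || threshold_sigma <= 0)
    stop("threshold_sigma must be a positive number")
  m <- expression_matrix(m)
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  lo <- mu - threshold_sigma * sd
  hi <- mu + threshold_sigma * sd
  st <- matrix(1L, nrow(m), ncol(m), dimnames = dimnames(m))
  ok <- is.finite(sd) & sd > 0
  st[ok & m < lo] <- 0L   # recycling by column: lo/hi are per-gene (row)
  st[ok & m > hi] <- 2L
  st
}

#' Plug-in mutual information between two discrete vectors
#'
#' Empirical (maximum-likelihood) mutual information from the joint count
#' table, in bits (base-2 log), with the `0 * log 0 = 0` convention and no
#' small-sample bias correction. Symmetric and non-negative.
#'
#' @param x,y equal-length vectors of discrete states.
#' @return mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 1L) stop("empty input")
  tab <- table(x, y)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log2(p[nz] / (px[row(p)[nz]] * py[col(p)[nz]])))
  max(mi, 0)
}

# Mutual information of every row of a state matrix with one vector.
# Vectorized over genes: for each (state a, level b) pair the joint counts of
# all genes at once are one matrix-vector product.
mi_rows <- function(S, y) {
  n <- ncol(S)
  xs <- sort(unique(as.vector(S)))
  ys <- sort(unique(y))
  ny <- vapply(ys, function(b) sum(y == b), numeric(1L))
  mi <- numeric(nrow(S))
  for (a in xs) {
    A <- S == a
    storage.mode(A) <- "double"
    cab <- vapply(ys, function(b) as.vector(A %*% (y == b)),
                  numeric(nrow(S)))
    cab <- matrix(cab, nrow = nrow(S))
    ra <- rowSums(cab)
    for (bi in seq_along(ys)) {
      c1 <- cab[, bi]
      pos <- c1 > 0
      mi[pos] <- mi[pos] +
        c1[pos] / n * log2(c1[pos] * n / (ra[pos] * ny[bi]))
    }
  }
  pmax(mi, 0)
}

#' Relevance of every gene with the class label
#'
#' The relevance D of a gene is the mutual information between its
#' discretized states and the binary phenotype, in bits.
#'
#' @param d discretized state matrix (see [discretize()]).
#' @param l label vector aligned to `d`'s samples.
#' @return named numeric vector, one relevance per gene.
#' @export
relevance_all <- function(d, l) {
  l <- check_aligned(d, l)
  stats::setNames(mi_rows(d, as.integer(l)), rownames(d))
}

check_aligned <- function(d, l) {
  if (length(l) != ncol(d))
    stop("labels and matrix differ in sample count")
  if (!is.null(names(l)) && !is.null(colnames(d)) &&
      !identical(names(l), colnames(d)))
    stop("labels are not aligned to the matrix sample order; see align_labels()")
  l
}

#' Greedy mRMR gene ranking
#'
#' Ranks genes by minimal-redundancy maximal-relevance forward selection.
#' The first gene maximizes relevance D = I(g, t); each subsequent step
#' selects, among unranked genes, the one maximizing the difference criterion
#' D(g) - R(g), where R(g) is the mean mutual information between g and the
#' already-ranked genes. Ties are broken toward the lowest input gene index,
#' so the ranking is deterministic and stable under reruns; scores within
#' 1e-9 bits of the step maximum count as tied, since analytically equal
#' criteria (e.g. genes with permuted joint tables) can differ in the last
#' floating-point digits depending on summation order.
#'
#' @param d discretized state matrix.
#' @param l aligned label vector.
#' @param top_n number of ranks to produce (default 200, the conventional
#'   first-stage cut); capped at the gene count.
#' @return a `data.frame` of class `ranked_gene_list` with columns
#'   `rank`, `gene_id`, `relevance`, `redundancy`, `score` (all MI values in
#'   bits; `score = relevance - redundancy` at the step the gene was chosen).
#' @export
mrmr_rank <- function(d, l, top_n = 200L) {
  if (!is.numeric(top_n) || length(top_n) != 1L || top_n < 1)
    stop("top_n must be a positive integer")
  if (nrow(d) < 2L) stop("need at least two genes to rank")
  l <- check_aligned(d, l)
  N <- nrow(d)
  n_rank <- min(as.integer(top_n), N)
  D <- mi_rows(d, as.integer(l))
  red_sum <- numeric(N)
  avail <- rep(TRUE, N)
  out_gene <- integer(n_rank)
  out_rel <- out_red <- out_score <- numeric(n_rank)
  for (step in seq_len(n_rank)) {
    m <- step - 1L
    red <- if (m == 0L) numeric(N) else red_sum / m
    score <- D - red
    score[!avail] <- -Inf
    j <- which(score >= max(score) - 1e-9)[1L]  # lowest-index tie-break
    out_gene[step] <- j
    out_rel[step] <- D[j]
    out_red[step] <- red[j]
    out_score[step] <- D[j] - red[j]
    avail[j] <- FALSE
    if (step < n_rank)
      red_sum <- red_sum + mi_rows(d, as.integer(d[j, ]))
  }
  res <- data.frame(rank = seq_len(n_rank),
                    gene_id = rownames(d)[out_gene],
                    relevance = out_rel,
                    redundancy = out_red,
                    score = out_score,
                    stringsAsFactors = FALSE)
  class(res) <- c("ranked_gene_list", "data.frame")
  res
}

#' Write / read a ranked gene list as TSV
#'
#' Columns: rank, gene_id, relevance_bits, redundancy_bits, score.
#'
#' @param ranked a `ranked_gene_list`.
#' @param path file path.
#' @export
write_ranked_list <- function(ranked, path) {
  df <- data.frame(rank = ranked$rank, gene_id = ranked$gene_id,
                   relevance_bits = ranked$relevance,
                   redundancy_bits = ranked$redundancy,
                   score = ranked$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  res <- data.frame(rank = as.integer(df$rank), gene_id = df$gene_id,
                    relevance = df$relevance_bits,
                    redundancy = df$redundancy_bits,
                    score = df$score, stringsAsFactors = FALSE)
  class(res) <- c("ranked_gene_list", "data.frame")
  res
}
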