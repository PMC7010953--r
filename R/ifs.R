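#' Build the incremental-feature-selection curve
#'
#' For each classifier family and each prefix size k = 1..`max_k`, runs
#' leave-one-out cross-validation on the continuous expression submatrix of
#' the top-k ranked genes and records the confusion counts and metrics. The
#' curve of LOOCV MCC against k is the object whose per-family peak defines
#' the selected biomarker panel. Classifiers see continuous expression;
#' discretization exists only inside the mRMR stage.
#'
#' For the kNN families the squared-distance matrix is grown incrementally
#' by one gene per prefix step and shared across k (and across the kNN
#' specs), which makes the quadratic-cost loop linear in the number of
#' prefixes; the shortcut is prediction-identical to naive per-fold
#' retraining and that identity is asserted in the test suite. Set
#' `fast = FALSE` to force naive retraining everywhere.
#'
#' @param ranked a `ranked_gene_list` from [mrmr_rank()].
#' @param X expression matrix (genes x samples), continuous values.
#' @param y label vector aligned to `X`'s samples.
#' @param families list of [classifier_spec()] objects (or family-name
#'   strings, which get default specs with `seed`).
#' @param max_k largest prefix size; default 200, capped at the ranked-list
#'   length.
#' @param fast use the kNN incremental-distance shortcut.
#' @param seed seed used when `families` are given as strings.
#' @return a `data.frame` of class `ifs_curve` in long format with columns
#'   `family`, `k`, `TP`, `FN`, `FP`, `TN`, `Sn`, `Sp`, `ACC`, `MCC`, and
#'   the gene rank order as attribute `"gene_order"`.
#' @export
build_curve <- function(ranked, X, y, families = default_classifier_set(),
                        max_k = 200L, fast = TRUE, seed = 1L) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  if (is.character(families))
    families <- lapply(families, classifier_spec, seed = seed)
  if (inherits(families, "classifier_spec")) families <- list(families)
  if (!length(families)) stop("at least one classifier family is required")
  fam_names <- vapply(families, function(s) s$family, character(1L))
  if (anyDuplicated(fam_names))
    stop("duplicate classifier families in `families`")
  missing <- setdiff(ranked$gene_id, rownames(X))
  if (length(missing))
    stop("ranked genes missing from matrix: ", paste(missing, collapse = ", "))
  if (!is.null(names(y))) y <- align_labels(X, y)
  y <- as.integer(y)
  max_k <- min(as.integer(max_k), nrow(ranked))
  if (max_k < 1L) stop("max_k must be at least 1")
  gene_order <- ranked$gene_id[seq_len(max_k)]
  Xs <- t(X[gene_order, , drop = FALSE])  # samples x genes, rank order
  n <- nrow(Xs)
  tab <- table(factor(y, levels = c(0L, 1L)))
  if (any(tab == 0L)) stop("both classes must be present")
  if (any(tab == 1L)) stop("a class with a single member makes LOOCV degenerate")

  rows <- vector("list", length(families) * max_k)
  row_i <- function(fi, k) (fi - 1L) * max_k + k
  knn_specs <- families[vapply(families, function(s)
    fast && is_knn(s$family) && !isTRUE(s$hyperparameters$scale_features),
    logical(1L))]
  other_specs <- setdiff(seq_along(families), match(
    vapply(knn_specs, function(s) s$family, character(1L)), fam_names))

  if (length(knn_specs)) {
    d2 <- matrix(0, n, n)
    ks <- vapply(knn_specs, function(s) knn_k(s$family), integer(1L))
    for (k in seq_len(max_k)) {
      g <- Xs[, k]
      d2 <- d2 + outer(g, g, "-")^2
      dd <- d2
      diag(dd) <- Inf
      for (si in seq_along(knn_specs)) {
        pred <- vapply(seq_len(n),
                       function(i) knn_vote(dd[i, ], y, ks[si]),
                       integer(1L))
        cm <- confusion_counts(y, pred)
        fi <- match(knn_specs[[si]]$family, fam_names)
        rows[[row_i(fi, k)]] <- curve_row(knn_specs[[si]]$family, k, cm)
      }
    }
  }
  for (fi in other_specs) {
    spec <- families[[fi]]
    for (k in seq_len(max_k)) {
      cm <- loocv(spec, Xs[, seq_len(k), drop = FALSE], y, fast = fast)
      rows[[row_i(fi, k)]] <- curve_row(spec$family, k, cm)
    }
  }
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  attr(curve, "gene_order") <- gene_order
  class(curve) <- c("ifs_curve", "data.frame")
  curve
}

curve_row <- function(family, k, cm) {
  m <- metrics(cm)
  data.frame(family = family, k = k, TP = cm$TP, FN = cm$FN, FP = cm$FP,
             TN = cm$TN, Sn = m$Sn, Sp = m$Sp, ACC = m$ACC, MCC = m$MCC,
             stringsAsFactors = FALSE)
}

#' Peak of one family's IFS curve
#'
#' The prefix size with the highest LOOCV MCC for the given family; ties go
#' to the smaller k (parsimony).
#'
#' @param curve an `ifs_curve` from [build_curve()].
#' @param family family name present in the curve.
#' @return object of class `peak_selection`: `family`, `k_star`, `mcc_star`
#'   and `gene_ids`, the rank-order prefix of length `k_star`.
#' @export
find_peak <- function(curve, family) {
  stopifnot(inherits(curve, "ifs_curve"))
  rows <- curve[curve$family == family, , drop = FALSE]
  if (!nrow(rows)) stop("no records for family ", family)
  rows <- rows[order(rows$k), , drop = FALSE]
  i <- which.max(rows$MCC)  # first max = smallest k on ties
  structure(list(family = family,
                 k_star = rows$k[i],
                 mcc_star = rows$MCC[i],
                 gene_ids = attr(curve, "gene_order")[seq_len(rows$k[i])]),
            class = "peak_selection")
}

#' Best peak across all families in a curve
#'
#' Ties on MCC are broken by smaller panel size, then by the family's order
#' of first appearance in the curve.
#'
#' @param curve an `ifs_curve`.
#' @return the winning `peak_selection`.
#' @export
select_best <- function(curve) {
  stopifnot(inherits(curve, "ifs_curve"))
  fams <- unique(curve$family)
  if (!length(fams)) stop("empty IFS curve")
  peaks <- lapply(fams, function(f) find_peak(curve, f))
  mcc <- vapply(peaks, function(p) p$mcc_star, numeric(1L))
  ks <- vapply(peaks, function(p) p$k_star, numeric(1L))
  peaks[[order(-mcc, ks, seq_along(peaks))[1L]]]
}

#' @export
print.peak_selection <- function(x, ...) {
  cat(sprintf("%s peak: MCC = %.3f with %d genes\n",
              x$family, x$mcc_star, x$k_star))
  invisible(x)
}

#' Write / read an IFS curve as long-format TSV
#'
#' The gene rank order travels in a commented header line so a written curve
#' reloads with its `gene_order` attribute intact.
#'
#' @param curve an `ifs_curve`.
#' @param path file path.
#' @export
write_ifs_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# gene_order: ",
                    paste(attr(curve, "gene_order"), collapse = ",")), con)
  utils::write.table(curve, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ifs_curve
#' @export
read_ifs_curve <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (grepl("^# gene_order: ", first))
    attr(df, "gene_order") <- strsplit(sub("^# gene_order: ", "", first),
                                       ",")[[1L]]
  class(df) <- c("ifs_curve", "data.frame")
  df
}

#' Plot an IFS curve (LOOCV MCC against panel size per family)
#'
#' @param curve an `ifs_curve`.
#' @return a ggplot object.
#' @export
plot_ifs_curve <- function(curve) {
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = k, y = MCC, colour = family)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Number of top-ranked genes",
                  y = "LOOCV MCC", colour = "Classifier") +
    ggplot2::theme_minimal()
}
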