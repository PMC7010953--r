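#' Construct a validated expression matrix
#'
#' Expression data is represented as a plain numeric matrix with genes as rows
#' and samples as columns (the L1000 convention), gene identifiers as row
#' names and sample identifiers as column names. This constructor validates
#' the invariants every downstream function relies on: unique identifiers on
#' both axes and all-finite values. Missing values are rejected rather than
#' imputed, since silent imputation would change mutual-information estimates.
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @return the validated matrix with `dimnames` set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty expression matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match row count")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length does not match column count")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene identifiers: ", paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample identifiers: ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite expression value for gene ", gene_ids[bad[1L, 1L]],
         ", sample ", sample_ids[bad[1L, 2L]])
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Construct a binary label vector
#'
#' Labels are stored as a named integer vector: names are sample identifiers,
#' values are 1 for the positive class (e.g. KRAS mutation +) and 0 for the
#' negative class. The positive class is always encoded explicitly as 1,
#' never inferred from factor level order.
#'
#' @param labels vector coercible to 0/1 integers.
#' @param sample_ids sample identifiers; defaults to `names(labels)`.
#' @return named integer vector of 0/1.
#' @export
label_vector <- function(labels, sample_ids = names(labels)) {
  if (is.null(sample_ids))
    stop("sample identifiers are required for labels")
  lab <- suppressWarnings(as.integer(as.character(labels)))
  if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
    stop("labels must be binary 0/1 (positive class = 1)")
  if (length(lab) != length(sample_ids))
    stop("labels and sample_ids differ in length")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in labels")
  names(lab) <- as.character(sample_ids)
  lab
}

#' Read an expression matrix from disk
#'
#' Two dialects are supported: plain delimited text (first column gene id,
#' header row of sample ids; tab- or comma-separated) and the GEO
#' series-matrix dialect, where the table sits between
#' `!series_matrix_table_begin` and `!series_matrix_table_end` lines and all
#' other metadata lines are ignored (sample titles, when present, are kept as
#' an attribute).
#'
#' @param path file to read.
#' @param format `"delimited"` or `"geo_series_matrix"`.
#' @param transpose if `TRUE` the file is samples x genes and is transposed
#'   to the canonical genes-as-rows orientation after reading.
#' @param sep field separator for the delimited dialect; guessed from the
#'   file extension (`.csv` is comma, anything else tab) when `NULL`.
#' @return validated expression matrix (see [expression_matrix()]).
#' @export
load_expression <- function(path, format = c("delimited", "geo_series_matrix"),
                            transpose = FALSE, sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "delimited") {
    if (is.null(sep))
      sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            check.names = FALSE, colClasses = "character",
                            comment.char = "")
    titles <- NULL
  } else {
    lines <- readLines(path)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
      stop("no series-matrix table block found in ", path)
    df <- utils::read.table(text = lines[(beg + 1L):(end - 1L)], header = TRUE,
                            sep = "\t", quote = "\"", check.names = FALSE,
                            colClasses = "character", comment.char = "")
    tl <- grep("^!Sample_title\t", lines, value = TRUE)
    titles <- if (length(tl))
      gsub("\"", "", strsplit(tl[1L], "\t")[[1L]][-1L]) else NULL
  }
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty expression matrix in ", path)
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate gene identifiers: ", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) || anyNA(vals) || anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop("non-numeric expression value for gene ", ids[bad[1L, 1L]],
         ", sample ", colnames(vals)[bad[1L, 2L]])
  }
  dimnames(num) <- list(ids, colnames(vals))
  if (transpose) num <- t(num)
  m <- expression_matrix(num)
  if (!is.null(titles)) attr(m, "sample_titles") <- titles
  m
}

#' Write an expression matrix to disk
#'
#' Inverse of [load_expression()]: `load(write(m))` reproduces `m` exactly
#' for both dialects.
#'
#' @param m expression matrix.
#' @param path output file.
#' @param format,sep as in [load_expression()].
#' @export
write_expression <- function(m, path,
                             format = c("delimited", "geo_series_matrix"),
                             sep = NULL) {
  format <- match.arg(format)
  m <- expression_matrix(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (format == "delimited") {
    if (is.null(sep))
      sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("!series_matrix_table_begin", con)
    names(df)[1L] <- "ID_REF"
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines("!series_matrix_table_end", con)
  }
  invisible(path)
}

#' Read sample labels from disk
#'
#' Accepts either a two-column delimited file (sample id, 0/1 label; header
#' optional) or a one-column list of positive-sample identifiers. The
#' one-column form needs the full sample universe to produce a label vector;
#' pass it via `sample_ids` or use [labels_from_positives()].
#'
#' @param path file to read.
#' @param sample_ids full sample universe, required for the one-column form.
#' @return named integer label vector (see [label_vector()]).
#' @export
read_labels <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "", quote = "\"",
                          colClasses = "character", comment.char = "#")
  if (ncol(df) >= 2L) {
    if (df[1L, 2L] %in% c("0", "1") == FALSE) df <- df[-1L, , drop = FALSE]
    label_vector(df[[2L]], df[[1L]])
  } else {
    if (is.null(sample_ids))
      stop("positive-id list needs the full sample_ids universe")
    labels_from_positives(df[[1L]], sample_ids)
  }
}

#' Build a label vector from a list of positive-sample ids
#'
#' @param positive_ids identifiers of positive-class samples.
#' @param sample_ids full ordered sample universe.
#' @return named integer label vector.
#' @export
labels_from_positives <- function(positive_ids, sample_ids) {
  unknown <- setdiff(positive_ids, sample_ids)
  if (length(unknown))
    stop("positive ids not among samples: ", paste(unknown, collapse = ", "))
  label_vector(as.integer(sample_ids %in% positive_ids), sample_ids)
}

#' Write a label vector as a two-column TSV
#'
#' @param l named integer label vector.
#' @param path output file.
#' @export
write_labels <- function(l, path) {
  utils::write.table(data.frame(sample_id = names(l), label = as.integer(l)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a label vector to a matrix's sample order
#'
#' Reorders `l` to the column order of `m`. Label entries for samples absent
#' from the matrix are dropped with a warning; a matrix sample missing from
#' the labels is a hard error. Idempotent.
#'
#' @param m expression matrix.
#' @param l named integer label vector.
#' @return label vector in `colnames(m)` order.
#' @export
align_labels <- function(m, l) {
  ids <- colnames(m)
  if (is.null(ids)) stop("matrix has no sample identifiers")
  missing <- setdiff(ids, names(l))
  if (length(missing))
    stop("samples missing from labels: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(l), ids)
  if (length(extra))
    warning("dropping ", length(extra), " label entries with no matrix sample")
  label_vector(l[ids], ids)
}
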