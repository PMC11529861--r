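#' Coerce input to a validated expression matrix
#'
#' Accepts either a numeric matrix (genes in rows, samples in columns, with
#' row and column names) or a data frame whose first column holds gene
#' identifiers and whose remaining columns are per-sample numeric expression.
#' Validation enforces the assumptions of the downstream model: no missing
#' values, unique gene and sample identifiers, and at least three samples
#' (the leave-one-out calibration needs a variance of leave-one-out
#' variances, which is undefined below N = 3).
#'
#' @param x matrix or data frame as described above.
#' @param drop_zero_variance drop genes whose expression is constant across
#'   samples instead of raising an error. Constant genes have a zero
#'   leave-one-out variance, which breaks both the degrees-of-freedom
#'   calibration and the covariance-to-correlation conversion, so they must
#'   be removed one way or the other.
#' @return numeric matrix (genes x samples) with `gene_ids`/`sample_ids`
#'   available as `rownames`/`colnames`.
#' @export
as_expression <- function(x, drop_zero_variance = FALSE) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("validation error: expression input must be a numeric matrix or a data frame with gene ids in column 1",
         call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("validation error: expression matrix needs gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "input-format error: missing or non-finite value at gene '%s', sample '%s' (missing entries are errors, not imputed)",
      rownames(x)[bad[1]], colnames(x)[bad[2]]), call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("validation error: duplicate gene ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("validation error: duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (ncol(x) < 3) {
    stop("insufficient-samples error: at least 3 samples are required", call. = FALSE)
  }
  v <- apply(x, 1, stats::var)
  degenerate <- rownames(x)[v == 0]
  if (length(degenerate) > 0) {
    if (drop_zero_variance) {
      warning("dropping ", length(degenerate), " zero-variance gene(s): ",
              paste(degenerate, collapse = ", "), call. = FALSE)
      x <- x[v > 0, , drop = FALSE]
      if (nrow(x) == 0) stop("degenerate-gene error: all genes have zero variance", call. = FALSE)
    } else {
      stop("degenerate-gene error: zero variance across samples for gene(s): ",
           paste(degenerate, collapse = ", "),
           " (use drop_zero_variance = TRUE to drop them)", call. = FALSE)
    }
  }
  x
}

#' Read a delimited expression matrix
#'
#' Reads a genes x samples table (first row: sample ids; first column: gene
#' ids) and optionally applies a pseudocount-1 log transform. The model
#' downstream assumes approximately Gaussian values, which raw RNA-seq
#' counts are not; log2(x + 1) is the conventional choice for bulk data.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @param log_transform one of `"none"`, `"log2_plus_1"`, `"ln_plus_1"`.
#'   When a transform is requested all values must be nonnegative.
#' @param drop_zero_variance see [as_expression()].
#' @param transpose set `TRUE` if the file stores samples in rows.
#' @return validated expression matrix (see [as_expression()]).
#' @export
read_expression <- function(path, delimiter = "\t",
                            log_transform = c("none", "log2_plus_1", "ln_plus_1"),
                            drop_zero_variance = FALSE, transpose = FALSE) {
  log_transform <- match.arg(log_transform)
  if (!file.exists(path)) stop("I/O error: file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(raw))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "input-format error: cell at gene '%s', sample '%s' does not parse as a number (value '%s')",
      ids[bad[1]], sample_ids[bad[2]], raw[bad[1], bad[2] + 1L]), call. = FALSE)
  }
  rownames(vals) <- ids
  colnames(vals) <- sample_ids
  if (transpose) vals <- t(vals)
  if (log_transform != "none") {
    if (any(vals < 0)) {
      bad <- which(vals < 0, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "input-format error: negative value at gene '%s', sample '%s' but a log transform was requested",
        rownames(vals)[bad[1]], colnames(vals)[bad[2]]), call. = FALSE)
    }
    vals <- switch(log_transform,
                   log2_plus_1 = log2(vals + 1),
                   ln_plus_1 = log(vals + 1))
  }
  as_expression(vals, drop_zero_variance = drop_zero_variance)
}

#' Write a dense per-sample network to TSV
#'
#' Writes the g x g weight matrix with gene ids as both header row and first
#' column. When the network carries p-values a sibling file
#' `<path minus extension>.pvalues.tsv` with the same layout is written.
#'
#' @param net a `bonobo_network` (see [bonobo()]) or a plain named square
#'   matrix.
#' @param path output path for the weight matrix.
#' @param precision number of decimal places to print.
#' @export
write_dense_network <- function(net, path, precision = 6) {
  if (inherits(net, "bonobo_network")) {
    w <- net$correlation
    p <- net$pvalues
  } else {
    w <- net
    p <- NULL
  }
  .write_matrix_tsv(w, path, precision)
  if (!is.null(p)) {
    sib <- sub("(\\.[^./]+)?$", ".pvalues.tsv", path)
    .write_matrix_tsv(p, sib, precision)
  }
  invisible(NULL)
}

.write_matrix_tsv <- function(m, path, precision) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("I/O error: cannot write ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
  fmt <- sprintf("%%.%df", precision)
  body <- apply(m, 1, function(r) paste(sprintf(fmt, r), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
}

#' Read back a dense network TSV written by [write_dense_network()]
#' @param path file path.
#' @return numeric matrix with gene ids as dimnames.
#' @export
read_dense_network <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  as.matrix(raw)
}

#' Write a sparse network edge list to TSV
#'
#' One row per retained edge with header `gene_a gene_b weight pvalue`.
#' Gene pairs are canonicalised (`gene_a` lexicographically before
#' `gene_b`), self-edges are never emitted, and rows are sorted by ascending
#' p-value, ties broken by the gene pair.
#'
#' @param net a `bonobo_sparse` object (see [sparsify()]) or a data frame
#'   with columns gene_a, gene_b, weight, pvalue.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  edges <- if (inherits(net, "bonobo_sparse")) net$edges else tibble::as_tibble(net)
  edges <- .canonical_edges(edges)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("I/O error: cannot write ", path, call. = FALSE))
  on.exit(close(con))
  writeLines("gene_a\tgene_b\tweight\tpvalue", con)
  if (nrow(edges) > 0) {
    writeLines(sprintf("%s\t%s\t%.10g\t%.10g",
                       edges$gene_a, edges$gene_b, edges$weight, edges$pvalue), con)
  }
  invisible(NULL)
}

.canonical_edges <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b", "weight", "pvalue") %in% names(edges)))
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  flip <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[flip]
  edges$gene_a[flip] <- edges$gene_b[flip]
  edges$gene_b[flip] <- tmp
  edges[order(edges$pvalue, edges$gene_a, edges$gene_b), , drop = FALSE]
}
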