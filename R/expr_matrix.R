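#' Expression matrix with per-sample metadata
#'
#' The central container of the package: a genes x samples numeric matrix
#' of expression values together with per-sample metadata and an explicit
#' scale flag. Values are either TPM (`scale = "tpm"`, all non-negative)
#' or log-transformed expression `log10(TPM + 1)` (`scale = "log10p1"`).
#' All downstream statistics operate on the log scale.
#'
#' @param values Numeric matrix, genes as rows (unique rownames = gene
#'   ids), samples as columns (unique colnames = sample ids). No missing
#'   values allowed.
#' @param samples Data frame of per-sample metadata with at least a
#'   `sample` column matching `colnames(values)`; conventional columns
#'   are `stage`, `strain`, `sex`, `pair` and `role` (one of `"embryo"`,
#'   `"technical"`, `"tissue"`). Missing conventional columns are filled
#'   with `NA`.
#' @param scale Either `"tpm"` or `"log10p1"`.
#'
#' @return An object of class `expr_matrix`: a list with elements
#'   `values`, `samples` and `scale`.
#' @export
#' @examples
#' m <- matrix(c(0, 9, 99, 9), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' em <- expr_matrix(m, data.frame(sample = c("s1", "s2")), scale = "tpm")
#' em
expr_matrix <- function(values, samples, scale = c("tpm", "log10p1")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyNA(values))
    stop("`values` must not contain missing values")
  if (anyDuplicated(rownames(values)))
    stop("gene ids must be unique")
  if (anyDuplicated(colnames(values)))
    stop("sample ids must be unique")
  if (scale == "tpm" && any(values < 0))
    stop("TPM values must be non-negative")
  samples <- as.data.frame(samples)
  if (is.null(samples$sample))
    stop("`samples` must have a `sample` column")
  if (!setequal(samples$sample, colnames(values)) ||
      nrow(samples) != ncol(values))
    stop("`samples$sample` must match the matrix columns one-to-one")
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  for (col in c("stage", "strain", "sex", "pair", "role"))
    if (is.null(samples[[col]])) samples[[col]] <- NA_character_
  structure(list(values = values, samples = samples, scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  st <- unique(x$samples$stage)
  if (!all(is.na(st)))
    cat("  stages: ", paste(st, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene ids of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample ids of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x An `expr_matrix`.
#' @param genes Character vector of gene ids to keep (default: all).
#' @param samp Character vector of sample ids to keep (default: all).
#' @return The subsetted `expr_matrix`; input order of `genes`/`samp`
#'   is respected.
#' @export
subset_expr <- function(x, genes = NULL, samp = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(genes)) genes <- gene_ids(x)
  if (is.null(samp)) samp <- sample_ids(x)
  missing_g <- setdiff(genes, gene_ids(x))
  if (length(missing_g))
    stop("unknown gene ids: ", paste(utils::head(missing_g, 3), collapse = ", "))
  missing_s <- setdiff(samp, sample_ids(x))
  if (length(missing_s))
    stop("unknown sample ids: ", paste(utils::head(missing_s, 3), collapse = ", "))
  v <- x$values[genes, samp, drop = FALSE]
  expr_matrix(v, x$samples[match(samp, x$samples$sample), , drop = FALSE],
              scale = x$scale)
}

#' Combine the samples of two expression matrices
#'
#' Used to pool two cohorts (e.g. the two wild populations) before a
#' joint low-expression filter. Gene sets must be identical and scales
#' must agree.
#'
#' @param a,b `expr_matrix` objects on the same genes and scale.
#' @return A single `expr_matrix` with the samples of `a` then `b`.
#' @export
bind_samples <- function(a, b) {
  stopifnot(inherits(a, "expr_matrix"), inherits(b, "expr_matrix"))
  if (a$scale != b$scale) stop("scales differ")
  if (!identical(gene_ids(a), gene_ids(b))) stop("gene sets differ")
  if (length(intersect(sample_ids(a), sample_ids(b))))
    stop("duplicated sample ids across matrices")
  expr_matrix(cbind(a$values, b$values), rbind(a$samples, b$samples),
              scale = a$scale)
}

#' Write an expression matrix and its metadata as TSV
#'
#' The matrix file is tab-delimited with a header row of sample ids and
#' gene ids in the first column (`gene_id`); the metadata file has one
#' row per sample.
#'
#' @param x An `expr_matrix`.
#' @param values_path,metadata_path Output file paths.
#' @return Invisibly, `x`.
#' @export
write_expr_tsv <- function(x, values_path, metadata_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = gene_ids(x), x$values, check.names = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metadata_path)) {
    meta <- cbind(x$samples, scale = x$scale)
    utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' Read an expression matrix written by [write_expr_tsv()]
#'
#' @param values_path Matrix TSV (first column `gene_id`, one column per
#'   sample).
#' @param metadata_path Optional sample-metadata TSV; when absent,
#'   metadata is filled with `NA`.
#' @param scale Scale flag of the stored values; overridden by a `scale`
#'   column in the metadata when present.
#' @return An `expr_matrix`.
#' @export
read_expr_tsv <- function(values_path, metadata_path = NULL,
                          scale = c("tpm", "log10p1")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(values_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  if (!is.null(metadata_path)) {
    meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                              colClasses = "character")
    if (!is.null(meta$scale)) {
      scale <- unique(meta$scale)
      meta$scale <- NULL
    }
  } else {
    meta <- data.frame(sample = colnames(v))
  }
  expr_matrix(v, meta, scale = scale)
}
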