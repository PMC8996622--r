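#' Absolute per-gene expression differences over a pair design
#'
#' For each gene j and each pair (i, k) of the design, computes
#' `|x_j^i - x_j^k|` on the log scale. Symmetric in the pair order.
#'
#' @param m An `expr_matrix` on the `log10p1` scale.
#' @param pairs Pair design data frame with columns `sample_i`,
#'   `sample_k` (see [twin_pair_design()], [cross_pair_design()],
#'   [technical_pair_design()]).
#' @return Numeric matrix genes x pairs of absolute differences; column
#'   names `sample_i|sample_k`.
#' @export
abs_pair_differences <- function(m, pairs) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log10p1")
    stop("pair differences are defined on the log10p1 scale")
  miss <- setdiff(unique(c(pairs$sample_i, pairs$sample_k)), sample_ids(m))
  if (length(miss))
    stop("sample id(s) missing from matrix: ",
         paste(utils::head(miss, 3), collapse = ", "))
  d <- abs(m$values[, pairs$sample_i, drop = FALSE] -
             m$values[, pairs$sample_k, drop = FALSE])
  colnames(d) <- paste(pairs$sample_i, pairs$sample_k, sep = "|")
  d
}

#' Per-gene technical error from a quadruplicate
#'
#' The technical error of gene j is the mean of its absolute expression
#' differences over all C(4,2) = 6 unordered replicate combinations.
#' Invariant under replicate reordering.
#'
#' @param m An `expr_matrix` of technical replicates (`log10p1` scale).
#' @param n_required Expected replicate count (default 4); set to `NA`
#'   to accept any number >= 2.
#' @return Named numeric vector of per-gene technical error.
#' @export
technical_error <- function(m, n_required = 4) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!is.na(n_required) && ncol(m$values) != n_required)
    stop("expected ", n_required, " technical replicates, got ",
         ncol(m$values), " (set n_required = NA to override)")
  if (ncol(m$values) < 2) stop("need at least 2 replicates")
  d <- abs_pair_differences(m, technical_pair_design(m))
  rowMeans(d)
}

#' One-sided rank-sum p-value for "a stochastically greater than b"
#'
#' Mann-Whitney/Wilcoxon rank-sum test with H1 that sample `a` tends to
#' exceed sample `b`. The exact distribution is used when the smaller
#' sample has at most 8 values and there are no ties; otherwise the
#' mid-rank normal approximation with continuity and tie correction.
#'
#' @param a,b Non-empty numeric vectors.
#' @return The one-sided p-value.
#' @export
#' @examples
#' rank_sum_greater(c(5, 6, 7), c(1, 2, 3))  # exact: 1/20 = 0.05
rank_sum_greater <- function(a, b) {
  if (!length(a) || !length(b)) stop("samples must be non-empty")
  pooled <- c(a, b)
  if (max(pooled) == min(pooled)) return(1)   # fully degenerate
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && min(length(a), length(b)) <= 8
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "greater", exact = exact,
                       correct = TRUE)$p.value)
}

#' Filter genes whose twin variation exceeds the technical error
#'
#' For every gene, the twin absolute differences (one per twin pair) are
#' compared with the six technical-replicate absolute differences by a
#' one-sided rank-sum test; genes with p < `alpha` (raw p, no
#' multiple-testing correction) pass and are the universe of all
#' variation analyses. The per-gene mean of the six technical
#' differences is reported as the technical-error summary.
#'
#' @param m Twin `expr_matrix` (`log10p1`), already low-expression
#'   filtered.
#' @param twin_pairs Twin pair design (>= 2 pairs).
#' @param tech Technical-replicate `expr_matrix` on the same genes.
#' @param alpha Significance level, default 0.01.
#' @return Data frame (one row per gene): `gene`, `n_pairs`,
#'   `mean_twin_diff`, `tech_error`, `p`, `pass`.
#' @export
filter_by_technical_error <- function(m, twin_pairs, tech, alpha = 0.01) {
  stopifnot(inherits(m, "expr_matrix"), inherits(tech, "expr_matrix"))
  if (nrow(twin_pairs) < 2)
    stop("need at least 2 twin pairs")
  common <- intersect(gene_ids(m), gene_ids(tech))
  if (!length(common)) stop("no shared genes between twin and technical data")
  m <- subset_expr(m, genes = common)
  tech <- subset_expr(tech, genes = common)
  twin_d <- abs_pair_differences(m, twin_pairs)
  tech_d <- abs_pair_differences(tech, technical_pair_design(tech))
  p <- vapply(seq_along(common), function(j)
    rank_sum_greater(twin_d[j, ], tech_d[j, ]), numeric(1))
  data.frame(gene = common,
             n_pairs = nrow(twin_pairs),
             mean_twin_diff = rowMeans(twin_d),
             tech_error = rowMeans(tech_d),
             p = p,
             pass = p < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}
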