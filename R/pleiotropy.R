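#' Count the contexts (tissues/stages) in which each gene is expressed
#'
#' A gene is expressed in a context iff its mean TPM over that context's
#' replicate samples is at or above `tpm_threshold` (boundary
#' inclusive). Spatial pleiotropy counts tissues (25 by default in the
#' study design), temporal pleiotropy counts developmental stages (16).
#'
#' @param m An `expr_matrix` on the TPM scale whose samples are
#'   replicates of contexts.
#' @param contexts Character vector assigning each sample to a context;
#'   defaults to the `stage` metadata column.
#' @param tpm_threshold Expression threshold, default 1 TPM.
#' @return Data frame `gene`, `n_contexts` (0..number of contexts).
#' @export
context_expression_count <- function(m, contexts = m$samples$stage,
                                     tpm_threshold = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "tpm")
    stop("pleiotropy thresholds are on the TPM scale; got ", m$scale)
  if (length(contexts) != ncol(m$values))
    stop("`contexts` must assign every sample")
  if (anyNA(contexts)) stop("missing context labels")
  ctx <- unique(contexts)
  expressed <- vapply(ctx, function(cx)
    rowMeans(m$values[, contexts == cx, drop = FALSE]) >= tpm_threshold,
    logical(nrow(m$values)))
  data.frame(gene = gene_ids(m),
             n_contexts = as.integer(rowSums(expressed)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genes annotated to a root GO term or any of its descendants
#'
#' Computes the descendant closure of `root` from a child -> parent edge
#' list and returns the genes annotated with any term in the closure.
#' The default root is the "developmental process" term, giving the
#' developmental gene set.
#'
#' @param annotations Data frame `gene`, `term`.
#' @param ontology_edges Data frame `child`, `parent` (term ids).
#' @param root Root term id, default `"GO:0032502"`.
#' @return Character vector of gene ids (sorted, unique).
#' @export
developmental_gene_set <- function(annotations, ontology_edges,
                                   root = "GO:0032502") {
  stopifnot(all(c("gene", "term") %in% names(annotations)),
            all(c("child", "parent") %in% names(ontology_edges)))
  known <- unique(c(ontology_edges$child, ontology_edges$parent))
  if (!root %in% known)
    stop("root term ", root, " absent from the ontology edges")
  closure <- root
  repeat {
    add <- ontology_edges$child[ontology_edges$parent %in% closure]
    add <- setdiff(add, closure)
    if (!length(add)) break
    closure <- c(closure, add)
  }
  sort(unique(annotations$gene[annotations$term %in% closure]))
}

#' Genes expressed throughout embryogenesis
#'
#' Constitutively expressed genes: replicate-mean log expression at or
#' above `threshold` at *every* sampled developmental stage.
#'
#' @param stage_means Numeric matrix genes x stages of replicate-mean
#'   `log10(TPM+1)` expression (>= 1 stage).
#' @param threshold Expression threshold, default 0.1 (inclusive).
#' @return Character vector of gene ids.
#' @export
constitutive_gene_set <- function(stage_means, threshold = 0.1) {
  if (!is.matrix(stage_means) || ncol(stage_means) < 1)
    stop("`stage_means` must be a genes x stages matrix with >= 1 stage")
  rownames(stage_means)[rowSums(stage_means < threshold) == 0]
}

#' The fraction of genes with the smallest corrected variation
#'
#' Selects `floor(fraction * n)` genes with the smallest corrected
#' variation (default: the most stable 10%); ties at the cut are broken
#' by gene id.
#'
#' @param table A gene variation table (needs `gene`, `corrected`).
#' @param fraction Fraction in (0, 1], default 0.10.
#' @return Character vector of selected gene ids.
#' @export
least_variable_fraction <- function(table, fraction = 0.10) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]")
  n_take <- floor(fraction * nrow(table))
  ord <- order(table$corrected, table$gene)
  table$gene[ord][seq_len(n_take)]
}

#' One-sided enrichment test of annotation terms in a gene set
#'
#' For each term, a 2x2 table of term membership in the selected set vs
#' the background (universe minus selected) is tested for enrichment
#' with the one-sided Fisher's exact test, whose p-value is the
#' hypergeometric upper tail; q-values are Benjamini-Hochberg over all
#' terms. Fold enrichment is the frequency ratio
#' `(k / n_selected) / ((K - k) / n_background)` (infinite when the term
#' is absent from the background but present in the selection).
#'
#' @param selected Character vector of selected genes (subset of
#'   `universe`).
#' @param universe Character vector: all analyzed genes.
#' @param annotations Data frame `gene`, `term`; genes outside the
#'   universe are ignored, genes without terms are allowed.
#' @return Data frame (one row per term, sorted by p): `term`, `k`
#'   (selected with term), `K` (universe with term), `n` (selected
#'   size), `N` (universe size), `fold`, `p`, `q`.
#' @export
enrichment_test <- function(selected, universe, annotations) {
  selected <- unique(selected); universe <- unique(universe)
  if (!length(selected)) stop("empty selection")
  if (!all(selected %in% universe))
    stop("`selected` must be a subset of `universe`")
  background <- setdiff(universe, selected)
  if (!length(background)) stop("empty background")
  ann <- annotations[annotations$gene %in% universe, , drop = FALSE]
  terms <- sort(unique(ann$term))
  n_sel <- length(selected); n_bg <- length(background)
  N <- length(universe)
  k <- vapply(terms, function(t0)
    length(intersect(ann$gene[ann$term == t0], selected)), integer(1))
  K <- vapply(terms, function(t0)
    length(unique(ann$gene[ann$term == t0])), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n_sel, lower.tail = FALSE)
  kb <- K - k
  fold <- ifelse(k == 0, 0,
                 ifelse(kb == 0, Inf, (k / n_sel) / (kb / n_bg)))
  out <- data.frame(term = terms, k = k, K = K, n = n_sel, N = N,
                    fold = fold, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Report terms enriched more than a fold cutoff
#'
#' Filters an enrichment table to rows with fold strictly greater than
#' `fold_cut` (a fold of exactly 2 is excluded by "more than 2 times")
#' and flags which of them meet the FDR cutoff.
#'
#' @param enrichment Output of [enrichment_test()].
#' @param fold_cut Fold-enrichment cutoff (strict), default 2.
#' @param q_cut FDR cutoff used for the `significant` flag, default
#'   0.01.
#' @return The filtered table with an added logical `significant`
#'   column.
#' @export
twofold_report <- function(enrichment, fold_cut = 2, q_cut = 0.01) {
  out <- enrichment[enrichment$fold > fold_cut, , drop = FALSE]
  out$significant <- out$q <= q_cut
  rownames(out) <- NULL
  out
}
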