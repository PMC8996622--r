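#' Per-gene raw expression variation over a pair design
#'
#' The raw variation of gene j is the mean of `|x_j^i - x_j^k|` over
#' all pairs of the design (twin pairs for stability, sex-matched
#' cross-population pairs for intraspecies variation).
#'
#' @param m An `expr_matrix` (`log10p1`).
#' @param pairs Pair design with >= 1 pair.
#' @return Named numeric vector of per-gene raw variation.
#' @export
gene_variation <- function(m, pairs) {
  if (!nrow(pairs)) stop("empty pair list")
  rowMeans(abs_pair_differences(m, pairs))
}

#' Running-median correction of expression-level bias
#'
#' Expression variation depends on the absolute expression level; the
#' correction removes this trend. Genes are sorted by mean expression
#' (ties broken by gene id for determinism); for each gene the median
#' raw variation over a window of +/- (window-1)/2 neighbours is
#' subtracted. Near the edges the window shrinks symmetrically so both
#' sides keep equal counts (the first and last gene have a window of
#' size 1, hence corrected value 0). Corrected values may be negative.
#'
#' @param table Data frame with columns `gene`, `mean_expr` and `raw`
#'   (e.g. from [gene_variation_table()]).
#' @param window Odd window size in genes, default 501 (+/- 250).
#' @return The input table, original row order, with added columns
#'   `running_median` and `corrected = raw - running_median`.
#' @export
running_median_correct <- function(table, window = 501) {
  stopifnot(all(c("gene", "mean_expr", "raw") %in% names(table)))
  window <- as.integer(window)
  if (window < 1 || window %% 2 == 0)
    stop("`window` must be odd and >= 1")
  n <- nrow(table)
  if (window > n)
    warning("window (", window, ") exceeds gene count (", n,
            "); windows shrink accordingly")
  ord <- order(table$mean_expr, table$gene)
  raw_s <- table$raw[ord]
  half <- (window - 1L) %/% 2L
  med <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    stats::median(raw_s[(i - h):(i + h)])
  }, numeric(1))
  out <- table
  out$running_median[ord] <- med
  out$corrected <- out$raw - out$running_median
  out
}

#' Per-gene variation table with running-median correction
#'
#' Builds the full per-gene variation table for one cohort: mean log
#' expression over all individuals entering the comparison, raw
#' variation over the pair design, and the running-median-corrected
#' variation.
#'
#' @param m An `expr_matrix` (`log10p1`) holding every individual of
#'   the cohort.
#' @param pairs Pair design.
#' @param window Running-median window, default 501.
#' @param cohort Cohort label stored in the table (e.g. `"twin"`,
#'   `"intraspecies"`).
#' @return Data frame `gene`, `mean_expr`, `raw`, `running_median`,
#'   `corrected`, `cohort`.
#' @export
gene_variation_table <- function(m, pairs, window = 501,
                                 cohort = "twin") {
  raw <- gene_variation(m, pairs)
  tab <- data.frame(gene = gene_ids(m),
                    mean_expr = rowMeans(m$values),
                    raw = unname(raw),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- running_median_correct(tab, window = window)
  tab$cohort <- cohort
  tab
}

#' Intraspecies per-gene expression variation
#'
#' Mean absolute expression difference over all sex-matched
#' cross-population pairs, normalized with the same running-median
#' procedure as the twin variation. Mean expression (the sort key) is
#' taken over all individuals of both populations.
#'
#' @param m_a,m_b Population `expr_matrix` objects on the same genes.
#' @param pairs Optional cross-pair design (default: all sex-matched
#'   pairs).
#' @param window Running-median window.
#' @return A gene variation table (cohort `"intraspecies"`).
#' @export
intraspecies_gene_variation <- function(m_a, m_b, pairs = NULL,
                                        window = 501) {
  if (!identical(gene_ids(m_a), gene_ids(m_b)))
    stop("populations must share the same gene set")
  if (is.null(pairs)) pairs <- cross_pair_design(m_a, m_b)
  joint <- bind_samples(m_a, m_b)
  gene_variation_table(joint, pairs, window = window,
                       cohort = "intraspecies")
}

## -- orthology -----------------------------------------------------------

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Standard 12-column tab-separated BLAST output; only qseqid, sseqid,
#' evalue and bitscore are used downstream, and files carrying just
#' those four columns are accepted.
#'
#' @param path Path to the TSV (no header).
#' @return Data frame with columns `qseqid`, `sseqid`, `evalue`,
#'   `bitscore`.
#' @export
read_blast_hits <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) == 4) {
    names(df) <- c("qseqid", "sseqid", "evalue", "bitscore")
  } else if (ncol(df) >= 12) {
    df <- df[, c(1, 2, 11, 12)]
    names(df) <- c("qseqid", "sseqid", "evalue", "bitscore")
  } else {
    stop("expected 4 or >= 12 columns in BLAST tabular file: ", path)
  }
  for (col in c("evalue", "bitscore")) {
    if (!is.numeric(df[[col]])) {
      num <- suppressWarnings(as.numeric(df[[col]]))
      stop("malformed ", col, " at line ", which(is.na(num))[1],
           " of ", path)
    }
  }
  df
}

## best hit per query: smallest e-value, ties by larger bitscore, then
## lexicographically smallest subject id
best_hits <- function(hits) {
  o <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

#' Resolve 1:1 orthologs as reciprocal best hits
#'
#' A pair (a, b) is retained iff b is a's best hit in the A->B table and
#' a is b's best hit in the B->A table, both hits passing the e-value
#' cutoff. Best = smallest e-value, ties broken by larger bitscore, then
#' lexicographically smallest subject id. The resulting map is
#' one-to-one by construction.
#'
#' @param hits_ab,hits_ba Hit tables (data frames from
#'   [read_blast_hits()] or with the same four columns).
#' @param evalue_cutoff Keep hits with e-value strictly below this
#'   (default 1e-5).
#' @param keep_weak_hits If `TRUE`, invert the filter to e-value >
#'   cutoff (a literal reading of some methods text; not recommended —
#'   it discards all good hits).
#' @return Data frame `gene_a`, `gene_b`.
#' @export
resolve_rbh <- function(hits_ab, hits_ba, evalue_cutoff = 1e-5,
                        keep_weak_hits = FALSE) {
  need <- c("qseqid", "sseqid", "evalue", "bitscore")
  for (h in list(hits_ab, hits_ba))
    if (!all(need %in% names(h)))
      stop("hit tables need columns: ", paste(need, collapse = ", "))
  flt <- function(h) {
    keep <- if (keep_weak_hits) h$evalue > evalue_cutoff
            else h$evalue < evalue_cutoff
    h[keep, , drop = FALSE]
  }
  ab <- best_hits(flt(hits_ab))
  ba <- best_hits(flt(hits_ba))
  ## a -> b and b -> a must agree
  back <- ba$sseqid[match(ab$sseqid, ba$qseqid)]
  keep <- !is.na(back) & back == ab$qseqid
  out <- data.frame(gene_a = ab$qseqid[keep], gene_b = ab$sseqid[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$gene_a), , drop = FALSE]
}

#' Interspecies per-gene expression variation over 1:1 orthologs
#'
#' `|x_j^ref - x_j^other|` of replicate-averaged log expression for each
#' ortholog pair, running-median corrected against the reference
#' species' mean expression. Ortholog pairs missing from either profile
#' are dropped (count reported via a message).
#'
#' @param profile_ref Named numeric: replicate-averaged log expression
#'   of the reference species (phylotypic stage).
#' @param profile_other Same for the compared species.
#' @param map Ortholog map data frame (`gene_a`/`gene_b` or
#'   `gene_ref`/`gene_other`).
#' @param window Running-median window.
#' @param species Cohort label suffix.
#' @return A gene variation table (genes = reference ids; cohort
#'   `"interspecies:<species>"`). Empty map gives an empty table.
#' @export
interspecies_gene_variation <- function(profile_ref, profile_other, map,
                                        window = 501,
                                        species = "species") {
  if (!is.null(map$gene_ref)) {
    map <- data.frame(gene_a = map$gene_ref, gene_b = map$gene_other,
                      stringsAsFactors = FALSE)
  }
  ok <- map$gene_a %in% names(profile_ref) &
    map$gene_b %in% names(profile_other)
  dropped <- sum(!ok)
  if (dropped)
    message(dropped, " ortholog pair(s) missing from a profile; dropped")
  map <- map[ok, , drop = FALSE]
  tab <- data.frame(
    gene = map$gene_a,
    mean_expr = unname(profile_ref[map$gene_a]),
    raw = abs(unname(profile_ref[map$gene_a]) -
                unname(profile_other[map$gene_b])),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!nrow(tab)) {
    tab$running_median <- numeric(0)
    tab$corrected <- numeric(0)
  } else {
    tab <- running_median_correct(tab, window = window)
  }
  tab$cohort <- rep(paste0("interspecies:", species), nrow(tab))
  tab
}

#' Correlation between two per-gene variation tables
#'
#' Spearman correlation between the corrected variations of the genes
#' shared by two tables (e.g. twin stability vs intraspecies
#' conservation), with the p-value of the test of no correlation
#' (exact for n <= 10 without ties, t approximation otherwise).
#'
#' @param t1,t2 Gene variation tables (need `gene` and `corrected`).
#' @param column Which variation column to correlate (default
#'   `"corrected"`).
#' @return List with `rho`, `p` and `n` (shared genes).
#' @export
stability_conservation_correlation <- function(t1, t2,
                                               column = "corrected") {
  shared <- intersect(t1$gene, t2$gene)
  if (length(shared) < 10)
    stop("need >= 10 shared genes, got ", length(shared))
  x <- t1[[column]][match(shared, t1$gene)]
  y <- t2[[column]][match(shared, t2$gene)]
  exact <- length(shared) <= 10 && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Split a variation table into expression quintiles
#'
#' Genes are split into five groups of (near-)equal size by mean
#' expression, lowest first; when n is not divisible by 5 the remainder
#' is distributed to the lowest-expression groups (12 genes give sizes
#' 3, 3, 2, 2, 2). Ties in expression are broken by gene id.
#'
#' @param table A gene variation table (needs `gene`, `mean_expr`).
#' @return Named list of 5 sub-tables (`Q1` lowest ... `Q5` highest);
#'   their union is the input.
#' @export
expression_quintile_split <- function(table) {
  n <- nrow(table)
  if (n < 5) stop("need at least 5 genes")
  base <- n %/% 5L
  rem <- n %% 5L
  sizes <- rep(base, 5) + c(rep(1L, rem), rep(0L, 5 - rem))
  ord <- order(table$mean_expr, table$gene)
  grp <- rep(seq_len(5), sizes)
  out <- lapply(seq_len(5), function(g) {
    t0 <- table[ord[grp == g], , drop = FALSE]
    rownames(t0) <- NULL
    t0
  })
  names(out) <- paste0("Q", seq_len(5))
  out
}
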