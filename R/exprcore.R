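#' Log-transform a TPM expression matrix
#'
#' Applies `x -> log10(x + 1)` to every value. All variation statistics
#' in the package are computed on this scale.
#'
#' @param m An `expr_matrix` on the TPM scale.
#' @return An `expr_matrix` on the `log10p1` scale, metadata preserved.
#' @export
#' @examples
#' m <- matrix(c(0, 9, 99, 9), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' em <- expr_matrix(m, data.frame(sample = c("s1", "s2")), "tpm")
#' log_transform(em)$values   # 0 -> 0, 9 -> 1, 99 -> 2
log_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "tpm")
    stop("input is already log-transformed (scale = ", m$scale, ")")
  v <- log10(m$values + 1)
  expr_matrix(v, m$samples, scale = "log10p1")
}

#' Invert the log transform
#'
#' Maps `log10(TPM + 1)` values back to TPM, truncating at zero (small
#' negative log values can arise in synthetic data before truncation).
#'
#' @param m An `expr_matrix` on the `log10p1` scale.
#' @return An `expr_matrix` on the TPM scale.
#' @export
unlog_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log10p1") stop("input is not on the log10p1 scale")
  expr_matrix(pmax(10^m$values - 1, 0), m$samples, scale = "tpm")
}

#' Filter out genes with low expression
#'
#' Keeps gene j only if its log expression is at or above `threshold`
#' in *every* sample of the matrix (the analyzed cohort); the boundary
#' is inclusive. Idempotent; gene order preserved.
#'
#' @param m An `expr_matrix` on the `log10p1` scale.
#' @param threshold Non-negative scalar, default 0.1.
#' @return The filtered `expr_matrix`.
#' @export
filter_low_expression <- function(m, threshold = 0.1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log10p1")
    stop("low-expression filter is defined on the log10p1 scale")
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stop("`threshold` must be a single non-negative number")
  keep <- rowSums(m$values < threshold) == 0
  expr_matrix(m$values[keep, , drop = FALSE], m$samples, scale = m$scale)
}

## -- count-level operations (read-depth bias surrogate) ------------------

#' Subsample a count matrix to a fixed depth per sample
#'
#' Draws `depth` reads per sample without replacement from the
#' gene-labelled read pool (multivariate hypergeometric), so column sums
#' equal `depth` exactly. A with-replacement multinomial option is
#' provided; at high depths the two are indistinguishable.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param depth Target depth (one integer, applied to every sample).
#' @param method `"hypergeometric"` (without replacement, default) or
#'   `"multinomial"`.
#' @return Integer matrix of the same shape with `colSums == depth`.
#'   Uses the current RNG state; seed with [set.seed()].
#' @export
subsample_counts <- function(counts, depth,
                             method = c("hypergeometric", "multinomial")) {
  method <- match.arg(method)
  stopifnot(is.matrix(counts), all(counts >= 0))
  depth <- as.integer(depth)
  totals <- colSums(counts)
  low <- which(totals < depth)
  if (length(low))
    stop("depth ", depth, " exceeds the total of sample(s): ",
         paste(colnames(counts)[low], collapse = ", "))
  out <- counts
  for (i in seq_len(ncol(counts))) {
    out[, i] <- if (method == "hypergeometric")
      rmvhyper_one(counts[, i], depth)
    else
      stats::rmultinom(1, depth, counts[, i] / totals[i])[, 1]
  }
  out
}

## sequential marginal draws: X_j | previous ~ Hypergeometric
rmvhyper_one <- function(x, k) {
  n <- length(x)
  out <- integer(n)
  rem_total <- sum(x)
  rem_k <- k
  for (j in seq_len(n)) {
    if (rem_k == 0L) break
    out[j] <- stats::rhyper(1, x[j], rem_total - x[j], rem_k)
    rem_k <- rem_k - out[j]
    rem_total <- rem_total - x[j]
  }
  out
}

#' Convert counts to a TPM-like scale
#'
#' Per-sample proportions times 1e6. Synthetic genes carry no lengths,
#' so no length correction is applied; all downstream statistics are
#' scale-consistent with this surrogate.
#'
#' @param counts Genes x samples count matrix.
#' @return Numeric matrix on a TPM-like scale.
#' @export
counts_to_tpm <- function(counts) {
  sweep(counts, 2, colSums(counts), "/") * 1e6
}

#' Whole-embryo variation as a function of read depth
#'
#' Subsamples every sample of a count matrix to each target depth,
#' converts to TPM-like proportions, log-transforms, and computes the
#' mean twin-pair variance V over the given pair design. Used to check
#' that the distance index is not driven by depth differences: the
#' resulting curve decreases (in expectation) with depth.
#'
#' @param counts Genes x samples count matrix; column names are sample
#'   ids referenced by `pairs`.
#' @param depths Increasing vector of target depths, all feasible.
#' @param pairs Pair design data frame (`sample_i`, `sample_k`), e.g.
#'   from [twin_pair_design()].
#' @param samples Optional metadata data frame passed to the
#'   intermediate `expr_matrix`.
#' @return Data frame with columns `depth` and `mean_V`.
#'   Uses the current RNG state; seed with [set.seed()].
#' @export
depth_bias_curve <- function(counts, depths, pairs, samples = NULL) {
  if (is.unsorted(depths))
    stop("`depths` must be sorted ascending")
  if (is.null(samples))
    samples <- data.frame(sample = colnames(counts))
  mean_v <- vapply(depths, function(d) {
    sub <- subsample_counts(counts, d)
    em <- expr_matrix(counts_to_tpm(sub), samples, scale = "tpm")
    em <- log_transform(em)
    mean(vapply(seq_len(nrow(pairs)), function(r) {
      pair_variance(em$values[, pairs$sample_i[r]],
                    em$values[, pairs$sample_k[r]])
    }, numeric(1)))
  }, numeric(1))
  data.frame(depth = depths, mean_V = mean_v)
}

## -- pair designs --------------------------------------------------------

#' Twin pair design from sample metadata
#'
#' Builds the list of within-pair comparisons from the `pair` metadata
#' column: each pair id with exactly two embryo samples contributes one
#' (sample_i, sample_k) row. Twins are sex-matched by construction of
#' the study design; a mismatch raises an error.
#'
#' @param m An `expr_matrix` whose metadata carries `pair` (and
#'   optionally `sex`, `role`).
#' @return Data frame with columns `sample_i`, `sample_k`, `kind`
#'   (`"twin"`).
#' @export
twin_pair_design <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  meta <- m$samples
  meta <- meta[is.na(meta$role) | meta$role == "embryo", , drop = FALSE]
  meta <- meta[!is.na(meta$pair), , drop = FALSE]
  sp <- split(meta, meta$pair)
  rows <- lapply(sp, function(d) {
    if (nrow(d) != 2) return(NULL)
    if (!any(is.na(d$sex)) && d$sex[1] != d$sex[2])
      stop("pair ", d$pair[1], " is not sex-matched")
    data.frame(sample_i = d$sample[1], sample_k = d$sample[2],
               kind = "twin", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(sample_i = character(),
                                      sample_k = character(),
                                      kind = character())
  rownames(out) <- NULL
  out
}

#' All sex-matched cross-population pairs
#'
#' Enumerates every (population A, population B) sample pair with equal
#' sex labels; used for intraspecies diversity and intraspecies gene
#' variation.
#'
#' @param m_a,m_b `expr_matrix` objects for the two populations.
#' @return Data frame with columns `sample_i` (from `m_a`), `sample_k`
#'   (from `m_b`), `kind` (`"cross_population"`).
#' @export
cross_pair_design <- function(m_a, m_b) {
  stopifnot(inherits(m_a, "expr_matrix"), inherits(m_b, "expr_matrix"))
  a <- m_a$samples; b <- m_b$samples
  grid <- expand.grid(i = seq_len(nrow(a)), k = seq_len(nrow(b)))
  keep <- is.na(a$sex[grid$i]) | is.na(b$sex[grid$k]) |
    a$sex[grid$i] == b$sex[grid$k]
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) stop("no sex-matched cross-population pairs")
  data.frame(sample_i = a$sample[grid$i], sample_k = b$sample[grid$k],
             kind = "cross_population", stringsAsFactors = FALSE,
             row.names = NULL)
}

#' All unordered pairs among technical replicates
#'
#' Four technical replicates yield the six unordered combinations whose
#' absolute expression differences estimate the technical error.
#'
#' @param m An `expr_matrix` of technical replicates (or any matrix
#'   whose every sample belongs to one replicate set).
#' @return Data frame with columns `sample_i`, `sample_k`, `kind`
#'   (`"technical"`).
#' @export
technical_pair_design <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  ids <- sample_ids(m)
  cmb <- utils::combn(ids, 2)
  data.frame(sample_i = cmb[1, ], sample_k = cmb[2, ],
             kind = "technical", stringsAsFactors = FALSE)
}
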