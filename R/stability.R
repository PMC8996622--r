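#' Whole-embryo distance between two expression profiles
#'
#' The variance of the distribution of per-gene log-expression
#' differences: with `y_j = x_j^i - x_j^k`,
#' `V = (1/N) * sum_j (y_j - mean(y))^2` (population variance, dividing
#' by N). Mean-centering makes V invariant to constant shifts between
#' the profiles; scaling both profiles by c scales V by c^2.
#'
#' @param x_i,x_k Numeric log-expression profiles over the same genes
#'   (equal length >= 2; if named, names must match).
#' @return The variance V (non-negative scalar).
#' @export
#' @examples
#' pair_variance(c(1, 2, 3), c(1, 1, 1))  # y = (0,1,2), V = 2/3
pair_variance <- function(x_i, x_k) {
  if (length(x_i) != length(x_k))
    stop("profiles have different lengths")
  if (!is.null(names(x_i)) && !is.null(names(x_k)) &&
      !identical(names(x_i), names(x_k)))
    stop("profiles are over different gene sets")
  n <- length(x_i)
  if (n < 2) stop("need at least 2 genes")
  y <- x_i - x_k
  mean((y - mean(y))^2)
}

#' Stage-wise developmental stability from twin pairs
#'
#' Computes the whole-embryo distance V for every twin pair of a stage;
#' the stage's developmental stability is summarized as the mean V
#' (smaller = more stable).
#'
#' @param m An `expr_matrix` (`log10p1`), genes restricted to the
#'   analysis universe (low-expression and technical-filter survivors).
#' @param pairs Twin pair design (>= 1 pair).
#' @return List with `V` (named per-pair variances) and `mean_V`.
#' @export
stage_stability <- function(m, pairs) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!nrow(pairs)) stop("need at least 1 pair")
  v <- vapply(seq_len(nrow(pairs)), function(r)
    pair_variance(m$values[, pairs$sample_i[r]],
                  m$values[, pairs$sample_k[r]]), numeric(1))
  names(v) <- paste(pairs$sample_i, pairs$sample_k, sep = "|")
  list(V = v, mean_V = mean(v))
}

#' Intraspecies diversity between two populations
#'
#' The whole-embryo distance V over all sex-matched cross-population
#' pairs; symmetric in the population order.
#'
#' @param m_a,m_b `expr_matrix` objects of the two populations over the
#'   same genes.
#' @param pairs Optional cross-pair design; defaults to
#'   [cross_pair_design()] on the two cohorts.
#' @return List with `V` (per cross pair) and `mean_V`.
#' @export
intraspecies_diversity <- function(m_a, m_b, pairs = NULL) {
  stopifnot(inherits(m_a, "expr_matrix"), inherits(m_b, "expr_matrix"))
  if (!identical(gene_ids(m_a), gene_ids(m_b)))
    stop("populations must share the same gene set")
  if (is.null(pairs)) pairs <- cross_pair_design(m_a, m_b)
  joint <- bind_samples(m_a, m_b)
  stage_stability(joint, pairs)
}

#' Spearman distance between two profiles
#'
#' `1 - rho` with Spearman's rank correlation (mid-ranks for ties); 0
#' for identical profiles, 2 for exactly reversed ranks. Used as the
#' rank-based counterpart of the variance distance V.
#'
#' @param x_i,x_k Numeric profiles over the same genes (length >= 3).
#' @return `1 - rho`.
#' @export
spearman_distance <- function(x_i, x_k) {
  if (length(x_i) != length(x_k)) stop("profiles have different lengths")
  if (length(x_i) < 3) stop("need at least 3 genes")
  if (stats::sd(rank(x_i)) == 0 || stats::sd(rank(x_k)) == 0)
    stop("constant profile: Spearman distance undefined")
  1 - stats::cor(x_i, x_k, method = "spearman")
}

#' Kruskal-Wallis omnibus test over stage groups
#'
#' Tie-corrected H statistic referred to a chi-square with k - 1 df.
#' Fully degenerate input (every value identical) is reported as H = 0,
#' p = 1 with a warning.
#'
#' @param groups Non-empty list of non-empty numeric vectors (e.g. the
#'   per-pair V values of each stage).
#' @return List with `H`, `df` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(!lengths(groups))) stop("groups must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  if (max(x) == min(x)) {
    warning("all values identical; Kruskal-Wallis degenerate")
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

## pairwise standardized rank-sum statistic (tie-corrected mid-ranks);
## the continuity correction shrinks |W - E| by 1/2 since W is discrete
sd_pair_stat <- function(x, y, continuity = TRUE) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  e <- n1 * (n + 1) / 2
  v <- n1 * n2 / (n * (n - 1)) * (sum(r^2) - n * (n + 1)^2 / 4)
  if (v <= 0) return(NA_real_)
  d <- w - e
  if (continuity) d <- sign(d) * max(abs(d) - 0.5, 0)
  d / sqrt(v)
}

#' Steel-Dwass all-pairs multiple comparisons
#'
#' Nonparametric all-pairs comparison following a Kruskal-Wallis test.
#' For each pair of groups the Wilcoxon rank-sum statistic on that pair
#' alone is standardized with tie correction; the family-wise p-value
#' refers `sqrt(2) * |t|` to the studentized-range distribution with k
#' groups and infinite df (the asymptotic form used for moderate sample
#' sizes). A permutation alternative computes, under global reshuffling
#' of all observations, the distribution of the maximum standardized
#' pairwise statistic and reports `P(max >= |t_obs|)`.
#'
#' Degenerate pairs (zero rank variance) are reported as p = 1 with a
#' warning.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param nperm Permutations for `method = "permutation"`.
#' @param continuity Apply a continuity correction of 1/2 to the
#'   discrete rank-sum statistic (default `TRUE`; markedly improves
#'   small-sample agreement with the permutation reference).
#' @return List with `p` (symmetric k x k matrix of family-wise
#'   p-values, `NA` diagonal), `statistic` (standardized pairwise
#'   statistics) and `method`. Group names are taken from `names(groups)`.
#' @export
steel_dwass <- function(groups, method = c("asymptotic", "permutation"),
                        nperm = 10000, continuity = TRUE) {
  method <- match.arg(method)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  pr <- utils::combn(k, 2)
  tstat <- apply(pr, 2, function(ix)
    sd_pair_stat(groups[[ix[1]]], groups[[ix[2]]], continuity))
  degenerate <- is.na(tstat)
  if (any(degenerate))
    warning("degenerate (constant) group pair; p set to 1")

  if (method == "asymptotic") {
    pval <- ifelse(degenerate, 1,
                   stats::ptukey(sqrt(2) * abs(tstat), nmeans = k,
                                 df = Inf, lower.tail = FALSE))
  } else {
    x <- unlist(groups, use.names = FALSE)
    sizes <- lengths(groups)
    idx <- rep(seq_len(k), sizes)
    obs <- abs(tstat)
    maxstat <- numeric(nperm)
    for (b in seq_len(nperm)) {
      xp <- x[sample.int(length(x))]
      sp <- split(xp, idx)
      maxstat[b] <- max(abs(apply(pr, 2, function(ix)
        sd_pair_stat(sp[[ix[1]]], sp[[ix[2]]], continuity))), na.rm = TRUE)
    }
    pval <- vapply(obs, function(t0) {
      if (is.na(t0)) return(1)
      (1 + sum(maxstat >= t0)) / (nperm + 1)
    }, numeric(1))
  }

  pm <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  sm <- pm
  for (c0 in seq_len(ncol(pr))) {
    i <- pr[1, c0]; j <- pr[2, c0]
    pm[i, j] <- pm[j, i] <- pval[c0]
    sm[i, j] <- sm[j, i] <- tstat[c0]
  }
  list(p = pm, statistic = sm, method = method)
}

#' Stage comparison: omnibus test plus all-pairs comparisons
#'
#' Convenience wrapper running [kruskal_wallis()] and [steel_dwass()]
#' on per-stage collections of whole-embryo distances.
#'
#' @param v_by_stage Named list of per-pair V values (or 1 - rho
#'   distances), one element per stage.
#' @param ... Passed to [steel_dwass()].
#' @return List with `mean_V` (per stage), `kruskal` and `steel_dwass`.
#' @export
stage_comparison <- function(v_by_stage, ...) {
  list(mean_V = vapply(v_by_stage, mean, numeric(1)),
       kruskal = kruskal_wallis(v_by_stage),
       steel_dwass = steel_dwass(v_by_stage, ...))
}
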