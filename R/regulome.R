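## Coordinate conventions: all positions in this module are 0-based;
## intervals are half-open [start, end). TSS `pos` is the 0-based
## coordinate of the transcription start site. Files use BED (0-based
## half-open) and VCF (1-based) conventions at the boundary.

## strand-aware promoter/proximal window, half-open, mirrored about the
## TSS on the minus strand
proximal_window <- function(pos, strand, proximal = c(-100, 50)) {
  lo <- proximal[1]; hi <- proximal[2]
  s <- ifelse(strand == "-", pos - hi + 1, pos + lo)
  e <- ifelse(strand == "-", pos - lo + 1, pos + hi)
  cbind(start = s, end = e)
}

overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Assign ATAC peaks to genes and apply the regulatory-window rule
#'
#' Each peak is linked to the gene with the closest TSS on its
#' chromosome (distance from the TSS point to the peak interval; exact
#' ties are broken toward the lexicographically smallest gene id). The
#' peak is then retained as a potential regulatory region of that gene
#' iff more than half of its length lies inside the union of the gene's
#' distal window (+/- `distal_flank` bp around the TSS) and its
#' strand-aware proximal window (`proximal` offsets along the gene
#' strand, -100..+50 by default); a peak overlapping exactly half its
#' length is excluded.
#'
#' @param tss Data frame `gene`, `chrom`, `pos` (0-based), `strand`
#'   (one TSS per gene).
#' @param peaks Data frame `chrom`, `start`, `end` (0-based half-open),
#'   optional `name`.
#' @param distal_flank Distal half-width in bp, default 5000.
#' @param proximal Proximal window offsets relative to the TSS,
#'   default `c(-100, 50)` (half-open, so 150 bp).
#' @return Data frame, one row per peak: `name`, `chrom`, `start`,
#'   `end`, `gene`, `distance`, `overlap`, `retained`. Peaks on
#'   chromosomes without any TSS get `gene = NA` and are not retained.
#' @export
assign_peaks <- function(tss, peaks, distal_flank = 5000,
                         proximal = c(-100, 50)) {
  stopifnot(all(c("gene", "chrom", "pos", "strand") %in% names(tss)),
            all(c("chrom", "start", "end") %in% names(peaks)))
  if (anyDuplicated(tss$gene)) stop("one TSS per gene required")
  bad <- which(!(peaks$start < peaks$end) | peaks$start < 0)
  if (length(bad))
    stop("malformed peak interval at record ", bad[1])
  if (any(tss$pos < 0)) stop("negative TSS position")
  if (is.null(peaks$name))
    peaks$name <- sprintf("peak_%05d", seq_len(nrow(peaks)))

  np <- nrow(peaks)
  gene <- rep(NA_character_, np)
  distance <- rep(NA_real_, np)

  for (ch in unique(peaks$chrom)) {
    t0 <- tss[tss$chrom == ch, , drop = FALSE]
    pidx <- which(peaks$chrom == ch)
    if (!nrow(t0)) next
    o <- order(t0$pos, t0$gene)
    ps <- t0$pos[o]; gs <- t0$gene[o]
    for (i in pidx) {
      s <- peaks$start[i]; e <- peaks$end[i]
      n_lo <- findInterval(s - 1, ps)       # TSS strictly left of peak
      n_hi <- findInterval(e - 1, ps)       # TSS at positions < end
      if (n_hi > n_lo) {                    # >= 1 TSS inside the peak
        cand <- (n_lo + 1):n_hi
        d <- 0
      } else {
        cand <- integer(0); dl <- Inf; dr <- Inf
        if (n_lo >= 1) dl <- s - ps[n_lo]
        if (n_lo < length(ps)) dr <- ps[n_lo + 1] - (e - 1)
        d <- min(dl, dr)
        if (dl == d) cand <- c(cand, which(ps == ps[n_lo]))
        if (dr == d) cand <- c(cand, which(ps == ps[n_lo + 1]))
      }
      gene[i] <- min(gs[cand])
      distance[i] <- d
    }
  }

  gi <- match(gene, tss$gene)
  pos <- tss$pos[gi]
  ds <- pos - distal_flank; de <- pos + distal_flank
  pw <- proximal_window(pos, tss$strand[gi], proximal)
  ov <- overlap_len(peaks$start, peaks$end, ds, de) +
    overlap_len(peaks$start, peaks$end, pw[, 1], pw[, 2]) -
    overlap_len(peaks$start, peaks$end,
                pmax(ds, pw[, 1]), pmin(de, pw[, 2]))
  ov[is.na(gene)] <- 0
  len <- peaks$end - peaks$start
  data.frame(name = peaks$name, chrom = peaks$chrom,
             start = peaks$start, end = peaks$end,
             gene = gene, distance = distance, overlap = ov,
             retained = !is.na(gene) & ov > len / 2,
             stringsAsFactors = FALSE, row.names = NULL)
}

## merge half-open intervals (matrix with start/end), assumes same gene
merge_intervals <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]; out_s <- c(); out_e <- c()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Count substitution events in each gene's open-chromatin regions
#'
#' For every gene, the retained peaks are clipped to the distal window
#' (+/- `distal_flank` around the TSS) and merged; each substitution
#' site falling inside (half-open, so a SNP at the end coordinate is
#' outside) contributes one event per carrier sample, summed across all
#' samples.
#'
#' @param assignment Output of [assign_peaks()].
#' @param snps Data frame `chrom`, `pos` (0-based) plus logical
#'   per-sample carrier columns (or an integer `n_carriers` column).
#' @param tss TSS table as in [assign_peaks()].
#' @param distal_flank Distal half-width, default 5000.
#' @return Named integer vector of per-gene (SNP, sample) event counts,
#'   0 for genes without assigned regions. SNPs on chromosomes absent
#'   from the TSS table are skipped with a warning.
#' @export
count_snps <- function(assignment, snps, tss, distal_flank = 5000) {
  counts <- stats::setNames(integer(nrow(tss)), tss$gene)
  if (!nrow(snps)) return(counts)
  unknown <- setdiff(unique(snps$chrom), unique(tss$chrom))
  if (length(unknown)) {
    warning("skipping SNPs on unknown chromosome(s): ",
            paste(unknown, collapse = ", "))
    snps <- snps[!snps$chrom %in% unknown, , drop = FALSE]
  }
  carriers <- if (!is.null(snps$n_carriers)) as.integer(snps$n_carriers)
  else {
    flag_cols <- vapply(snps, is.logical, logical(1))
    if (!any(flag_cols)) stop("no carrier flags or `n_carriers` column")
    as.integer(rowSums(snps[, flag_cols, drop = FALSE]))
  }
  kept <- assignment[assignment$retained, , drop = FALSE]
  if (!nrow(kept)) return(counts)
  for (g in unique(kept$gene)) {
    rows <- kept[kept$gene == g, , drop = FALSE]
    gi <- match(g, tss$gene)
    cs <- pmax(rows$start, tss$pos[gi] - distal_flank)
    ce <- pmin(rows$end, tss$pos[gi] + distal_flank)
    ok <- cs < ce
    if (!any(ok)) next
    mrg <- merge_intervals(cs[ok], ce[ok])
    on_chrom <- snps$chrom == tss$chrom[gi]
    for (r in seq_len(nrow(mrg))) {
      hit <- on_chrom & snps$pos >= mrg[r, 1] & snps$pos < mrg[r, 2]
      counts[g] <- counts[g] + sum(carriers[hit])
    }
  }
  counts
}

#' Count TATA-box motif matches in a promoter sequence
#'
#' Exact-string scan of the four TATA-box motifs (TATAAAAA, TATAAATA,
#' TATATAAA, TATATATA) at every offset; overlapping matches (two-base
#' shifts of TATA repeats) are all counted, and matches on the reverse
#' strand (equivalently, of the reverse-complement motifs) are counted
#' separately and added when `both_strands = TRUE`.
#'
#' @param promoter A promoter sequence: single character string or
#'   [Biostrings::DNAString] over A/C/G/T/N.
#' @param both_strands Scan both strands (default) or forward only.
#' @return Integer match count.
#' @export
#' @examples
#' scan_tata("TATATATATATA")                       # 3 + 3 = 6
#' scan_tata("TATATATATATA", both_strands = FALSE) # 3
scan_tata <- function(promoter, both_strands = TRUE) {
  if (is.character(promoter)) {
    if (grepl("[^ACGTN]", promoter))
      stop("promoter contains characters outside A/C/G/T/N")
    promoter <- Biostrings::DNAString(promoter)
  }
  n <- sum(vapply(.tata_motifs, function(m)
    Biostrings::countPattern(m, promoter), integer(1)))
  if (both_strands) {
    rc <- Biostrings::reverseComplement(promoter)
    n <- n + sum(vapply(.tata_motifs, function(m)
      Biostrings::countPattern(m, rc), integer(1)))
  }
  as.integer(n)
}

#' Vectorized TATA scan over a promoter set
#'
#' @param promoters Named character vector or
#'   [Biostrings::DNAStringSet].
#' @param both_strands As in [scan_tata()].
#' @return Named integer vector of match counts.
#' @export
scan_tata_set <- function(promoters, both_strands = TRUE) {
  if (is.character(promoters)) {
    if (any(grepl("[^ACGTN]", promoters)))
      stop("promoter contains characters outside A/C/G/T/N")
    promoters <- Biostrings::DNAStringSet(promoters)
  }
  counts <- Reduce(`+`, lapply(.tata_motifs, function(m)
    Biostrings::vcountPattern(m, promoters)))
  if (both_strands) {
    rc <- Biostrings::reverseComplement(promoters)
    counts <- counts + Reduce(`+`, lapply(.tata_motifs, function(m)
      Biostrings::vcountPattern(m, rc)))
  }
  stats::setNames(as.integer(counts), names(promoters))
}

#' Per-gene regulatory feature table
#'
#' Summarizes the regulome of each gene: number and total length of
#' retained regulatory peaks, substitution events in open chromatin,
#' and TATA-box matches in the proximal promoter.
#'
#' @param assignment Output of [assign_peaks()].
#' @param snp_counts Named vector from [count_snps()] (optional).
#' @param tata_counts Named vector from [scan_tata_set()] (optional).
#' @param tss TSS table (defines the gene universe).
#' @return Data frame `gene`, `n_peaks`, `total_peak_length`,
#'   `n_snps`, `n_tata`.
#' @export
regulatory_features <- function(assignment, snp_counts = NULL,
                                tata_counts = NULL, tss) {
  kept <- assignment[assignment$retained, , drop = FALSE]
  n_peaks <- table(factor(kept$gene, levels = tss$gene))
  lens <- tapply(kept$end - kept$start,
                 factor(kept$gene, levels = tss$gene), sum)
  out <- data.frame(gene = tss$gene,
                    n_peaks = as.integer(n_peaks),
                    total_peak_length =
                      as.integer(ifelse(is.na(lens), 0, lens)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$n_snps <- if (is.null(snp_counts)) 0L else
    as.integer(ifelse(is.na(snp_counts[out$gene]), 0,
                      snp_counts[out$gene]))
  out$n_tata <- if (is.null(tata_counts)) 0L else
    as.integer(ifelse(is.na(tata_counts[out$gene]), 0,
                      tata_counts[out$gene]))
  out
}

#' Correlate regulatory features with gene expression stability
#'
#' Spearman correlation (and p of the no-correlation test) of each
#' feature column against the corrected expression variation of the
#' shared genes. Constant feature columns are reported with `NA` rho
#' and flagged undefined.
#'
#' @param features Data frame with a `gene` column plus numeric feature
#'   columns.
#' @param table Gene variation table (needs `gene`, `corrected`).
#' @return Data frame `feature`, `rho`, `p`, `n`, `defined`.
#' @export
feature_stability_correlation <- function(features, table) {
  shared <- intersect(features$gene, table$gene)
  if (length(shared) < 10)
    stop("need >= 10 shared genes, got ", length(shared))
  y <- table$corrected[match(shared, table$gene)]
  cols <- setdiff(names(features), "gene")
  rows <- lapply(cols, function(cn) {
    x <- features[[cn]][match(shared, features$gene)]
    if (!is.numeric(x)) return(NULL)
    if (length(unique(x)) == 1)
      return(data.frame(feature = cn, rho = NA_real_, p = NA_real_,
                        n = length(shared), defined = FALSE))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    data.frame(feature = cn, rho = unname(ct$estimate), p = ct$p.value,
               n = length(shared), defined = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
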