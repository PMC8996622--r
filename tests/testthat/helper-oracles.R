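## Independent brute-force oracles used to check the package
## implementations. Deliberately naive: quadratic loops, explicit
## windows, no shared code with R/.

## running-median correction: explicit window per gene after sorting by
## mean expression (ties by gene id), symmetric shrink at the edges
oracle_running_median <- function(gene, mean_expr, raw, window) {
  n <- length(raw)
  ord <- order(mean_expr, gene)
  rs <- raw[ord]
  half <- (window - 1) / 2
  corrected_sorted <- numeric(n)
  for (i in seq_len(n)) {
    h <- half
    if (i - h < 1) h <- i - 1
    if (i + h > n) h <- n - i
    corrected_sorted[i] <- rs[i] - median(rs[(i - h):(i + h)])
  }
  out <- numeric(n)
  out[ord] <- corrected_sorted
  out
}

## sliding-window exact-string TATA scan without Biostrings
oracle_scan_tata <- function(seq, both_strands = TRUE) {
  motifs <- c("TATAAAAA", "TATAAATA", "TATATAAA", "TATATATA")
  count_fwd <- function(s) {
    n <- nchar(s)
    if (n < 8) return(0L)
    win <- substring(s, 1:(n - 7), 8:n)
    sum(win %in% motifs)
  }
  revcomp <- function(s) {
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }
  n <- count_fwd(seq)
  if (both_strands) n <- n + count_fwd(revcomp(seq))
  n
}

## reciprocal best hits by double loop
oracle_rbh <- function(hits_ab, hits_ba, cutoff = 1e-5) {
  best <- function(h, q) {
    rows <- h[h$qseqid == q & h$evalue < cutoff, , drop = FALSE]
    if (!nrow(rows)) return(NA_character_)
    rows <- rows[order(rows$evalue, -rows$bitscore, rows$sseqid), ,
                 drop = FALSE]
    rows$sseqid[1]
  }
  out <- NULL
  for (q in sort(unique(hits_ab$qseqid))) {
    b <- best(hits_ab, q)
    if (is.na(b)) next
    if (identical(best(hits_ba, b), q))
      out <- rbind(out, data.frame(gene_a = q, gene_b = b,
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out)) data.frame(gene_a = character(), gene_b = character())
  else out
}

## peak -> gene assignment with all-pairs distances and explicit
## base-by-base window overlap
oracle_assign_peaks <- function(tss, peaks, distal_flank = 5000,
                                proximal = c(-100, 50)) {
  n <- nrow(peaks)
  gene <- character(n); retained <- logical(n)
  for (i in seq_len(n)) {
    cand <- tss[tss$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(cand)) { gene[i] <- NA; next }
    span <- peaks$start[i]:(peaks$end[i] - 1)
    d <- vapply(cand$pos, function(p)
      if (p %in% span) 0 else min(abs(p - span)), numeric(1))
    hit <- cand[d == min(d), , drop = FALSE]
    g <- sort(hit$gene)[1]
    gene[i] <- g
    row <- tss[tss$gene == g, ]
    dist_win <- (row$pos - distal_flank):(row$pos + distal_flank - 1)
    prox_win <- if (row$strand == "-")
      (row$pos - proximal[2] + 1):(row$pos - proximal[1])
    else
      (row$pos + proximal[1]):(row$pos + proximal[2] - 1)
    ov <- length(intersect(span, union(dist_win, prox_win)))
    retained[i] <- ov > length(span) / 2
  }
  data.frame(name = peaks$name, gene = gene, retained = retained,
             stringsAsFactors = FALSE)
}

## max-statistic permutation reference for Steel-Dwass family-wise p
oracle_steel_dwass_perm <- function(groups, nperm = 10000) {
  k <- length(groups)
  sizes <- lengths(groups)
  idx <- rep(seq_len(k), sizes)
  x <- unlist(groups, use.names = FALSE)
  stat <- function(a, b) {
    n1 <- length(a); n2 <- length(b); n <- n1 + n2
    r <- rank(c(a, b))
    w <- sum(r[1:n1])
    v <- n1 * n2 / (n * (n - 1)) * (sum(r^2) - n * (n + 1)^2 / 4)
    (w - n1 * (n + 1) / 2) / sqrt(v)
  }
  pr <- combn(k, 2)
  obs <- abs(apply(pr, 2, function(ix) stat(groups[[ix[1]]],
                                            groups[[ix[2]]])))
  mx <- numeric(nperm)
  for (b in seq_len(nperm)) {
    sp <- split(x[sample.int(length(x))], idx)
    mx[b] <- max(abs(apply(pr, 2, function(ix) stat(sp[[ix[1]]],
                                                    sp[[ix[2]]]))))
  }
  vapply(obs, function(t0) (1 + sum(mx >= t0)) / (nperm + 1), numeric(1))
}

## random BLAST-style hit tables over two small gene universes
random_hit_tables <- function(n_a = 8, n_b = 8, n_hits = 40) {
  ga <- sprintf("a%02d", 1:n_a)
  gb <- sprintf("b%02d", 1:n_b)
  mk <- function(qs, ss) data.frame(
    qseqid = sample(qs, n_hits, TRUE),
    sseqid = sample(ss, n_hits, TRUE),
    evalue = 10^runif(n_hits, -30, -2),
    bitscore = round(runif(n_hits, 50, 500), 1),
    stringsAsFactors = FALSE)
  list(ab = mk(ga, gb), ba = mk(gb, ga))
}

## small expression matrix built directly from values
make_em <- function(values, scale = "log10p1", stage = NA, pair = NULL,
                    sex = NULL, role = "embryo") {
  meta <- data.frame(sample = colnames(values), stage = stage,
                     role = role, stringsAsFactors = FALSE)
  if (!is.null(pair)) meta$pair <- pair
  if (!is.null(sex)) meta$sex <- sex
  expr_matrix(values, meta, scale = scale)
}
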